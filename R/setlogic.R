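## Dual-evidence classification of hypoxia-responsive transcripts by factor
## dependency. For a factor F with mutant M, three differential comparisons
## feed the scheme: Total (control N vs H), F-independent (mutant N vs H)
## and the cross comparison (control-H vs mutant-H). Then
##   independent_H = Total  intersect  F-independent
##   set2          = Total  minus      independent_H
##   dependent_H   = cross  intersect  set2
## so a transcript is called F-dependent only on two lines of evidence: it
## stops responding in the mutant AND its hypoxic level differs between
## control and mutant. Independent and dependent calls are mutually
## exclusive by construction.

#' Per-comparison gating defaults
#'
#' The seven comparisons of the reference factorial design with their
#' published FDR gates (percent converted to fractions) and the common
#' 1.5-fold gate. The mutant N-vs-H gate for the ERR scheme is deliberately
#' looser (7.84%) than the others (<1%): relaxing the factor-independent
#' evidence makes the *dependent* call more conservative.
#'
#' @return Tibble: `comparison`, `a`, `b`, `max_q`, `min_abs_fold`.
#' @export
default_gates <- function() {
  tibble::tribble(
    ~comparison,          ~a,                    ~b,                      ~max_q,
    "control_N_vs_H",     "control_normoxia",    "control_hypoxia",       0.00733,
    "hif_N_vs_H",         "hif_mutant_normoxia", "hif_mutant_hypoxia",    0.00414,
    "control_H_vs_hif_H", "control_hypoxia",     "hif_mutant_hypoxia",    0.00721,
    "err_N_vs_H",         "err_mutant_normoxia", "err_mutant_hypoxia",    0.0784,
    "control_H_vs_err_H", "control_hypoxia",     "err_mutant_hypoxia",    0.00619,
    "dm_N_vs_H",          "double_mutant_normoxia", "double_mutant_hypoxia", 0.00662,
    "control_H_vs_dm_H",  "control_hypoxia",     "double_mutant_hypoxia", 0.00703
  ) |>
    dplyr::mutate(min_abs_fold = 1.5)
}

as_set_tbl <- function(x, name = "set") {
  if (is.character(x)) {
    return(tibble::tibble(set = name, probe_id = x,
                          direction = NA_character_))
  }
  if (!all(c("probe_id") %in% names(x))) {
    abort("A gene set needs a probe_id column (or a character vector).")
  }
  x <- tibble::as_tibble(x)
  if (!"direction" %in% names(x)) x$direction <- NA_character_
  if (!"set" %in% names(x)) x$set <- name
  if (anyDuplicated(x$probe_id)) abort("Gene-set members must be unique.")
  x[, c("set", "probe_id", "direction")]
}

#' Classify transcripts as factor-independent or factor-dependent
#'
#' Applies the dual-evidence scheme to three directed gene sets: the hypoxia
#' response in the control background (`total_h`), the hypoxia response in
#' the factor mutant (`factor_independent`), and the direct comparison of
#' hypoxia-treated control vs. mutant samples (`cross_h`, oriented "control-H
#' vs mutant-H" so a transcript lower in the mutant has direction `down`).
#'
#' With `direction_mode = "concordant"`, intersections also require
#' compatible directions: an independent call needs the same direction in
#' control and mutant, and a dependent call needs the cross direction
#' *opposite* to the hypoxic direction (a hypoxia-induced transcript that
#' depends on the factor must sit lower in the mutant's hypoxic samples).
#'
#' @param total_h,factor_independent,cross_h Gene-set tibbles
#'   (`probe_id`, `direction`) or character vectors.
#' @param direction_mode `"ignore"` (membership-only, default) or
#'   `"concordant"`.
#' @param universe Optional character vector of all probe ids; an input probe
#'   outside it is an error.
#' @param factor_name Label recorded on the result.
#' @return Tibble of per-probe flags over the union of the inputs:
#'   `probe_id`, `direction` (hypoxic direction from `total_h`), `in_total`,
#'   `independent_H`, `candidate_set2`, `dependent_H`.
#' @export
classify_factor <- function(total_h, factor_independent, cross_h,
                            direction_mode = c("ignore", "concordant"),
                            universe = NULL, factor_name = "factor") {
  direction_mode <- match.arg(direction_mode)
  tot <- as_set_tbl(total_h, "total")
  ind <- as_set_tbl(factor_independent, "independent")
  crs <- as_set_tbl(cross_h, "cross")
  if (!is.null(universe)) {
    stray <- setdiff(c(tot$probe_id, ind$probe_id, crs$probe_id), universe)
    if (length(stray)) {
      abort(paste0("Probe(s) outside the universe: ",
                   paste(utils::head(stray, 5), collapse = ", ")))
    }
  }
  probes <- sort(unique(c(tot$probe_id, ind$probe_id, crs$probe_id)))
  dir_tot <- tot$direction[match(probes, tot$probe_id)]
  dir_ind <- ind$direction[match(probes, ind$probe_id)]
  dir_crs <- crs$direction[match(probes, crs$probe_id)]

  in_total <- probes %in% tot$probe_id
  in_ind <- probes %in% ind$probe_id
  in_crs <- probes %in% crs$probe_id

  if (direction_mode == "concordant") {
    same_dir <- !is.na(dir_tot) & !is.na(dir_ind) & dir_tot == dir_ind
    opp_dir <- !is.na(dir_tot) & !is.na(dir_crs) & dir_tot != dir_crs
    independent_H <- in_total & in_ind & same_dir
    candidate_set2 <- in_total & !independent_H
    dependent_H <- candidate_set2 & in_crs & opp_dir
  } else {
    independent_H <- in_total & in_ind
    candidate_set2 <- in_total & !independent_H
    dependent_H <- candidate_set2 & in_crs
  }

  out <- tibble::tibble(probe_id = probes, direction = dir_tot,
                        in_total = in_total, independent_H = independent_H,
                        candidate_set2 = candidate_set2,
                        dependent_H = dependent_H)
  attr(out, "factor_name") <- factor_name
  attr(out, "direction_mode") <- direction_mode
  out
}

calls_to_set <- function(calls, flag, name) {
  keep <- calls[[flag]]
  tibble::tibble(set = name, probe_id = calls$probe_id[keep],
                 direction = calls$direction[keep])
}

#' Run the full dependency-classification pipeline on a factorial matrix
#'
#' Performs every differential comparison required by the requested schemes
#' (control N vs H; each mutant N vs H; control-H vs each mutant-H), gates
#' each with its own fold/FDR thresholds, and applies the dual-evidence
#' scheme per factor. The HIF scheme yields the mutually exclusive
#' HIF-independent (HI) and HIF-dependent (HD) sets; the ERR and
#' double-mutant schemes yield ED and DM the same way. DM is constructed
#' independently from the double-mutant comparisons, not derived from
#' HD/ED.
#'
#' @param exprs Expression tibble (`probe_id` + sample columns).
#' @param samples Sample sheet (`sample_id`, `genotype`, `oxygen`,
#'   `replicate`).
#' @param config A [de_config()]; per-comparison sub-seeds are derived from
#'   its seed.
#' @param gates Per-comparison thresholds, as [default_gates()].
#' @param schemes Which factors to classify: any of `"hif"`, `"err"`, `"dm"`.
#' @param direction_mode Passed to [classify_factor()].
#' @return An object of class `dependency_scheme`: a list with `sets` (named
#'   list of gene-set tibbles: `Total`, per-factor `*_independent`, `*_set1`,
#'   `*_set2`, and the final `HI`, `HD`, `ED`, `DM`), `de` (named list of
#'   `sam_de` results per comparison), `calls` (per-factor flag tibbles),
#'   `gates`, `universe`, and `config`.
#' @export
run_full_scheme <- function(exprs, samples, config = de_config(),
                            gates = default_gates(),
                            schemes = c("hif", "err", "dm"),
                            direction_mode = c("ignore", "concordant")) {
  direction_mode <- match.arg(direction_mode)
  schemes <- match.arg(schemes, several.ok = TRUE)
  scheme_info <- list(
    hif = list(genotype = "hif_mutant", independent = "hif_N_vs_H",
               cross = "control_H_vs_hif_H", dep = "HD", ind = "HI"),
    err = list(genotype = "err_mutant", independent = "err_N_vs_H",
               cross = "control_H_vs_err_H", dep = "ED", ind = "ERR_independent_H"),
    dm = list(genotype = "double_mutant", independent = "dm_N_vs_H",
              cross = "control_H_vs_dm_H", dep = "DM", ind = "DM_independent_H"))

  needed <- unique(c("control_N_vs_H",
                     unlist(lapply(scheme_info[schemes],
                                   function(s) c(s$independent, s$cross)))))
  gates <- gates[match(needed, gates$comparison), ]
  if (anyNA(gates$comparison)) {
    abort("`gates` must contain a row for every required comparison.")
  }
  for (sc in schemes) {
    g <- scheme_info[[sc]]$genotype
    if (!g %in% samples$genotype) {
      abort(paste0("Scheme \"", sc, "\" needs genotype \"", g,
                   "\" in the sample sheet."))
    }
  }

  de <- list(); sets <- list()
  for (i in seq_len(nrow(gates))) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    res <- sam_compare(exprs, samples, gates$a[i], gates$b[i], cfg_i)
    de[[gates$comparison[i]]] <- res
    sets[[gates$comparison[i]]] <-
      call_differential(res, name = gates$comparison[i],
                        min_abs_fold = gates$min_abs_fold[i],
                        max_q = gates$max_q[i])
  }

  universe <- exprs$probe_id
  total <- sets[["control_N_vs_H"]]
  out_sets <- list(Total = dplyr::mutate(total, set = "Total"))
  calls <- list()
  for (sc in schemes) {
    info <- scheme_info[[sc]]
    ind_set <- sets[[info$independent]]
    crs_set <- sets[[info$cross]]
    cl <- classify_factor(total, ind_set, crs_set,
                          direction_mode = direction_mode,
                          universe = universe, factor_name = sc)
    calls[[sc]] <- cl
    pre <- toupper(sc)
    out_sets[[paste0(pre, "_independent")]] <-
      dplyr::mutate(ind_set, set = paste0(pre, "_independent"))
    out_sets[[paste0(pre, "_set1")]] <-
      dplyr::mutate(crs_set, set = paste0(pre, "_set1"))
    out_sets[[paste0(pre, "_set2")]] <-
      calls_to_set(cl, "candidate_set2", paste0(pre, "_set2"))
    out_sets[[info$ind]] <- calls_to_set(cl, "independent_H", info$ind)
    out_sets[[info$dep]] <- calls_to_set(cl, "dependent_H", info$dep)
  }

  structure(list(sets = out_sets, de = de, calls = calls, gates = gates,
                 universe = universe, config = config,
                 direction_mode = direction_mode),
            class = "dependency_scheme")
}

#' @export
print.dependency_scheme <- function(x, ...) {
  cat("Factor-dependency classification (", length(x$universe),
      " probes)\n", sep = "")
  sizes <- vapply(x$sets, nrow, integer(1))
  for (nm in names(sizes)) cat(sprintf("  %-20s %d\n", nm, sizes[[nm]]))
  invisible(x)
}

#' Tri-state concordance calls across genotypes
#'
#' For each probe and genotype, calls the hypoxic response `up`, `down` or
#' `none` from that genotype's N-vs-H differential result, using a strict
#' FDR gate by default and a per-genotype relaxed gate where configured (the
#' reference analysis relaxed some backgrounds from <1% to 1-5%).
#'
#' @param de_by_genotype Named list of `sam_de` results (one N-vs-H
#'   comparison per genotype), aligned on the same probes.
#' @param strict_q Default FDR gate (fraction).
#' @param relaxed_q Named numeric vector of per-genotype relaxed gates; every
#'   value must be >= `strict_q`.
#' @param min_abs_fold Fold gate.
#' @return Tibble: `probe_id`, `genotype`, `state`, `gate_used`,
#'   `fold_change`, `q_value`.
#' @export
concordance_calls <- function(de_by_genotype, strict_q = 0.01,
                              relaxed_q = NULL, min_abs_fold = 1.5) {
  if (!is.null(relaxed_q)) {
    if (is.null(names(relaxed_q)) || any(!nzchar(names(relaxed_q)))) {
      abort("`relaxed_q` must be named by genotype.")
    }
    if (any(relaxed_q < strict_q)) {
      abort("A relaxed gate cannot be stricter than `strict_q`.")
    }
  }
  probes <- de_by_genotype[[1]]$probe_id
  for (de in de_by_genotype) {
    if (!identical(de$probe_id, probes)) {
      abort("All differential results must be aligned on the same probes.")
    }
  }
  purrr::imap_dfr(de_by_genotype, function(de, genotype) {
    relaxed <- genotype %in% names(relaxed_q)
    gate <- if (relaxed) relaxed_q[[genotype]] else strict_q
    called <- abs(de$fold_change) >= min_abs_fold & de$q_value < gate
    tibble::tibble(
      probe_id = de$probe_id, genotype = genotype,
      state = ifelse(!called, "none",
                     ifelse(de$fold_change > 0, "up", "down")),
      gate_used = if (relaxed) "relaxed" else "strict",
      fold_change = de$fold_change, q_value = de$q_value)
  })
}
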