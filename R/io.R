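## Readers/writers for the pipeline's plain-text dialects (expression TSV +
## sample-sheet CSV, GMT gene sets, metabolite TSVs, long Ct TSV) and the
## end-to-end orchestration with a reproducibility manifest.

#' Read an expression matrix and its sample sheet
#'
#' The matrix is tab-delimited with probes as rows, first column `probe_id`,
#' one column per sample; the sheet is CSV with `sample_id`, `genotype`,
#' `oxygen`, `replicate`. Every matrix sample must be annotated.
#'
#' @param matrix_path,sheet_path File paths.
#' @return List with `exprs` and `samples` tibbles.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  exprs <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                           progress = FALSE)
  if (names(exprs)[1] != "probe_id") {
    abort("The first matrix column must be probe_id.")
  }
  if (anyDuplicated(exprs$probe_id)) {
    abort(paste0("Duplicated probe id(s): ",
                 paste(utils::head(unique(
                   exprs$probe_id[duplicated(exprs$probe_id)]), 5),
                   collapse = ", ")))
  }
  vals <- exprs[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))) || anyNA(vals)) {
    abort("Expression values must be numeric with no missing cells.")
  }
  samples <- readr::read_csv(sheet_path, show_col_types = FALSE,
                             progress = FALSE)
  metab_require_cols(samples, c("sample_id", "genotype", "oxygen",
                                "replicate"))
  missing <- setdiff(names(vals), samples$sample_id)
  if (length(missing)) {
    abort(paste0("Sample(s) in the matrix missing from the sheet: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- samples[samples$sample_id %in% names(vals), ]
  list(exprs = exprs, samples = samples)
}

#' Write an expression matrix and sample sheet
#'
#' @param exprs,samples Tibbles as returned by [simulate_expression()].
#' @param matrix_path,sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(exprs, samples, matrix_path, sheet_path) {
  readr::write_tsv(exprs, matrix_path, progress = FALSE)
  readr::write_csv(samples, sheet_path, progress = FALSE)
  invisible(c(matrix_path, sheet_path))
}

#' Write gene sets as GMT
#'
#' One line per set: name, description, then tab-separated members with an
#' `:up`/`:down` suffix where a direction is recorded. Members are written in
#' lexicographic order so output is byte-stable.
#'
#' @param sets Named list of gene-set tibbles (or one long tibble with a
#'   `set` column).
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.data.frame(sets)) sets <- split(sets, sets$set)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("Every set needs a nonempty name.")
  }
  if (any(grepl("\t", names(sets)))) {
    abort("Set names must not contain tab characters.")
  }
  lines <- vapply(names(sets), function(nm) {
    s <- as_set_tbl(sets[[nm]], nm)
    s <- s[order(s$probe_id), ]
    members <- ifelse(is.na(s$direction), s$probe_id,
                      paste0(s$probe_id, ":", s$direction))
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else ""
    paste(c(nm, desc, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path; `:up`/`:down` member suffixes become the
#'   `direction` column.
#' @return Long tibble: `set`, `description`, `probe_id`, `direction`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    members <- if (length(f) > 2) f[-(1:2)] else character(0)
    has_dir <- grepl(":(up|down)$", members)
    direction <- rep(NA_character_, length(members))
    direction[has_dir] <- sub("^.*:", "", members[has_dir])
    tibble::tibble(
      set = f[1], description = if (length(f) >= 2) f[2] else "",
      probe_id = sub(":(up|down)$", "", members),
      direction = direction)
  })
}

#' Write / read a metabolite table
#'
#' Three files mirror the platform layout: a compound-by-sample abundance
#' TSV, a parallel detection-flag TSV, and a sample CSV carrying genotype,
#' oxygen, replicate and protein mass.
#'
#' @param metabolites Long metabolite tibble (see [simulate_metabolites()]).
#' @param abundance_path,flags_path,samples_path File paths.
#' @return Invisibly, the paths.
#' @export
write_metabolites <- function(metabolites, abundance_path, flags_path,
                              samples_path) {
  wide <- function(col) {
    metabolites |>
      dplyr::select("compound", "sample_id", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "sample_id",
                         values_from = dplyr::all_of(col))
  }
  readr::write_tsv(wide("abundance"), abundance_path, progress = FALSE)
  readr::write_tsv(wide("detected"), flags_path, progress = FALSE)
  samples <- dplyr::distinct(metabolites, .data$sample_id, .data$genotype,
                             .data$oxygen, .data$replicate,
                             .data$protein_mass)
  readr::write_csv(samples, samples_path, progress = FALSE)
  invisible(c(abundance_path, flags_path, samples_path))
}

#' @rdname write_metabolites
#' @export
read_metabolites <- function(abundance_path, flags_path, samples_path) {
  longify <- function(path, col) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
      tidyr::pivot_longer(-"compound", names_to = "sample_id",
                          values_to = col)
  }
  ab <- longify(abundance_path, "abundance")
  fl <- longify(flags_path, "detected")
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  ab |>
    dplyr::left_join(fl, by = c("compound", "sample_id")) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::select("compound", "sample_id", "genotype", "oxygen",
                  "replicate", "abundance", "detected", "protein_mass")
}

#' Write a simulated dataset to a directory
#'
#' Emits the expression TSV + sample-sheet CSV, the truth TSV, the
#' metabolite TSV trio, and the long-form Ct TSV.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of output paths.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_expression(config)
  write_expression(sim$exprs, sim$samples, p("expression.tsv"),
                   p("samples.csv"))
  readr::write_tsv(sim$truth, p("truth.tsv"), progress = FALSE)
  met <- simulate_metabolites(config)
  write_metabolites(met$metabolites, p("metabolites.tsv"),
                    p("metabolite_flags.tsv"), p("metabolite_samples.csv"))
  ct <- simulate_ct(config)
  readr::write_tsv(ct, p("ct.tsv"), progress = FALSE)
  invisible(c(expression = p("expression.tsv"), samples = p("samples.csv"),
              truth = p("truth.tsv"), metabolites = p("metabolites.tsv"),
              ct = p("ct.tsv")))
}

#' Run the expression pipeline end to end
#'
#' Reads (or accepts) an expression matrix and sample sheet, runs every
#' differential comparison and dependency scheme, computes Venn partitions
#' and pairwise hypergeometric overlap tests of the final sets, optionally
#' runs term enrichment, and writes everything plus a JSON manifest that
#' fully determines the run (package version, seed, gates, universe size,
#' file list with MD5 checksums). Outputs are byte-identical across reruns
#' with the same inputs and config.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `expression` and `sample_sheet` paths (or `exprs`/`samples` tibbles
#'   supplied directly), `out_dir`, optional `seed`, `n_permutations`,
#'   `exhaustive_limit`, `s0_mode`, `schemes`, `direction_mode`, `gates`
#'   (data frame overriding [default_gates()] rows by comparison),
#'   `annotation` (two-column TSV path: term_id, probe_id), and `universe`
#'   (`"matrix"`, the default, or a count).
#' @return Invisibly, the `dependency_scheme` object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config$out_dir is required.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$exprs)) {
    exprs <- config$exprs; samples <- config$samples
  } else {
    dat <- read_expression(config$expression, config$sample_sheet)
    exprs <- dat$exprs; samples <- dat$samples
  }

  decfg <- de_config(
    s0_mode = config$s0_mode %||% "cv_minimization",
    n_permutations = config$n_permutations %||% 200L,
    exhaustive_limit = config$exhaustive_limit %||% 10000L,
    seed = config$seed %||% 1L)
  gates <- default_gates()
  if (!is.null(config$gates)) {
    ov <- tibble::as_tibble(config$gates)
    idx <- match(ov$comparison, gates$comparison)
    if (anyNA(idx)) abort("Unknown comparison in config$gates.")
    for (col in intersect(names(ov), c("max_q", "min_abs_fold"))) {
      gates[[col]][idx] <- ov[[col]]
    }
  }
  schemes <- config$schemes %||% c("hif", "err", "dm")
  res <- run_full_scheme(exprs, samples, decfg, gates, schemes = schemes,
                         direction_mode = config$direction_mode %||% "ignore")

  files <- character(0)
  for (nm in names(res$de)) {
    f <- p(paste0("de_", nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(res$de[[nm]]), f, progress = FALSE)
    files <- c(files, f)
  }
  f <- p("sets.gmt"); write_gene_sets(res$sets, f); files <- c(files, f)
  calls_wide <- tidy(res)
  f <- p("dependency_calls.tsv")
  readr::write_tsv(calls_wide, f, progress = FALSE); files <- c(files, f)

  universe_n <- if (is.null(config$universe) ||
                    identical(config$universe, "matrix")) {
    length(res$universe)
  } else as.integer(config$universe)
  final <- intersect(c("HI", "HD", "ED", "DM"), names(res$sets))
  final <- final[vapply(final, function(nm) nrow(res$sets[[nm]]) > 0,
                        logical(1))]
  if (length(final) >= 2) {
    f <- p("overlap_tests.tsv")
    readr::write_tsv(overlap_tests(res$sets[final], universe_n), f,
                     progress = FALSE)
    files <- c(files, f)
    venn_groups <- list(c("HI", "HD", "ED"), c("HD", "ED", "DM"))
    for (vg in venn_groups) {
      if (all(vg %in% final)) {
        f <- p(paste0("venn_", paste(tolower(vg), collapse = "_"), ".tsv"))
        readr::write_tsv(venn_partition(res$sets[vg]), f, progress = FALSE)
        files <- c(files, f)
      }
    }
  }
  if (!is.null(config$annotation)) {
    ann <- readr::read_tsv(config$annotation, show_col_types = FALSE,
                           progress = FALSE)
    for (nm in final) {
      f <- p(paste0("enrichment_", nm, ".tsv"))
      readr::write_tsv(enrich_terms(res$sets[[nm]], ann, universe_n), f,
                       progress = FALSE)
      files <- c(files, f)
    }
  }

  manifest <- list(
    package = "hifdep",
    version = as.character(utils::packageVersion("hifdep")),
    seed = decfg$seed, s0_mode = decfg$s0_mode,
    n_permutations = decfg$n_permutations,
    exhaustive_limit = decfg$exhaustive_limit,
    schemes = schemes, direction_mode = res$direction_mode,
    universe_n = universe_n,
    gates = gates[, c("comparison", "max_q", "min_abs_fold")],
    outputs = tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
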