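## Metabolite-table pipeline: below-detection imputation, per-sample protein
## normalization, log2 abundances relative to the control-normoxia group,
## and per-compound one-way ANOVA with pairwise contrasts. The intended
## order is impute -> normalize_protein -> relative_log2 / anova_contrasts;
## each step records itself in the `metab_steps` attribute and the modelling
## steps refuse tables that still contain masked values.

metab_require_cols <- function(tbl, cols) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(paste0("Metabolite table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
}

add_step <- function(tbl, step) {
  attr(tbl, "metab_steps") <- c(attr(tbl, "metab_steps"), step)
  tbl
}

#' Impute below-detection metabolite values
#'
#' Two-branch rule applied per compound within each genotype-by-oxygen
#' replicate group: if *every* replicate in the group is undetected, each is
#' assigned the minimum detected value across **all** compounds in the table
#' (a global post-hoc detection floor); if at least one replicate is
#' detected, the undetected ones are assigned the minimum detected value of
#' **that compound**. Detected entries are never altered.
#'
#' @param tbl Long metabolite tibble (`compound`, `genotype`, `oxygen`,
#'   `abundance`, `detected`; undetected abundances may be `NA`).
#' @return The table with `abundance` filled in; `detected` flags untouched.
#' @export
impute_below_detection <- function(tbl) {
  metab_require_cols(tbl, c("compound", "genotype", "oxygen",
                            "abundance", "detected"))
  if (!any(tbl$detected)) abort("No detected values anywhere in the table.")
  global_min <- min(tbl$abundance[tbl$detected], na.rm = TRUE)
  out <- tbl |>
    dplyr::group_by(.data$compound) |>
    dplyr::mutate(compound_min = ifelse(
      any(.data$detected),
      suppressWarnings(min(.data$abundance[.data$detected], na.rm = TRUE)),
      NA_real_)) |>
    dplyr::group_by(.data$compound, .data$genotype, .data$oxygen) |>
    dplyr::mutate(abundance = dplyr::case_when(
      detected ~ abundance,
      !any(detected) ~ global_min,
      TRUE ~ compound_min)) |>
    dplyr::ungroup() |>
    dplyr::select(-"compound_min")
  attr(out, "metab_steps") <- attr(tbl, "metab_steps")
  add_step(out, "impute_below_detection")
}

#' Normalize metabolite abundances by protein content
#'
#' Divides every abundance by its sample's protein mass (Bradford-style
#' normalization); units become counts per microgram.
#'
#' @param tbl Long metabolite tibble with `abundance` and `protein_mass`
#'   columns; run [impute_below_detection()] first so no value is masked.
#' @return The table with normalized `abundance`.
#' @export
normalize_protein <- function(tbl) {
  metab_require_cols(tbl, c("abundance", "protein_mass"))
  if (anyNA(tbl$abundance)) {
    abort("Masked abundances present; run impute_below_detection() first.")
  }
  if (any(!is.finite(tbl$protein_mass) | tbl$protein_mass <= 0)) {
    abort("Every sample needs a positive protein mass.")
  }
  out <- dplyr::mutate(tbl, abundance = .data$abundance / .data$protein_mass)
  attr(out, "metab_steps") <- attr(tbl, "metab_steps")
  add_step(out, "normalize_protein")
}

#' Log2 group means relative to the reference group
#'
#' Per compound, averages abundance on the linear (normalized) scale within
#' each genotype-by-oxygen group and reports `log2(group mean / reference
#' mean)`; the reference group (control normoxia by default) maps to exactly
#' 0. This is the heat-map quantity: log2-transformed average values plotted
#' relative to the wild-type normoxic level.
#'
#' @param tbl Imputed, protein-normalized long metabolite tibble.
#' @param ref_genotype,ref_oxygen Reference group.
#' @return Tibble: `compound`, `genotype`, `oxygen`, `log2_ratio`.
#' @export
relative_log2 <- function(tbl, ref_genotype = "control",
                          ref_oxygen = "normoxia") {
  metab_require_cols(tbl, c("compound", "genotype", "oxygen", "abundance"))
  if (anyNA(tbl$abundance)) {
    abort("Masked abundances present; run impute_below_detection() first.")
  }
  means <- tbl |>
    dplyr::group_by(.data$compound, .data$genotype, .data$oxygen) |>
    dplyr::summarise(mean_abundance = mean(.data$abundance), .groups = "drop")
  ref <- dplyr::filter(means, .data$genotype == ref_genotype,
                       .data$oxygen == ref_oxygen)
  if (nrow(ref) == 0) abort("Reference group absent from the table.")
  if (any(ref$mean_abundance <= 0)) {
    abort("Reference group mean is zero for some compound.")
  }
  out <- means |>
    dplyr::left_join(dplyr::select(ref, "compound",
                                   ref_mean = "mean_abundance"),
                     by = "compound") |>
    dplyr::mutate(log2_ratio = log2(.data$mean_abundance / .data$ref_mean)) |>
    dplyr::select("compound", "genotype", "oxygen", "log2_ratio")
  attr(out, "metab_steps") <- c(attr(tbl, "metab_steps"), "relative_log2")
  out
}

#' Default metabolite contrasts for a factorial design
#'
#' Hypoxia-vs-normoxia within each genotype, plus control-vs-mutant within
#' each oxygen level.
#'
#' @param genotypes Genotypes present in the table.
#' @return Tibble: `genotype_a`, `oxygen_a`, `genotype_b`, `oxygen_b`.
#' @export
default_metab_contrasts <- function(genotypes) {
  within_geno <- tibble::tibble(genotype_a = genotypes, oxygen_a = "normoxia",
                                genotype_b = genotypes, oxygen_b = "hypoxia")
  mutants <- setdiff(genotypes, "control")
  vs_control <- tidyr::crossing(genotype_b = mutants,
                                oxygen = c("normoxia", "hypoxia")) |>
    dplyr::transmute(genotype_a = "control", oxygen_a = .data$oxygen,
                     genotype_b = .data$genotype_b, oxygen_b = .data$oxygen)
  dplyr::bind_rows(within_geno, vs_control)
}

#' Per-compound one-way ANOVA with contrasts
#'
#' For each compound, fits a one-way ANOVA of log2 abundance across all
#' genotype-by-oxygen groups, then tests the stated pairwise contrasts with
#' the pooled residual variance (t on the ANOVA's residual degrees of
#' freedom). Contrast estimates are log2 mean differences oriented "a vs b"
#' (b relative to a). q-values are Benjamini-Hochberg within each contrast
#' across compounds.
#'
#' @param tbl Imputed, protein-normalized long metabolite tibble.
#' @param contrasts Contrast table as [default_metab_contrasts()]; defaults
#'   to the groups present.
#' @return A `metab_stats` tibble: `compound`, `contrast`, `estimate_log2`,
#'   `t`, `df`, `p_value`, `q_value`, `f_statistic`, `anova_p`; the applied
#'   pipeline steps are recorded in attribute `metab_steps`.
#' @export
anova_contrasts <- function(tbl, contrasts = NULL) {
  metab_require_cols(tbl, c("compound", "genotype", "oxygen", "abundance"))
  if (anyNA(tbl$abundance)) {
    abort("Masked abundances present; run impute_below_detection() first.")
  }
  if (any(tbl$abundance <= 0)) abort("Abundances must be positive to log.")
  tbl <- dplyr::mutate(tbl,
                       group = paste(.data$genotype, .data$oxygen, sep = "_"),
                       log2_abundance = log2(.data$abundance))
  sizes <- dplyr::count(tbl, .data$compound, .data$group)
  if (any(sizes$n < 2)) abort("Every group needs >= 2 replicates.")
  if (length(unique(tbl$group)) < 2) abort("Need >= 2 groups.")
  if (is.null(contrasts)) {
    contrasts <- default_metab_contrasts(unique(tbl$genotype))
    present <- unique(tbl$group)
    contrasts <- dplyr::filter(
      contrasts,
      paste(.data$genotype_a, .data$oxygen_a, sep = "_") %in% present,
      paste(.data$genotype_b, .data$oxygen_b, sep = "_") %in% present)
  }
  contrasts <- dplyr::mutate(
    contrasts,
    group_a = paste(.data$genotype_a, .data$oxygen_a, sep = "_"),
    group_b = paste(.data$genotype_b, .data$oxygen_b, sep = "_"),
    contrast = paste(.data$group_a, "vs", .data$group_b))

  out <- purrr::map_dfr(split(tbl, tbl$compound), function(d) {
    fit <- lm(log2_abundance ~ group, data = d)
    an <- anova(fit)
    mse <- an[["Mean Sq"]][2]
    dfres <- an[["Df"]][2]
    gm <- tapply(d$log2_abundance, d$group, mean)
    gn <- tapply(d$log2_abundance, d$group, length)
    purrr::map_dfr(seq_len(nrow(contrasts)), function(i) {
      ga <- contrasts$group_a[i]; gb <- contrasts$group_b[i]
      est <- gm[[gb]] - gm[[ga]]
      se <- sqrt(mse * (1 / gn[[ga]] + 1 / gn[[gb]]))
      tval <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
      tibble::tibble(
        compound = d$compound[1], contrast = contrasts$contrast[i],
        estimate_log2 = est, t = tval, df = dfres,
        p_value = 2 * pt(-abs(tval), dfres),
        f_statistic = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1])
    })
  })
  out <- out |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, "BH")) |>
    dplyr::ungroup() |>
    dplyr::relocate("q_value", .after = "p_value")
  attr(out, "metab_steps") <- c(attr(tbl, "metab_steps"),
                                "log2", "anova_contrasts")
  class(out) <- c("metab_stats", class(out))
  out
}
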