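## Relative qPCR quantification against a reference gene, hypoxia/normoxia
## fold changes, and delta-Ct t-tests with Bonferroni correction.
## Amplification efficiency is fixed at 2 (standard delta-Ct, no efficiency
## correction).

qpcr_delta_ct <- function(ct_table, gene, reference) {
  metab_require_cols(ct_table, c("sample_id", "gene", "ct"))
  tgt <- dplyr::filter(ct_table, .data$gene == !!gene)
  if (nrow(tgt) == 0) abort(paste0("Gene not in the Ct table: ", gene))
  ref <- dplyr::filter(ct_table, .data$gene == !!reference)
  ref <- dplyr::select(ref, "sample_id", ref_ct = "ct")
  out <- dplyr::left_join(tgt, ref, by = "sample_id")
  if (anyNA(out$ref_ct)) {
    abort(paste0("Reference gene \"", reference,
                 "\" missing for sample(s): ",
                 paste(utils::head(out$sample_id[is.na(out$ref_ct)], 5),
                       collapse = ", ")))
  }
  dplyr::mutate(out, delta_ct = .data$ct - .data$ref_ct)
}

#' Reference-normalized relative expression per sample
#'
#' `2^-(ct_gene - ct_reference)`, assuming perfect doubling per cycle; adding
#' a constant to every Ct of a sample (a loading shift) cancels out.
#'
#' @param ct_table Long Ct tibble (`sample_id`, `gene`, `ct`, plus sample
#'   annotations).
#' @param gene Target gene.
#' @param reference Reference (normalizer) gene; defaults to the table's
#'   `reference_gene` attribute, else `"rp49"`.
#' @return The target-gene rows with `delta_ct` and `rel_expr` columns.
#' @export
relative_expression <- function(ct_table, gene, reference = NULL) {
  reference <- reference %||% attr(ct_table, "reference_gene") %||% "rp49"
  out <- qpcr_delta_ct(ct_table, gene, reference)
  dplyr::mutate(out, rel_expr = 2^-.data$delta_ct)
}

#' Hypoxia/normoxia fold change of relative expression
#'
#' Mean reference-normalized expression in hypoxia divided by the mean in
#' normoxia, per grouping variable (genotype by default); 1.0 means no net
#' response.
#'
#' @inheritParams relative_expression
#' @param by Grouping column(s) of the Ct table (default `"genotype"`).
#' @return Tibble: grouping columns, `n_hypoxia`, `n_normoxia`, `fold_hn`.
#' @export
hn_fold_change <- function(ct_table, gene, reference = NULL,
                           by = "genotype") {
  rel <- relative_expression(ct_table, gene, reference)
  metab_require_cols(rel, c("oxygen", by))
  out <- rel |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_hypoxia = sum(.data$oxygen == "hypoxia"),
      n_normoxia = sum(.data$oxygen == "normoxia"),
      fold_hn = mean(.data$rel_expr[.data$oxygen == "hypoxia"]) /
        mean(.data$rel_expr[.data$oxygen == "normoxia"]),
      .groups = "drop")
  if (any(out$n_hypoxia == 0 | out$n_normoxia == 0)) {
    abort("Both oxygen groups must be present in every stratum.")
  }
  out
}

#' Delta-Ct t-tests with Bonferroni correction
#'
#' Two-tailed unpaired t-tests on per-sample delta-Ct (target minus
#' reference), one per requested comparison, with the Bonferroni-adjusted
#' p-value `min(1, p * m_tests)`. The family size `m_tests` must be supplied
#' explicitly (it is a reporting decision, not derivable from the table) and
#' is recorded in the output.
#'
#' @inheritParams relative_expression
#' @param comparisons Tibble with columns `genotype_a`, `oxygen_a`,
#'   `genotype_b`, `oxygen_b` (one row per comparison).
#' @param m_tests Bonferroni family size (>= number of comparisons).
#' @param var_equal Classical equal-variance t-test (default TRUE); set FALSE
#'   for Welch.
#' @return Tibble: comparison columns, `mean_delta_ct_a/b`, `t`, `df`,
#'   `p_value`, `p_adjusted`, `m_tests`.
#' @export
delta_ct_tests <- function(ct_table, gene, reference = NULL, comparisons,
                           m_tests = nrow(comparisons), var_equal = TRUE) {
  reference <- reference %||% attr(ct_table, "reference_gene") %||% "rp49"
  if (m_tests < nrow(comparisons)) {
    abort("`m_tests` must be at least the number of comparisons.")
  }
  dct <- qpcr_delta_ct(ct_table, gene, reference)
  metab_require_cols(dct, c("genotype", "oxygen"))
  purrr::map_dfr(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    xa <- dct$delta_ct[dct$genotype == cmp$genotype_a &
                         dct$oxygen == cmp$oxygen_a]
    xb <- dct$delta_ct[dct$genotype == cmp$genotype_b &
                         dct$oxygen == cmp$oxygen_b]
    if (length(xa) < 2 || length(xb) < 2) {
      abort("Each side of a comparison needs >= 2 replicates.")
    }
    if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
      tt <- list(statistic = 0, parameter = length(xa) + length(xb) - 2,
                 p.value = 1)
    } else {
      # signed for side b minus side a, consistent with the package's
      # "a vs b" orientation
      tt <- t.test(xb, xa, var.equal = var_equal)
    }
    tibble::tibble(
      genotype_a = cmp$genotype_a, oxygen_a = cmp$oxygen_a,
      genotype_b = cmp$genotype_b, oxygen_b = cmp$oxygen_b,
      mean_delta_ct_a = mean(xa), mean_delta_ct_b = mean(xb),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      p_adjusted = min(1, tt$p.value * m_tests),
      m_tests = m_tests)
  })
}
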