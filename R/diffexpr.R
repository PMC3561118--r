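## SAM-style two-class differential expression: regularized relative
## difference d = (mean_b - mean_a) / (s + s0), a data-driven fudge factor
## s0, and permutation-based per-probe q-values with exhaustive enumeration
## of label assignments whenever the design is small enough.

#' Differential-expression configuration
#'
#' @param s0_mode How the fudge factor s0 is chosen: `"cv_minimization"`
#'   (coefficient-of-variation minimization over percentile candidates of the
#'   per-probe standard error, the standard SAM recipe), `"median_s"`, or
#'   `"fixed"`.
#' @param s0_fixed Value used when `s0_mode = "fixed"` (log2 units, >= 0).
#' @param n_permutations Number of sampled label permutations when exhaustive
#'   enumeration is not feasible.
#' @param exhaustive_limit Enumerate all distinct group-label assignments
#'   when their number is at most this (a 3-vs-3 design has 20, so small
#'   factorial designs are always exhaustive and deterministic).
#' @param seed Seed for sampled permutations.
#' @param tie_rule Whether a permuted |d*| equal to the probe's |d| counts as
#'   an exceedance (`"geq"`, conservative, default) or not (`"gt"`).
#' @return List of class `de_config`.
#' @export
de_config <- function(s0_mode = c("cv_minimization", "median_s", "fixed"),
                      s0_fixed = NULL,
                      n_permutations = 200L,
                      exhaustive_limit = 10000L,
                      seed = 1L,
                      tie_rule = c("geq", "gt")) {
  s0_mode <- match.arg(s0_mode)
  tie_rule <- match.arg(tie_rule)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  if (s0_mode == "fixed") {
    if (is.null(s0_fixed) || s0_fixed < 0) {
      abort("`s0_fixed` must be a nonnegative number when s0_mode = \"fixed\".")
    }
  }
  structure(list(s0_mode = s0_mode, s0_fixed = s0_fixed,
                 n_permutations = as.integer(n_permutations),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 seed = as.integer(seed), tie_rule = tie_rule),
            class = "de_config")
}

#' Signed fold change from log2 group means
#'
#' For a comparison "a vs b" the linear ratio is `r = 2^(mean_b - mean_a)`
#' (b relative to a). The signed display convention reports `+r` when
#' `r >= 1` and `-1/r` otherwise, so a halving shows as -2 rather than 0.5.
#'
#' @param mean_log2_a,mean_log2_b Log2 group means (vectorized).
#' @return Signed fold change(s), dimensionless.
#' @export
#' @examples
#' fold_change(4, 6)  # +4
#' fold_change(6, 4)  # -4
fold_change <- function(mean_log2_a, mean_log2_b) {
  r <- 2^(mean_log2_b - mean_log2_a)
  ifelse(r >= 1, r, -1 / r)
}

#' SAM relative-difference statistic for one probe
#'
#' `d = (mean(b) - mean(a)) / (s + s0)` with `s` the pooled standard error
#' `sqrt((1/na + 1/nb) * (SS_a + SS_b) / (na + nb - 2))`. Antisymmetric under
#' swapping the groups. A zero denominator with zero difference yields 0; a
#' zero denominator with nonzero difference yields signed infinity (the
#' noiseless limit).
#'
#' @param group_a,group_b Numeric vectors of log2 intensities (>= 2 each).
#' @param s0 Fudge factor (>= 0).
#' @return The d statistic.
#' @export
sam_statistic <- function(group_a, group_b, s0 = 0) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Both groups need at least 2 values.")
  }
  if (s0 < 0) abort("`s0` must be >= 0.")
  sam_d_matrix(rbind(c(group_a, group_b)),
               seq_along(group_a),
               length(group_a) + seq_along(group_b), s0)$d
}

## Vectorized d/s over the rows of a matrix, for column index sets ia/ib.
sam_d_matrix <- function(X, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  Xa <- X[, ia, drop = FALSE]; Xb <- X[, ib, drop = FALSE]
  ma <- rowMeans(Xa); mb <- rowMeans(Xb)
  ssa <- rowSums((Xa - ma)^2); ssb <- rowSums((Xb - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  diff <- mb - ma
  denom <- s + s0
  d <- ifelse(denom == 0,
              ifelse(diff == 0, 0, sign(diff) * Inf),
              diff / denom)
  list(d = unname(d), s = unname(s), mean_a = unname(ma), mean_b = unname(mb))
}

#' Estimate the SAM fudge factor s0
#'
#' In `cv_minimization` mode (default), candidates are the 0, 5, ..., 100
#' percentiles of the per-probe pooled standard error `s`; for each candidate
#' the probes are binned into up to 100 quantile windows of `s`, the median
#' absolute deviation of `d` is computed per window, and the candidate
#' minimizing the coefficient of variation of those MADs is returned. This
#' damps the small-variance probes that otherwise dominate the top of the d
#' ranking. `median_s` returns the median per-probe `s`; `fixed` returns
#' `s0_fixed`.
#'
#' @param exprs Expression tibble (`probe_id` + sample columns).
#' @param group_a,group_b Character vectors of sample column names.
#' @param s0_mode,s0_fixed See [de_config()].
#' @return Scalar s0 (log2 units, >= 0).
#' @export
estimate_s0 <- function(exprs, group_a, group_b,
                        s0_mode = c("cv_minimization", "median_s", "fixed"),
                        s0_fixed = NULL) {
  s0_mode <- match.arg(s0_mode)
  if (s0_mode == "fixed") {
    if (is.null(s0_fixed) || s0_fixed < 0) abort("Invalid `s0_fixed`.")
    return(s0_fixed)
  }
  X <- exprs_matrix(exprs, c(group_a, group_b))
  st <- sam_d_matrix(X, seq_along(group_a),
                     length(group_a) + seq_along(group_b), 0)
  if (s0_mode == "median_s") return(unname(median(st$s)))
  if (nrow(X) < 10) {
    abort("cv_minimization needs at least 10 probes.")
  }
  s0_cv_minimize(mb_minus_ma = st$mean_b - st$mean_a, s = st$s)
}

s0_cv_minimize <- function(mb_minus_ma, s,
                           alphas = seq(0, 1, by = 0.05)) {
  if (diff(range(s)) < .Machine$double.eps) return(unname(median(s)))
  cand <- unname(quantile(s, alphas, type = 7))
  nbin <- min(100L, max(2L, floor(length(s) / 10)))
  bin <- dplyr::ntile(s, nbin)
  cvs <- vapply(cand, function(s0) {
    da <- mb_minus_ma / (s + s0)
    mads <- tapply(da, bin, mad)
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(NA_real_)
    sd(mads) / m
  }, numeric(1))
  if (all(is.na(cvs))) return(unname(median(s)))
  cand[which.min(cvs)]
}

## All (or sampled) assignments of the pooled samples to group a.
## Returns an na x B integer matrix of group-a positions within 1..n.
perm_assignments <- function(n, na, exhaustive_limit, n_permutations, seed) {
  total <- choose(n, na)
  if (total <= exhaustive_limit) {
    list(idx = combn(n, na), exhaustive = TRUE, n_assignments = total)
  } else {
    set.seed(seed)
    idx <- replicate(n_permutations, sort(sample.int(n, na)))
    list(idx = matrix(idx, nrow = na), exhaustive = FALSE,
         n_assignments = n_permutations)
  }
}

count_at_least <- function(thresholds, sorted_vals, tie_rule) {
  n <- length(sorted_vals)
  if (tie_rule == "geq") {
    n - findInterval(thresholds, sorted_vals, left.open = TRUE)
  } else {
    n - findInterval(thresholds, sorted_vals)
  }
}

#' Permutation q-values for a two-group comparison
#'
#' For each probe with threshold `t = |d|`, the q-value is the median over
#' label permutations of the number of permuted `|d*|` values at or above
#' `t`, divided by the number of observed probes called at `t`, clipped to
#' [0, 1], with monotonicity enforced so q never increases with |d|. All
#' distinct label assignments are enumerated when their number is at most
#' `exhaustive_limit` (deterministic); otherwise `n_permutations` assignments
#' are sampled under `seed`.
#'
#' @inheritParams estimate_s0
#' @param s0 Fudge factor used for both observed and permuted statistics.
#' @param config A [de_config()].
#' @return Tibble: `probe_id`, `d`, `q_value`.
#' @export
permutation_qvalues <- function(exprs, group_a, group_b, s0,
                                config = de_config()) {
  X <- exprs_matrix(exprs, c(group_a, group_b))
  q <- perm_q_matrix(X, seq_along(group_a),
                     length(group_a) + seq_along(group_b), s0, config)
  tibble::tibble(probe_id = exprs$probe_id, d = q$d, q_value = q$q)
}

perm_q_matrix <- function(X, ia, ib, s0, config) {
  n <- length(ia) + length(ib)
  obs <- sam_d_matrix(X, ia, ib, s0)
  t_obs <- abs(obs$d)
  sorted_obs <- sort(t_obs)
  R <- count_at_least(t_obs, sorted_obs, config$tie_rule)

  asn <- perm_assignments(n, length(ia), config$exhaustive_limit,
                          config$n_permutations, config$seed)
  cols <- c(ia, ib)
  V <- matrix(0, nrow = nrow(X), ncol = asn$n_assignments)
  for (b in seq_len(asn$n_assignments)) {
    a_pos <- asn$idx[, b]
    d_star <- sam_d_matrix(X, cols[a_pos], cols[-a_pos], s0)$d
    V[, b] <- count_at_least(t_obs, sort(abs(d_star)), config$tie_rule)
  }
  v_med <- apply(V, 1, median)
  q <- pmin(1, pmax(0, v_med / R))
  ord <- order(t_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  list(d = obs$d, q = q, exhaustive = asn$exhaustive,
       n_assignments = asn$n_assignments)
}

exprs_matrix <- function(exprs, sample_ids) {
  if (!"probe_id" %in% names(exprs)) abort("`exprs` needs a probe_id column.")
  if (anyDuplicated(exprs$probe_id)) abort("Duplicate probe_id values.")
  missing <- setdiff(sample_ids, names(exprs))
  if (length(missing)) {
    abort(paste0("Sample(s) absent from the expression table: ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(exprs[, sample_ids, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) abort("Expression values must be numeric and complete.")
  rownames(X) <- exprs$probe_id
  X
}

#' SAM differential expression between two sample groups
#'
#' Runs the full SAM-style analysis: s0 estimation, per-probe d statistics,
#' permutation q-values, and signed fold changes from the log2 group means.
#' The comparison is "a vs b": fold changes and d report group b relative to
#' group a, so a transcript induced in group b is positive.
#'
#' @param exprs Expression tibble (`probe_id` + one column per sample).
#' @param group_a,group_b Character vectors of sample column names (>= 2
#'   each).
#' @param config A [de_config()].
#' @param comparison Optional label stored on the result.
#' @return A `sam_de` tibble: `probe_id`, `mean_log2_a`, `mean_log2_b`,
#'   `fold_change` (signed), `d`, `q_value`; attributes `s0`,
#'   `n_assignments`, `exhaustive`, `comparison`.
#' @export
sam_de <- function(exprs, group_a, group_b, config = de_config(),
                   comparison = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each compared group needs at least 2 replicates.")
  }
  X <- exprs_matrix(exprs, c(group_a, group_b))
  ia <- seq_along(group_a); ib <- length(group_a) + seq_along(group_b)
  s0 <- estimate_s0(exprs, group_a, group_b,
                    s0_mode = config$s0_mode, s0_fixed = config$s0_fixed)
  obs <- sam_d_matrix(X, ia, ib, s0)
  pq <- perm_q_matrix(X, ia, ib, s0, config)
  out <- tibble::tibble(
    probe_id = exprs$probe_id,
    mean_log2_a = obs$mean_a, mean_log2_b = obs$mean_b,
    fold_change = fold_change(obs$mean_a, obs$mean_b),
    d = obs$d, q_value = pq$q)
  attr(out, "s0") <- s0
  attr(out, "n_assignments") <- pq$n_assignments
  attr(out, "exhaustive") <- pq$exhaustive
  attr(out, "comparison") <- comparison %||% "a vs b"
  class(out) <- c("sam_de", class(out))
  out
}

#' SAM comparison between two genotype-by-oxygen conditions
#'
#' Convenience wrapper around [sam_de()] that resolves sample groups from a
#' sample sheet. Conditions are named `"<genotype>_<oxygen>"`, e.g.
#' `"control_hypoxia"`.
#'
#' @param exprs Expression tibble.
#' @param samples Sample sheet (`sample_id`, `genotype`, `oxygen`, ...).
#' @param a,b Condition labels; the comparison is "a vs b" (b relative to a).
#' @param config A [de_config()].
#' @return A `sam_de` tibble (see [sam_de()]).
#' @export
sam_compare <- function(exprs, samples, a, b, config = de_config()) {
  cond <- paste(samples$genotype, samples$oxygen, sep = "_")
  ga <- samples$sample_id[cond == a]
  gb <- samples$sample_id[cond == b]
  if (length(ga) == 0) abort(paste0("No samples for condition ", a))
  if (length(gb) == 0) abort(paste0("No samples for condition ", b))
  sam_de(exprs, ga, gb, config, comparison = paste(a, "vs", b))
}

#' Gate a differential result into a directed gene set
#'
#' A probe is included iff `|fold_change| >= min_abs_fold` and
#' `q_value < max_q`; direction is `up` for positive signed fold, `down`
#' otherwise.
#'
#' @param de A `sam_de` tibble (or any tibble with `probe_id`,
#'   `fold_change`, `q_value`).
#' @param name Set name.
#' @param min_abs_fold Fold gate (>= 1, default 1.5).
#' @param max_q FDR gate, a fraction in (0, 1).
#' @return Tibble: `set`, `probe_id`, `direction`.
#' @export
call_differential <- function(de, name = "set", min_abs_fold = 1.5,
                              max_q = 0.01) {
  if (min_abs_fold < 1) abort("`min_abs_fold` must be >= 1.")
  if (max_q <= 0 || max_q >= 1) abort("`max_q` must be in (0, 1).")
  keep <- abs(de$fold_change) >= min_abs_fold & de$q_value < max_q
  tibble::tibble(set = name,
                 probe_id = de$probe_id[keep],
                 direction = ifelse(de$fold_change[keep] > 0, "up", "down"))
}
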