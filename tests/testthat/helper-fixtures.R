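# Shared fixture builders: tiny expression tibbles and a brute-force SAM
# oracle kept deliberately naive and independent of the package internals.

toy_exprs <- function(values, probe_ids = NULL) {
  # values: probes x samples matrix; sample columns named s1..sn
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  n <- nrow(values)
  probe_ids <- probe_ids %||% sprintf("p%02d", seq_len(n))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                   tibble::as_tibble(as.data.frame(values)))
}

# Naive SAM statistic from the textbook formula, one probe at a time.
oracle_d <- function(a, b, s0) {
  na <- length(a); nb <- length(b)
  s <- sqrt((1 / na + 1 / nb) *
              (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2))
  if (s + s0 == 0) {
    if (mean(b) - mean(a) == 0) return(0)
    return(sign(mean(b) - mean(a)) * Inf)
  }
  (mean(b) - mean(a)) / (s + s0)
}

# Brute-force permutation q-values: enumerate every assignment of the pooled
# samples to group a with combn, count exceedances with explicit loops, take
# the median count over assignments, divide by the observed call count, clip
# and enforce monotonicity by an O(n^2) scan.
oracle_qvalues <- function(X, na, nb, s0, tie = `>=`) {
  n_probe <- nrow(X)
  d_obs <- vapply(seq_len(n_probe), function(i) {
    oracle_d(X[i, 1:na], X[i, na + 1:nb], s0)
  }, numeric(1))
  t_obs <- abs(d_obs)
  assigns <- combn(na + nb, na)
  counts <- matrix(0, n_probe, ncol(assigns))
  for (p in seq_len(ncol(assigns))) {
    ia <- assigns[, p]
    d_star <- vapply(seq_len(n_probe), function(i) {
      oracle_d(X[i, ia], X[i, -ia], s0)
    }, numeric(1))
    for (i in seq_len(n_probe)) {
      counts[i, p] <- sum(tie(abs(d_star), t_obs[i]))
    }
  }
  q <- numeric(n_probe)
  for (i in seq_len(n_probe)) {
    R <- sum(tie(t_obs, t_obs[i]))
    q[i] <- min(1, max(0, median(counts[i, ]) / R))
  }
  for (i in seq_len(n_probe)) {
    q[i] <- min(q[t_obs >= t_obs[i]])
  }
  q
}

`%||%` <- rlang::`%||%`
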