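test_that("signed fold change follows the display convention", {
  expect_equal(fold_change(4, 6), 4)
  expect_equal(fold_change(6, 4), -4)
  expect_equal(fold_change(5, 5), 1)
  # antisymmetric for all non-unit ratios
  x <- runif(20, 2, 10); y <- runif(20, 2, 10)
  nz <- x != y
  expect_equal(fold_change(x, y)[nz], -fold_change(y, x)[nz])
})

test_that("d statistic matches the pooled-standard-error hand computation", {
  expect_equal(sam_statistic(c(4, 4.1, 3.9), c(5, 5.2, 4.8), s0 = 0.1),
               1 / (sqrt((1/3 + 1/3) * (0.02 + 0.08) / 4) + 0.1),
               tolerance = 1e-12)
  expect_equal(sam_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.5), 0)
  # antisymmetric under group swap; |d| strictly shrinks as s0 grows
  a <- rnorm(4); b <- rnorm(4) + 1
  expect_equal(sam_statistic(a, b, 0.2), -sam_statistic(b, a, 0.2))
  expect_lt(abs(sam_statistic(a, b, 0.4)), abs(sam_statistic(a, b, 0.2)))
  expect_error(sam_statistic(1, c(1, 2), 0), "at least 2")
})

test_that("s0 estimation modes behave as specified", {
  set.seed(1)
  X <- toy_exprs(matrix(rnorm(600), nrow = 100))
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  expect_equal(estimate_s0(X, ga, gb, "fixed", s0_fixed = 0.2), 0.2)
  # constant per-probe s: median_s returns that constant
  Y <- toy_exprs(rbind(c(0, 1, 2, 0, 1, 2) + 5,
                       c(0, 1, 2, 0, 1, 2) + 9,
                       c(0, 1, 2, 0, 1, 2)))
  s_const <- sqrt((1/3 + 1/3) * (2 + 2) / 4)
  expect_equal(estimate_s0(Y, ga, gb, "median_s"), s_const)
  expect_error(estimate_s0(toy_exprs(matrix(rnorm(30), 5)), ga, gb,
                           "cv_minimization"), "at least 10")
})

test_that("cv-minimizing s0 equals an exhaustive grid search", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 6, sd = rep(runif(n, 0.1, 1), 6)), nrow = n)
  X[1:20, 4:6] <- X[1:20, 4:6] + 2
  tb <- toy_exprs(X)
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  got <- estimate_s0(tb, ga, gb, "cv_minimization")
  # naive grid search over the same percentile candidates and binning
  d_num <- rowMeans(X[, 4:6]) - rowMeans(X[, 1:3])
  s <- vapply(seq_len(n), function(i) {
    sqrt((1/3 + 1/3) *
           (sum((X[i, 1:3] - mean(X[i, 1:3]))^2) +
              sum((X[i, 4:6] - mean(X[i, 4:6]))^2)) / 4)
  }, numeric(1))
  cand <- unname(quantile(s, seq(0, 1, by = 0.05), type = 7))
  bin <- dplyr::ntile(s, min(100, floor(n / 10)))
  cvs <- sapply(cand, function(s0) {
    mads <- tapply(d_num / (s + s0), bin, mad)
    sd(mads) / mean(mads)
  })
  expect_equal(got, cand[which.min(cvs)])
  expect_gte(got, 0)
})

test_that("exhaustive permutation q-values equal the brute-force oracle", {
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 6), nrow = 25)
    X[1:4, 4:6] <- X[1:4, 4:6] + 3
    tb <- toy_exprs(X)
    got <- permutation_qvalues(tb, paste0("s", 1:3), paste0("s", 4:6),
                               s0 = 0.1, de_config(seed = 1))
    expect_equal(got$q_value, oracle_qvalues(X, 3, 3, 0.1))
    # gt tie rule against the strict-inequality oracle
    got_gt <- permutation_qvalues(tb, paste0("s", 1:3), paste0("s", 4:6),
                                  s0 = 0.1, de_config(seed = 1,
                                                      tie_rule = "gt"))
    expect_equal(got_gt$q_value, oracle_qvalues(X, 3, 3, 0.1, tie = `>`))
  }
})

test_that("sampled q-values converge to the enumerated values", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), nrow = 40)
  X[1:6, 4:6] <- X[1:6, 4:6] + 2.5
  tb <- toy_exprs(X)
  ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
  exact <- permutation_qvalues(tb, ga, gb, 0.1, de_config())$q_value
  err <- vapply(c(50, 2000), function(B) {
    smp <- permutation_qvalues(tb, ga, gb, 0.1,
                               de_config(n_permutations = B, seed = 11,
                                         exhaustive_limit = 1))$q_value
    max(abs(smp - exact))
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lte(err[2], err[1])
})

test_that("degenerate matrices and dominant probes hit the q extremes", {
  tb <- toy_exprs(matrix(5, nrow = 8, ncol = 6))
  q <- permutation_qvalues(tb, paste0("s", 1:3), paste0("s", 4:6), 0.1,
                           de_config())
  expect_true(all(q$q_value == 1))
  # one probe whose |d| beats every permuted |d*|
  set.seed(4)
  X <- matrix(rnorm(30 * 8, sd = 0.1), nrow = 30)
  X[1, 5:8] <- X[1, 5:8] + 50
  q <- permutation_qvalues(toy_exprs(X), paste0("s", 1:4), paste0("s", 5:8),
                           0.05, de_config())
  expect_equal(q$q_value[1], 0)
})

test_that("group swap negates d and folds but preserves q and membership", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 6), nrow = 30)
    X[1:5, 4:6] <- X[1:5, 4:6] + 2
    tb <- toy_exprs(X)
    ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
    cfg <- de_config(s0_mode = "median_s")
    ab <- sam_de(tb, ga, gb, cfg)
    ba <- sam_de(tb, gb, ga, cfg)
    expect_equal(ab$d, -ba$d)
    nz <- abs(ab$fold_change) > 1
    expect_equal(ab$fold_change[nz], -ba$fold_change[nz])
    expect_equal(ab$q_value, ba$q_value)
    s1 <- call_differential(ab, max_q = 0.2)
    s2 <- call_differential(ba, max_q = 0.2)
    expect_identical(s1$probe_id, s2$probe_id)
    expect_true(all(s1$direction != s2$direction) || nrow(s1) == 0)
  }
})

test_that("gating applies the fold and FDR thresholds jointly", {
  de <- tibble::tibble(probe_id = c("a", "b", "c", "d"),
                       fold_change = c(1.6, 1.4, -1.6, 2.0),
                       q_value = c(0.005, 0.001, 0.009, 0.02))
  got <- call_differential(de, "sel", min_abs_fold = 1.5, max_q = 0.01)
  expect_identical(got$probe_id, c("a", "c"))
  expect_identical(got$direction, c("up", "down"))
  expect_error(call_differential(de, max_q = 0), "max_q")
  expect_error(call_differential(de, min_abs_fold = 0.5), "min_abs_fold")
})

test_that("sam_de results carry tidy and glance views", {
  set.seed(6)
  tb <- toy_exprs(matrix(rnorm(20 * 6), nrow = 20))
  de <- sam_de(tb, paste0("s", 1:3), paste0("s", 4:6),
               de_config(s0_mode = "median_s"), comparison = "x vs y")
  expect_s3_class(de, "sam_de")
  td <- tidy(de)
  expect_false(inherits(td, "sam_de"))
  g <- glance(de)
  expect_identical(g$comparison, "x vs y")
  expect_identical(g$n_assignments, 20)
  expect_true(g$exhaustive)
  expect_s3_class(autoplot(de), "ggplot")
})
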