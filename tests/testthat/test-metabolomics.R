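metab_fixture <- function() {
  # two compounds, two groups, three replicates; cmpB undetected in one group
  tidyr::crossing(
    compound = c("cmpA", "cmpB"),
    genotype = "control", oxygen = c("normoxia", "hypoxia"),
    replicate = 1:3) |>
    dplyr::mutate(
      sample_id = paste(genotype, oxygen, replicate, sep = "_"),
      abundance = dplyr::case_when(
        compound == "cmpA" & oxygen == "normoxia" ~ c(12, 44, 48)[replicate],
        compound == "cmpA" & oxygen == "hypoxia" ~ c(90, 95, 100)[replicate],
        compound == "cmpB" & oxygen == "normoxia" ~ c(30, 33, NA)[replicate],
        TRUE ~ NA_real_),
      detected = !is.na(abundance),
      protein_mass = 2)
}

test_that("the two imputation branches fill masked values correctly", {
  tbl <- metab_fixture()
  out <- impute_below_detection(tbl)
  # fully undetected group -> global minimum detected value (12, from cmpA)
  filled <- out$abundance[out$compound == "cmpB" & out$oxygen == "hypoxia"]
  expect_equal(filled, rep(12, 3))
  # partially detected group -> that compound's detected minimum (30)
  part <- out$abundance[out$compound == "cmpB" & out$oxygen == "normoxia"]
  expect_equal(part, c(30, 33, 30))
  # detected entries never change; nothing below the global detected minimum
  expect_equal(out$abundance[tbl$detected], tbl$abundance[tbl$detected])
  expect_true(all(out$abundance >= 12))
  expect_error(impute_below_detection(
    dplyr::mutate(tbl, detected = FALSE, abundance = NA_real_)),
    "No detected")
})

test_that("a six-replicate all-undetected group takes the global floor", {
  tbl <- tidyr::crossing(compound = c("ok", "gone"), genotype = "control",
                         oxygen = "normoxia", replicate = 1:6) |>
    dplyr::mutate(abundance = c(rep(NA_real_, 6), 12, 14, 16, 18, 20, 22),
                  compound = rep(c("gone", "ok"), each = 6),
                  detected = !is.na(abundance), protein_mass = 1)
  out <- impute_below_detection(tbl)
  expect_equal(out$abundance[out$compound == "gone"], rep(12, 6))
})

test_that("protein normalization divides by per-sample mass", {
  tbl <- impute_below_detection(metab_fixture())
  out <- normalize_protein(tbl)
  expect_equal(out$abundance, tbl$abundance / 2)
  expect_error(normalize_protein(dplyr::mutate(tbl, protein_mass = 0)),
               "positive protein")
  expect_error(normalize_protein(metab_fixture()), "impute")
  expect_identical(attr(out, "metab_steps"),
                   c("impute_below_detection", "normalize_protein"))
})

test_that("relative log2 is zero at the reference and log-ratio elsewhere", {
  tbl <- tidyr::crossing(compound = "c1", genotype = "control",
                         oxygen = c("normoxia", "hypoxia"),
                         replicate = 1:3) |>
    dplyr::mutate(abundance = c(198, 200, 202, 49, 50, 51)[
      order(rep(1:2, 3))],
      detected = TRUE, protein_mass = 1)
  # arrange explicitly: hypoxia mean 50, normoxia mean 200
  tbl$abundance <- c(49, 50, 51, 198, 200, 202)
  out <- relative_log2(tbl)
  expect_equal(out$log2_ratio[out$oxygen == "normoxia"], 0)
  expect_equal(out$log2_ratio[out$oxygen == "hypoxia"], -2)
  doubled <- dplyr::mutate(tbl, abundance = ifelse(oxygen == "hypoxia",
                                                   400, abundance))
  expect_equal(relative_log2(doubled)$log2_ratio[
    doubled$oxygen[1:2] == "hypoxia"][1], 1)
  expect_error(relative_log2(dplyr::filter(tbl, oxygen == "hypoxia")),
               "Reference")
})

test_that("one-way ANOVA with contrasts matches textbook sums of squares", {
  tbl <- tibble::tibble(
    compound = "c1", genotype = "control",
    oxygen = rep(c("normoxia", "hypoxia"), each = 3),
    replicate = rep(1:3, 2),
    abundance = 2^c(1, 2, 3, 2, 3, 4),  # log2 values {1,2,3} vs {2,3,4}
    detected = TRUE, protein_mass = 1)
  out <- anova_contrasts(
    tbl, contrasts = tibble::tibble(genotype_a = "control",
                                    oxygen_a = "normoxia",
                                    genotype_b = "control",
                                    oxygen_b = "hypoxia"))
  # SSB = 1.5, SSW = 4, F = 1.5 / (4/4) = 1.5 on (1, 4) df
  expect_equal(out$f_statistic, 1.5)
  expect_equal(out$anova_p, pf(1.5, 1, 4, lower.tail = FALSE))
  # contrast t on pooled MSE: est 1, se sqrt(1 * 2/3)
  expect_equal(out$estimate_log2, 1)
  expect_equal(out$t, 1 / sqrt(2 / 3))
  expect_equal(out$p_value, 2 * pt(-1 / sqrt(2 / 3), 4))
  # two-group one-way ANOVA agrees with the equal-variance t-test
  expect_equal(out$p_value, out$anova_p)
})

test_that("flat compounds give F = 0 and planted shifts rank first", {
  flat <- tidyr::crossing(compound = "flat", genotype = c("control", "mut"),
                          oxygen = c("normoxia", "hypoxia"),
                          replicate = 1:3) |>
    dplyr::mutate(abundance = 2^(5 + c(-0.1, 0, 0.1)[replicate]),
                  genotype = ifelse(genotype == "mut", "hif_mutant",
                                    genotype),
                  detected = TRUE, protein_mass = 1)
  out <- anova_contrasts(flat)
  expect_equal(unique(out$f_statistic), 0)
  expect_equal(unique(out$anova_p), 1)

  set.seed(14)
  cfg <- sim_config(seed = 14, metabolite_replicates = 6,
                    genotypes = c("control", "hif_mutant"))
  gm <- tidyr::crossing(compound = sprintf("c%02d", 1:10),
                        genotype = c("control", "hif_mutant"),
                        oxygen = c("normoxia", "hypoxia")) |>
    dplyr::mutate(mean = ifelse(compound == "c01" & oxygen == "hypoxia",
                                4e5, 1e5), cv = 0.2)
  met <- simulate_metabolites(cfg, group_means = gm)$metabolites
  stats <- met |>
    impute_below_detection() |>
    normalize_protein() |>
    anova_contrasts()
  hyp <- dplyr::filter(stats,
                       contrast == "control_normoxia vs control_hypoxia")
  expect_identical(hyp$compound[which.min(hyp$p_value)], "c01")
  expect_error(anova_contrasts(dplyr::filter(met, replicate == 1)),
               "replicates")
})
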