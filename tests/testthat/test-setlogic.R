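test_that("classify_factor performs the dual-evidence set algebra", {
  got <- classify_factor(c("a", "b", "c"), c("b", "c", "d"), c("a", "e"))
  ind <- got$probe_id[got$independent_H]
  set2 <- got$probe_id[got$candidate_set2]
  dep <- got$probe_id[got$dependent_H]
  expect_identical(ind, c("b", "c"))
  expect_identical(set2, "a")
  expect_identical(dep, "a")
  # empty total: nothing can be called
  e <- classify_factor(character(0), c("x"), c("y"))
  expect_true(all(!e$in_total & !e$independent_H & !e$dependent_H))
  expect_error(classify_factor(c("a"), c("b"), c("c"),
                               universe = c("a", "b")), "universe")
})

test_that("partition, containment and exclusivity hold on random sets", {
  set.seed(10)
  universe <- sprintf("g%03d", 1:200)
  for (i in 1:20) {
    tot <- sample(universe, sample(0:80, 1))
    ind <- sample(universe, sample(0:80, 1))
    crs <- sample(universe, sample(0:80, 1))
    cl <- classify_factor(tot, ind, crs, universe = universe)
    expect_equal(sum(cl$independent_H) + sum(cl$candidate_set2),
                 sum(cl$in_total))
    expect_true(all(cl$probe_id[cl$dependent_H] %in%
                      cl$probe_id[cl$candidate_set2]))
    expect_true(all(cl$probe_id[cl$candidate_set2] %in%
                      cl$probe_id[cl$in_total]))
    expect_true(all(cl$probe_id[cl$independent_H] %in%
                      cl$probe_id[cl$in_total]))
    expect_false(any(cl$independent_H & cl$dependent_H))
  }
})

test_that("concordant mode requires compatible directions", {
  tot <- tibble::tibble(probe_id = c("a", "b"), direction = c("up", "up"))
  ind <- tibble::tibble(probe_id = c("a", "b"), direction = c("up", "down"))
  crs <- tibble::tibble(probe_id = c("b"), direction = c("down"))
  cl <- classify_factor(tot, ind, crs, direction_mode = "concordant")
  # a: same direction in mutant -> independent; b: discordant independent
  # evidence, and lower in mutant hypoxia -> dependent
  expect_identical(cl$probe_id[cl$independent_H], "a")
  expect_identical(cl$probe_id[cl$dependent_H], "b")
  # in ignore mode b is independent instead (membership only)
  cl2 <- classify_factor(tot, ind, crs, direction_mode = "ignore")
  expect_identical(cl2$probe_id[cl2$independent_H], c("a", "b"))
})

test_that("noiseless planted classes are recovered exactly by the scheme", {
  cfg <- sim_config(n_probes = 300,
                    class_fractions = c(HD = 0.1, HI = 0.1, ED = 0.1),
                    noise_sd = 0, seed = 31)
  sim <- simulate_expression(cfg)
  res <- run_full_scheme(sim$exprs, sim$samples, de_config(seed = 31))
  td <- tidy(res)
  ec <- expected_calls(sim$truth)
  m <- dplyr::inner_join(td, ec, by = "probe_id")
  expect_identical(m$HI, m$expected_HI)
  expect_identical(m$HD, m$expected_HD)
  expect_identical(m$ED, m$expected_ED)
  expect_identical(m$DM, m$expected_DM)
  # planted HD probes land in HD and never HI; HI probes the reverse
  truthy <- dplyr::inner_join(m, sim$truth, by = "probe_id")
  expect_true(all(truthy$HD[truthy$class == "HD"]))
  expect_false(any(truthy$HI[truthy$class == "HD"]))
  expect_true(all(truthy$HI[truthy$class == "HI"]))
  expect_false(any(truthy$HD[truthy$class == "HI"]))
})

test_that("HI and HD are mutually exclusive and sizes partition Total", {
  cfg <- sim_config(n_probes = 400, seed = 7)
  sim <- simulate_expression(cfg)
  res <- run_full_scheme(sim$exprs, sim$samples, de_config(seed = 3))
  g <- glance(res)
  expect_equal(g$n_HI + g$n_HIF_set2, g$n_Total)
  expect_length(intersect(res$sets$HI$probe_id, res$sets$HD$probe_id), 0)
  expect_true(all(res$sets$HD$probe_id %in% res$sets$HIF_set2$probe_id))
  expect_error(run_full_scheme(sim$exprs,
                               dplyr::filter(sim$samples,
                                             genotype != "err_mutant"),
                               de_config(), schemes = "err"), "err_mutant")
})

test_that("seeded noisy recovery matches the pilot-run fixture", {
  cfg <- sim_config(n_probes = 2000, class_fractions = c(HD = 0.10),
                    effect_range = c(2, 2), noise_sd = 0.25, seed = 42)
  sim <- simulate_expression(cfg)
  res <- run_full_scheme(sim$exprs, sim$samples, de_config(seed = 42),
                         schemes = "hif")
  m <- dplyr::inner_join(tidy(res), expected_calls(sim$truth), "probe_id")
  sens <- sum(m$HD & m$expected_HD) / sum(m$expected_HD)
  fdr <- sum(m$HD & !m$expected_HD) / max(1, sum(m$HD))
  expect_identical(nrow(res$sets$HD), 201L)
  expect_identical(nrow(res$sets$Total), 208L)
  expect_equal(sens, 1)
  expect_equal(fdr, 1 / 201)
})

test_that("concordance calls honour per-genotype strict/relaxed gates", {
  mk <- function(fc, q) {
    out <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                          mean_log2_a = 0, mean_log2_b = 0,
                          fold_change = fc, q_value = q)
    class(out) <- c("sam_de", class(out))
    out
  }
  de <- list(control = mk(c(2, 2, 1.0), c(0.005, 0.03, 0.0001)),
             err_mutant = mk(c(2, -2, 1.0), c(0.005, 0.03, 0.0001)))
  calls <- concordance_calls(de, strict_q = 0.01,
                             relaxed_q = c(err_mutant = 0.05))
  ctrl <- dplyr::filter(calls, genotype == "control")
  mut <- dplyr::filter(calls, genotype == "err_mutant")
  # q = 0.03 fails the strict gate but passes the relaxed one
  expect_identical(ctrl$state, c("up", "none", "none"))
  expect_identical(mut$state, c("up", "down", "none"))
  expect_identical(unique(ctrl$gate_used), "strict")
  expect_identical(unique(mut$gate_used), "relaxed")
  # |fold| = 1 is never called regardless of q
  expect_identical(calls$state[calls$probe_id == "p3"], c("none", "none"))
  expect_error(concordance_calls(de, strict_q = 0.05,
                                 relaxed_q = c(err_mutant = 0.01)),
               "relaxed")
})
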