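## Synthetic factorial hypoxia datasets with planted factor-dependency
## classes. The generator emulates an RMA-style log2 expression matrix for a
## genotype x oxygen design, a metabolite abundance table with
## below-detection censoring, and a qPCR Ct table — each with a ground-truth
## record so recovery by the downstream pipeline can be scored.

SIM_CLASSES <- c("HI", "HD", "ED", "HD_ED", "DM_only",
                 "negative_regulation", "null")

SIM_GENOTYPES <- c("control", "hif_mutant", "err_mutant", "double_mutant")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the reference design: four genotypes (wild-type control,
#' a HIF-alpha loss-of-function mutant, an ERR mutant and the double mutant),
#' normoxia vs. a single 6-h hypoxia exposure, three biological replicates per
#' genotype-by-oxygen cell, additive Gaussian noise on the log2 scale, and
#' log2 hypoxic-induction effects drawn from +/- Uniform(0.8, 3) so that most
#' planted responders clear a 1.5-fold gate without saturating it.
#'
#' @param n_probes Number of probe sets to simulate.
#' @param replicates_per_cell Biological replicates per genotype-by-oxygen
#'   cell (>= 2).
#' @param genotypes Subset of `control`, `hif_mutant`, `err_mutant`,
#'   `double_mutant`.
#' @param class_fractions Named fractions of probes assigned to each planted
#'   dependency class (`HI`, `HD`, `ED`, `HD_ED`, `DM_only`,
#'   `negative_regulation`); the remainder is the null class. Must sum to
#'   <= 1.
#' @param effect_range Range of the absolute log2 hypoxic effect; signs are
#'   assigned per probe (up/down with equal probability).
#' @param baseline_range Range of baseline log2 intensities (uniform), spanning
#'   the bulk of an RMA-normalized array.
#' @param noise_sd Within-group standard deviation, log2 units. The source
#'   arrays do not report a within-group variance; 0.25 log2 units is a
#'   typical replicate scatter for RMA-summarized arrays and is the default.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#'   Per-stage sub-seeds (metabolites, Ct) are derived from it.
#' @param n_compounds,metabolite_replicates,detection_floor Metabolite stage:
#'   number of compounds, replicates per treatment group (the reference
#'   design measured six), and the abundance below which a measurement is
#'   censored as undetected.
#' @param negative_factor Factor (`"hif"` or `"err"`) whose loss *amplifies*
#'   induction for the `negative_regulation` class.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000,
                       replicates_per_cell = 3,
                       genotypes = SIM_GENOTYPES,
                       class_fractions = c(HD = 0.05, HI = 0.05, ED = 0.05,
                                           HD_ED = 0.02, DM_only = 0.02,
                                           negative_regulation = 0.01),
                       effect_range = c(0.8, 3.0),
                       baseline_range = c(5, 12),
                       noise_sd = 0.25,
                       seed = 1L,
                       n_compounds = 60,
                       metabolite_replicates = 6,
                       detection_floor = 1000,
                       negative_factor = "err") {
  if (length(genotypes) == 0 || !all(genotypes %in% SIM_GENOTYPES)) {
    abort(paste0("`genotypes` must be a nonempty subset of: ",
                 paste(SIM_GENOTYPES, collapse = ", ")))
  }
  if (!"control" %in% genotypes) {
    abort("`genotypes` must include \"control\" (the reference background).")
  }
  if (replicates_per_cell < 2) abort("`replicates_per_cell` must be >= 2.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (detection_floor <= 0) abort("`detection_floor` must be > 0.")
  if (length(class_fractions)) {
    bad <- setdiff(names(class_fractions), setdiff(SIM_CLASSES, "null"))
    if (length(bad)) {
      abort(paste0("Unknown dependency class(es): ",
                   paste(bad, collapse = ", ")))
    }
    if (any(class_fractions < 0) || sum(class_fractions) > 1 + 1e-12) {
      abort("`class_fractions` must be nonnegative and sum to <= 1.")
    }
  }
  if (!negative_factor %in% c("hif", "err")) {
    abort("`negative_factor` must be \"hif\" or \"err\".")
  }
  structure(
    list(n_probes = as.integer(n_probes),
         replicates_per_cell = as.integer(replicates_per_cell),
         genotypes = genotypes,
         class_fractions = class_fractions,
         effect_range = effect_range,
         baseline_range = baseline_range,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         n_compounds = as.integer(n_compounds),
         metabolite_replicates = as.integer(metabolite_replicates),
         detection_floor = detection_floor,
         negative_factor = negative_factor),
    class = "sim_config")
}

## Per-class effect multiplier in a genotype. HIF is functional in control
## and err_mutant; ERR in control and hif_mutant. The negative-regulation
## class doubles the effect where the named repressing factor is absent.
class_multiplier <- function(class, genotype, negative_factor = "err") {
  hif_ok <- genotype %in% c("control", "err_mutant")
  err_ok <- genotype %in% c("control", "hif_mutant")
  factor_ok <- if (negative_factor == "hif") hif_ok else err_ok
  switch(class,
    null = rep(0, length(genotype)),
    HI = rep(1, length(genotype)),
    HD = as.numeric(hif_ok),
    ED = as.numeric(err_ok),
    HD_ED = as.numeric(hif_ok & err_ok),
    DM_only = as.numeric(genotype != "double_mutant"),
    negative_regulation = ifelse(factor_ok, 1, 2),
    abort(paste0("Unknown dependency class: ", class)))
}

sim_sample_sheet <- function(genotypes, reps, oxygen = c("normoxia", "hypoxia")) {
  grid <- expand.grid(replicate = seq_len(reps), oxygen = oxygen,
                      genotype = genotypes, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste(grid$genotype, grid$oxygen, grid$replicate, sep = "_"),
    genotype = grid$genotype, oxygen = grid$oxygen,
    replicate = as.integer(grid$replicate))
}

#' Simulate a factorial log2 expression matrix with planted dependencies
#'
#' Draws baseline log2 intensities per probe, assigns each probe a dependency
#' class, and adds the probe's signed log2 hypoxic effect to hypoxia samples
#' of exactly the genotypes where the class rule says the response survives:
#' `HD` needs functional HIF (control, err_mutant); `ED` needs functional ERR
#' (control, hif_mutant); `HI` responds everywhere; `HD_ED` needs both
#' factors; `DM_only` is abolished only in the double mutant;
#' `negative_regulation` responds everywhere but twice as strongly where the
#' repressing factor is lost; `null` never responds. Gaussian noise
#' (`noise_sd`) is added to every observation.
#'
#' @param config A [sim_config()].
#' @return A list with `exprs` (tibble: `probe_id` + one column per sample),
#'   `samples` (the sample sheet), and `truth` (one row per probe:
#'   `probe_id`, `class`, `direction`, signed `effect_log2`, and the realized
#'   signed effect per genotype in `effect_<genotype>` columns).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_probes
  probe_id <- sprintf("probe_%05d", seq_len(n))

  counts <- floor(config$class_fractions * n)
  classes <- rep("null", n)
  if (length(counts) && sum(counts) > 0) {
    planted <- rep(names(counts), counts)
    classes[sample.int(n, length(planted))] <- sample(planted)
  }
  direction <- ifelse(classes == "null", NA_character_,
                      sample(c("up", "down"), n, replace = TRUE))
  magnitude <- runif(n, config$effect_range[1], config$effect_range[2])
  effect <- ifelse(is.na(direction), 0,
                   ifelse(direction == "down", -magnitude, magnitude))
  baseline <- runif(n, config$baseline_range[1], config$baseline_range[2])

  samples <- sim_sample_sheet(config$genotypes, config$replicates_per_cell)

  mult <- sapply(config$genotypes, function(g) {
    vapply(classes, function(cl)
      class_multiplier(cl, g, config$negative_factor), numeric(1))
  })
  mult <- matrix(mult, nrow = n,
                 dimnames = list(probe_id, config$genotypes))

  vals <- matrix(0, nrow = n, ncol = nrow(samples),
                 dimnames = list(probe_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    g <- samples$genotype[j]
    shift <- if (samples$oxygen[j] == "hypoxia") effect * mult[, g] else 0
    vals[, j] <- baseline + shift
  }
  if (config$noise_sd > 0) {
    vals <- vals + matrix(rnorm(length(vals), sd = config$noise_sd),
                          nrow = n)
  }

  truth <- tibble::tibble(probe_id = probe_id, class = classes,
                          direction = direction, effect_log2 = effect)
  for (g in config$genotypes) {
    truth[[paste0("effect_", g)]] <- unname(effect * mult[, g])
  }

  exprs <- tibble::as_tibble(as.data.frame(vals))
  exprs <- dplyr::bind_cols(tibble::tibble(probe_id = probe_id), exprs)
  list(exprs = exprs, samples = samples, truth = truth)
}

#' Expected scheme membership implied by planted truth
#'
#' Converts a truth table from [simulate_expression()] into the set
#' memberships the dual-evidence schemes *should* report, by applying the
#' scheme definitions to the noiseless planted effects: a probe belongs to
#' the factor-independent class when it responds in both control and the
#' mutant, and to the factor-dependent class when it responds in control,
#' fails to respond in the mutant, and its hypoxic level differs between
#' control and mutant by at least the fold gate. Note that a planted `ED`
#' probe is, by construction, also HIF-independent (it responds without HIF)
#' and double-mutant-dependent (its response needs ERR, absent in the double
#' mutant); this mapping encodes those implications.
#'
#' @param truth Truth tibble with `effect_<genotype>` columns.
#' @param min_abs_fold Fold gate the scheme will apply (default 1.5).
#' @return Tibble: `probe_id`, `expected_total`, `expected_HI`,
#'   `expected_HD`, `expected_ED`, `expected_DM` (logical; mutant columns
#'   present only when the genotype was simulated).
#' @export
expected_calls <- function(truth, min_abs_fold = 1.5) {
  gate <- log2(min_abs_fold)
  eff <- function(g) truth[[paste0("effect_", g)]]
  responds <- function(g) abs(eff(g)) >= gate
  out <- tibble::tibble(probe_id = truth$probe_id,
                        expected_total = responds("control"))
  scheme <- c(HI = "hif_mutant", HD = "hif_mutant",
              ED = "err_mutant", DM = "double_mutant")
  for (nm in names(scheme)) {
    g <- scheme[[nm]]
    if (!paste0("effect_", g) %in% names(truth)) next
    independent <- out$expected_total & responds(g)
    if (nm == "HI") {
      out$expected_HI <- independent
    } else {
      dependent <- out$expected_total & !independent &
        abs(eff("control") - eff(g)) >= gate
      out[[paste0("expected_", nm)]] <- dependent
    }
  }
  out
}

#' Simulate a metabolite abundance table with detection censoring
#'
#' Compound-by-sample abundances are drawn log-normally around per-group true
#' means (mean-preserving, fixed coefficient of variation). Values under
#' `detection_floor` are flagged undetected and masked to `NA`, matching how
#' a metabolomics platform reports below-threshold measurements. A per-sample
#' protein mass (for Bradford-style normalization) is included.
#'
#' @param config A [sim_config()].
#' @param group_means Optional tibble (`compound`, `genotype`, `oxygen`,
#'   `mean`, `cv`) of true group means; by default compounds get a log-normal
#'   baseline, a quarter of them a planted hypoxic shift, and a few sit near
#'   the detection floor so censoring is exercised.
#' @return List with `metabolites` (long tibble: `compound`, `sample_id`,
#'   `genotype`, `oxygen`, `replicate`, `abundance`, `detected`,
#'   `protein_mass`) and `truth` (the group-mean table used).
#' @export
simulate_metabolites <- function(config = sim_config(), group_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$detection_floor <= 0) abort("`detection_floor` must be > 0.")
  set.seed(config$seed + 1L)

  if (is.null(group_means)) {
    compound <- sprintf("compound_%03d", seq_len(config$n_compounds))
    base <- rlnorm(config$n_compounds, meanlog = log(5e4), sdlog = 1)
    n_low <- min(3L, config$n_compounds)
    base[seq_len(n_low)] <- config$detection_floor *
      runif(n_low, 0.2, 1.5)
    shifted <- runif(config$n_compounds) < 0.25
    hyp_fold <- ifelse(shifted,
                       2^(sample(c(-1, 1), config$n_compounds, TRUE) *
                            runif(config$n_compounds, 1, 2)), 1)
    grid <- expand.grid(compound = compound, genotype = config$genotypes,
                        oxygen = c("normoxia", "hypoxia"),
                        stringsAsFactors = FALSE)
    idx <- match(grid$compound, compound)
    group_means <- tibble::tibble(
      compound = grid$compound, genotype = grid$genotype,
      oxygen = grid$oxygen,
      mean = base[idx] * ifelse(grid$oxygen == "hypoxia", hyp_fold[idx], 1),
      cv = 0.25)
  }
  if (!all(c("compound", "genotype", "oxygen", "mean") %in%
             names(group_means))) {
    abort("`group_means` needs columns compound, genotype, oxygen, mean.")
  }
  if (is.null(group_means$cv)) group_means$cv <- 0.25

  samples <- sim_sample_sheet(unique(group_means$genotype),
                              config$metabolite_replicates,
                              oxygen = unique(group_means$oxygen))
  samples$protein_mass <- runif(nrow(samples), 80, 120)

  long <- tidyr::crossing(group_means,
                          replicate = seq_len(config$metabolite_replicates))
  long <- dplyr::left_join(long, samples,
                           by = c("genotype", "oxygen", "replicate"))
  sdlog <- sqrt(log(1 + long$cv^2))
  draw <- rlnorm(nrow(long), meanlog = log(pmax(long$mean, .Machine$double.xmin)) -
                   sdlog^2 / 2, sdlog = sdlog)
  long$abundance <- ifelse(long$mean <= 0, 0, draw)
  long$detected <- long$abundance >= config$detection_floor
  long$abundance[!long$detected] <- NA_real_

  metabolites <- dplyr::select(long, "compound", "sample_id", "genotype",
                               "oxygen", "replicate", "abundance",
                               "detected", "protein_mass")
  metabolites <- dplyr::arrange(metabolites, .data$compound,
                                .data$genotype, .data$oxygen, .data$replicate)
  list(metabolites = metabolites, truth = group_means)
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow `ct = 34 - log2(expression) + noise`, so a doubling of
#' expression costs one cycle. The reference gene (`rp49` by default) has
#' constant expression across all conditions; target genes carry a log2
#' hypoxic induction applied in hypoxia samples.
#'
#' @param config A [sim_config()].
#' @param genes Optional tibble (`gene`, `effect_log2`, `base_log2`) of
#'   target genes; defaults to four hypoxia-responsive targets.
#' @param reference_gene Name of the normalizer gene (always added, constant).
#' @param ct_noise_sd Technical noise on Ct, in cycles.
#' @return Long tibble: `sample_id`, `genotype`, `oxygen`, `replicate`,
#'   `gene`, `ct`, with the reference gene recorded in attribute
#'   `reference_gene`.
#' @export
simulate_ct <- function(config = sim_config(), genes = NULL,
                        reference_gene = "rp49", ct_noise_sd = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene = c("ldh", "fatiga", "pfk", "nmnat"),
      effect_log2 = c(2, 3, 1.5, 1),
      base_log2 = c(7, 6, 8, 7))
  }
  if (reference_gene %in% genes$gene) {
    abort("`reference_gene` must not appear among the target genes.")
  }
  genes <- dplyr::bind_rows(
    genes,
    tibble::tibble(gene = reference_gene, effect_log2 = 0, base_log2 = 10))

  samples <- sim_sample_sheet(config$genotypes, config$replicates_per_cell)
  long <- tidyr::crossing(samples, genes)
  expr <- long$base_log2 +
    ifelse(long$oxygen == "hypoxia", long$effect_log2, 0)
  long$ct <- 34 - expr +
    (if (ct_noise_sd > 0) rnorm(nrow(long), sd = ct_noise_sd) else 0)
  out <- dplyr::select(long, "sample_id", "genotype", "oxygen",
                       "replicate", "gene", "ct")
  attr(out, "reference_gene") <- reference_gene
  out
}
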