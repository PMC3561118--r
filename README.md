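# hifdep

Which transcription factor does a hypoxic transcriptional response run
through? `hifdep` answers that question for factorial genotype-by-oxygen
expression designs: wild-type controls, a HIF-alpha mutant, an ERR mutant
and the double mutant, each profiled under normoxia and hypoxia. It is
aimed at transcriptomics analysts who have a normalized log2 expression
matrix (RMA-style) plus a sample sheet and want per-transcript dependency
calls, not just per-comparison gene lists.

## What it computes

**Differential expression.** A SAM-style regularized relative difference
per probe,

    d = (mean_b − mean_a) / (s + s0)

with `s` the pooled standard error and `s0` a data-driven fudge factor
(coefficient-of-variation minimization over percentile candidates of `s`).
Per-probe q-values come from label permutations — exhaustively enumerated
whenever the design is small enough (a 3-vs-3 comparison has only 20
assignments, so results are deterministic), sampled with a seed otherwise.
Gene sets are gated jointly on |fold| ≥ 1.5 (signed convention: −2 means
halved) and a per-comparison FDR threshold.

**Dependency classification.** For each factor F with mutant M, the
dual-evidence scheme combines three gated comparisons:

    independent_H = Total ∩ F-independent        (responds without F)
    candidate_set2 = Total − independent_H
    dependent_H   = cross ∩ candidate_set2       (two lines of evidence)

where `Total` is the control N-vs-H response, `F-independent` the mutant
N-vs-H response, and `cross` the direct control-H vs mutant-H comparison.
Run against the HIF mutant this yields the mutually exclusive
HIF-independent (HI) and HIF-dependent (HD) sets; against the ERR mutant,
ED; against the double mutant, DM.

**Supporting statistics.** Cumulative hypergeometric overlap tests and
Venn partitions of the resulting sets, hypergeometric term enrichment with
BH correction, metabolomics below-detection imputation / protein
normalization / relative-log2 heat-map values / per-compound ANOVA with
contrasts, and ΔCT qPCR quantification with Bonferroni-corrected t-tests.

**Synthetic ground truth.** `simulate_expression()` plants dependency
classes (HD, HI, ED, both-required, double-mutant-only, negative
regulation) with known effects, so the whole pipeline is validated by
recovery against truth; `simulate_metabolites()` and `simulate_ct()` do the
same for the other stages.

## Worked example

```r
library(hifdep)
library(dplyr)

cfg <- sim_config(n_probes = 2000, seed = 1)   # 4 genotypes x 2 oxygen x 3 reps
sim <- simulate_expression(cfg)
res <- run_full_scheme(sim$exprs, sim$samples, de_config(seed = 1))
res
#> Factor-dependency classification (2000 probes)
#>   Total                409
#>   ...
#>   HI                   257
#>   HD                   139
#>   ED                   140
#>   DM                   278

inner_join(tidy(res), expected_calls(sim$truth), by = "probe_id") |>
  summarise(hd_sens = sum(HD & expected_HD) / sum(expected_HD),
            hd_fdr  = sum(HD & !expected_HD) / sum(HD))
#>   hd_sens  hd_fdr
#> 1   0.986 0.00719

overlap_tests(res$sets[c("HI", "HD", "ED")], length(res$universe))
#>   set_a set_b set_a_size set_b_size overlap_k universe_n      p_value
#> 1    HI    HD        257        139         0       2000 1.000000e+00
#> 2    HI    ED        257        140        96       2000 3.882987e-59
#> 3    HD    ED        139        140        40       2000 1.386288e-16
```

Reading the output: of 2000 simulated probes, 409 respond to hypoxia in the
control background; the scheme splits them into 257 HIF-independent and 139
HIF-dependent transcripts (mutually exclusive by construction — their
overlap is 0 and its hypergeometric p is 1). HD recovery against the
planted truth is 98.6% sensitive with a 0.7% false-discovery fraction. The
strongly significant HI∩ED overlap (96 transcripts) is the signature the
design exists to detect: a large part of the HIF-independent hypoxic
response is ERR-dependent. The HD∩ED overlap (40) is exactly the planted
"requires both factors" class.

The top of a differential result looks like:

```r
arrange(tidy(res$de$control_N_vs_H), q_value, desc(abs(fold_change))) |> head(3)
#>   probe_id    mean_log2_a mean_log2_b fold_change     d q_value
#> 1 probe_01304        5.73        9.10       10.4   5.07       0
#> 2 probe_01216        9.02       12.3         9.65  6.28       0
#> 3 probe_01043       11.3         8.06       -9.51 -4.82       0
```

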