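---
title: "Classifying hypoxia-responsive transcripts by factor dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hypoxia-responsive transcripts by factor dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifdep)
library(dplyr)
```

## The scientific problem

When an animal is shifted into low oxygen, hundreds of transcripts change.
The classical driver of that response is HIF, the oxygen-labile
hypoxia-inducible factor (encoded by *sima* in *Drosophila*), but a
substantial part of the hypoxic transcriptome — notably the glycolytic
program — can be driven instead by the estrogen-related receptor (dERR), or
by both factors together. A factorial design disentangles this: profile
wild-type animals, a HIF mutant, an ERR mutant and the double mutant, each
under normoxia and a single hypoxic exposure, and ask for every transcript
*which* genotype still mounts the response.

`hifdep` implements that analysis end to end: SAM-style permutation
differential expression with fold-change and FDR gating, the dual-evidence
set-logic schemes that classify each hypoxia-responsive transcript as
HIF-independent (HI), HIF-dependent (HD), ERR-dependent (ED) or
double-mutant-dependent (DM), overlap and enrichment statistics, and the
companion metabolomics and qPCR stages. A synthetic-data generator with
planted dependency classes makes every stage testable against known ground
truth.

## Differential expression: the regularized d statistic

For a two-group comparison "a vs b" (b reported relative to a) each probe
gets

$$ d = \frac{\bar{x}_b - \bar{x}_a}{s + s_0}, \qquad
   s = \sqrt{\left(\tfrac{1}{n_a}+\tfrac{1}{n_b}\right)
   \frac{SS_a + SS_b}{n_a + n_b - 2}} $$

where $s$ is the pooled standard error of the mean difference and $s_0$ a
small additive "fudge factor" that stops near-zero-variance probes from
dominating the ranking. By default $s_0$ is chosen by the standard
coefficient-of-variation minimization: candidates are the 5-percentile
steps of the $s$ distribution; for each candidate the MAD of $d$ is
computed inside quantile windows of $s$, and the candidate minimizing the
coefficient of variation of those MADs wins. Degenerate inputs are handled
explicitly: an all-constant $s$ distribution returns the median $s$, and in
noiseless data ($s + s_0 = 0$) the statistic is $0$ for a zero difference
and signed infinity otherwise, which keeps the permutation machinery
well-defined in the zero-noise recovery tests.

Significance is permutation-based. For probe $i$ with threshold
$t_i = |d_i|$,

$$ q_i = \mathrm{median}_\pi \;
   \#\{j : |d^{*\pi}_j| \ge t_i\} \; / \; \#\{j : |d_j| \ge t_i\} $$

clipped to $[0,1]$, with monotonicity enforced so that $q$ never increases
with $|d|$. Ties count as exceedances (`tie_rule = "geq"`), the conservative
choice. When the number of distinct group-label assignments is at most
`exhaustive_limit` (10,000 by default — a 3-vs-3 design has only 20) every
assignment is enumerated and the result is fully deterministic; larger
designs fall back to seeded sampling. The test suite checks the enumerated
q-values against an independent brute-force oracle and checks that sampled
q-values converge to the enumerated ones.

Fold changes are computed from the log2 group means (a geometric mean on
the linear scale, matching RMA-style log2 intensities) and displayed with
the signed convention: $+r$ for $r \ge 1$, $-1/r$ otherwise, so a halving
reads $-2$. A probe enters a gene set only if it passes *both* gates:
$|\mathrm{fold}| \ge 1.5$ and $q$ below the per-comparison FDR threshold.

## The dual-evidence dependency schemes

For a factor F with mutant M, three gated comparisons feed the scheme:

* **Total** — control normoxia vs. control hypoxia (the hypoxic response);
* **F-independent** — mutant normoxia vs. mutant hypoxia;
* **cross** — control hypoxia vs. mutant hypoxia.

Then

* `independent_H = Total ∩ F-independent` (responds without F),
* `candidate_set2 = Total − independent_H`,
* `dependent_H = cross ∩ candidate_set2`.

The dependent call therefore needs two independent lines of evidence: the
response disappears in the mutant, *and* the mutant's hypoxic level differs
directly from the control's. Independent and dependent calls are mutually
exclusive by construction, and `|independent_H| + |candidate_set2| =
|Total|` is asserted as a package invariant. Run with the HIF mutant the
scheme yields HI/HD; with the ERR mutant, ED; with the double mutant, DM.
DM is built independently from the double-mutant comparisons rather than
derived from HD ∪ ED, because loss of both factors can reveal dependencies
neither single mutant shows.

`run_full_scheme()` wires the seven comparisons together with the
per-comparison FDR gates used as defaults (fractions 0.00733, 0.00414,
0.00721, 0.0784, 0.00619, 0.00662, 0.00703; fold gate 1.5 everywhere). The
one loose gate (7.84%) belongs to the ERR-mutant N-vs-H comparison — the
*independent* evidence of the ERR scheme — where a looser gate makes the
final ED call more conservative, since anything that scrapes into the
independent set is removed from the dependent candidates.

Two genuinely open design choices are exposed rather than hard-coded:

* **Direction concordance.** By default intersections are membership-only
  (`direction_mode = "ignore"`). In `"concordant"` mode an independent call
  additionally requires the same direction in control and mutant, and a
  dependent call requires the cross-comparison direction opposite to the
  hypoxic direction (an induced transcript must sit *lower* in the mutant's
  hypoxia samples). Membership-only is the default because the scheme's
  published description is set algebra on gated lists; concordant mode is
  available for stricter analyses.
* **Classification unit.** Probes (probe sets), not genes; any gene-level
  collapsing is left to the user.

`concordance_calls()` produces the companion tri-state (up/down/none) view
per genotype, with an optional per-genotype relaxed FDR gate (the original
analysis relaxed some backgrounds from <1% to 1–5%); a relaxed gate
stricter than the strict gate is rejected.

## Overlap and enrichment statistics

Set overlaps are tested with the cumulative hypergeometric upper tail,
inclusive at the observed count: $p = P(X \ge k)$ for population $N$,
$|A|$ successes and $|B|$ draws. The universe defaults to the number of
probes in the analyzed matrix and is configurable, since the appropriate
reference (whole array vs. expressed probes) is a judgment call; the choice
is recorded in the pipeline manifest. `venn_partition()` gives the
exhaustive disjoint regions for two or three sets, and `enrich_terms()`
runs the same hypergeometric test per annotation term with
Benjamini–Hochberg q-values across the tested terms. Ontology structure
(DAG propagation, term redundancy) is out of scope — enrichment runs on
whatever flat term-to-probe table is supplied.

## Metabolomics stages

The metabolite pipeline is ordered impute → protein-normalize → log2 →
model, and the modelling steps refuse tables that still contain masked
values, so the order cannot silently be skipped; each step also records
itself in the `metab_steps` attribute.

* **Imputation.** Written for six replicates per group in the reference
  design and generalized to any group size: a group whose replicates are
  *all* undetected receives the minimum detected value across all compounds
  (read as a global post-hoc detection floor, since instrument-specific
  limits are not available); a group with at least one detected replicate
  receives that compound's minimum detected value. Detected entries are
  never altered, and no imputed value can fall below the global detected
  minimum.
* **Normalization.** Division by per-sample protein mass.
* **Heat-map values.** Group means are taken arithmetically on the linear
  normalized scale and then logged relative to the control-normoxia mean
  (log2 of the average, not the average of logs), so the reference group is
  identically zero.
* **Inference.** One model per compound: a one-way ANOVA across all
  genotype-by-oxygen groups, with the stated pairwise contrasts tested
  against the pooled residual variance, and BH q-values per contrast across
  compounds. Fitting one pooled model (rather than a separate two-group
  test per contrast) is the default because it matches "one-way ANOVA with
  contrasts"; per-pair tests can be had by passing a single-row contrast
  table to a subsetted table.

## qPCR stages

Relative expression is $2^{-\Delta C_T}$ against a reference gene (rp49 by
default), assuming doubling efficiency — the standard ΔCT method without
efficiency correction. The hypoxia/normoxia fold change is the ratio of
mean relative expressions (1.0 = no net response). Hypothesis tests are
two-tailed unpaired t-tests on ΔCT (equal-variance by default, Welch via
`var_equal = FALSE`) with Bonferroni adjustment `min(1, p·m)`; the family
size `m_tests` must be given explicitly because it is a reporting decision
(per gene? per stage?) that cannot be inferred from the table, and it is
echoed in the output.

## The synthetic-data generator

`simulate_expression()` emulates the statistical skeleton of an
RMA-normalized factorial experiment: per-probe baselines uniform on
[5, 12] log2 units, additive Gaussian noise (0.25 log2 units by default —
the source arrays report no within-group variance, so this is a choice,
exposed in `sim_config()` and typical of replicate scatter on summarized
arrays), three replicates per genotype-by-oxygen cell, and planted
dependency classes whose hypoxic log2 effect is added exactly in the
genotypes where the class rule says the response survives. Effects are
drawn from ±Uniform(0.8, 3.0) so most responders clear the 1.5-fold gate
(log2 ≈ 0.585) without saturating the recovery tests. A
`negative_regulation` class doubles the effect where the named repressing
factor is lost, emulating transcripts for which losing one factor is more
consequential than losing both. One RNG stream per dataset is seeded from
`sim_config(seed=)`; the metabolite and Ct stages derive their sub-seeds
deterministically, so identical configs give bit-identical datasets.

`expected_calls()` converts planted truth into the memberships the schemes
*should* produce — including the cross-scheme implications (a planted
ED transcript is also HIF-independent and double-mutant-dependent) — which
is what recovery is scored against.

What the generator does **not** emulate: probe-level CEL structure, spatial
artifacts, intensity-dependent variance, cross-hybridizing probe sets,
correlated genes, or developmental time courses. Passing recovery tests
therefore show that the inference machinery is correct under the model's
assumptions (symmetric log-scale noise, independent probes), not that real
arrays meet those assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 20,000 probes × 24 samples
for noisy recovery (5% each HD/HI/ED at |log2 effect| ≥ 1.5), 10,000 null
probes for gate calibration, 2,000 probes for the zero-noise exact-recovery
check, and 25–40-probe 3-vs-3 matrices for the brute-force permutation
oracle — sizes at which exhaustive enumeration (20 assignments) keeps every
q-value deterministic. Other numerical decisions: permutation tie counting
is inclusive; q-monotonicity is enforced by a running minimum down the |d|
ranking; the s0 grid search skips candidates with undefined CV and falls
back to the median s if none is usable; gene-set files are written with
lexicographically sorted members so outputs are byte-stable; and
`run_pipeline()` writes a manifest (seed, gates, universe, MD5 of every
output) from which a rerun reproduces the outputs byte-for-byte.

## Known limitations

* The scheme cannot flag transcripts that respond in *both* control and
  mutant but with different magnitude (they land in the independent set);
  the negative-regulation simulation class exists precisely to document
  this blind spot.
* Permutation q-values from 20 exhaustive assignments are granular; very
  small designs cannot resolve q below ~1/20 except through the
  across-probe pooling in the numerator.
* Probe sets mapping multiple genes are treated as single units.
* RMA normalization, GO acquisition and platform chemistry are upstream of
  this package: it consumes normalized matrices and flat annotation tables.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_probes = 2000, seed = 1)
sim <- simulate_expression(cfg)
res <- run_full_scheme(sim$exprs, sim$samples, de_config(seed = 1))
glance(res)
autoplot(res)

m <- inner_join(tidy(res), expected_calls(sim$truth), by = "probe_id")
summarise(m, hd_sens = sum(HD & expected_HD) / sum(expected_HD))

overlap_tests(res$sets[c("HI", "HD", "ED")], length(res$universe))
```
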