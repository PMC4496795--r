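---
title: "Quantifying TF–miRNA regulatory rewiring between normal and tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TF-miRNA regulatory rewiring between normal and tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrewire)
```

## The model

Transcription factors (TFs) activate or repress transcription; miRNAs
repress and fine-tune their targets post-transcriptionally. Together they
form a typed directed network in which four regulation classes matter:
unidirectional TF regulation (`TFout`), unidirectional miRNA regulation
(`miRout`), reciprocal TF–TF circuits (`BiTT`), and reciprocal TF–miRNA
feedback loops (`BiTM`). A `BiTM` loop in which the TF activates the miRNA
while the miRNA represses the TF is a negative feedback device: in healthy
tissue the two sides hold each other near equilibrium, so their measured
co-expression is weak; if the TF is overexpressed in tumor, it can overrun
the miRNA's fine-tuning and the pair becomes strongly positively
correlated. Detecting exactly this signature — a feedback pair whose
co-expression changes consistently between conditions across many cohorts
— is the purpose of the pipeline.

The working statistic is condition-specific standardized co-expression.
For each regulation, Spearman's ρ is computed over the *n* samples of one
cohort and condition in which both endpoints were profiled ("matched
samples"), then variance-stabilized and standardized:

$$z = \operatorname{arctanh}(\rho)\,\sqrt{n-3}.$$

Standardization removes the dependence of the sampling spread on *n*, so
z values are comparable across cohorts of different size. Spearman (not
Pearson) is used because expression abundances are heavy-tailed and the
statistic should be invariant under monotone transformations such as
log-scaling.

Differential co-expression of a regulation between normal and tumor is

$$D(z) = |z_N - z_T|,$$

computed for every regulation significantly correlated
($|z| \ge 2.5$) in **at least one** condition. Requiring significance in
both conditions would delete precisely the gained and lost regulations
the analysis is after; requiring it in one keeps them while still
excluding pure noise pairs. Feedback loops are then ranked by the mean of
D over all cohorts, restricted to pairs with a D value in *every* cohort —
a consistency requirement that favors pan-cancer rewiring over a large
change in a single cohort.

Rewiring of whole networks is described at two levels. First, overlap:
the Jaccard fraction of shared interactors (nodes touching a retained
regulation) versus shared interactions (retained regulations) between the
normal and tumor networks selected at the same top-k%. Interactor overlap
exceeding interaction overlap is the signature of partner switching.
Jaccard is used because the source analyses plot "proportions of the
intersection" without fixing a denominator; Jaccard is symmetric, bounded
in [0, 1], and the interactor-vs-interaction comparison is robust to that
choice. Second, per-edge rewiring types: a gained or lost regulation is
type I, II or III according to whether 2, 1 or 0 of its endpoints remain
interactors in the other condition's network.

## Thresholds and defaults

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `z_thresh` | 2.5 | Significance on the standardized z (unitless); 2.5 corresponds to a one-sided normal tail of ~0.006 (quoted as P < 0.01). The z value itself is the working quantity; it is never converted to a p-value. Inclusive: \|z\| = 2.5 passes. |
| `top_k` | 0.05, 0.10, 0.15, 0.20 | Fractions defining "highly correlated" networks for overlap/rewiring summaries. Ranking is by \|z\| (not \|ρ\|) because standardization is the sample-size correction; with constant *n* the two orders coincide. `ceiling(k·N)` records retained; ties broken by (\|z\| desc, pair key asc) for determinism. |
| `dc_fraction` | 0.10 | Fraction of eligible regulations flagged differentially co-expressed (top D(z)). |
| `de_alpha` | 0.05 | Significance for the differential-expression substitute (two-sided rank-sum; direction from log2 fold-change of mean log2(x+1)). |
| `amplitude_cutoff` | 0.67 | Drug-signature amplitude a = 2(t−c)/(\|t\|+\|c\|); a two-fold change (t = 2c, c > 0) gives a = 2/3, so 0.67 ≈ two-fold. Comparisons are strict (`a > 0.67`), and 0.67 is applied literally, not as 2/3. |
| `min_n` | 4 | Minimal matched-sample count for a finite z (`sqrt(n−3)` must be positive); the minimal mathematical requirement, not a power consideration. |

Other fixed conventions: bidirectional pairs are scored once per pair
under a canonical key (lexicographically smaller id first, C-locale
ordering) since Spearman is symmetric; a z of exactly 0 counts as
positive in the sign-activity tables; \|ρ\| = 1 is clamped to 1 − 10⁻⁷
before `arctanh` so z stays finite and ranking is preserved (clamped
records are flagged); sign-enrichment uses the 100% network of the same
scoring run as background, one-sided Fisher's exact tests at α = 0.05
with no multiplicity correction (each class/sign is reported with its raw
p, as is conventional for per-bar annotation); gene-set enrichment
reports raw hypergeometric p as the primary quantity with
Benjamini–Hochberg q alongside.

Two taxonomy decisions the four-class scheme does not settle: a
non-reciprocal TF→miRNA or TF→TF edge is `TFout` (all non-reciprocal TF
edges are "unidirectional TF to target" regardless of target kind), and a
reciprocal miRNA–miRNA pair — which the bidirectional classes, both
requiring a TF, do not anticipate — is classified as two `miRout` edges
with a warning. Class proportions for `BiTT`/`BiTM` are reported at the
pair level (each reciprocal unit counted once), which is also how scoring
works.

## The exact small-sample tests

`fisher_exact()` wraps the standard exact hypergeometric test;
`geneset_enrichment()` is its upper-tail special case computed via
`phyper`. The Wilcoxon rank-sum comparison of overlap fractions needs an
exact two-sided p **with ties** at cohort-sized samples (7 vs 7 or
smaller); `ranksum_test()` therefore enumerates all group assignments of
the pooled values for combined sizes ≤ 12 (average ranks, twice the
smaller tail, capped at 1) and falls back to the normal approximation
with tie correction above that. `fisher_combined()` is
$-2\sum\ln p_i \sim \chi^2_{2k}$. The differential-expression step is a
deliberately self-contained substitute for a count-model DE test: a
two-sided rank-sum p plus a log2 fold-change of mean log2(x+1), with the
same decision role (α = 0.05, direction by fold-change sign). It is
rank-based, hence invariant to monotone normalization, but it does not
model count dispersion; with strong normalization differences between
groups it will disagree with a negative-binomial test.

## What the synthetic generator emulates

`simulation_spec()` defaults define the study conditions used throughout
the tests: seven cohorts (named after TCGA-style tumor types purely as
labels), 60 normal + 60 tumor samples each, 250 directed regulations
(120 TFout, 100 miRout, 5 BiTT and 10 BiTM pairs) among 15 TFs, 15
miRNAs and 120 genes — sized so a full seven-cohort pipeline runs in
seconds. Regulator out-degrees are drawn by preferential attachment,
giving the heavy-tailed degree structure of real regulatory networks.
Class-default planted Spearman correlations are +0.4 (TFout), +0.5
(BiTT, BiTM) and −0.3 (miRout), identical in normal and tumor — TFs
predominantly activate, miRNAs repress, and nothing rewires unless
planted. `plant_dc_loop()` overrides one BiTM pair to ρ_N = 0, ρ_T = 0.8
with a +1 log2 tumor shift of its TF; the pair chosen is the one whose TF
has the largest unidirectional out-degree, emulating a hub regulator
whose overexpression activates a sizeable downstream program.

Expression is generated on a latent Gaussian log2 scale and exponentiated
(`2^(8 + latent)`), a monotone map that leaves Spearman correlations
untouched while keeping abundances large enough that the DE substitute's
+1 pseudocount is negligible. Planted correlations use the Gaussian
Pearson parameter `2·sin(πρ_S/6)` so the planted **Spearman** value is
exact in population. Pairs are planted in priority order (planted loop,
then BiTT, BiTM, TFout, miRout, each by pair key) with the dependent
endpoint chosen by kind (the target; the miRNA of a BiTM pair; the
later-sorting TF of a BiTT pair); a pair whose dependent endpoint was
already planted or already used as a source stays unplanted and is
recorded as a conflict in the truth record. Tumor mean shifts are applied
before planting, so a shifted regulator's overexpression propagates to
its planted targets — this is what makes the planted TF's target module
"activated" in tumor, and up-shifts the planted loop's miRNA the way a
TF-driven feedback loop would. Targets of a common regulator share its
latent factor, so they carry residual mutual correlations of order ρ², as
co-regulated genes do in real data.

Deliberately **not** emulated: count noise (negative-binomial dispersion),
batch effects, normalization artifacts, identifier mapping, and
biological network motifs beyond degree heterogeneity. Passing tests on
this generator therefore demonstrate the statistical machinery — ranking,
calibration, conservation, recovery — not robustness to the technical
noise of real RNA-seq; on real data the usual upstream normalization and
QC remain the user's responsibility.

`generate_annotations()` draws cancer-association labels at a default
fraction of 0.15 of nodes (roughly the order of curated cancer-gene lists
relative to profiled genes), optionally forcing the planted loop's
endpoints — and, via `force_pairs`, any listed pairs through their
low-degree target endpoints — to be annotated, which creates the expected
over-representation of cancer-associated regulations among DC pairs
without blanketing the background through hub regulators. The drug
fixture spans known up/down/neutral amplitude classes, including the
strict-boundary case t = 2c (a = 2/3, *not* classified up at the literal
0.67 cutoff).

## Numerical and degenerate-input conventions

All string ordering uses C-locale (radix) collation so canonical pair
keys and tie-breaks never depend on the session locale. Every generator
and pipeline output is a pure function of (spec, seed); `run_pipeline()`
derives per-stage substreams from the single config seed, and double runs
are byte-identical (asserted by digest comparison in the tests).
Degenerate inputs signal rather than crash where the scientific
convention is to skip: constant expression vectors, missing features and
n < 4 edges become logged skip records; t = c = 0 drug signatures become
NA with a warning; an empty overlap comparison warns and reports 0;
ineligible D(z) pairs are returned with reasons (`missing_condition`,
`not_significant`). Hard errors are reserved for structural problems:
gene-kind regulators, unknown node kinds, malformed files, empty
backgrounds or universes, cohorts with no samples.

## Problem sizes used by the test suite

Unit tests run on networks of tens of edges. The statistical suites use:
10,000 null edges at n = 60 for calibration of the |z| ≥ 2.5 rule
(expected exceedance 2·(1−Φ(2.5)) ≈ 0.0124, asserted within 3 Monte-Carlo
standard errors); exhaustive enumeration of all 2×2 tables with N ≤ 40
against the exact-test implementation; 100 seeded replicates of the full
seven-cohort, 250-edge planted-loop recovery (asserting rank 1 in ≥ 95);
and 200 seeds for enrichment calibration (Kolmogorov–Smirnov uniformity
at α = 0.01). These sizes were chosen so each suite pins its property
with comfortable Monte-Carlo margins while the whole suite stays in the
low minutes on a laptop core.

## Known limitations

* D(z) compares z scores whose null variance under Spearman is ~6% larger
  than the Gaussian 1/(n−3); the |z| ≥ 2.5 rule is therefore very
  slightly anti-conservative, which the calibration suite quantifies.
* Eligibility in every cohort is a hard requirement for the feedback-loop
  ranking; a loop absent (or unprofiled) in one cohort is reported in the
  `partial` attribute but never ranked.
* The rewiring-type classification depends on the selection rule (top-k%)
  through which endpoints count as "retained"; it is meaningful only when
  both condition networks are selected under the same rule, which
  `run_pipeline()` enforces.
* Per-category CN/NC/CC enrichment tests each category's share among DC
  BiTM pairs against the non-DC background share; with few BiTM pairs the
  exact tests are discrete and conservative.
* The gained/lost split of rewiring types is reported alongside the
  pooled percentages; cross-cohort summaries in `run_pipeline()` pool
  them.
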