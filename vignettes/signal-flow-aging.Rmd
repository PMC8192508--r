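---
title: "Signal-flow analysis of aging methylation and expression on signed regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-flow analysis of aging methylation and expression on signed regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingflow)
library(dplyr)
```

## The problem

DNA methylation at CpG sites drifts steadily with age, and part of that
drift sits in the regulatory neighbourhood of transcription factor (TF)
genes. If an age-associated methylation change tracks the expression of a
nearby TF, the TF's activity can be treated as an *input signal* that
propagates through the gene regulatory network (GRN) and ends at genes whose
expression itself changes with age. Once the network explains which inputs
drive which differentially expressed genes (DEGs), two in-silico questions
follow: which *intermediate* network nodes, if pushed up or down, would
steer the DEGs back against their aging direction, and which drug
perturbation profiles already do so.

`agingflow` implements that chain as composable, tested steps:

1. **markers** — call age-associated differentially methylated positions
   (DMPs) and DEGs, link DMPs to TF genes within 5 kb, and quantify overlap
   with known marker panels by a hypergeometric test;
2. **network** — cut the input-to-output subnetwork out of a canonical GRN
   and assign each edge a mode of action (activation/inhibition) from
   expression partial correlations;
3. **sfa** — propagate per-sample methylation-derived inputs to steady-state
   activities;
4. **targets** — classify DEGs by direction-of-activity-change (DAC)
   consistency and rank intermediate nodes as reverse-aging targets;
5. **screen** — score perturbagen modZ profiles for signature reversal.

A synthetic-data module generates cohorts, omics matrices, ground-truth
networks and drug profiles with planted effects, so every stage is testable
end to end without access to restricted human data.

## The signal-flow model

The network is a directed graph of TF→target edges, each carrying a sign
$s \in \{-1,+1\}$. Activities follow the damped linear fixed point

$$x = \alpha W x + (1-\alpha)\, b, \qquad
  W_{ij} = \frac{s(j \to i)}{d_{\mathrm{in}}(i)},$$

where $b$ holds the basal (input) signals and $\alpha \in [0,1)$ balances
upstream flow against basal activity ($\alpha = 0.5$ by default). Because
each row of $|W|$ sums to at most 1, $\alpha W$ is a contraction and the
solution $x = (1-\alpha)(I - \alpha W)^{-1} b$ is unique; the package
computes it by a direct linear solve and cross-checks it against Jacobi
iteration in the test suite. Linearity gives three properties the tests
exploit: superposition over inputs, exact antisymmetry ($x(-b) = -x(b)$),
and a per-input contribution decomposition whose columns sum to the joint
solution.

Two modelling choices here were genuinely open and are package decisions:

* **Weight normalisation.** The upstream method literature states the
  fixed-point form but not the exact normalisation; `agingflow` uses
  $1/d_{\mathrm{in}}$, which shares a node's in-weight equally among its
  regulators and guarantees convergence for every $\alpha < 1$.
* **Input injection.** Methylation-derived signals enter through the basal
  term $b$, not as clamped node states, so $\alpha$ retains its advertised
  meaning of balancing flow against basal activity.

Per sample, each representative DMP's beta value is expressed as a cohort
Z-score for its position, scaled to $[-1, 1]$ by the maximum absolute
Z-score over samples (max-abs scaling — monotone, odd, and attains the
stated range; the map itself was unspecified upstream), and signed by the
direction of the DMP-TF correlation.

## Marker calling

DMPs are Pearson correlations of beta value with age, tested two-sidedly by
the t transform and deliberately **not** multiple-testing corrected —
with millions of CpGs against a few dozen samples the correction would
leave nothing, and raw-P DMP calling is the accepted practice the pipeline
mirrors. Zero-variance positions are excluded as untestable rather than
assigned $p = 1$, since their correlation is undefined.

DEGs come from a per-gene negative-binomial GLM with log link on
`~ age + sex` with a median-of-ratios library-size offset, method-of-moments
dispersion (floored at $10^{-8}$), a Wald test on the age coefficient, and
Benjamini–Hochberg correction. This is a transparent stand-in for the
standard DESeq2 analysis (age continuous, sex covariate): it reproduces the
design without re-implementing shrinkage estimators, and a test
cross-checks it against DESeq2 itself (log2-fold-change correlation > 0.99
on the synthetic study). Sex is removed from methylation by a location-only
two-group adjustment (each sex's per-position mean shifted to the pooled
mean) — a deliberate simplification of empirical-Bayes batch correction
that is exact for a two-level batch variable affecting only the mean.

DMP-TF links are Pearson correlations between beta values and size-factor
normalised log2 expression. A CpG is a candidate for a TF when its distance
to the TSS *or* to the gene-body interval is at most 5 kb (inclusive; "within
5 kb" read inclusively, with distance = min of the two). Normalised rather
than raw expression is used because the correlation should not be driven by
library size. Per TF, the smallest-P link is the *representative* (ties
broken by larger |r|, then DMP id), and only representatives feed the
signal-flow inputs.

Marker-panel overlap uses the upper-tail hypergeometric probability
$P(X \ge k)$ computed in log space, so enrichments around $10^{-35}$ do not
underflow:

```{r hypergeom}
overlap_enrichment(2682537, 32, 222032, 32)
overlap_enrichment(19229, 50, 188, 20)
```

## Network reconstruction

From a canonical (unsigned) edge list, the aging subnetwork keeps the input
TFs, output DEGs, and every node that is reachable from an input *and*
reaches an output — a strict path-membership reading of "via which inputs
regulate outputs" (the looser "connected" reading admits dead ends that can
never carry signal). Then, in order: genes in the lower 5% of expression
variance are removed (strictly-below quantile cut, so equal variances remove
nothing); each remaining edge TF→g is tested by plain Pearson *and* partial
correlation (controls = the other TFs with kept edges into g), both at
P < 0.05; the edge's sign is the sign of the partial correlation; and path
membership is re-enforced to a fixed point. The upstream description states
the filters but not their order; variance → significance → path was chosen
because each later filter only makes sense on the survivors of the earlier
one, and the fixed-point iteration makes the result order-stable. When the
control set would exhaust the degrees of freedom, the $n-5$ controls most
correlated with the target are kept (logged). Both filters share the 0.05
threshold, matching the joint "P > 0.05" exclusion phrasing.

## Targets and the perturbation scan

Per-sample activities give each output DEG a DAC: the Pearson correlation
of activity with age. DEGs split into `consistent` (significant, DAC sign
matches the RNA-seq fold-change sign), `inconsistent`, and
`nonsignificant`; Pearson with the t-test is used throughout for
consistency with the marker stage. Only consistent DEGs — the ones the
network demonstrably explains — are used as the reversal criterion.

The scan assigns $+1$ and $-1$ basal inputs to every intermediate node in
turn (inputs and outputs excluded) and counts validated DEGs whose
activity sign opposes their aging direction with $|x| > \varepsilon$
($\varepsilon = 10^{-9}$, pure floating-point hygiene: reversal is
sign-based, so numerically-zero activities must not count). By linearity
the $-1$ scan is the exact negation of the $+1$ scan. Nodes are ranked by
the better of their two signs, and the top 5% of intermediate *nodes*
(floor, minimum 1) become candidates — with 167 intermediates that is
exactly 8, reproducing the published arithmetic; ranking by (node, sign)
pairs instead is available via the scan table.

```{r arithmetic}
floor(0.05 * (235 - 22 - 46))
```

## Drug screening

Within each perturbation condition, modZ scores are transformed to midrank
percentiles $100(\mathrm{rank}-0.5)/G$ (average ranks for ties; the
transform is pooled per condition, not per gene across conditions — the
natural reading of transforming a profile vector into percentiles). Calls
are `up` at or above the upper tertile, `down` at or below the lower
(inclusive boundaries, for deterministic edge behaviour). A signature gene
is *reversed* when its aging direction and the call oppose; per drug, the
condition reversing the most DEGs is kept (ties by the summed distance of
reversed genes from the 50th percentile, then condition label), and a drug
is a candidate when it reverses strictly more than half of the screenable
DEGs — with 19 screenable markers this means 10 or more.

## What the synthetic data emulate — and what they do not

`sim_config()` defines the reference study conditions: 100 samples aged
20–74 (uniform; sex Bernoulli(0.5); smoking in a third of males and
deliberately not adjusted for), 2,000 CpGs with 10% true DMPs, a 300-gene
scale-free network over 60 TFs with 30% inhibitory edges, 15% true DEGs,
and 12 drugs of which 2 are planted signature reversers.

Key generator parameters, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `dmp_slope_range` | 0.003–0.005 beta/yr | planted DMP slope magnitude; converted to the logit scale at each position's baseline so betas stay in (0,1) |
| `methyl_noise_sd` | 0.3 (logit) | per-observation methylation noise |
| `deg_lfc_range` | 0.015–0.025 log2/yr | planted DEG effect magnitude |
| `nb_dispersion` | 0.02 | NB dispersion, typical of abundant blood transcripts; Poisson in the 0 limit |
| `coupling_r` | 0.7 | target \|correlation\| between a driver DMP and its TF's activity |
| `tf_age_leak` | 0.25 | fraction of the methylation age trend passed into TF activities |
| `network_effect_scale` | 2.5 ln/activity | how strongly propagated activity moves expression |
| `alpha` | 0.5 | damping, matching the inference default |

Three constructions deserve explanation because they decide what a passing
test means:

* **Coherent effect directions.** Expression is generated by the *same*
  damped linear propagation the inference assumes, and each output DEG's
  planted fold-change sign equals the sign of its network-propagated age
  trend. Parameter recovery is therefore a well-posed test of the pipeline,
  not of model mismatch (a `model_mismatch_sd` switch adds lognormal noise
  for robustness experiments).
* **The age-trend leak.** TF activities couple to the realised methylation
  of their driver DMP, but with the age component attenuated to a quarter
  (`tf_age_leak`); output age trends ride on the planted per-year effects
  instead. At desk scale this is what keeps the study's role structure
  intact: a 300-gene BH burden is far more permissive than a 19,000-gene
  one, and a TF layer carrying the full methylation age trend would itself
  be called differentially expressed wholesale, relabelling every
  intermediate as an output and leaving the target scan nothing to rank.
* **The planted reverser.** One intermediate hub is fed by exactly two
  input TFs whose signed trend contributions cancel, making it
  trend-neutral; its direct edges to ~90% of outputs are then oriented
  against the planted aging directions. A batched solver scan at generation
  time verifies it reverses at least 60% of planted DEG directions and
  strictly tops every other intermediate (with a margin), retrying with
  fresh topology otherwise. This makes "the planted reverser is the best
  target" true in the ground truth, so its recovery through the *inferred*
  network is a fair end-to-end test. A side effect: with
  `frac_negative_edges = 0`, the reverser's oriented edges may still be
  inhibitory; only the randomly signed edges are guaranteed activating.
* Outputs whose ±1 path contributions cancel exactly (not rare with ±1
  input trends) receive a random planted direction and surface downstream
  as nonsignificant DACs.

The generator does **not** emulate: linkage/correlation structure among
CpGs, batch effects beyond sex, read-level bisulfite noise, nonlinear or
saturating regulation, cell-type composition, or the weak genome-wide
effect sizes of real blood aging data. Passing recovery bands therefore
show the pipeline is correct and well calibrated under its own model
assumptions at realistic desk-scale signal strengths — not that it would
recover markers from any particular real cohort.

## Numerical choices and degenerate inputs

* Hypergeometric tails, and nothing else, are computed in log space.
* The steady state is a dense LU solve; networks here are a few hundred
  nodes, where dense factorisation beats iteration and is exact.
* Correlation P values use the t transform; `|r| = 1` maps to `p = 0`.
* Collinear partial-correlation controls are pruned by QR rank detection.
* Zero-variance rows: excluded in DMP calling, skipped with a warning in
  input conversion (signal 0), removed with a log entry in edge assignment.
* All-zero genes are excluded from DEG calling; a non-converging NB fit
  falls back to a Gaussian fit on log2(normalised + 1) with a flag.
* Ties are broken deterministically everywhere (documented per function),
  so identical inputs and seed reproduce identical output bytes.

## Problem sizes used by the tests

The recovery suite runs 20 replicate studies at the default conditions
(100 samples, 2,000 CpGs, 300 genes); solver equivalence sweeps 1,000
random signed networks of up to 100 nodes; calibration uses 1,800 null
CpGs and 30 age permutations. These sizes give the stochastic bands
(≥ 90% edge-sign recovery, ≥ 80% DMP recovery, planted reverser among the
top-5% candidates in ≥ 80% of replicates, reverser drug ranked first in
≥ 90%) comfortable Monte-Carlo margins while keeping the whole suite fast
enough to run habitually.

## Limitations

The linear signal-flow model ignores saturation, cooperativity and
feedback sign reversals; the location-only sex adjustment does not touch
scale or higher moments; the NB GLM uses per-gene moment dispersions
without shrinkage, which is slightly anticonservative for low counts; the
partial-correlation control set is restricted to co-regulators within the
subnetwork, so genome-wide confounding is out of scope; and candidate
targets and drugs are in-silico prioritisations — nothing here models
binding, dosing or toxicity.
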