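---
title: "Network attack tolerance as a resilience measure: models and methods"
author: "brainNAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network attack tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainNAT)
```

## The scientific question

In early Parkinson's disease (PD), progressive loss of presynaptic
dopaminergic terminals — quantified by putaminal dopamine-transporter
(DaT) SPECT z-scores — degrades motor function, but individuals with
similar dopaminergic deficits differ widely in clinical severity.
*Motor reserve* and *cognitive reserve* describe this dissociation.
brainNAT implements a graph-theoretical candidate mechanism: **network
attack tolerance (NAT)**, the capacity of a functional brain network to
retain efficient communication while its most connected nodes are
successively removed. The package provides the complete analysis chain
from ROI time series to NAT scores and the statistics relating NAT to
dopaminergic integrity, lifestyle reserve proxies, and behavior, plus a
synthetic-cohort generator that emulates the statistical structure of a
22 PD / 39 HC study so every stage is testable without access to
clinical data.

## From time series to attack tolerance

**Connectivity.** Each participant's connectome is the matrix of
Fisher-transformed Pearson correlations between ROI time series
(`fisherConnectivity()`); correlations are clamped to
$\pm(1-10^{-7})$ so duplicated series stay finite, and the diagonal is
zero. The reference atlas has 300 non-overlapping ROIs with four labeled
subnetworks: somatomotor (SMN, 51 ROIs), default-mode (DMN, 65),
frontoparietal (FPN, 36) and attention (ATN, 27).

**Thresholding.** There is no consensus density for NAT analyses, so
each network — the global graph and each subnetwork's own submatrix — is
proportionally thresholded at nine densities $d \in \{0.10, 0.15,
\dots, 0.50\}$: exactly $k = \mathrm{round}(d\,n(n-1)/2)$ edges with the
largest weights are kept (round half up) and binarized. Two choices are
deliberate and configurable:

* *Signed ranking.* "Strongest" means largest signed Fisher-z value,
  the convention of the standard connectome toolboxes for
  unsigned-intent graphs; `rank = "absolute"` ranks by magnitude
  instead. Whether negative edges may survive at high densities is thus
  an explicit configuration choice, not a hidden one.
* *Per-network density control.* Subnetworks are thresholded on their
  own submatrices, not induced from the thresholded global graph, so
  density is an interpretable covariate per network. The two
  constructions genuinely differ, and a test asserts that they do.

Ties at the cut are broken by ascending (row, column) index, which makes
the retained edge set fully deterministic.

**Attack and NAT.** Global efficiency of a binary graph is the average
inverse shortest-path length over ordered node pairs,

$$GE = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{L_{ij}},$$

with disconnected pairs contributing 0 and $GE = 0$ by convention for
$N \le 1$ (the efficiency of nothing is nothing). The targeted attack
removes, at every step, the node with the highest degree *recomputed on
the surviving subgraph* (adaptive attack, the standard in the robustness
literature; a static initial-ranking mode is available for sensitivity
analysis), ties again by ascending index. $GE$ of a surviving subgraph
uses the surviving node count as $N$. The attack curve holds $GE$ after
$k = 0, \dots, N-1$ removals, and

$$\mathrm{NAT} = \frac{1}{N} \sum_{k=0}^{N-1} GE_k,$$

the area under the curve normalized by the number of attacks — literally
the fraction of the maximum possible efficiency retained: a graph at
$GE = 1$ throughout scores 1. The hot loop (all-pairs BFS after each
removal) is implemented in C++ with bitset frontiers; an independent
pure-R brute-force oracle checks it exactly on all small graphs, and
igraph's efficiency serves as a second cross-check.

## Reserve proxies and behavior

**Lifetime physical activity.** Activity diaries record, per life
period, the activities performed with their MET intensity, years,
months per year and weekly hours. The weekly energy expenditure of a
period is

$$\mathrm{WEE}_{period} = \sum_i
  \frac{\mathrm{years}_i \cdot \mathrm{months}_i \cdot
        \mathrm{hours}_i}{12 \cdot \mathrm{years}_{period}}
  \cdot \mathrm{MET}_i,$$

and lifetime PA is the mean of the 19–35 and 35–50 year periods; the
12–19 and 50+ periods are parsed but excluded (recall bias and
proximity to diagnosis, respectively). Education in years is the
cognitive reserve proxy and enters untransformed.

**Composite scores.** Raw test scores of PD participants are
z-standardized against the healthy-control sample (unbiased SD).
Duration-based tests (hand-function, timed-up-and-go, trail-making) are
negated *before* standardization — equivalent to negating the z-score,
and the simplest form to audit; a test verifies the involution. The
general motor (GMP) and cognitive (GCP) composites are the *sum* of the
per-domain z-scores, consistent with the spread such composites show
over half a dozen tests; `mode = "mean"` is available. Tests with zero
reference variance are excluded with a warning, and a missing test
score propagates to a missing composite, handled by complete-case
analysis downstream.

## Statistical models

**NAT models.** NAT is a fraction that is, by construction, never 0 or
1 on realistic graphs, and each participant contributes nine densities,
so the package fits a beta-response GLMM with a logit link and
per-participant random intercepts (via `glmmTMB`): eight fixed slopes —
putaminal DaT, PA, education, age, sex (female reference), density
(continuous, since a single density slope is reported), and two fMRI
sequence contrasts (level 1 reference). With 22 participants this is
198 observations per network model. Responses touching the boundary are
nudged into $(\varepsilon, 1-\varepsilon)$ with a warning. The reported
explained-variance statistic is the squared correlation between
observed and fitted NAT, a standard GLMM pseudo-R²; only the reporting
slot is contractual, not the particular flavor. No multiple-testing
correction is applied across the five network models ($\alpha = 0.05$
per test), mirroring the analysis design the package emulates.

**Moderation and Johnson–Neyman.** Because NAT is a repeated measure
over densities, its mean across the nine densities per network is the
behavioral predictor. The GMP model regresses the motor composite on
mean NAT, PA, their interaction, and education, DaT, age, sex and
sequence contrasts; the GCP model swaps the roles of PA and education.
The conditional NAT effect at moderator value $w$ is $b_1 + b_3 w$ with
standard error $\sqrt{V_{11} + w^2 V_{33} + 2 w V_{13}}$; the
Johnson–Neyman boundaries solve $|t(w)| = t_{1-\alpha/2,\,df}$
analytically (a quadratic in $w$, `johnsonNeyman()`), using the
residual degrees of freedom of the moderation model — standard JN
practice, stated rather than inferred. Regions are clipped to the
observed moderator range; when no boundary falls inside it the result
is explicitly "everywhere" or "nowhere". A dense grid-plus-bisection
oracle verifies the boundaries to four decimals, and at every boundary
the recomputed two-sided p equals $\alpha$.

Whether both sequence contrasts are estimable in a 22-person moderation
model is data-dependent; the design is therefore guarded by an explicit
rank check that names collinear columns, and the sequence-restricted
sensitivity analysis (`sensitivitySubgroup()`) drops the contrasts, as
they are constant within a subgroup.

## The synthetic cohort: what it emulates, and what it does not

`cohortConfig()` defaults are the emulated study conditions: 22 PD
(age 62.1 ± 8.0, 15 m / 7 f, education 15.8 ± 2.7, putaminal DaT
z −3.6 ± 0.7) and 39 HC (63.5 ± 6.5, 26 m / 13 f, 16.7 ± 2.8, no DaT);
lifetime PA log-normal with median 58.3 (PA is nonnegative and heavily
right-skewed); fMRI sequences allocated 4/17/1 with 740/500/740
volumes. Sex and sequence use deterministic largest-remainder counts in
random order — the study's fixed design — so all sequence levels exist
and the GLMM always carries its eight slopes. Activity diaries are
constructed so that evaluating the WEE formula reproduces each drawn PA
value exactly, exercising the scoring path end to end.

**Connectome model.** Time series are multivariate normal from a factor
model: a global factor sets the between-network correlation (0.10), one
factor per subnetwork sets the within-network correlation (base 0.45
plus planted effects, clipped), a per-participant jitter of the
baseline coupling (SD 0.05) supplies the individual differences that
the random intercepts absorb, and a constant offset of 100 puts the
temporal SNR at a realistic scale (~100).

A uniform change of within-block coupling cannot change the topology of
a proportionally thresholded subnetwork graph — the edge count is fixed
by density, and a homogeneous block thresholds to an exchangeable
random graph whatever its mean coupling. Planting a DaT→SMN-NAT effect
therefore requires a *topological* mechanism: a small core of hub ROIs
(8, echoing the subcortical members of the somatomotor network) whose
factor loadings inflate as DaT integrity falls. Lower DaT thus
concentrates SMN connectivity onto the core; the thresholded graph
becomes hub-dominated, and a degree-targeted attack destroys it
faster — lower NAT. The same mechanism links education to the attention
network. The homogeneous coupling slopes (0.06 per DaT z, 0.02 per
education year) remain, so mean within-block correlation also rises
with the covariate; with the core mechanism switched off
(`coreSize = 0`) the homogeneous slope is recovered exactly by
regression, which is how the generator is tested.

**Behavior model.** Latent motor ability is
$\texttt{gmpIntercept} + \beta_{NAT}\,\mathrm{NAT} +
 s\,\mathrm{NAT}\cdot\min(\mathrm{PA}, \mathrm{knot})$ plus noise, for
PD only; HC ability is pure noise, and cognitive ability is independent
of NAT in both groups (the null cognitive finding). The moderation
enters only below a single knot (default WEE 45) because the emulated
result is "significant only below a WEE threshold", not a particular
functional form; the knot makes that literal while remaining one
configurable number. The NAT slope (40 latent units per NAT unit) is
scaled to the realized between-participant spread of mean global NAT
(≈0.014 under the default connectome model — proportional thresholding
removes overall coupling level, so NAT varies through topology only),
and the moderation slope is negative (−0.35 per WEE unit), so the
conditional NAT effect is strongest in sedentary participants — the
direction the emulated study reports. Each test score maps latent
ability linearly onto its own scale (durations with negative sign);
with `noiseSd = 0` the whole behavioral layer is deterministic, which
several tests exploit.

**What passing tests do not show.** The generator produces stationary
Gaussian series with exact block structure: no hemodynamics, motion,
physiological noise, spatial autocorrelation, or image-space artifacts,
and planted effect sizes are free parameters, not estimates of any
empirical coefficients. Tests passing on this cohort demonstrate that
the pipeline recovers structure that is present by construction — they
validate the machinery, not the neurobiology.

## Numerical choices and degenerate inputs

* Edge counts use round-half-up, making "exactly k edges" testable.
* Correlation clamp $\pm(1-10^{-7})$; GE convention 0 for $N \le 1$;
  NAT of an empty curve is an error, of an all-zero curve 0.
* All tie-breaks (edge cut, attack victim) are by ascending index.
* Zero-variance ROIs abort connectivity with the ROI named; constant
  series yield infinite tSNR, excluded from scan summaries with a
  warning.
* Beta-GLMM estimation is delegated to `glmmTMB` (ML via TMB); the
  contract is parameter recovery on simulated data: 95% Wald CI
  coverage of a planted density slope at the 22×9 design, verified over
  100 replicates.
* Stage-wise seeding (`seed + 0..3` for cohort, diaries, connectomes,
  behavior) makes runs bit-reproducible and lets precomputed matrices
  be fed back without changing downstream randomness.

## Problem sizes used in the tests

Unit and property tests run on reduced fixtures chosen to keep the
suite quick while preserving every structural property: a 50-ROI atlas
with the same five labels (subnetwork sizes 10/13/8/6/13), 14–22
synthetic participants, time series of 150–2000 volumes, exhaustive
attack-oracle checks on all random graphs of up to 8 nodes, 100
replicates for CI coverage, 500 for the interaction type-I error, and
$10^5$-point grids for the Johnson–Neyman oracle. The acceptance script
runs the full default configuration: 300 ROIs, 22 PD + 39 HC, nine
densities, five networks.

## Known limitations

* NAT heterogeneity between synthetic participants is modest; at study
  scale (n = 22) the behavioral moderation is intrinsically
  low-powered, and the package reports whatever the data support,
  including "nowhere" JN regions.
* The beta GLMM assumes a common precision across observations; no
  random slopes are offered, matching the emulated design.
* No random-failure baseline, edge attacks, or weighted-graph
  efficiency: graphs are binarized before attack by design.
* GCP missingness is supported (complete-case) but not planted by the
  generator.
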