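# brainNAT

Quantifying the resilience of functional brain networks by **network
attack tolerance (NAT)** — the fraction of a network's maximum global
efficiency retained while its most connected nodes are iteratively
removed — and relating it to dopaminergic integrity, lifestyle reserve
proxies, and motor/cognitive performance in early Parkinson's disease
(PD).

The package is aimed at researchers studying motor and cognitive
reserve with graph-theoretical connectomics: it implements the complete
chain from ROI time series to resilience statistics, and ships a
synthetic-cohort generator emulating a 22 PD / 39 HC study design so
that every stage runs and is tested without clinical data.

## The model in brief

For each participant and network (whole brain plus the somatomotor,
default-mode, frontoparietal and attention subnetworks):

1. **Connectivity** — Fisher-z correlation matrix of ROI BOLD series:
   z<sub>ij</sub> = artanh(r<sub>ij</sub>).
2. **Density sweep** — proportional thresholding at densities
   d = 0.10, 0.15, …, 0.50: keep the k = round(d·n(n−1)/2) strongest
   edges, binarize.
3. **Targeted attack** — remove the highest-degree node (degree
   recomputed each step), recording global efficiency

   GE = 1/(N(N−1)) · Σ<sub>i≠j</sub> 1/L<sub>ij</sub>

   after every removal (disconnected pairs contribute 0).
4. **NAT** — the area under the efficiency curve normalized by the
   number of nodes: NAT = (Σ<sub>k</sub> GE<sub>k</sub>)/N ∈ (0, 1).
5. **Statistics** — per network, a beta-response GLMM (logit link,
   participant random intercepts; 22 × 9 densities = 198 observations,
   8 fixed slopes: putaminal DaT z-score, physical activity, education,
   age, sex, density, two fMRI sequence contrasts); linear moderation
   models of composite motor/cognitive performance on mean NAT with
   Johnson–Neyman significance regions; lifetime physical activity as
   MET-weighted weekly energy expenditure (WEE) averaged over the 19–35
   and 35–50 year periods.

## Worked example

```r
library(brainNAT)

atlas <- syntheticAtlas()
atlas
#> ROIAtlas with 300 ROIs
#>   membership: SMN=51, DMN=65, FPN=36, ATN=27, none=121

config <- runConfig(seed = 1)     # 22 PD + 39 HC, default conditions
bundle <- runPipeline(config)
#> [cohort] 61 participants (22 PD), 244 diary rows
#> [connectome] 61 matrices of 300 ROIs; mean tSNR 100.1
#> [attack] 990 NAT records (22 participants x 5 networks x 9 densities)
#> [stats] 5 networks fitted in 17.9 s

head(bundle$natTable, 3)
#>   participant network density        nat
#> 1        PD01  global    0.10 0.05127291
#> 2        PD01  global    0.15 0.28488890
#> 3        PD01  global    0.20 0.36498546

bundle$glmmFits$SMN
#> NATModelFit [SMN]: beta GLMM (logit link), 198 obs, pseudo-R2 0.98
#>          term  estimate       se    ciLow    ciHigh        p
#>   (Intercept) -2.195343 0.434692 -3.04732 -1.343363 4.41e-07
#>  putaminalDaT  0.288570 0.042319  0.20563  0.371514 9.18e-12
#>            pa -0.000601 0.000238 -0.00107 -0.000134 1.16e-02
#>     education -0.006640 0.010918 -0.02804  0.014759 5.43e-01
#>           age -0.003986 0.004816 -0.01343  0.005453 4.08e-01
#>          sexm -0.044266 0.053395 -0.14892  0.060386 4.07e-01
#>       density  5.830040 0.078794  5.67561  5.984473 0.00e+00
#>     sequence2  0.201696 0.069163  0.06614  0.337254 3.54e-03
#>     sequence3  0.218982 0.177113 -0.12815  0.566118 2.16e-01

bundle$moderationGMP$global
#> ModerationFit [global -> GMP]: n=22, F(9,12)=1.14, p=0.408
bundle$jnRegions$global
#> JNRegion (alpha=0.05, df=12): nowhere
```

Reading the output: each NAT record is the retained-efficiency fraction
for one participant, network, and density (NAT rises steeply with
density — denser graphs tolerate attacks better). In the SMN model the
positive `putaminalDaT` slope (0.29 on the logit scale, p ≈ 1e-11)
recovers the planted association between dopaminergic integrity and
somatomotor attack tolerance, and `density` is by far the strongest
term, as expected. The 22-person moderation model illustrates the
honest flip side: at study scale the NAT × activity interaction is
under-powered, and the Johnson–Neyman region can legitimately be
"nowhere" for a given synthetic draw.

The sequence-restricted sensitivity analysis refits everything on the
participants scanned with one sequence (17 of 22 under the default
allocation), dropping the sequence contrasts:

```r
sub <- sensitivitySubgroup(bundle, 2)
nrow(sub$natTable)
#> [1] 765          # 17 participants x 5 networks x 9 densities
```

`writeBundle(bundle, "out/")` exports every table (cohort, diaries,
NAT records, coefficient tables, JN regions, provenance) as
tab-separated text.

## Package layout

| Component | Contents |
| --- | --- |
| `ROIAtlas`, `ConnectivityMatrix`, `ThresholdedGraph`, `AttackCurve` | S4 data containers with validity checks |
| `fisherConnectivity`, `proportionalThreshold`, `densitySweep`, `temporalSNR` | connectome construction and QC |
| `globalEfficiency`, `targetedAttack`, `natScore`, `natTable`, `meanNAT` | attack-tolerance engine (C++ core) |
| `periodWEE`, `lifetimePA`, `diaryPA`, `compositeScores` | reserve proxies and behavioral composites |
| `fitNATModel`, `fitModeration`, `johnsonNeyman` | beta GLMM, moderation, JN regions |
| `cohortConfig`, `generateCohort`, `generateTimeseries`, `generateBehavior`, `generateDiaries` | synthetic cohort |
| `runConfig`, `runPipeline`, `sensitivitySubgroup`, `writeBundle` | orchestration |

See `vignettes/brainNAT-methods.Rmd` for the full account of the
models, the generator's assumptions, and the numerical choices.
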