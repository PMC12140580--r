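# dynmod

Time-resolved modular analysis of functional connectivity, built around the
question: do the dynamics of whole-brain network organization at rest
predict how fast a person will learn a sensorimotor task?

`dynmod` takes region-by-time signal panels (parcellated, nuisance-regressed
resting-state BOLD, or any multichannel series), builds windowed
wavelet-coherence networks, partitions them into spatiotemporal modules by
multilayer modularity maximization, and derives the network measures that
carry the behavioural signal — together with the behavioural side (learning
curves, subgroups, a scalar learning score) and the inferential machinery
connecting the two. A synthetic cohort generator with planted structure
makes the entire chain testable end to end without any imaging data.

## The model

For each subject, each z-scored regional series is decomposed with the
maximal-overlap discrete wavelet transform (Haar, scale 1: 0.125–0.25 Hz at
a 2-s TR). In 64-s windows (32 volumes, 50% overlap), band-averaged
magnitude-squared coherence gives a layer matrix `A_l`; coherences below
the 95th percentile of a 10,000-draw shuffle null are zeroed. The layer
stack is partitioned by maximizing the multilayer quality

    Q = (1/2mu) * sum_{ijlr} [ (A_ijl - gamma k_il k_jl / (2 m_l)) d_lr
                               + d_ij omega c_lr ] d(g_il, g_jr)

(Newman–Girvan null, gamma = omega = 1, ordinal inter-layer coupling) with a
generalized Louvain heuristic, 100 runs per subject. From the ensembles
come:

- **node strength** — summed connection weight, per region and window;
- **cohesion strength / disjointedness** — how often a region changes
  modules *with partners* (same source and target) vs *alone*, per
  transition;
- **module allegiance** `P = T/C` — the probability two regions share a
  module, pooled over slices, partitions and subjects;
- **recruitment / integration** of labeled networks —
  `I_kk` and `I'_{k1,k2} = I_{k1,k2} / sqrt(I_{k1,k1} I_{k2,k2})`;
- **summary networks** from symmetric NMF of `P` (`Y ~ HH'`, H >= 0,
  Newton-like projected gradient, 250 inits, rank selection by
  reconstruction error, dispersion, cophenetic correlation and explained
  variance).

Behaviour: binned median endpoint errors, early/late error per day,
savings, k-means subgroups (validated against a multivariate-normal null)
and a sign-fixed PC1 learning score. Inference: OLS per measure with
leave-one-out cross-validation, 10,000-permutation validation,
Benjamini–Hochberg FDR within declared families, Steiger/Williams tests for
correlation changes between scans.

See `vignettes/dynamic-modularity.Rmd` for the full methods account.

## Worked example

```r
library(dynmod)

cfg <- cohort_config(n_subjects = 8, n_regions = 24, n_volumes = 96,
                     subgroup_sizes = c(FF = 4, SS = 2, SF = 2),
                     n_modules_planted = 3, seed = 1)
cohort <- generate_cohort(cfg)

g   <- generate_modular_timeseries(cfg, 1)
thr <- coherence_null_threshold(g$panel, n_iter = 1000, seed = 2)
net <- build_multilayer(g$panel, threshold = as.numeric(thr))
net
#> <multilayer_network> 24 regions x 5 layers, band 0.125-0.250 Hz,
#>   threshold 0.546, sparsity 53.7%
ens <- partition_ensemble(net, R = 5, seed = 3)
ens
#> <partition_ensemble> R = 5 runs, mean Q = 0.2797 (range 0.2600-0.2896)
ensemble_reconfig(ens)
#> <reconfig_scores> 24 regions: mean cohesion 0.508, mean disjointedness 0.050

report <- run_pipeline(cohort, runs = 5, null_iters = 500, n_perm = 999,
                       restarts = 100, k_range = 2:4, seed = 1, quiet = TRUE)
report
#> <dynmod_report> 8 subjects, scans: rest1
#>   behavior: k = 3, PC1 explains 62% of variance
#>   focal models (predictor -> PC1):
#>         measure   beta r_squared       p perm_p
#>               q -8.444    0.4319 0.07659  0.102
#>        cohesion  9.463    0.6976 0.00985  0.013
#>  disjointedness 30.823    0.0899 0.47058  0.602
#>        strength  0.671    0.7222 0.00754  0.088
#>       recruit_1  6.609    0.4131 0.08566  0.106
#>     integrate_2 -2.323    0.1150 0.41112  0.732
```

Reading the report: one row per regression of a network measure on the PC1
learning score. `beta` is the slope, `p` the OLS F-test p value, `perm_p`
the permutation-validated LOOCV p value. In this deliberately tiny cohort
(8 subjects, 2 partition runs each) only the strongest planted effect —
cohesive reconfiguration predicting faster learning — reaches significance;
at the default cohort size (32 subjects, study-scale settings) all five
planted associations (cohesion +, disjointedness −, recruitment +,
integration −, strength +) are recovered with the correct sign in ≥ 95% of
replicate cohorts (this is exercised by the test suite and the acceptance
script). Subgroup counts in `cohort_config()` (15/10/7 FF/SS/SF at
n = 32), scan geometry (142 regions, 180 volumes, TR 2 s) and analysis
defaults follow the study design the package reimplements.

A thin CLI over the same functions lives at `inst/scripts/dynmod.R`
(`simulate`, `connect`, `pipeline`, `behavior` subcommands).

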