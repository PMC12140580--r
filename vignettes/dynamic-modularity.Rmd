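---
title: "Dynamic modularity of windowed coherence networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modularity of windowed coherence networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynmod` implements a complete time-resolved modular analysis of
region-by-time signal panels, of the kind used to relate resting-state fMRI
network dynamics to behavioural performance on a visuomotor-rotation (VMR)
learning task. This vignette describes the models, the tunable parameters
and their defaults, the synthetic-data model used for validation, and the
numerical choices made where the design was genuinely open.

## The analysis chain

For each subject the pipeline is

1. **Wavelet band decomposition.** Each z-scored regional time course
   (default 142 regions x 180 volumes at a 2-s sampling interval) is
   decomposed with the maximal-overlap discrete wavelet transform (Haar
   family, periodic boundary). Scale 1 carries the band
   $[1/(4\,\mathrm{tr}),\,1/(2\,\mathrm{tr})]$ = 0.125–0.25 Hz at
   $\mathrm{tr} = 2$ s. The transform is undecimated, so the coefficient
   series keeps the native time resolution and can be windowed directly;
   the full series is decomposed once and the coefficients are then
   windowed.

2. **Windowed band coherence.** The coefficient series is sliced into 64-s
   windows (32 volumes) overlapping by 50% (a 180-volume rest scan gives 10
   windows). In each window, every region pair's magnitude-squared
   coherence is estimated by Welch's method — 16-sample Hann-tapered
   segments with 50% overlap (three segments per window) — and averaged
   over the discrete frequencies inside the band. With only three segments
   the estimator is noisy and positively biased under independence; this is
   exactly what the shuffle null absorbs. The segment length is an exposed
   argument (`seg_length`) recorded with the network.

3. **Shuffle-null threshold.** The null model draws two distinct regions
   and two random window start times, permutes the sample order inside each
   window (destroying auto- and cross-correlation while preserving the
   marginal distribution), and computes the same band coherence; the 95th
   percentile of 10,000 draws is the subject's global threshold (one
   threshold per scan, not per window). Coherences below it are set to
   zero. On synthetic cohorts at the default coupling levels this yields
   mean sparsities in the mid-80% range.

4. **Multilayer modularity.** The thresholded layer stack is partitioned by
   maximizing the multilayer quality function
   $$Q = \frac{1}{2\mu}\sum_{ijlr}\Big[\big(A_{ijl} - \gamma\,
   \tfrac{k_{il}k_{jl}}{2m_l}\big)\delta_{lr} + \delta_{ij}\,\omega\,
   c_{lr}\Big]\,\delta(g_{il}, g_{jr})$$
   with the Newman–Girvan intra-layer null model, resolution $\gamma = 1$,
   inter-layer coupling $\omega = 1$ on temporally adjacent layers
   ($c_{lr} = 1$ iff $|l - r| = 1$), and $2\mu$ the total multilayer weight
   including couplings. The generalized Louvain heuristic runs on the
   $L \times N$ supra-node problem: node sweeps consider all strictly
   improving moves and pick among them with probability proportional to the
   quality gain; aggregation rounds are deterministic; the converged
   partition is re-fed as the starting point until output equals input up
   to relabeling (with an iteration cap that raises an error rather than
   silently stopping). One hundred independent runs form the partition
   ensemble; the subject's modularity score is the ensemble mean Q.

5. **Reconfiguration metrics.** At each window transition a region either
   stays, moves with partners, or moves alone. *Cohesion strength* counts,
   for each region, the partners making the identical source-to-target
   module move, summed over partners and transitions and divided by
   $L - 1$; a "mutual move" requires identical source *and* target modules,
   and each partner counts separately. *Disjointedness* is the fraction of
   transitions at which the region moves with no partner. Module identity
   across layers comes directly from the multilayer labels (no relabeling
   step is needed because couplings make labels persistent). Scores are
   averaged over the ensemble, then over regions, for subject scalars. The
   two measures are computed independently; no functional relation between
   them is imposed.

6. **Allegiance, recruitment, integration.** The allegiance matrix is
   $P = T/C$, where $T_{ij}$ counts co-assignments of regions $i, j$ over
   all time slices, partitions and (for group matrices) subjects, and $C$
   is the slice total; group matrices pool counts before normalizing.
   Given a labeling of regions into networks, the interaction of networks
   $k_1, k_2$ is the mean of $P$ over the ordered block
   $C_{k_1} \times C_{k_2}$ — the diagonal is included when $k_1 = k_2$
   (the literal reading of the formula; recruitment of a size-$m$ network
   with no off-diagonal allegiance is therefore $1/m$, not 0).
   Recruitment is $I_{kk}$; integration is
   $I'_{k_1k_2} = I_{k_1k_2}/\sqrt{I_{k_1k_1} I_{k_2k_2}}$, which may
   exceed 1 and is not clamped. The optional zeroing null permutes labels
   within each slice (1,000 draws, per-entry 95th percentile by default).

7. **Summary networks by SymNMF.** $\min_{H \ge 0}\|Y - HH^\top\|_F^2$ is
   solved by a curvature-scaled projected-gradient scheme (per-column Gram
   diagonal scaling, Armijo backtracking, monotone descent enforced,
   stopping at relative loss change $< 10^{-6}$ or 500 iterations), from
   250 uniform-[0,1] initializations, keeping the best by loss. Rank
   selection over 2–15 reports mean reconstruction RMSE, the dispersion
   coefficient $\rho = N^{-2}\sum_{ij} 4(\bar c_{ij} - \tfrac12)^2$ of the
   across-init consensus matrix, the cophenetic correlation
   (average-linkage on $1 - \bar c$), and explained variance, computed both
   against the matrix mean and against zero (the reference is unstated in
   the source methods, so both are reported). Hard clusters come from each
   region's maximal loading on the raw (unnormalized) $H$, ties broken to
   the lowest factor index. Rank acceptance is not automated: all criteria
   are reported, and `select_rank()` implements the documented default
   heuristic (smallest rank with explained variance $\ge$ 0.8).

8. **Behaviour.** Per day, 40 learning bins of 8 trials; the bin score is
   the median endpoint error of the trials present (discarded trials are
   simply absent rows). Early and late error are the means of bins 1–3 and
   38–40; savings is early(day 1) − early(day 2), an exact identity in the
   code. Subgroups come from k-means over the five measures with 1,000
   random restarts for each $k \in 2..9$, scored by the mean Silhouette
   width and the Calinski–Harabasz index; the selected $k$ must agree
   between the two indices, and disagreement is reported loudly rather
   than resolved silently. Significance uses a multivariate-normal
   parametric null matched to the sample mean and covariance (1,000
   iterations, recording each iteration's maximum index over $k$). The PC1
   learning score is the first principal component of the z-scored
   measures, sign-fixed so that higher scores mean faster learning
   (negative correlation with mean early error).

9. **Inference.** Simple OLS of each network measure on PC1; internal
   validity by leave-one-out cross-validation computed with the hat-matrix
   identity $e_{(-i)} = r_i/(1 - h_{ii})$, validated by permuting the
   predictor–outcome mapping 10,000 times. The source description of
   significance ("in the 95th percentile of the null") is ambiguous;
   because prediction *error* is the statistic, the implemented rule — the
   only one consistent with the small p values reported alongside it — is
   that the observed MSE must undercut the null: $p$ is the add-one
   proportion of null MSEs $\le$ the observed MSE. Families of tests
   (recruitment across networks, integration across partners) are
   FDR-corrected by Benjamini–Hochberg. Correlation changes between scans
   use the Williams form of Steiger's test with $n - 3$ df; pooled-variance
   two-sample t tests compare subgroups (df $= n_1 + n_2 - 2$).

## The synthetic cohort model

The generator plants exactly the statistical structure the analysis
assumes, so every downstream stage is testable without imaging data.

**Panels.** Default cohort: 32 subjects in three learner profiles — FF
(fast both days, n = 15), SS (slow both days, n = 10), SF (slow then fast,
n = 7) — each with two 142 x 180 resting panels at tr = 2 s. Within a
planted block, regions of the same module share a standard-normal latent
signal; region noise is scaled as
$\sigma = \texttt{noise\_sd}\,\sqrt{1/\rho - 1}$ so the within-module
correlation equals the planted coupling $\rho$ exactly at the default
`noise_sd = 1`, and 1 in the noiseless limit. Couplings are profile-linked
(FF 0.8, SS 0.3, SF 0.55, plus a ±0.05 per-subject jitter) — chosen for
testability since resting inter-subject coupling variability is not well
characterized empirically.

Planted partitions are piecewise-constant on *non-overlapping* blocks of
one window length (32 volumes). A 50%-overlap window grid cannot have
well-defined per-layer partitions if memberships change at every window
start — half the windows would straddle two partitions — so changes occur
at every second window start and each layer's ground truth is the
partition of the block containing its start. Between blocks, membership
evolves by cohesive events (groups of 3–5 regions moving together,
Poisson-rated per profile: FF 2, SS 0.5, SF 1 per transition) and disjoint
events (lone movers: FF 0.5, SS 3, SF 1.5), never emptying a module.

**Behaviour.** Trial errors follow
$a\,e^{-t/\tau_{\mathrm{day}}} + b$ (a = 40°, b = 5°) with additive
Gaussian noise (2° default) truncated at ±180°, time constants per profile
(FF 25/18, SS 130/110, SF 130/18 trials) modulated by the planted coupling
through `effect_slope`, so that stronger coupling means faster learning
within every profile. The five planted brain-behaviour associations
(cohesion +, disjointedness −, recruitment +, integration −, strength +)
therefore all flow from two planted ingredients: coupling strength and
switch-event coordination.

**What the generator does not emulate:** spatial autocorrelation and
hemodynamic smoothing of real BOLD, head-motion and physiological
artifacts, heavy-tailed noise, inter-regional coupling heterogeneity
within a module, and non-exponential learning curves. Passing tests
demonstrate that the estimators recover planted structure of the assumed
form; they are not evidence about artifact robustness on real scans.

## Numerical and design choices

- **Coherence estimator.** 16-sample Hann segments at 50% overlap inside
  the 32-sample window. With three segments the per-window estimate is
  noisy; consequently genuinely coupled pairs (coupling 0.8, band
  coherence ≈ 0.64) survive the 95th-percentile null threshold in roughly
  85% of windows rather than essentially always. Tests freeze that
  empirically computed level. Users wanting a tighter estimator can pass
  `seg_length = 8` (seven segments, coarser band grid).
- **Louvain internals.** Dense supra-modularity matrix (fine up to a few
  thousand supra-nodes); probabilistic move selection applies in the node
  sweeps only; ties (no improving move) keep the current assignment;
  sweep order is re-randomized per sweep from the run seed; outer
  stable-partition loop compares partitions up to label permutation.
- **k-means restarts.** `stats::kmeans` with `nstart` selects the restart
  with the lowest within-cluster sum of squares — the objective k-means
  optimizes — rather than the sum of unsquared distances; the two rankings
  essentially never differ on well-separated behavioural data, and the C
  implementation makes 1,000 restarts affordable.
- **Null-network family.** The modularity significance check supports
  temporal (layer-order permutation), connectional (within-layer
  edge-weight permutation), and nodal (per-layer node relabeling that
  scrambles inter-layer couplings) nulls; the family is a config choice,
  with `connectional` the default used in the examples.
- **Degenerate inputs.** Zero-variance windows raise "degenerate window"
  errors naming the region and window; empty layers contribute only
  coupling terms to Q; an all-empty network with $\omega = 0$ has
  undefined Q and errors; an all-zero SymNMF loading row errors in
  `assign_clusters()` but falls to the tie-break factor inside the
  rank-selection consensus (one unreconstructed region should not abort a
  250-init sweep).
- **Seeding.** Every stochastic stage derives its seed deterministically
  from (master seed, stage label, subject index) via a 31-bit hash
  (`derive_seed()`), so results are independent of execution order and
  caching.
- **Problem sizes.** The test suite and the acceptance script run the full
  algorithms at reduced sizes chosen for desk-scale runs — e.g. ensembles
  of 2–10 partitions, 150–2,000-draw nulls, 10–20 replicate cohorts of
  16–24 subjects — while function defaults keep the study-scale values
  (100 runs, 10,000 null iterations and permutations, 250 inits, 1,000
  restarts). Scaled-down calibration tests state their replicate counts
  and use binomial confidence bounds at those counts.

## Known limitations

- The generalized Louvain heuristic is stochastic and can miss the global
  optimum on adversarial instances; on exhaustive 5-node/2-layer
  benchmarks, best-of-100 runs attains the true maximum in ≥ 95% of
  instances.
- Recruitment/integration values depend on the diagonal-inclusion
  convention (documented above); comparisons with implementations that
  exclude the diagonal require the exposed alternative.
- The permutation validation is internal only; nothing here validates
  predictions across independent cohorts.
- At three Welch segments per window, per-window coherence has high
  variance; band- and window-level averaging, the shuffle null, and
  ensemble averaging are what make the downstream metrics stable.

## A worked miniature

```{r, eval = FALSE}
library(dynmod)
cfg <- cohort_config(n_subjects = 8, n_regions = 24, n_volumes = 96,
                     subgroup_sizes = c(FF = 4, SS = 2, SF = 2),
                     n_modules_planted = 3, seed = 1)
cohort <- generate_cohort(cfg)
report <- run_pipeline(cohort, runs = 5, null_iters = 500, n_perm = 999,
                       restarts = 100, seed = 1, quiet = TRUE)
print(report)
```
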