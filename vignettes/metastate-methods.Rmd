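---
title: "Detecting metastates of dynamic functional brain networks from node centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metastates of dynamic functional brain networks from node centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metastate)
```

## The model

Resting-state functional connectivity is not static: the correlation
structure of regional BOLD signals drifts and recurs on a time scale of
seconds to minutes. A *metastate* is a whole-brain pattern that the network
keeps revisiting over a scan. Most clustering approaches operate directly on
the vectorized connectivity matrices; this package instead clusters the
**node-centrality profile** of each windowed network. The centrality vector
is a low-dimensional, topology-aware summary — a region is important when it
is strongly connected to other important regions — which makes the
recovered states directly interpretable as *hub patterns*.

The pipeline is:

1. **Sliding-window connectivity.** For a censored ROI series of $T$ usable
   volumes, rectangular windows of width $w$ volumes stepped by $s$ give
   $\lfloor (T - w)/s \rfloor + 1$ windows; each window yields a Pearson
   correlation matrix, Fisher z-transformed ($z = \operatorname{atanh} r$).
2. **Proportional thresholding.** In every window the strongest fraction
   $d$ of the $N(N-1)/2$ edges (ranked by signed weight) keep their
   weights; the rest are zeroed. Fixing the density rather than an absolute
   cutoff keeps edge counts comparable across windows and subjects.
3. **Node centrality.** Degree centrality is the weighted strength
   $C_D(i) = \sum_{j \ne i} A_{ij}$. Eigenvector centrality is the leading
   eigenvector of $A$, $C_E = \tfrac{1}{\lambda_1} A \, C_E$, sign-fixed
   nonnegative and unit-norm. Each window's vector is z-normalized across
   regions; the window-by-region matrix of z-scores is the clustering input.
4. **Two-stage k-means++** under correlation distance
   $d(u, v) = 1 - \operatorname{corr}(u, v)$: a group-level fit over all
   subjects' windows (k-means++ seeding, Lloyd iterations, 10 restarts),
   then per-subject Lloyd refinement initialized at the group centers. The
   cluster centers — mean centrality vectors — are the metastates.
5. **Dynamics and reliability.** Per subject: dwell time (windows per
   state, or seconds after multiplying by the TR) and the matrix of
   transition counts. Across two sessions, each feature's test-retest
   reliability is the pooled-moment intraclass correlation coefficient
   $$\mathrm{ICC} = \frac{\sum_{i=1}^n (x_{1i} - \bar x)(x_{2i} - \bar x)}
   {(n - 1)\, s_x^2},$$
   with $\bar x$ the mean and $s_x^2$ the variance of all $2n$
   observations. ICC < 0.4 is conventionally read as poor reliability and
   > 0.75 as good.
6. **Hubs and rich club.** A state's hubs are the regions scoring above
   mean + 1 SD of its pattern. For a weighted structural network, the
   rich-club coefficient at rank $r$ is
   $$\Phi^w(r) = \frac{W_{>r}}{\sum_{l=1}^{E_{>r}} w_l^{\mathrm{rank}}},$$
   the weight inside the top-$r$-strength subgraph divided by the sum of
   the same number of globally strongest weights, normalized by the mean
   over degree-preserving random networks; $\Phi^w_{\mathrm{norm}}(r) > 1$
   indicates a rich-club effect.

## Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| window length | 60 | s | the 50–60 s range balances temporal resolution against correlation estimation noise; at TR 2.5 s this is 24 volumes |
| window step | 1 | TR | maximal temporal sampling of the state sequence |
| edge density | 0.40 | fraction | matches the density of group-level significantly-positive edges (one-sided t-test, FDR q < 0.05) in typical resting-state cohorts |
| FD threshold | 0.3 | mm | standard motion-censoring cutoff; subjects under 200 remaining volumes are excluded |
| k range | 2–10 | — | scanned by the elbow criterion |
| distance | correlation | — | shape, not magnitude, defines a state; magnitudes are already z-scored away |
| hub threshold | mean + 1 SD | z-units | the classic top-ranking hub rule; sample SD (divisor $n-1$) |
| null networks | 1000 | — | stable estimate of the null rich-club mean |

## Numerical choices

* **Fisher-z clamp.** $|r|$ is capped at $1 - 10^{-7}$ before `atanh`, so
  degenerate windows (duplicated signals) stay finite.
* **Signed ranking.** Proportional thresholding ranks edges by signed
  weight — the analysis targets positive connectivity; after global-signal
  regression, strongly negative edges are deliberately not competitive with
  positive ones. The retained count is `round(density * M)` (half away
  from zero); ties across the cut are broken by (row, column) order with a
  warning.
* **Negative weights and centrality.** Any negative weights surviving the
  threshold are zeroed before the eigenvector computation: the
  Perron–Frobenius theorem guarantees a nonnegative leading eigenvector
  only for nonnegative matrices. Disconnected windows use the leading
  eigenvector of the full matrix (mass concentrates on the dominant
  component); isolated nodes are listed in a warning. The solver is a dense
  symmetric eigendecomposition up to 256 regions and power iteration
  (tolerance $10^{-10}$, cap $10^4$ iterations) beyond; a degenerate
  leading eigenvalue is an error rather than an arbitrary pick.
* **Window bookkeeping.** Windows are defined on the post-censoring
  concatenated series — censored volumes are deleted, never interpolated —
  and counted as $\lfloor (T - w)/s \rfloor + 1$. Because preprocessing
  pipelines differ in how many volumes they drop, outputs always record the
  window count and start indices (0-based internally, 1-based in reports)
  rather than assuming one.
* **Centroids under correlation distance.** Cluster centers are plain
  arithmetic means of member vectors. For z-scored rows (zero mean, equal
  norm) the mean direction is the exact minimizer of summed correlation
  distance, so Lloyd iterations descend monotonically — the implementation
  asserts this every iteration. Empty clusters are re-seeded at the sample
  farthest from its current center; assignment ties break to the lowest
  state index.
* **Elbow rule.** The number of states is chosen as the arg-max of the
  second-order difference of the best-inertia curve (maximal curvature),
  with a mean-silhouette curve reported alongside as a complementary
  validity index. Validity indices for k-means are genuinely plural; the
  second-difference rule is simple, deterministic and recovers planted k
  reliably, so it is the single default, and the silhouette curve lets a
  user audit the choice.
* **ICC convention.** The pooled variance uses divisor $2(n-1)$, which
  makes ICC of a duplicated measurement exactly 1 (with divisor $2n - 1$
  it would exceed 1). The coefficient is reported raw — negative values are
  possible and are not clamped — and the 0.4/0.75 cutoffs are applied to
  raw values. Features with zero variance across subjects are reported as
  `NA`, not zero-filled, since the coefficient is undefined there. Dwell
  ICC uses window counts; multiplying both sessions by the TR leaves the
  coefficient unchanged (asserted in the tests). This pooled-moment form
  is a consistency-type coefficient, not a variance-components ICC(2,1);
  the two agree in rank ordering but not numerically.
* **Session alignment.** The two sessions are clustered independently and
  aligned afterwards by the optimal bijection between center sets
  (Hungarian assignment minimizing summed correlation distance), so no
  information leaks between sessions before the reliability analysis.
* **Rich-club nulls.** Topology is randomized by Maslov–Sneppen double-edge
  swaps (10 × edge count attempts), preserving the degree sequence exactly;
  the original weight multiset is then shuffled onto the surviving edges.
  This preserves degree and weight distributions but not the strength
  sequence — the standard "equal size, similar connectivity distribution"
  null. Node ranking uses weighted degree (strength), descending, with ties
  broken by label order.

## The synthetic generator

`synthetic_spec()` defaults describe the emulated study: 23 subjects, two
sessions, 5 states over 90 regions, 200 windows per session at TR 2.5 s,
snr 5, mean dwell 10 windows, retest correlation 0.8. The pieces:

* **State sequences** follow a Markov chain with geometric dwell (mean
  `mean_dwell`) — the simplest memoryless model of states that recur; no
  biological realism is claimed for the dwell distribution. Per-subject
  state propensities (Gaussian latents passed through a softmax with gain
  0.8) tilt the transition weights, creating the between-subject
  variability that reliability analysis needs; session II mixes the shared
  latent with fresh noise at weight $\sqrt{1 - \rho^2}$, so `retest_rho`
  controls the planted test-retest reliability. Mean dwell 10 windows and
  retest correlation 0.8 were fixed once as representative of the stable,
  repeatable dynamics the method targets.
* **Centrality series** are state templates (hubs at +1, non-hubs at a
  compensating negative level so templates are zero-mean — which keeps
  z-normalization near-identity at high snr and the planted hub sets
  exactly recoverable) plus $N(0, 1)/\mathrm{snr}$ noise, row z-scored.
* **ROI time series** draw each window from a single-factor Gaussian
  model: the active state's hub regions load on a shared factor with
  loading $\sqrt{0.3 \cdot \mathrm{snr}}$ (hub–hub correlation
  $\approx 0.6$ at snr 5), everything else is independent noise.
  Windowing the concatenated series at the generator's width re-exposes
  the planted states.
* **Core-periphery networks** (complete high-weight core, sparse low-weight
  periphery) plant a rich club whose normalized coefficient must exceed 1
  inside the core.

What the generator does *not* emulate: hemodynamic autocorrelation, 1/f
noise spectra, head motion, spatial smoothness, or gradual state
transitions. Passing recovery tests on these data therefore shows the
estimator chain is correct and well-calibrated under its own model — not
that real fMRI satisfies that model.

## Problem sizes used in the packaged checks

The test suite validates the estimator chain on deliberately small planted
instances (3–5 states, 12–40 regions, tens of windows per subject), where
exhaustive oracles are feasible: k-means fits are compared against
exhaustive partition search on up to 8 samples, state matching against all
$5!$ bijections, the rich-club coefficient against a brute-force
recomputation on up to 12 nodes, and the eigenvector solver against power
iteration on 100 random graphs. The headline checks run at the emulated
study scale: 23 subjects × 200 windows × 90 regions for elbow selection,
500 replicates for the null-ICC bound, and 1000 nulls for the rich-club
curve.

## Worked example

```{r, eval = FALSE}
spec <- synthetic_spec(n_subjects = 6, n_states = 3, n_regions = 30,
                       windows_per_session = 60, seed = 42)
gen <- generate_centrality_series(spec)

sel <- elbow_select_k(do.call(rbind, gen$samples$I), c(2, 8), seed = 42)
sel$k                       # 3 — the planted number of states

fitI  <- two_stage_fit(gen$samples$I,  sel$k, seed = 42)
fitII <- two_stage_fit(gen$samples$II, sel$k, seed = 43)
mt <- match_states(fitII$group$centers, fitI$group$centers)

dynI  <- lapply(fitI$subject_labels, state_dynamics, k = sel$k)
dynII <- lapply(lapply(fitII$subject_labels,
                       function(l) mt$permutation[l]),
                state_dynamics, k = sel$k)
icc_matrix(dynI, dynII, k = sel$k)   # planted retest_rho = 0.8

detect_hubs(fitI$group$centers[1, ])  # recovers a planted hub block
```

## Limitations

* Sliding-window correlation itself is contested as an estimator of
  time-resolved connectivity; this package implements the estimator, it
  does not arbitrate that debate. Tapered windows and model-based
  alternatives (DCC, HMMs) are out of scope.
* The elbow rule is one defensible operationalization among several; with
  weakly separated states, different validity indices can disagree. The
  full validity curve is always returned.
* The pooled-moment ICC is not a variance-components ICC; comparisons with
  ICC(2,1)/ICC(3,1) values from other software are not exact.
* Hub detection by mean + 1 SD is a ranking heuristic without an error
  model; no significance is attached to hub membership.
* Voxel-level preprocessing (slice timing, motion correction, nuisance
  regression, filtering) and tractography are assumed done upstream; the
  package starts from ROI series and precomputed structural matrices.
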