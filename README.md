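# metastate

Detection of recurring whole-brain states ("metastates") in resting-state
fMRI from the **node-centrality profiles** of dynamic functional networks,
with test-retest reliability analysis and structural rich-club comparison.

## What problem this solves

Dynamic functional connectivity studies summarize a resting-state scan as a
sequence of sliding-window correlation networks and ask which patterns
recur. Clustering the raw connectivity vectors works but lives in an
$N(N-1)/2$-dimensional space and yields states that are hard to read.
This package clusters each window's **eigenvector-centrality vector**
instead — an $N$-dimensional, topology-aware profile in which a region
scores high when it connects to other high-scoring regions. The resulting
states are hub patterns: directly comparable to intrinsic sub-networks
(sensorimotor, occipital, default-mode, ...) and to the structural rich
club. It is aimed at researchers analyzing ROI-level BOLD time series
(e.g. AAL-90 parcellations) across repeated sessions.

## The method

For each subject and session:

1. volumes with framewise displacement > 0.3 mm are censored (subjects
   under 200 remaining volumes excluded);
2. rectangular sliding windows (60 s, step 1 TR) yield Fisher-z Pearson
   connectivity matrices, `z = atanh(r)`;
3. each window is proportionally thresholded to its strongest 40% of edges
   (weights retained);
4. eigenvector centrality `CE = (1/λ₁) A CE` is computed per window and
   z-normalized across regions;
5. two-stage k-means++ under correlation distance `1 − corr(u, v)` (group
   fit, then per-subject refinement from the group centers) extracts K
   metastates, K chosen by an elbow criterion over k = 2..10;
6. dwell times and transition counts summarize each subject's state
   sequence; across two sessions their reliability is the pooled-moment
   intraclass correlation coefficient

   ICC = Σᵢ (x₁ᵢ − x̄)(x₂ᵢ − x̄) / ((n − 1) s²ₓ),

   with x̄, s²ₓ the mean and variance of all 2n observations (ICC < 0.4
   poor, > 0.75 good);
7. each state's hubs are the regions above mean + 1 SD of its centrality
   pattern; weighted structural networks are tested for a rich club via
   Φʷ(r) — club weight over the equally many strongest weights — normalized
   against 1000 degree-preserving nulls (Φ_norm > 1 ⇒ rich-club effect).

A synthetic-data module plants known states, hub sets, test-retest
reliability and rich-club structure, so every stage is validated against
ground truth.

## Worked example

```r
library(metastate)

# 6 subjects, two sessions, 3 planted states over 30 regions
spec <- synthetic_spec(n_subjects = 6, n_states = 3, n_regions = 30,
                       windows_per_session = 60, seed = 42)
gen <- generate_centrality_series(spec)

sel <- elbow_select_k(do.call(rbind, gen$samples$I), c(2, 8), seed = 42)
sel$k
#> [1] 3

fitI  <- two_stage_fit(gen$samples$I,  sel$k, seed = 42)
fitII <- two_stage_fit(gen$samples$II, sel$k, seed = 43)
mt <- match_states(fitII$group$centers, fitI$group$centers)
round(mt$matched_distances, 4)   # matched session-II/I centers nearly coincide
#> [1] 0.0017 0.0011 0.0010

dynI  <- lapply(fitI$subject_labels, state_dynamics, k = sel$k)
dynII <- lapply(lapply(fitII$subject_labels, function(l) mt$permutation[l]),
                state_dynamics, k = sel$k)
round(icc_matrix(dynI, dynII, k = sel$k), 3)
#>       S1    S2    S3
#> S1 0.492 0.520 0.908
#> S2 0.664 0.472 0.217
#> S3 0.486 1.000 0.548

detect_hubs(fitI$group$centers[1, ])
#> <hub_set> 7 hubs above 0.9422 (mean + 1 SD): R001, R002, ..., R007
```

The elbow criterion recovers the planted K = 3; matched cluster centers
across sessions are nearly identical (correlation distance ≈ 0.001); the
ICC matrix (diagonal = dwell-time reliability, off-diagonal = transition
reliability) reflects the planted retest correlation of 0.8, noisily at
n = 6; and the first state's detected hubs are exactly its planted 7-region
hub block.

The same stages are available from the shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "metastate", package = "metastate"))')
Rscript $CLI simulate --out sim --subjects 6 --states 3 --regions 30 --seed 42
Rscript $CLI run --manifest sim/manifest.tsv --out results --window-s 60 --step 24 --k 3 --seed 42
```

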