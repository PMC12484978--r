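---
title: "Neural state segmentation and age-effect analysis: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural state segmentation and age-effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

While watching a continuous stimulus such as a movie, local multivoxel
activity in most cortical regions is piecewise stable: it dwells in a
*neural state* for seconds to tens of seconds and then transitions abruptly
to a new pattern. Segmenting a region's timepoint-by-voxel matrix into such
states, without any stimulus annotation, lets one ask how the temporal
granularity of cortical processing is organised — and how it changes with
age — and how the detected state boundaries relate to the moments where human
observers say one meaningful event ends and another begins.

`neurostates` implements the full chain: state segmentation (GSBS), group
preparation (masking, searchlights, hyperalignment, averaging), boundary
metrics (durations, dispersion, boundary strength, event overlap,
inter-subject synchrony), rank-based age inference with FDR control,
perturbation simulations, and a synthetic-cohort generator with planted
ground truth.

## The segmentation model

GSBS assumes the data are piecewise stationary in *pattern* (not amplitude):
each TR's spatial pattern is a noisy copy of its state's prototype. Rows are
z-scored first, which makes the Pearson correlation between two TRs a scaled
dot product and removes global amplitude differences.

* **Greedy placement.** Starting from a single state, each iteration adds the
  state start that maximises the within-state fit (mean correlation between
  each TR and its state's mean pattern). For z-scored rows this fit has a
  closed form — the sum over states of (state length) × SD(state-mean
  pattern) — which the implementation exploits via prefix sums, making a full
  segmentation O(k_max · T · V).
* **Finetuning.** After every addition, each boundary may move within ±1 TR
  (configurable window) if that strictly increases the fit; passes repeat to
  convergence (at most 10). The state count never changes and the fit never
  decreases.
* **Model selection.** At each k the t-distance — a pooled-variance
  two-sample t contrasting within-state TR-pair correlations against
  adjacent-state TR-pair correlations — is recorded; the selected k maximises
  it. A Welch form is available (`var.equal = FALSE`); for model selection
  the difference is second order.
* **Determinism.** All ties (greedy candidates, finetune moves, equal
  t-distances) resolve toward the earliest TR / smallest k; identical input
  gives an identical segmentation.

The greedy objective (fit) and the selection objective (t-distance) are
distinct on purpose; because descriptions of the procedure differ in where
each criterion acts, `criterion = "tdistance"` lets the greedy step optimise
the t-distance directly instead. Both choices recover planted boundaries on
the synthetic benchmarks; the fit criterion is the default and is roughly
T times faster.

### Degenerate inputs and numerical conventions

* Constant rows cannot be z-scored; the error names the offending TR.
* Singleton states contribute fit 1 (a TR correlates perfectly with itself);
  a state whose mean pattern is constant contributes 0.
* The t-distance is undefined when every state is a single TR (no
  within-state pairs); during model selection such k are skipped with a
  warning. On noiseless data the t-distance may be `Inf`; comparisons still
  work.
* On *structureless* (pure noise) input the t-distance curve is shallow and
  drifts upward with k, so the selected k is unstable and tends toward the
  upper search bound. `optimal_k` is meaningless on such data; inspect
  `tidy(fit)` (the full curve) before trusting a selection.
* TR indices are 1-based throughout: TR *i* covers `[(i-1)·TR, i·TR)`
  seconds, and a boundary vector lists the first TR of each new state
  (TR 1 implicitly starts the first state).

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `TR` | 2.47 | s | acquisition interval; converts TRs to seconds |
| `k_max` | T/2 | states | search bound; states average ≥ 2 TRs |
| `finetune_window` | 1 | TRs | local refinement radius per pass |
| searchlight `radius`, `step`, `min_size` | 3, 2, 15 | voxels | spherical neighbourhoods over the mask |
| `activity_frac`, `gm_thresh` | 0.70, 0.2 | — | mask: per-subject activity floor and grey-matter probability |
| `hrf_shift_s`, `window_s` | 5, 1 | s | hemodynamic delay and tolerance when mapping event onsets to TRs |
| `cluster_window_s`, `min_agree` | 2.47, 5 | s, observers | consensus clustering of observer keypresses |
| `n_groups`, `group_size` | 34, 17 | — | age-group construction |
| `q` | 0.05 | — | Benjamini–Hochberg FDR level |
| noise `levels`, `shifts`, `reps` | .05/.5/1, 1–2 TRs, 100 | — | perturbation simulations |

The `window_s = 1` tolerance is read as ±0.5 s around the shifted onset
(total width 1 s); a window endpoint exactly on a TR edge includes both
adjacent TRs. The duration CV uses quartiles by the inverse-ECDF-with-
averaging convention (`type = 2`, equal to Tukey's hinges on even-length
samples), fixed so that, e.g., durations {2, 4, 6, 8} give IQR 4 and CV 0.8.
"Different from zero across groups" for the overlap is tested with a
one-sample Wilcoxon signed-rank test (a two-sample rank-sum against a
constant is ill-posed); exact null for n ≤ 25 without ties, normal
approximation otherwise.

## Hyperalignment and group preparation

Within each age group, subjects are rotated into a shared voxel space by
orthogonal Procrustes (no scaling — columns are z-scored first, so
"rotation" is the only free transformation; reflections are permitted).
Alignment is a two-pass template procedure: subject 2 is aligned to subject
1, each later subject to the running mean of its aligned predecessors, and a
second pass re-aligns everyone to the pass-1 mean. Alignment is independent
per region/searchlight; whole-brain alignment with transformation stitching
across overlapping searchlights is out of scope, and users aligning real
multi-region data should be aware the two differ. When the shared signal is
rank-deficient (fewer effective patterns than voxels) only the occupied
subspace is constrained; recovery of the exact rotation requires full-rank
signal. Searchlight centres sit on a step-2 lattice anchored at the mask's
minimum bounding corner (the lattice phase is otherwise arbitrary; anchoring
makes it deterministic).

## The synthetic cohort

The generator emulates what the analysis needs and nothing more:

* **Piecewise-stationary patterns** — each state has a fixed V-dim Gaussian
  pattern; all groups reuse the same pattern pool with different durations,
  so age effects are purely temporal.
* **Age-dependent durations** — group g's mean duration is
  `duration_map(age_g)` with ages evenly spaced over 18–88 (bracket medians
  of a lifespan cohort). Durations are `min_dur` plus a rounded gamma draw.
  The gamma shape (default 4, duration CV ≈ 0.5) is a deliberate design
  choice: it keeps state-to-state variability realistic while leaving the
  planted age gradient identifiable at the modest group counts used in
  validation; `duration_shape = 1` reproduces the heavy-tailed exponential
  limit if more stimulus-like irregularity is wanted.
* **Per-subject boundary jitter** — each boundary moves by a rounded
  Gaussian displacement, resampled to preserve ordering, so the subject's
  state count is preserved (matching how the boundary-shift simulation
  reasons about inter-subject variability).
* **Noise** — i.i.d. Gaussian per voxel per TR.
* **Events** — onsets are back-placed at `(b-1)·TR − 5` s for a seeded
  subset of the youngest group's boundaries, so after the pipeline's +5 s
  hemodynamic shift they align with those planted boundaries. Boundaries too
  early to admit a nonnegative onset are skipped (warned when
  `event_fraction = 1`).

Defaults (34 groups × 17 subjects, T = 193, V = 97, TR = 2.47 s,
`pattern_sd` 1, `noise_sd` 0.5, `jitter_sd` 0.5, `event_fraction` 0.5,
duration map rising 4 → 9 TRs over 18–88) mirror the cohort design the
package models; per-group averages then have SNR ≈ `pattern_sd /
(noise_sd/√17)` ≈ 8, comfortably in the regime where both the number and the
location of boundaries are recoverable.

What it does **not** emulate: hemodynamic convolution (the analysis operates
on unconvolved states by design), spatial autocorrelation between voxels,
scanner drift and motion artefacts, heavy-tailed BOLD noise, and realistic
cross-subject voxel misalignment (subjects are generated in a shared voxel
space, so hyperalignment is near-identity on synthetic data). Passing the
synthetic benchmarks therefore demonstrates the correctness of the
algorithms and the sensitivity of the inference chain under the stated noise
model — not robustness to real-scanner artefacts.

## Validation design and problem sizes

The test suite validates each stage against independent oracles (naive pair
enumeration, exhaustive segmentation for T ≤ 12, permutation and
sign-enumeration nulls for the rank statistics) and runs these end-to-end
checks, with all sizes chosen to keep a full run inside a few minutes:

* greedy + finetune reaches ≥ 95% of the exhaustive-optimum fit on ≥ 95% of
  200 random instances (T ≤ 12, k ≤ 3);
* planted boundaries (T = 60, V = 97, 6 states) are recovered exactly, with
  the correct k, in 100/100 seeds at pattern/noise SD ratio 5;
* a monotone duration map (4 → 9 TRs) in cohorts of 10 groups × 5 subjects
  (T = 100, V = 50) is detected — positive, FDR-significant Spearman rho —
  in ≥ 90% of 20 cohort seeds, with the 20 seeds treated as the
  multiple-testing family; a flat map under the same conditions yields a
  false-positive rate within the FDR level.

The boundary-shift simulation check uses group-level noise (`noise_sd` 1.2 ×
`pattern_sd`): at realistic noise, averaging a 1–2-TR-delayed copy with the
original slightly *reduces* the detected state count, as expected. At very
low noise the opposite happens — the blended transition TRs are crisp enough
to be resolved as extra singleton states — which is worth knowing before
applying the simulation to nearly noiseless data.

## Known limitations

* `optimal_k` on structureless data is meaningless (see above); there is no
  built-in "no states" null test.
* The pipeline driver treats a synthetic cohort as a single region; mapping
  analyses across many searchlights use `age_effect_map()` and the
  searchlight utilities directly.
* Partial Spearman correlations use the rank-then-partial-Pearson
  construction with a t approximation; for very small group counts an exact
  permutation test would be preferable.
* FDR is applied per analysis family (one correction per metric map), not
  pooled across all analyses.
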