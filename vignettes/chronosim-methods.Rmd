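---
title: "chronosim: models, generators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronosim: models, generators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronosim)
```

This vignette is the package's own account of its science: what each stage
models, which knobs matter, what the synthetic generators do and do not
emulate, and where open design choices were settled. It states no empirical
result that the test suite does not itself compute.

## 1. Entropy collapse as a speed measure

The scoring stage asks a deliberately minimal question of an image: when a
recurrent convolutional network processes it over and over, how fast does
the network's output distribution sharpen? We use an untrained network on
purpose — the collapse-rate phenomenon survives random weights, which means
it reflects intrinsic image structure (contrast, edges, spectral content)
rather than learned semantics, and it keeps the package free of any training
pipeline.

Mechanically, each of the 8 layers receives its feedforward input plus
`lateral_gain` times its own post-ReLU output from the previous timestep,
injected into the pre-activation. Because activations are non-negative and
re-injected, their magnitude grows across timesteps, the readout logits grow
with them, and the softmax sharpens: entropy falls from near ln K toward 0.
Different images drive different growth rates, which is exactly the
between-image variation the speed parameter captures.

Tunable parameters, with defaults and why:

* `n_classes = 100` — the softmax width K. Only the entropy ceiling
  ln K depends on it; orderings are insensitive.
* `input_size = c(32, 32, 3)`, `channels_per_layer = rep(16, 8)` — a
  desk-scale geometry: ~200 images score in seconds on one CPU.
* `weight_init_scale = 1.0`, `lateral_gain = 0.8` — chosen **once**, by
  scanning a 3 × 4 grid during development, so that the mean trace starts
  just below ln K, declines on average across the 8 timesteps (the property
  the power fit presupposes, asserted over 100 fixture images in the test
  suite), and is still mid-collapse at the final timestep with clear
  between-image spread in fitted A. Larger scales collapse to 0 by timestep
  4; smaller ones never leave the ceiling.
* Entropy is in natural log units (nats) package-wide. No log base is
  canonical here; every downstream quantity (orderings, thresholds) is
  base-covariant, so one base is fixed and documented.

What a green test does *not* establish: the fixture images (gratings, blobs,
filtered noise) are stand-ins with controllable contrast and scale, not
models of natural scenes; and the first-timestep entropy sits within ~1e-4
of the ceiling rather than strictly below it, because with zero biases and a
global-average-pooled readout the timestep-1 logits are small. Both are
acceptable for the package's purpose (producing realistically distributed
collapse rates), not claims about any published network.

## 2. Fitting E = A·T^B + C

The collapse model is linear in (A, C) once B is fixed, so the fitter
profiles them out exactly (ordinary least squares against the regressors
T^B and 1) and searches only over B ≥ 0: a deterministic coarse grid
(0.1–6), bracketing, then golden-section refinement to tolerance 1e-12.
This replaces the superficially obvious 3-parameter multi-start search,
which is badly conditioned — a small A trades against a large B — with a
1-D problem that cannot diverge in A or C. Consequences the tests rely on:
constant traces give exactly A = 0 and rss = 0; noiseless synthetic traces
refit to 1e-5; and with 0.01-nat Gaussian noise the median |Â − A| stays
within 10 % of |A| over the A ∈ [−0.5, −0.05] range.

The source equation is described in words as a "two-parameter" model while
displaying three symbols; the displayed equation governs here and all three
parameters are estimated.

The duration-categorization proxy maps the 7 log-spaced durations linearly
onto probe timesteps 2–8 (the correspondence is otherwise unspecified) and
answers "long" when the entropy at the probe has already fallen to or below
the threshold; a value exactly at threshold counts as "long", so the
long-response count is monotone in the threshold.

## 3. Stimulus sampling

All three strategies operate on an (image, memorability, A) table.
Memorability bins are equal-width on [0.2, 1], half-open except the last;
per-bin quotas are total/n_bins (392/7 = 56), remainders to the lowest bins.
Ties in A break by image id so a selection never depends on row order — the
suite checks equivalence against an independently coded brute-force selector
over a thousand randomized toy tables.

Open choices settled here:

* *Constant-memorability band.* Scores are continuous, so "memorability of
  0.5" is implemented as |m − 0.5| ≤ `mem_tolerance` (default 0.005;
  the pipeline uses 0.02 against its 20 000-image synthetic corpus so each
  speed bin is populated). Within the band, the observed A range is cut into
  7 equal-width bins, bin 1 = slowest (largest A).
* *Test/foil split.* Foils are described as sampled "in the same manner" as
  test items, which we read as matched composition: the split is stratified
  50/50 within each bin (28 + 28 of each 56), seeded; a plain random split
  sits behind `stratified = FALSE`.

## 4. The behavior generators

The generators are a stated world, not a dial: defaults were fixed before
the acceptance thresholds were evaluated and are not revisited per-run.

**Bisection (logit model).** The schedule is exact: 7 blocks × 196 trials,
every image once per block, durations balanced 28-per-value within block and
shuffled (balance removes duration/image confounds in recovery tests; the
original trial-level randomization is unstated). Choice follows
`logit P(long) = β0 + β_dur·z + β_mem·mem_c + β_speed·A_c + β_int·mem_c·A_c
+ u_s + v_s·A_c` with z the standardized log duration, memorability centered
and A standardized over the stimulus set — the *same coding the fitter
uses*, so recovered coefficients are directly comparable (the source's
coding is unstated; this is our choice). Defaults β = (0, 2, 1.2, −0.8,
0.5), random-effect SDs (0.5, 0.3): a strong duration effect, a clear
memorability dilation, a faster-is-longer speed effect, and a positive
interaction, all at magnitudes a bisection GLMM on 20 × 1372 trials can
resolve. RTs are lognormal (median 600 ms, σ = 0.25 log units) with 1 % of
trials multiplied by 5 — injected outliers so the 3-SD log-RT filter has
work to do.

Note for recovery studies: because the generator's duration effect is
strong, fits that *omit* duration (the source's analysis choice, and the
pipeline default via `duration_term = FALSE`) recover attenuated β's — the
usual non-collapsibility of logistic coefficients, not a bug. The
recovery/calibration tests therefore set `duration_term = TRUE`.

**Inverted-U alternative.** `P(long) = clip(−M1(s − M2)² + M3, 1e-3,
1 − 1e-3)` on the speediness axis s = −A_c (sign flipped so larger =
faster). Clipping is needed because the raw quadratic can leave [0, 1]. The
default memorability map applies the three stated modulations linearly over
[0.2, 1]: M1 0.25 → 0.10 (wider curves), M2 −0.3 → 0.5 (peak at faster
speeds), M3 0.56 → 0.80 (higher peaks).

**Recognition.** Old items are endorsed with a bin-graded probability,
linear from `base_hit − spread/2` to `base_hit + spread/2` across the 7
sampling bins, so the expected per-bin range *is* the `spread` parameter
(defaults 0.5 and 0.17); foils are endorsed at `fa_rate` (0.3). Responses
are independent Bernoulli draws — no subject-level recognition variance —
which keeps the spread parameter exact on the probability scale; the
empirical range estimator is therefore slightly upward-biased by sampling
noise (~0.01 at 20 subjects), which the ±0.03 recovery check absorbs.

**Score tables.** Memorability is Beta(2, 2) rescaled to [0.2, 1]; A is
drawn through a Gaussian copula with a *weak negative* rank dependence on
memorability and an SD growing linearly (factor 1 + `hetero`) with
memorability. Because the heteroscedastic scaling perturbs global ranks, the
delivered Spearman correlation is attenuated relative to the latent copula;
the generator measures that attenuation on a deterministic internal
Monte-Carlo stream and solves for the latent correlation, so the
`target_spearman` argument (default −0.1134, the corpus-scale value) is
delivered within sampling error. The conditional distribution of A defaults
to uniform rather than normal: with Gaussian tails, equal-width speed bins
with equal quotas are generically infeasible (the outer bins of an observed
range never hold 56 items), whereas a bounded conditional mirrors the
bounded observed speed range of a real corpus.

## 5. Inference: numerical choices

* **RT filter** — per subject, two-sided |z| > 3 on log RT; "greater than 3
  SDs" could be read upper-tail-only, so `tail = "upper"` is available.
  Boundary values are retained; subjects with < 10 trials pass through with
  a warning.
* **GLMM** — lme4::glmer, binomial/logit, bobyqa, Laplace (`nAGQ = 1`) or
  the penalized-likelihood step (`nAGQ = 0`) where hundreds of fits must
  stay inside a time budget (development spot checks put the two within
  0.01 on the designs used here). Constant responses raise an explicit
  separation error. Acceptance is by parameter recovery against the
  generators, not by equality with any specific solver.
* **LR tests** — χ² = 2Δℓ with df = parameter-count difference; identical
  specifications return χ² = 0, p = 1; non-nested pairs error. Term-wise
  ("type III-style") testing drops the interaction from the full model and
  each main effect from the no-interaction model.
* **Binned surfaces** — equal-width bins over the observed covariate ranges
  (no canonical edges exist); cell means are pooled proportions, with
  per-subject means retained for error bands; empty cells are missing with
  count 0.
* **Inverted-U fit** — weighted least squares of cell means on (1, s, s²)
  with counts as weights; vertex form (M1, M2, M3) is reported, and
  non-negative curvature flags "no inverted-U" while still reporting the
  parameters. An 11-point noiseless parabola is recovered exactly (a
  quadratic interpolates), which the suite asserts at 1e-9.
* **Spread** — the dispersion of per-bin hit rates is not defined in the
  source; we use the range (max − min), the most literal reading of a
  "shift" between best and worst bins.
* **RM-ANOVA / contrasts** — textbook one-way repeated-measures
  decomposition (subject as block), F = MS_bin/MS_error with df (b−1,
  (b−1)(n−1)) and partial η²; pairwise pooled-variance t tests with
  Bonferroni-multiplied p (capped at 1) and Cohen's D on the pooled SD.

## 6. The pipeline and seeds

`run_pipeline()` chains scores → sample → simulate → analyze, persisting
every intermediate CSV plus a manifest (seed, config MD5, row counts, filter
counts, convergence flags). One global seed expands into fixed per-stage
substreams, so a stage can be re-run in isolation and the whole run is
byte-reproducible. The constant-memorability group is analyzed with speed as
the only fixed effect and a random intercept (its memorability column is
deliberately degenerate); the other two groups get the full
memorability × speed model with a by-subject speed slope.

## 7. Known limitations

* The scoring network is a caricature at desk scale: no training, no
  published architecture weights, nearest-neighbour resizing. It delivers a
  *distribution* of collapse rates, not comparable absolute A values.
* The generators draw trials independently given the subject effects: no
  sequential dependencies, no drifting internal standard in the bisection
  task, no item-level day-1-to-day-2 coupling in recognition.
* PNG/JPEG input requires the png/jpeg packages; the dependency-free raster
  path is ASCII netpbm only.
* The skewed variant of the dilation/compression curve (skewed Gaussian or
  exponential quadratic) is out of scope; only the symmetric quadratic is
  fitted.
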