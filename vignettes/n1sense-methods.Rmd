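---
title: "Methods: simulating and analysing developmental visual N1 sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing developmental visual N1 sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n1sense)
```

## The problem

The visual N1 is a negative-going ERP component over bilateral
occipito-temporal electrodes, peaking roughly 170–260 ms after a visual
stimulus in children. Its amplitude indexes category-sensitive processing in
ventral occipito-temporal cortex: familiar character classes (digits,
letters) elicit a stronger (more negative) N1 than matched unfamiliar
controls (false fonts). Developmental studies track two contrasts per child
and hemisphere — **coarse** digit sensitivity (digits − false fonts) and
**fine** digit sensitivity (digits − letters) — across school grades, and
relate them to numeracy and literacy scores.

`n1sense` implements that analysis chain end to end, together with a
synthetic longitudinal cohort generator, so every stage is testable against
a known ground truth.

## The synthetic cohort

The generator's defaults encode the study conditions the package targets:

* **Cohort.** 62 children, five timepoints (kindergarten to fifth grade);
  per-timepoint group sizes 23/22/27/27/42 with 1–5 visits per child. The
  visit pattern is drawn so per-timepoint counts match exactly, with every
  child attending at least once.
* **Task.** Three conditions (DIG/LET/FF) in separate parts, each 4 blocks
  of 15 items with 6 targets per condition, 613 ms stimuli, ISI 331 or
  695 ms, fixation gaps between blocks. Only the 54 non-targets per
  condition feed the ERPs.
* **Forward model.** Each non-target event injects a Gaussian temporal
  kernel (FWHM 60 ms; peak latency 228/218/220/210/208 ms at T1..T5,
  i.e., the centres of the per-timepoint N1 windows) times a zero-mean
  spatial topography times the condition amplitude. The topography places
  Gaussian-on-sphere lobes at the LOT/ROT cluster centroids with an anterior
  counter-lobe, is mean-centred (consistent with the average reference), and
  scaled to unit mean over the cluster channels, so injected amplitudes read
  directly in cluster-mean μV. An earlier positive component (120 ms,
  condition-independent) gives the GFP its canonical first-then-second
  maximum structure. The montage is a mirror-symmetric spherical lattice, so
  the left cluster is the exact mirror of the right one.
* **Effects.** FF −6 μV, DIG −8 μV at all timepoints (coarse effect −2 μV);
  LET −7 μV except −8 μV at T2, so the fine contrast vanishes at T2 — the
  transient letter enhancement during intensive letter training.
* **Noise.** 1/f background (exponent 1, SD 6 μV) plus white sensor noise
  (SD 2 μV); artifact epochs (boxcar deflections of 280–400 μV on a random
  10% channel subset) at rate 0.05; frontal blink transients at rate 0.05.
  These are removable only by amplitude-threshold rejection, matching the
  scope of the preprocessing stage.
* **Amplitude-level mode.** For statistical recovery work the generator also
  emits amplitude records directly: condition amplitude + subject offset
  (SD 2 μV, shared across visits — the random intercept) + a subject-specific
  digit deviation (SD 1 μV — each child's own coarse sensitivity) + residual
  noise (SD 1.8 μV). The noise split is calibrated so the total record-level
  SD (≈2.06 μV) reproduces the effect-to-noise ratio implied by the reported
  F statistics of comparable studies with these group sizes; with ~480
  records in the coarse model, a −2 μV effect then yields a condition F in
  the hundreds, as observed empirically in this literature.
* **Behavior.** Scores are monotone transforms of a per-child latent skill.
  A Gaussian copula on ranks couples latent skill to the *simulated* coarse
  sensitivity at a configurable cell (default: T4, left hemisphere,
  arithmetic percentile) at a target Spearman ρ (default 0.6, positive:
  better skills ↔ weaker sensitivity). Coupling to the realized effect, not
  a pre-noise latent, is deliberate: it makes the target ρ the estimand the
  correlation stage should recover, up to sampling error only.

What the generator does **not** emulate: volume-conducted head-model
topographies, MR-environment artifacts, ocular artifacts requiring ICA,
latency jitter across trials, or non-stationary noise. Passing tests
therefore validate the pipeline's statistical machinery and its contracts,
not its robustness to every pathology of real clinical EEG.

## Preprocessing

* **Filtering.** Zero-phase (forward–backward) Butterworth cascade: order-2
  high-pass at 0.1 Hz, order-2 low-pass at 30 Hz, order-2 band-stop 48–52 Hz.
  The cascade is applied per channel with `signal::filtfilt`; separate edge
  sections keep the coefficients well-conditioned at 0.1 Hz relative to a
  1 kHz rate. Verified properties: a 50 Hz sinusoid leaves < 1% residual; a
  10 Hz in-band tone is attenuated < 5%; the whole chain is linear.
* **Downsampling.** Integer-factor decimation (1000 → 500 Hz); the 30 Hz
  low-pass doubles as the anti-aliasing filter, so the band edge must lie
  below the target Nyquist.
* **Interpolation.** Bad channels are replaced by the inverse-distance
  weighted mean of their k = 4 nearest good neighbours (chord distance on
  the sphere), capped at 5 bad channels per subject.
* **Average reference.** Subtract the per-sample channel mean; a projection
  (idempotent), leaving channel means 0 to 1e-9.
* **Epoching.** Half-open window [−100, 613) ms on the post-downsampling
  grid: the onset sample is the first sample at/after the event time, and a
  sample at latency $k/f_s$ belongs to the epoch iff $-100 \le 1000·k/f_s <
  613$ — 357 samples at 500 Hz. This convention is arbitrary but stated;
  both endpoints of the *analysis window* (below) are inclusive.
  Baseline subtraction of the prestimulus mean is on by default with a
  switch to disable: the cluster-amplitude analyses need a baseline, while
  GFP and TANOVA are offset-invariant either way.
* **Rejection and inclusion.** An epoch is discarded if any sample on any
  channel exceeds ±200 μV — read as absolute amplitude, not peak-to-peak,
  which is the stricter and simpler reading of an "amplitudes ±200 μV"
  criterion. A subject-visit is included iff every condition retains ≥ 20
  epochs (inclusive bound). Visual-inspection rejection is out of scope; the
  threshold rule is the only criterion.

## ERP features

The N1 window is selected per timepoint from the GFP of the unweighted mean
ERP over all subjects and conditions. Local maxima are samples strictly
greater than both neighbours (plateaus resolve to their centre sample;
optional 10 ms moving-average smoothing is off by default because the
grand-average GFP of pooled cohorts is already smooth). The search range
80–350 ms skips pre-onset and late bumps; within it, maxima are ordered by
latency and the **second** is taken — the first is the earlier positive
component. The window is peak ± 30 ms, endpoints snapped to the sampling
grid and both included. An optional topography-check hook can veto a
candidate (e.g., requiring posterior negativity); it is disabled by default
since no concrete criterion is established, and the candidate list is
returned for audit.

Cluster mean amplitudes average over the 9 cluster channels and all window
samples; the operation is linear in the ERP, so differences of cluster means
equal cluster means of difference waves.

## TANOVA

Maps are strength-normalized per subject, condition and sample (divided by
their GFP; zero-GFP maps pass through flagged). Normalization is applied at
the subject-condition level — rather than to condition grand averages —
because the permutation exchanges subject-level maps, and exchangeability
must hold for the objects actually permuted. The statistic is the
generalized dissimilarity $s=\sqrt{\frac1K\sum_c \mathrm{GFP}(M_c-\bar
M)^2}$; for two conditions it reduces algebraically to half the GFP of the
grand-average difference map, which enables a fully vectorised permutation
path (within-subject label swaps are sign flips of per-subject difference
maps, so all permutations evaluate as one matrix product). The generic K≥2
path shuffles labels within each subject explicitly; both paths are pinned
to a literal-formula oracle and to exhaustive enumeration on 3 subjects × 2
conditions in the tests. P-values use the add-one convention
$(1+b)/(1+B)$ so zero p-values cannot occur; per-sample tests are reported
without multiplicity correction across samples, mirroring the field's
"periods of p < 0.05" read-out (a max-statistic correction would be the
obvious extension). An alternative statistic (sum of pairwise map
dissimilarities) was considered and not shipped: every topographic test this
package reports compares two conditions, and for K = 2 the pairwise
dissimilarity is a monotone (scalar) transform of the generalized
dissimilarity, so the permutation p-values would be identical.

## Inference

The mixed model is `amplitude ~ hemisphere * condition * timepoint` with a
per-subject random intercept, fitted by maximum likelihood via `nlme::lme`
(factors with a single level are dropped from the formula). Normalized
(Pearson) residuals beyond ±3 mark outliers; exclusion runs **one** pass
followed by one refit — a fixed-point loop could cascade and is deliberately
avoided, matching the single reported exclusion count such analyses publish.
Per-timepoint condition contrasts come from estimated marginal means with
containment degrees of freedom (the df convention of nlme-style reports;
Satterthwaite is not used), signed digits-minus-control so digit sensitivity
appears as negative t. Contrast p-values are reported unadjusted, as is
standard for planned follow-ups of a significant interaction; the grid stage
is where multiplicity is controlled.

Spearman correlations use midranks; p-values come from exact rank-permutation
enumeration for n ≤ 9 and the t approximation otherwise. The brain–behavior
grid defaults to 36 cells — 2 hemispheres × 2 contrasts × 9 behavior/
timepoint combinations (number knowledge at T1; concurrent arithmetic
percentile, arithmetic raw and reading at T4 and T5; T1 sensitivity against
the latest arithmetic and reading scores) — with BH-FDR applied across the
whole family, separately for the unfiltered and the outlier-excluded
variants. Neural outliers within a cell are |value − median| > 3·MAD; the
rule is reported alongside the unfiltered result rather than replacing it,
since no canonical exclusion rule exists for these measures.

## Numerical and design choices

* Seeds: a master seed fans out to per-subject and per-stage seeds through a
  fixed affine counter scheme (`derive_seed`), keeping every derived seed a
  valid 32-bit integer; two runs with the same master seed are
  byte-identical.
* Degenerate inputs: monotone GFP traces raise an error instructing manual
  window entry; zero-GFP maps are flagged, not normalized; zero-variance
  electrodes get ±Inf t with a flag; zero rank variance yields an undefined
  correlation, flagged.
* Problem sizes in the shipped tests and acceptance script are chosen for
  single-CPU runs: 24-channel montages and reduced designs for signal-mode
  end-to-end checks, 500 exchangeable-null cohorts × 500 permutations for
  TANOVA calibration, 100 amplitude-level cohorts for contrast recovery, 200
  replicates for correlation recovery. The statistical conclusions these
  support (calibration, power, bias) are sample-size-explicit in the
  reported metrics.

## Known limitations

Signal-mode simulation of the full 124-channel, five-timepoint cohort is
memory- and time-intensive; parameter-recovery work therefore runs at the
amplitude-record level, which is the mixed model's unit of analysis. The
TANOVA normalization convention (per subject-condition map) is one of two
defensible readings of "normalized amplitudes"; the other (per condition
grand average) is a one-line change but not exposed. EDF import/export is
not provided; recordings interchange through a documented plain-text array
container with a JSON sidecar.
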