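---
title: "Methods: band-limited fALFF of group-ICA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-limited fALFF of group-ICA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Resting-state BOLD fluctuations carry most of their power below 0.1 Hz, and
that low-frequency range is conventionally subdivided into infra-slow bands:
slow-5 (0.01–0.027 Hz) and slow-4 (0.027–0.073 Hz) dominate gray matter.
Cohort studies of healthy aging and of ischemic stroke report that these two
bands are differentially disturbed: late-stage stroke is associated with a
*reallocation* of oscillation amplitude from slow-5 to slow-4 across many
cortical networks with no net change in total resting-state power, whereas
healthy aging shows a default-mode-specific slow-5 reduction accompanied by
a slow-5 *increase* in task-positive (visual, sensorimotor) networks.

`slowosc` implements the full measurement chain for such questions:

1. **Preprocessing** — discard equilibration volumes, detrend, optional
   despiking, and motion screening by Euclidean-norm framewise displacement.
2. **Group spatial ICA** — two-stage PCA reduction (subject, then group),
   natural-gradient Infomax unmixing, GICA back-reconstruction of
   subject-specific time courses and maps, ICASSO-style stability
   resampling, template-based network identification, and a spectral
   robustness filter.
3. **Spectra** — one-sided FFT amplitude spectra of component time courses,
   Gaussian smoothing, fractional amplitude (fALFF) per band, and a
   0.0015-Hz discrete bin grid.
4. **Group statistics** — per-bin Student t-tests, one-way ANOVA with Tukey
   HSD pairwise contrasts, and pre-registered directional t-tests.
5. **A synthetic cohort generator** with full ground truth, so the whole
   chain is testable without clinical MRI data.

# The estimator: group spatial ICA

Let $X_i$ be the voxels-by-time matrix of subject $i$ after preprocessing
(each voxel series zero-mean). Each subject is reduced to $p$ temporal
principal components ($F_i$, time × $p$), the reductions
$R_i = F_i^\top X_i^\top$ are stacked over subjects, and a group PCA reduces
the stack to $k$ rows, which are whitened and unmixed with Infomax:
$S = W Z$, where the samples are voxels (spatial ICA). Subject time courses
are back-reconstructed through the pseudo-inverse chain,
$T_i = F_i G_i A$, and subject maps by regressing $X_i$ on $T_i$.

Defaults and why:

* `k = 28` — a mid-order unconstrained model, the standard order for
  whole-cortex network decomposition. Simulation tests use `k = 8` on
  five planted networks; scaled-down orders are valid everywhere.
* `pca_dim = 1.5 k` — a common two-stage heuristic; the subject stage only
  needs to retain comfortably more directions than the group stage
  extracts.
* Infomax with logistic nonlinearity, natural-gradient full-data updates,
  `lrate = 0.1`, `tol = 1e-6` on the squared weight increment,
  `maxit = 512`, and learning-rate annealing (halve and reset) on
  divergence. The planted spatial sources are sparse non-negative blobs,
  i.e. strongly super-Gaussian, which is the regime the logistic Infomax
  rule separates.
* Component sign is made identifiable by orienting every map to positive
  skewness, and template matching re-flips a map when its best template
  correlation is negative.
* Stability: the ICA is rerun under random initialization plus
  subject-level bootstrap; all runs' maps are clustered by average-linkage
  on $1 - |r|$ and each reference component is scored by mean
  within-cluster minus mean between-cluster similarity, clipped to
  $[0, 1]$. This is a transparent surrogate for the ICASSO cluster-quality
  index, with the contract stated rather than the toolbox reproduced.
* Robustness filter: a component is kept when its mean
  low-frequency (0.01–0.1 Hz) to high-frequency (0.1 Hz–Nyquist) power
  ratio across subjects strictly exceeds 50; zero high-frequency power
  counts as infinitely robust.

Component numbering is an arbitrary ICA permutation; all invariance
properties (e.g. under global rescaling of the data) are therefore stated at
the level of matched network labels, not raw component indices.

# Spectra and fALFF

Amplitude spectra are one-sided magnitude spectra (`|FFT|`, the square root
of power — the convention of the fALFF literature) at the Fourier
frequencies $k/(T \cdot \mathrm{TR})$, without windowing. A 220-volume scan
at TR = 2.6 s gives a resolution of ≈ 0.00175 Hz and a Nyquist frequency of
≈ 0.1923 Hz.

Spectra are smoothed with a Gaussian kernel of σ = 2 *Fourier bins*
(reflection at the boundaries, so interior amplitude mass is conserved);
fALFF is computed from the smoothed spectrum by default, with a flag for
raw-spectrum sensitivity analyses. Bands are half-open $[lo, hi)$ — a
frequency exactly at 0.027 Hz belongs to slow-4 — except the
Nyquist-terminated bands (full range, high-frequency), which are closed
above so the Nyquist bin is counted exactly once.

fALFF of a numerator band over a denominator band is the ratio of summed
smoothed amplitudes. Slow-5 and slow-4 fALFF use the full acquired range
(0–Nyquist) as denominator; resting-state fALFF uses 0.01–0.073 Hz over the
full range; the slow-5 share uses the resting band as denominator. Because
the bands are disjoint, slow-5 + slow-4 fALFF equals resting fALFF exactly,
and every fALFF is invariant to positive rescaling of the series.

The discrete bin analysis resamples the smoothed spectrum by linear
interpolation onto the centers of 34 half-open bins of width 0.0015 Hz from
0.009 to 0.060 Hz — interpolation, not aggregation, because the bin width is
finer than the native Fourier resolution.

Composite components (DMN = pDMN + aDMN + vDMN; visual–sensorimotor) are
unweighted means of the member spectra; at the table level the composite
fALFF is the member mean, which is exact when the members share denominator
mass (they do, by construction, in the generator).

# The synthetic cohort generator

The generator defines the study conditions: four groups (young healthy, old
healthy, stroke ≤ 7 days, stroke 1–6 months), 230 volumes at TR = 2.6 s
(a 10-minute scan), five planted networks (pDMN, aDMN, vDMN, visual,
sensorimotor) as sums of Gaussian blobs on a 20 × 24 × 20 voxel grid with
pairwise spatial correlation below 0.3, and per-network time courses built
from random-phase sinusoids at every Fourier frequency inside slow-5 and
slow-4 (band RMS amplitudes `slow5_amp`, `slow4_amp`) plus white broadband
noise. Phases are drawn per sinusoid, not per band, to avoid degenerate
phase-locked series. Voxel data are map ⊗ time-course mixtures plus white
voxel noise (SD 0.06 against blob peak 1). Noise is white throughout: the
study being emulated modelled no scanner autocorrelation and acquired no
physiological recordings, and no hemodynamic convolution or lesion model is
attempted.

Because the analysis discards the first 10 volumes, the sinusoid
frequencies are placed on the Fourier grid of the *retained* segment; the
generative fALFF targets therefore refer to the spectra the pipeline actually
measures. (An earlier design placed them on the full-scan grid; the
truncation then spreads every tone off-grid and biases measured slow-5
fALFF down by about 0.06 — a useful reminder that amplitude spectra, unlike
power, are not leakage-additive.)

Group effect sizes are the printed group means of the motivating study
translated into amplitudes: per component the slow-5 fALFF targets
(e.g. pDMN 0.383 old-healthy → 0.329 stroke-late) are inverted numerically
— via the analytic expected spectrum, including smoothing leakage and the
Rician amplitude of the noise floor — under the constraint that the total
resting-band amplitude mass equals a per-group value. For stroke-late that
mass equals the old-healthy mass: the slow-5 deficit is a pure reallocation
toward slow-4 with no net resting-power change, which is precisely how the
study evidenced "no net power change" (an unchanged resting fALFF). Young
healthy values are not printed in the study; the defaults apply the aging
pattern in reverse (DMN slow-5 fALFF +0.035, task-positive −0.045, DMN
resting mass +15%), chosen once and fixed.

Between-subject dispersion is a log-normal multiplicative jitter
(`sdlog = 0.3`) on each subject's band amplitudes, which yields a measured
slow-5 fALFF SD of ≈ 0.09–0.1 — the dispersion implied by the study's
printed t statistics (a 0.054 shift with t = 1.499 at n = 42/16 implies
SD ≈ 0.12).

The broadband floor inside each component time course (`broadband_amp =
0.004` against a resting amplitude mass of 1) is set so planted components
pass the LF/HF > 50 robustness criterion by a wide margin, as the study's
retained components did. A consequence worth knowing: the measured resting
fALFF then sits near its ceiling (≈ 0.92) with a left-skewed distribution,
so a small-sample two-sided t-test on it runs slightly hot even under the
planted null; the package's no-deficit check is the one-sided test in the
deficit direction, which is also what the claim "no stroke-late reduction"
asserts.

Synthetic motion tracks are mean-reverting AR(1) series (coefficient 0.95,
moving-average-smoothed innovations) rescaled to a target RMS framewise
displacement (default 0.1 mm), with rotations carried in degrees and
converted on a 50-mm lever arm — the common convention; the motivating
study does not state a radius. A pure random walk is *not* used: over 230
frames it drifts past any plausible peak-to-peak exclusion threshold, which
is behaviourally wrong for a still subject.

## What passing tests do and do not show

The generator emulates band-structured stationary oscillations with linear
spatial mixing and white noise. Real resting-state data add spatial
autocorrelation, scanner drifts and motion artefacts coupled into the
signal, hemodynamic filtering, non-stationarity, and template mismatch.
Tests passing on this generator validate the estimator chain (reduction,
unmixing, back-reconstruction, spectral measurement, statistics) and the
direction and rough magnitude of group-effect recovery — not preprocessing
choices for real scanners, nor ICA order selection on real data.

# Preprocessing surrogates

Slice timing, rigid realignment, spatial normalization and spatial
smoothing are deliberately out of scope: synthetic cohorts are generated
aligned on a common grid, and those stages are off-the-shelf registration
orthogonal to the spectral contribution. What is kept is the temporal
chain: discarding the first 10 volumes, polynomial detrending (order 1
default), a transparent despiking rule (clip samples farther than 5 MADs
from a 7-point running median), and motion exclusion. Exclusion uses the
strict peak-to-peak range per parameter (> 2 mm drops the scan, exactly
2 mm keeps it); the motivating study's wording does not disambiguate
peak-to-peak from framewise displacement, and peak-to-peak is the choice
recorded here.

# Statistics layer

Bin-wise comparisons use the pooled-variance (Student) two-sample t-test
with two-sided uncorrected p-values — the bin analysis of the motivating
study reports uncorrected significance — with optional Benjamini–Hochberg
columns. The omnibus test is a one-way fixed-effects ANOVA followed by
Tukey HSD with the Tukey–Kramer unequal-n correction (group sizes of the
emulated study: 43/42/14/16). Directional contrasts must be declared a
priori; the code refuses to infer a direction from the data. The study
mixes one- and two-tailed wording ("post hoc uncorrected one-sample
t-test" where two groups are compared); the package implements two-sample
forms throughout and exposes the directional variant explicitly.

# Numerical choices and problem sizes

* Gaussian smoothing kernel truncated at 4σ and renormalized; reflection
  padding.
* Tie-breaking in template matching is greedy by descending absolute
  correlation with each component and each template used at most once.
* Degenerate inputs: all-zero series give an undefined-fALFF error (zero
  denominator mass); constant motion tracks give zero displacement; an
  exactly-at-threshold robustness ratio is *not* robust (strict
  inequality).
* Test and acceptance problem sizes (the package's own desk-scale choices):
  12-subject cohorts with k = 8 for ICA recovery across 10 seeds; 1000
  replicates at n = 12/group for t-test and Tukey calibration (128-volume
  series); 11 replicates at n = 12/group for effect-pattern sign recovery,
  run on the generator's planted time courses — the ICA stage has its own
  recovery criterion, and repeating it inside every replicate would not
  change what the sign criterion measures.

# Known limitations

* The analytic expected spectrum combines tone and noise amplitudes in
  quadrature (a Rician-mean approximation), accurate here because the
  planted tones are far above the noise floor.
* Resting fALFF lives near its ceiling under a robustness-compatible noise
  floor, so aging's *total-power* decrease, while planted (+15% DMN mass in
  the young), is statistically invisible at desk-scale n; the package makes
  no claim about recovering it.
* The stability index is a contract-stated surrogate, not the ICASSO
  toolbox's exact quality index.
* Variance explained is reported at the group-PCA stage; the 89.1% printed
  in the motivating study is specific to its clinical data and is not a
  package target.
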