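---
title: "Methods: functional activity readouts for neuronal cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional activity readouts for neuronal cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuract)
```

`neuract` quantifies the functional state of cultured neuronal networks from
three readouts that are routinely combined in disease-in-a-dish studies
(for example when tracking synucleinopathy-like pathology spreading through
compartmentalized cultures): somatic calcium oscillations from fluorescence
time-lapse imaging, extracellular spiking from microelectrode arrays (MEAs),
and a multiparametric "fingerprint" of the network's pharmacological response
to serial glutamatergic stimulation. This vignette documents the models, the
tunable parameters, the numerical choices, and what the simulation-based
validation does and does not establish.

## Calcium-oscillation quantification

### Model and pipeline

Somata are segmented on one reference frame of an 8-bit movie: pixels
strictly brighter than the threshold (default 50 on the 0–255 scale) are
foreground, 8-connected components are candidate ROIs, and components below
the minimum particle size (default 20 px²) are discarded as non-somatic
debris. A background ROI is selected automatically as the darkest square
window (side `ceiling(sqrt(min_area))`) that touches no foreground
component; the per-frame ROI trace is the arithmetic mean over member
pixels.

Each raw trace is processed in a fixed order:

1. pointwise subtraction of the background trace;
2. a centered moving-average of the configured window (default 10 frames);
3. ΔF/F₀, with F₀ the mean of the lowest 20% of the smoothed samples
   (`k = ceiling(0.2 n)`);
4. a least-squares line fit of ΔF/F₀ against frame index, with only the
   slope component `slope · (t − mean(t))` subtracted, so bleaching or
   focus trends are removed while the mean level is preserved.

Peaks are local maxima of the normalized trace whose topographic prominence
reaches the threshold (default 0.05 ΔF/F₀ units). A peak's *duration* is its
full width at half prominence with linearly interpolated crossings (the
quantity is not standardized in the field; half-prominence width is the
common instrument-independent choice). Neurons with fewer than 3 peaks are
discarded; per-neuron metrics are the means of the peak parameters plus the
mean successive peak interval and the oscillation frequency (peaks per
second), and the per-recording summary takes medians over retained neurons.

### Numerical choices worth knowing about

* **Smoothing window symmetry.** The moving average uses a symmetric
  centered window of half-width `floor(w/2)` that shrinks symmetrically at
  the trace ends. Symmetric windows map affine traces to affine traces
  exactly, which is what makes the detrending step remove a pure linear
  ramp to machine precision; an asymmetric "w left, w−1 right" window would
  leave edge artifacts of the order of one slope step.
* **Peak-time refinement.** A fast-rise/slow-decay transient smoothed over
  ~3 s has its maximum displaced forward by two to three frames. Detection
  and all peak *parameters* therefore use the smoothed trace, but the
  reported peak *time* is refined to the maximum of the unsmoothed ΔF/F₀
  (lightly pre-averaged over 3 points for noise robustness) within half a
  smoothing window of the detection — the same raw-signal refinement idea
  the spike detector uses.
* **Boundary peaks are dropped.** Within half a smoothing window of either
  trace end, the shrinking window under-averages noise, so apparent
  threshold crossings there are unreliable and are excluded.
* **Thresholding convention.** The 0–255 segmentation threshold is read as
  a lower bound (foreground strictly brighter), which selects bright
  Fluo-4-loaded somata on a dark background.
* **F₀ ordering.** The lowest-20% baseline is computed after background
  subtraction and smoothing; a non-positive F₀ (background exceeding the
  ROI's resting fluorescence) is an error naming the ROI rather than a
  silent sign flip.

## MEA spike detection and firing-rate analysis

Spike detection combines a stationary (undecimated) wavelet transform with
the Teager energy operator (TEO). Per channel: the detail coefficients at
the deepest level of a sym5 stationary transform are computed by the
à-trous cascade (group-delay compensated); the TEO
ψ(n) = x(n)² − x(n−1)·x(n+1) sharpens transient energy against background;
ψ is smoothed with a unit-sum Hamming window (default 25 samples, 2 ms at
12.5 kHz); the detection threshold is `multiplier ·
median(|ψ|)/0.6745` (a robust MAD-based noise scale, default multiplier 8);
time-ordered local maxima above threshold are accepted subject to a 1 ms
refractory period; and each event time is refined to the largest absolute
raw-signal excursion within ±0.5 ms.

Two choices depart from habit and deserve explanation:

* **Decomposition depth 3.** At 12.5 kHz the level-3 detail band
  (≈0.78–1.56 kHz) matches the spectral content of a ~1 ms biphasic
  extracellular spike; level 2 (1.56–3.1 kHz) sits mostly above it. On
  simulated ground truth at SNR 5 the level-3 detector holds sensitivity
  1.00 at zero false discovery across a wide threshold range (multiplier
  8–16), whereas level 2 had no operating point with comfortable margins.
* **Amplitude validation.** The deep-detail wavelet response has sidelobes
  a few milliseconds from each spike. In quiet recordings the MAD-based
  threshold collapses toward zero and those sidelobes would be reported as
  events, so a refined event is kept only if its raw excursion exceeds 3
  robust SDs of the channel. At any realistic SNR this floor is far below
  true spike amplitude.

Electrode quality control retains a channel iff its rate is at least the
configured spikes-per-minute threshold — 10/min for conventional wells,
1/min for tripartite compartments, comparisons inclusive — at most the
tonic-spiking bound (default 100 Hz), and not manually excluded; reasons
are recorded and the operation is idempotent. Firing summaries are
arithmetic means of per-channel rates over retained channels, per well or
per compartment, and percent changes to baseline propagate missingness
(zero or missing baselines yield `NA`, never infinities).

## Pharmacological fingerprint

The serial stimulation protocol (baseline 1 → NMDA + glycine → D-AP5 →
wash → baseline 2 → AMPA → CNQX) yields four features per compartment, each
a percent change against its governing reference: f1 = NMDA+glycine vs
baseline 1, f2 = D-AP5 vs NMDA+glycine, f3 = AMPA vs baseline 2, f4 = CNQX
vs AMPA. Conventional layouts give 4 features; tripartite layouts
concatenate proximal, distal1, distal2 in that fixed order for 12.

Missing cells are mean-padded with the column mean pooled over both groups,
then every column is centered and scaled by its *population* (divide-by-n)
SD — the convention under which "mean 0, SD 1" holds as an exact identity
on the data matrix; constant columns are flagged and left centered. PCA is
computed by SVD of the standardized matrix, with a deterministic sign
convention (the largest-magnitude loading of each component is positive)
so repeated runs are bit-identical.

Group overlap is measured in a 2D component projection (PC1–PC2 by
default): each group's points are replaced by their convex hull, the hull
intersection is computed by Sutherland–Hodgman convex clipping, and

> overlap % = 100 · area(A ∩ B) / min(area A, area B).

The hull is the natural planar footprint of a surface meshed over a
scatter of points; density-weighted alternatives are out of scope. The
result is made exactly symmetric in group order by clipping in a canonical
order, and groups with fewer than three distinct non-collinear projected
points give a flagged degenerate result rather than a number.

## Statistical tests and relative quantification

All comparisons are two-sided and nonparametric with mid-ranks under ties:
Mann-Whitney U for independent groups (exact enumeration of all group
assignments for per-group n ≤ 8, tie-corrected normal approximation
otherwise), Wilcoxon signed-rank for paired data (zero differences dropped;
exact sign-pattern enumeration for n ≤ 15), and Kruskal-Wallis (via
`stats::kruskal.test`, tie-corrected) with Dunn's pairwise z-tests on
pooled ranks and Bonferroni correction capped at 1. The exact branches are
implemented directly because the standard exact routines decline ties;
they are verified in the test suite against independent brute-force
enumeration oracles and against `stats::wilcox.test` where the two
coincide. ΔΔCT relative quantification averages Ct replicates first, then
RQ = 2^(−ΔΔCT) against a reference gene and calibrator sample; the
calibrator's RQ is exactly 1 by construction.

## The synthetic-data generators

No public recordings accompany the study design this package supports, so
every stage is validated against seeded generators whose defaults define
the reference conditions:

* **Calcium** (`calcium_sim_spec`): 214 frames at 0.28 s (one minute),
  96×96 px, soma disks of radius 4 px at resting intensity 80 on a
  background of 10, with the top-left corner kept cell-free so a background
  ROI always exists. Events are homogeneous Poisson (0.1 Hz) with a 5 s
  absolute refractory period — the spacing of slow network-wide
  oscillations — and each adds the kernel
  (1 − e^(−u/0.3 s))·e^(−u/2.5 s), rescaled to a peak of 20 intensity
  units (ΔF/F₀ ≈ 0.29 against the background-subtracted baseline of 70).
  Pixel noise is Gaussian (SD 2 = amplitude/10) and clipping to [0, 255]
  happens after noise addition, mirroring 8-bit acquisition. The amplitude
  and kinetics were fixed so that the canonical detection threshold of
  0.05 sits several smoothed-noise SDs above the floor when the noise is a
  tenth of the transient amplitude — the regime in which prominence-based
  detection is reliable and which slow, moderate-amplitude widefield
  Fluo-4 transients occupy. Event times keep ten frames' margin from both
  recording ends so every true maximum is interior. The trace-path
  generator's background trace carries pixel noise divided by 5, emulating
  the 25-pixel averaged background ROI of the movie path.
* **MEA** (`mea_sim_spec`): 24 channels (one tripartite compartment) at
  12.5 kHz for 60 s — a deliberate scale-down of 10-minute sessions that
  keeps per-channel spike counts in the hundreds; refractory-thinned
  5 Hz Poisson trains; a Hann-windowed single-cycle biphasic template
  (1 ms, 100 µV peak, negative phase first) in 20 µV Gaussian noise
  (SNR 5).
* **Pharmacology** (`pharm_sim_spec`): 20 networks per group; lognormal
  baseline rates (median 2 Hz, σ_log 0.4); condition rates are the
  governing baseline times a group-specific factor with unit-mean
  lognormal noise (CV 0.2); controls respond strongly
  (NMDA+glycine ×1.8, D-AP5 ×0.5, AMPA ×2.0, CNQX ×0.3) while the treated
  group is blunted (×1.2, ×0.8, ×1.3, ×0.6), the signature of reduced
  glutamatergic drive; values are missing completely at random (5%), the
  regime in which mean padding is unbiased and hence the correct null for
  testing the imputation path.

What passing these simulations shows — and what it does not. The
generators reproduce the statistical structure the analysis assumes
(Poisson event statistics, additive Gaussian noise, multiplicative
pharmacological effects, MCAR missingness); they do not attempt
biophysical calcium buffering, electrode drift or impedance variation,
bursting or network synchrony, photobleaching nonlinearity, or outliers
that are not missing at random. Recovery on these simulations therefore
validates the computations, not the biology: on real recordings the
parameters (thresholds, windows, retention rules) still need the usual
per-dataset sanity checks.

### Separation experiment design

The null/effect validation of the fingerprint runs the full pipeline on two
groups drawn from one distribution (expected overlap stays high, ≈75–80%
on average at n = 20 per group) and on cohorts where the treated group's
*standardized* f1 is shifted by 0–6 pooled SDs. The shift is applied after
standardization deliberately: re-standardizing after a raw shift would
rescale f1 back to unit variance, so the separation would carry no excess
variance and PCA would have no reason to place it in the leading
components — the test would then measure an arbitrary rotation rather than
the overlap machinery. Expected overlap decreases monotonically along the
shift grid and reaches 0% at 6 SDs. Because convex hulls are sensitive to
single points, individual null draws can fall below the long-run mean;
bounds are therefore asserted on replicate means (50 replicates).

### Problem sizes used in validation

The shipped test-suite and the acceptance script use 100-trace calcium
cohorts (≈370 events), one 32-channel × 60 s MEA recording (≈9,500
spikes), 50-replicate fingerprint grids at n = 20 networks per group, and
5,000-replicate null calibration of the Mann-Whitney test — sizes chosen
so the whole validation runs in a few minutes on one CPU while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The ROI model is a single reference-frame threshold; cells that are dark
  at the reference frame are invisible, and overlapping somata merge.
* SWTTEO parameters are tuned for ~1 ms spikes at 12.5 kHz; other sampling
  rates need `swt_level` revisited (the detail band scales with fs).
* The overlap statistic is a convex-hull measure: a single outlier can
  inflate a hull, and multimodal groups are summarized by one hull each.
* Exact tests enumerate combinations; they are intended for the small-n
  regime (per-group n ≤ 8 / paired n ≤ 15) and switch to tie-corrected
  normal approximations beyond it.
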