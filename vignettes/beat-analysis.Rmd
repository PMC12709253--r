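---
title: "Measuring the wavelength of the ciliary beat: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the wavelength of the ciliary beat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliawave)
```

## The measurement problem

An isolated, reactivated axoneme beats at 60–70 Hz with a bending wave that
travels from base to tip, while its intrinsic curvature asymmetry makes the
whole organelle swim in circles. High-speed phase-contrast imaging followed
by filament tracking yields, for every frame, an ordered list of centerline
coordinates in micrometres. Everything in this package starts from that
table — image acquisition and tracking are outside its scope.

The working representation is the tangent angle ψ(s, t): the lab-frame
angle of the filament's tangent at arc length s and time t. It is the
natural coordinate for a slender filament — curvature is ∂ψ/∂s, rigid-body
rotation is an additive term, and a traveling bending wave is (to first
approximation) a sinusoid in s whose phase advances linearly in t:

$$\psi(s, t) \;=\; C_0\, s \;+\; a \sin\!\big(2\pi s/\lambda_0 - 2\pi f t + \phi\big) \;+\; \Omega t ,$$

with static curvature $C_0$ (the circular-arc component responsible for
circular swimming), amplitude $a$, wavelength $\lambda_0$, beat frequency
$f$, and frame rotation rate $\Omega$. The analysis pipeline inverts this
model stage by stage; the synthetic generator produces data from exactly
this model so every stage can be checked against known truth.

## Pipeline stages and their assumptions

**Geometry.** Per frame, arc length is accumulated from segment chords,
x(s) and y(s) are interpolated with cubic splines, and ψ is obtained by
central differences of the resampled coordinates on a regular grid (default
spacing 0.218 µm, matching pixel-wise tracking), with second-order
one-sided stencils at the two ends. A first-order end stencil would read
the angle half a sample inward; because the leading angle later serves as
the rotation reference, that half-sample bias would propagate to the whole
field, so the extra stencil order matters. Angles are unwrapped along s so
no neighbouring samples differ by π or more. Frame length is measured by
integration along the fitted spline (an 8×-refined chord sum): a raw
polyline chord sum systematically underestimates arc length by
≈ (κ·ds)²/24 per segment, which is enough to clip one sample off the
common resampling grid when the true length sits on a grid boundary. Frames
with fewer than 4 points are rejected; frames whose length deviates more
than 5% from the median are flagged as likely tracking failures (the
threshold is configurable; nothing in the data fixes it).

**Rotation removal.** The leading tangent angle ψ(0, t) oscillates around
a growing trend as the axoneme rotates. After unwrapping in time, the trend
is fitted by LOESS (degree 2, exact "direct" surface) and subtracted from
ψ(s, t) at every s, frame by frame. The span is the one free parameter: it
must be long compared with a beat period, short compared with any swimming
manoeuvre. The default covers five beat periods of a provisional
frequency taken from the leading angle's spectrum; with 65 Hz beats in a
1 s record that is a span of ≈ 0.08. The least-squares slope of the fitted
trend is reported as the rotation rate Ω. Because the oscillation leaks
slightly into any finite-span smoother, recovered rates carry ~2% bias at
the defaults — well inside the 5% accuracy the pipeline claims for Ω.

**Beat segmentation and decomposition.** The record is cut into
consecutive windows of round(1/(f·dt)) frames; a trailing partial window
is discarded. The static component ψ̄(s) is the time average over complete
windows only — averaging over a partial cycle would bias it by up to
a·(missing phase fraction). The dynamic component is the residual
ψ_d = ψ − ψ̄; by construction its time mean over the used frames is zero.
The static curvature C₀ is the ordinary least-squares slope of ψ̄(s)
versus s, the static profile being close to linear (a circular arc).

**Frequency.** Temporal power spectra of ψ_d at each s are averaged over
s and the dominant bin is refined by a three-point parabola in log power —
the standard first-order-unbiased refinement of a DFT peak; it is exact
when the tone sits on a bin and errs by well under 0.2 Hz for off-grid
tones at these record lengths. Records whose largest peak is not at least
10× the median spectral power are rejected as having no resolvable
oscillation; that prominence floor is what turns an amplitude-zero input
into a clean error instead of a nonsense frequency.

**Wave velocity.** Zero crossings of ψ_d(s) are located per frame by sign
change and linear interpolation, after a 0.5 µm running-mean smoothing that
exists only to stop angle noise from manufacturing spurious crossings near
the zeros. Crossings are linked frame-to-frame by nearest neighbour inside
a gate of 1.5× the median per-frame displacement from a coarse first pass
(floored at two arc samples, so standing patterns still link); each track
with at least 3 frames contributes the slope of its s-versus-t line, and
the mean slope is the wave velocity. Crossings reaching the window ends
terminate their tracks. All retained tracks are used; nothing restricts
them to the interior.

## The wavelength estimator

For each frame the finite-window spatial spectrum

$$G_\psi(k, t) = \Big(\int \psi_d \cos(ks)\, ds\Big)^2 + \Big(\int \psi_d \sin(ks)\, ds\Big)^2$$

is computed by trapezoid integration on the arc grid, with no taper —
G is invariant to the arc-length origin, so only the window length matters.
G is averaged over the frames of each beat window, the average is maximised
over a 2048-point k-grid spanning wavelengths between a quarter and twice
the tracked length, and the gridded argmax is refined by a three-point
parabola (keeping discretization error far below the 1% bias budget; the
refined step is ~0.001 rad/µm at L = 10 µm). Per-beat wavelengths 2π/k̂
are averaged over the 20–110 beats a 1 s record contains, and the quoted
uncertainty is the standard error of that mean. Peaks landing on the search
boundary are flagged as possible out-of-range wavelengths.

Averaging G per beat and pooling the per-beat argmax values (the default)
and averaging G over all frames before a single argmax are both
implemented; on clean records they agree to well within a grid step, and
the per-beat route additionally yields the beat-to-beat spread.

**Why the beat average matters.** For ψ_d = a·sin(k₀s − ωt) on a window of
length T, averaging the phase uniformly over a beat gives the closed form

$$\langle G\rangle(k) = a^2\left[\frac{\sin^2((k_0-k)T/2)}{(k_0-k)^2} + \frac{\sin^2((k_0+k)T/2)}{(k_0+k)^2}\right].$$

The difference term peaks exactly at k₀; the sum term is a finite-window
tail whose slope at k₀ displaces the maximum unless T holds an integer
number of wavelengths. A single frame at a fixed phase carries an
additional interference bias of order 1/(k₀T) — about 1% at T = 4λ₀ —
that the phase average cancels; this is why unbiasedness claims attach to
the beat-averaged spectrum only. The closed form is verified in the tests
against composite-Simpson quadrature with an 8-point phase grid (exact for
the trigonometric polynomial the beat average involves) to 10⁻⁸ relative.

**Bias and the analysis window.** On the standard discrete grid (0.218 µm
spacing, 15-frame beat windows at 65 Hz) the estimator's systematic error
on noise-free traveling waves is 0.32% at window = λ₀ and smaller at every
larger window/wavelength ratio; below a ratio of ~0.5 the peak leaves the
searched range and the estimate is unreliable. `bias_curve()` regenerates
this curve on demand.

The `s_trim` option restricts integration to an interior window — e.g.
`s_trim = 0.1` analyses the middle 80% of the axoneme, the appropriate
choice for tracked microscopy data whose end coordinates are the least
reliable, while the wavenumber search range keeps using the full tracked
length. It is deliberately **not** the default, and validation runs use the
full window: trimming shortens the effective window to 0.8L, and at
λ₀ ≈ L that pushes the window/wavelength ratio to 0.8, where the
finite-window tail inflates the bias to ≈ 2% — a property of the window,
not of the data quality. On simulated beats the full window is both
available and unbiased; on real traces the trim trades this small,
predictable bias against tracking artefacts. The bias tests assert the
untrimmed behaviour and a companion test documents the trimmed one.

**Noise.** Uniform angle noise adds an essentially flat floor to ⟨G⟩,
which shifts the argmax only through its k-dependence — negligible after
averaging over beats. With ±50% uniform noise (noise amplitude half the
beat amplitude) the pooled estimate moves by ~0.4 refined grid steps
(~0.06%), and the estimator remains within 2% of truth; the v/f
alternative degrades far more (see below).

## Cross-validation: λ = v/f

The conventional wavelength estimate divides the zero-crossing wave
velocity by the DFT frequency. On noise-free synthetic beats the two
methods agree within 3%. Under strong angle noise, replicate simulations
show the variance of λ_v/f exceeding that of the Fourier estimate by more
than an order of magnitude: crossing positions inherit noise directly
(position jitter ≈ noise SD divided by the local slope a·k₀), whereas the
Fourier estimate pools every sample of every frame before taking a single
argmax. This variance ordering is asserted in the acceptance tests over 50
replicate seeds.

## The crossing-count comparison test

To compare wavelength-versus-length data from two preparations without
assuming a functional form, one preparation is interpolated linearly over
length to form a reference curve, and the other's points (restricted to
the overlapping length range, ordered by length) contribute the count n of
sign changes of their residuals. Under the null that both preparations
sample the same curve, residual signs behave like fair coin flips, so n
has mean ≈ N/2 and standard deviation ≈ √N/2; the statistic
t = |n − N/2|/(√N/2) is referred to a t distribution with ⌊N/2⌋ degrees of
freedom, two-sided, with Bonferroni correction across comparisons.
Exactly-zero residuals inherit the previous sign and flag the result.

Two approximations are acknowledged rather than hidden. The count has
N − 1 opportunities, so its null mean is (N−1)/2, half a crossing below
N/2; and interpolating a noisy reference correlates neighbouring
residuals, nudging the mean down further (≈ 9.2 for N = 20 in simulation)
and the SD slightly below √N/2. Monte-Carlo calibration over 1000
same-curve replicates shows the realised type-I error at α = 0.05 is
~4–5%, i.e. the test is mildly conservative and safe to use as a
significance screen; the tests assert 5% ± 2% and moment agreement within
10–15%. Reference-curve construction by linear interpolation is itself an
interpretation of "one preparation's data crossing another's"; the null
calibration is what validates it.

The regression helper applies the complementary rule used for trend
screening: a fitted slope is deemed not significant when it lies within
two standard errors of zero (the 95% confidence-interval rule).

## Mechanics closed forms

Three resistive-force-theory quantities summarise the physics downstream
of the measurements: the Machin number Ma = f ξ⊥λ⁴/(8π³κ) (hydrodynamic
relative to bending forces; Ma ≪ 1 is the bending-dominated regime), the
propulsive force per unit length F/L = 2π²(ξ⊥ − ξ∥) f y₀²/λ of a
small-amplitude sinusoidal beat, and the swimming speed v = F/(Lξ∥). Drag
coefficients ξ⊥, ξ∥ (pN·s/µm²) and flexural rigidity κ (pN·µm²) are
user-supplied — published values vary with buffer and method and none are
hardcoded; examples in the documentation use literature-typical magnitudes
(ξ⊥ ≈ 2ξ∥ ≈ 0.0034 pN·s/µm², κ ≈ 400 pN·µm²) labelled as such.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
the traveling-wave tangent field with static curvature, rigid-body
rotation, the 0.218 µm / 1 ms / 1000-frame sampling of the imaging
conditions, i.i.d. uniform angle noise (the stress model under which the
estimator was validated), optional Gaussian coordinate jitter emulating
tracker error, and an optional linear amplitude taper (no measured value
constrains tapering, so the default is uniform amplitude). Centerlines are
integrated from the field with circular-arc elements — exact for
piecewise-linear tangent angle — so the points sit at their true arc
spacing; a trapezoid rule here would shorten every segment by ≈ Δψ²/8 and
bias downstream length measurements. Defaults (L = 10 µm, λ₀ = 10 µm,
a = 0.5 rad, f = 65 Hz, C₀ = 0.2 rad/µm) sit at the centre of the measured
ranges for reactivated axonemes.

It does **not** emulate frequency drift or beat-to-beat waveform
variability, amplitude envelopes beyond the linear taper, correlated
tracking noise, rigid-body translation, or hydrodynamic coupling to the
wall. Passing tests on synthetic data therefore demonstrate correctness of
the estimators under the stated model, not robustness to every failure
mode of real microscopy; the length-deviation flags and boundary-peak
flags exist to surface such failures on real data rather than absorb them.

## Numerical choices and degenerate inputs

- Wavenumber search: 2048 uniform grid points plus parabolic refinement;
  halving the grid step never worsens the estimate by more than one coarse
  step (asserted as a property test).
- Integrals: trapezoid on the native arc grid; no windowing function.
- Beat windows shorter than 3 frames (undersampled) and frequencies
  outside (1/duration, Nyquist) are errors, as are records with no
  resolvable spectral peak, empty analysis windows, all-frames-rejected
  inputs and degenerate (constant-time) records.
- Segmentation windows are fixed-length; the ~2.5% mismatch between 15
  frames and the true 15.38-frame period at 65 Hz leaves a small residual
  in per-beat phase coverage that averages out across the 66 beats of a
  record (visible as the 0.32% bias figure above).
- Determinism: all noise flows through a single seed; identical parameters
  and seed give bit-identical fields, and reports are reproducible
  (config hash and seed are recorded in the provenance block).

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on synthetic
records of 200–1000 frames and 8–25 µm axonemes: five window/wavelength
ratios for the bias bound, 50 noisy replicates for the variance
comparison, and 1000 Monte-Carlo replicates for the crossing-test
calibration. These sizes hold every Monte-Carlo standard error well below
the tolerance it guards while keeping the whole suite in the
single-minute range on one core.

## Known limitations

- The estimator needs at least half a wavelength inside the window;
  wavelengths beyond twice the window are reported only as boundary flags.
- Wave velocity assumes a single dominant traveling wave; standing waves
  give v ≈ 0 by design, and mixed standing/traveling patterns are
  averaged, not decomposed.
- LOESS rotation removal assumes the rotation trend is smooth on the
  five-beat timescale; rapid re-orientations will leak into the dynamic
  field.
- The crossing-count test is mildly conservative and its reference-curve
  interpolation is one of several defensible readings of the procedure it
  implements.
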