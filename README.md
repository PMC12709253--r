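# ciliawave

Quantitative waveform analysis of the traveling-wave beat of cilia and
flagella, starting from digitized centerline coordinates.

Isolated, reactivated axonemes (the microtubule core of a cilium) beat with
a bending wave that travels from base to tip while the whole organelle swims
in circles. Given per-frame centerline coordinates `(x, y)` of the tracked
filament, `ciliawave` reconstructs the tangent-angle representation
ψ(s, t) (angle of the local tangent versus arc length s), removes the
rigid-body rotation of the swimming frame, splits the beat into its static
component (the time-averaged circular arc, with static curvature C₀) and
its dynamic component ψ_d(s, t), and measures the beat's wavelength,
frequency and wave velocity. It is written for experimentalists analysing
high-speed microscopy of *Chlamydomonas* axonemes and similar
micro-swimmers, and for anyone validating waveform estimators on synthetic
beats.

The core statistic is a finite-window Fourier estimator of the dominant
angular wavenumber k₀ = 2π/λ₀ of the dynamic beat. For each frame,

G_ψ(k, t) = ( ∫ ψ_d(s, t) cos(ks) ds )² + ( ∫ ψ_d(s, t) sin(ks) ds )²,

is proportional to the spatial power spectrum of ψ_d; G is averaged over
each beat cycle, maximised over k in the range corresponding to wavelengths
between a quarter and twice the tracked length, and the per-beat wavelengths
2π/k̂ are pooled into a mean with a standard error. For a sinusoidal
traveling wave whose wavelength does not exceed the analysis window the
estimator's systematic error is below 1%, and the beat-averaged spectrum has
the closed form

⟨G⟩(k) = a² [ sin²((k₀−k)T/2)/(k₀−k)² + sin²((k₀+k)T/2)/(k₀+k)² ],

which peaks exactly at k₀ when the window length T equals λ₀.

The package also provides:

- beat frequency by temporal DFT with parabolic (log-power) peak
  interpolation, and wave velocity by linking the zero crossings of
  ψ_d(s) across frames — giving the conventional wavelength λ = v/f used to
  cross-check the Fourier estimator;
- a nonparametric crossing-count test comparing wavelength-versus-length
  data between preparations (t = |n − N/2| / (√N/2) with N/2 degrees of
  freedom, Bonferroni-corrected), and a two-standard-error slope
  significance rule for regressions;
- closed-form low-Reynolds-number quantities: Machin number
  Ma = f ξ⊥ λ⁴ / (8π³κ), propulsive force per unit length
  F/L = 2π²(ξ⊥ − ξ∥) f y₀²/λ, and swimming speed v = F/(Lξ∥);
- a synthetic traveling-wave generator (`beat_params()`,
  `generate_tangent_field()`, `generate_centerlines()`) that emulates the
  imaging conditions (1000 frames at 1 ms, 0.218 µm arc sampling, ~65 Hz
  beat, static curvature ~0.2 rad/µm, optional uniform angle noise) so every
  stage is testable without microscopy data.

## Worked example

```r
library(ciliawave)

# a 10 um axoneme beating at 65 Hz with wavelength = length, rotating at
# 1 rad/s, as tracked centerlines
p  <- beat_params(length_um = 10, wavelength_um = 10, frequency_hz = 65,
                  static_curvature_per_um = 0.2, rotation_rate_rad_s = 1)
cl <- generate_centerlines(p)

report <- analyze_axoneme(cl, id = "synthetic-10um")
report
#> <axoneme_report> synthetic-10um
#>   L = 9.81 um | lambda = 10.05 +/- 0.0067 um (66 beats) | f = 65 Hz
#>   v = 650.2 um/s | v/f = 10 um | C0 = 0.2 rad/um | Omega = 1.02 rad/s
```

All four generating parameters are recovered: wavelength 10.05 µm (true
10; the ~0.5% excess is the documented finite-window bias at λ ≈ window),
frequency 65.00 Hz, static curvature 0.20 rad/µm, rotation rate
1.02 rad/s. `glance(report)` returns the same numbers as a one-row tibble
for batch work, and `tidy()` / `autoplot()` methods expose per-beat
wavelengths, spectra and fields.

Estimator validation (bias curve, ±50% noise robustness, analytic-spectrum
overlay) is bundled:

```r
validate_estimator()
#> <validation_report>
#>   max |bias| for ratio >= 1: 0.323%
#>   noise shift: 0.367 refined grid steps (noise 50%)
#>   analytic vs numeric peak: |dk| = 0 (grid step 0.0011)
#>   pass: bias_below_1pct, noise_shift_below_one_step, analytic_peak_matches
```

A thin command-line front end over these functions (subcommands `simulate`,
`analyze`, `compare`, `validate`) is installed at
`inst/cli/ciliawave.R`.

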