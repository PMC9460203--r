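# fmcwvitals

Non-contact estimation of respiration and heart rates from
frequency-modulated continuous-wave (FMCW) radar, for researchers and
engineers building contactless vital-sign monitors. A person sitting in
front of a millimetre-wave radar modulates the phase of the reflected
chirps with sub-millimetre chest motion; this package turns that phase
into breathing and heartbeat frequencies, and ships a full scene
simulator so every stage can be developed and tested without radar
hardware.

## The processing chain

A target at range `R` with chest displacement `D(t)` imposes the
two-way carrier phase

    psi(t) = (4 pi / lambda) * (D(t) + R),        lambda = c / fc,

on the beat (IF) signal (about 3.9 mm wavelength at 77 GHz, so
millimetre breathing motion spans several radians). The chain is:

1. **Static clutter filtering** — subtract the across-frame mean from
   every fast-time sample: stationary reflectors cancel exactly, while
   periodic vital motion averages towards zero and survives.
2. **Range FFT + bin selection** — FFT along fast time; the subject's
   bin is the one with maximal slow-time variance of the complex
   profile (after clutter removal the subject is defined by variation,
   not brightness).
3. **Extended DACM demodulation** — accumulate per-frame phase
   increments `atan2(I[k-1]Q[k] - Q[k-1]I[k], I[k]I[k-1] + Q[k]Q[k-1])`,
   avoiding the arctangent's ±pi wrapping entirely.
4. **Adaptive alpha-stable EEMD** — the core of the package. Ensemble
   empirical mode decomposition separates the heartbeat tone from
   respiration harmonics that fall in the same 0.8–2 Hz band. Two
   departures from classic Gaussian EEMD:
   * the ensemble noise is **symmetric alpha-stable** (index
     `alpha` in (0, 2]; `alpha = 2` recovers Gaussian), matching the
     impulsive character of ambient noise in public spaces, with each
     noise realization pre-decomposed by EMD and its q-th mode used to
     perturb stage q (antithetic ± pairs, so residual noise cancels);
   * decomposition **terminates early** once a mode's extrema rate
     `sigma = (#maxima + #minima) / (2 T)` falls inside the
     respiration band (0.1–0.5 Hz) and its mean peak-to-trough
     amplitude `gamma` lies inside the phase-scaled displacement
     window `(4 pi / lambda) * [1 mm, 12 mm]` — that mode is the
     respiration IMF, and no further modes are computed.
5. **Rate estimation** — autocorrelation peak (headline), windowed
   spectral peak, and peak counting, reported side by side in Hz and
   per-minute units.

The alpha-stable machinery (numerically integrated density with an
asymptotic tail series, Chambers–Mallows–Stuck sampling, maximum-
likelihood stability-index estimation) is exposed directly:
`alpha_stable_pdf()`, `sample_alpha_stable()`, `estimate_alpha_ml()`.

## Worked example

```r
library(fmcwvitals)

# the reference simulation: respiration 0.32 Hz (+ harmonics 2/3/4/6),
# heartbeat 1.54 Hz, 20 Hz sampling, 60 s, noise at 0.2 of signal sd
sim <- simulate_vital_phase(rng_seed = 1)
report <- run_pipeline(phase = sim$phase, config = eemd_config(rng_seed = 42))
print(report)
#> <vitals_report>
#>   4 IMFs, terminated early: TRUE
#>     component     method frequency_hz rate_per_min             flag
#> 1 respiration   autocorr    0.3174603     19.04762             <NA>
#> 2 respiration   spectral    0.3222656     19.33594             <NA>
#> 3 respiration peak_count    0.3166667     19.00000             <NA>
#> 4   heartbeat   autocorr    1.4285714     85.71429 weak periodicity
#> 5   heartbeat   spectral    1.5429688     92.57812             <NA>
#> 6   heartbeat peak_count    2.4166667    145.00000             <NA>
```

Four IMFs sufficed: the fourth triggered the respiration termination
criteria, and the second was labeled heartbeat. The spectral estimate
pins the heartbeat at 1.543 Hz (92.6 bpm; truth 1.54 Hz) and
respiration at 0.322 Hz (truth 0.32 Hz). The autocorrelation estimate
is quantized to integer lags (1/13th vs 1/14th of a second here) and
flags itself when its peak is weak; the raw peak count overcounts noisy
ripples on the heartbeat mode — reporting all three side by side is
deliberate, and the spectral column is the one to trust for sharp
tones.

The full radar path starts from a simulated IF cube instead:

```r
cfg  <- radar_config()           # 77 GHz, 4 GHz sweep, 20 Hz frames
d    <- simulate_displacement(vital_sign_params(harmonics = default_harmonics()),
                              fs = 20, duration = 60)
cube <- simulate_if_cube(cfg, list(
          scene_target(0.65, "vital", displacement = d),
          scene_target(1.30, "static", reflectivity = 2)),
        n_frames = 1200, noise_scale = 0.01, rng_seed = 5)
run_pipeline(cube = cube, config = eemd_config(rng_seed = 9))
```

which filters the static reflector, selects the 0.65 m bin, and
produces the same style of report. A thin command-line wrapper with
`simulate` / `filter` / `phase` / `decompose` / `rates` / `run` /
`fixtures` subcommands lives at `inst/cli/fmcwvitals.R`.

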