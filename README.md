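# rhythmdesign

Optimal measurement timing for biological rhythm detection.

Biological-rhythm studies (circadian transcriptomics, hormone profiling,
circalunar/circannual ecology) almost universally sample at equally spaced
times. That is provably the best choice when the period is known and sampling
is unconstrained — and can be a quietly terrible one when a rest window
forbids overnight sampling, when several candidate periods are probed at
once, or when the period is only known to lie in a range. `rhythmdesign`
computes the *exact* statistical power of cosinor-based rhythm detection at
arbitrary measurement times and optimizes the times themselves.

## The statistics in one paragraph

For the cosinor model `Y(t) = M + A·cos(2πft − φ) + ε`, `ε ~ N(0, σ²)`,
rhythm detection is the F-test that both trigonometric coefficients vanish.
At measurement times **t** its power is
`γ = 1 − F_λ(F⁻¹(1−α; 2, N−3); 2, N−3)` with noncentrality
`λ = bᵀ(H(XᵀX)⁻¹Hᵀ)⁻¹b / σ²`, where `X` is the cosinor design matrix at
**t**, `H` selects the trig coefficients and `b = (A cos φ, A sin φ)`. The
worst case of `λ` over all acrophases φ is `(A²/σ²)·ξ_min`, the smallest
eigenvalue of a 2×2 information matrix, so designs are ranked by `ξ_min`
(or by `J = min over target frequencies of ξ_min`) without knowing
amplitude or noise; `ξ_min ≤ N/2` always, with equality for equispaced
designs below their Nyquist rate `N/2`. The package's optimizers —
exhaustive necklace search, eigenvector cutting planes for the
mixed-integer conic formulation, differential evolution, and an
anchored constrained search — maximize exactly this criterion, and a
free-period permutation test (peak or integrated amplitude statistic)
benchmarks the resulting schedules under continuous period uncertainty.

## Worked example: an 8 h rest window

Eight samples on a 24 h cycle, no sampling during an 8 h rest window.
The naive schedule spreads the samples evenly across the allowed 16 h;
the optimal one is found by exhaustively scoring all C(32, 8) = 10,518,300
placements on a half-hour grid by the minimum-eigenvalue criterion:

```r
library(rhythmdesign)

naive <- naive_constrained_design(8, start = 0, end = 8/24)
round(as.numeric(naive) * 24, 2)
#> [1]  0.00  8.00 10.29 12.57 14.86 17.14 19.43 21.71
worstcase_power_acrophase(naive, 1, amplitude = 2.5, n_phase = 512)
#> <acrophase_scan> f=1  power range [0.7175, 0.9468]  delta = 22.93 pp

allowed <- rest_window_mask(48, 0, 8/24)
opt <- optimize_brute(8, 48, frequencies = 1, allowed = allowed, cap = 1.1e7)
round(as.numeric(opt$design) * 24, 2)
#> [1]  8.0  8.5 14.5 15.0 16.5 17.0 23.0 23.5
worstcase_power_acrophase(opt$design, 1, amplitude = 2.5, n_phase = 512)
#> <acrophase_scan> f=1  power range [0.8708, 0.8750]  delta = 0.4133 pp
```

Read: depending on when the rhythm peaks, the naive design's power swings
between 72% and 95% (a 22.9-point spread) at amplitude 2.5, σ = 1,
α = 0.05, while the optimized schedule — pairs of half-hour-spaced samples
hugging the window edges and mid-arc — holds power within 0.4 points of
constant at ~87%.

Targeting several periods at once costs nothing when an equiphase
construction exists:

```r
d2 <- equiphase_design(12, c(1, 12))   # 24 h and 2 h rhythms, N = 12
multifreq_objective(d2, c(1, 12))
#> <objective_report> J = 6  (worst-case lambda 6, worst-case power 0.4411)
```

`J = 6 = N/2` is the theoretical maximum at *both* frequencies — the
schedule detects 24 h and 2 h rhythms as well as a dedicated equispaced
design would detect either alone (worst-case power here quoted at A = σ).

See the vignette (`vignettes/rhythm-design-power.Rmd`) for the model,
conventions, and the free-period permutation machinery.

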