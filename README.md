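# nucurve

Sequence-based prediction of nucleosome positions from intrinsic DNA
curvature, for chromatin and regulatory-genomics work where experimental
nucleosome maps are unavailable or a sequence-encoded baseline is wanted.

Nucleosomal core DNA bends sharply, and part of that bendability is written
in the sequence: each dinucleotide step carries small roll (ρ) and tilt (τ)
wedge angles, and wedges recurring in phase with the helical repeat
accumulate into curvature of the helix axis. The package

1. computes the **curvature curve** of a sequence from a 16-step roll/tilt
   table,

   |C| = | (ν₀/W) Σⱼ (ρⱼ − i·τⱼ) · exp(2πij/ν₀) |,  j = 0..W−1,

   with ν₀ = 10.4 bp/turn and W = 10 steps by default;
2. cross-correlates it against the canonical **curvature pattern** of
   nucleosomal core DNA (elevated over ~50 bp at each end of the wrapped
   segment, lower over the ~47-bp middle; zero-mean, unit-norm) — a matched
   filter whose peaks mark candidate dyads (**curvature profile**);
3. calls dyads with **MSCWT** — the per-position maximum over scales
   (25–100 bp) of a Mexican-hat continuous wavelet transform — taking local
   maxima above the 0.70 spectrum quantile, greedily, at ≥100 bp
   separation; each dyad becomes a 147-bp call (dyad ± 73 bp).

Around the predictor it provides the matching evaluation toolkit
(matching-ratio sweeps over 1–60 bp deviations, the interval overlap ratio
[2(73−d)+d]/147, hexamer occupancy ratios and their Pearson correlation
between call sets), site-centered analyses (strand-aware anchored average
profiles, two-class k-means TSS classification over [−150, +50] bp, WW/SS
dinucleotide and poly(dA:dT) fraction profiles), JASPAR PWM promoter
scanning with cross-TF average binding profiles, and seeded synthetic
fixture generators so everything runs and is testable without any genome
download.

## Worked example

```r
library(nucurve)

mod <- nucleosome_model()      # idealized 147-bp template, default angles
mod
#> Curvature-profile nucleosome positioning model
#>   template: idealized, length 147, dyad index 73
#>   curvature: nu0 = 10.40 bp/turn, window = 10 steps
#>   peak calling: 16 wavelet scales (25-100 bp), min spacing 100 bp, q = 0.70

# a 50-kb synthetic genome with nucleosome cassettes every 190 bp,
# ground truth recorded
fx <- simulate(mod, seed = 7, length = 50000)

calls <- predict(mod, fx$genome)   # curve -> matched filter -> MSCWT -> calls
summary(calls)
#> 251 nucleosome calls on synth, dyads 194-49687; mean spacing 198.0 bp (median 190)

head(calls, 3)
#>   chrom dyad    score start end
#> 1 synth  194 32.57925   121 268
#> 2 synth  475 32.66356   402 549
#> 3 synth  666 29.71447   593 740

# score the prediction against the planted truth
mc <- match_curve(fx$truth$dyads, calls$dyad)
round(mc$matching_ratio[c(10, 20, 40)], 3)
#> [1] 0.779 0.787 0.787
```

The model recovers ~79% of the planted dyads within ±20 bp on this seed
(84–88% is typical across seeds), the calls' mean centre-to-centre spacing
sits near the planted 190-bp repeat, and the matching-ratio curve is flat
beyond ~±20 bp because matched calls are already that accurate. `predict`
attaches the matched-filter profile as `attr(calls, "profile")`;
`write_calls_bed()` exports BED6.

A command-line wrapper over the same functions is installed as
`exec/nucurve` (subcommands `curve`, `pattern`, `predict`, `evaluate`,
`sites`, `pwm`, `simulate`).

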