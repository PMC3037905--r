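---
title: "Predicting nucleosome positions from DNA curvature profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nucleosome positions from DNA curvature profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucurve)
```

## The model

A nucleosome wraps ~147 bp of DNA around the histone octamer, and the
wrapped DNA must bend sharply. Part of that bendability is intrinsic to the
sequence: successive base-pair steps carry small "wedge" deformations —
roll (bending into the grooves) and tilt (bending toward the backbones) —
and when wedges of like direction recur in phase with the helical repeat,
their contributions accumulate into macroscopic curvature of the helix
axis. `nucurve` exploits this to predict nucleosome positions from sequence
alone, in three stages.

**1. Curvature curve.** For a window of $W$ dinucleotide steps the
curvature vector is

$$C = \frac{\nu_0}{W}\sum_{j=0}^{W-1}(\rho_j - i\,\tau_j)\,
      e^{2\pi i j/\nu_0},$$

with $\rho_j$, $\tau_j$ the roll and tilt angles (degrees) of the $j$-th
step and $\nu_0$ the helical periodicity (default 10.4 bp/turn). The phase
factor advances one full turn every $\nu_0$ steps, so wedges that recur at
the helical repeat add coherently while randomly phased wedges cancel. The
modulus $|C|$, assigned to the window's center base, measures local
deviation from straight B-DNA; sliding the window along a sequence gives
the *curvature curve*. Windows touching an N are masked to 0 rather than
interpolated — absence of sequence evidence should not fake signal.

Two conventions deserve a note. First, the phase exponent is implemented
as $e^{2\pi i j/\nu_0}$: only with the periodicity in the denominator does
the phase advance $2\pi$ per helical repeat (an `exp_convention = "literal"`
switch retains the alternative reading $e^{2\pi i j \nu_0}$ for
comparison, though it carries no helical meaning). Second, with the step
term written $\rho - i\tau$ and a positive phase exponent, *coherent*
bending corresponds to $\rho_j = \cos(2\pi j/\nu_0)$,
$\tau_j = +\sin(2\pi j/\nu_0)$ — the wedge vector counter-rotating against
the helical phase — which is what the package's property tests assert.

**2. Curvature pattern.** Nucleosomal core DNA has a characteristic
curvature shape: stronger bending over roughly 50 bp at each end of the
wrapped segment, weaker over the ~47-bp middle. `build_pattern()` estimates
this template as the positionwise mean curvature curve of aligned 146/147-bp
core sequences (e.g. from nucleosome crystal structures); when no such set
is supplied, `idealized_pattern()` provides a piecewise stand-in (high
plateaus over the two 50-bp ends, a low middle, 5-bp half-cosine ramps),
mirror-symmetric about the dyad. Either way the template is scaled to zero
mean and unit L2 norm. That normalization is deliberate: it turns the next
stage into a proper matched filter, insensitive to the baseline curvature
level and to the overall angle scale of whichever roll/tilt table is used.

**3. Curvature profile and dyad calling.** The *curvature profile* is the
sliding dot product of the curvature curve with the template, each
placement's score assigned to the position aligned with the template's dyad
index — a matched filter whose peaks mark candidate dyads.
Peaks are localized by the maximal spectrum of a continuous wavelet
transform (MSCWT): the profile is transformed with a Mexican-hat wavelet at
scales 25–100 bp (step 5) and, per position, the maximum coefficient over
scales is kept. The zero-mean wavelet removes baseline; maximizing over a
scale range sharpens peaks of nucleosome-like width wherever their exact
width falls in that range. Strict local maxima of the spectrum that exceed
its 0.70 quantile are accepted greedily in descending spectrum order,
subject to a 100-bp minimum dyad separation (ties leftmost, for exact
reproducibility); each accepted dyad becomes a 147-bp call, dyad ± 73 bp.
Calls whose interval would leave the track are dropped, never clipped.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nu0` | 10.4 bp/turn | helical periodicity in the phase factor |
| `window` | 10 steps | curvature integration length, ~1 turn |
| template `end_len`/`mid_len` | 50/47 bp | high/low sections of the idealized template |
| `high`/`low` | 1.0/0.2 | template plateau amplitudes before normalization |
| `scales` | 25–100 by 5 | CWT scale grid (bp) |
| `threshold_quantile` | 0.70 | spectrum quantile a peak must exceed |
| `min_distance` | 100 bp | minimum dyad separation (below the 147-bp core, since neighbouring calls may genuinely overlap) |

The quantile threshold (rather than an absolute value) is used because
matched-filter profiles are in arbitrary units. Whether peaks should be
thresholded on the profile or on the wavelet spectrum is not decidable from
first principles; the spectrum is used, since it is also the object whose
local maxima are accepted.

## The roll/tilt table

The default table (`inst/extdata/roll_tilt_wedge.tsv`) is a published
wedge-model set of dinucleotide roll/tilt angles in which complementary
steps carry equal roll and opposite tilt — the strand symmetry that makes
the curvature curve of a reverse-complemented sequence the reverse of the
original curve (asserted in the tests). Any 16-row table in the same TSV
dialect can be substituted via `read_roll_tilt()`; all package tests that
probe numeric behavior build their tables explicitly rather than relying
on the default's specific values, so swapping tables cannot silently
change what the tests mean. Because the curvature sum is linear in the
angles and the template is unit-normalized, rescaling all angles by a
common factor rescales curves but leaves calls unchanged.

## Evaluation statistics

* `matching_ratio(ref, pred, d)` — the fraction of reference dyads with at
  least one predicted dyad within ±d bp ("any-within" matching; a greedy
  `one_to_one` mode exists for sensitivity analysis). `match_curve()`
  sweeps d = 1..60.
* `overlap_ratio(d)` implements the published interval-overlap formula
  $[2(73-d)+d]/147$ literally; the natural geometric overlap of two 147-bp
  intervals at offset $d$ would be $(147-d)/147$, and a comment in the code
  notes the discrepancy, but fidelity to the printed formula wins.
* `hexamer_occupancy()` classifies every forward-strand hexamer occurrence
  as occupied iff its 6-bp span lies entirely inside at least one call
  (strict containment — unambiguous and symmetric), and
  `occupancy_correlation()` is the Pearson correlation of two call sets'
  occupancy-ratio vectors over hexamers present in both. Hexamer counting
  does not collapse reverse complements by default (`collapse_rc` exists).

## Site-centered analyses

`anchored_profile()` aligns any score track on anchor sites (TSSs, SNPs,
miRNA target sites), flips minus-strand windows so positive offsets point
downstream, optionally z-scores each site's window ("scaled signal"
averaging is undefined in the source material; per-site z-scoring is the
default interpretation because it makes tracks with different units
comparable, and a raw mode is retained), and averages positionwise.
Edge-truncated sites contribute only their covered offsets — `n_sites` is
tracked per offset — rather than being discarded (`strict = TRUE`
discards).

`classify_tss()` k-means-clusters the per-site signal vectors over
[−150, +50] bp around each TSS into two classes (k = 2, Euclidean, 20
seeded restarts, raw vectors; whether the original analysis scaled them is
unstated, and raw is the less manipulated choice). The cluster with the
higher mean signal is class I ("occupied"), the other class II
("nucleosome-free") — tying labels to occupancy ordering, not cluster
index, keeps them stable across seeds. If all site vectors are identical
the classification is degenerate; all sites are assigned class I with a
warning.

`dinucleotide_fraction_profile()` (WW = AA/AT/TA/TT, SS = CC/CG/GC/GG —
both classes closed under reverse complement) and
`polytract_fraction_profile()` (pure A-runs or pure T-runs of ≥ `min_run`
bases; 4 by default, since "poly(dA:dT)" has no canonical minimum) report
per-offset fractions of sites, strand-aware.

## PWM promoter scanning

PFMs in JASPAR text form are converted to base-2 log-odds PWMs with
pseudocount 0.5 and a uniform background (all three are arguments; none is
dictated by the source material). `scan_scores()` reports, per placement,
the maximum of the forward and reverse-complement strand scores, masking
placements that contain N. `average_binding_profile()` min–max normalizes
each (TF, promoter) scan to [0, 1] across the promoter before averaging —
without this, TFs with wider log-odds ranges would dominate the cross-TF
average; a constant scan contributes 0.5 with a warning.

## Synthetic fixtures: what they emulate, and what they do not

Every stage is testable offline against seeded generators whose ground
truth is recorded:

* `random_genome()` — i.i.d. bases at a given GC fraction.
* `plant_signal_pattern()` — zero baseline + the curvature template
  (rescaled to unit peak amplitude) centered at known dyads + Gaussian
  noise, so `1/noise_sd` is the fixture's SNR. This is the matched-filter
  testbed: the planted waveform is exactly what the filter seeks.
* `plant_sequence_nucleosomes()` — a random genome carrying 147-bp
  cassettes at a regular dyad repeat (default 190 bp, a typical
  internucleosome distance). Within a cassette, 3-bp A tracts (first end)
  and T tracts (second end) sit on a 10.3-bp phase grid across the two
  ~50-bp ends, single AA/TT dinucleotides on an 11.1-bp grid across the
  ~47-bp middle, and the filler alternates G/C. The design is dictated by
  what the curvature window can sense: a *single* WW step per helical turn
  is invisible against the incoherent wedge noise of random sequence
  (measured: no end-vs-middle contrast at all), whereas a 3-bp tract
  contributes two nearly in-phase wedge steps and the alternating-G/C
  filler cancels pairwise — so cassette ends carry strong coherent
  bending, the sparser middle less, and the background none. Tract length
  3 deliberately stays below the package's 4-bp poly(dA:dT) convention.
* `tss_class_fixture()` — raised-cosine occupancy bumps (+1) or troughs
  (−1) over [−150, +50] at half of the sites each, plus Gaussian noise
  (default sd 1/3, an SNR-3 classification problem).

These fixtures establish that the arithmetic, the filter, the peak caller
and the classifier do what they claim under known truth. They do **not**
emulate real chromatin: no remodeller activity, no statistical positioning
against boundaries, no linker-length variability, no genome-scale base
composition beyond GC fraction, and a sequence-encoded signal far cleaner
than real nucleosome-positioning sequences. Passing them bounds
implementation error, not biological accuracy.

## Numerical choices and degenerate inputs

* The CWT is computed by FFT convolution (power-of-two padding), with the
  kernel truncated at ±5 scale units and the track extended by edge-value
  replication; the track mean is subtracted first, so a constant track has
  an identically zero spectrum and adding a constant provably never
  changes the call set.
* A peak must also exceed `1e-8` of the spectrum's maximum — a pure
  floating-point floor so that all-dust spectra (flat or empty tracks)
  yield no calls; it is far below any meaningful signal.
* Equal-height spectrum peaks are resolved leftmost-first; greedy
  acceptance in descending spectrum order makes call sets deterministic.
* Pattern normalization divides by the L2 norm and fails loudly on a
  constant template rather than returning NaNs.
* `matching_ratio` uses sorted `findInterval` lookups (O(n log m)), and the
  tests check it against an exhaustive pairwise oracle.

## Known limitations

* The matched filter's own autocorrelation has positive side lobes near
  ±100 bp. In a *regular* nucleosome array with repeat in roughly the
  200–220 bp range, side lobes from flanking nucleosomes superpose midway
  between dyads at least `min_distance` from both, and jitter can let such
  linker-centered candidates through the exclusion rule. At the 190-bp
  repeat used by the fixtures this does not occur (the ±95-bp midpoints
  self-exclude), but on real arrays with longer repeats the
  `threshold_quantile` or `min_distance` may need raising.
* Hexamer occupancy ratios stabilize slowly: at 50 kb each hexamer has
  only ~12 occurrences and the ratios are dominated by binomial noise.
  The acceptance script therefore computes the predicted-vs-planted
  occupancy correlation on a 200-kb fixture (~50 occurrences per hexamer);
  chromosome-scale input is needed before the statistic is fully stable.
* Only the curvature modulus is used; bend *direction* is discarded, as in
  the underlying model.
* The two-column score-track dialect does not state whether positions
  index a fragment start or midpoint; the parser treats them simply as
  "the position of the score".

## Problem sizes

The test suite and `scripts/acceptance.R` run on fixtures of 50–200 kb
with 260–1050 planted nucleosomes, 500-dyad signal-level tracks of 100 kb,
200-site TSS fixtures, and 10-promoter × 1-TF PWM scans — sizes chosen so
the full pipeline, not a stub, is exercised in seconds per stage.

## A worked run

```{r example}
mod <- nucleosome_model()
mod
fx <- simulate(mod, seed = 7, length = 20000)
calls <- predict(mod, fx$genome)
summary(calls)
sc <- spacing_stats(calls)
sc$mean
mc <- match_curve(fx$truth$dyads, calls$dyad)
mc$matching_ratio[c(10, 20, 40)]
```
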