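---
title: "Complexity and spectral markers for EEG group discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and spectral markers for EEG group discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmarkers)
```

## The problem

Alzheimer's disease slows the EEG: low-frequency (delta/theta) power rises,
high-frequency (alpha/beta) power falls, and the signal becomes more regular
— less "complex" — as cortical connectivity degrades. `eegmarkers`
operationalises this as a screening problem: given 8-second, 128 Hz,
19-channel EEG segments from healthy and AD groups recorded under a fixed
eye condition, find the (measure, electrode, frequency band, parameter)
combination that best separates the groups, then quantify how well that
single feature classifies individual subjects.

Everything in the package flows through that protocol: six scalar measures,
a dyadic wavelet band decomposition, ANOVA/AUC screening with parameter
scans, a stratified K-fold SVM, and a cost benchmark. A synthetic cohort
generator supplies data with the assumed structure so that the whole chain
can be calibrated and property-tested without access to a clinical cohort.

## Band decomposition

Channels are decomposed with the 4-tap orthogonal Daubechies wavelet at
J = 4 levels under **periodized** boundary handling. At fs = 128 Hz the
dyadic sub-bands map onto the conventional EEG rhythms:

| set | range (Hz) | band |
|-----|-----------|------|
| d1  | 32–64     | discarded (signals are band-limited to 0.5–30 Hz) |
| d2  | 16–32     | beta |
| d3  | 8–16      | alpha |
| d4  | 4–8       | theta |
| a4  | 0–4       | delta |

The dyadic edges differ slightly from the conventional 15–30 / 8–15 Hz
definitions; they are the only edges realisable by a dyadic transform.
Periodization was chosen (the level count and boundary rule being open
implementation choices) because it makes the transform exactly orthogonal:
coefficient count equals sample count, energy is conserved to machine
precision, and the four band signals plus the d1 reconstruction sum back to
the original signal to ~1e-15 relative error. These identities are
property-tested, and one pyramid level is checked against an explicitly
constructed orthogonal analysis matrix.

A consequence worth knowing: reconstructing a single coefficient set is a
subspace projection, not a brick-wall filter. A 6 Hz tone keeps ≈71% of its
energy in the theta set, a 10 Hz tone ≈67% in alpha (10 Hz sits close to the
8 Hz dyadic edge). Band features therefore measure "energy mapped to the
band's coefficient set", the standard dyadic-wavelet convention.

## The six measures

**Wavelet coherence (`wc`).** Complex Morlet transform (ω₀ = 6), evaluated
as an exact zero-padded discrete version of the transform integral with the
kernel truncated where its envelope falls below e⁻¹⁸, on a geometric scale
grid (default 6 voices/octave over 0.5–30 Hz). The textbook normalised
cross-spectrum has unit modulus pointwise, so — as is standard practice —
cross- and auto-spectra are smoothed before the ratio: a Gaussian time
kernel with standard deviation equal to the scale (so smoothing tracks the
wavelet's own resolution), then a 3-point boxcar across scales. The scalar
per pair is the mean coherence over the time–scale plane restricted to the
band's frequency range. Self-coherence is exactly 1; independent white-noise
pairs average ≈0.6 under these windows, and the gap is what carries
information. An electrode-level value, when needed, is the mean of the pair
summaries over the 18 pairs containing the electrode.

**Katz fractal dimension (`fd`).** F = ln(T−1) / ln(d(T−1)/D) with D the
summed adjacent-point distance (unit abscissa steps) and d the maximum
distance from the first point, abscissa included. Any straight line gives
exactly 1. The abscissa-inclusive d follows the formulation the protocol
states, rather than Katz's original ordinate-only convention; with
unit-variance inputs the difference is immaterial for ranking.

**Quadratic entropy (`qe`).** Sample-entropy counting with Chebyshev
distance: B counts matching length-m template pairs within tolerance r, A
the matching (m+1)-extensions, self-matches excluded, and
Q = −ln(A/B) + ln(2r). Two conventions needed fixing. First, both template
lengths are indexed over i = 1…T−m (the in-bounds convention), so every
counted template has an extension and the printed index limits that would
run past the series end are avoided; with equal index ranges the
normalising prefactors cancel and E = −ln(ΣA/ΣB). Second, r is expressed in
standard-deviation units: the series is z-scored before matching (constant
series are left unscaled, making Q = ln(2r) exact there — the degenerate
anchor used in tests). B = 0 is reported as `NA` with a warning rather than
a number. The counting kernel is compiled; a single O(T²) pass yields the
whole r-grid for a given m, which is what makes the 40-point (m, r) scan
affordable.

**Relative wavelet energy (`we`).** The fraction of total squared
coefficient energy (all J+1 sets, d1 included) in the band's set. For the
unfiltered signal the "band" is the complete set, so the value is
identically 1 — the measure is non-discriminative on raw signals, and the
screening layer treats such zero-variance keys as p = 1 rather than an
error.

**Quantile-graph mean jump length (`qg`).** Points are assigned to Q
empirical quantile bins via average ranks (`ceiling(Q·rank/T)` capped at Q):
tied values share a bin, so constant and heavily tied series stay well
defined, and for distinct values this reproduces left-closed/right-open
empirical quantile intervals. The weighted directed adjacency counts lag-k
transitions (ΣA = T−k), W is its row-normalised Markov matrix (empty rows
stay zero), and Δₖ = (1/Q)·Σ W[i,j]·|i−j|. Two notational gaps in the
source formulation were resolved as S = W and N = Q in the trace form; the
choices are verified against hand-computable cases (alternating
two-quantile series: Δ₁ = 1, Δ₂ = 0; strictly increasing 1…5 with Q = 5:
Δ₁ = 0.8). Default Q follows the 2·T^(1/3) rule (Q = 20 at T = 1024).

**Visibility-graph complexity (`vg`).** Natural visibility: nodes i < j
connect iff every intermediate point lies strictly below the chord. The
strict inequality is the original convention; the printed non-strict variant
would connect collinear runs and was rejected. Construction is a compiled
O(T²) running-maximum-slope sweep, verified against an O(T³) brute-force
oracle on all series lengths ≤ 200 across 50 random trials. The largest
adjacency eigenvalue is computed by shifted power iteration (A + I keeps the
top eigenvalue dominant on bipartite-ish graphs) from a deterministic
uniform start vector with tolerance 1e-10, falling back to a dense
symmetric eigendecomposition for small slow-converging cases. The index
4c(1−c) vanishes at both extremes (path graph, complete graph) and peaks at
c = 1/2.

## Screening and classification

For each (electrode/pair, band, measure, parameter tuple) key, the screen
computes the one-way fixed-effects ANOVA p value (two groups, so equivalent
to a pooled t test) and the rank-based Mann–Whitney AUC with ties counted
half, oriented as max(AUC, 1−AUC). Parameter scans use the protocol grids —
r = 0.05…1.00 by 0.05 with m ∈ {1, 2}; Q = 20 with k = 1…25 — and pick the
lowest p, ties broken toward the lexically smallest tuple so reruns are
deterministic. Comparisons are restricted to like-eye-condition pairs
(A vs C, B vs D); mixed pairs are rejected at validation. p values are raw:
no multiple-testing correction is applied, matching the screening protocol,
and the output headers say so.

Classification uses a radial-basis SVM (cost 1, features standardised on
training folds — the kernel and regularisation being unstated in the
protocol, these are the robust defaults for a 1-D feature) under
stratified K = 10 cross-validation; stratification keeps the 12-subject
control group represented in every training fold against 80 AD subjects.
The pooled out-of-fold confusion matrix yields Acc/Sen/Spe with AD as the
positive class (swapping the convention swaps Sen and Spe exactly, which is
tested).

## The synthetic cohort generator

Each channel is a sum of four narrowband Gaussian processes (flat spectra
over 0.5–4, 4–8, 8–15, 15–30 Hz) plus a 1/f background over 0.5–30 Hz,
synthesised in the frequency domain, mixed at power fractions 0.7 (split
delta/theta/alpha/beta = 0.20/0.20/0.35/0.25 for eyes-open healthy) and 0.3
(background), then standardised to a 20 µV scale. Filtered noise rather
than sinusoids keeps the entropy and fractal measures non-degenerate.
Eyes-closed groups get a 1.6× alpha weight (renormalised) — the classic
posterior alpha rise.

The AD effect has three components, all proportional to the effect dials
and all exactly zero at zero effect:

1. **Weight shift** (`delta_shift` = s): a fraction s of the alpha and beta
   weights moves into delta (60%) and theta (40%).
2. **Within-delta slowing**: the AD delta process's amplitude spectrum is
   tilted as f^(−2s) toward the low band edge. This is the generative form
   of "slowing": without it, amplitude-blind measures (the quantile and
   visibility graphs are rank/geometry-based) would barely see a pure
   weight shift in the delta band, because band extraction renormalises
   away amplitude. With it, the delta-band mean jump length separates
   groups at AUC ≈ 0.9 for s = 0.5.
3. **Smoothing** (`autocorr_boost` = σ, in samples): a Gaussian low-pass
   with time-domain standard deviation σ, reducing waveform complexity.

Defaults (s = 0.4, σ = 0.5) are the package's choice of a moderate,
realistic effect; the source protocol gives no quantitative healthy-vs-AD
spectra. Randomness is counter-based: every channel's seed derives from
(master seed, group, subject, channel), so cohorts are reproducible
piecewise and generation order cannot matter.

What the generator does **not** emulate: artifacts, volume
conduction/channel mixing (channels are independent), non-stationarity
within a segment, between-subject spectral heterogeneity, and disease
staging. Passing tests therefore demonstrate that the pipeline detects and
calibrates the *assumed* spectral/complexity structure — not that any
measure works on clinical recordings.

One behaviour worth stating plainly: because the AD weight shift changes
the oscillation/background mixture in *every* reweighted band, suppressed
high bands (beta) can screen as strongly as delta for amplitude- and
roughness-sensitive measures. The robust qualitative signature — asserted
in tests — is that every measure detects the effect in the delta band and
the best keys concentrate in low-frequency/unfiltered bands, not that
delta literally ranks first for all six measures.

## Benchmark

The cost experiment times each measure on fresh white noise over
T = 500…10,000 in steps of 100 (96 points), median over repeats, normalised
by the time at T = 500; very fast calls are looped until the total exceeds
5 ms so timer resolution does not quantise the curve. Parameters are fixed
while timing (m = 2, r = 0.2; Q = 2·T^(1/3), k = 1); wavelet-energy inputs
are truncated to the largest multiple of 16 (the J = 4 dyadic constraint;
at most 15 samples, negligible). Wall-times are hardware-dependent, so the
designed readout is the ordering and the fitted log–log exponents: the
visibility graph, with its T×T adjacency, is the most expensive measure at
T = 10,000, and tests assert exactly that ordering.

## Problem sizes used by the test suite

The suite exercises the full study geometry where it matters (19 channels ×
1024 samples; a 12 + 80 subject pair for the classification property) and
smaller cohorts elsewhere: null calibration uses 100 replicate 20 vs 20
cohorts on one channel; monotonicity uses a 3-point effect grid
(s = 0.2/0.5/0.8) with 20 replicates of 12 vs 12; oracle equivalence runs 50
random series up to T = 200 (visibility) and T ≤ 512 (entropy); the
benchmark test times the two endpoint lengths 500 and 10,000. These sizes
were chosen to give stable statistics for each property while keeping the
suite comfortably reproducible on one CPU.

## Known limitations

- The dyadic band edges (16–32, 8–16 Hz) are an approximation to the
  conventional beta/alpha definitions; features near band edges leak.
- Coherence smoothing windows (Gaussian sd = scale; 3-point scale boxcar)
  are a fixed design choice; other windows shift the null level of the
  summary (≈0.6 for independent noise here). Comparisons are meaningful
  within a fixed configuration, not across smoothing choices.
- The Katz denominator degenerates for some exactly-symmetric artificial
  series (d(T−1) = D); such inputs raise an error rather than a value.
- Quadratic entropy is `NA` when no template matches (tiny r on short
  series) and `Inf` when A = 0; grid scans drop non-finite keys.
- Raw p values across 19 electrodes × bands × grids are optimistically
  small under multiple comparisons; the package reports them as the
  protocol does and flags the caveat in output headers.
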