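---
title: "Convex-envelope quantification of multi-voxel 1H-MRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-envelope quantification of multi-voxel 1H-MRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqoce)
```

## The problem

In vivo proton MR spectroscopy measures brain metabolites — choline (Cho,
~3.22 ppm), creatine (Cr, ~3.03 ppm), N-acetyl aspartate (NAA, ~2.02 ppm),
lactate and lipids (1.0–1.7 ppm) — whose relative levels change
characteristically in gliomas: Cho rises with proliferation, NAA falls with
neuronal loss, and lipid–lactate (LL) signal appears with necrosis.  Chemical
shift imaging (CSI) acquires a whole grid of voxel spectra per exam, far too
many to quantify interactively.  The obstacle to simple frequency-domain
quantification is the baseline: the residual tail of the imperfectly
suppressed water resonance (4.7 ppm) is orders of magnitude larger than the
metabolite peaks and fluctuates from voxel to voxel.

This package implements an automated quantification built on one geometric
idea: **the lower convex envelope of a spectral segment is a good baseline
estimate** when the true baseline is smooth and the peaks are narrow.  Peaks
protrude upward from the baseline, so the pointwise-maximal convex minorant
of the trace slides underneath them and touches the trace only on peak-free
stretches.

## The pipeline

Each voxel is processed in five steps.

1. **Preprocessing** (`apodize()`, `fid_to_spectrum()`).  The raw complex
   FID is damped with an exponential window `exp(-pi * lb * t)`
   (`line_broadening` lb in Hz, default 2 — a standard mild Lorentzian
   broadening), Fourier transformed, and displayed as the *magnitude*
   spectrum on a decreasing ppm axis (`ppm = reference + f/transmitter`,
   carrier at 4.7 ppm where water suppression is centred).  Magnitude mode
   is a deliberate choice: the pipeline contains no phase correction, and
   every downstream step requires a real, non-negative trace.  No zero
   filling is applied.

2. **Envelope fitting** (`lower_convex_envelope()`).  The envelope is built
   by an incremental scan: starting from the first three points, each new
   point is appended and the penultimate hull vertex is deleted while the
   convexity inequality
   `h(k-2)(I(k)-I(k-1)) + h(k)(I(k-1)-I(k-2)) > h(k-1)(I(k)-I(k-2))`
   fails; removed points are finally restored by linear interpolation.
   Every point is deleted at most once, so the scan is linear-time — the
   property that makes whole-grid processing cheap.  The inequality is
   strict, so collinear middle points are deleted and restored exactly by
   interpolation; ties are harmless.  Inputs of length one or two are
   trivially convex and returned unchanged.  `envelope_oracle()` recomputes
   the same object from the planar convex hull (`grDevices::chull`) and is
   used throughout the tests as an independent check, alongside a
   brute-force chord construction.

3. **Bias correction** (`bias_correct()`).  B0 inhomogeneity shifts the
   whole spectrum by an unknown offset.  The envelope is fitted on the
   2.0 ± 0.5 ppm window and subtracted; the residual argmax is taken as the
   actual NAA position, and the spectrum is circularly shifted so it lands
   on the bin nearest 2.02 ppm.  The shift is a whole number of bins
   (position is defined by an argmax, so sub-bin interpolation would add
   nothing), and an exact tie in the argmax — e.g. a featureless trace — is
   broken toward the bin nearest 2.02 ppm, giving a zero shift.

4. **Sectional baseline removal** (`sectional_baseline()`,
   `remove_baseline()`).  One envelope over the whole 1.0–4.3 ppm range
   would bridge across broad features, so envelopes are fitted on four
   overlapping sections — h1: 4.3–3.2, h2: 3.9–2.0, h3: 3.0–1.5,
   h4: 1.7–1.0 ppm — and combined piecewise, taking the pointwise *minimum*
   on the overlaps:

   | interval (ppm)  | baseline        |
   |-----------------|-----------------|
   | 4.3 ≥ x > 3.9   | h1              |
   | 3.9 ≥ x > 3.2   | min(h1, h2)     |
   | 3.2 ≥ x > 3.0   | h2              |
   | 3.0 ≥ x > 2.0   | min(h2, h3)     |
   | 2.0 ≥ x > 1.7   | h3              |
   | 1.7 ≥ x > 1.5   | min(h3, h4)     |
   | 1.5 ≥ x > 1.0   | h4              |

   The overlaps matter: an envelope always touches the trace at its section
   endpoints, so when a peak sits at an endpoint (Cho at 3.22 next to h1's
   3.2 boundary, NAA at 2.02 next to h2's 2.0 boundary) that section's
   envelope is locally inflated — and the overlapping partner section, whose
   boundary is elsewhere, supplies the lower and correct value through the
   minimum.  Section endpoints snap to the nearest bin centre; a bin belongs
   to an interval by its ppm value, with the single bin at 4.3 ppm closing
   the top interval.  Because each envelope is a minorant of the trace on
   its own section, the combined baseline never exceeds the spectrum and the
   residual is non-negative by construction (clamped at zero against
   floating-point round-off).  Bins outside 1.0–4.3 ppm are zeroed.

5. **Peak detection** (`detect_peaks()`).  Each metabolite's height is the
   maximum residual within its theoretical position ± 0.1 ppm (Cho 3.22,
   Cr 3.03, NAA 2.02, Lac 1.33 ppm — literature positions, overridable via
   `metabolite_panel()`).  The combined lipid–lactate height (LL) is the
   maximum residual over the whole 1.7–1.0 ppm range rather than a point
   window: lipid and lactate overlap there, and a range maximum cannot fail
   the way model fitting of two overlapping lines can.  Ratios Cho/NAA,
   Cho/Cr and LL/Cr are computed, with a missing or zero denominator giving
   a missing ratio, never a zero.

`quantify_spectrum()` runs steps 2–5 and returns a classed fit object
(`print`, `summary`, `plot`, `coef`, `fitted`, `residuals` methods);
`quantify_csi()` maps it over a grid, flagging per-voxel failures in the
output table instead of aborting.  Region-of-interest readings average 1–3
voxels per region (`aggregate_roi()`), ignoring missing values; per-expert
ROI readings are combined by plain averaging (the normalization step of the
original two-expert protocol is not specified anywhere we could follow, so
the package implements the simplest defensible choice and flags it here).

## Cohort statistics

The grading analysis treats each case's tumoral-area ratios as one
observation per ratio.

* `independent_t_test()` — pooled-variance two-sample t test (Welch by
  flag) for LGG vs HGG differences.
* `kruskal_wallis_pairwise()` — tie-corrected omnibus H across the tumoral,
  peritumoral and contralateral areas, followed by Dunn-style pairwise z
  tests on the pooled ranks (unadjusted by default, Bonferroni optional).
  Pairwise two-group H statistics are also reported, since clinical software
  often prints pairwise "h" values without documenting their construction;
  no exact correspondence is promised.
* `fit_logistic_ratios()` — maximum-likelihood logistic regression of grade
  group on Cho/Cr, Cho/NAA and LL/Cr, reported in the convention
  `p = 1/(1 + exp(-(-a + b*ChoCr + c*ChoNAA + d*LLCr)))` with `a` equal to
  minus the intercept.  Complete cases only: rows missing LL/Cr drop out
  only when LL/Cr is a predictor, so two-predictor fits (the usual choice
  for reference-software tables whose LL values are unreliable) keep the
  full cohort.  A near-zero deviance or diverging coefficients raise a
  separation error rather than returning a meaningless fit.
* `roc_analysis()` — empirical ROC over thresholds at midpoints between
  consecutive distinct scores (± infinite sentinels).  The trapezoidal AUC
  is then exactly the normalized Mann-Whitney U with half credit for ties —
  an identity the tests verify on random instances.  The operating point
  maximizes Youden's J, ties broken toward the lower threshold.

## The synthetic-data generators

Every stage is testable without any acquisition, because the generators
produce data with known ground truth.

`spectrum_spec()` / `generate_spectrum()` / `generate_fid()` build a voxel
as narrow metabolite peaks on a broad residual-water tail plus seeded white
noise, either directly in the frequency domain or as the corresponding sum
of damped complex exponentials (Lorentzian width fwhm maps to
`T2 = 1/(pi * fwhm_Hz)`; one-sided acquisition makes the *magnitude*-mode
width `sqrt(3)` times the absorption width, which the tests account for).
Default conditions emulate a 3 T short-TE CSI voxel: 1024 points, 1200 Hz
sweep at 123.25 MHz, carrier at 4.7 ppm, amplitudes Cho 6 / Cr 5 / NAA 8 /
Lac 2 a.u.  Two generator choices deserve justification:

* **Tail shape.**  The water tail is a Lorentzian of FWHM 1.2 ppm and
  amplitude 40 a.u. centred at 4.7 ppm.  A Lorentzian is convex beyond
  `fwhm/(2*sqrt(3))` from its centre, so this width keeps the tail convex on
  the whole analysis range (its inflection sits above 4.3 ppm) — the
  smooth-baseline regime the envelope method assumes.  The generator can
  produce non-convex tails (wider ones) for stress testing, but the default
  represents the intended operating regime.
* **Peak lineshape.**  Default peaks are Gaussian.  With Lorentzian peaks
  the heavy wings of the close Cho/Cr pair overlap and lift the trace
  ~0.5 a.u. above the true tail between them, so the "true height above
  baseline" is no longer the nominal amplitude and recovery error cannot be
  attributed to the algorithm.  Gaussian peaks are effectively compactly
  supported, making the generated amplitude an unambiguous recovery target.
  Lorentzian lineshapes remain available per peak and are used in the
  Fourier-pair tests.

What the generators do *not* emulate: J-coupling multiplets, macromolecule
baselines, B0 inhomogeneity varying across the voxel, eddy-current
lineshape distortion, and chemical-shift displacement.  Passing recovery
tests therefore demonstrate correctness of the algorithm under its own
assumptions, not clinical accuracy on real spectra.

`cohort_spec()` / `generate_cohort()` draw per-case ratio tables from
lognormal distributions (ratio data of this kind are right-skewed) matched
to target means and SDs per grade group and area.  The defaults are the
study conditions of the 78-case glioma cohort this method was evaluated on:
36 LGG / 42 HGG cases, tumoral moments Cho/NAA 1.04 ± 0.43 (LGG) vs
1.35 ± 0.50 (HGG), Cho/Cr 1.27 ± 0.31 vs 1.70 ± 0.76, LL/Cr 1.07 ± 1.32 vs
2.65 ± 2.51, and area-level moments Cho/NAA 0.59 ± 0.16 (peritumoral) and
0.47 ± 0.11 (contralateral) with Cho/Cr 0.95 ± 0.16 and 0.84 ± 0.16.
LL/Cr outside the tumor is not reported by grade in that study; the package
uses 0.80 ± 0.40 (peritumoral) and 0.60 ± 0.30 (contralateral), modest
values consistent with minimal necrosis in non-tumoral tissue.  A
configurable fraction of LL values can be set missing (29/78 emulates the
reference software's failure rate); missing values stay missing through the
whole statistics chain.

## Numerical choices and degenerate inputs

* Envelope ties: strict inequality deletes collinear vertices; linear
  interpolation restores them bit-exactly at data values (hull vertices are
  copied, not re-interpolated).
* Empty sequences, non-finite values, zero-length groups, single-class
  labels, and axis ranges that do not cover a required section all raise
  errors naming the offending object.
* An all-zero voxel in a CSI grid is flagged in its output row; the rest of
  the grid is unaffected.
* The `.rda`-style reader treats the header as ASCII `Key: value` pairs
  between sentinel lines and the payload as little-endian doubles,
  interleaved real/imaginary; header truncation and payload-size mismatch
  raise distinct errors, and field-name synonyms are resolved through a
  configurable alias table.  The byte layout is a compatibility convention
  of this package, chosen to match common Siemens exports.

## Problem sizes used in the checks

The shipped verification uses 1,000 random sequences (lengths 1–200) for
envelope/oracle agreement, 100 noiseless seeded voxels for shift and height
recovery (thresholds: one bin, 5%), 50 replicates of n = 5,000 for logistic
coefficient bias (< 0.05), and one 16×16×1 grid of 1,024-point voxels as a
throughput sanity check — sizes at which each property is measured with
comfortable statistical margin.

## A worked example

```{r example, eval = FALSE}
out <- generate_spectrum(spectrum_spec(seed = 1, ppm_shift = -0.10))
fit <- quantify_spectrum(out$spectrum)
summary(fit)
#> Shift applied: +0.0951 ppm
#> Peak heights (a.u.):
#>   Cho    Cr   NAA   Lac    LL
#> 5.931 4.950 7.910 1.996 1.996
#> Ratios:
#> cho_naa  cho_cr   ll_cr
#>   0.750   1.198   0.403
```

The induced −0.10 ppm mis-calibration is recovered to within one bin
(+0.0951, bin width 0.0095 ppm) and the heights match the generated
amplitudes (6, 5, 8, 2) to within a few percent; LL equals the Lac height
because lactate is the only signal in 1.0–1.7 ppm here.

## Known limitations

* Magnitude-mode spectra broaden peaks (`sqrt(3)` for Lorentzian lines) and
  mix absorption with dispersion; heights are therefore relative measures,
  suitable for ratios, not absolute concentrations.
* The envelope under-peaks baseline: across a peak the baseline is a chord,
  so a slowly curving true baseline is slightly underestimated beneath wide
  peaks, biasing heights upward by the sagitta.
* The method quantifies peak *maxima*, not areas; strongly overlapping
  resonances (Glx, myo-inositol) are out of scope.
* Grade-group statistics assume one observation per case per area;
  longitudinal or multi-slice correlation is not modelled.
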