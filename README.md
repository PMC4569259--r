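# aqoce — convex-envelope based automated quantification of multi-voxel ¹H-MRS

In vivo proton MR spectroscopy of the brain measures metabolite resonances —
choline (Cho, 3.22 ppm), creatine (Cr, 3.03 ppm), N-acetyl aspartate (NAA,
2.02 ppm), lactate and lipids (LL, 1.0–1.7 ppm) — whose ratios (Cho/NAA,
Cho/Cr, LL/Cr) help grade gliomas non-invasively. Chemical shift imaging
(CSI) yields a whole grid of voxel spectra per exam, each sitting on a large,
voxel-dependent baseline from the residual water tail, so interactive
quantification does not scale. This package is for spectroscopists and
neuro-oncology researchers who need an automated, parameter-free,
reproducible frequency-domain quantification of such grids, plus the cohort
statistics used to evaluate grading performance.

## Method

For a spectral segment *f*{1..k}, the baseline estimate is the **lower
convex envelope** *h* = the pointwise-maximal convex minorant of *f*, built
by a linear-time incremental scan: append point *i*, delete the penultimate
hull vertex while

> h(k−2)·(I(k)−I(k−1)) + h(k)·(I(k−1)−I(k−2)) > h(k−1)·(I(k)−I(k−2))

fails (I = retained indices), then restore deleted points by linear
interpolation. Per voxel the pipeline is:

1. exponential apodization (default 2 Hz) and FFT to a magnitude spectrum on
   a decreasing ppm axis (carrier at 4.7 ppm);
2. bias correction: envelope-subtract the 2.0 ± 0.5 ppm window and shift the
   residual argmax (the NAA peak) to 2.02 ppm;
3. sectional baseline: envelopes h1–h4 on 4.3–3.2, 3.9–2.0, 3.0–1.5 and
   1.7–1.0 ppm, combined piecewise with a pointwise minimum on overlaps;
4. subtraction, giving a non-negative residual on 1.0–4.3 ppm;
5. peak detection: height = max residual within theoretical position
   ± 0.1 ppm (LL = max over 1.7–1.0 ppm), then ratio computation.

For grading, the case-level tumoral ratios feed pooled t tests,
Kruskal–Wallis/Dunn area comparisons, a logistic combination

> p = 1 / (1 + exp(−(−a + b·Cho/Cr + c·Cho/NAA + d·LL/Cr)))

and an empirical ROC whose operating point maximizes Youden's J.

## Worked example

```r
library(aqoce)

# a synthetic voxel with a known -0.10 ppm calibration error
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

The induced −0.10 ppm shift is recovered to within one bin (bin width
0.0095 ppm) and the heights match the generated amplitudes (Cho 6, Cr 5,
NAA 8, Lac 2) to within a few percent. `plot(fit)` overlays the aligned
spectrum, the sectional baseline and the residual.

Whole grids and cohorts:

```r
ds  <- generate_csi(spectrum_spec(seed = 7), csi_dims = c(16L, 16L, 1L))
tab <- quantify_csi(ds)            # one row per voxel: heights, ratios, flags

rec <- generate_cohort(cohort_spec(seed = 7))   # 36 LGG / 42 HGG, 3 areas
tum <- rec[rec$area == "tumoral", ]
m   <- fit_logistic_ratios(tum)
roc_analysis(predict(m, tum), as.integer(tum$grade_group == "HGG"))
#> ROC: AUC = 0.821; best cut-off 0.612 (sensitivity 73.8%, specificity 88.9%)
```

A thin command-line wrapper lives at `exec/aqoce`
(`aqoce quantify IN.rda --out results.csv`, `aqoce stats COHORT.csv`,
`aqoce simulate spectrum|cohort`).

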