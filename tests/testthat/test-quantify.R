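test_that("bias correction recovers an induced calibration shift", {
  # NAA generated at 1.92 ppm (induced shift -0.10) -> correction +0.10
  sp <- generate_spectrum(shifted_spec(seed = 1, shift = -0.10))
  bc <- bias_correct(sp$spectrum)
  expect_lt(abs(bc$shift_ppm - 0.10), ppm_bin_width())
  post <- bc$spectrum
  win <- abs(post$ppm - 2.02) <= 0.1
  expect_lt(abs(post$ppm[win][which.max(post$intensity[win])] - 2.02),
            ppm_bin_width())

  # NAA already on target -> no shift
  sp0 <- generate_spectrum(shifted_spec(seed = 2, shift = 0))
  expect_lte(abs(bias_correct(sp0$spectrum)$shift_bins), 1L)
})

test_that("a featureless spectrum yields zero shift by the tie-break rule", {
  n <- 512
  ppm <- seq(6, 0.5, length.out = n)
  flat <- mrs_spectrum(ppm, rep(3, n))
  bc <- bias_correct(flat)
  expect_identical(bc$shift_bins, 0L)
  expect_identical(bc$shift_ppm, 0)
})

test_that("bias correction demands axis coverage of the search window", {
  ppm <- seq(4.0, 2.2, length.out = 128)
  expect_error(bias_correct(mrs_spectrum(ppm, rep(1, 128))), "does not cover")
})

test_that("a sectionwise-convex spectrum is its own baseline", {
  n <- 1024
  ppm <- seq(5.5, 0.2, length.out = n)
  intensity <- 2 + (ppm - 0.2)^2          # convex in ppm, hence per section
  sp <- mrs_spectrum(ppm, intensity)
  bl <- sectional_baseline(sp)
  i <- bl$region_idx
  expect_equal(bl$combined[i], intensity[i], tolerance = 1e-9)
  res <- remove_baseline(sp, bl)
  expect_true(all(res$intensity[i] == 0))
})

test_that("the baseline tracks the generated water tail on peak-free bins", {
  sp <- generate_spectrum(spectrum_spec(seed = 4))
  fit <- quantify_spectrum(sp$spectrum)
  ppm <- sp$spectrum$ppm
  i <- fit$baseline$region_idx
  peak_free <- vapply(ppm[i], function(x)
    all(abs(x - sp$truth$peak_ppm) > 0.15), logical(1))
  err <- abs(fit$baseline$combined[i] - sp$truth$tail[i])[peak_free]
  expect_lt(max(err), 0.05 * sp$spectrum$intensity[i][1])  # 5% of tail level
})

test_that("the combined baseline follows the sectional minimum rule", {
  sp <- generate_spectrum(spectrum_spec(seed = 5))$spectrum
  bl <- sectional_baseline(sp)
  ppm <- sp$ppm
  h1 <- rep(NA_real_, length(ppm)); h1[bl$sections$h1$idx] <-
    bl$sections$h1$envelope$values
  h2 <- rep(NA_real_, length(ppm)); h2[bl$sections$h2$idx] <-
    bl$sections$h2$envelope$values
  overlap <- which(ppm <= 3.9 & ppm > 3.2 & !is.na(h1) & !is.na(h2))
  expect_gt(length(overlap), 10)
  expect_equal(bl$combined[overlap], pmin(h1[overlap], h2[overlap]))
  # single-coverage interval equals its own section's envelope
  solo <- which(ppm <= 3.2 & ppm > 3.0 & !is.na(h2))
  expect_equal(bl$combined[solo], h2[solo])
})

test_that("baseline removal leaves a non-negative residual that is zero at hull vertices", {
  set.seed(6)
  for (rep in 1:20) {
    n <- 512
    ppm <- seq(5.2, 0.6, length.out = n)
    intensity <- pmax(rnorm(n, 5, 2), 0)     # arbitrary random spectrum
    sp <- mrs_spectrum(ppm, intensity)
    bl <- sectional_baseline(sp)
    res <- remove_baseline(sp, bl)
    i <- bl$region_idx
    expect_true(all(res$intensity >= 0))
    expect_true(all(res$intensity[-i] == 0))
    # hull vertices of h4 lie in its solo interval [1.5, 1.0): residual 0
    s4 <- bl$sections$h4
    verts <- s4$idx[s4$envelope$hull_indices]
    solo4 <- verts[ppm[verts] <= 1.5]
    expect_true(all(res$intensity[solo4] == 0))
  }
})

test_that("axis mismatch between spectrum and baseline is rejected", {
  sp <- generate_spectrum(spectrum_spec(seed = 7))$spectrum
  bl <- sectional_baseline(sp)
  other <- mrs_spectrum(sp$ppm * 1.001, sp$intensity)
  expect_error(remove_baseline(other, bl), "different ppm axis")
})

test_that("peak detection computes window maxima and guarded ratios", {
  n <- 1024
  ppm <- seq(5.5, 0.2, length.out = n)
  zero <- mrs_spectrum(ppm, rep(0, n))
  q0 <- detect_peaks(zero)
  expect_true(all(q0$heights == 0))
  expect_true(all(is.na(unlist(q0$ratios))))

  # spikes of known heights: Cho=2, Cr=1, NAA=2, LL=3
  intensity <- rep(0, n)
  intensity[which.min(abs(ppm - 3.22))] <- 2
  intensity[which.min(abs(ppm - 3.03))] <- 1
  intensity[which.min(abs(ppm - 2.02))] <- 2
  intensity[which.min(abs(ppm - 1.20))] <- 3
  q <- detect_peaks(mrs_spectrum(ppm, intensity))
  expect_equal(q$ratios$cho_naa, 1.0)
  expect_equal(q$ratios$cho_cr, 2.0)
  expect_equal(q$ratios$ll_cr, 3.0)
})

test_that("LL is the larger of overlapping lipid and lactate maxima", {
  peaks <- data.frame(name = c("Cr", "NAA", "Lac", "Lip"),
                      ppm = c(3.03, 2.02, 1.33, 1.15),
                      amplitude = c(5, 8, 3, 7), fwhm = 0.06,
                      lineshape = "gaussian", stringsAsFactors = FALSE)
  sp <- generate_spectrum(spectrum_spec(peaks = peaks, seed = 8))
  fit <- quantify_spectrum(sp$spectrum)
  expect_equal(unname(coef(fit)[["LL"]]), 7, tolerance = 0.05)
  # optional sum mode adds the lactate and lipid window maxima
  q_sum <- detect_peaks(fit$residual, ll_mode = "sum")
  expect_equal(unname(q_sum$heights[["LL"]]), 10, tolerance = 0.1)
})

test_that("ROI aggregation averages ratios and honours missingness", {
  mk <- function(cho_naa, cho_cr, ll_cr)
    structure(list(voxel_index = c(1L, 1L, 1L),
                   heights = c(Cho = 1, Cr = 1, NAA = 1, Lac = 1, LL = 1),
                   shift_ppm = 0,
                   ratios = list(cho_naa = cho_naa, cho_cr = cho_cr,
                                 ll_cr = ll_cr)),
              class = "voxel_quant")
  one <- aggregate_roi(list(mk(1, 2, 3)))
  expect_equal(unlist(one$ratios), c(cho_naa = 1, cho_cr = 2, ll_cr = 3))

  two <- aggregate_roi(list(mk(1, 1, 1), mk(2, 2, 2)))
  expect_equal(two$ratios$cho_naa, 1.5)

  three <- aggregate_roi(list(mk(1, 1, 1), mk(1, 1, 4), mk(1, 1, NA)))
  expect_equal(three$ratios$ll_cr, 2.5)
  expect_equal(unname(three$n_used["ll_cr"]), 2)

  expect_error(aggregate_roi(list()), "at least one")
  expect_warning(aggregate_roi(list(mk(1, 1, 1), mk(1, 1, 1),
                                    mk(1, 1, 1), mk(1, 1, 1))), "1-3")
})

test_that("grid quantification composes the single-voxel pipeline", {
  ds <- generate_csi(spectrum_spec(seed = 10), csi_dims = c(2L, 2L, 1L))
  tab <- quantify_csi(ds, line_broadening = 2)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$flag == ""))
  # first voxel must match the stand-alone pipeline
  sp <- fid_to_spectrum(apodize(csi_fid(ds, 1, 1, 1), 2),
                        voxel_index = c(1L, 1L, 1L))
  fit <- quantify_spectrum(sp)
  expect_equal(tab$cho_naa[1], fit$quant$ratios$cho_naa)
  expect_equal(tab$shift_ppm[1], fit$shift_ppm)
  # determinism
  expect_identical(quantify_csi(ds, line_broadening = 2), tab)
})

test_that("an all-zero voxel is flagged without aborting the grid", {
  ds <- generate_csi(spectrum_spec(seed = 11), csi_dims = c(2L, 1L, 1L))
  ds$fids[[2]]$samples[] <- 0 + 0i
  tab <- quantify_csi(ds)
  expect_equal(tab$flag[1], "")
  expect_match(tab$flag[2], "all-zero")
  expect_true(is.na(tab$cho_naa[2]))
  expect_false(is.na(tab$cho_naa[1]))
})

test_that("pipeline is shift-consistent and recovers ratios under an extra shift", {
  base <- quantify_spectrum(generate_spectrum(shifted_spec(20, 0))$spectrum)
  delta <- 0.08
  shifted <- quantify_spectrum(
    generate_spectrum(shifted_spec(20, delta))$spectrum)
  expect_lt(abs(shifted$shift_ppm - (base$shift_ppm - delta)),
            ppm_bin_width() + 1e-9)
  for (rc in c("cho_naa", "cho_cr", "ll_cr")) {
    expect_lt(abs(shifted$quant$ratios[[rc]] / base$quant$ratios[[rc]] - 1),
              0.02)
  }
})
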