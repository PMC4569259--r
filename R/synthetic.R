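#' Specification of a synthetic MRS spectrum
#'
#' Describes a voxel spectrum as narrow metabolite lineshapes on a broad
#' residual-water tail plus white noise, with an optional induced chemical-
#' shift mis-calibration.  The axis is parameterized exactly like an acquired
#' FID (points, dwell time, transmitter frequency, carrier reference), so the
#' spectrum-domain and time-domain generators share one ppm grid.
#'
#' Defaults emulate a 3 T short-TE CSI voxel: 1024 points, 1200 Hz sweep
#' (dwell 1/1200 s) at 123.25 MHz referenced to water at 4.7 ppm, peaks at
#' Cho 3.22 / Cr 3.03 / NAA 2.02 / Lac 1.33 ppm with width 0.06 ppm, and a
#' residual-water tail of amplitude 40 a.u. and width 1.2 ppm.  The tail
#' width keeps its restriction to 1.0-4.3 ppm convex (a Lorentzian is convex
#' beyond fwhm/(2*sqrt(3)) from its centre), matching the smooth-baseline
#' assumption the envelope fit relies on.  The default peak lineshape is
#' Gaussian: its compact support keeps the nominal amplitude an unambiguous
#' ground truth for the recovered height (Lorentzian wings of the nearby
#' Cho/Cr pair overlap and blur what "true height above baseline" means);
#' Lorentzian peaks are available per entry.
#'
#' @param peaks data.frame: \code{ppm}, \code{amplitude} (a.u., >= 0),
#'   \code{fwhm} (ppm, > 0), \code{lineshape} ("lorentzian" or "gaussian").
#' @param water_tail Numeric triple: amplitude, fwhm (ppm), centre (ppm).
#' @param noise_sd White-noise standard deviation (a.u.).
#' @param ppm_shift Induced mis-calibration: every feature appears at its
#'   nominal position plus this offset (ppm).
#' @param n_points Axis length (>= 64).
#' @param dwell_time Seconds per sample.
#' @param transmitter_freq MHz.
#' @param reference_ppm Carrier position, ppm.
#' @param seed Integer seed making the generators pure functions of the spec.
#' @return An object of class \code{"spectrum_spec"}.
#' @export
spectrum_spec <- function(peaks = NULL,
                          water_tail = c(amplitude = 40, fwhm = 1.2,
                                         center = 4.7),
                          noise_sd = 0, ppm_shift = 0, n_points = 1024,
                          dwell_time = 1 / 1200, transmitter_freq = 123.25,
                          reference_ppm = 4.7, seed = 1L) {
  if (is.null(peaks)) {
    peaks <- data.frame(
      name = c("Cho", "Cr", "NAA", "Lac"),
      ppm = c(3.22, 3.03, 2.02, 1.33),
      amplitude = c(6, 5, 8, 2),
      fwhm = 0.06,
      lineshape = "gaussian",
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("ppm", "amplitude", "fwhm", "lineshape") %in% names(peaks)),
            all(peaks$amplitude >= 0), all(peaks$fwhm > 0),
            all(peaks$lineshape %in% c("lorentzian", "gaussian")),
            n_points >= 64, noise_sd >= 0)
  structure(list(peaks = peaks, water_tail = water_tail,
                 noise_sd = noise_sd, ppm_shift = ppm_shift,
                 n_points = as.integer(n_points), dwell_time = dwell_time,
                 transmitter_freq = transmitter_freq,
                 reference_ppm = reference_ppm, seed = as.integer(seed)),
            class = "spectrum_spec")
}

.lineshape_eval <- function(x, center, amplitude, fwhm, lineshape) {
  if (lineshape == "lorentzian") {
    g <- fwhm / 2
    amplitude * g^2 / ((x - center)^2 + g^2)
  } else {
    amplitude * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
  }
}

#' Generate a synthetic spectrum with ground truth
#'
#' Sums the spec's lineshapes and water tail on the ppm grid (every feature
#' displaced by \code{ppm_shift}), adds seeded white noise, and clamps at
#' zero (magnitude spectra are non-negative).
#'
#' @param spec A [spectrum_spec()].
#' @param voxel_index Optional voxel index for the spectrum.
#' @return List: \code{spectrum} ([mrs_spectrum()]) and \code{truth} (list:
#'   \code{amplitudes} named by peak, \code{peak_ppm} displaced positions,
#'   \code{tail} per-bin tail values, \code{shift} the induced offset).
#' @export
generate_spectrum <- function(spec, voxel_index = c(1L, 1L, 1L)) {
  stopifnot(inherits(spec, "spectrum_spec"))
  ppm <- ppm_axis(spec$n_points, spec$dwell_time, spec$transmitter_freq,
                  spec$reference_ppm)
  wt <- spec$water_tail
  tail_vals <- .lineshape_eval(ppm, wt[[3]] + spec$ppm_shift, wt[[1]], wt[[2]],
                               "lorentzian")
  intensity <- tail_vals
  pk <- spec$peaks
  for (j in seq_len(nrow(pk)))
    intensity <- intensity +
      .lineshape_eval(ppm, pk$ppm[j] + spec$ppm_shift, pk$amplitude[j],
                      pk$fwhm[j], pk$lineshape[j])
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    intensity <- intensity + stats::rnorm(length(ppm), sd = spec$noise_sd)
  }
  nm <- if (!is.null(pk$name)) pk$name else paste0("peak", seq_len(nrow(pk)))
  list(spectrum = mrs_spectrum(ppm, pmax(intensity, 0), voxel_index),
       truth = list(amplitudes = stats::setNames(pk$amplitude, nm),
                    peak_ppm = stats::setNames(pk$ppm + spec$ppm_shift, nm),
                    tail = tail_vals, shift = spec$ppm_shift))
}

#' Generate the time-domain counterpart of a synthetic spectrum
#'
#' Builds the FID as a sum of damped complex exponentials (Lorentzian peaks
#' decay at rate \eqn{\pi \cdot fwhm_{Hz}}, i.e. \eqn{T_2 = 1/(\pi\,fwhm)};
#' Gaussian peaks decay as \eqn{\exp(-(\pi\,fwhm\,t)^2 / (4\ln 2))}) plus the
#' water tail and seeded complex noise, so that [fid_to_spectrum()] recovers
#' peaks at the spec's positions with heights close to the spec amplitudes.
#'
#' @param spec A [spectrum_spec()].
#' @return A [fid_signal()].
#' @export
generate_fid <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  n <- spec$n_points
  t <- (seq_len(n) - 1) * spec$dwell_time
  s <- complex(real = numeric(n), imaginary = numeric(n))
  add_component <- function(s, center_ppm, amplitude, fwhm_ppm, lineshape) {
    f_hz <- (center_ppm - spec$reference_ppm) * spec$transmitter_freq
    fwhm_hz <- fwhm_ppm * spec$transmitter_freq
    decay <- if (lineshape == "lorentzian") exp(-pi * fwhm_hz * t)
             else exp(-(pi * fwhm_hz * t)^2 / (4 * log(2)))
    # scale so the discrete magnitude spectrum peaks near 'amplitude'
    scale_ht <- if (lineshape == "lorentzian")
      (1 - exp(-pi * fwhm_hz * spec$dwell_time))
    else
      1 / sum(exp(-(pi * fwhm_hz * t)^2 / (4 * log(2))))
    s + amplitude * scale_ht * decay * exp(2i * pi * f_hz * t)
  }
  pk <- spec$peaks
  for (j in seq_len(nrow(pk)))
    s <- add_component(s, pk$ppm[j] + spec$ppm_shift, pk$amplitude[j],
                       pk$fwhm[j], pk$lineshape[j])
  wt <- spec$water_tail
  if (wt[[1]] > 0)
    s <- add_component(s, wt[[3]] + spec$ppm_shift, wt[[1]], wt[[2]],
                       "lorentzian")
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    s <- s + complex(real = stats::rnorm(n, sd = spec$noise_sd),
                     imaginary = stats::rnorm(n, sd = spec$noise_sd))
  }
  fid_signal(s, spec$dwell_time, spec$transmitter_freq, spec$reference_ppm)
}

#' Generate a synthetic CSI dataset
#'
#' A grid of voxels, each generated by [generate_fid()] from the same base
#' spec with a per-voxel seed (derived from \code{spec$seed}).
#'
#' @param spec A [spectrum_spec()] used for every voxel.
#' @param csi_dims Integer triple (rows, cols, slices).
#' @param patient_id Identifier written into the header.
#' @return A [csi_dataset()].
#' @export
generate_csi <- function(spec, csi_dims = c(2L, 2L, 1L),
                         patient_id = "synthetic") {
  n_vox <- prod(csi_dims)
  fids <- lapply(seq_len(n_vox), function(v) {
    sp <- spec
    sp$seed <- spec$seed + v - 1L
    generate_fid(sp)
  })
  csi_dataset(fids, csi_dims, patient_id = patient_id)
}

.default_cohort_targets <- function() {
  # (mean, sd) per grade group and area for each ratio; tumoral rows follow
  # the grading-study conditions, peritumoral/contralateral LL values are
  # package choices (not reported per grade in that study)
  g <- expand.grid(grade_group = c("LGG", "HGG"),
                   area = c("tumoral", "peritumoral", "contralateral"),
                   stringsAsFactors = FALSE)
  tgt <- list(
    LGG.tumoral       = c(1.04, 0.43, 1.27, 0.31, 1.07, 1.32),
    HGG.tumoral       = c(1.35, 0.50, 1.70, 0.76, 2.65, 2.51),
    LGG.peritumoral   = c(0.59, 0.16, 0.95, 0.16, 0.80, 0.40),
    HGG.peritumoral   = c(0.59, 0.16, 0.95, 0.16, 0.80, 0.40),
    LGG.contralateral = c(0.47, 0.11, 0.84, 0.16, 0.60, 0.30),
    HGG.contralateral = c(0.47, 0.11, 0.84, 0.16, 0.60, 0.30))
  m <- do.call(rbind, tgt[paste(g$grade_group, g$area, sep = ".")])
  colnames(m) <- c("cho_naa_mean", "cho_naa_sd", "cho_cr_mean", "cho_cr_sd",
                   "ll_cr_mean", "ll_cr_sd")
  cbind(g, as.data.frame(m))
}

#' Specification of a synthetic ratio cohort
#'
#' Cohorts are drawn per (grade group x area) cell from lognormal
#' distributions matched to target means and standard deviations (ratio data
#' of this kind are right-skewed).  Defaults reproduce the grading-study
#' conditions: 36 LGG and 42 HGG cases, three areas per case, tumoral ratio
#' moments equal to the reported group statistics.
#'
#' @param n_lgg,n_hgg Cases per grade group.
#' @param targets data.frame like \code{.default_cohort_targets()}: one row
#'   per (grade_group, area) with \code{*_mean} / \code{*_sd} columns for the
#'   three ratios.
#' @param missing_ll_fraction Fraction of LL/Cr values set missing (emulating
#'   quantification failures of reference software; 29/78 for Siemens-style
#'   tables).
#' @param source Provenance label for the records.
#' @param seed Integer seed.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_lgg = 36L, n_hgg = 42L, targets = NULL,
                        missing_ll_fraction = 0, source = "AQoCE",
                        seed = 1L) {
  if (is.null(targets)) targets <- .default_cohort_targets()
  stopifnot(n_lgg >= 1L, n_hgg >= 1L,
            missing_ll_fraction >= 0, missing_ll_fraction <= 1)
  sd_cols <- grep("_sd$", names(targets), value = TRUE)
  if (any(targets[sd_cols] <= 0)) stop("target SDs must be > 0")
  structure(list(n_lgg = as.integer(n_lgg), n_hgg = as.integer(n_hgg),
                 targets = targets,
                 missing_ll_fraction = missing_ll_fraction,
                 source = source, seed = as.integer(seed)),
            class = "cohort_spec")
}

# lognormal parameters matching a target mean m and sd s
.lnorm_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic ratio cohort
#'
#' Seeded lognormal draws per (grade group x area) cell with exact group
#' sizes; LL/Cr values are set missing completely at random at the specified
#' fraction.
#'
#' @param spec A [cohort_spec()].
#' @return A \code{case_records} data.frame with one row per case per area.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_by_group <- c(LGG = spec$n_lgg, HGG = spec$n_hgg)
  ids <- c(paste0("L", seq_len(spec$n_lgg)), paste0("H", seq_len(spec$n_hgg)))
  grades <- c(rep("II", spec$n_lgg), rep("IV", spec$n_hgg))
  rows <- list()
  for (k in seq_len(nrow(spec$targets))) {
    tg <- spec$targets[k, ]
    n <- n_by_group[[tg$grade_group]]
    draw <- function(m, s) {
      p <- .lnorm_params(m, s)
      stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
    }
    sel <- if (tg$grade_group == "LGG") seq_len(spec$n_lgg)
           else spec$n_lgg + seq_len(spec$n_hgg)
    ll <- draw(tg$ll_cr_mean, tg$ll_cr_sd)
    if (spec$missing_ll_fraction > 0)
      ll[stats::runif(n) < spec$missing_ll_fraction] <- NA_real_
    rows[[k]] <- data.frame(
      case_id = ids[sel], who_grade = grades[sel], area = tg$area,
      cho_naa = draw(tg$cho_naa_mean, tg$cho_naa_sd),
      cho_cr = draw(tg$cho_cr_mean, tg$cho_cr_sd),
      ll_cr = ll,
      stringsAsFactors = FALSE)
  }
  case_records(do.call(rbind, rows), source = spec$source)
}
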