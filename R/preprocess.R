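#' Construct a free induction decay (FID) signal
#'
#' Container for one voxel's complex time-domain MRS signal plus the
#' acquisition metadata needed to place its spectrum on a ppm axis.
#'
#' @param samples Complex (or numeric, coerced) vector, length >= 8.
#' @param dwell_time Sampling interval in seconds (> 0).
#' @param transmitter_freq Transmitter (carrier) frequency in MHz (> 0).
#' @param reference_ppm Chemical shift assigned to the carrier, in ppm.
#'   Defaults to 4.7 (water, on which CHESS suppression is centred).
#' @return An object of class \code{"fid_signal"}.
#' @export
fid_signal <- function(samples, dwell_time, transmitter_freq,
                       reference_ppm = 4.7) {
  samples <- as.complex(samples)
  if (length(samples) < 8L) stop("FID must have at least 8 samples")
  if (anyNA(samples)) stop("FID samples must not contain NA")
  if (!is.numeric(dwell_time) || length(dwell_time) != 1L || dwell_time <= 0)
    stop("'dwell_time' must be a positive scalar (seconds)")
  if (!is.numeric(transmitter_freq) || length(transmitter_freq) != 1L ||
      transmitter_freq <= 0)
    stop("'transmitter_freq' must be a positive scalar (MHz)")
  structure(
    list(samples = samples, dwell_time = as.numeric(dwell_time),
         transmitter_freq = as.numeric(transmitter_freq),
         reference_ppm = as.numeric(reference_ppm)),
    class = "fid_signal")
}

#' @export
print.fid_signal <- function(x, ...) {
  cat(sprintf("FID: %d complex points, dwell %.3g s (SW %.0f Hz), %.2f MHz, ref %.2f ppm\n",
              length(x$samples), x$dwell_time, 1 / x$dwell_time,
              x$transmitter_freq, x$reference_ppm))
  invisible(x)
}

#' Construct a spectrum
#'
#' Real-valued intensity on a strictly decreasing ppm axis (the display
#' convention for NMR/MRS spectra).
#'
#' @param ppm Strictly decreasing numeric axis (ppm).
#' @param intensity Non-negative numeric vector, same length as \code{ppm}.
#' @param voxel_index Optional integer triple (row, col, slice).
#' @return An object of class \code{"mrs_spectrum"}.
#' @export
mrs_spectrum <- function(ppm, intensity, voxel_index = c(1L, 1L, 1L)) {
  if (length(ppm) != length(intensity))
    stop("'ppm' and 'intensity' must have the same length")
  if (any(diff(ppm) >= 0)) stop("'ppm' must be strictly decreasing")
  if (any(intensity < 0)) stop("'intensity' must be non-negative")
  structure(
    list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
         voxel_index = as.integer(voxel_index)),
    class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("MRS spectrum: %d bins, %.2f to %.2f ppm (voxel %s)\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              paste(x$voxel_index, collapse = ",")))
  invisible(x)
}

#' @export
plot.mrs_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "chemical shift (ppm)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Exponential apodization of an FID
#'
#' Multiplies sample \eqn{i} (0-based) by \eqn{\exp(-\pi \cdot lb \cdot t_i)}
#' with \eqn{t_i = i \cdot dwell}, i.e. a Lorentzian line broadening of
#' \code{line_broadening} Hz.  This damps the noisy tail of the FID before
#' Fourier transformation.
#'
#' @param fid A [fid_signal()].
#' @param line_broadening Line broadening in Hz (>= 0).  0 is the identity.
#' @return The apodized \code{fid_signal} (same length).
#' @export
apodize <- function(fid, line_broadening = 2) {
  stopifnot(inherits(fid, "fid_signal"))
  if (!is.numeric(line_broadening) || length(line_broadening) != 1L ||
      is.na(line_broadening) || line_broadening < 0)
    stop("'line_broadening' must be a non-negative scalar (Hz)")
  n <- length(fid$samples)
  t <- (seq_len(n) - 1) * fid$dwell_time
  fid$samples <- fid$samples * exp(-pi * line_broadening * t)
  fid
}

#' ppm axis of the discrete spectrum of an FID
#'
#' The DFT bin frequencies, centred on the carrier, mapped to ppm via
#' \code{reference_ppm + f_Hz / transmitter_freq_MHz} and sorted decreasing.
#' Bin spacing is \code{1 / (n * dwell_time * transmitter_freq)} ppm.
#'
#' @param n Number of points.
#' @param dwell_time Seconds.
#' @param transmitter_freq MHz.
#' @param reference_ppm ppm of the carrier.
#' @return Strictly decreasing numeric vector of length \code{n}.
#' @keywords internal
ppm_axis <- function(n, dwell_time, transmitter_freq, reference_ppm = 4.7) {
  freq_hz <- (seq_len(n) - 1 - floor(n / 2)) / (n * dwell_time)
  rev(reference_ppm + freq_hz / transmitter_freq)
}

#' Fourier transform an FID to a magnitude spectrum
#'
#' Discrete Fourier transform of the (typically apodized) FID, frequency axis
#' centred on the carrier and converted to ppm, reordered so ppm decreases.
#' Intensity is the magnitude of the complex spectrum: the pipeline applies no
#' phase correction, and the downstream envelope and peak logic require a real
#' non-negative trace.
#'
#' @param fid A [fid_signal()].
#' @param voxel_index Optional integer triple carried into the spectrum.
#' @param zero_fill Optional total length to zero-pad the FID to before the
#'   transform (must be >= the FID length).  Off by default: padding only
#'   interpolates the spectrum, it adds no information.
#' @return An [mrs_spectrum()].
#' @export
fid_to_spectrum <- function(fid, voxel_index = c(1L, 1L, 1L),
                            zero_fill = NULL) {
  stopifnot(inherits(fid, "fid_signal"))
  if (!is.null(zero_fill)) {
    zero_fill <- as.integer(zero_fill)
    if (zero_fill < length(fid$samples))
      stop("'zero_fill' must be at least the FID length")
    fid$samples <- c(fid$samples,
                     rep(0 + 0i, zero_fill - length(fid$samples)))
  }
  n <- length(fid$samples)
  sp <- stats::fft(fid$samples)
  # reorder DFT output to ascending frequency (negative first), then flip to
  # descending ppm; R's fft puts frequencies 0..(n-1)/(n*dt) in order, with
  # bins above n/2 aliased negative
  half <- floor(n / 2)
  shifted <- sp[c((n - half + 1L):n, 1L:(n - half))]
  mrs_spectrum(
    ppm = ppm_axis(n, fid$dwell_time, fid$transmitter_freq, fid$reference_ppm),
    intensity = rev(Mod(shifted)),
    voxel_index = voxel_index)
}
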