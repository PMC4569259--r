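#' Metabolite panel
#'
#' Point metabolites are quantified as the maximum baseline-removed intensity
#' within \code{theoretical_ppm +/- halfwidth}; the combined lipid-lactate
#' signal (LL) is quantified over the fixed range 1.7 to 1.0 ppm.
#'
#' @param entries data.frame with columns \code{name}, \code{theoretical_ppm},
#'   \code{halfwidth}.  Defaults: Cho 3.22, Cr 3.03, NAA 2.02, Lac 1.33 ppm,
#'   all with halfwidth 0.1 ppm.
#' @param ll_range Length-2 decreasing ppm range for the combined
#'   lipid-lactate maximum.
#' @return An object of class \code{"metabolite_panel"}.
#' @export
metabolite_panel <- function(entries = NULL, ll_range = c(1.7, 1.0)) {
  if (is.null(entries)) {
    entries <- data.frame(
      name = c("Cho", "Cr", "NAA", "Lac"),
      theoretical_ppm = c(3.22, 3.03, 2.02, 1.33),
      halfwidth = 0.1,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "theoretical_ppm", "halfwidth") %in% names(entries)))
  if (any(entries$halfwidth <= 0)) stop("halfwidth must be > 0")
  if (any(entries$theoretical_ppm < 0 | entries$theoretical_ppm > 4.7))
    stop("theoretical positions must lie in [0, 4.7] ppm")
  if (length(ll_range) != 2L || diff(ll_range) >= 0)
    stop("'ll_range' must be a decreasing ppm pair")
  structure(list(entries = entries, ll_range = as.numeric(ll_range)),
            class = "metabolite_panel")
}

# nearest-bin index for a ppm value on a decreasing axis
.bin_at <- function(ppm, x) which.min(abs(ppm - x))

# contiguous index run covering [lo, hi] with endpoints snapped to bin centres
.section_idx <- function(ppm, hi, lo) {
  if (hi > ppm[1] + (ppm[1] - ppm[2]) / 2 || lo < ppm[length(ppm)] -
      (ppm[1] - ppm[2]) / 2)
    stop(sprintf("ppm axis does not cover [%g, %g]", lo, hi))
  .bin_at(ppm, hi):.bin_at(ppm, lo)
}

#' NAA-anchored chemical-shift bias correction
#'
#' Fits a lower convex envelope on the 2.0 +/- 0.5 ppm window, subtracts it,
#' and takes the argmax of the residual as the actual NAA position.  The
#' spectrum is then circularly index-shifted so that bin lands on the bin
#' nearest 2.02 ppm.  Ties in the argmax (e.g. an all-zero residual) are
#' broken toward the bin nearest 2.02 ppm, giving a zero shift for featureless
#' input.  The shift is a whole number of bins; no sub-bin interpolation.
#'
#' @param spectrum An [mrs_spectrum()] whose axis covers 1.5 to 2.5 ppm.
#' @param target_ppm Position NAA is aligned to (default 2.02 ppm).
#' @param window Search window half-width in ppm (default 0.5 around 2.0).
#' @return List with \code{spectrum} (aligned), \code{shift_ppm},
#'   \code{shift_bins}.
#' @export
bias_correct <- function(spectrum, target_ppm = 2.02, window = 0.5) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  ppm <- spectrum$ppm
  idx <- .section_idx(ppm, 2.0 + window, 2.0 - window)
  env <- lower_convex_envelope(spectrum$intensity[idx])
  resid <- spectrum$intensity[idx] - env$values
  best <- which(resid >= max(resid) - 1e-12)
  # tie-break toward the bin nearest the target
  found <- idx[best[which.min(abs(ppm[idx[best]] - target_ppm))]]
  target_bin <- .bin_at(ppm, target_ppm)
  shift_bins <- target_bin - found
  n <- length(ppm)
  if (shift_bins != 0) {
    pos <- ((seq_len(n) - 1 - shift_bins) %% n) + 1
    spectrum$intensity <- spectrum$intensity[pos]
  }
  list(spectrum = spectrum,
       shift_ppm = ppm[target_bin] - ppm[found],
       shift_bins = shift_bins)
}

.default_sections <- list(h1 = c(4.3, 3.2), h2 = c(3.9, 2.0),
                          h3 = c(3.0, 1.5), h4 = c(1.7, 1.0))

#' Sectional convex-envelope baseline
#'
#' Fits lower convex envelopes on four overlapping ppm sections
#' (h1: 4.3-3.2, h2: 3.9-2.0, h3: 3.0-1.5, h4: 1.7-1.0) and assembles the
#' whole-range baseline on 4.3 to 1.0 ppm piecewise:
#' \preformatted{
#'   h1             4.3 >= x > 3.9
#'   min(h1, h2)    3.9 >= x > 3.2
#'   h2             3.2 >= x > 3.0
#'   min(h2, h3)    3.0 >= x > 2.0
#'   h3             2.0 >= x > 1.7
#'   min(h3, h4)    1.7 >= x > 1.5
#'   h4             1.5 >= x > 1.0
#' }
#' Section endpoints snap to the nearest bin centre; a bin belongs to an
#' interval by its ppm value, and the single bin at 4.3 ppm closes the top
#' interval.  Where a designated envelope is undefined at an edge bin (a snap
#' artefact) the minimum runs over the designated envelopes that are defined.
#' The overlap-minimum keeps the baseline below the spectrum even where a peak
#' sits at a section endpoint (hull endpoints always touch the data).
#'
#' @param spectrum An [mrs_spectrum()] covering 1.0 to 4.3 ppm (the aligned
#'   spectrum from [bias_correct()]).
#' @param sections Named list of four decreasing (hi, lo) ppm pairs.
#' @return An object of class \code{"baseline_model"}: \code{sections} (each
#'   with \code{range}, \code{idx}, \code{envelope}), \code{combined} (full
#'   axis, \code{NA} outside 4.3-1.0), \code{region_idx}, \code{ppm}.
#' @export
sectional_baseline <- function(spectrum, sections = .default_sections) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  ppm <- spectrum$ppm
  f <- spectrum$intensity
  sec <- lapply(names(sections), function(nm) {
    rg <- sections[[nm]]
    idx <- tryCatch(.section_idx(ppm, rg[1], rg[2]), error = function(e)
      stop(sprintf("section %s: %s", nm, conditionMessage(e))))
    list(range = rg, idx = idx, envelope = lower_convex_envelope(f[idx]))
  })
  names(sec) <- names(sections)
  # per-section envelope values on the full axis (NA outside the section)
  n <- length(ppm)
  vals <- lapply(sec, function(s) {
    v <- rep(NA_real_, n); v[s$idx] <- s$envelope$values; v
  })
  region_idx <- .section_idx(ppm, 4.3, 1.0)
  combined <- rep(NA_real_, n)
  top_bin <- region_idx[1]
  for (i in region_idx) {
    x <- ppm[i]
    use <- if (i == top_bin || x > 3.9) "h1"
      else if (x > 3.2) c("h1", "h2")
      else if (x > 3.0) "h2"
      else if (x > 2.0) c("h2", "h3")
      else if (x > 1.7) "h3"
      else if (x > 1.5) c("h3", "h4")
      else "h4"
    v <- unlist(lapply(vals[use], `[`, i))
    if (all(is.na(v))) v <- unlist(lapply(vals, `[`, i))  # snap-edge fallback
    combined[i] <- min(v, na.rm = TRUE)
  }
  structure(list(sections = sec, combined = combined,
                 region_idx = region_idx, ppm = ppm),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Sectional convex-envelope baseline:",
      length(x$region_idx), "bins on [4.3, 1.0] ppm;",
      paste(vapply(x$sections, function(s)
        length(s$envelope$hull_indices), integer(1)), collapse = "/"),
      "hull vertices per section\n")
  invisible(x)
}

#' Subtract the sectional baseline from a spectrum
#'
#' Residual = intensity minus combined baseline on 4.3 to 1.0 ppm (clamped at
#' zero against floating-point round-off; the envelope is a minorant so the
#' true residual is non-negative).  Bins outside 4.3-1.0 ppm are set to 0.
#'
#' @param spectrum The aligned [mrs_spectrum()] the baseline was built from.
#' @param baseline A [sectional_baseline()] model built on the same ppm axis.
#' @return An [mrs_spectrum()] holding the residual.
#' @export
remove_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "mrs_spectrum"),
            inherits(baseline, "baseline_model"))
  if (length(spectrum$ppm) != length(baseline$ppm) ||
      any(spectrum$ppm != baseline$ppm))
    stop("baseline was built from a different ppm axis")
  res <- numeric(length(spectrum$ppm))
  i <- baseline$region_idx
  res[i] <- pmax(spectrum$intensity[i] - baseline$combined[i], 0)
  mrs_spectrum(spectrum$ppm, res, spectrum$voxel_index)
}

.compute_ratios <- function(heights) {
  ratio <- function(num, den)
    if (!is.na(den) && den > 0 && !is.na(num)) num / den else NA_real_
  list(cho_naa = ratio(heights[["Cho"]], heights[["NAA"]]),
       cho_cr = ratio(heights[["Cho"]], heights[["Cr"]]),
       ll_cr = ratio(heights[["LL"]], heights[["Cr"]]))
}

#' Window-maximum metabolite peak detection
#'
#' For each point metabolite in the panel, the height is the maximum residual
#' intensity within its theoretical position +/- halfwidth; the combined
#' lipid-lactate (LL) height is the maximum residual over the panel's LL
#' range (1.7 to 1.0 ppm by default).  Ratios Cho/NAA, Cho/Cr and LL/Cr are
#' computed; a missing or zero denominator yields a missing ratio.
#'
#' @param residual Baseline-removed [mrs_spectrum()] from [remove_baseline()].
#' @param panel A [metabolite_panel()].
#' @param shift_ppm Bias-correction shift recorded in the result.
#' @param ll_mode \code{"max"} (default): LL is the single maximum over the
#'   LL range.  \code{"sum"}: LL is the lactate-window maximum plus the
#'   maximum over the remaining (lipid) part of the LL range below it.
#' @return An object of class \code{"voxel_quant"}: \code{voxel_index},
#'   \code{heights} (named numeric, includes \code{LL}), \code{shift_ppm},
#'   \code{ratios} (list cho_naa, cho_cr, ll_cr).
#' @export
detect_peaks <- function(residual, panel = metabolite_panel(),
                         shift_ppm = 0, ll_mode = c("max", "sum")) {
  ll_mode <- match.arg(ll_mode)
  stopifnot(inherits(residual, "mrs_spectrum"),
            inherits(panel, "metabolite_panel"))
  ppm <- residual$ppm
  ent <- panel$entries
  heights <- vapply(seq_len(nrow(ent)), function(j) {
    sel <- abs(ppm - ent$theoretical_ppm[j]) <= ent$halfwidth[j]
    if (!any(sel)) return(NA_real_)
    max(residual$intensity[sel])
  }, numeric(1))
  names(heights) <- ent$name
  sel <- ppm <= panel$ll_range[1] & ppm >= panel$ll_range[2]
  heights[["LL"]] <- if (!any(sel)) NA_real_
  else if (ll_mode == "max") max(residual$intensity[sel])
  else {
    # lactate window from the panel (or its conventional position), lipid =
    # the rest of the LL range below it
    lac_row <- match("Lac", ent$name)
    lac_pos <- if (!is.na(lac_row)) ent$theoretical_ppm[lac_row] else 1.33
    lac_hw <- if (!is.na(lac_row)) ent$halfwidth[lac_row] else 0.1
    lac_sel <- sel & abs(ppm - lac_pos) <= lac_hw
    lip_sel <- sel & ppm < lac_pos - lac_hw
    max(residual$intensity[lac_sel], 0) + max(residual$intensity[lip_sel], 0)
  }
  structure(list(voxel_index = residual$voxel_index, heights = heights,
                 shift_ppm = shift_ppm, ratios = .compute_ratios(heights)),
            class = "voxel_quant")
}

#' @export
print.voxel_quant <- function(x, ...) {
  cat(sprintf("Voxel (%s): shift %+.3f ppm\n",
              paste(x$voxel_index, collapse = ","), x$shift_ppm))
  print(round(x$heights, 3))
  r <- x$ratios
  cat(sprintf("Cho/NAA = %.3f  Cho/Cr = %.3f  LL/Cr = %.3f\n",
              r$cho_naa, r$cho_cr, r$ll_cr))
  invisible(x)
}

#' Quantify one spectrum with the convex-envelope pipeline
#'
#' Runs bias correction, sectional baseline fitting, baseline removal and
#' peak detection on a single spectrum, returning a classed fit object.
#'
#' @param spectrum An [mrs_spectrum()] covering 1.0 to 4.3 ppm.
#' @param panel A [metabolite_panel()].
#' @return An object of class \code{"aqoce_fit"}: the input \code{spectrum},
#'   the \code{aligned} spectrum, \code{shift_ppm}, \code{shift_bins}, the
#'   \code{baseline} model, the \code{residual} spectrum and the
#'   \code{quant} ([detect_peaks()] result).
#' @examples
#' sp <- generate_spectrum(spectrum_spec(seed = 1))
#' fit <- quantify_spectrum(sp$spectrum)
#' coef(fit)
#' @export
quantify_spectrum <- function(spectrum, panel = metabolite_panel()) {
  bc <- bias_correct(spectrum)
  bl <- sectional_baseline(bc$spectrum)
  res <- remove_baseline(bc$spectrum, bl)
  q <- detect_peaks(res, panel, shift_ppm = bc$shift_ppm)
  structure(list(spectrum = spectrum, aligned = bc$spectrum,
                 shift_ppm = bc$shift_ppm, shift_bins = bc$shift_bins,
                 baseline = bl, residual = res, quant = q, panel = panel),
            class = "aqoce_fit")
}

#' @export
print.aqoce_fit <- function(x, ...) {
  cat("Convex-envelope MRS quantification\n")
  print(x$quant)
  invisible(x)
}

#' @export
coef.aqoce_fit <- function(object, ...) object$quant$heights

#' @export
fitted.aqoce_fit <- function(object, ...) object$baseline$combined

#' @export
residuals.aqoce_fit <- function(object, ...) object$residual$intensity

#' @export
summary.aqoce_fit <- function(object, ...) {
  r <- object$quant$ratios
  out <- list(shift_ppm = object$shift_ppm, heights = object$quant$heights,
              ratios = c(cho_naa = r$cho_naa, cho_cr = r$cho_cr,
                         ll_cr = r$ll_cr))
  class(out) <- "summary.aqoce_fit"
  out
}

#' @export
print.summary.aqoce_fit <- function(x, ...) {
  cat(sprintf("Shift applied: %+.4f ppm\nPeak heights (a.u.):\n", x$shift_ppm))
  print(round(x$heights, 3))
  cat("Ratios:\n")
  print(round(x$ratios, 3))
  invisible(x)
}

#' @export
plot.aqoce_fit <- function(x, ...) {
  ppm <- x$aligned$ppm
  i <- x$baseline$region_idx
  graphics::plot(ppm, x$aligned$intensity, type = "l",
                 xlim = rev(range(ppm)), xlab = "chemical shift (ppm)",
                 ylab = "intensity (a.u.)", ...)
  graphics::lines(ppm[i], x$baseline$combined[i], col = "red")
  graphics::lines(ppm[i], x$residual$intensity[i], col = "blue")
  graphics::legend("topright", c("aligned", "baseline", "residual"),
                   col = c("black", "red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Average metabolite ratios over the voxels of a region of interest
#'
#' Unweighted mean of each ratio across the selected voxels (typically 1-3
#' per region, chosen by tumor size), ignoring missing values; the number of
#' voxels contributing to each ratio is reported.
#'
#' @param quants Non-empty list of [detect_peaks()] results (or
#'   \code{aqoce_fit} objects, whose quantifications are taken).
#' @return A \code{voxel_quant}-like list with averaged \code{ratios},
#'   averaged \code{heights}, and \code{n_used} per ratio.
#' @export
aggregate_roi <- function(quants) {
  if (length(quants) == 0L) stop("'quants' must contain at least one voxel")
  quants <- lapply(quants, function(q)
    if (inherits(q, "aqoce_fit")) q$quant else q)
  if (!all(vapply(quants, inherits, logical(1), "voxel_quant")))
    stop("'quants' must be voxel_quant or aqoce_fit objects")
  if (length(quants) > 3L)
    warning("more than 3 voxels in one ROI; the protocol uses 1-3")
  rat <- sapply(quants, function(q)
    unlist(q$ratios[c("cho_naa", "cho_cr", "ll_cr")]))
  if (is.null(dim(rat))) rat <- matrix(rat, nrow = 3)
  hts <- sapply(quants, function(q) q$heights)
  ratios <- rowMeans(rat, na.rm = TRUE)
  ratios[is.nan(ratios)] <- NA_real_
  structure(list(
    ratios = as.list(ratios),
    heights = rowMeans(hts, na.rm = TRUE),
    n_used = rowSums(!is.na(rat)),
    n_voxels = length(quants)),
    class = "roi_quant")
}

#' Quantify every voxel of a CSI dataset
#'
#' Applies apodization, Fourier transformation and the full quantification
#' pipeline to each voxel of the grid.  Per-voxel failures (e.g. an all-zero
#' voxel) are flagged in the output row, never abort the grid.
#'
#' @param dataset A [csi_dataset()].
#' @param panel A [metabolite_panel()].
#' @param line_broadening Apodization in Hz (default 2).
#' @return data.frame with one row per voxel: \code{row}, \code{col},
#'   \code{slice}, \code{shift_ppm}, one height column per metabolite plus
#'   \code{LL}, the three ratios, and \code{flag} (\code{""} or the error
#'   message).
#' @export
quantify_csi <- function(dataset, panel = metabolite_panel(),
                         line_broadening = 2) {
  stopifnot(inherits(dataset, "csi_dataset"))
  d <- dataset$header$csi_dims
  met_names <- c(panel$entries$name, "LL")
  rows <- list()
  for (s in seq_len(d[3])) for (cc in seq_len(d[2])) for (r in seq_len(d[1])) {
    fid <- csi_fid(dataset, r, cc, s)
    row <- data.frame(row = r, col = cc, slice = s, shift_ppm = NA_real_,
                      stringsAsFactors = FALSE)
    for (nm in met_names) row[[paste0("height_", tolower(nm))]] <- NA_real_
    row$cho_naa <- NA_real_; row$cho_cr <- NA_real_; row$ll_cr <- NA_real_
    row$flag <- ""
    fit <- tryCatch({
      sp <- fid_to_spectrum(apodize(fid, line_broadening),
                            voxel_index = c(r, cc, s))
      if (all(sp$intensity == 0)) stop("all-zero voxel")
      quantify_spectrum(sp, panel)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      row$flag <- conditionMessage(fit)
    } else {
      q <- fit$quant
      row$shift_ppm <- q$shift_ppm
      for (nm in met_names)
        row[[paste0("height_", tolower(nm))]] <- unname(q$heights[[nm]])
      row$cho_naa <- q$ratios$cho_naa
      row$cho_cr <- q$ratios$cho_cr
      row$ll_cr <- q$ratios$ll_cr
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
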