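#' Lower convex envelope of a sequence
#'
#' Computes the lower convex envelope (the pointwise-maximal convex minorant)
#' of a real sequence by a single incremental scan, the baseline-fitting
#' primitive of the AQoCE pipeline.  The scan keeps a stack of hull vertices;
#' each new point is appended and the penultimate vertex is deleted while the
#' convexity inequality
#' \deqn{h(k-2)\,(I(k)-I(k-1)) + h(k)\,(I(k-1)-I(k-2)) > h(k-1)\,(I(k)-I(k-2))}
#' fails, where \eqn{I} are the retained (1-based) indices.  Deleted points are
#' finally restored by linear interpolation between flanking hull vertices.
#' Each point is deleted at most once, so the total work is linear in
#' \code{length(f)}.
#'
#' The inequality is strict, so collinear middle points are deleted and then
#' restored exactly by the interpolation step; ties are harmless.  Sequences
#' of length 1 or 2 are trivially convex and returned unchanged.
#'
#' @param f Numeric vector (length >= 1, finite values).
#' @return An object of class \code{"envelope"}: a list with
#'   \item{values}{numeric vector, same length as \code{f}; the envelope.}
#'   \item{hull_indices}{increasing integer vector of retained vertex indices
#'     (1-based); always contains the first and last index.}
#'   \item{n_deleted}{number of vertex deletions performed by the scan
#'     (at most \code{length(f) - 2}).}
#' @seealso [envelope_oracle()] for an independent reference computation.
#' @examples
#' e <- lower_convex_envelope(c(3, 1, 2, 0, 4))
#' e$values        # 3 1 0.5 0 4
#' e$hull_indices  # 1 2 4 5
#' @export
lower_convex_envelope <- function(f) {
  if (length(f) == 0L)
    stop("'f' must have length >= 1")
  if (!is.numeric(f) || anyNA(f) || any(!is.finite(f)))
    stop("'f' must be finite numeric")
  f <- as.numeric(f)
  k <- length(f)
  if (k < 3L) {
    return(structure(
      list(values = f, hull_indices = seq_len(k), n_deleted = 0L),
      class = "envelope"))
  }
  idx <- integer(k)
  top <- 0L
  ndel <- 0L
  for (i in seq_len(k)) {
    while (top >= 2L) {
      a <- idx[top - 1L]
      b <- idx[top]
      # keep vertex b when the strict convexity inequality holds
      if (f[a] * (i - b) + f[i] * (b - a) > f[b] * (i - a)) break
      top <- top - 1L
      ndel <- ndel + 1L
    }
    top <- top + 1L
    idx[top] <- i
  }
  hull <- idx[seq_len(top)]
  values <- stats::approx(hull, f[hull], xout = seq_len(k))$y
  values[hull] <- f[hull]   # exact at vertices, no interpolation round-off
  structure(
    list(values = values, hull_indices = hull, n_deleted = ndel),
    class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat("Lower convex envelope:", length(x$values), "points,",
      length(x$hull_indices), "hull vertices\n")
  invisible(x)
}

#' Independent lower-convex-envelope reference
#'
#' Computes the same envelope as [lower_convex_envelope()] by an unrelated
#' route: the planar convex hull of the points \eqn{(i, f_i)} via
#' \code{grDevices::chull} (compiled geometric code), from which the lower
#' chain is extracted and linearly interpolated.  The extracted chain is
#' self-validated against the minorant property.  Intended for verification;
#' use [lower_convex_envelope()] in pipelines (it also reports hull vertices).
#'
#' @param f Numeric vector (length >= 1).
#' @return Numeric vector: the envelope values.
#' @export
envelope_oracle <- function(f) {
  if (length(f) == 0L)
    stop("'f' must have length >= 1")
  f <- as.numeric(f)
  k <- length(f)
  if (k <= 2L) return(f)
  if (diff(range(f)) == 0) return(f)   # constant: degenerate hull
  x <- seq_len(k)
  h <- grDevices::chull(x, f)
  # rotate the cyclic hull order to start at the leftmost point (index 1)
  s <- which(h == 1L)
  h <- c(h[s:length(h)], h[seq_len(s - 1L)])
  r <- which(h == k)
  chains <- list(h[1:r], rev(c(h[r:length(h)], 1L)))
  scale <- max(abs(f), 1)
  for (ch in chains) {
    if (any(diff(ch) <= 0L)) next
    # the lower chain is the one that is convex AND a pointwise minorant
    # (a flat-topped hull makes the concave upper chain a minorant too)
    if (length(ch) >= 3L) {
      slopes <- diff(f[ch]) / diff(ch)
      if (any(diff(slopes) < -1e-9 * scale)) next
    }
    v <- stats::approx(ch, f[ch], xout = x)$y
    v[ch] <- f[ch]
    if (all(v <= f + 1e-9 * scale)) return(v)
  }
  stop("internal error: no convex minorant chain found")
}
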