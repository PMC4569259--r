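# Brute-force lower-convex-envelope oracle by the exhaustive chord test:
# the envelope at i is the maximum over all chords through two data points
# that lie at or below f at every index (the supremum of affine minorants).
# O(k^3); for small sequences only.
chord_envelope <- function(f) {
  k <- length(f)
  if (k <= 2) return(f)
  x <- seq_len(k)
  h <- rep(-Inf, k)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    slope <- (f[b] - f[a]) / (b - a)
    line <- f[a] + slope * (x - a)
    if (all(line <= f + 1e-12)) h <- pmax(h, line)
  }
  h
}

# random test sequences including ties and plateaus
random_sequence <- function(len) {
  f <- stats::rnorm(len)
  if (len >= 4 && stats::runif(1) < 0.4) {
    # inject a plateau / tied values
    i <- sample(len - 2, 1)
    f[i:(i + 2)] <- f[i]
  }
  if (stats::runif(1) < 0.3) f <- round(f, 1)  # coarse grid: many exact ties
  f
}

# a small noiseless synthetic voxel spec with an induced calibration shift
shifted_spec <- function(seed, shift) {
  spectrum_spec(seed = seed, ppm_shift = shift, noise_sd = 0)
}

ppm_bin_width <- function(spec = spectrum_spec()) {
  1 / (spec$n_points * spec$dwell_time * spec$transmitter_freq)
}
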