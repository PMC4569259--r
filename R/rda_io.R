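# Siemens-style ".rda" CSI raw format (dialect):
#   ">>> Begin of header <<<"            one line
#   "Key: value" pairs                   ASCII, one per line
#   ">>> End of header <<<"              one line
#   binary payload                       little-endian 8-byte floats,
#                                        interleaved (real, imag), voxel-major
# Required keys: CSIMatrixSize, VectorSize, DwellTime, MRFrequency.
# Key synonyms are mapped through a configurable alias table because field
# names vary across software versions.

.rda_begin <- ">>> Begin of header <<<"
.rda_end   <- ">>> End of header <<<"

.rda_default_aliases <- list(
  CSIMatrixSize = c("CSIMatrixSize", "MatrixSize", "CSIMatrix"),
  VectorSize    = c("VectorSize", "VectorLength", "NumberOfPoints"),
  DwellTime     = c("DwellTime", "DwellTimeSec", "SamplingInterval"),
  MRFrequency   = c("MRFrequency", "TransmitterFrequency", "Frequency"),
  PatientID     = c("PatientID", "PatientName"),
  ReferencePPM  = c("ReferencePPM", "PPMReference")
)

#' Construct a CSI dataset
#'
#' A grid of per-voxel FIDs plus the shared acquisition header, mirroring a
#' Siemens-style CSI raw export.
#'
#' @param fids List of [fid_signal()] objects in voxel-major order: row
#'   fastest, then column, then slice.
#' @param csi_dims Integer triple (rows, cols, slices), all >= 1.
#' @param patient_id Opaque identifier string.
#' @return An object of class \code{"csi_dataset"} with elements
#'   \code{header} (list: patient_id, csi_dims, vector_length, dwell_time,
#'   transmitter_freq, reference_ppm) and \code{fids}.
#' @export
csi_dataset <- function(fids, csi_dims, patient_id = "anonymous") {
  csi_dims <- as.integer(csi_dims)
  if (length(csi_dims) != 3L || any(csi_dims < 1L))
    stop("'csi_dims' must be three integers >= 1")
  if (length(fids) != prod(csi_dims))
    stop(sprintf("grid shape mismatch: %d FIDs but csi_dims imply %d voxels",
                 length(fids), prod(csi_dims)))
  if (!all(vapply(fids, inherits, logical(1), "fid_signal")))
    stop("'fids' must all be fid_signal objects")
  vl <- unique(vapply(fids, function(f) length(f$samples), integer(1)))
  if (length(vl) != 1L)
    stop("all FIDs must have the same number of samples")
  f1 <- fids[[1L]]
  structure(
    list(header = list(patient_id = as.character(patient_id),
                       csi_dims = csi_dims,
                       vector_length = vl,
                       dwell_time = f1$dwell_time,
                       transmitter_freq = f1$transmitter_freq,
                       reference_ppm = f1$reference_ppm),
         fids = fids),
    class = "csi_dataset")
}

#' @export
print.csi_dataset <- function(x, ...) {
  h <- x$header
  cat(sprintf("CSI dataset '%s': %dx%dx%d voxels, %d points each\n",
              h$patient_id, h$csi_dims[1], h$csi_dims[2], h$csi_dims[3],
              h$vector_length))
  invisible(x)
}

#' Extract one voxel's FID from a CSI dataset
#'
#' @param dataset A [csi_dataset()].
#' @param row,col,slice 1-based voxel coordinates.
#' @return A [fid_signal()].
#' @export
csi_fid <- function(dataset, row, col, slice = 1L) {
  stopifnot(inherits(dataset, "csi_dataset"))
  d <- dataset$header$csi_dims
  if (row < 1 || row > d[1] || col < 1 || col > d[2] ||
      slice < 1 || slice > d[3])
    stop("voxel index out of range")
  dataset$fids[[(slice - 1L) * d[1] * d[2] + (col - 1L) * d[1] + row]]
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a CSI dataset in the .rda dialect
#'
#' Emits the ASCII header between the begin/end sentinels followed by the
#' binary payload (little-endian doubles, interleaved real/imaginary).  The
#' output is byte-stable for identical input.
#'
#' @param dataset A valid [csi_dataset()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_rda()]
#' @export
write_rda <- function(dataset, path) {
  stopifnot(inherits(dataset, "csi_dataset"))
  h <- dataset$header
  if (length(dataset$fids) != prod(h$csi_dims))
    stop("grid shape mismatch: dataset invalid")
  header <- c(
    .rda_begin,
    paste0("PatientID: ", h$patient_id),
    paste0("CSIMatrixSize: ", paste(h$csi_dims, collapse = " ")),
    paste0("VectorSize: ", h$vector_length),
    paste0("DwellTime: ", .fmt_num(h$dwell_time)),
    paste0("MRFrequency: ", .fmt_num(h$transmitter_freq)),
    paste0("ReferencePPM: ", .fmt_num(h$reference_ppm)),
    .rda_end)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  for (fid in dataset$fids) {
    inter <- as.numeric(rbind(Re(fid$samples), Im(fid$samples)))
    writeBin(inter, con, size = 8L, endian = "little")
  }
  invisible(path)
}

.parse_header_num <- function(fields, key, aliases) {
  for (alias in aliases[[key]]) {
    if (alias %in% names(fields)) {
      val <- suppressWarnings(as.numeric(strsplit(trimws(fields[[alias]]),
                                                  "\\s+")[[1]]))
      if (anyNA(val))
        stop(sprintf("unparseable numeric value for header field '%s'", alias))
      return(val)
    }
  }
  stop(sprintf("required header field '%s' (or a synonym) not found", key))
}

#' Read a CSI dataset in the .rda dialect
#'
#' Parses the ASCII key-value header between the begin/end sentinels, then
#' reads the binary payload as \code{2 * vector_length * prod(csi_dims)}
#' little-endian doubles interpreted as interleaved (real, imaginary) pairs.
#'
#' @param path Path to the file.
#' @param aliases Alias table mapping canonical header keys to accepted field
#'   names; see the package default.
#' @return A [csi_dataset()].
#' @export
read_rda <- function(path, aliases = .rda_default_aliases) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- as.raw(10L)
  # locate the end sentinel in the byte stream (payload may contain NULs, so
  # search the raw bytes, not a decoded string)
  end_at <- grepRaw(.rda_end, raw, fixed = TRUE)
  if (length(end_at) == 0L)
    stop(sprintf("header-parse error: end sentinel '%s' not found", .rda_end))
  end_at <- end_at[1L]
  payload_start <- end_at + nchar(.rda_end)  # byte after sentinel
  # skip the newline terminating the sentinel line
  if (payload_start <= length(raw) && raw[payload_start] == nl)
    payload_start <- payload_start + 1L
  header_txt <- rawToChar(raw[seq_len(end_at - 1L)])
  lines <- strsplit(header_txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || trimws(lines[1]) != .rda_begin)
    stop(sprintf("header-parse error: begin sentinel '%s' not found",
                 .rda_begin))
  kv <- lines[-1L]
  m <- regexpr(":", kv, fixed = TRUE)
  if (any(m < 0)) stop("header-parse error: malformed 'Key: value' line")
  fields <- as.list(trimws(substring(kv, m + 1L)))
  names(fields) <- trimws(substring(kv, 1L, m - 1L))

  dims <- .parse_header_num(fields, "CSIMatrixSize", aliases)
  if (length(dims) == 1L) dims <- c(dims, 1, 1)
  if (length(dims) == 2L) dims <- c(dims, 1)
  vector_length <- .parse_header_num(fields, "VectorSize", aliases)
  dwell <- .parse_header_num(fields, "DwellTime", aliases)
  freq <- .parse_header_num(fields, "MRFrequency", aliases)
  ref <- tryCatch(.parse_header_num(fields, "ReferencePPM", aliases),
                  error = function(e) 4.7)
  pid <- "anonymous"
  for (alias in aliases$PatientID)
    if (alias %in% names(fields)) { pid <- fields[[alias]]; break }

  n_voxels <- prod(dims)
  n_expected <- 2 * vector_length * n_voxels
  payload <- if (payload_start > length(raw)) raw(0) else
    raw[payload_start:length(raw)]
  if (length(payload) < 8L * n_expected)
    stop(sprintf(
      "truncation error: payload holds %d values but header declares %d",
      length(payload) %/% 8L, n_expected))
  values <- readBin(payload, "double", n = n_expected, size = 8L,
                    endian = "little")
  fids <- vector("list", n_voxels)
  per_voxel <- 2L * vector_length
  for (v in seq_len(n_voxels)) {
    block <- values[((v - 1L) * per_voxel + 1L):(v * per_voxel)]
    re <- block[seq(1L, per_voxel, by = 2L)]
    im <- block[seq(2L, per_voxel, by = 2L)]
    fids[[v]] <- fid_signal(complex(real = re, imaginary = im),
                            dwell_time = dwell, transmitter_freq = freq,
                            reference_ppm = ref)
  }
  csi_dataset(fids, csi_dims = dims, patient_id = pid)
}
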