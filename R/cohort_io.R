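.grade_levels <- c("I", "II", "III", "IV")
.area_levels <- c("tumoral", "peritumoral", "contralateral")
.ratio_cols <- c("cho_naa", "cho_cr", "ll_cr")

#' Map WHO glioma grades to grade groups
#'
#' WHO grades I-II are low-grade gliomas (LGG), III-IV high-grade (HGG).
#'
#' @param who_grade Character vector of grades ("I", "II", "III", "IV").
#' @return Character vector "LGG"/"HGG".
#' @export
grade_group <- function(who_grade) {
  who_grade <- toupper(trimws(as.character(who_grade)))
  bad <- which(!who_grade %in% .grade_levels)
  if (length(bad))
    stop(sprintf("unknown WHO grade '%s' (row %d)", who_grade[bad[1]], bad[1]))
  ifelse(who_grade %in% c("I", "II"), "LGG", "HGG")
}

#' Validate and normalize a table of case records
#'
#' A case record is one case/area observation: WHO grade, grade group, area
#' label, and the three metabolite ratios (Cho/NAA, Cho/Cr, Lip-Lac/Cr).
#' Missing Lip-Lac/Cr values stay \code{NA}; they are never coerced to 0.
#'
#' @param df data.frame with columns \code{case_id}, \code{who_grade},
#'   \code{area}, \code{cho_naa}, \code{cho_cr}, \code{ll_cr} and optionally
#'   \code{grade_group} and \code{source}.
#' @param source Ratio provenance label recorded in the \code{source} column
#'   when the table has none ("AQoCE" or "Siemens").
#' @return data.frame of validated case records (class \code{case_records}).
#' @export
case_records <- function(df, source = "AQoCE") {
  need <- c("case_id", "who_grade", "area", .ratio_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df$who_grade <- toupper(trimws(as.character(df$who_grade)))
  df$area <- tolower(trimws(as.character(df$area)))
  bad <- which(!df$area %in% .area_levels)
  if (length(bad))
    stop(sprintf("unknown area label '%s' (row %d)", df$area[bad[1]], bad[1]))
  gg <- grade_group(df$who_grade)
  if (!is.null(df$grade_group)) {
    if (any(df$grade_group != gg))
      stop("grade_group column inconsistent with who_grade")
  }
  df$grade_group <- gg
  for (col in .ratio_cols) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    neg <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(neg))
      stop(sprintf("negative ratio %s (row %d)", col, neg[1]))
  }
  if (is.null(df$source)) df$source <- source
  out <- df[c("case_id", "who_grade", "grade_group", "area",
              .ratio_cols, "source")]
  class(out) <- c("case_records", "data.frame")
  out
}

#' Read a cohort ratio table
#'
#' Reads a per-case/per-area table of metabolite ratios (CSV, or XLSX when the
#' readxl package is available) and returns validated case records.  Empty
#' ratio cells become \code{NA}.
#'
#' @param path CSV or XLSX file with columns \code{case_id},
#'   \code{who_grade}, \code{area}, \code{cho_naa}, \code{cho_cr},
#'   \code{ll_cr}.
#' @param source Provenance label ("AQoCE" or "Siemens") used when the file
#'   has no \code{source} column.
#' @return A \code{case_records} data.frame.
#' @export
read_cohort_table <- function(path, source = "AQoCE") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package; use CSV instead")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  case_records(df, source = source)
}

#' Write a cohort ratio table as CSV
#'
#' @param records A \code{case_records} data.frame (or coercible).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Pathology records of the 78-case glioma cohort
#'
#' The published pathology table of the 78 preoperative glioma cases studied
#' with this pipeline: patient number, sex, age, lesion location, histological
#' type and WHO grade.  Grades I-II map to LGG (36 cases) and III-IV to HGG
#' (42 cases).
#'
#' @return data.frame with columns \code{case_id}, \code{sex}, \code{age},
#'   \code{location}, \code{histology}, \code{who_grade}, \code{grade_group}.
#' @export
glioma_pathology <- function() {
  path <- system.file("extdata", "glioma_pathology.csv", package = "aqoce",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$grade_group <- grade_group(df$who_grade)
  df
}
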