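#' Tidy time-course data of parent and intermediate concentrations
#'
#' Validates and canonicalises a table of replicate concentration
#' observations. Columns: \code{time} (days), \code{compound} (one of
#' \code{"parent"}, \code{"intermediate"}), \code{replicate} (id),
#' \code{conc} (mg/L; may be \code{NA} when censored), \code{below_lod}
#' (logical censoring flag) and optionally \code{lod} (the limit of
#' detection, mg/L). Records are sorted by (compound, time, replicate) so
#' every downstream computation is invariant to the input row order.
#'
#' @param df A data.frame with the columns above (\code{below_lod} and
#'   \code{lod} optional; default not censored).
#' @return A \code{time_course_data} object (a sorted data.frame).
#' @export
time_course_data <- function(df) {
  need <- c("time", "compound", "replicate", "conc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("time_course_data: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"below_lod" %in% names(df)) df$below_lod <- FALSE
  if (!"lod" %in% names(df)) df$lod <- NA_real_
  df$below_lod <- as.logical(df$below_lod)
  df$compound <- as.character(df$compound)
  bad_cmp <- !df$compound %in% c("parent", "intermediate")
  if (any(bad_cmp)) {
    stop("time_course_data: compound must be 'parent' or 'intermediate'; got ",
         paste(unique(df$compound[bad_cmp]), collapse = ", "))
  }
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("time_course_data: times must be finite and >= 0 (days)")
  }
  obs <- !df$below_lod
  if (any(obs & (is.na(df$conc) | df$conc < 0))) {
    stop("time_course_data: concentrations must be >= 0 unless flagged below_lod")
  }
  key <- paste(df$time, df$compound, df$replicate)
  if (anyDuplicated(key)) {
    stop("time_course_data: duplicate (time, compound, replicate) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df <- df[order(df$compound, df$time, df$replicate),
           c("time", "compound", "replicate", "conc", "below_lod", "lod")]
  rownames(df) <- NULL
  class(df) <- c("time_course_data", "data.frame")
  df
}

# Rows usable in a fitting objective under the given LOD policy.
# exclude: drop censored rows; half_lod: substitute lod/2 for censored rows.
.usable_rows <- function(data, lod_policy = c("exclude", "half_lod")) {
  lod_policy <- match.arg(lod_policy)
  df <- as.data.frame(data)
  if (lod_policy == "exclude") {
    df <- df[!df$below_lod, , drop = FALSE]
  } else {
    cen <- df$below_lod
    if (any(cen & is.na(df$lod))) {
      stop("half_lod policy needs a lod value on every censored row")
    }
    df$conc[cen] <- df$lod[cen] / 2
  }
  df
}

#' Read a tidy time-course CSV
#'
#' Parses the fixed dialect: UTF-8, comma-separated, header
#' \code{time_d,compound,replicate,conc_mg_per_L,below_lod} (optionally a
#' sixth column \code{lod_mg_per_L}), "." decimal separator, \code{below_lod}
#' in \{0, 1\}. A censored row may leave \code{conc_mg_per_L} empty.
#'
#' @param path Path to the CSV file.
#' @return A \code{\link{time_course_data}} object.
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("read_timecourse_csv: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("time_d", "compound", "replicate", "conc_mg_per_L", "below_lod")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("read_timecourse_csv: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- function(x, col) {
    x[x == ""] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0) {
      stop("read_timecourse_csv: non-numeric ", col, " on data line(s) ",
           paste(bad, collapse = ", "))
    }
    v
  }
  flag <- raw$below_lod
  if (!all(flag %in% c("0", "1"))) {
    stop("read_timecourse_csv: below_lod must be 0 or 1 on data line(s) ",
         paste(which(!flag %in% c("0", "1")), collapse = ", "))
  }
  df <- data.frame(
    time = num(raw$time_d, "time_d"),
    compound = raw$compound,
    replicate = raw$replicate,
    conc = num(raw$conc_mg_per_L, "conc_mg_per_L"),
    below_lod = flag == "1",
    lod = if ("lod_mg_per_L" %in% names(raw)) num(raw$lod_mg_per_L, "lod_mg_per_L")
          else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$conc) & !df$below_lod)) {
    stop("read_timecourse_csv: empty conc_mg_per_L on uncensored data line(s) ",
         paste(which(is.na(df$conc) & !df$below_lod), collapse = ", "))
  }
  time_course_data(df)
}

#' Write a tidy time-course CSV
#'
#' Inverse of \code{\link{read_timecourse_csv}}; canonical files round-trip
#' byte-for-byte.
#'
#' @param data A \code{\link{time_course_data}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse_csv <- function(data, path) {
  df <- as.data.frame(time_course_data(as.data.frame(data)))
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, digits = 15,
                                                 scientific = FALSE))
  has_lod <- any(!is.na(df$lod))
  header <- c("time_d", "compound", "replicate", "conc_mg_per_L", "below_lod",
              if (has_lod) "lod_mg_per_L")
  lines <- paste(
    fmt(df$time), df$compound, df$replicate, fmt(df$conc),
    ifelse(df$below_lod, "1", "0"),
    sep = ","
  )
  if (has_lod) lines <- paste(lines, fmt(df$lod), sep = ",")
  writeLines(c(paste(header, collapse = ","), lines), path, useBytes = TRUE)
  invisible(path)
}
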