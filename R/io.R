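#' Read a rumen measurement file
#'
#' Reads a delimited text file of post-prandial rumen samples into a
#' validated measurement table. Each row is one sample: an animal, a
#' sampling-day label (1..9), the hours since the morning feed delivery
#' (0, 1, 2, 4 or 6) and the acid status as pH and/or hydrogen-ion
#' concentration. Whichever of pH / \eqn{[H^+]} is missing is filled in from
#' the other; if both are present they must agree (\eqn{[H^+] = 10^{-pH}})
#' within `tol` relative, otherwise the row is rejected — data integrity is
#' preferred over silently trusting one column.
#'
#' @param path Path to a delimited file with a header row.
#' @param dialect Named character vector mapping the canonical column names
#'   `animal_id`, `day_label`, `time_h`, `ph`, `h_conc`, `day_offset` to the
#'   names used in the file, so external deposits can be ingested without
#'   editing. Only names that differ need to be supplied.
#' @param sep Field separator, default `","`.
#' @param tol Relative tolerance for pH / \eqn{[H^+]} agreement, default 1e-6.
#' @return A data frame of validated measurement records with columns
#'   `animal_id`, `day_label`, `time_h`, `ph`, `h_conc` (and `day_offset` if
#'   present in the file).
#' @export
read_measurements <- function(path, dialect = NULL, sep = ",", tol = 1e-6) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("animal_id", "day_label", "time_h", "ph", "h_conc",
                 "day_offset")
  names_map <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canonical)
    if (length(bad)) {
      stop("unknown dialect keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    names_map[names(dialect)] <- dialect
  }
  present <- names_map[names_map %in% names(raw)]
  out <- raw[unname(present)]
  names(out) <- names(present)
  validate_measurements(out, tol = tol)
}

#' Validate a measurement table
#'
#' Applies the record invariants: required columns present, numeric fields
#' parseable, `time_h` in \{0, 1, 2, 4, 6\}, `day_label` in 1..9,
#' \eqn{[H^+] > 0}, no duplicated (animal, day, hour) triplet, and pH /
#' \eqn{[H^+]} consistency. Missing `ph` or `h_conc` is filled from the
#' other column.
#'
#' @param records Data frame with at least `animal_id`, `day_label`,
#'   `time_h`, and one of `ph`, `h_conc`.
#' @param tol Relative tolerance for pH / \eqn{[H^+]} agreement.
#' @return The validated, completed data frame.
#' @export
validate_measurements <- function(records, tol = 1e-6) {
  required <- c("animal_id", "day_label", "time_h")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!("ph" %in% names(records)) && !("h_conc" %in% names(records))) {
    stop("need at least one of columns `ph`, `h_conc`", call. = FALSE)
  }
  n <- nrow(records)
  num_or_die <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !is.na(x))
    if (length(bad)) {
      stop("unparseable numeric in `", what, "` at rows: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    y
  }
  records$day_label <- num_or_die(records$day_label, "day_label")
  records$time_h <- num_or_die(records$time_h, "time_h")
  if ("ph" %in% names(records)) records$ph <- num_or_die(records$ph, "ph")
  if ("h_conc" %in% names(records)) {
    records$h_conc <- num_or_die(records$h_conc, "h_conc")
  }
  if ("day_offset" %in% names(records)) {
    records$day_offset <- num_or_die(records$day_offset, "day_offset")
  }

  bad_t <- which(!(records$time_h %in% c(0, 1, 2, 4, 6)))
  if (length(bad_t)) {
    stop("time_h outside {0,1,2,4,6} at rows: ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  }
  bad_d <- which(!(records$day_label %in% 1:9))
  if (length(bad_d)) {
    stop("day_label outside 1..9 at rows: ",
         paste(utils::head(bad_d, 5), collapse = ", "), call. = FALSE)
  }

  has_ph <- "ph" %in% names(records) & if ("ph" %in% names(records))
    !is.na(records$ph) else rep(FALSE, n)
  has_h <- "h_conc" %in% names(records) & if ("h_conc" %in% names(records))
    !is.na(records$h_conc) else rep(FALSE, n)
  none <- which(!has_ph & !has_h)
  if (length(none)) {
    stop("rows with neither ph nor h_conc: ",
         paste(utils::head(none, 5), collapse = ", "), call. = FALSE)
  }
  both <- which(has_ph & has_h)
  if (length(both)) {
    expect <- 10^(-records$ph[both])
    rel <- abs(records$h_conc[both] - expect) / expect
    bad <- both[rel > tol]
    if (length(bad)) {
      stop("ph and h_conc disagree beyond tolerance at rows: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!("h_conc" %in% names(records))) records$h_conc <- NA_real_
  if (!("ph" %in% names(records))) records$ph <- NA_real_
  fill_h <- is.na(records$h_conc)
  records$h_conc[fill_h] <- 10^(-records$ph[fill_h])
  fill_ph <- is.na(records$ph)
  records$ph[fill_ph] <- -log10(records$h_conc[fill_ph])
  bad_h <- which(!is.finite(records$h_conc) | records$h_conc <= 0)
  if (length(bad_h)) {
    stop("non-positive or non-finite h_conc at rows: ",
         paste(utils::head(bad_h, 5), collapse = ", "), call. = FALSE)
  }

  key <- paste(records$animal_id, records$day_label, records$time_h,
               sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(key[dup])
    stop("duplicated (animal, day, hour) triplets: ",
         paste(utils::head(offenders, 5), collapse = "; "), call. = FALSE)
  }
  records
}

#' Write a measurement table to CSV
#'
#' @param records Measurement data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
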