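#' Read a Cq table from a qPCR array export
#'
#' Reads a delimited text file with one row per assay-by-group well and
#' returns a validated `cq_matrix` data frame. Wells whose Cq field equals
#' `undetermined_token` (the instrument's flag for no amplification before
#' the cycle limit) are kept with `cq = NA` and `undetermined = TRUE`.
#'
#' @param path Path to a TSV or CSV file with columns `assay_id`, `plate`,
#'   `group`, `cq`. The delimiter is inferred from the file extension
#'   (`.csv` gives comma, anything else tab).
#' @param undetermined_token String marking non-amplified wells
#'   (default `"Undetermined"`).
#' @return A data frame of class `cq_matrix` with columns `assay_id`
#'   (character), `plate` (character, `"A"`/`"B"`), `group` (character,
#'   `"Con"`/`"N3"`), `cq` (numeric, `NA` when undetermined) and
#'   `undetermined` (logical).
#' @seealso [write_cq_table()], [detect_calls()], [classify_and_summarize()]
#' @export
read_cq_table <- function(path, undetermined_token = "Undetermined") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  needed <- c("assay_id", "plate", "group", "cq")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_fmt("Cq table format error: missing column(s) %s",
             paste(missing_cols, collapse = ", "))
  }
  undet <- raw$cq == undetermined_token
  cq <- suppressWarnings(as.numeric(raw$cq))
  bad <- which(!undet & is.na(cq))
  if (length(bad) > 0) {
    stop_fmt("Cq parse error: non-numeric cq '%s' in row %d (assay %s)",
             raw$cq[bad[1]], bad[1], raw$assay_id[bad[1]])
  }
  cq[undet] <- NA_real_
  out <- data.frame(assay_id = raw$assay_id, plate = raw$plate,
                    group = raw$group, cq = cq, undetermined = undet,
                    stringsAsFactors = FALSE)
  as_cq_matrix(out)
}

#' Validate and classify a Cq data frame
#'
#' Checks the `cq_matrix` invariants: one well per (assay, group), one plate
#' per assay, finite Cq whenever a well is not flagged undetermined.
#'
#' @param x A data frame with columns `assay_id`, `plate`, `group`, `cq`
#'   and optionally `undetermined` (defaults to `is.na(cq)`).
#' @return `x` with class `cq_matrix` prepended.
#' @export
as_cq_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("assay_id", "plate", "group", "cq")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop_fmt("cq_matrix requires column(s) %s",
             paste(missing_cols, collapse = ", "))
  }
  if (is.null(x$undetermined)) x$undetermined <- is.na(x$cq)
  check_levels(x$plate, c("A", "B"), "plate")
  check_levels(x$group, c("Con", "N3"), "group")
  key <- paste(x$assay_id, x$group, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE]
    stop_fmt("duplicate (assay_id, group) row: (%s, %s)",
             d$assay_id[1], d$group[1])
  }
  plates_per_assay <- tapply(x$plate, x$assay_id,
                             function(p) length(unique(p)))
  if (any(plates_per_assay > 1)) {
    stop_fmt("assay %s is assigned to more than one plate",
             names(plates_per_assay)[plates_per_assay > 1][1])
  }
  if (any(!x$undetermined & (!is.finite(x$cq) | x$cq <= 0))) {
    stop_fmt("non-finite or non-positive Cq in a well not flagged undetermined")
  }
  if (any(x$undetermined & !is.na(x$cq))) x$cq[x$undetermined] <- NA_real_
  class(x) <- unique(c("cq_matrix", class(x)))
  x
}

#' Write a Cq table
#'
#' Inverse of [read_cq_table()]: Cq values are written with full precision
#' (`format = "%.17g"` equivalent via `as.character`), so a write/read
#' round trip preserves values bit-exactly.
#'
#' @param x A `cq_matrix` data frame.
#' @param path Output path; `.csv` gives comma-separated, else TSV.
#' @param undetermined_token Token written for undetermined wells.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path, undetermined_token = "Undetermined") {
  x <- as_cq_matrix(x)
  cq_chr <- vapply(x$cq, function(v) {
    if (is.na(v)) undetermined_token else sprintf("%.17g", v)
  }, character(1))
  out <- data.frame(assay_id = x$assay_id, plate = x$plate,
                    group = x$group, cq = cq_chr, stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
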