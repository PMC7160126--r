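# Cohort CSV input/output.
#
# One flat CSV schema carries a cohort: header row mandatory, decimal
# point ".", missing values as empty cells, units fixed by the column
# names. Unknown columns are preserved and passed through untouched.

.REQUIRED_COLS <- c("eye_id", "axial_length_mm", "acd_mm",
                    "mean_corneal_radius_mm", "sa8_um",
                    "implanted_power_d", "postop_se_d")
.OPTIONAL_NUM_COLS <- c("sa6_um", "q6", "q8", "ecc6", "ecc8", "true_pe_d")

# hard physical plausibility bounds for biometry (open intervals)
.BIOMETRY_BOUNDS <- list(axial_length_mm = c(15, 40),
                         acd_mm = c(1.5, 6),
                         mean_corneal_radius_mm = c(6, 12))

.parse_num_col <- function(raw, col) {
  raw <- trimws(as.character(raw))
  raw[raw == ""] <- NA
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & is.na(x))
  if (length(bad))
    stop("parse error in column '", col, "', line ", bad[1L] + 1L,
         ": cannot read '", raw[bad[1L]], "' as a number", call. = FALSE)
  x
}

#' Read and write cohort CSV files
#'
#' `read_cohort()` reads a cohort CSV, validates the schema (required
#' columns `eye_id`, `axial_length_mm`, `acd_mm`,
#' `mean_corneal_radius_mm`, `sa8_um`, `implanted_power_d`,
#' `postop_se_d`; optional `sa6_um`, `q6`, `q8`, `ecc6`, `ecc8`,
#' `true_pe_d`), coerces numeric columns with line-numbered parse errors,
#' and checks biometry against physical plausibility bounds
#' (AL in (15, 40) mm, ACD in (1.5, 6) mm, radius in (6, 12) mm).
#' Unknown columns are preserved untouched. `write_cohort()` writes with
#' full double precision so a write/read round trip is lossless.
#'
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort()`: the cohort data frame. `write_cohort()`:
#'   `path`, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(.REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    stop("cohort schema error: missing column '", missing_cols[1L], "'",
         call. = FALSE)
  num_cols <- intersect(c(setdiff(.REQUIRED_COLS, "eye_id"),
                          .OPTIONAL_NUM_COLS), names(raw))
  for (col in num_cols) raw[[col]] <- .parse_num_col(raw[[col]], col)
  for (col in names(.BIOMETRY_BOUNDS)) {
    b <- .BIOMETRY_BOUNDS[[col]]
    x <- raw[[col]]
    bad <- which(!is.na(x) & (x <= b[1] | x >= b[2]))
    if (length(bad))
      stop("implausible ", col, " for ", raw$eye_id[bad[1L]], ": ",
           x[bad[1L]], " outside (", b[1], ", ", b[2], ")", call. = FALSE)
  }
  raw
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  out <- cohort
  num <- vapply(out, is.numeric, TRUE)
  # format() would quantize; as.character keeps 15 significant digits
  out[num] <- lapply(out[num], function(x) {
    s <- vapply(x, function(v) if (is.na(v)) "" else
      format(v, digits = 15, scientific = FALSE), "")
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
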