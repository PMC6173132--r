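#' Canonical column mapping for audit review files
#'
#' Maps the canonical field names used internally to the column headers of an
#' input file. `default_column_map()` is the identity map on the canonical
#' names; [deposited_column_map()] is a starting point for the archived audit
#' export whose headers differ.
#'
#' @return Named character vector: names are canonical fields, values are the
#'   file headers they are read from.
#' @export
default_column_map <- function() {
  c(scan_id = "scan_id", volunteer_id = "volunteer_id",
    sonographer_id = "sonographer_id", expert_id = "expert_id",
    qualification = "qualification", y_left = "y_left", y_right = "y_right")
}

#' Column mapping for the archived audit data export
#'
#' A best-effort header map for the publicly deposited audit file ("biprobit
#' format" CSV). The exact headers are described by the archive's own
#' `DataKey.txt`; this map is a documented assumption and should be
#' overridden (any subset of fields) once the data key has been inspected.
#'
#' @param ... Named overrides, e.g. `y_left = "lo_confirmed"`.
#' @return Named character vector as in [default_column_map()].
#' @export
deposited_column_map <- function(...) {
  map <- c(scan_id = "scanid", volunteer_id = "volid",
           sonographer_id = "sonographer", expert_id = "reviewer",
           qualification = "qualification", y_left = "lo", y_right = "ro")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(map))
    if (length(bad)) stop("unknown fields in column map: ",
                          paste(bad, collapse = ", "))
    map[names(ov)] <- ov
  }
  map
}

normalize_outcome <- function(x, col) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad)) stop("column '", col, "' has outcome values outside ",
                          "{0, 1, missing} at row(s) ",
                          paste(utils::head(bad, 5), collapse = ", "))
    return(as.integer(x))
  }
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na", ".")] <- NA
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "yes", "y", "true", "confirmed", "seen")] <- 1L
  out[x %in% c("0", "no", "n", "false", "not confirmed", "not seen")] <- 0L
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) stop("column '", col, "' has outcome values outside ",
                        "{0, 1, missing} at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Construct a validated audit dataset from a data frame
#'
#' Validates and normalises one-row-per-review audit data: binary/missing
#' outcomes, a single sonographer per scan, experts nested in qualification.
#' Rows where both outcomes are missing carry no information and are dropped
#' (with a message and a recorded count).
#'
#' @param df Data frame with (possibly mapped) canonical columns.
#' @param column_map Mapping from canonical names to `df` headers; see
#'   [default_column_map()].
#' @return An object of class `audit_data`: list with `records` (data frame
#'   with columns scan_id, volunteer_id, sonographer_id, expert_id,
#'   qualification, y_left, y_right), `n_scans`, `n_records`,
#'   `n_assessments`, `n_dropped` and `column_map`.
#' @export
as_audit_data <- function(df, column_map = default_column_map()) {
  req <- default_column_map()
  map <- req
  map[names(column_map)] <- column_map
  missing_cols <- map[!(map %in% names(df))]
  # volunteer_id and qualification are reconstructible; the rest are required
  hard <- setdiff(names(missing_cols), c("volunteer_id", "qualification"))
  if (length(hard))
    stop("column(s) not found in input: ",
         paste(sprintf("%s (mapped from '%s')", map[hard], hard),
               collapse = ", "))

  rec <- data.frame(
    scan_id = as.character(df[[map["scan_id"]]]),
    volunteer_id = if ("volunteer_id" %in% names(missing_cols))
      as.character(df[[map["scan_id"]]]) else
      as.character(df[[map["volunteer_id"]]]),
    sonographer_id = as.character(df[[map["sonographer_id"]]]),
    expert_id = as.character(df[[map["expert_id"]]]),
    qualification = if ("qualification" %in% names(missing_cols))
      NA_character_ else as.character(df[[map["qualification"]]]),
    stringsAsFactors = FALSE
  )
  rec$y_left <- normalize_outcome(df[[map["y_left"]]], map["y_left"])
  rec$y_right <- normalize_outcome(df[[map["y_right"]]], map["y_right"])

  drop <- is.na(rec$y_left) & is.na(rec$y_right)
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with both outcomes missing dropped")
    rec <- rec[!drop, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no usable review records")
  rownames(rec) <- NULL

  # one sonographer per scan
  tab <- unique(rec[, c("scan_id", "sonographer_id")])
  dup <- tab$scan_id[duplicated(tab$scan_id)]
  if (length(dup))
    stop("scan(s) with conflicting sonographer labels: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))

  # experts nested in qualification
  if (!all(is.na(rec$qualification))) {
    qt <- unique(rec[!is.na(rec$qualification),
                     c("expert_id", "qualification")])
    dq <- qt$expert_id[duplicated(qt$expert_id)]
    if (length(dq))
      stop("expert(s) with more than one qualification: ",
           paste(unique(dq), collapse = ", "))
  }

  structure(list(
    records = rec,
    n_scans = length(unique(rec$scan_id)),
    n_records = nrow(rec),
    n_assessments = sum(!is.na(rec$y_left)) + sum(!is.na(rec$y_right)),
    n_dropped = n_dropped,
    column_map = map
  ), class = "audit_data")
}

#' Read long-format audit review data from CSV
#'
#' One row per scan-by-expert review; outcome columns must be codable as
#' 0/1/missing (numeric, logical, or yes/no-style strings). Rows with both
#' outcomes missing are dropped with a recorded count.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Header mapping, see [default_column_map()].
#' @return An [as_audit_data()] object.
#' @export
read_audit_csv <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_audit_data(df, column_map)
}

#' Read audit review data from a Stata file
#'
#' Convenience wrapper around `haven::read_dta()`; the CSV route
#' ([read_audit_csv()]) is canonical.
#'
#' @inheritParams read_audit_csv
#' @export
read_audit_dta <- function(path, column_map = default_column_map()) {
  if (!requireNamespace("haven", quietly = TRUE))
    stop("reading .dta files requires the 'haven' package")
  df <- as.data.frame(haven::read_dta(path))
  df[] <- lapply(df, function(x) if (inherits(x, "haven_labelled"))
    as.vector(x) else x)
  as_audit_data(df, column_map)
}

#' Write an audit dataset to canonical CSV
#'
#' @param data An `audit_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(data, path) {
  stopifnot(inherits(data, "audit_data"))
  write.csv(data$records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.audit_data <- function(x, ...) {
  cat("Audit review dataset\n")
  cat("  scans:        ", x$n_scans, "\n")
  cat("  review rows:  ", x$n_records, "\n")
  cat("  assessments:  ", x$n_assessments,
      sprintf(" (LO %d, RO %d)\n", sum(!is.na(x$records$y_left)),
              sum(!is.na(x$records$y_right))))
  cat("  sonographers: ", length(unique(x$records$sonographer_id)), "\n")
  cat("  experts:      ", length(unique(x$records$expert_id)), "\n")
  if (x$n_dropped > 0)
    cat("  dropped rows (both outcomes missing):", x$n_dropped, "\n")
  invisible(x)
}

prop_row <- function(stratum_type, stratum, outcome, num, den) {
  data.frame(stratum_type = stratum_type, stratum = stratum,
             outcome = outcome, numerator = num, denominator = den,
             proportion = if (den > 0) num / den else NA_real_,
             stringsAsFactors = FALSE)
}

raw_props_one <- function(rec, stratum_type, stratum) {
  l <- rec$y_left[!is.na(rec$y_left)]
  r <- rec$y_right[!is.na(rec$y_right)]
  both <- rec[!is.na(rec$y_left) & !is.na(rec$y_right), ]
  rbind(
    prop_row(stratum_type, stratum, "LO", sum(l), length(l)),
    prop_row(stratum_type, stratum, "RO", sum(r), length(r)),
    prop_row(stratum_type, stratum, "joint",
             sum(both$y_left == 1 & both$y_right == 1), nrow(both))
  )
}

#' Raw (model-free) confirmation proportions
#'
#' Confirmed visualisation proportions for the left ovary, right ovary and
#' jointly for both, overall and by sonographer and by expert. The joint
#' denominator counts only reviews with both outcomes observed. Empty strata
#' yield `NA`, never 0.
#'
#' @param data An `audit_data` object.
#' @return Data frame with stratum_type, stratum, outcome, numerator,
#'   denominator and proportion.
#' @export
raw_proportions <- function(data) {
  stopifnot(inherits(data, "audit_data"))
  rec <- data$records
  rec$sonographer_id <- as.character(rec$sonographer_id)
  rec$expert_id <- as.character(rec$expert_id)
  out <- raw_props_one(rec, "overall", "overall")
  for (s in sort(unique(rec$sonographer_id)))
    out <- rbind(out, raw_props_one(rec[rec$sonographer_id == s, ],
                                    "sonographer", s))
  for (e in expert_sort(rec$expert_id))
    out <- rbind(out, raw_props_one(rec[rec$expert_id == e, ], "expert", e))
  rownames(out) <- NULL
  out
}

#' Cross-tabulation of review counts by sonographer and expert
#'
#' Counts review rows per (sonographer, expert) cell and flags departures
#' from a balanced design (all non-empty cells equal).
#'
#' @param data An `audit_data` object.
#' @return A contingency table with attribute `balanced` (logical).
#' @export
design_summary <- function(data) {
  stopifnot(inherits(data, "audit_data"))
  rec <- data$records
  tab <- table(sonographer = rec$sonographer_id, expert = rec$expert_id)
  nz <- tab[tab > 0]
  attr(tab, "balanced") <- length(nz) > 0 && length(unique(as.vector(nz))) == 1
  tab
}

#' Ovarian volume by the prolate ellipsoid formula
#'
#' Volume from three orthogonal diameters: `d1 * d2 * d3 * 0.5423`.
#'
#' @param d1,d2,d3 Diameters in millimetres (positive).
#' @return Volume in cubic millimetres.
#' @examples
#' ovarian_volume(10, 10, 10) # 542.3
#' @export
ovarian_volume <- function(d1, d2, d3) {
  if (any(c(d1, d2, d3) <= 0, na.rm = TRUE))
    stop("all diameters must be positive")
  d1 * d2 * d3 * 0.5423
}
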