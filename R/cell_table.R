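#' Read a long-format cell-level intensity table
#'
#' Reads a CSV with one row per segmented cell and validates it into a
#' `cell_table`: a data frame carrying a subject identifier, an optional
#' cell-type label, and one or more continuous marker-intensity columns.
#' Rows with a missing value in any marker column are dropped (with a
#' message giving the count), matching the convention that unquantified
#' cells are excluded rather than imputed.
#'
#' @param path path to a comma-separated file with a header row.
#' @param subject_col name of the subject-identifier column.
#' @param markers character vector of marker column names. If `NULL`, every
#'   column other than `subject_col`, `cell_id_col` and `cell_type_col` is
#'   taken to be a marker.
#' @param cell_id_col,cell_type_col optional column names; `NULL` if absent.
#' @return A `cell_table` (data frame) with attribute `"markers"`.
#'   Subject ids are always character.
#' @export
read_cell_table <- function(path, subject_col = "subject_id", markers = NULL,
                            cell_id_col = NULL, cell_type_col = NULL) {
  if (!file.exists(path))
    md_stop(sprintf("file not found: %s", path), "markerdens_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  as_cell_table(df, subject_col = subject_col, markers = markers,
                cell_id_col = cell_id_col, cell_type_col = cell_type_col)
}

#' Validate a data frame as a cell table
#'
#' @param df a data frame of per-cell rows.
#' @inheritParams read_cell_table
#' @return A validated `cell_table`.
#' @export
as_cell_table <- function(df, subject_col = "subject_id", markers = NULL,
                          cell_id_col = NULL, cell_type_col = NULL) {
  for (col in c(subject_col, cell_id_col, cell_type_col)) {
    if (!col %in% names(df))
      md_stop(sprintf("required column '%s' not present (found: %s)",
                      col, paste(names(df), collapse = ", ")),
              "markerdens_schema_error")
  }
  meta <- c(subject_col, cell_id_col, cell_type_col)
  if (is.null(markers)) markers <- setdiff(names(df), meta)
  missing_m <- setdiff(markers, names(df))
  if (length(missing_m))
    md_stop(sprintf("marker column(s) not present: %s",
                    paste(missing_m, collapse = ", ")),
            "markerdens_schema_error")
  if (!length(markers))
    md_stop("no marker columns present", "markerdens_schema_error")
  for (m in markers) {
    if (!is.numeric(df[[m]]))
      md_stop(sprintf("marker column '%s' is not numeric", m),
              "markerdens_schema_error")
    if (any(is.infinite(df[[m]])))
      md_stop(sprintf("marker column '%s' contains non-finite values", m),
              "markerdens_schema_error")
  }

  out <- df[, c(meta, markers), drop = FALSE]
  names(out)[1] <- "subject_id"
  if (!is.null(cell_id_col)) names(out)[names(out) == cell_id_col] <- "cell_id"
  if (!is.null(cell_type_col)) names(out)[names(out) == cell_type_col] <- "cell_type"
  out$subject_id <- as.character(out$subject_id)
  if (any(is.na(out$subject_id)))
    md_stop("missing subject identifiers", "markerdens_schema_error")

  keep <- stats::complete.cases(out[, markers, drop = FALSE])
  if (any(!keep)) {
    message(sprintf("dropping %d row(s) with missing marker values", sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  if (!nrow(out))
    md_stop("no usable rows after dropping missing marker values",
            "markerdens_empty_input_error")
  rownames(out) <- NULL
  structure(out, markers = markers,
            class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d subject(s), marker(s): %s\n",
              nrow(x), length(unique(x$subject_id)),
              paste(attr(x, "markers"), collapse = ", ")))
  NextMethod()
}

#' Restrict a cell table to a cell-type compartment
#'
#' Keeps only cells whose `cell_type` matches one of the requested labels
#' (e.g. analysis of a functional marker within CK+ tumor cells). Subjects
#' left with zero cells are removed with a warning, since no density can be
#' estimated for them.
#'
#' @param table a `cell_table` with a `cell_type` column.
#' @param cell_type character vector of labels to keep.
#' @return The filtered `cell_table`.
#' @export
filter_cells <- function(table, cell_type) {
  stopifnot(inherits(table, "cell_table"))
  if (!"cell_type" %in% names(table))
    md_stop("table has no 'cell_type' column to filter on",
            "markerdens_schema_error")
  avail <- unique(table$cell_type)
  unknown <- setdiff(cell_type, avail)
  if (length(unknown))
    md_stop(sprintf("unknown cell type(s): %s (available: %s)",
                    paste(unknown, collapse = ", "),
                    paste(avail, collapse = ", ")),
            "markerdens_lookup_error")
  before <- unique(table$subject_id)
  out <- table[table$cell_type %in% cell_type, , drop = FALSE]
  if (!nrow(out))
    md_stop("no cells remain after cell-type filtering",
            "markerdens_empty_input_error")
  lost <- setdiff(before, unique(out$subject_id))
  if (length(lost))
    warning(sprintf("%d subject(s) dropped (no matching cells): %s",
                    length(lost), paste(lost, collapse = ", ")))
  rownames(out) <- NULL
  structure(out, markers = attr(table, "markers"),
            class = class(table))
}

#' Min-max scale a marker over the pooled cohort and split by subject
#'
#' Scales the raw intensities of one marker to \[0, 1\] with the pooled
#' cohort-wide minimum and maximum, `x' = (x - min) / (max - min)`, and
#' returns the scaled values partitioned by subject. Pooled (rather than
#' per-subject) scaling preserves the between-subject density differences
#' that the distance analysis measures.
#'
#' @param table a `cell_table`.
#' @param marker marker column name.
#' @param min_cells subjects with fewer cells than this trigger a warning
#'   (kernel density estimates from very few cells are unreliable).
#' @return A named list of numeric vectors in \[0, 1\], one per subject, of
#'   class `subject_samples`, with attributes `marker` and `range` (the raw
#'   min/max used).
#' @export
scale_marker <- function(table, marker, min_cells = 10L) {
  stopifnot(inherits(table, "cell_table"))
  if (!marker %in% attr(table, "markers"))
    md_stop(sprintf("unknown marker '%s' (available: %s)", marker,
                    paste(attr(table, "markers"), collapse = ", ")),
            "markerdens_lookup_error")
  x <- table[[marker]]
  rng <- range(x)
  if (diff(rng) == 0)
    md_stop(sprintf("marker '%s' is constant cohort-wide; cannot scale", marker),
            "markerdens_degenerate_scale_error")
  scaled <- (x - rng[1]) / (rng[2] - rng[1])
  out <- split(scaled, table$subject_id)
  few <- names(out)[lengths(out) < min_cells]
  if (length(few))
    warning(sprintf("subject(s) with fewer than %d cells: %s",
                    min_cells, paste(few, collapse = ", ")))
  structure(out, marker = marker, range = rng,
            class = "subject_samples")
}

#' @export
print.subject_samples <- function(x, ...) {
  cat(sprintf("<subject_samples> marker '%s', %d subject(s), cells/subject: %s\n",
              attr(x, "marker") %||% "?", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Write a cell table back to CSV
#'
#' @param table a `cell_table`.
#' @param path output path.
#' @export
write_cell_table <- function(table, path) {
  df <- as.data.frame(table)
  # full 17-significant-digit formatting so numeric round trips are
  # bit-exact
  for (m in attr(table, "markers"))
    df[[m]] <- formatC(df[[m]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a subject-level outcome table
#'
#' Expects one row per subject. Continuous outcomes use column `y`;
#' survival outcomes use `time` and `event` (0/1). Any other columns are
#' treated as covariates.
#'
#' @param path CSV path.
#' @return A data frame with attribute `"outcome_kind"` (`"continuous"` or
#'   `"survival"`) and `"covariates"` (character vector, possibly empty).
#' @export
read_outcome_table <- function(path) {
  if (!file.exists(path))
    md_stop(sprintf("file not found: %s", path), "markerdens_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"subject_id" %in% names(df))
    md_stop("outcome table needs a 'subject_id' column", "markerdens_schema_error")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    md_stop("outcome table has duplicated subject ids", "markerdens_schema_error")
  if (all(c("time", "event") %in% names(df))) {
    kind <- "survival"
    if (any(df$time < 0)) md_stop("negative survival times", "markerdens_schema_error")
    if (!all(df$event %in% c(0, 1)))
      md_stop("'event' must be 0/1", "markerdens_schema_error")
    covs <- setdiff(names(df), c("subject_id", "time", "event"))
  } else if ("y" %in% names(df)) {
    kind <- "continuous"
    covs <- setdiff(names(df), c("subject_id", "y"))
  } else {
    md_stop("outcome table needs either 'y' or 'time'+'event' columns",
            "markerdens_schema_error")
  }
  structure(df, outcome_kind = kind, covariates = covs)
}
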