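#' Read 3D path recordings from a trajectory table
#'
#' Reads marker trajectories stored as a plain-text table (CSV) with one row
#' per recorded frame and columns naming the repetition id, frame index, and
#' x/y/z coordinates in centimetres. Rows are grouped by repetition id and
#' ordered by frame index (ties keep file order), yielding one path per
#' distinct id.
#'
#' @param source path to a CSV file, or a data frame already in that layout.
#' @param grouping name of the repetition-id column. Default `"rep_id"`.
#' @param frame_col,coord_cols names of the frame-index column and the three
#'   coordinate columns.
#' @return Named list of [rv_path] objects, one per distinct repetition id,
#'   in order of first appearance.
#' @seealso [repetition_set()] to assemble the result into an aligned set.
#' @export
read_paths <- function(source, grouping = "rep_id", frame_col = "frame",
                       coord_cols = c("x", "y", "z")) {
  if (is.character(source)) {
    if (!file.exists(source))
      rv_io_error(sprintf("trajectory file not found: %s", source))
    df <- utils::read.csv(source, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  } else if (is.data.frame(source)) {
    df <- source
  } else {
    rv_domain_error("source must be a file path or a data frame")
  }

  needed <- c(grouping, frame_col, coord_cols)
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    rv_format_error(sprintf("trajectory table is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  if (nrow(df) == 0L)
    rv_empty_error("trajectory table contains no rows")

  num <- lapply(c(frame_col, coord_cols), function(col) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad) > 0)
      rv_parse_error(sprintf(
        "non-numeric value '%s' in column '%s' at data row %d",
        raw[bad[1]], col, bad[1]))
    if (anyNA(val))
      rv_parse_error(sprintf("missing value in column '%s' at data row %d",
                             col, which(is.na(val))[1]))
    val
  })
  names(num) <- c(frame_col, coord_cols)

  ids <- as.character(df[[grouping]])
  order_ids <- unique(ids)
  paths <- lapply(order_ids, function(id) {
    sel <- which(ids == id)
    # stable sort: ties in frame value keep file order
    sel <- sel[order(num[[frame_col]][sel])]
    rv_path(cbind(x = num[[coord_cols[1]]][sel],
                  y = num[[coord_cols[2]]][sel],
                  z = num[[coord_cols[3]]][sel]),
            label = id, source_index = num[[frame_col]][sel])
  })
  names(paths) <- order_ids
  paths
}

#' Write paths to a trajectory table
#'
#' Inverse of [read_paths()]: serializes paths (or a whole repetition set,
#' standard path included) to the `rep_id,frame,x,y,z` CSV layout.
#'
#' @param paths a named list of [rv_path], a single [rv_path], or an
#'   `rv_repset` (whose standard is written under its own label).
#' @param file destination path.
#' @param digits significant digits retained in the table.
#' @export
write_paths <- function(paths, file, digits = 12) {
  if (inherits(paths, "rv_repset"))
    paths <- c(list(paths$standard), paths$repetitions)
  if (inherits(paths, "rv_path")) paths <- list(paths)
  rows <- lapply(paths, function(p) {
    n <- nrow(p$points)
    frame <- if (!is.null(p$source_index) && length(p$source_index) == n)
      p$source_index else seq_len(n)
    data.frame(rep_id = p$label, frame = frame,
               x = p$points[, "x"], y = p$points[, "y"], z = p$points[, "z"])
  })
  df <- do.call(rbind, rows)
  df$x <- signif(df$x, digits); df$y <- signif(df$y, digits)
  df$z <- signif(df$z, digits)
  ok <- tryCatch({
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rv_io_error(sprintf("cannot write trajectory table to: %s", file))
  invisible(file)
}

#' Write an RV curve to a plain-text table
#'
#' One row per threshold rung, descending radius, with columns
#' `d_cm`, `volume_cm3`, `reliability`, `n_success`.
#'
#' @param curve an [compute_rv_curve()] result.
#' @param file destination path.
#' @export
write_rv_table <- function(curve, file) {
  if (!inherits(curve, "rv_curve"))
    rv_domain_error("curve must be an rv_curve")
  if (nrow(curve) == 0L)
    rv_empty_error("refusing to write an empty RV curve")
  out <- data.frame(d_cm = curve$d, volume_cm3 = curve$volume,
                    reliability = curve$reliability,
                    n_success = curve$n_success)
  ok <- tryCatch({
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rv_io_error(sprintf("cannot write RV table to: %s", file))
  invisible(file)
}

#' Read back an RV table written by [write_rv_table()]
#'
#' @param file path to the table.
#' @return data frame with columns `d_cm`, `volume_cm3`, `reliability`,
#'   `n_success`.
#' @export
read_rv_table <- function(file) {
  if (!file.exists(file))
    rv_io_error(sprintf("RV table not found: %s", file))
  df <- utils::read.csv(file)
  miss <- setdiff(c("d_cm", "volume_cm3", "reliability", "n_success"),
                  names(df))
  if (length(miss) > 0)
    rv_format_error(sprintf("RV table is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  df
}
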