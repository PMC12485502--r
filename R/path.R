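#' Construct a 3D path
#'
#' An `rv_path` is an ordered sequence of 3D marker positions (in
#' centimetres) describing one recorded trajectory: either the standard
#' (expert reference) path or one training repetition.
#'
#' @param points numeric matrix with one row per sample and three columns
#'   (x, y, z), or a data frame with columns `x`, `y`, `z`. Coordinates in
#'   centimetres.
#' @param label free-text identifier (e.g. the repetition id).
#' @param source_index optional vector of original frame indices; kept for
#'   provenance, not used in computation.
#' @return An object of class `rv_path`: a list with elements `points`
#'   (n x 3 matrix with columns x, y, z), `label`, and `source_index`.
#' @examples
#' p <- rv_path(cbind(x = 0, y = 0, z = c(0, 1, 2)), label = "std")
#' arc_length(p)
#' @export
rv_path <- function(points, label = "", source_index = NULL) {
  if (is.data.frame(points)) {
    miss <- setdiff(c("x", "y", "z"), names(points))
    if (length(miss) > 0)
      rv_format_error(sprintf("path data frame is missing column(s): %s",
                              paste(miss, collapse = ", ")))
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    rv_format_error("path points must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) < 2L)
    rv_degenerate_error("a path needs at least 2 points")
  if (!all(is.finite(points)))
    rv_domain_error("path coordinates must all be finite")
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  structure(
    list(points = points, label = as.character(label)[1],
         source_index = source_index),
    class = "rv_path"
  )
}

#' @export
print.rv_path <- function(x, ...) {
  cat(sprintf("<rv_path> '%s': %d points, arc length %.4g cm\n",
              x$label, nrow(x$points), arc_length(x)))
  invisible(x)
}

#' Total arc length of a path
#'
#' Sums the Euclidean lengths of consecutive point-to-point segments of the
#' piecewise-linear path. For the standard path this is the tube length `h`
#' used in the working-space volume \eqn{V = \pi d^2 h}.
#'
#' @param path an [rv_path].
#' @return Arc length in centimetres (non-negative scalar).
#' @export
arc_length <- function(path) {
  pts <- as_path_matrix(path)
  if (nrow(pts) < 2L)
    rv_degenerate_error("arc_length needs a path with at least 2 points")
  seg <- diff(pts)
  sum(sqrt(rowSums(seg^2)))
}

#' Resample a path at equal arc-length increments
#'
#' Re-indexes a path at `n_points` positions spaced equally along its
#' piecewise-linear geometry, preserving both endpoints exactly. This is the
#' preparation step that puts the standard path and every repetition on a
#' common index length so deviations can be paired pointwise.
#'
#' @param path an [rv_path] with at least 2 points and positive arc length.
#' @param n_points number of output points (>= 2).
#' @return An [rv_path] with exactly `n_points` points.
#' @export
resample_by_arclength <- function(path, n_points) {
  pts <- as_path_matrix(path)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    rv_domain_error("n_points must be an integer >= 2")
  if (nrow(pts) < 2L)
    rv_degenerate_error("cannot resample a path with fewer than 2 points")

  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0)
    rv_degenerate_error("path has zero arc length (all points coincident)")

  # drop zero-length segments so the arc-length parameter is strictly
  # increasing; interpolation is unaffected
  keep <- c(TRUE, seg > 0)
  s <- s[keep]
  pts <- pts[keep, , drop = FALSE]

  target <- seq(0, total, length.out = n_points)
  out <- vapply(1:3, function(k) {
    stats::approx(s, pts[, k], xout = target, method = "linear",
                  ties = "ordered")$y
  }, numeric(n_points))
  out <- matrix(out, ncol = 3L)
  # endpoints exact, immune to interpolation round-off
  out[1L, ] <- pts[1L, ]
  out[n_points, ] <- pts[nrow(pts), ]

  lab <- if (inherits(path, "rv_path")) path$label else ""
  rv_path(out, label = lab)
}

as_path_matrix <- function(path) {
  if (inherits(path, "rv_path")) return(path$points)
  if (is.matrix(path) && ncol(path) == 3L) return(path)
  rv_domain_error("expected an rv_path or an n x 3 coordinate matrix")
}

#' Assemble a standard path and its training repetitions
#'
#' Bundles the expert reference path together with M imitation repetitions
#' and brings every path to a common point count N. A path is resampled by
#' arc length only when its point count differs from the target, so
#' ensembles that already share the standard's sampling are left untouched
#' and keep their exact pointwise correspondence.
#'
#' @param standard the standard path ([rv_path]).
#' @param repetitions list of [rv_path] repetitions (M >= 1), in training
#'   order.
#' @param n_points target common length N; defaults to the standard path's
#'   point count.
#' @return An object of class `rv_repset`: list with `standard`,
#'   `repetitions`, and `common_length`.
#' @export
repetition_set <- function(standard, repetitions, n_points = NULL) {
  if (!inherits(standard, "rv_path"))
    rv_domain_error("standard must be an rv_path")
  if (inherits(repetitions, "rv_path")) repetitions <- list(repetitions)
  if (!is.list(repetitions) || length(repetitions) < 1L)
    rv_empty_error("repetitions must be a non-empty list of rv_path objects")
  if (!all(vapply(repetitions, inherits, logical(1), "rv_path")))
    rv_domain_error("every repetition must be an rv_path")

  n <- if (is.null(n_points)) nrow(standard$points) else as.integer(n_points)
  if (is.na(n) || n < 2L)
    rv_domain_error("common length N must be an integer >= 2")

  fit <- function(p) {
    if (nrow(p$points) == n) p else resample_by_arclength(p, n)
  }
  structure(
    list(standard = fit(standard),
         repetitions = lapply(repetitions, fit),
         common_length = n),
    class = "rv_repset"
  )
}

#' @export
print.rv_repset <- function(x, ...) {
  cat(sprintf("<rv_repset> M = %d repetitions, N = %d points, standard '%s' (h = %.4g cm)\n",
              length(x$repetitions), x$common_length, x$standard$label,
              arc_length(x$standard)))
  invisible(x)
}

#' Restrict a repetition set to its first m repetitions
#'
#' @param reps an [repetition_set()] object.
#' @param m prefix count, 1 <= m <= M.
#' @return An `rv_repset` containing repetitions 1..m.
#' @export
prefix_repetitions <- function(reps, m) {
  stopifnot(inherits(reps, "rv_repset"))
  m <- as.integer(m)
  M <- length(reps$repetitions)
  if (is.na(m) || m < 1L || m > M)
    rv_domain_error(sprintf("prefix count m must be in 1..%d", M))
  structure(
    list(standard = reps$standard,
         repetitions = reps$repetitions[seq_len(m)],
         common_length = reps$common_length),
    class = "rv_repset"
  )
}
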