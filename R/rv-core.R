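#' Pointwise Euclidean deviations between repetitions and the standard path
#'
#' For repetition m and index n the deviation is the Euclidean distance
#' between the repetition's n-th point and the standard path's n-th point:
#' \deqn{d_{mn} = \lVert t_{mn} - s_n \rVert .}
#' Correspondence is strictly by index, which is why all paths must first
#' share a common length (see [repetition_set()]); no elastic alignment is
#' performed.
#'
#' @param reps an [repetition_set()] object, or the standard [rv_path] (in
#'   which case `repetitions` must be supplied).
#' @param repetitions optional list of [rv_path] when `reps` is the standard
#'   path.
#' @return An object of class `rv_devmat`: list with `values` (M x N matrix
#'   of deviations in cm), `per_path_max` (length-M row maxima), `M`, `N`.
#' @export
pointwise_deviations <- function(reps, repetitions = NULL) {
  if (inherits(reps, "rv_repset")) {
    standard <- reps$standard
    repetitions <- reps$repetitions
  } else if (inherits(reps, "rv_path") && !is.null(repetitions)) {
    standard <- reps
    if (inherits(repetitions, "rv_path")) repetitions <- list(repetitions)
  } else {
    rv_domain_error(
      "supply an rv_repset, or a standard rv_path plus repetitions")
  }
  N <- nrow(standard$points)
  bad <- which(vapply(repetitions, function(p) nrow(p$points), 0L) != N)
  if (length(bad) > 0)
    rv_alignment_error(sprintf(
      "repetition %d has a different point count than the standard path (N = %d); resample first (see repetition_set)",
      bad[1], N))

  values <- t(vapply(repetitions, function(p) {
    sqrt(rowSums((p$points - standard$points)^2))
  }, numeric(N)))
  values <- matrix(values, nrow = length(repetitions), ncol = N)
  structure(
    list(values = values, per_path_max = apply(values, 1L, max),
         M = nrow(values), N = N),
    class = "rv_devmat"
  )
}

#' @export
print.rv_devmat <- function(x, ...) {
  cat(sprintf("<rv_devmat> M = %d paths x N = %d points; max deviation %.4g cm\n",
              x$M, x$N, max(x$per_path_max)))
  invisible(x)
}

#' Descending ladder of candidate tolerance radii
#'
#' Collects deviation values, removes duplicates, and sorts them in
#' descending order so each rung can serve as a tube radius. The
#' `"maxima"` origin keeps only the distinct per-path maxima, which is
#' lossless for reliability: a path conforms at radius d iff its maximum
#' deviation does, so every attainable reliability value appears at some
#' per-path maximum. `"full"` uses the complete deviation multiset.
#'
#' @param dev an [pointwise_deviations()] result.
#' @param origin `"maxima"` (default) or `"full"`.
#' @return Numeric vector of strictly descending radii (cm), with attribute
#'   `origin`.
#' @export
threshold_ladder <- function(dev, origin = c("maxima", "full")) {
  origin <- match.arg(origin)
  if (!inherits(dev, "rv_devmat"))
    rv_domain_error("dev must be an rv_devmat")
  if (length(dev$values) == 0L)
    rv_empty_error("deviation matrix is empty")
  vals <- if (origin == "maxima") dev$per_path_max else as.vector(dev$values)
  out <- sort(unique(vals), decreasing = TRUE)
  attr(out, "origin") <- origin
  out
}

#' Cylindrical working-space volume
#'
#' Volume of the tube of radius `d` coaxial with the standard path:
#' \eqn{V = \pi d^2 h}, with `h` the tube length in cm (by default the
#' standard path's arc length).
#'
#' @param d tube radius in cm (>= 0).
#' @param h tube length in cm (> 0).
#' @return Volume in cm^3.
#' @export
tube_volume <- function(d, h) {
  if (any(!is.finite(d)) || any(d < 0))
    rv_domain_error("tube radius d must be finite and >= 0")
  if (any(!is.finite(h)) || any(h <= 0))
    rv_domain_error("tube length h must be finite and > 0")
  pi * d^2 * h
}

#' Empirical reliability at a tolerance radius
#'
#' A repetition conforms at radius `d_j` when every one of its pointwise
#' deviations stays within `d_j` — equivalently, when its maximum deviation
#' does (the state function \eqn{Z = d_{mn} - d_j} is nowhere positive).
#' Reliability is the conforming fraction \eqn{R_j = n_j / M}.
#'
#' @param dev an [pointwise_deviations()] result.
#' @param d_j tolerance radius in cm (>= 0).
#' @return List with `reliability` (in \[0, 1\]) and `n_success` (integer).
#' @export
reliability_at_threshold <- function(dev, d_j) {
  if (!inherits(dev, "rv_devmat"))
    rv_domain_error("dev must be an rv_devmat")
  if (!is.finite(d_j) || d_j < 0)
    rv_domain_error("threshold d_j must be finite and >= 0")
  n <- sum(dev$per_path_max <= d_j)
  list(reliability = n / dev$M, n_success = as.integer(n))
}

#' Compute the Reliability Volume curve
#'
#' For each rung of the threshold ladder, pairs the empirical reliability
#' with the working-space volume at that radius, producing the ordered set
#' of (d_j, V_j, R_j) triples that constitutes the RV metric. The tube
#' length is the standard path's arc length (`h_mode = "arclength"`) or a
#' caller-supplied constant such as the 2 cm workspace height
#' (`h_mode = "fixed"`).
#'
#' @param reps an [repetition_set()] object.
#' @param h_mode `"arclength"` (default) or `"fixed"`.
#' @param fixed_h tube length in cm, required when `h_mode = "fixed"`.
#' @param ladder `"maxima"` (default, lossless; M rungs) or `"full"`
#'   (complete deviation multiset).
#' @return An object of class `rv_curve`: a data frame with columns `d`,
#'   `volume`, `reliability`, `n_success`, ordered by descending `d`, and
#'   attributes `h`, `M`, `h_mode`.
#' @examples
#' std <- rv_path(cbind(x = 0, y = 0, z = c(0, 1, 2)), "std")
#' rep1 <- rv_path(std$points + 0.1, "r1")
#' curve <- compute_rv_curve(repetition_set(std, list(rep1)))
#' curve
#' @export
compute_rv_curve <- function(reps, h_mode = c("arclength", "fixed"),
                             fixed_h = NULL,
                             ladder = c("maxima", "full")) {
  h_mode <- match.arg(h_mode)
  ladder <- match.arg(ladder)
  if (!inherits(reps, "rv_repset"))
    rv_domain_error("reps must be an rv_repset (see repetition_set)")
  h <- if (h_mode == "arclength") {
    arc_length(reps$standard)
  } else {
    if (is.null(fixed_h)) rv_domain_error("fixed_h is required when h_mode = 'fixed'")
    as.numeric(fixed_h)
  }
  if (!is.finite(h) || h <= 0)
    rv_domain_error("tube length h must be finite and > 0")

  dev <- pointwise_deviations(reps)
  rungs <- threshold_ladder(dev, origin = ladder)
  rel <- vapply(rungs, function(d) {
    r <- reliability_at_threshold(dev, d)
    c(r$reliability, r$n_success)
  }, numeric(2))

  out <- data.frame(d = as.numeric(rungs),
                    volume = tube_volume(as.numeric(rungs), h),
                    reliability = rel[1L, ],
                    n_success = as.integer(rel[2L, ]))
  structure(out, h = h, M = dev$M, h_mode = h_mode, ladder = ladder,
            class = c("rv_curve", "data.frame"))
}

#' @export
print.rv_curve <- function(x, ...) {
  cat(sprintf("Reliability Volume curve: M = %d repetitions, h = %.4g cm (%s)\n",
              attr(x, "M"), attr(x, "h"), attr(x, "h_mode")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot method for RV curves: reliability against working-space volume
#'
#' @param x an `rv_curve`.
#' @param ... passed to [graphics::plot.default].
#' @export
plot.rv_curve <- function(x, ...) {
  ord <- order(x$volume)
  graphics::plot(x$volume[ord], x$reliability[ord], type = "s",
                 xlab = expression(V ~ (cm^3)), ylab = "R",
                 ylim = c(0, 1), ...)
  graphics::points(x$volume[ord], x$reliability[ord], pch = 16, cex = 0.6)
  invisible(x)
}

#' Smallest working-space volume reaching a target reliability
#'
#' Scans the RV curve for the smallest volume whose reliability is at least
#' `r_target`. The rung at the global maximum deviation always has R = 1,
#' so a qualifying volume always exists.
#'
#' @param curve an [compute_rv_curve()] result.
#' @param r_target target reliability in (0, 1].
#' @return Volume in cm^3.
#' @export
volume_at_reliability <- function(curve, r_target) {
  if (!inherits(curve, "rv_curve"))
    rv_domain_error("curve must be an rv_curve")
  if (!is.finite(r_target) || r_target <= 0 || r_target > 1)
    rv_domain_error("r_target must lie in (0, 1]")
  ok <- curve$reliability >= r_target
  if (!any(ok))
    rv_domain_error("no rung reaches the target reliability (malformed curve)")
  min(curve$volume[ok])
}

#' Conventional spherical working volume
#'
#' The comparison baseline: for each repetition, the mean Euclidean distance
#' of its points to the path's own centroid defines a sphere radius
#' \eqn{\bar r}; the repetition's working volume is
#' \eqn{\frac{4}{3}\pi \bar r^3}. The set-level value is the arithmetic mean
#' across repetitions. Unlike the RV tube, this average-based measure is
#' insensitive to single worst-case excursions.
#'
#' @param reps an [repetition_set()] object or a list of [rv_path].
#' @return Mean spherical working volume in cm^3.
#' @export
conventional_working_volume <- function(reps) {
  paths <- if (inherits(reps, "rv_repset")) reps$repetitions
           else if (inherits(reps, "rv_path")) list(reps)
           else reps
  if (length(paths) < 1L)
    rv_empty_error("at least one repetition is required")
  vols <- vapply(paths, function(p) {
    pts <- as_path_matrix(p)
    ctr <- colMeans(pts)
    rbar <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
    if (rbar == 0) {
      warning("degenerate repetition (all points coincident): volume 0")
      return(0)
    }
    (4 / 3) * pi * rbar^3
  }, numeric(1))
  mean(vols)
}
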