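#' Per-repetition noise schedule for simulated training
#'
#' Defines the per-axis perturbation scale sigma_m (cm) for each simulated
#' repetition. Three kinds emulate common training dynamics:
#' \describe{
#'   \item{flat}{constant sigma — a trainee at steady state.}
#'   \item{learning}{sigma decays geometrically from `sigma` to `sigma / 2`
#'     across the schedule — precision improving with practice.}
#'   \item{fatigue}{flat sigma with an episodic spike: sigma multiplied by
#'     `spike_factor` over `spike_len` consecutive repetitions starting at
#'     `spike_at` — a transient lapse the stopping rule should catch.}
#' }
#'
#' @param kind `"flat"`, `"learning"`, or `"fatigue"`.
#' @param n_reps number of repetitions M (>= 1).
#' @param sigma baseline per-axis noise scale in cm (> 0).
#' @param spike_factor multiplier applied during a fatigue spike (default 3).
#' @param spike_at first spiked repetition (default: just past mid-series).
#' @param spike_len number of consecutive spiked repetitions (default 5).
#' @param seed integer seed for reproducible simulation, or `NULL`.
#' @return An object of class `noise_profile`: list with `sigma_schedule`
#'   (length `n_reps`), `kind`, `seed`.
#' @export
noise_profile <- function(kind = c("flat", "learning", "fatigue"),
                          n_reps, sigma = 0.1, spike_factor = 3,
                          spike_at = NULL, spike_len = 5, seed = NULL) {
  kind <- match.arg(kind)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    rv_domain_error("n_reps must be an integer >= 1")
  if (!is.finite(sigma) || sigma <= 0)
    rv_domain_error("sigma must be > 0")

  schedule <- switch(kind,
    flat = rep(sigma, n_reps),
    learning = {
      # geometric decay: sigma_1 = sigma, sigma_M = sigma / 2
      if (n_reps == 1L) sigma
      else sigma * 2^(-(seq_len(n_reps) - 1) / (n_reps - 1))
    },
    fatigue = {
      if (is.null(spike_at)) spike_at <- n_reps %/% 2L + 1L
      spike_at <- as.integer(spike_at)
      span <- spike_at:min(n_reps, spike_at + as.integer(spike_len) - 1L)
      if (spike_at < 1L || spike_at > n_reps)
        rv_domain_error("spike_at must lie within 1..n_reps")
      s <- rep(sigma, n_reps)
      s[span] <- sigma * spike_factor
      s
    })
  structure(list(sigma_schedule = schedule, kind = kind, seed = seed),
            class = "noise_profile")
}

#' Deterministic standard paths for simulation
#'
#' Generates a reference trajectory sampled at arc-length-uniform positions.
#' The default `"helix"` winds two full loops (4*pi radians) at radius
#' `scale` with a small pitch, emulating the two-loop suture geometry of a
#' knot-tying task; `"circle"` is a single planar loop of radius `scale`;
#' `"line"` is a straight segment of length `scale` along z.
#'
#' @param kind `"helix"`, `"circle"`, or `"line"`.
#' @param scale characteristic size in cm (helix/circle radius, line length).
#' @param n_points number of samples N (>= 2).
#' @param pitch helix rise in cm per radian of turn (default 0.3 / (2*pi),
#'   i.e. 0.3 cm per loop).
#' @return An [rv_path].
#' @export
make_standard_path <- function(kind = c("helix", "circle", "line"),
                               scale = 1, n_points = 200,
                               pitch = 0.3 / (2 * pi)) {
  kind <- match.arg(kind)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    rv_domain_error("n_points must be an integer >= 2")
  if (!is.finite(scale) || scale <= 0)
    rv_domain_error("scale must be > 0")

  pts <- switch(kind,
    line = {
      z <- seq(0, scale, length.out = n_points)
      cbind(x = 0, y = 0, z = z)
    },
    circle = {
      # constant-speed parametrization, so uniform angle = uniform arc length
      th <- seq(0, 2 * pi, length.out = n_points)
      cbind(x = scale * cos(th), y = scale * sin(th), z = 0)
    },
    helix = {
      th <- seq(0, 4 * pi, length.out = n_points)
      cbind(x = scale * cos(th), y = scale * sin(th), z = pitch * th)
    })
  rv_path(pts, label = sprintf("standard_%s", kind))
}

#' Simulate training repetitions around a standard path
#'
#' Repetition m is the standard path with independent isotropic Gaussian
#' perturbations of per-axis scale sigma_m added to every point. Noise is
#' i.i.d. across points (no temporal autocorrelation): the pointwise
#' deviation at each index then follows sigma_m times a chi distribution
#' with 3 degrees of freedom, which [analytic_reliability()] exploits as a
#' closed-form oracle.
#'
#' @param standard an [rv_path].
#' @param profile a [noise_profile()]; its `seed` (when non-`NULL`) makes
#'   the ensemble reproducible.
#' @return An [repetition_set()] with M = `length(profile$sigma_schedule)`
#'   repetitions, already index-aligned with the standard path.
#' @export
simulate_repetitions <- function(standard, profile) {
  if (!inherits(standard, "rv_path"))
    rv_domain_error("standard must be an rv_path")
  if (!inherits(profile, "noise_profile"))
    rv_domain_error("profile must be a noise_profile")
  if (!is.null(profile$seed)) set.seed(as.integer(profile$seed))
  n <- nrow(standard$points)
  reps <- lapply(seq_along(profile$sigma_schedule), function(m) {
    s <- profile$sigma_schedule[m]
    noise <- matrix(stats::rnorm(3L * n, mean = 0, sd = s), ncol = 3L)
    rv_path(standard$points + noise, label = sprintf("rep_%03d", m))
  })
  repetition_set(standard, reps)
}

#' Closed-form reliability under isotropic noise
#'
#' When every point of a repetition is the standard point plus isotropic
#' Gaussian noise of per-axis scale sigma, each pointwise deviation is
#' sigma times a chi-distributed variable with 3 degrees of freedom, and
#' all N deviations are independent. The probability that a whole path
#' stays within radius d is therefore
#' \deqn{R(d) = F_{\chi_3}(d / \sigma)^N}
#' with \eqn{F_{\chi_3}} the chi(3) cumulative distribution (evaluated via
#' the chi-squared distribution on the squared variable). This is the
#' independent oracle against which the empirical reliability estimator is
#' validated.
#'
#' @param d tolerance radius in cm (>= 0; vectorized).
#' @param sigma per-axis noise scale in cm (> 0).
#' @param n_points number of path points N (>= 1).
#' @return Success probability in \[0, 1\].
#' @export
analytic_reliability <- function(d, sigma, n_points) {
  if (any(!is.finite(d)) || any(d < 0))
    rv_domain_error("d must be finite and >= 0")
  if (!is.finite(sigma) || sigma <= 0)
    rv_domain_error("sigma must be > 0")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    rv_domain_error("n_points must be an integer >= 1")
  stats::pchisq((d / sigma)^2, df = 3)^n_points
}

#' Recover the noise scale from a deviation matrix
#'
#' Under a flat isotropic-noise profile the deviations are sigma * chi(3)
#' variates with mean \eqn{\sigma \cdot 2\sqrt{2/\pi}}; inverting the sample
#' mean gives a simple consistent estimate of sigma.
#'
#' @param dev an [pointwise_deviations()] result.
#' @return Estimated sigma in cm.
#' @export
estimate_sigma <- function(dev) {
  if (!inherits(dev, "rv_devmat"))
    rv_domain_error("dev must be an rv_devmat")
  mean(dev$values) / (2 * sqrt(2 / pi))
}
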