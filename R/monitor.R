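#' RV curve on a prefix of the training series
#'
#' Evaluates the Reliability Volume on repetitions 1..m only, the building
#' block for tracking skill evolution across a session: snapshots at growing
#' repetition counts are cumulative prefixes, so reliabilities at checkpoint
#' m have denominator m.
#'
#' @inheritParams compute_rv_curve
#' @param m prefix count, 1 <= m <= M.
#' @return An `rv_curve` computed on the first `m` repetitions.
#' @export
prefix_rv <- function(reps, m, h_mode = c("arclength", "fixed"),
                      fixed_h = NULL, ladder = c("maxima", "full")) {
  compute_rv_curve(prefix_repetitions(reps, m), h_mode = h_mode,
                   fixed_h = fixed_h, ladder = ladder)
}

#' Construct a monitor trace
#'
#' A monitor trace records, at strictly increasing repetition checkpoints,
#' either the reliability at a fixed working-space volume or the volume at a
#' fixed target reliability. Traces are usually produced by
#' [reliability_trace()] / [volume_trace()], but can be built directly from
#' externally reported reliability sequences for stopping-rule analysis.
#'
#' @param checkpoints strictly increasing repetition counts.
#' @param values reliability (or volume) at each checkpoint.
#' @param fixed_volume the volume (cm^3) at which reliability is tracked,
#'   or `NULL`.
#' @param fixed_reliability the reliability at which volume is tracked, or
#'   `NULL`. Exactly one of `fixed_volume` / `fixed_reliability` must be set.
#' @return An object of class `monitor_trace`: data frame with columns
#'   `checkpoint` and `value`, plus attributes `kind` (`"reliability"` or
#'   `"volume"`) and the fixed quantity.
#' @export
monitor_trace <- function(checkpoints, values, fixed_volume = NULL,
                          fixed_reliability = NULL) {
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) < 1L || anyNA(checkpoints))
    rv_domain_error("checkpoints must be positive integers")
  if (any(diff(checkpoints) <= 0))
    rv_domain_error("checkpoints must be strictly increasing")
  if (length(values) != length(checkpoints))
    rv_domain_error("values and checkpoints must have equal length")
  if (is.null(fixed_volume) == is.null(fixed_reliability))
    rv_domain_error(
      "exactly one of fixed_volume / fixed_reliability must be given")
  kind <- if (!is.null(fixed_volume)) "reliability" else "volume"
  structure(
    data.frame(checkpoint = checkpoints, value = as.numeric(values)),
    kind = kind, fixed_volume = fixed_volume,
    fixed_reliability = fixed_reliability,
    class = c("monitor_trace", "data.frame")
  )
}

#' @export
print.monitor_trace <- function(x, ...) {
  fixed <- if (attr(x, "kind") == "reliability")
    sprintf("R at V = %.4g cm^3", attr(x, "fixed_volume"))
  else
    sprintf("V (cm^3) at R = %.4g", attr(x, "fixed_reliability"))
  cat(sprintf("<monitor_trace> %s over %d checkpoints\n", fixed, nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Reliability at a fixed working-space volume across checkpoints
#'
#' At each checkpoint m, computes the fraction of the first m repetitions
#' whose maximum deviation stays within the tube radius implied by the fixed
#' volume, \eqn{d = \sqrt{V / (\pi h)}}. Fluctuations of this trace across a
#' session are the signal the stopping rule watches for fatigue or
#' distraction.
#'
#' @inheritParams compute_rv_curve
#' @param checkpoints increasing repetition counts, each <= M.
#' @param fixed_volume working-space volume V in cm^3 (> 0).
#' @return A [monitor_trace()] of kind `"reliability"`.
#' @export
reliability_trace <- function(reps, checkpoints, fixed_volume,
                              h_mode = c("arclength", "fixed"),
                              fixed_h = NULL) {
  h_mode <- match.arg(h_mode)
  if (!inherits(reps, "rv_repset"))
    rv_domain_error("reps must be an rv_repset")
  if (!is.finite(fixed_volume) || fixed_volume <= 0)
    rv_domain_error("fixed_volume must be > 0")
  M <- length(reps$repetitions)
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 1L) || any(checkpoints > M))
    rv_domain_error(sprintf("checkpoints must lie in 1..%d", M))

  h <- if (h_mode == "arclength") arc_length(reps$standard)
       else {
         if (is.null(fixed_h))
           rv_domain_error("fixed_h is required when h_mode = 'fixed'")
         as.numeric(fixed_h)
       }
  d <- sqrt(fixed_volume / (pi * h))
  maxima <- pointwise_deviations(reps)$per_path_max
  vals <- vapply(checkpoints, function(m) {
    sum(maxima[seq_len(m)] <= d) / m
  }, numeric(1))
  monitor_trace(checkpoints, vals, fixed_volume = fixed_volume)
}

#' Working-space volume at a fixed reliability across checkpoints
#'
#' At each checkpoint m, evaluates [volume_at_reliability()] on the RV curve
#' of the first m repetitions. A downward trend at fixed reliability (e.g.
#' R = 0.95) reflects improving precision at a constant success probability.
#'
#' @inheritParams reliability_trace
#' @param r_target target reliability in (0, 1].
#' @return A [monitor_trace()] of kind `"volume"`.
#' @export
volume_trace <- function(reps, checkpoints, r_target = 0.95,
                         h_mode = c("arclength", "fixed"), fixed_h = NULL) {
  h_mode <- match.arg(h_mode)
  if (!inherits(reps, "rv_repset"))
    rv_domain_error("reps must be an rv_repset")
  M <- length(reps$repetitions)
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 1L) || any(checkpoints > M))
    rv_domain_error(sprintf("checkpoints must lie in 1..%d", M))
  vals <- vapply(checkpoints, function(m) {
    volume_at_reliability(
      prefix_rv(reps, m, h_mode = h_mode, fixed_h = fixed_h), r_target)
  }, numeric(1))
  monitor_trace(checkpoints, vals, fixed_reliability = r_target)
}

#' Fatigue-aware stopping rule on a reliability trace
#'
#' Scans consecutive checkpoint pairs in order and triggers at the first
#' pair whose absolute reliability change reaches the threshold
#' (|dR| >= `delta_threshold`, improvements included). Training should then
#' pause, with skill read from the last stable measurement: the checkpoint
#' immediately preceding the triggering change.
#'
#' @param trace a [monitor_trace()] of kind `"reliability"` with at least
#'   two checkpoints.
#' @param delta_threshold reliability change threshold (default 0.05).
#' @return An object of class `stopping_decision`: list with `triggered`,
#'   `trigger_checkpoint`, `stop_checkpoint`, `delta_r`, and the threshold.
#' @examples
#' tr <- monitor_trace(c(10, 25, 50), c(0.90, 0.96, 0.90),
#'                     fixed_volume = 427.84)
#' apply_stopping_rule(tr)
#' @export
apply_stopping_rule <- function(trace, delta_threshold = 0.05) {
  if (!inherits(trace, "monitor_trace"))
    rv_domain_error("trace must be a monitor_trace")
  if (attr(trace, "kind") != "reliability")
    rv_domain_error(
      "the stopping rule applies to reliability traces at a fixed volume")
  if (!is.finite(delta_threshold) || delta_threshold <= 0)
    rv_domain_error("delta_threshold must be > 0")
  if (nrow(trace) < 2L)
    rv_stop("a stopping decision needs at least two checkpoints",
            "rv_insufficient_data_error")

  deltas <- diff(trace$value)
  hit <- which(abs(deltas) >= delta_threshold)
  if (length(hit) == 0L) {
    dec <- list(triggered = FALSE, trigger_checkpoint = NA_integer_,
                stop_checkpoint = NA_integer_, delta_r = NA_real_,
                delta_threshold = delta_threshold)
  } else {
    i <- hit[1L]
    dec <- list(triggered = TRUE,
                trigger_checkpoint = trace$checkpoint[i + 1L],
                stop_checkpoint = trace$checkpoint[i],
                delta_r = deltas[i],
                delta_threshold = delta_threshold)
  }
  structure(dec, class = "stopping_decision")
}

#' @export
print.stopping_decision <- function(x, ...) {
  if (x$triggered) {
    cat(sprintf(
      "Stopping rule triggered: |dR| = %.3f (>= %.3f) between checkpoints %d and %d.\nStop training at repetition %d (last stable measurement).\n",
      abs(x$delta_r), x$delta_threshold, x$stop_checkpoint,
      x$trigger_checkpoint, x$stop_checkpoint))
  } else {
    cat(sprintf(
      "No reliability change reached |dR| >= %.3f; continue training.\n",
      x$delta_threshold))
  }
  invisible(x)
}
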