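# Shared fixture builders: everything is generated in code.

# straight standard path of length 2 cm along z, n points
line_standard <- function(n = 3) {
  rv_path(cbind(x = 0, y = 0, z = seq(0, 2, length.out = n)), label = "std")
}

# copy of a path offset by a constant vector
offset_path <- function(path, dx = 0, dy = 0, dz = 0, label = "rep") {
  p <- path$points
  p[, 1] <- p[, 1] + dx; p[, 2] <- p[, 2] + dy; p[, 3] <- p[, 3] + dz
  rv_path(p, label = label)
}

# repetition whose single worst excursion (hence per-path max deviation)
# is exactly `peak`, at an interior index
peaked_path <- function(standard, peak, at = 2L, label = "rep") {
  p <- standard$points
  p[at, 1] <- p[at, 1] + peak
  rv_path(p, label = label)
}

# repetition set whose per-path maximum deviations are exactly `maxima`
repset_with_maxima <- function(maxima, n = 5) {
  std <- line_standard(n)
  reps <- lapply(seq_along(maxima), function(i)
    peaked_path(std, maxima[i], at = 1L + (i %% (n - 1L)),
                label = sprintf("rep%d", i)))
  repetition_set(std, reps)
}

# uniformly random path in the unit cube
random_path <- function(n, label = "rnd") {
  rv_path(matrix(stats::runif(3 * n), ncol = 3), label = label)
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# literal double-loop reliability count applying the state function
# Z = d_mn - d_j <= 0 for all n; independent of the package's counting path
brute_force_reliability <- function(values, d_j) {
  M <- nrow(values); n_ok <- 0L
  for (m in seq_len(M)) {
    conforms <- TRUE
    for (n in seq_len(ncol(values))) {
      if (values[m, n] - d_j > 0) conforms <- FALSE
    }
    if (conforms) n_ok <- n_ok + 1L
  }
  list(reliability = n_ok / M, n_success = n_ok)
}
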