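test_that("pointwise deviations are index-paired Euclidean distances", {
  std <- line_standard(3)
  same <- pointwise_deviations(repetition_set(std, list(std)))
  expect_equal(same$values, matrix(0, 1, 3))

  # 3-4-5 triangle at one index
  p <- std$points; p[2, 1] <- p[2, 1] + 3; p[2, 2] <- p[2, 2] + 4
  dev <- pointwise_deviations(std, rv_path(p))
  expect_equal(dev$values[1, ], c(0, 5, 0))
  expect_equal(dev$per_path_max, 5)

  shifted <- offset_path(std, 1, 1, 1)
  dev2 <- pointwise_deviations(std, shifted)
  expect_equal(dev2$values[1, ], rep(sqrt(3), 3))
})

test_that("length-mismatched paths are rejected with an alignment error", {
  std <- line_standard(3)
  long <- line_standard(5)
  expect_error(pointwise_deviations(std, long),
               "resample", class = "rv_alignment_error")
})

test_that("threshold ladder sorts unique radii descending", {
  std <- line_standard(2)
  # two repetitions with deviation rows (1,3) and (2,2)
  r1 <- std$points; r1[1, 1] <- 1; r1[2, 1] <- 3
  r2 <- std$points; r2[1, 1] <- 2; r2[2, 1] <- 2
  dev <- pointwise_deviations(std, list(rv_path(r1), rv_path(r2)))
  expect_equal(dev$values, rbind(c(1, 3), c(2, 2)))
  expect_equal(as.numeric(threshold_ladder(dev, "full")), c(3, 2, 1))
  expect_equal(as.numeric(threshold_ladder(dev, "maxima")), c(3, 2))
  zero <- pointwise_deviations(std, std)
  expect_equal(as.numeric(threshold_ladder(zero, "full")), 0)
})

test_that("tube volume is the closed-form cylinder", {
  expect_equal(tube_volume(1, 1), pi)
  expect_equal(tube_volume(0, 5), 0)
  expect_equal(tube_volume(2, 3), 12 * pi)
  expect_error(tube_volume(-1, 1), class = "rv_domain_error")
  expect_error(tube_volume(1, 0), class = "rv_domain_error")
})

test_that("reliability counts paths whose every deviation stays inside", {
  reps <- repset_with_maxima(c(1, 2, 3, 4, 5))
  dev <- pointwise_deviations(reps)
  r <- reliability_at_threshold(dev, 3)
  expect_equal(r$reliability, 0.6)
  expect_equal(r$n_success, 3L)
  expect_equal(reliability_at_threshold(dev, max(dev$per_path_max)),
               list(reliability = 1, n_success = 5L))
  expect_equal(reliability_at_threshold(dev, 0.5),
               list(reliability = 0, n_success = 0L))
})

test_that("the RV curve pairs each ladder rung with volume and reliability", {
  # per-path maxima {1, 2} against a straight standard of arc length 2
  reps <- repset_with_maxima(c(1, 2))
  curve <- compute_rv_curve(reps)
  expect_s3_class(curve, "rv_curve")
  expect_equal(attr(curve, "h"), 2)
  expect_equal(curve$d, c(2, 1))
  expect_equal(curve$volume, c(8 * pi, 2 * pi))
  expect_equal(curve$reliability, c(1, 0.5))
  expect_equal(curve$n_success, c(2L, 1L))

  # fixed tube length (2 cm workspace height)
  fixed <- compute_rv_curve(reps, h_mode = "fixed", fixed_h = 2)
  expect_equal(fixed$volume, c(8 * pi, 2 * pi))
  expect_error(compute_rv_curve(reps, h_mode = "fixed"),
               class = "rv_domain_error")
})

test_that("a repetition identical to the standard yields the trivial curve", {
  std <- line_standard(4)
  curve <- compute_rv_curve(repetition_set(std, list(std)))
  expect_equal(nrow(curve), 1)
  expect_equal(curve$d, 0)
  expect_equal(curve$volume, 0)
  expect_equal(curve$reliability, 1)
})

test_that("with M = 1 every reliability is 0 or 1", {
  set.seed(5)
  std <- random_path(10, "std")
  curve <- compute_rv_curve(repetition_set(std, list(random_path(10))),
                            ladder = "full")
  expect_true(all(curve$reliability %in% c(0, 1)))
})

test_that("volume_at_reliability scans for the smallest qualifying rung", {
  reps <- repset_with_maxima(c(1, 2, 3))
  curve <- compute_rv_curve(reps)  # R = 1, 2/3, 1/3 at d = 3, 2, 1
  expect_equal(volume_at_reliability(curve, 0.95), tube_volume(3, 2))
  expect_equal(volume_at_reliability(curve, 1.0), tube_volume(3, 2))
  expect_equal(volume_at_reliability(curve, 0.5), tube_volume(2, 2))
  expect_equal(volume_at_reliability(curve, 0.2), tube_volume(1, 2))
  expect_error(volume_at_reliability(curve, 0), class = "rv_domain_error")
  expect_error(volume_at_reliability(curve, 1.2), class = "rv_domain_error")
})

test_that("conventional working volume averages per-path centroid spheres", {
  r <- 1.5
  axes <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0),
                c(0, -r, 0), c(0, 0, r), c(0, 0, -r))
  expect_equal(conventional_working_volume(list(rv_path(axes))),
               (4 / 3) * pi * r^3)
  # radii 1 and 2 about their own centroids -> mean of the two sphere
  # volumes, ((4/3)pi + (32/3)pi) / 2 = 6 pi
  expect_equal(
    conventional_working_volume(list(rv_path(axes / r), rv_path(2 * axes / r))),
    6 * pi)
  expect_warning(
    v0 <- conventional_working_volume(list(rv_path(matrix(3, 4, 3)))),
    "degenerate")
  expect_equal(v0, 0)
})

test_that("reliability is non-decreasing in the radius across ladders", {
  set.seed(101)
  for (i in 1:20) {
    M <- sample(2:10, 1); N <- sample(2:20, 1)
    std <- random_path(N, "std")
    reps <- repetition_set(std, lapply(seq_len(M), function(j)
      random_path(N)))
    dev <- pointwise_deviations(reps)
    rungs <- threshold_ladder(dev, "full")
    rel <- vapply(rungs, function(d)
      reliability_at_threshold(dev, d)$reliability, numeric(1))
    expect_true(all(diff(rel) <= 0))        # descending d -> R shrinks
    expect_true(rel[1] == 1)                # largest rung contains all
    # granularity: all reliabilities are multiples of 1/M
    expect_equal(rel * M, round(rel * M), tolerance = 1e-12)
  }
})

test_that("the per-path-maxima ladder is lossless for reliability", {
  set.seed(202)
  for (i in 1:20) {
    M <- sample(2:10, 1); N <- sample(2:20, 1)
    std <- random_path(N, "std")
    reps <- repetition_set(std, lapply(seq_len(M), function(j)
      random_path(N)))
    dev <- pointwise_deviations(reps)
    both <- union(threshold_ladder(dev, "full"),
                  threshold_ladder(dev, "maxima"))
    # R(d) computed from either ladder agrees at every rung of either:
    # the maxima ladder drops no attainable reliability value
    for (d in both) {
      expect_equal(reliability_at_threshold(dev, d),
                   brute_force_reliability(dev$values, d))
    }
    curve_max <- compute_rv_curve(reps, ladder = "maxima")
    curve_full <- compute_rv_curve(reps, ladder = "full")
    # every nonzero reliability the full ladder attains appears on the
    # maxima ladder (rungs below every per-path max only ever add R = 0)
    expect_true(all(setdiff(curve_full$reliability,
                            curve_max$reliability) == 0))
    expect_true(all(curve_max$reliability %in% curve_full$reliability))
  }
})
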