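test_that("resampling is the identity on tracks already on the target grid", {
  t_ms <- seq(0, 2000, by = 1000 / 60)
  tr <- gaze_track("p1", "A", t_ms, sin(t_ms / 100) * 50 + 100,
                   cos(t_ms / 100) * 50 + 100, nominal_rate_hz = 60)
  out <- resample_gaze(tr, 60)
  expect_equal(out$x, tr$x)
  expect_equal(out$y, tr$y)
  expect_true(all(out$valid))
})

test_that("downsampling a constant 120 Hz track gives a constant 60 Hz track", {
  t_ms <- seq(0, 1000, by = 1000 / 120)
  tr <- gaze_track("p1", "A", t_ms, rep(300, length(t_ms)),
                   rep(200, length(t_ms)), nominal_rate_hz = 120)
  out <- resample_gaze(tr, 60)
  expect_true(all(out$x == 300) && all(out$y == 200))
  expect_equal(diff(out$time_ms), rep(1000 / 60, length(out$time_ms) - 1))
})

test_that("a 250 Hz sinusoid resampled to 60 Hz tracks the analytic curve", {
  t_ms <- seq(0, 4000, by = 1000 / 250)
  f <- function(t) 400 + 200 * sin(2 * pi * 0.5 * t / 1000)
  tr <- gaze_track("p1", "A", t_ms, f(t_ms), rep(100, length(t_ms)),
                   nominal_rate_hz = 250)
  out <- resample_gaze(tr, 60)
  # worst case: analytic slope (2*pi*0.5*200 px/s) times one input period
  bound <- 2 * pi * 0.5 * 200 * (1 / 250) + 1e-9
  expect_true(all(abs(out$x - f(out$time_ms)) <= bound))
})

test_that("resampling marks gaps with no valid sample nearby as invalid", {
  t_ms <- c(0, 16.7, 33.3, 200, 216.7)
  tr <- gaze_track("p1", "A", t_ms, 1:5, 1:5, nominal_rate_hz = 60)
  out <- resample_gaze(tr, 60)
  expect_false(all(out$valid))
  expect_true(all(out$valid[out$time_ms < 40]))
})

test_that("fixation maps equal the brute-force triple loop", {
  pos <- rbind(c(1.2, 3.7), c(4.0, 0.5), c(2.5, 2.5))
  m <- build_fixation_map(pos, 5, 5, sigma_px = 1, downsample = 1)
  oracle <- matrix(0, 5, 5)
  for (iy in 1:5) for (ix in 1:5) for (k in 1:3) {
    oracle[iy, ix] <- oracle[iy, ix] +
      exp(-((ix - 0.5 - pos[k, 1])^2 + (iy - 0.5 - pos[k, 2])^2) / 2)
  }
  expect_equal(m$values, oracle, tolerance = 1e-12)
  expect_equal(m$n_contributors, 3)
})

test_that("fixation maps use unit-peak bumps and are linear in positions", {
  one <- build_fixation_map(cbind(644, 516), 1280, 1024, sigma_px = 40,
                            downsample = 8)
  expect_equal(max(one$values), 1, tolerance = 1e-12)
  two <- build_fixation_map(rbind(c(644, 516), c(644, 516)), 1280, 1024,
                            sigma_px = 40, downsample = 8)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-12)
  expect_error(build_fixation_map(matrix(numeric(0), ncol = 2),
                                  100, 100, 10), "insufficient")
})

test_that("normalization gives mean 0 / SD 1 and flags constant maps", {
  m <- build_fixation_map(rbind(c(1, 1), c(3.3, 2.1)), 5, 5,
                          sigma_px = 1, downsample = 1)
  raw <- m$values
  nm <- normalize_map(m)
  expect_true(nm$valid && nm$normalized)
  expect_lt(abs(mean(nm$values)), 1e-9)
  expect_equal(sd(nm$values), 1, tolerance = 1e-9)
  # independent recomputation
  expect_equal(nm$values, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)

  const <- build_fixation_map(cbind(1e6, 1e6), 5, 5, sigma_px = 1,
                              downsample = 1)  # bump entirely off-grid
  expect_false(normalize_map(const)$valid)
})

test_that("nss_value is a nearest-cell lookup with the expected sign pattern", {
  m <- normalize_map(build_fixation_map(cbind(640, 512), 1280, 1024,
                                        sigma_px = 40, downsample = 8))
  at_peak <- nss_value(m, c(640, 512))
  expect_equal(at_peak, max(m$values))
  expect_gt(at_peak, 0)
  expect_lt(nss_value(m, c(5, 5)), 0)  # far corner is below the mean
  # indexing oracle on the 5x5 toy map
  toy <- normalize_map(build_fixation_map(rbind(c(1.2, 3.7), c(4, 0.5)),
                                          5, 5, sigma_px = 1,
                                          downsample = 1))
  expect_equal(nss_value(toy, c(1.5, 3.5)), toy$values[4, 2])
})

test_that("too few reference participants yields all-missing series", {
  cohort <- constant_gaze_cohort(n_per_group = 4)
  s <- nss_timecourse(cohort, "A01", reference_group = "A", min_refs = 4)
  expect_true(all(is.na(s$nss)))
  expect_true(all(s$reason == "insufficient_refs"))
})

test_that("identical gaze in all participants gives the constant map maximum", {
  cohort <- constant_gaze_cohort(n_per_group = 6, pos = c(400, 300))
  s <- nss_timecourse(cohort, "A01", reference_group = "A")
  expect_true(all(s$reason == "ok"))
  expect_equal(length(unique(round(s$nss, 12))), 1)
  ref <- normalize_map(build_fixation_map(
    matrix(rep(c(400, 300), 5), ncol = 2, byrow = TRUE), 1280, 1024,
    sigma_px = visual_angle_px(1.2, screen_px = 1280), downsample = 8))
  expect_equal(s$nss[1], max(ref$values), tolerance = 1e-9)
})

test_that("fast NSS engine matches the straight-line map-based oracle", {
  for (seed in 1:2) {
    cohort <- random_gaze_cohort(n_per_group = 3, duration_s = 2,
                                 seed = seed, dropout = 0.1)
    ref_ids <- c("A02", "A03", "B01", "B02", "B03")
    s <- nss_timecourse(cohort, "A01", ref_ids = ref_ids, step_ms = 40,
                        min_refs = 4, sigma_px = 6, downsample = 1)
    o <- naive_nss_timecourse(cohort, "A01", ref_ids, step_ms = 40,
                              min_refs = 4, sigma_px = 6, downsample = 1)
    expect_equal(s$reason, o$reason)
    expect_equal(s$nss, o$nss, tolerance = 1e-9)
  }
  # downsampled grid variant
  cohort <- random_gaze_cohort(n_per_group = 3, duration_s = 2, seed = 9,
                               screen = c(640, 480))
  ref_ids <- c("B01", "B02", "B03", "A02", "A03")
  s <- nss_timecourse(cohort, "A01", ref_ids = ref_ids, step_ms = 40,
                      min_refs = 4, sigma_px = 25, downsample = 8)
  o <- naive_nss_timecourse(cohort, "A01", ref_ids, step_ms = 40,
                            min_refs = 4, sigma_px = 25, downsample = 8)
  expect_equal(s$nss, o$nss, tolerance = 1e-9)
})

test_that("a participant never contributes to their own reference map", {
  # A01 fixates a far corner; all others share one position. If A01 leaked
  # into its own reference map there would be a bump at the corner and the
  # NSS read there would rise above the others-only oracle value.
  cohort <- constant_gaze_cohort(n_per_group = 6, pos = c(640, 512))
  corner <- cohort[["A01"]]
  cohort[["A01"]] <- gaze_track("A01", "A", corner$time_ms,
                                rep(20, length(corner$time_ms)),
                                rep(20, length(corner$time_ms)),
                                nominal_rate_hz = 60)
  s <- nss_timecourse(cohort, "A01", reference_group = "A",
                      sigma_px = 40, downsample = 8)
  others_only <- normalize_map(build_fixation_map(
    matrix(rep(c(640, 512), 5), ncol = 2, byrow = TRUE),
    1280, 1024, sigma_px = 40, downsample = 8))
  expect_equal(s$nss[1], nss_value(others_only, c(20, 20)),
               tolerance = 1e-9)
  expect_false("A01" %in% attr(s, "reference"))
})

test_that("identical groups produce difference scores of exactly zero", {
  cohort <- constant_gaze_cohort(n_per_group = 6)
  sc <- nss_difference_scores(cohort, seed = 1)
  expect_equal(sc$score, rep(0, nrow(sc)))
  expect_equal(attr(sc, "M"), 0)
})

test_that("difference scores refuse groups too small for leave-one-out", {
  cohort <- constant_gaze_cohort(n_per_group = 4)
  expect_error(nss_difference_scores(cohort, min_refs = 4),
               "min_refs \\+ 1")
})

test_that("missing-data bookkeeping reconciles exactly", {
  cohort <- random_gaze_cohort(n_per_group = 6, duration_s = 3, seed = 4,
                               screen = c(640, 480), dropout = 0.2)
  sc <- nss_difference_scores(cohort, sigma_px = 25, downsample = 16,
                              seed = 4)
  drops <- attr(sc, "drop_counts")
  expect_identical(attr(sc, "retained_pairs") + sum(drops),
                   attr(sc, "total_pairs"))
  expect_equal(attr(sc, "retention"),
               attr(sc, "retained_pairs") / attr(sc, "total_pairs"))
  expect_true(all(sc$n_steps >= 1))
})

test_that("relabeling groups leaves null-world mean scores unchanged", {
  flip <- function(cohort) {
    out <- lapply(cohort, function(tr) {
      tr$group <- if (tr$group == "A") "B" else "A"
      tr
    })
    attributes(out) <- attributes(cohort)
    out
  }
  Ms <- sapply(1:8, function(s) {
    cohort <- generate_gaze_cohort(gaze_world(s, n = 6, duration_s = 30))
    c(orig = attr(nss_difference_scores(cohort, downsample = 32,
                                        seed = s), "M"),
      swap = attr(nss_difference_scores(flip(cohort), downsample = 32,
                                        seed = s), "M"))
  })
  expect_gt(t.test(Ms["orig", ], Ms["swap", ])$p.value, 0.01)
})
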