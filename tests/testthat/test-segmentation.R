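test_that("magnitude series follows the analytic unit-peak kernel", {
  tr <- list(press_train("p1", "A", 5000))
  s <- magnitude_series(tr, kernel_sd_ms = 1000, duration_ms = 10000)
  expect_equal(magnitude_at(s, 5000), 1)
  expect_equal(magnitude_at(s, 6000), exp(-0.5))
  expect_equal(magnitude_at(s, 5000 + 1500), exp(-1.125))
  # normalization: two participants pressing at the same instant
  tr2 <- list(press_train("p1", "A", 5000), press_train("p2", "A", 5000))
  s2 <- magnitude_series(tr2, duration_ms = 10000)
  expect_equal(magnitude_at(s2, 5000), 1)
})

test_that("magnitude grid values equal the brute-force double loop", {
  set.seed(42)
  trains <- lapply(1:5, function(i)
    press_train(paste0("p", i), "A", runif(sample(3:8, 1), 0, 60000)))
  s <- magnitude_series(trains, kernel_sd_ms = 1000, grid_step_ms = 100,
                        duration_ms = 60000)
  oracle <- numeric(length(s$time_ms))
  for (g in seq_along(s$time_ms)) {
    for (tr in trains) for (p in tr$times_ms) {
      oracle[g] <- oracle[g] + exp(-(s$time_ms[g] - p)^2 / (2 * 1000^2))
    }
  }
  oracle <- oracle / 5
  expect_equal(s$values, oracle, tolerance = 1e-12)
})

test_that("kernel mass is conserved away from the edges", {
  trains <- list(press_train("p1", "A", c(50000, 51000, 80000)),
                 press_train("p2", "A", c(49000, 100000)))
  s <- magnitude_series(trains, kernel_sd_ms = 1000, grid_step_ms = 100,
                        duration_ms = 150000)
  mass <- sum(s$values) * 100
  expect_equal(mass, 5 * 1000 * sqrt(2 * pi) / 2, tolerance = 0.01)
})

test_that("single-press contribution is symmetric about the press", {
  s <- magnitude_series(list(press_train("p", "A", 30000)),
                        duration_ms = 60000)
  d <- seq(100, 5000, by = 100)
  expect_equal(magnitude_at(s, 30000 - d), magnitude_at(s, 30000 + d))
})

test_that("exclude_participant equals physically deleting the participant", {
  set.seed(7)
  trains <- lapply(1:4, function(i)
    press_train(paste0("p", i), "A", runif(5, 0, 30000)))
  names(trains) <- paste0("p", 1:4)
  a <- magnitude_series(trains, exclude_participant = "p2",
                        duration_ms = 30000)
  b <- magnitude_series(trains[-2], duration_ms = 30000)
  expect_identical(a$values, b$values)
  expect_identical(a$n_participants_normalizer, 3L)
  expect_error(magnitude_series(trains["p1"], exclude_participant = "p1"),
               "no participants")
})

test_that("identical press trains across groups give zero difference scores", {
  presses <- c(5000, 12000, 20000)
  cohort <- c(lapply(1:4, function(i) press_train(paste0("A", i), "A",
                                                  presses)),
              lapply(1:4, function(i) press_train(paste0("B", i), "B",
                                                  presses)))
  sc <- segmentation_difference_scores(cohort)
  expect_equal(sc$score, rep(0, 8))
  expect_equal(attr(sc, "M"), 0)
})

test_that("zero-press participants are reported, not scored", {
  cohort <- list(press_train("A1", "A", c(1000, 2000)),
                 press_train("A2", "A", c(1500)),
                 press_train("A3", "A", numeric(0)),
                 press_train("B1", "B", c(1200)),
                 press_train("B2", "B", c(2500)))
  sc <- segmentation_difference_scores(cohort)
  expect_false("A3" %in% sc$participant_id)
  expect_identical(attr(sc, "dropped_participants"), "A3")
})

test_that("a lone shared press time is detected as the single boundary", {
  cohort <- lapply(1:6, function(i)
    press_train(paste0("p", i), "A", 100000))
  bs <- detect_boundaries(cohort, n_permutations = 200, seed = 1,
                          duration_ms = 300000)
  expect_equal(bs$times_ms, 100000)
})

test_that("null exceedance of the permutation threshold is near alpha", {
  set.seed(99)
  trains <- lapply(1:20, function(i)
    press_train(paste0("P", i), "A", runif(20, 0, 600e3)))
  bs <- detect_boundaries(trains, n_permutations = 500, seed = 3,
                          duration_ms = 600e3)
  exc <- mean(bs$series$values > bs$threshold)
  expect_gt(exc, 0.02)
  expect_lt(exc, 0.09)
})

test_that("permutation threshold is non-increasing in alpha", {
  set.seed(5)
  trains <- lapply(1:8, function(i)
    press_train(paste0("p", i), "A", runif(10, 0, 120e3)))
  th <- sapply(c(0.01, 0.05, 0.2), function(a)
    detect_boundaries(trains, n_permutations = 200, alpha = a, seed = 2,
                      duration_ms = 120e3)$threshold)
  expect_true(all(diff(th) <= 0))
})

test_that("latent boundaries are recovered from a realistic press cohort", {
  cfg <- cohort_config(n_group_a = 15, n_group_b = 15, duration_s = 620,
                       boundary_times_s = seq(15, 600, length.out = 20),
                       press_prob = 0.8, seed = 11)
  pc <- generate_press_cohort(cfg)
  bs <- detect_boundaries(pc, n_permutations = 300, seed = 11)
  hits <- sapply(cfg$boundary_times_s * 1000,
                 function(b) any(abs(bs$times_ms - b) <= 2000))
  expect_gte(mean(hits), 0.8)
  # reported boundaries respect the minimum separation
  if (length(bs$times_ms) > 1)
    expect_true(all(diff(bs$times_ms) >= bs$min_separation_ms))
})

test_that("boundary detection validates its inputs", {
  expect_error(detect_boundaries(list(press_train("p", "A", numeric(0))),
                                 n_permutations = 200), "no presses")
  expect_error(detect_boundaries(list(press_train("p", "A", 1000)),
                                 n_permutations = 50), "at least 200")
})
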