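test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(n_group_a = 0), "group sizes")
  expect_error(cohort_config(duration_s = -1), "duration")
  expect_error(cohort_config(dropout_rate = 1.2), "dropout_rate")
  expect_error(cohort_config(duration_s = 30,
                             boundary_times_s = c(5, 35)),
               "strictly inside")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("noise-free unbiased gaze equals the shared attractor exactly", {
  cfg <- cohort_config(n_group_a = 3, n_group_b = 3, duration_s = 5,
                       gaze_noise_sd = 0, indiv_offset_sd = 0,
                       group_bias_px = 0, dropout_rate = 0, seed = 3)
  cohort <- generate_gaze_cohort(cfg)
  att <- attr(cohort, "attractor")
  for (tr in cohort) {
    expect_identical(tr$x, att$x)
    expect_identical(tr$y, att$y)
    expect_true(all(tr$valid))
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- cohort_config(n_group_a = 3, n_group_b = 3, duration_s = 10,
                       seed = 7)
  expect_identical(generate_gaze_cohort(cfg), generate_gaze_cohort(cfg))
  expect_identical(generate_press_cohort(cfg), generate_press_cohort(cfg))
  items <- make_memory_items(10, cfg)
  expect_identical(items, make_memory_items(10, cfg))
  expect_identical(
    generate_memory_responses(items, cfg$boundary_times_s, cfg),
    generate_memory_responses(items, cfg$boundary_times_s, cfg))
  cfg2 <- cohort_config(n_group_a = 3, n_group_b = 3, duration_s = 10,
                        seed = 8)
  expect_false(identical(generate_gaze_cohort(cfg),
                         generate_gaze_cohort(cfg2)))
})

test_that("group gaze bias is recovered as the between-group x displacement", {
  cfg <- cohort_config(n_group_a = 10, n_group_b = 10, duration_s = 60,
                       gaze_noise_sd = 20, indiv_offset_sd = 0,
                       group_bias_px = 200, dropout_rate = 0, seed = 21)
  cohort <- generate_gaze_cohort(cfg)
  mx <- function(g) mean(unlist(lapply(cohort, function(tr)
    if (tr$group == g) tr$x)))
  # clipping at the screen edge can shave a few px off the injected 200
  expect_equal(mx("B") - mx("A"), 200, tolerance = 0.03)
})

test_that("null worlds are exchangeable across group labels", {
  diffs <- sapply(1:20, function(s) {
    cfg <- cohort_config(n_group_a = 5, n_group_b = 5, duration_s = 10,
                         group_bias_px = 0, seed = s)
    cohort <- generate_gaze_cohort(cfg)
    mx <- function(g) mean(unlist(lapply(cohort, function(tr)
      if (tr$group == g) tr$x)))
    mx("B") - mx("A")
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("press trains hit every boundary when press_prob=1 and jitter=0", {
  cfg <- cohort_config(n_group_a = 4, n_group_b = 4, duration_s = 100,
                       boundary_times_s = c(10, 30, 50, 70, 90),
                       press_prob = 1, press_jitter_sd_s = 0,
                       spurious_rate_hz = 0, seed = 5)
  pc <- generate_press_cohort(cfg)
  for (tr in pc) expect_equal(tr$times_ms, cfg$boundary_times_s * 1000)

  cfg0 <- cohort_config(n_group_a = 4, n_group_b = 4, duration_s = 100,
                        boundary_times_s = c(10, 30, 50, 70, 90),
                        press_prob = 0, spurious_rate_hz = 0, seed = 5)
  for (tr in generate_press_cohort(cfg0))
    expect_length(tr$times_ms, 0)
})

test_that("boundary-locked press counts match the binomial expectation", {
  cfg <- cohort_config(n_group_a = 15, n_group_b = 15, duration_s = 630,
                       boundary_times_s = seq(15, 615, length.out = 20),
                       press_prob = 0.8, press_jitter_sd_s = 0.2,
                       spurious_rate_hz = 0, seed = 13)
  pc <- generate_press_cohort(cfg)
  total <- sum(sapply(pc, function(tr) length(tr$times_ms)))
  # Binomial(600, 0.8): mean 480, sd ~9.8; allow 4 sd
  expect_lt(abs(total - 480), 40)
})

test_that("group-specific boundaries are pressed only by their group", {
  cfg <- cohort_config(n_group_a = 6, n_group_b = 6, duration_s = 200,
                       boundary_times_s = seq(10, 190, by = 10),
                       press_prob = 1, press_jitter_sd_s = 0,
                       spurious_rate_hz = 0,
                       group_specific_boundaries = 0.5, seed = 2)
  pc <- generate_press_cohort(cfg)
  vis <- attr(pc, "visibility")
  expect_equal(sum(vis$visible_to != "both"), 10)  # round(0.5 * 19), half-to-even
  for (tr in pc) {
    allowed <- vis$time_s[vis$visible_to %in% c("both", tr$group)] * 1000
    expect_true(all(tr$times_ms %in% allowed))
  }
})

test_that("memory responses are all correct in the degenerate accuracy world", {
  cfg <- cohort_config(n_group_a = 3, n_group_b = 3, duration_s = 100,
                       boundary_times_s = c(20, 60),
                       accuracy_base = 1, accuracy_slope = 0, seed = 4)
  items <- make_memory_items(10, cfg)
  resp <- generate_memory_responses(items, cfg$boundary_times_s, cfg)
  merged <- merge(resp, items)
  expect_true(all(merged$answer == merged$correct_answer))
  expect_true(all(resp$confidence %in% 1:5))
})

test_that("items outside the stimulus are rejected", {
  cfg <- cohort_config(duration_s = 100, boundary_times_s = c(50), seed = 1)
  items <- data.frame(item_id = "x", probe_time_s = 150,
                      content_group = "A", correct_answer = "yes")
  expect_error(generate_memory_responses(items, c(50), cfg),
               "within the stimulus duration")
})

test_that("confidence own-group bias is recovered and absent when zero", {
  run <- function(bias, seed) {
    cfg <- cohort_config(n_group_a = 15, n_group_b = 15, duration_s = 300,
                         boundary_times_s = seq(10, 290, by = 15),
                         confidence_bias = bias, seed = seed)
    items <- make_memory_items(52, cfg)
    resp <- generate_memory_responses(items, cfg$boundary_times_s, cfg)
    own <- resp$group == items$content_group[match(resp$item_id,
                                                   items$item_id)]
    mean(resp$confidence[own]) - mean(resp$confidence[!own])
  }
  null_diffs <- sapply(1:5, function(s) run(0, s))
  expect_lt(max(abs(null_diffs)), 0.1)
  rec <- mean(sapply(1:5, function(s) run(0.8, s)))
  expect_equal(rec, 0.8, tolerance = 0.1)
})
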