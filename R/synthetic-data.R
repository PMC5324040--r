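# Synthetic cohorts with known ground truth: shared-attractor gaze, boundary-
# locked press trains, and boundary-distance-dependent memory responses.

#' Construct a single gaze track
#'
#' @param participant_id Participant identifier.
#' @param group Group label.
#' @param time_ms Strictly increasing sample times, ms from stimulus onset.
#' @param x,y Gaze coordinates in pixels.
#' @param valid Logical validity flags (same length as `time_ms`).
#' @param nominal_rate_hz Nominal sampling rate.
#' @param calibration_error_deg Calibration accuracy metadata, degrees.
#' @return A `gaze_track` object.
#' @export
gaze_track <- function(participant_id, group, time_ms, x, y,
                       valid = rep(TRUE, length(time_ms)),
                       nominal_rate_hz = NA_real_,
                       calibration_error_deg = NA_real_) {
  n <- length(time_ms)
  stopifnot(length(x) == n, length(y) == n, length(valid) == n)
  if (n == 0L) stop_config("gaze track must contain at least one sample")
  if (is.unsorted(time_ms, strictly = TRUE))
    stop_config("gaze sample times must be strictly increasing")
  structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         time_ms = as.numeric(time_ms), x = as.numeric(x), y = as.numeric(y),
         valid = as.logical(valid),
         nominal_rate_hz = nominal_rate_hz,
         calibration_error_deg = calibration_error_deg),
    class = "gaze_track")
}

#' @export
print.gaze_track <- function(x, ...) {
  cat(sprintf(
    "Gaze track %s (group %s): %d samples @ %g Hz, %.1f%% valid\n",
    x$participant_id, x$group, length(x$time_ms), x$nominal_rate_hz,
    100 * mean(x$valid)))
  invisible(x)
}

# Ornstein-Uhlenbeck-style smooth random walk, reflected into [lo, hi].
# Mimics ball-following gaze with a single smoothness knob (the correlation
# time tau); stationary SD is an eighth of the axis extent.
ou_trajectory <- function(n, dt_s, tau_s, lo, hi) {
  mu <- (lo + hi) / 2
  sd_stat <- (hi - lo) / 8
  phi <- exp(-dt_s / tau_s)
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  z <- rnorm(n, 0, 1)
  x <- numeric(n)
  x[1] <- mu + sd_stat * z[1]
  for (i in seq_len(n)[-1]) {
    x[i] <- mu + phi * (x[i - 1] - mu) + innov_sd * z[i]
  }
  reflect_into(x, lo, hi)
}

participant_ids <- function(cfg) {
  c(sprintf("%s%02d", cfg$group_labels[1], seq_len(cfg$n_group_a)),
    sprintf("%s%02d", cfg$group_labels[2], seq_len(cfg$n_group_b)))
}

participant_groups <- function(cfg) {
  rep(cfg$group_labels, c(cfg$n_group_a, cfg$n_group_b))
}

#' Generate a synthetic gaze cohort
#'
#' All participants follow one shared smooth attractor trajectory. Each
#' participant carries a stable idiosyncratic offset (SD `indiv_offset_sd`
#' per axis, drawn once), group B additionally receives a horizontal
#' offset of `group_bias_px`, every sample gets white noise of SD
#' `gaze_noise_sd`, positions are clipped to the screen, and a fraction
#' `dropout_rate` of samples is flagged invalid.
#'
#' @param config A [cohort_config()].
#' @return A `gaze_cohort`: list of [gaze_track()] objects with the shared
#'   attractor stored in `attr(, "attractor")`.
#' @examples
#' cohort <- generate_gaze_cohort(cohort_config(n_group_a = 3, n_group_b = 3,
#'                                              duration_s = 5, seed = 42))
#' length(cohort)
#' @export
generate_gaze_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    dt_s <- 1 / config$sample_rate_hz
    n <- floor(config$duration_s * config$sample_rate_hz) + 1L
    time_ms <- (seq_len(n) - 1L) * (1000 / config$sample_rate_hz)
    ax <- ou_trajectory(n, dt_s, config$attractor_smoothness,
                        0, config$screen_w)
    ay <- ou_trajectory(n, dt_s, config$attractor_smoothness,
                        0, config$screen_h)
    ids <- participant_ids(config)
    groups <- participant_groups(config)
    tracks <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      bias <- if (groups[i] == config$group_labels[2]) config$group_bias_px
              else 0
      off <- rnorm(2, 0, config$indiv_offset_sd)
      x <- ax + bias + off[1]
      y <- ay + off[2]
      if (config$gaze_noise_sd > 0) {
        x <- x + rnorm(n, 0, config$gaze_noise_sd)
        y <- y + rnorm(n, 0, config$gaze_noise_sd)
      }
      x <- pmin(pmax(x, 0), config$screen_w)
      y <- pmin(pmax(y, 0), config$screen_h)
      valid <- if (config$dropout_rate > 0) {
        runif(n) >= config$dropout_rate
      } else rep(TRUE, n)
      tracks[[i]] <- gaze_track(ids[i], groups[i], time_ms, x, y, valid,
                                nominal_rate_hz = config$sample_rate_hz,
                                calibration_error_deg = 0.5)
    }
    names(tracks) <- ids
    structure(tracks, class = "gaze_cohort",
              attractor = data.frame(time_ms = time_ms, x = ax, y = ay),
              config = config)
  })
}

#' @export
print.gaze_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("Gaze cohort: %d tracks (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

# Assign each latent boundary to "both" groups or, for a fraction
# group_specific_boundaries, to exactly one group (alternating A/B among a
# seeded sample of boundaries).
boundary_visibility <- function(config) {
  k <- length(config$boundary_times_s)
  vis <- rep("both", k)
  n_spec <- round(config$group_specific_boundaries * k)
  if (n_spec > 0) {
    idx <- sample.int(k, n_spec)
    vis[idx] <- rep(config$group_labels, length.out = n_spec)
  }
  vis
}

#' Construct a press train
#'
#' @param participant_id Participant identifier.
#' @param group Group label.
#' @param times_ms Sorted press timestamps in ms; duplicates collapsed.
#' @return A `press_train` object.
#' @export
press_train <- function(participant_id, group, times_ms) {
  times_ms <- sort(unique(as.numeric(times_ms)))
  structure(list(participant_id = as.character(participant_id),
                 group = as.character(group), times_ms = times_ms),
            class = "press_train")
}

#' Generate a synthetic press cohort
#'
#' Each participant marks each latent boundary visible to their group with
#' probability `press_prob`, at the boundary time plus Gaussian jitter, and
#' additionally emits spurious presses from a homogeneous Poisson process.
#' Presses are clipped to the stimulus and sorted.
#'
#' @param config A [cohort_config()].
#' @return A `press_cohort`: list of `press_train` objects, with the
#'   boundary visibility table in `attr(, "visibility")`.
#' @export
generate_press_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, 2L), {
    vis <- boundary_visibility(config)
    ids <- participant_ids(config)
    groups <- participant_groups(config)
    dur_ms <- config$duration_s * 1000
    trains <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      b <- config$boundary_times_s[vis == "both" | vis == groups[i]]
      hit <- b[runif(length(b)) < config$press_prob]
      presses <- hit * 1000 +
        rnorm(length(hit), 0, config$press_jitter_sd_s * 1000)
      n_spur <- rpois(1, config$spurious_rate_hz * config$duration_s)
      presses <- c(presses, runif(n_spur, 0, dur_ms))
      presses <- presses[presses >= 0 & presses <= dur_ms]
      trains[[i]] <- press_train(ids[i], groups[i], presses)
    }
    names(trains) <- ids
    structure(trains, class = "press_cohort",
              visibility = data.frame(time_s = config$boundary_times_s,
                                      visible_to = vis),
              config = config)
  })
}

#' @export
print.press_cohort <- function(x, ...) {
  n_press <- vapply(x, function(tr) length(tr$times_ms), integer(1))
  cat(sprintf("Press cohort: %d participants, %d presses total (median %g per participant)\n",
              length(x), sum(n_press), stats::median(n_press)))
  invisible(x)
}

#' Generate a synthetic memory-item table
#'
#' Items probe central moments of the stimulus: each has a probe time, a
#' content-group label (which team the probed event belongs to) and a
#' yes/no correct answer.
#'
#' @param n_items Number of items.
#' @param config A [cohort_config()] supplying duration, labels and seed.
#' @return A data.frame with columns `item_id`, `probe_time_s`,
#'   `content_group`, `correct_answer`.
#' @export
make_memory_items <- function(n_items, config) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, 3L), {
    data.frame(
      item_id = sprintf("item%02d", seq_len(n_items)),
      probe_time_s = sort(runif(n_items, 1, config$duration_s - 1)),
      content_group = sample(config$group_labels, n_items, replace = TRUE),
      correct_answer = sample(c("yes", "no"), n_items, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic memory responses
#'
#' For every participant and item, the probability of a correct answer is a
#' decreasing logistic function of the item's forward distance to the next
#' event boundary; it contains no own-group term, so accuracy is unbiased
#' by construction. Confidence is drawn on a latent continuous scale with
#' an additive own-group bias (`confidence_bias`) and rounded/clipped to
#' the integer scale 1-5.
#'
#' @param items Item table as from [make_memory_items()].
#' @param boundaries A [boundary_set] or numeric vector of boundary times
#'   in seconds; used to compute each item's boundary distance.
#' @param config A [cohort_config()].
#' @param test_times Character vector of test occasions to simulate.
#' @param delayed_logit_drop Log-odds penalty applied to accuracy at any
#'   test occasion other than the first (default 0).
#' @return A data.frame with one row per participant x item x test time:
#'   `participant_id`, `group`, `item_id`, `test_time`, `answer`,
#'   `confidence`.
#' @export
generate_memory_responses <- function(items, boundaries, config,
                                      test_times = c("immediate", "delayed"),
                                      delayed_logit_drop = 0) {
  validate_cohort_config(config)
  if (any(items$probe_time_s < 0 | items$probe_time_s > config$duration_s))
    stop_config("item probe times must lie within the stimulus duration")
  bt_s <- boundary_times_s(boundaries)
  d <- boundary_distance(items$probe_time_s, bt_s)
  dist_s <- d$distance_s
  dist_s[is.na(dist_s)] <- max(dist_s, na.rm = TRUE)

  p_correct <- function(distance, occasion_idx) {
    drop <- if (occasion_idx > 1L) delayed_logit_drop else 0
    if (config$accuracy_slope == 0 && drop == 0 && config$accuracy_base >= 1)
      return(rep(1, length(distance)))
    base <- min(max(config$accuracy_base, 1e-12), 1 - 1e-12)
    stats::plogis(stats::qlogis(base) - config$accuracy_slope * distance - drop)
  }

  ids <- participant_ids(config)
  groups <- participant_groups(config)
  with_seed(derive_seed(config$seed, 4L), {
    rows <- vector("list", length(ids) * length(test_times))
    k <- 0L
    for (i in seq_along(ids)) {
      own <- items$content_group == groups[i]
      for (j in seq_along(test_times)) {
        p <- p_correct(dist_s, j)
        correct <- runif(nrow(items)) < p
        answer <- ifelse(correct, items$correct_answer,
                         ifelse(items$correct_answer == "yes", "no", "yes"))
        latent <- config$confidence_base +
          config$confidence_bias * own +
          rnorm(nrow(items), 0, config$confidence_noise_sd)
        confidence <- pmin(5L, pmax(1L, as.integer(round(latent))))
        k <- k + 1L
        rows[[k]] <- data.frame(
          participant_id = ids[i], group = groups[i],
          item_id = items$item_id, test_time = test_times[j],
          answer = answer, confidence = confidence,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
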