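# Fixture builders shared across test files. All data are generated in
# code; nothing is read from disk.

# Cohort in which every participant's gaze is the same constant position.
constant_gaze_cohort <- function(n_per_group = 5, pos = c(640, 512),
                                 duration_s = 2, rate = 60,
                                 groups = c("A", "B")) {
  t_ms <- seq(0, duration_s * 1000, by = 1000 / rate)
  tracks <- list()
  for (g in groups) for (i in seq_len(n_per_group)) {
    id <- sprintf("%s%02d", g, i)
    tracks[[id]] <- gaze_track(id, g, t_ms,
                               rep(pos[1], length(t_ms)),
                               rep(pos[2], length(t_ms)),
                               nominal_rate_hz = rate)
  }
  structure(tracks, class = "gaze_cohort", screen_w = 1280, screen_h = 1024)
}

# Small random cohort for oracle comparisons (no generator involvement).
random_gaze_cohort <- function(n_per_group = 3, duration_s = 2, rate = 60,
                               seed = 1, screen = c(100, 80),
                               dropout = 0) {
  set.seed(seed)
  t_ms <- seq(0, duration_s * 1000, by = 1000 / rate)
  tracks <- list()
  for (g in c("A", "B")) for (i in seq_len(n_per_group)) {
    id <- sprintf("%s%02d", g, i)
    valid <- if (dropout > 0) runif(length(t_ms)) >= dropout
             else rep(TRUE, length(t_ms))
    tracks[[id]] <- gaze_track(id, g, t_ms,
                               runif(length(t_ms), 0, screen[1]),
                               runif(length(t_ms), 0, screen[2]),
                               valid, nominal_rate_hz = rate)
  }
  structure(tracks, class = "gaze_cohort",
            screen_w = screen[1], screen_h = screen[2])
}

# Straight-line NSS reimplementation through the exported map primitives:
# gather valid reference samples at each step, build + normalize the map,
# read the participant's gaze. Used as the oracle for the fast engine.
naive_nss_timecourse <- function(cohort, participant, ref_ids, step_ms,
                                 min_refs, sigma_px, downsample) {
  scr <- c(attr(cohort, "screen_w"), attr(cohort, "screen_h"))
  target <- cohort[[participant]]
  dur <- max(sapply(cohort, function(tr) max(tr$time_ms)))
  steps <- seq(0, dur, by = step_ms)
  period <- 1000 / target$nominal_rate_hz
  sample_at <- function(tr, t) {
    k <- round(t / period) + 1
    if (k < 1 || k > length(tr$time_ms)) return(NULL)
    if (abs(tr$time_ms[k] - t) > 20 + 1e-9) return(NULL)
    list(x = tr$x[k], y = tr$y[k], valid = tr$valid[k])
  }
  out <- rep(NA_real_, length(steps))
  reason <- rep("ok", length(steps))
  for (si in seq_along(steps)) {
    refs <- list()
    for (rid in ref_ids) {
      s <- sample_at(cohort[[rid]], steps[si])
      if (!is.null(s) && s$valid) refs[[length(refs) + 1]] <- c(s$x, s$y)
    }
    tg <- sample_at(target, steps[si])
    if (is.null(tg) || !tg$valid) {
      reason[si] <- "invalid_gaze"
      next
    }
    if (length(refs) < min_refs) {
      reason[si] <- "insufficient_refs"
      next
    }
    m <- build_fixation_map(do.call(rbind, refs), scr[1], scr[2],
                            sigma_px, downsample)
    m <- normalize_map(m)
    if (!m$valid) {
      reason[si] <- "constant_map"
      next
    }
    out[si] <- nss_value(m, c(tg$x, tg$y))
  }
  list(time_ms = steps, nss = out, reason = reason)
}

# Study conditions used by the simulation-based checks: desk-scale null /
# biased gaze worlds.
gaze_world <- function(seed, bias_px = 0, n = 8, duration_s = 90) {
  cohort_config(n_group_a = n, n_group_b = n, duration_s = duration_s,
                gaze_noise_sd = 40, indiv_offset_sd = 50,
                dropout_rate = 0.05, group_bias_px = bias_px, seed = seed)
}

press_world <- function(seed, gsb = 0, n = 15, duration_s = 300) {
  cohort_config(n_group_a = n, n_group_b = n, duration_s = duration_s,
                boundary_times_s = seq(10, 290, by = 15),
                group_specific_boundaries = gsb, seed = seed)
}

gaze_world_M_p <- function(seed, bias_px = 0) {
  cfg <- gaze_world(seed, bias_px)
  sc <- nss_difference_scores(generate_gaze_cohort(cfg), downsample = 32,
                              seed = seed)
  tt <- one_sample_t(sc$score)
  c(M = attr(sc, "M"), p = tt$p, t = tt$t, n = tt$n)
}
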