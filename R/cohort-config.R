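#' Configuration of a synthetic two-group viewing cohort
#'
#' Bundles every knob of the synthetic-data generators: two groups of
#' observers watch one shared stimulus; gaze follows a common smooth
#' attractor trajectory with optional group-specific spatial bias and
#' sample dropout; button presses are locked to latent event boundaries
#' with jitter and spurious presses, optionally with boundaries visible to
#' only one group; memory accuracy declines with boundary distance while
#' confidence may carry an own-group bias that accuracy, by construction,
#' never has.
#'
#' With `group_bias_px = 0`, `group_specific_boundaries = 0` and
#' `confidence_bias = 0` the configuration describes a null world in which
#' the two group labels are exchangeable.
#'
#' @param n_group_a,n_group_b Number of participants per group (> 0).
#' @param duration_s Stimulus duration in seconds.
#' @param screen_w,screen_h Screen size in pixels.
#' @param attractor_smoothness Correlation time (seconds) of the shared
#'   attractor trajectory; larger values give smoother pursuit-like gaze.
#' @param gaze_noise_sd Per-sample white gaze noise, pixels.
#' @param indiv_offset_sd SD (pixels) of each participant's stable
#'   idiosyncratic gaze offset, drawn once per participant per axis.
#'   Captures persistent between-observer differences in where people
#'   look; the between-participant variance that group-level t-tests
#'   rest on comes from this term.
#' @param group_bias_px Horizontal offset (pixels) added to group B's gaze;
#'   0 gives a null world.
#' @param dropout_rate Fraction of samples flagged invalid, i.i.d.
#' @param sample_rate_hz Gaze sampling rate in Hz.
#' @param boundary_times_s Latent event-boundary timestamps, strictly
#'   inside (0, duration_s).
#' @param press_prob Probability a participant marks any one boundary.
#' @param press_jitter_sd_s SD (seconds) of Gaussian press jitter.
#' @param spurious_rate_hz Poisson rate of non-boundary presses.
#' @param group_specific_boundaries Fraction of boundaries visible to only
#'   one group (0 = null world).
#' @param accuracy_base Probability of a correct memory response at zero
#'   boundary distance.
#' @param accuracy_slope Decline of correct-response log-odds per second of
#'   boundary distance (>= 0).
#' @param confidence_base Mean of the latent confidence scale (1-5 units).
#' @param confidence_bias Additive own-group shift of latent confidence,
#'   in scale points; 0 = null.
#' @param confidence_noise_sd SD of latent confidence noise.
#' @param group_labels Two distinct group labels.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce byte-identical cohorts.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_group_a = 6, n_group_b = 6, duration_s = 30)
#' cfg$boundary_times_s
#' @export
cohort_config <- function(n_group_a = 10L,
                          n_group_b = 10L,
                          duration_s = 60,
                          screen_w = 1280L,
                          screen_h = 1024L,
                          attractor_smoothness = 1.5,
                          gaze_noise_sd = 30,
                          indiv_offset_sd = 50,
                          group_bias_px = 0,
                          dropout_rate = 0.05,
                          sample_rate_hz = 60,
                          boundary_times_s = NULL,
                          press_prob = 0.8,
                          press_jitter_sd_s = 0.5,
                          spurious_rate_hz = 0.01,
                          group_specific_boundaries = 0,
                          accuracy_base = 0.9,
                          accuracy_slope = 0.02,
                          confidence_base = 3,
                          confidence_bias = 0,
                          confidence_noise_sd = 0.7,
                          group_labels = c("A", "B"),
                          seed = 1L) {
  if (is.null(boundary_times_s)) {
    boundary_times_s <- seq(duration_s / 10, duration_s * 0.95,
                            length.out = max(2L, round(duration_s / 20)))
  }
  cfg <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    duration_s = duration_s, screen_w = screen_w, screen_h = screen_h,
    attractor_smoothness = attractor_smoothness,
    gaze_noise_sd = gaze_noise_sd, indiv_offset_sd = indiv_offset_sd,
    group_bias_px = group_bias_px,
    dropout_rate = dropout_rate, sample_rate_hz = sample_rate_hz,
    boundary_times_s = sort(boundary_times_s),
    press_prob = press_prob, press_jitter_sd_s = press_jitter_sd_s,
    spurious_rate_hz = spurious_rate_hz,
    group_specific_boundaries = group_specific_boundaries,
    accuracy_base = accuracy_base, accuracy_slope = accuracy_slope,
    confidence_base = confidence_base, confidence_bias = confidence_bias,
    confidence_noise_sd = confidence_noise_sd,
    group_labels = as.character(group_labels),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_group_a <= 0L || cfg$n_group_b <= 0L)
    stop_config("group sizes must be positive (got %d, %d)",
                cfg$n_group_a, cfg$n_group_b)
  if (!is.finite(cfg$duration_s) || cfg$duration_s <= 0)
    stop_config("duration_s must be positive")
  if (cfg$screen_w <= 0 || cfg$screen_h <= 0)
    stop_config("screen dimensions must be positive")
  if (cfg$sample_rate_hz <= 0)
    stop_config("sample_rate_hz must be positive")
  if (cfg$attractor_smoothness <= 0)
    stop_config("attractor_smoothness must be positive")
  for (p in c("dropout_rate", "press_prob", "group_specific_boundaries")) {
    v <- cfg[[p]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop_config("%s must lie in [0, 1] (got %g)", p, v)
  }
  if (cfg$indiv_offset_sd < 0)
    stop_config("indiv_offset_sd must be non-negative")
  if (cfg$gaze_noise_sd < 0 || cfg$press_jitter_sd_s < 0 ||
      cfg$spurious_rate_hz < 0 || cfg$confidence_noise_sd < 0)
    stop_config("noise SDs and rates must be non-negative")
  if (cfg$accuracy_slope < 0)
    stop_config("accuracy_slope must be non-negative")
  if (cfg$accuracy_base < 0 || cfg$accuracy_base > 1)
    stop_config("accuracy_base must lie in [0, 1]")
  if (length(cfg$group_labels) != 2L ||
      anyDuplicated(cfg$group_labels))
    stop_config("group_labels must be two distinct labels")
  b <- cfg$boundary_times_s
  if (length(b) && (any(b <= 0) || any(b >= cfg$duration_s)))
    stop_config("boundary_times_s must lie strictly inside (0, duration_s)")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  groups: %s (n=%d), %s (n=%d); duration %g s @ %g Hz\n",
              x$group_labels[1], x$n_group_a, x$group_labels[2],
              x$n_group_b, x$duration_s, x$sample_rate_hz))
  cat(sprintf(
    "  gaze: noise %g px, individual offset %g px, group bias %g px, dropout %.1f%%\n",
    x$gaze_noise_sd, x$indiv_offset_sd, x$group_bias_px,
    100 * x$dropout_rate))
  cat(sprintf(
    "  presses: %d boundaries, p(press) %g, jitter %g s, spurious %g Hz, group-specific %g\n",
    length(x$boundary_times_s), x$press_prob, x$press_jitter_sd_s,
    x$spurious_rate_hz, x$group_specific_boundaries))
  cat(sprintf("  memory: base acc %g, slope %g /s, conf bias %g; seed %d\n",
              x$accuracy_base, x$accuracy_slope, x$confidence_bias, x$seed))
  invisible(x)
}
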