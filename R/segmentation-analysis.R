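# Event-segmentation agreement: kernel-smoothed press magnitude, leave-one-
# out cross-group difference scores, and permutation-based event boundaries.

press_times_list <- function(trains) {
  lapply(trains, function(tr) {
    if (inherits(tr, "press_train")) tr$times_ms else as.numeric(tr)
  })
}

# Sum of unit-peak Gaussians around press times, evaluated at `at_ms`.
# Exact (no kernel truncation).
gauss_sum_exact <- function(presses_ms, at_ms, sd_ms) {
  if (length(presses_ms) == 0L) return(numeric(length(at_ms)))
  colSums(exp(-outer(presses_ms, at_ms, "-")^2 / (2 * sd_ms^2)))
}

# Same sum on a uniform grid, accumulating each press only within
# +/- 10 SD (exp(-50) ~ 2e-22: exact to double precision), so the cost is
# linear in presses rather than presses x grid.
gauss_sum_grid <- function(presses_ms, grid_ms, step_ms, sd_ms) {
  n <- length(grid_ms)
  if (length(presses_ms) == 0L) return(numeric(n))
  K <- ceiling(10 * sd_ms / step_ms)
  if (n <= 2L * K + 1L || length(presses_ms) * 1.0 * n < 2e6) {
    return(gauss_sum_exact(presses_ms, grid_ms, sd_ms))
  }
  base_idx <- round((presses_ms - grid_ms[1]) / step_ms) + 1L
  offs <- -K:K
  idx <- outer(offs, base_idx, "+")
  tt <- grid_ms[1] + (idx - 1L) * step_ms
  w <- exp(-sweep(tt, 2, presses_ms, "-")^2 / (2 * sd_ms^2))
  keep <- idx >= 1L & idx <= n
  out <- numeric(n)
  acc <- rowsum(w[keep], idx[keep])
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Segmentation magnitude series of a set of press trains
#'
#' Around every button press a unit-peak Gaussian (`kernel_sd_ms`, default
#' 1000 ms) is placed; the per-time sum over all included participants'
#' presses is divided by the number of included participants. The result
#' is interpretable as expected per-participant agreement: if every
#' participant presses at the same instant the series equals 1 there.
#'
#' @param trains A `press_cohort`, list of `press_train`s, or list of
#'   numeric press-time vectors (ms).
#' @param kernel_sd_ms Gaussian kernel SD in ms (default 1000).
#' @param exclude_participant Optional participant id (or list index)
#'   excluded before summing, for leave-one-out scoring.
#' @param grid_step_ms Evaluation grid step in ms (default 100).
#' @param duration_ms Stimulus duration; default spans the last press.
#' @return A `magnitude_series`: `time_ms`, `values` on the grid, the
#'   kernel SD, the participant normalizer, and the included press times
#'   (so [magnitude_at()] can evaluate exactly at arbitrary times).
#' @export
magnitude_series <- function(trains, kernel_sd_ms = 1000,
                             exclude_participant = NULL,
                             grid_step_ms = 100, duration_ms = NULL) {
  ids <- names(trains)
  if (is.null(ids))
    ids <- vapply(seq_along(trains), function(i) {
      tr <- trains[[i]]
      if (inherits(tr, "press_train")) tr$participant_id else as.character(i)
    }, character(1))
  keep <- rep(TRUE, length(trains))
  if (!is.null(exclude_participant))
    keep <- !(ids %in% as.character(exclude_participant))
  if (!any(keep))
    stop_config("no participants left after exclusion")
  times <- press_times_list(trains)[keep]
  n_inc <- sum(keep)
  presses <- sort(unlist(times, use.names = FALSE))
  if (is.null(duration_ms))
    duration_ms <- if (length(presses)) max(presses) else 0
  grid <- seq(0, duration_ms, by = grid_step_ms)
  values <- gauss_sum_grid(presses, grid, grid_step_ms, kernel_sd_ms) / n_inc
  structure(list(time_ms = grid, values = values,
                 kernel_sd_ms = kernel_sd_ms,
                 n_participants_normalizer = n_inc,
                 presses_ms = presses, duration_ms = duration_ms,
                 grid_step_ms = grid_step_ms),
            class = "magnitude_series")
}

#' Evaluate a magnitude series exactly at arbitrary times
#'
#' @param series A [magnitude_series()].
#' @param at_ms Numeric vector of times in ms.
#' @return Magnitude values (exact analytic evaluation, not grid lookup).
#' @export
magnitude_at <- function(series, at_ms) {
  stopifnot(inherits(series, "magnitude_series"))
  gauss_sum_exact(series$presses_ms, at_ms, series$kernel_sd_ms) /
    series$n_participants_normalizer
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf(
    "Segmentation magnitude series: %d presses / %d participants, kernel SD %g ms, grid %g..%g ms (step %g)\n",
    length(x$presses_ms), x$n_participants_normalizer, x$kernel_sd_ms,
    min(x$time_ms), max(x$time_ms), x$grid_step_ms))
  invisible(x)
}

#' @export
plot.magnitude_series <- function(x, ..., boundaries = NULL) {
  graphics::plot(x$time_ms / 1000, x$values, type = "l",
                 xlab = "time (s)", ylab = "segmentation magnitude", ...)
  if (!is.null(boundaries)) {
    graphics::abline(v = boundary_times_s(boundaries), col = "red", lty = 2)
    graphics::abline(h = boundaries$threshold, col = "grey40", lty = 3)
  }
  invisible(x)
}

#' Same-group minus other-group segmentation difference scores
#'
#' At each of a participant's own press times, the own-group magnitude
#' (with that participant left out, normalized by the remaining n - 1
#' members, avoiding autocorrelation with their own presses) and the
#' other-group magnitude (normalized by that group's size) are evaluated
#' analytically. The per-press differences are averaged within
#' participant; a positive mean indicates segmentation more consistent
#' with one's own group.
#'
#' @param cohort A `press_cohort` or named list of `press_train`s covering
#'   exactly two groups.
#' @param kernel_sd_ms Gaussian kernel SD in ms (default 1000).
#' @return A `seg_scores` object: data.frame (`participant_id`, `group`,
#'   `score`, `n_presses`) with attributes `M`, `SD` and the ids of
#'   participants without presses (`dropped_participants`).
#' @export
segmentation_difference_scores <- function(cohort, kernel_sd_ms = 1000) {
  ids <- vapply(cohort, `[[`, character(1), "participant_id")
  groups <- vapply(cohort, `[[`, character(1), "group")
  glev <- unique(groups)
  if (length(glev) != 2L)
    stop_config("need exactly two groups, got: %s",
                paste(glev, collapse = ", "))
  times <- press_times_list(cohort)
  rows <- list()
  dropped <- character(0)
  for (i in seq_along(ids)) {
    own_presses <- times[[i]]
    if (length(own_presses) == 0L) {
      dropped <- c(dropped, ids[i])
      next
    }
    own_idx <- which(groups == groups[i])
    oth_idx <- which(groups != groups[i])
    own_pool <- sort(unlist(times[setdiff(own_idx, i)], use.names = FALSE))
    oth_pool <- sort(unlist(times[oth_idx], use.names = FALSE))
    m_own <- gauss_sum_exact(own_pool, own_presses, kernel_sd_ms) /
      (length(own_idx) - 1L)
    m_oth <- gauss_sum_exact(oth_pool, own_presses, kernel_sd_ms) /
      length(oth_idx)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = ids[i], group = groups[i],
      score = mean(m_own - m_oth), n_presses = length(own_presses),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop_config("no participant has any presses")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("seg_scores", "diff_scores", "data.frame"),
            M = mean(out$score), SD = stats::sd(out$score),
            kernel_sd_ms = kernel_sd_ms, dropped_participants = dropped)
}

boundary_times_s <- function(boundaries) {
  if (inherits(boundaries, "boundary_set")) boundaries$times_ms / 1000
  else as.numeric(boundaries)
}

# Strict-ish local maxima of v: first index of any plateau that is higher
# than both flanking values (series ends count as -Inf).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer(0))
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  # plateau handling: rise strictly from the left, no rise to the right
  which(v > left & v >= right)
}

#' Detect significant event boundaries by circular-shift permutation
#'
#' The observed pooled magnitude series is compared against a null built
#' by circularly shifting each participant's press train by an independent
#' uniform offset (wrapping at the stimulus duration) and recomputing the
#' pooled series. The shift preserves each participant's press count and
#' inter-press structure while destroying cross-participant alignment.
#' The threshold is the (1 - alpha) quantile of all pooled null values;
#' boundaries are local maxima of the observed series above it, greedily
#' thinned so that no two survive within `min_separation_ms` (higher peaks
#' win; equal peaks resolve to the earlier time).
#'
#' @param trains Press trains (cohort, list, or list of numeric ms).
#' @param n_permutations Number of circular-shift permutations (>= 200).
#' @param alpha Significance level of the null quantile (default 0.05).
#' @param min_separation_ms Minimum spacing of reported boundaries
#'   (default 2000 ms).
#' @param seed Seed for the permutation offsets.
#' @param kernel_sd_ms,grid_step_ms,duration_ms Passed to the magnitude
#'   computation (defaults 1000 ms kernel, 100 ms grid).
#' @return A `boundary_set`: boundary `times_ms`, `threshold`,
#'   `n_permutations`, `alpha`, plus the observed series for plotting.
#' @export
detect_boundaries <- function(trains, n_permutations = 1000, alpha = 0.05,
                              min_separation_ms = 2000, seed = 1L,
                              kernel_sd_ms = 1000, grid_step_ms = 100,
                              duration_ms = NULL) {
  if (n_permutations < 200)
    stop_config("n_permutations must be at least 200")
  times <- press_times_list(trains)
  if (!length(unlist(times)))
    stop_config("no presses in any train")
  if (is.null(duration_ms)) {
    cfg <- attr(trains, "config")
    duration_ms <- if (!is.null(cfg)) cfg$duration_s * 1000
                   else max(unlist(times))
  }
  obs <- magnitude_series(trains, kernel_sd_ms = kernel_sd_ms,
                          grid_step_ms = grid_step_ms,
                          duration_ms = duration_ms)
  n_part <- obs$n_participants_normalizer
  grid <- obs$time_ms

  null_vals <- with_seed(derive_seed(seed, 11L), {
    vals <- numeric(length(grid) * n_permutations)
    for (p in seq_len(n_permutations)) {
      shifted <- unlist(lapply(times, function(tt) {
        if (!length(tt)) return(tt)
        (tt + stats::runif(1, 0, duration_ms)) %% duration_ms
      }), use.names = FALSE)
      v <- gauss_sum_grid(sort(shifted), grid, grid_step_ms,
                          kernel_sd_ms) / n_part
      vals[((p - 1L) * length(grid) + 1L):(p * length(grid))] <- v
    }
    vals
  })
  threshold <- stats::quantile(null_vals, 1 - alpha, names = FALSE, type = 7)

  peaks <- local_maxima(obs$values)
  peaks <- peaks[obs$values[peaks] > threshold]
  # greedy thinning: higher peaks first, earlier time breaks ties
  ord <- peaks[order(-obs$values[peaks], grid[peaks])]
  kept <- numeric(0)
  for (i in ord) {
    if (!length(kept) || all(abs(grid[i] - grid[kept]) >= min_separation_ms))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  structure(list(times_ms = grid[kept], threshold = threshold,
                 n_permutations = n_permutations, alpha = alpha,
                 min_separation_ms = min_separation_ms, seed = seed,
                 series = obs),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf(
    "Event boundaries: %d significant peaks (threshold %.4f at alpha %g, %d permutations)\n",
    length(x$times_ms), x$threshold, x$alpha, x$n_permutations))
  if (length(x$times_ms))
    cat("  at (s):", paste(sprintf("%.1f", x$times_ms / 1000),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.boundary_set <- function(x, ...) {
  plot(x$series, boundaries = x, ...)
}
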