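# Normalized scanpath saliency (NSS) gaze coherence.
#
# At each analysis step a fixation map is built from the reference group's
# gaze positions (Gaussian bump per observer), normalized to zero mean /
# unit SD over cells, and read out at the test observer's gaze position.
# Values above 0 mean the observer looked where the reference group looked.

#' Resample a gaze track to a uniform rate
#'
#' Places output samples on a uniform grid at `target_hz`; each output
#' sample takes the nearest valid input sample within half an output
#' period, otherwise it is flagged invalid.
#'
#' @param track A [gaze_track()].
#' @param target_hz Target sampling rate (> 0).
#' @return A [gaze_track()] on the uniform grid.
#' @export
resample_gaze <- function(track, target_hz = 60) {
  stopifnot(inherits(track, "gaze_track"), target_hz > 0)
  if (length(track$time_ms) == 0L)
    stop_config("cannot resample an empty gaze track")
  period <- 1000 / target_hz
  t_out <- seq(0, max(track$time_ms) + period / 2, by = period)
  t_out <- t_out[t_out <= max(track$time_ms) + period / 2]
  vt <- track$time_ms[track$valid]
  x <- y <- rep(NA_real_, length(t_out))
  valid <- rep(FALSE, length(t_out))
  if (length(vt)) {
    vi <- which(track$valid)
    # nearest valid input sample to each output time
    pos <- findInterval(t_out, vt)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(vt))
    d_lo <- abs(t_out - vt[lo])
    d_hi <- abs(t_out - vt[hi])
    pick <- ifelse(d_hi < d_lo, hi, lo)
    dist <- pmin(d_lo, d_hi)
    ok <- dist <= period / 2 + 1e-9
    src <- vi[pick[ok]]
    x[ok] <- track$x[src]
    y[ok] <- track$y[src]
    valid[ok] <- TRUE
  }
  x[!valid] <- 0
  y[!valid] <- 0
  gaze_track(track$participant_id, track$group, t_out, x, y, valid,
             nominal_rate_hz = target_hz,
             calibration_error_deg = track$calibration_error_deg)
}

grid_dims <- function(screen_w, screen_h, downsample) {
  c(nx = as.integer(ceiling(screen_w / downsample)),
    ny = as.integer(ceiling(screen_h / downsample)))
}

cell_centers <- function(n, downsample) (seq_len(n) - 0.5) * downsample

cell_index <- function(coord, downsample, n) {
  pmin(n, pmax(1L, floor(coord / downsample) + 1L))
}

#' Build a raw fixation map from gaze positions
#'
#' The map is the sum of isotropic unit-peak Gaussian bumps centred at
#' each position, evaluated at the centres of a grid downsampled from
#' screen resolution.
#'
#' @param positions Two-column matrix (x, y) of gaze positions in pixels;
#'   at least one row.
#' @param screen_w,screen_h Screen size in pixels.
#' @param sigma_px Spatial kernel SD in pixels (> 0).
#' @param downsample Grid downsampling factor (cell edge in pixels).
#' @param time_ms Time stamp carried as metadata.
#' @return A `fixation_map`: values matrix (rows = y cells, cols = x
#'   cells), `n_contributors`, `normalized = FALSE`, `valid = TRUE`.
#' @examples
#' m <- build_fixation_map(cbind(640, 512), 1280, 1024, sigma_px = 40)
#' max(m$values)  # unit peak
#' @export
build_fixation_map <- function(positions, screen_w, screen_h, sigma_px,
                               downsample = 8, time_ms = NA_real_) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) < 1L)
    stop_config("insufficient reference positions: need at least one")
  stopifnot(sigma_px > 0, downsample > 0)
  dims <- grid_dims(screen_w, screen_h, downsample)
  cx <- cell_centers(dims["nx"], downsample)
  cy <- cell_centers(dims["ny"], downsample)
  # separable kernel: bump_i = gy_i %o% gx_i
  gx <- exp(-outer(cx, positions[, 1], "-")^2 / (2 * sigma_px^2))
  gy <- exp(-outer(cy, positions[, 2], "-")^2 / (2 * sigma_px^2))
  values <- gy %*% t(gx)
  structure(list(values = values, time_ms = time_ms,
                 n_contributors = nrow(positions),
                 normalized = FALSE, valid = TRUE,
                 screen_w = screen_w, screen_h = screen_h,
                 sigma_px = sigma_px, downsample = downsample),
            class = "fixation_map")
}

#' Normalize a fixation map to zero mean and unit SD
#'
#' Normalization uses only the values of this map at its own time point.
#' A constant map (cell SD = 0) cannot be normalized; it is returned with
#' `valid = FALSE` so the caller can drop the time point.
#'
#' @param map A raw `fixation_map`.
#' @return The map with normalized values and `normalized = TRUE`, or with
#'   `valid = FALSE` if the map is constant.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "fixation_map"))
  if (map$normalized) stop_config("map is already normalized")
  m <- mean(map$values)
  s <- stats::sd(map$values)
  if (!is.finite(s) || s < 1e-12) {
    map$valid <- FALSE
    return(map)
  }
  map$values <- (map$values - m) / s
  map$normalized <- TRUE
  map
}

#' @export
print.fixation_map <- function(x, ...) {
  cat(sprintf(
    "Fixation map %dx%d cells (downsample %g), %d contributor(s), %s%s\n",
    nrow(x$values), ncol(x$values), x$downsample, x$n_contributors,
    if (x$normalized) "normalized" else "raw",
    if (x$valid) "" else " [invalid: constant map]"))
  invisible(x)
}

#' Read the NSS value of a gaze position from a normalized map
#'
#' Nearest-cell lookup on the downsampled grid (no interpolation),
#' matching the discrete fixation-map semantics.
#'
#' @param map A normalized, valid `fixation_map`.
#' @param gaze Numeric length-2 vector (x, y) in pixels.
#' @return The map value at the gaze position.
#' @export
nss_value <- function(map, gaze) {
  stopifnot(inherits(map, "fixation_map"))
  if (!map$normalized) stop_config("nss_value needs a normalized map")
  if (!map$valid) stop_config("map is invalid (constant at this time point)")
  ix <- cell_index(gaze[1], map$downsample, ncol(map$values))
  iy <- cell_index(gaze[2], map$downsample, nrow(map$values))
  map$values[iy, ix]
}

# ---------------------------------------------------------------------------
# Fast exact NSS engine.
#
# The Gaussian bump is separable, so for reference set R at one step:
#   value at target cell (cx*, cy*) = sum_i kx_i * ky_i
#   cell mean  = sum_i Sx_i * Sy_i / Ncells          (Sx_i = sum_c gx_i(c))
#   cell sumsq = sum_{i,j} Px_ij * Py_ij             (Px_ij = sum_c gx_i gx_j)
# Everything vectorises over time steps; invalid reference samples are
# zeroed columns and drop out of all three sums. Results are identical (to
# rounding) to building, normalizing and indexing the full map.

# target_x/y/valid: length-T vectors. ref_x/y/valid: nref x T matrices.
# Returns list(nss, reason, n_refs).
nss_engine <- function(target_x, target_y, target_valid,
                       ref_x, ref_y, ref_valid,
                       screen_w, screen_h, sigma_px, downsample,
                       min_refs = 4L, chunk = 2000L) {
  T_ <- length(target_x)
  nref <- nrow(ref_x)
  dims <- grid_dims(screen_w, screen_h, downsample)
  nx <- dims["nx"]; ny <- dims["ny"]
  ncells <- as.numeric(nx) * as.numeric(ny)
  cx <- cell_centers(nx, downsample)
  cy <- cell_centers(ny, downsample)
  two_s2 <- 2 * sigma_px^2

  n_valid <- colSums(ref_valid)
  tcx <- (cell_index(target_x, downsample, nx) - 0.5) * downsample
  tcy <- (cell_index(target_y, downsample, ny) - 0.5) * downsample

  value <- mean_v <- ss <- numeric(T_)
  for (start in seq(1L, T_, by = chunk)) {
    idx <- start:min(start + chunk - 1L, T_)
    Gx <- vector("list", nref)
    Gy <- vector("list", nref)
    sx <- sy <- matrix(0, nref, length(idx))
    for (i in seq_len(nref)) {
      gx <- exp(-outer(cx, ref_x[i, idx], "-")^2 / two_s2)
      gy <- exp(-outer(cy, ref_y[i, idx], "-")^2 / two_s2)
      inval <- !ref_valid[i, idx]
      if (any(inval)) {
        gx[, inval] <- 0
        gy[, inval] <- 0
      }
      Gx[[i]] <- gx; Gy[[i]] <- gy
      sx[i, ] <- colSums(gx)
      sy[i, ] <- colSums(gy)
      kx <- exp(-(tcx[idx] - ref_x[i, idx])^2 / two_s2)
      ky <- exp(-(tcy[idx] - ref_y[i, idx])^2 / two_s2)
      kv <- kx * ky
      kv[inval] <- 0
      value[idx] <- value[idx] + kv
    }
    mean_v[idx] <- colSums(sx * sy) / ncells
    ssc <- numeric(length(idx))
    for (i in seq_len(nref)) {
      ssc <- ssc + colSums(Gx[[i]] * Gx[[i]]) * colSums(Gy[[i]] * Gy[[i]])
      if (i < nref) for (j in (i + 1L):nref) {
        ssc <- ssc +
          2 * colSums(Gx[[i]] * Gx[[j]]) * colSums(Gy[[i]] * Gy[[j]])
      }
    }
    ss[idx] <- ssc
  }
  var_v <- (ss - ncells * mean_v^2) / (ncells - 1)
  sd_v <- sqrt(pmax(var_v, 0))

  reason <- rep("ok", T_)
  reason[sd_v < 1e-12] <- "constant_map"
  reason[n_valid < min_refs] <- "insufficient_refs"
  reason[!target_valid] <- "invalid_gaze"
  nss <- rep(NA_real_, T_)
  ok <- reason == "ok"
  nss[ok] <- (value[ok] - mean_v[ok]) / sd_v[ok]
  list(nss = nss, reason = reason, n_refs = n_valid)
}

# Map analysis-step times onto a 60 Hz track: a gaze sample is "at" a step
# if its grid time is nearest to the step time within +/- 20 ms.
step_samples <- function(track, step_times_ms, tol_ms = 20) {
  period <- 1000 / track$nominal_rate_hz
  k <- round(step_times_ms / period) + 1L
  ok <- k >= 1L & k <= length(track$time_ms)
  ok[ok] <- abs(track$time_ms[k[ok]] - step_times_ms[ok]) <= tol_ms + 1e-9
  x <- y <- numeric(length(step_times_ms))
  valid <- logical(length(step_times_ms))
  x[ok] <- track$x[k[ok]]
  y[ok] <- track$y[k[ok]]
  valid[ok] <- track$valid[k[ok]]
  list(x = x, y = y, valid = valid)
}

cohort_screen <- function(cohort) {
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) c(w = cfg$screen_w, h = cfg$screen_h)
  else c(w = attr(cohort, "screen_w"), h = attr(cohort, "screen_h"))
}

prepare_cohort_60hz <- function(cohort, analysis_hz = 60) {
  lapply(cohort, function(tr) {
    if (is.na(tr$nominal_rate_hz) ||
        abs(tr$nominal_rate_hz - analysis_hz) > 1e-9) {
      resample_gaze(tr, analysis_hz)
    } else tr
  })
}

#' NSS time course of one participant against a reference group
#'
#' At every analysis step the valid gaze positions of the reference
#' participants are gathered (the test participant is always excluded), a
#' fixation map is built and normalized for that step alone, and the test
#' participant's gaze position is read from it. Steps with fewer than
#' `min_refs` valid reference positions, an invalid test gaze, or a
#' constant map yield a missing value with a reason code.
#'
#' @param cohort A `gaze_cohort` (list of [gaze_track()]); tracks not at
#'   `analysis_hz` are resampled first.
#' @param participant Participant id to score.
#' @param reference_group Group label of the reference set, or NULL to use
#'   the participant's own group.
#' @param step_ms Analysis step in ms (default 40).
#' @param min_refs Minimum valid reference positions per step (default 4).
#' @param sigma_px Spatial kernel SD in pixels; default 1.2 degrees of
#'   visual angle at 65 cm via [visual_angle_px()].
#' @param downsample Grid downsampling factor (default 8).
#' @param ref_ids Optional explicit reference participant ids (overrides
#'   `reference_group`); the test participant is removed if present.
#' @param analysis_hz Rate of the common analysis grid (default 60).
#' @return An `nss_series`: data.frame with `time_ms`, `nss`, `reason`,
#'   `n_refs`; step and reference metadata as attributes.
#' @export
nss_timecourse <- function(cohort, participant, reference_group = NULL,
                           step_ms = 40, min_refs = 4L, sigma_px = NULL,
                           downsample = 8, ref_ids = NULL,
                           analysis_hz = 60) {
  ids <- vapply(cohort, `[[`, character(1), "participant_id")
  if (!participant %in% ids)
    stop_config("participant '%s' not found in cohort", participant)
  scr <- cohort_screen(cohort)
  if (is.null(sigma_px)) sigma_px <- visual_angle_px(1.2, screen_px = scr["w"])
  tracks <- prepare_cohort_60hz(cohort, analysis_hz)
  names(tracks) <- ids
  target <- tracks[[participant]]
  if (is.null(ref_ids)) {
    if (is.null(reference_group)) reference_group <- target$group
    ref_ids <- ids[vapply(tracks, `[[`, character(1), "group") ==
                     reference_group]
  }
  ref_ids <- setdiff(ref_ids, participant)
  if (length(ref_ids) == 0L)
    stop_config("no reference participants available")

  dur <- max(vapply(tracks, function(tr) max(tr$time_ms), numeric(1)))
  steps <- seq(0, dur, by = step_ms)
  tg <- step_samples(target, steps)
  rx <- ry <- matrix(0, length(ref_ids), length(steps))
  rv <- matrix(FALSE, length(ref_ids), length(steps))
  for (i in seq_along(ref_ids)) {
    s <- step_samples(tracks[[ref_ids[i]]], steps)
    rx[i, ] <- s$x; ry[i, ] <- s$y; rv[i, ] <- s$valid
  }
  eng <- nss_engine(tg$x, tg$y, tg$valid, rx, ry, rv,
                    scr["w"], scr["h"], sigma_px, downsample, min_refs)
  out <- data.frame(time_ms = steps, nss = eng$nss, reason = eng$reason,
                    n_refs = eng$n_refs)
  structure(out, class = c("nss_series", "data.frame"),
            participant = participant, reference = ref_ids,
            step_ms = step_ms, min_refs = min_refs,
            sigma_px = sigma_px, downsample = downsample)
}

#' @export
print.nss_series <- function(x, ...) {
  ok <- x$reason == "ok"
  cat(sprintf(
    "NSS series for %s vs %d reference(s): %d steps, %d valid (mean NSS %.3f)\n",
    attr(x, "participant"), length(attr(x, "reference")), nrow(x), sum(ok),
    mean(x$nss[ok])))
  invisible(x)
}

#' Same-group minus other-group NSS difference scores
#'
#' For each participant the own-group reference is all other members of
#' their group (n - 1 observers) and the other-group reference is a seeded
#' random sample of n - 1 members of the opposing group, drawn once per
#' participant per run so both references have equal size. A step
#' contributes only when the participant's gaze is valid and both fixation
#' maps rest on at least `min_refs` valid reference positions. Differences
#' (same-group NSS minus other-group NSS) are averaged over steps within
#' participant; a positive mean indicates gaze more coherent with one's
#' own group.
#'
#' @inheritParams nss_timecourse
#' @param min_group_values Minimum contributing steps a participant needs
#'   to receive a score (default 1).
#' @param seed Seed for the other-group reference sampling.
#' @return An `nss_scores` object: data.frame with one row per scored
#'   participant (`participant_id`, `group`, `score`, `n_steps`);
#'   attributes `M`, `SD`, `retention` (fraction of participant-step pairs
#'   retained), `drop_counts` by reason, and the run parameters.
#' @export
nss_difference_scores <- function(cohort, step_ms = 40, min_refs = 4L,
                                  min_group_values = 1L, seed = 1L,
                                  sigma_px = NULL, downsample = 8,
                                  analysis_hz = 60) {
  ids <- vapply(cohort, `[[`, character(1), "participant_id")
  groups <- vapply(cohort, `[[`, character(1), "group")
  glev <- unique(groups)
  if (length(glev) != 2L)
    stop_config("need exactly two groups, got: %s",
                paste(glev, collapse = ", "))
  for (g in glev) {
    if (sum(groups == g) < min_refs + 1L)
      stop_config(
        "group '%s' has %d members; need at least min_refs + 1 = %d for leave-one-out references",
        g, sum(groups == g), min_refs + 1L)
  }
  scr <- cohort_screen(cohort)
  if (is.null(sigma_px)) sigma_px <- visual_angle_px(1.2, screen_px = scr["w"])
  tracks <- prepare_cohort_60hz(cohort, analysis_hz)
  names(tracks) <- ids
  dur <- max(vapply(tracks, function(tr) max(tr$time_ms), numeric(1)))
  steps <- seq(0, dur, by = step_ms)

  samp <- lapply(tracks, step_samples, step_times_ms = steps)

  run_engine <- function(pid, ref_ids) {
    rx <- ry <- matrix(0, length(ref_ids), length(steps))
    rv <- matrix(FALSE, length(ref_ids), length(steps))
    for (i in seq_along(ref_ids)) {
      s <- samp[[ref_ids[i]]]
      rx[i, ] <- s$x; ry[i, ] <- s$y; rv[i, ] <- s$valid
    }
    tg <- samp[[pid]]
    nss_engine(tg$x, tg$y, tg$valid, rx, ry, rv,
               scr["w"], scr["h"], sigma_px, downsample, min_refs)
  }

  other_samples <- with_seed(derive_seed(seed, 7L), {
    lapply(seq_along(ids), function(i) {
      own_n <- sum(groups == groups[i])
      pool <- ids[groups != groups[i]]
      m <- min(own_n - 1L, length(pool))
      sort(sample(pool, m))
    })
  })

  drop <- c(invalid_gaze = 0L, insufficient_refs = 0L, constant_map = 0L)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    own_ids <- setdiff(ids[groups == groups[i]], ids[i])
    e_own <- run_engine(ids[i], own_ids)
    e_oth <- run_engine(ids[i], other_samples[[i]])
    ok <- e_own$reason == "ok" & e_oth$reason == "ok"
    # bookkeeping: one reason per dropped pair, target validity first
    bad <- !ok
    r <- ifelse(e_own$reason != "ok", e_own$reason, e_oth$reason)
    for (code in names(drop)) drop[code] <- drop[code] + sum(r[bad] == code)
    res[[i]] <- list(ok = ok, diff = e_own$nss[ok] - e_oth$nss[ok])
  }
  n_ok <- vapply(res, function(r) sum(r$ok), integer(1))
  score <- vapply(res, function(r) mean(r$diff), numeric(1))
  keep <- n_ok >= max(1L, min_group_values)
  out <- data.frame(participant_id = ids[keep], group = groups[keep],
                    score = score[keep], n_steps = n_ok[keep],
                    stringsAsFactors = FALSE)
  total_pairs <- length(ids) * length(steps)
  structure(out, class = c("nss_scores", "diff_scores", "data.frame"),
            M = mean(out$score), SD = stats::sd(out$score),
            retention = 1 - sum(drop) / total_pairs,
            retained_pairs = sum(n_ok), drop_counts = drop,
            total_pairs = total_pairs,
            dropped_participants = ids[!keep],
            other_reference = stats::setNames(other_samples, ids),
            step_ms = step_ms, min_refs = min_refs, sigma_px = sigma_px,
            downsample = downsample, seed = seed)
}
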