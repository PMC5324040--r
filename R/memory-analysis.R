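# Memory-probe analysis: boundary distance, Tukey outlier fence, tertile
# binning, cell aggregation, and fan-alignment contrasts.

#' Forward distance from probe times to the next event boundary
#'
#' Distance runs from the probe to the nearest boundary at or after it
#' (items exactly at a boundary score 0). Probes with no later boundary
#' get a missing distance and are flagged.
#'
#' @param probe_time_s Numeric probe times in seconds (or a data.frame
#'   with a `probe_time_s` column).
#' @param boundaries A [boundary_set] or numeric boundary times in
#'   seconds; must be non-empty.
#' @return data.frame with `probe_time_s`, `distance_s`,
#'   `no_later_boundary` flag.
#' @export
boundary_distance <- function(probe_time_s, boundaries) {
  if (is.data.frame(probe_time_s)) probe_time_s <- probe_time_s$probe_time_s
  bt <- sort(boundary_times_s(boundaries))
  if (!length(bt)) stop_config("boundary set is empty")
  # index of first boundary at or after the probe (1e-9 s tolerance)
  idx <- findInterval(probe_time_s - 1e-9, bt) + 1L
  has_later <- idx <= length(bt)
  d <- rep(NA_real_, length(probe_time_s))
  d[has_later] <- pmax(bt[idx[has_later]] - probe_time_s[has_later], 0)
  data.frame(probe_time_s = probe_time_s, distance_s = d,
             no_later_boundary = !has_later)
}

#' Flag boundary-distance outliers by the Tukey box-plot criterion
#'
#' An item is removed iff its distance exceeds Q3 + 1.5 * IQR, with
#' quartiles by linear interpolation (type 7). Missing distances are
#' removed with their own reason.
#'
#' @param distances Numeric distances (NA allowed).
#' @return data.frame with `distance_s`, `kept`, `reason`; the fence in
#'   `attr(, "fence")`.
#' @export
flag_outliers <- function(distances) {
  finite <- distances[is.finite(distances)]
  if (length(finite) < 4L)
    stop_config("need at least 4 finite distances to place a box-plot fence (got %d)",
                length(finite))
  q <- stats::quantile(finite, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  kept <- is.finite(distances) & distances <= fence
  reason <- rep("ok", length(distances))
  reason[is.finite(distances) & distances > fence] <- "beyond_fence"
  reason[!is.finite(distances)] <- "no_later_boundary"
  structure(data.frame(distance_s = distances, kept = kept,
                       reason = reason),
            fence = fence)
}

#' Assign kept distances to tertiles
#'
#' Cut points are the 1/3 and 2/3 empirical quantiles (type 7); intervals
#' are closed/open as `[0, c1]`, `(c1, c2]`, `(c2, max]`, labelled 1..3.
#'
#' @param distances Numeric distances of the kept items (>= 3 values).
#' @return Integer tertile labels with cut points in `attr(, "cuts")`.
#' @export
assign_tertiles <- function(distances) {
  stopifnot(length(distances) >= 3L, all(is.finite(distances)))
  cuts <- stats::quantile(distances, c(1, 2) / 3, names = FALSE, type = 7)
  lab <- ifelse(distances <= cuts[1], 1L,
                ifelse(distances <= cuts[2], 2L, 3L))
  structure(as.integer(lab), cuts = cuts)
}

#' Bin memory items by boundary distance
#'
#' Convenience wrapper chaining [boundary_distance()], [flag_outliers()]
#' and [assign_tertiles()]: annotates each item with its forward distance
#' to the next event boundary, removes box-plot outliers, and splits the
#' kept items into distance tertiles.
#'
#' @param items Item table with `item_id`, `probe_time_s`,
#'   `content_group`, `correct_answer`.
#' @param boundaries A [boundary_set] or numeric boundary times (s).
#' @return A `binned_items` data.frame (`item_id`, `probe_time_s`,
#'   `content_group`, `correct_answer`, `distance_s`, `kept`, `reason`,
#'   `tertile`) with attributes `fence` and `cuts`.
#' @export
bin_items <- function(items, boundaries) {
  d <- boundary_distance(items$probe_time_s, boundaries)
  fl <- flag_outliers(d$distance_s)
  out <- items
  out$distance_s <- d$distance_s
  out$kept <- fl$kept
  out$reason <- fl$reason
  out$tertile <- NA_integer_
  tert <- assign_tertiles(out$distance_s[out$kept])
  out$tertile[out$kept] <- tert
  structure(out, class = c("binned_items", "data.frame"),
            fence = attr(fl, "fence"), cuts = attr(tert, "cuts"))
}

#' @export
print.binned_items <- function(x, ...) {
  cuts <- attr(x, "cuts")
  cat(sprintf(
    "Binned items: %d kept / %d total (fence %.1f s); tertiles [0, %.1f], (%.1f, %.1f], (%.1f, %.1f] s\n",
    sum(x$kept), nrow(x), attr(x, "fence"), cuts[1], cuts[1], cuts[2],
    cuts[2], max(x$distance_s[x$kept])))
  invisible(x)
}

#' Aggregate memory responses into design cells
#'
#' Proportion correct and mean confidence per participant x test time x
#' content group x tertile, over kept items only, plus marginal means
#' with SEM across participants.
#'
#' @param responses Response table (`participant_id`, `group`, `item_id`,
#'   `test_time`, `answer`, `confidence`).
#' @param items A `binned_items` table from [bin_items()].
#' @return List with `cells` (per-participant cell means; empty cells
#'   absent) and `marginals` (across-participant mean, SEM and n per
#'   test time x content group x tertile).
#' @export
aggregate_cells <- function(responses, items) {
  stopifnot(inherits(items, "binned_items"))
  merged <- merge(responses, items[items$kept,
                                   c("item_id", "content_group",
                                     "correct_answer", "tertile")],
                  by = "item_id")
  if (!nrow(merged)) stop_config("no responses matched kept items")
  merged$correct <- as.integer(merged$answer == merged$correct_answer)
  cells <- stats::aggregate(
    cbind(accuracy = correct, confidence = confidence) ~
      participant_id + group + test_time + content_group + tertile,
    data = merged, FUN = mean)
  cells <- cells[order(cells$participant_id, cells$test_time,
                       cells$content_group, cells$tertile), ]
  rownames(cells) <- NULL
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  marg <- do.call(rbind, lapply(
    split(cells, cells[c("test_time", "content_group", "tertile")],
          drop = TRUE),
    function(d) data.frame(
      test_time = d$test_time[1], content_group = d$content_group[1],
      tertile = d$tertile[1], n = nrow(d),
      accuracy_mean = mean(d$accuracy), accuracy_sem = sem(d$accuracy),
      confidence_mean = mean(d$confidence),
      confidence_sem = sem(d$confidence))))
  rownames(marg) <- NULL
  list(cells = cells, marginals = marg)
}

#' Fan-alignment contrast of accuracy or confidence
#'
#' For each participant: mean of the measure over cells whose content
#' group matches the participant's own group, minus the mean over cells
#' depicting the other group. A positive mean across participants
#' indicates an own-group advantage in that measure. Participants missing
#' one of the two content-group levels are dropped and reported.
#'
#' @param cells Per-participant cell table from [aggregate_cells()].
#' @param measure `"accuracy"` or `"confidence"`.
#' @return An `alignment_scores` object: data.frame (`participant_id`,
#'   `group`, `score`) with attributes `M`, `SD`, `measure`,
#'   `dropped_participants`.
#' @export
fan_alignment_contrast <- function(cells,
                                   measure = c("confidence", "accuracy")) {
  measure <- match.arg(measure)
  if (is.list(cells) && !is.data.frame(cells)) cells <- cells$cells
  rows <- list()
  dropped <- character(0)
  for (pid in unique(cells$participant_id)) {
    d <- cells[cells$participant_id == pid, ]
    own <- d[[measure]][d$content_group == d$group]
    oth <- d[[measure]][d$content_group != d$group]
    if (!length(own) || !length(oth)) {
      dropped <- c(dropped, pid)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, group = d$group[1],
      score = mean(own) - mean(oth), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop_config("no participant has both content-group levels")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("alignment_scores", "diff_scores", "data.frame"),
            M = mean(out$score), SD = stats::sd(out$score),
            measure = measure, dropped_participants = dropped)
}

#' @export
print.diff_scores <- function(x, ...) {
  kind <- class(x)[1]
  label <- switch(kind,
                  nss_scores = "NSS (same - other group)",
                  seg_scores = "segmentation agreement (same - other group)",
                  alignment_scores = sprintf("fan-alignment %s (own - other team)",
                                             attr(x, "measure")),
                  "difference")
  cat(sprintf("Difference scores [%s]: n = %d, M = %.4f, SD = %.4f\n",
              label, nrow(x), attr(x, "M"), attr(x, "SD")))
  dropped <- attr(x, "dropped_participants")
  if (length(dropped))
    cat("  dropped:", paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Summary of a difference-score set: one-sample test plus Bayes factor
#'
#' @param object A `diff_scores` object.
#' @param r Cauchy prior scale for the Bayes factor.
#' @param side Direction of the one-tailed Bayes factor (the substantive
#'   prediction is an own-group advantage, i.e. `"positive"`).
#' @param ... Unused.
#' @return List with the score table, `ttest` ([one_sample_t()]) and
#'   `bf` ([jzs_bf_one_sample()]).
#' @export
summary.diff_scores <- function(object, r = sqrt(2) / 2,
                                side = "positive", ...) {
  tt <- one_sample_t(object$score)
  bf <- jzs_bf_one_sample(tt$t, tt$n, r = r, side = side)
  out <- list(scores = object, ttest = tt, bf = bf)
  class(out) <- "summary.diff_scores"
  out
}

#' @export
print.summary.diff_scores <- function(x, ...) {
  print(x$scores)
  tt <- x$ttest
  cat(sprintf("  t(%d) = %.2f, p = %.3f, d = %.2f; BF01 (%s) = %.2f\n",
              tt$df, tt$t, tt$p, tt$d, x$bf$side, x$bf$bf01))
  invisible(x)
}

#' @export
plot.diff_scores <- function(x, ...) {
  graphics::stripchart(x$score ~ factor(x$group), vertical = TRUE,
                       method = "jitter", pch = 16,
                       ylab = "difference score (same - other)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::abline(h = attr(x, "M"), col = "red")
  invisible(x)
}
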