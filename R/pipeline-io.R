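# Delimited-table io and end-to-end orchestration.
#
# Interchange format: headered UTF-8 tab-separated tables. Times are ms
# from stimulus onset, except item probe times which are given in seconds
# (as in stimulus protocols) and converted on load.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path, required_cols) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_config("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  df
}

#' Write a gaze cohort to a delimited table
#'
#' @param cohort A `gaze_cohort` or list of [gaze_track()]s.
#' @param path Output path (tab-separated, headered).
#' @export
write_gaze_table <- function(cohort, path) {
  rows <- lapply(cohort, function(tr) {
    data.frame(participant_id = tr$participant_id, group = tr$group,
               time_ms = tr$time_ms, x = tr$x, y = tr$y,
               valid = as.integer(tr$valid),
               calibration_error_deg = tr$calibration_error_deg)
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a gaze table, applying the calibration-accuracy filter
#'
#' Rows are parsed into per-participant [gaze_track()]s (sorted by time).
#' Tracks whose calibration error exceeds `calibration_cutoff_deg`
#' (default 0.8 degrees) are excluded at load time; exclusions are
#' reported in `attr(, "excluded")`.
#'
#' @param path Tab-separated file with columns `participant_id`, `group`,
#'   `time_ms`, `x`, `y`, `valid`, `calibration_error_deg`.
#' @param screen_w,screen_h Screen size metadata attached to the cohort.
#' @param calibration_cutoff_deg Exclusion threshold in degrees; `Inf`
#'   disables the filter.
#' @param group_labels Optional allowed group labels; unknown labels are a
#'   validation error.
#' @return A `gaze_cohort` with exclusion bookkeeping attributes.
#' @export
read_gaze_table <- function(path, screen_w = 1280, screen_h = 1024,
                            calibration_cutoff_deg = 0.8,
                            group_labels = NULL) {
  df <- read_tsv(path, c("participant_id", "group", "time_ms", "x", "y",
                         "valid", "calibration_error_deg"))
  bad <- which(!is.finite(df$time_ms) | !is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop_config("%s: malformed row(s) at line(s) %s", path,
                paste(utils::head(bad + 1L, 5), collapse = ", "))
  if (!is.null(group_labels)) {
    unknown <- setdiff(unique(df$group), group_labels)
    if (length(unknown))
      stop_config("%s: unknown group label(s): %s", path,
                  paste(unknown, collapse = ", "))
  }
  tracks <- list()
  excluded <- character(0)
  for (pid in unique(df$participant_id)) {
    d <- df[df$participant_id == pid, ]
    d <- d[order(d$time_ms), ]
    cal <- d$calibration_error_deg[1]
    if (is.finite(cal) && cal > calibration_cutoff_deg) {
      excluded <- c(excluded, pid)
      next
    }
    rate <- if (nrow(d) > 1) 1000 / stats::median(diff(d$time_ms))
            else NA_real_
    tracks[[pid]] <- gaze_track(pid, d$group[1], d$time_ms, d$x, d$y,
                                as.logical(d$valid),
                                nominal_rate_hz = rate,
                                calibration_error_deg = cal)
  }
  if (!length(tracks))
    stop_config("%s: no tracks remain after calibration filtering", path)
  structure(tracks, class = "gaze_cohort",
            screen_w = screen_w, screen_h = screen_h,
            excluded = excluded,
            calibration_cutoff_deg = calibration_cutoff_deg)
}

#' Write a press cohort to a delimited table
#' @param cohort A `press_cohort` or list of `press_train`s.
#' @param path Output path.
#' @export
write_press_table <- function(cohort, path) {
  rows <- lapply(cohort, function(tr) {
    if (length(tr$times_ms) == 0L)
      return(data.frame(participant_id = tr$participant_id,
                        group = tr$group, time_ms = numeric(0)))
    data.frame(participant_id = tr$participant_id, group = tr$group,
               time_ms = tr$times_ms)
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a press table
#'
#' @param path Tab-separated file with columns `participant_id`, `group`,
#'   `time_ms`.
#' @param all_participants Optional id/group table (columns
#'   `participant_id`, `group`) so participants with zero presses are
#'   kept as empty trains.
#' @return A `press_cohort`.
#' @export
read_press_table <- function(path, all_participants = NULL) {
  df <- read_tsv(path, c("participant_id", "group", "time_ms"))
  ids <- unique(df[c("participant_id", "group")])
  if (!is.null(all_participants))
    ids <- unique(rbind(ids, all_participants[c("participant_id", "group")]))
  trains <- lapply(seq_len(nrow(ids)), function(i) {
    press_train(ids$participant_id[i], ids$group[i],
                df$time_ms[df$participant_id == ids$participant_id[i]])
  })
  names(trains) <- ids$participant_id
  structure(trains, class = "press_cohort")
}

#' Read a memory-item table
#' @param path Tab-separated file with columns `item_id`, `probe_time_s`,
#'   `content_group`, `correct_answer`.
#' @return Item data.frame.
#' @export
read_item_table <- function(path) {
  read_tsv(path, c("item_id", "probe_time_s", "content_group",
                   "correct_answer"))
}

#' Read a memory-response table
#' @param path Tab-separated file with columns `participant_id`, `group`,
#'   `item_id`, `test_time`, `answer`, `confidence`.
#' @return Response data.frame.
#' @export
read_response_table <- function(path) {
  df <- read_tsv(path, c("participant_id", "group", "item_id", "test_time",
                         "answer", "confidence"))
  if (any(df$confidence %% 1 != 0 | df$confidence < 1 | df$confidence > 5))
    stop_config("%s: confidence must be an integer in 1..5", path)
  df
}

#' Assemble a pipeline run configuration
#'
#' Either `simulate` (a [cohort_config()]; the synthetic generators then
#' provide all inputs) or the four input paths must be given.
#'
#' @param simulate Optional [cohort_config()] for a fully synthetic run.
#' @param gaze_path,press_path,items_path,responses_path Input tables
#'   (ignored when `simulate` is given).
#' @param out_dir Optional output directory; created if needed.
#' @param step_ms NSS analysis step (default 40 ms).
#' @param min_refs Minimum reference observers per fixation map (4).
#' @param sigma_px Fixation-map kernel SD in pixels (default 1.2 degrees
#'   at 65 cm).
#' @param downsample Fixation-map grid factor (8).
#' @param kernel_sd_ms Segmentation kernel SD (1000 ms).
#' @param n_permutations Boundary-detection permutations (1000).
#' @param alpha Boundary significance level (0.05).
#' @param min_separation_ms Minimum boundary spacing (2000 ms).
#' @param bf_r Cauchy prior scale of the Bayes factors (`sqrt(2)/2`).
#' @param bf_side Direction of the one-tailed Bayes factors
#'   (`"positive"`: own-group advantage).
#' @param calibration_cutoff_deg Gaze calibration filter (0.8 deg).
#' @param n_items Number of synthetic memory items (52) when simulating.
#' @param seed Analysis seed (reference sampling, permutations).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, gaze_path = NULL, press_path = NULL,
                       items_path = NULL, responses_path = NULL,
                       out_dir = NULL, step_ms = 40, min_refs = 4L,
                       sigma_px = NULL, downsample = 8,
                       kernel_sd_ms = 1000, n_permutations = 1000,
                       alpha = 0.05, min_separation_ms = 2000,
                       bf_r = sqrt(2) / 2, bf_side = "positive",
                       calibration_cutoff_deg = 0.8, n_items = 52L,
                       seed = 1L) {
  if (is.null(simulate)) {
    paths <- c(gaze_path, press_path, items_path, responses_path)
    if (length(paths) != 4L)
      stop_config("either `simulate` or all four input paths are required")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_config("input path(s) do not exist: %s",
                  paste(missing, collapse = ", "))
  } else {
    stopifnot(inherits(simulate, "cohort_config"))
  }
  structure(list(simulate = simulate, gaze_path = gaze_path,
                 press_path = press_path, items_path = items_path,
                 responses_path = responses_path, out_dir = out_dir,
                 step_ms = step_ms, min_refs = as.integer(min_refs),
                 sigma_px = sigma_px, downsample = downsample,
                 kernel_sd_ms = kernel_sd_ms,
                 n_permutations = n_permutations, alpha = alpha,
                 min_separation_ms = min_separation_ms, bf_r = bf_r,
                 bf_side = bf_side,
                 calibration_cutoff_deg = calibration_cutoff_deg,
                 n_items = as.integer(n_items), seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gaze NSS difference scores, segmentation difference
#' scores, permutation boundary detection, memory-item binning and
#' fan-alignment contrasts, and the inference layer (one-sample t, Cohen's
#' d, one-tailed JZS Bayes factor, sequential Bayes factors). If
#' `config$out_dir` is set, score tables, a JSON manifest (seeds,
#' parameters, exclusion counts) and a plain-text summary are written.
#'
#' @param config A [run_config()].
#' @return A `cohseg_report` list with all intermediate objects and the
#'   inference summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gaze <- stage("simulate", generate_gaze_cohort(sim))
    presses <- stage("simulate", generate_press_cohort(sim))
    items <- stage("simulate", make_memory_items(config$n_items, sim))
  } else {
    gaze <- stage("read_gaze", read_gaze_table(
      config$gaze_path,
      calibration_cutoff_deg = config$calibration_cutoff_deg))
    presses <- stage("read_press", read_press_table(config$press_path))
    items <- stage("read_items", read_item_table(config$items_path))
  }

  gaze_scores <- stage("gaze_coherence", nss_difference_scores(
    gaze, step_ms = config$step_ms, min_refs = config$min_refs,
    seed = config$seed, sigma_px = config$sigma_px,
    downsample = config$downsample))
  seg_scores <- stage("segmentation", segmentation_difference_scores(
    presses, kernel_sd_ms = config$kernel_sd_ms))
  boundaries <- stage("boundaries", detect_boundaries(
    presses, n_permutations = config$n_permutations, alpha = config$alpha,
    min_separation_ms = config$min_separation_ms, seed = config$seed,
    kernel_sd_ms = config$kernel_sd_ms))

  if (!is.null(config$simulate)) {
    responses <- stage("simulate", generate_memory_responses(
      items, boundaries, config$simulate))
  } else {
    responses <- stage("read_responses",
                       read_response_table(config$responses_path))
  }
  binned <- stage("memory", bin_items(items, boundaries))
  cells <- stage("memory", aggregate_cells(responses, binned))
  conf_contrast <- stage("memory",
                         fan_alignment_contrast(cells, "confidence"))
  acc_contrast <- stage("memory",
                        fan_alignment_contrast(cells, "accuracy"))

  infer <- stage("inference", list(
    gaze = summary(gaze_scores, r = config$bf_r, side = config$bf_side),
    segmentation = summary(seg_scores, r = config$bf_r,
                           side = config$bf_side),
    confidence = summary(conf_contrast, r = config$bf_r,
                         side = config$bf_side),
    accuracy = summary(acc_contrast, r = config$bf_r,
                       side = config$bf_side),
    gaze_sequential = sequential_bf(gaze_scores$score, r = config$bf_r,
                                    side = config$bf_side)))

  report <- structure(
    list(config = config, gaze_scores = gaze_scores,
         seg_scores = seg_scores, boundaries = boundaries,
         binned_items = binned, cells = cells,
         confidence_contrast = conf_contrast,
         accuracy_contrast = acc_contrast, inference = infer),
    class = "cohseg_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

format_test_line <- function(label, s) {
  tt <- s$ttest
  sprintf("%s: M = %.4f, SD = %.4f, t(%d) = %.2f, p = %.3f, d = %.2f, BF01 = %.2f",
          label, attr(s$scores, "M"), attr(s$scores, "SD"),
          tt$df, tt$t, tt$p, tt$d, s$bf$bf01)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(as.data.frame(report$gaze_scores), p("gaze_scores.tsv"))
  write_tsv(as.data.frame(report$seg_scores), p("segmentation_scores.tsv"))
  write_tsv(data.frame(boundary_time_ms = report$boundaries$times_ms),
            p("boundaries.tsv"))
  write_tsv(as.data.frame(report$binned_items), p("binned_items.tsv"))
  write_tsv(report$cells$cells, p("memory_cells.tsv"))
  write_tsv(as.data.frame(report$inference$gaze_sequential),
            p("gaze_sequential_bf.tsv"))

  cfg <- report$config
  manifest <- list(
    package = "cohseg",
    seed = cfg$seed,
    parameters = cfg[c("step_ms", "min_refs", "downsample", "kernel_sd_ms",
                       "n_permutations", "alpha", "min_separation_ms",
                       "bf_r", "bf_side", "calibration_cutoff_deg")],
    sigma_px = attr(report$gaze_scores, "sigma_px"),
    synthetic = !is.null(cfg$simulate),
    exclusions = list(
      calibration = length(attr(report$gaze_scores, "excluded") %||%
                             character(0)),
      gaze_step_drops = as.list(attr(report$gaze_scores, "drop_counts")),
      gaze_retention = attr(report$gaze_scores, "retention"),
      zero_press_participants =
        attr(report$seg_scores, "dropped_participants"),
      items_removed = sum(!report$binned_items$kept)),
    boundaries = list(n = length(report$boundaries$times_ms),
                      threshold = report$boundaries$threshold,
                      alpha = report$boundaries$alpha,
                      n_permutations = report$boundaries$n_permutations),
    item_binning = list(fence_s = attr(report$binned_items, "fence"),
                        tertile_cuts_s = attr(report$binned_items, "cuts")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  lines <- c(
    "cohseg analysis summary",
    "=======================",
    format_test_line("Gaze NSS difference scores       ",
                     report$inference$gaze),
    format_test_line("Segmentation difference scores   ",
                     report$inference$segmentation),
    format_test_line("Confidence fan-alignment contrast",
                     report$inference$confidence),
    format_test_line("Accuracy fan-alignment contrast  ",
                     report$inference$accuracy),
    sprintf("Event boundaries: %d (threshold %.4f, alpha %g)",
            length(report$boundaries$times_ms),
            report$boundaries$threshold, report$boundaries$alpha))
  writeLines(lines, p("summary.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohseg_report <- function(x, ...) {
  cat("cohseg pipeline report\n")
  cat(" ", format_test_line("gaze", x$inference$gaze), "\n")
  cat(" ", format_test_line("segmentation", x$inference$segmentation), "\n")
  cat(" ", format_test_line("confidence", x$inference$confidence), "\n")
  cat(" ", format_test_line("accuracy", x$inference$accuracy), "\n")
  print(x$boundaries)
  invisible(x)
}
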