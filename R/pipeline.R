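#' Full run configuration with documented defaults
#'
#' Builds the nested parameter list driving the pipeline. Any subset of
#' values can be overridden via named nested lists; unknown keys are
#' rejected. Defaults: 30 fps capture, processing resize factor 0.5 for
#' file input, Stauffer--Grimson-style mixture settings, the shadow-test
#' thresholds of [shadow_params()] and the detector thresholds of
#' [detector_params()].
#'
#' @param ... named overrides, e.g. `detector = list(th1 = 1.6)`.
#' @return Object of class `fall_config` (a nested named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    fps = 30,
    resize = 0.5,
    init_frames = 10,
    gmm = list(k = 3, learning_rate = 0.01, match_threshold = 2.5,
               bg_threshold = 0.7, update_mode = "background_only"),
    diff = list(w1 = 0.5, w2 = 0.5, diff_threshold = 0.1),
    combine_mode = "union",
    morphology = list(open_radius = 1, close_radius = 2, min_area = 50),
    shadow = list(alpha = 0.4, beta = 0.9, t_s = 0.1, t_h = 0.1, t_n = 0.05,
                  sat_floor = 0.05, ssd_chroma_mode = "as_printed"),
    tracking = list(g_alpha = 0.5, g_beta = 0.4, g_gamma = 0.1,
                    gate_radius = NA, max_missed = 10, min_blob_area = 50),
    detector = list(th1 = 1.5, th2 = 1.0, th_velocity = 0.3, th_depth = 0.1,
                    velocity_window = 5, persistence = 5))
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  merged <- merge_config(defaults, over, path = "")
  structure(merged, class = "fall_config")
}

merge_config <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  nms <- names(over)
  if (is.null(nms) || any(nms == ""))
    stop("configuration overrides must be named")
  bad <- setdiff(nms, names(base))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (nm in nms) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(over[[nm]]))
        stop("configuration key '", nm, "' must be a named list")
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste0(path, ".", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values absent from the file keep their defaults; unknown keys are
#' rejected with an error naming them.
#'
#' @param path YAML file path.
#' @return A `fall_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  run_config(yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' @param config a `fall_config`.
#' @param path output file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_shadow_params <- function(config) do.call(shadow_params, config$shadow)

config_detector_params <- function(config) do.call(detector_params, config$detector)

#' Segment every frame of a sequence into background / object / shadow
#'
#' Initializes the mixture background model on the first `init_frames`
#' frames, then per frame combines the mixture foreground with the weighted
#' three-frame difference, cleans the mask morphologically and classifies
#' the moving region with the two-stage shadow test.
#'
#' @param frames list of [vframe]s.
#' @param config a `fall_config`.
#' @return List with `labels` (per-frame 0/1/2 matrices), `regions`
#'   (pre-classification moving-region masks) and the final `model`.
#' @export
segment_sequence <- function(frames, config = run_config()) {
  n <- length(frames)
  if (n < 1L) stop("empty frame sequence")
  n_init <- min(config$init_frames, n)
  model <- init_background(frames[seq_len(n_init)], k = config$gmm$k,
                           learning_rate = config$gmm$learning_rate,
                           match_threshold = config$gmm$match_threshold,
                           bg_threshold = config$gmm$bg_threshold,
                           update_mode = config$gmm$update_mode)
  sp <- config_shadow_params(config)
  labels <- vector("list", n)
  regions <- vector("list", n)
  for (i in seq_len(n)) {
    res <- gmm_foreground(model, frames[[i]], update = TRUE)
    model <- res$model
    prev <- frames[[max(i - 1L, 1L)]]
    nxt <- frames[[min(i + 1L, n)]]
    dmask <- weighted_frame_difference(prev, frames[[i]], nxt,
                                       config$diff$w1, config$diff$w2,
                                       config$diff$diff_threshold)
    region <- combine_masks(res$mask, dmask, config$combine_mode)
    region <- morphological_cleanup(region, config$morphology$open_radius,
                                    config$morphology$close_radius,
                                    config$morphology$min_area)
    labels[[i]] <- classify_moving_region(frames[[i]], model, region, sp)
    regions[[i]] <- region
  }
  list(labels = labels, regions = regions, model = model)
}

#' Run the complete fall-detection pipeline on a frame sequence
#'
#' Segmentation with shadow removal, blob extraction, alpha-beta-gamma
#' tracking and the two-stage fall cascade. The sequence verdict is `fall`
#' if any tracked object produced at least one fall event.
#'
#' @param frames list of [vframe]s.
#' @param config a `fall_config`.
#' @param keep_labels keep the per-frame label masks in the result
#'   (memory-heavy; default FALSE).
#' @return Object of class `fall_run` with fields `verdict`, `events`
#'   (data.frame over all objects), `per_object` (list of [detect_events()]
#'   results), `tracks` (a `track_set`), `frame_height`, `config` and,
#'   optionally, `labels`.
#' @export
process_sequence <- function(frames, config = run_config(),
                             keep_labels = FALSE) {
  seg <- segment_sequence(frames, config)
  h <- frame_dim(frames[[1L]])[1L]
  gate <- config$tracking$gate_radius
  if (is.na(gate) || is.null(gate)) gate <- 0.15 * h
  blob_frames <- lapply(seq_along(frames), function(i)
    extract_blobs(seg$labels[[i]], depth = frames[[i]]$depth,
                  frame = frames[[i]],
                  min_area = config$tracking$min_blob_area))
  tracks <- track_blobs(blob_frames, fps = config$fps,
                        gains = c(config$tracking$g_alpha,
                                  config$tracking$g_beta,
                                  config$tracking$g_gamma),
                        gate_radius = gate,
                        max_missed = config$tracking$max_missed)
  dp <- config_detector_params(config)
  per_object <- list()
  events <- data.frame(object_id = integer(0), onset_frame = integer(0),
                       end_frame = integer(0), stage = character(0))
  for (id in unique(tracks$history$object_id)) {
    hist <- tracks$history[tracks$history$object_id == id, ]
    if (nrow(hist) < 2L) next
    ev <- detect_events(hist, frame_height = h, params = dp,
                        fps = config$fps)
    per_object[[as.character(id)]] <- ev
    if (nrow(ev$events))
      events <- rbind(events, cbind(object_id = id, ev$events))
  }
  structure(list(
    verdict = if (nrow(events)) "fall" else "normal",
    events = events, per_object = per_object, tracks = tracks,
    frame_height = h, config = config,
    labels = if (keep_labels) seg$labels else NULL),
    class = "fall_run")
}

#' @export
print.fall_run <- function(x, ...) {
  cat(sprintf("<fall_run: verdict = %s, %d tracked object(s), %d event(s)>\n",
              x$verdict, length(unique(x$tracks$history$object_id)),
              nrow(x$events)))
  if (nrow(x$events)) for (r in seq_len(nrow(x$events)))
    cat(sprintf("  Fall Detect: object %d, frames %d-%d (stage %s)\n",
                x$events$object_id[r], x$events$onset_frame[r],
                x$events$end_frame[r], x$events$stage[r]))
  invisible(x)
}

#' @export
summary.fall_run <- function(object, ...) {
  h <- object$tracks$history
  cat("Fall-detection run\n")
  cat("  frames with detections:", length(unique(h$frame)), "\n")
  cat("  tracked objects:       ", length(unique(h$object_id)), "\n")
  cat("  verdict:               ", object$verdict, "\n")
  for (id in names(object$per_object)) {
    fr <- object$per_object[[id]]$frames
    cat(sprintf("  object %s: ratio %.2f-%.2f, max |velocity| %.2f, max |dZ| %.2f\n",
                id, min(fr$ratio), max(fr$ratio),
                max(abs(fr$velocity)), max(abs(fr$delta_z))))
  }
  invisible(object)
}

#' Plot the detector feature traces of a run
#'
#' Three stacked panels per tracked object: bounding-box aspect ratio with
#' the `th1` / `th2` thresholds, normalized vertical velocity with
#' `+/- th_velocity`, and depth variation with `+/- th_depth`; detected fall
#' frames are shaded.
#'
#' @param x a `fall_run`.
#' @param object_id which object to plot (default: first).
#' @param ... unused.
#' @export
plot.fall_run <- function(x, object_id = NULL, ...) {
  if (length(x$per_object) == 0L) {
    plot.new(); title("no tracked objects"); return(invisible(x))
  }
  if (is.null(object_id)) object_id <- names(x$per_object)[1L]
  fr <- x$per_object[[as.character(object_id)]]$frames
  dp <- config_detector_params(x$config)
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  shade <- function() if (any(fr$fall)) graphics::rect(
    fr$frame[which(fr$fall)] - 0.5, graphics::par("usr")[3L],
    fr$frame[which(fr$fall)] + 0.5, graphics::par("usr")[4L],
    col = grDevices::adjustcolor("red", 0.15), border = NA)
  plot(fr$frame, fr$ratio, type = "l", xlab = "", ylab = "MBR ratio",
       main = paste("object", object_id))
  shade()
  graphics::abline(h = c(dp$th1, dp$th2), lty = c(2, 3), col = "red")
  plot(fr$frame, fr$velocity, type = "l", xlab = "",
       ylab = "velocity (heights/s)")
  shade()
  graphics::abline(h = c(-1, 1) * dp$th_velocity, lty = 2, col = "red")
  plot(fr$frame, fr$delta_z, type = "l", xlab = "frame",
       ylab = "depth variation")
  shade()
  graphics::abline(h = c(-1, 1) * dp$th_depth, lty = 2, col = "red")
  invisible(x)
}

#' Run the pipeline over a benchmark suite and score it
#'
#' Renders each sequence of the suite, runs [process_sequence()], discards
#' the frames, and scores the per-sequence verdicts against the ground-truth
#' labels.
#'
#' @param bench a `fall_benchmark` from [generate_benchmark_suite()].
#' @param config a `fall_config`.
#' @param verbose print one line per sequence.
#' @return Object of class `fall_eval`: list with `results` (data.frame:
#'   id, activity, truth, verdict, n_events, stages), `confusion` and
#'   `metrics`.
#' @export
run_benchmark <- function(bench, config = run_config(), verbose = FALSE) {
  results <- data.frame(id = character(0), activity = character(0),
                        truth = character(0), verdict = character(0),
                        n_events = integer(0), stages = character(0))
  for (sq in bench) {
    scene <- render_sequence(sq$config)
    run <- process_sequence(scene$frames, config)
    stages <- paste(unique(run$events$stage), collapse = "+")
    results <- rbind(results, data.frame(
      id = sq$id, activity = sq$activity, truth = sq$label,
      verdict = run$verdict, n_events = nrow(run$events),
      stages = if (nzchar(stages)) stages else "none"))
    if (verbose)
      message(sprintf("%-16s truth=%-6s verdict=%-6s events=%d",
                      sq$id, sq$label, run$verdict, nrow(run$events)))
  }
  cm <- confusion_matrix(results$truth, results$verdict)
  structure(list(results = results, confusion = cm,
                 metrics = fall_metrics(cm)),
            class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat("Benchmark evaluation over", nrow(x$results), "sequences\n")
  print(x$metrics)
  invisible(x)
}
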