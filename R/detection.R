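#' Fall-detector parameters
#'
#' Thresholds of the two-stage cascade. Stage one fires on the bounding-box
#' aspect ratio alone (`ratio >= th1`); stage two requires the ratio to sit
#' in `[th2, th1)` together with a large normalized vertical velocity and a
#' large depth variation — the combination that catches backward/forward
#' falls whose silhouette never goes fully horizontal.
#'
#' @param th1 ratio threshold of the first detector (default 1.5).
#' @param th2 lower ratio bound of the second detector (`th2 < th1`).
#' @param th_velocity threshold on |normalized vertical velocity| in
#'   frame-heights per second (default 0.3).
#' @param th_depth threshold on |depth variation| over the window.
#' @param velocity_window frames over which velocity and depth variation are
#'   measured.
#' @param persistence consecutive frames a fall condition must hold before
#'   an event is emitted.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(th1 = 1.5, th2 = 1.0, th_velocity = 0.3,
                            th_depth = 0.1, velocity_window = 5,
                            persistence = 5) {
  if (th2 >= th1) stop("need th2 < th1")
  if (th1 <= 0 || th2 <= 0 || th_velocity <= 0 || th_depth <= 0)
    stop("thresholds must be > 0")
  if (velocity_window < 1 || persistence < 1) stop("windows must be >= 1")
  structure(list(th1 = th1, th2 = th2, th_velocity = th_velocity,
                 th_depth = th_depth,
                 velocity_window = as.integer(velocity_window),
                 persistence = as.integer(persistence)),
            class = "detector_params")
}

#' Bounding-box aspect ratio
#'
#' width / height of the minimum bounding rectangle; it rises sharply when a
#' body goes from upright to lying, which makes it the primary fall feature.
#'
#' @param mbr rectangle `(x, y, w, h)` or any vector with named `w`, `h`.
#' @return w / h.
#' @export
mbr_ratio <- function(mbr) {
  w <- if (!is.null(names(mbr))) mbr[["w"]] else mbr[3L]
  h <- if (!is.null(names(mbr))) mbr[["h"]] else mbr[4L]
  if (is.na(h) || h <= 0) stop("bounding box height must be > 0")
  if (w <= 0) stop("bounding box width must be > 0")
  w / h
}

#' Normalized vertical centroid velocity
#'
#' `v = (y_c[t] - y_c[t - window]) / (window * frame_height) * fps`; positive
#' is downward. With the default `fps = 1` the value is in frame-heights per
#' frame; the detector passes the sequence frame rate so the threshold is in
#' frame-heights per second. Returns `NA` when the history is shorter than
#' `window + 1` (the detector treats that as 0).
#'
#' @param y_history vertical centroid positions up to the current frame.
#' @param window backward window in frames.
#' @param frame_height frame height in pixels.
#' @param fps frames per second used to convert to per-second units.
#' @return Normalized velocity, or `NA` if the history is too short.
#' @export
vertical_velocity <- function(y_history, window, frame_height, fps = 1) {
  n <- length(y_history)
  if (n < window + 1L) return(NA_real_)
  (y_history[n] - y_history[n - window]) / (window * frame_height) * fps
}

#' Depth variation of the silhouette centroid
#'
#' Signed change of the mean object depth over the window:
#' `Z_c[t] - Z_c[t - window]`. Positive when the subject moves away from the
#' camera (backward fall), negative toward it (forward fall). Returns `NA`
#' on insufficient history; when the sequence has no depth channel the
#' pipeline feeds a constant 0 history, degrading the second detector to
#' ratio + velocity.
#'
#' @param z_history mean-depth history up to the current frame.
#' @param window backward window in frames.
#' @return Signed depth change, or `NA` if the history is too short.
#' @export
depth_variation <- function(z_history, window) {
  n <- length(z_history)
  if (n < window + 1L) return(NA_real_)
  z_history[n] - z_history[n - window]
}

#' First-stage fall test
#'
#' @param ratio bounding-box aspect ratio (> 0).
#' @param params a [detector_params] object.
#' @return `"fall"` iff `ratio >= th1` (inclusive), else `"escalate"`.
#' @export
ufed1 <- function(ratio, params = detector_params()) {
  if (ratio >= params$th1) "fall" else "escalate"
}

#' Second-stage fall test
#'
#' @param ratio bounding-box aspect ratio.
#' @param velocity normalized vertical velocity.
#' @param delta_z depth variation over the window.
#' @param params a [detector_params] object.
#' @return `"fall"` iff `th2 <= ratio < th1` and `|velocity| >= th_velocity`
#'   and `|delta_z| >= th_depth`; else `"normal"`.
#' @export
ufed2 <- function(ratio, velocity, delta_z, params = detector_params()) {
  if (ratio >= params$th2 && ratio < params$th1 &&
      abs(velocity) >= params$th_velocity &&
      abs(delta_z) >= params$th_depth) "fall" else "normal"
}

#' Run the fall-detection cascade over one object track
#'
#' Per frame the detector computes the aspect ratio, the normalized vertical
#' velocity and the depth variation, runs the stage-one test and, if it does
#' not fire, the stage-two test. A fall event is emitted when the combined
#' condition holds for `persistence` consecutive frames; consecutive fall
#' frames merge into one event. The event stage is the stage that held at
#' the triggering frame (the frame completing the persistence run).
#'
#' @param history per-frame track history data.frame with columns `frame`,
#'   `w`, `h`, `y_c`, `Z_c` (as produced by [track_blobs()]).
#' @param frame_height frame height in pixels.
#' @param params a [detector_params] object.
#' @param fps frame rate; velocity thresholding is done in per-second units.
#' @return Object of class `fall_events`: list with `events` (data.frame:
#'   onset_frame, end_frame, stage) and `frames` (per-frame decision
#'   data.frame: frame, ratio, velocity, delta_z, stage, fall).
#' @export
detect_events <- function(history, frame_height, params = detector_params(),
                          fps = 30) {
  n <- nrow(history)
  ratio <- history$w / history$h
  velocity <- delta_z <- numeric(n)
  wdw <- params$velocity_window
  for (i in seq_len(n)) {
    v <- vertical_velocity(history$y_c[seq_len(i)], wdw, frame_height, fps)
    z <- depth_variation(history$Z_c[seq_len(i)], wdw)
    velocity[i] <- if (is.na(v)) 0 else v
    delta_z[i] <- if (is.na(z)) 0 else z
  }
  stage1 <- ratio >= params$th1
  stage2 <- !stage1 & ratio >= params$th2 & ratio < params$th1 &
    abs(velocity) >= params$th_velocity & abs(delta_z) >= params$th_depth
  cond <- stage1 | stage2
  # run lengths of the combined condition
  run <- integer(n)
  for (i in seq_len(n)) run[i] <- if (cond[i]) (if (i > 1) run[i - 1L] else 0L) + 1L else 0L
  fall <- run >= params$persistence
  events <- data.frame(onset_frame = integer(0), end_frame = integer(0),
                       stage = character(0))
  i <- 1L
  while (i <= n) {
    if (fall[i]) {
      j <- i
      while (j < n && fall[j + 1L]) j <- j + 1L
      start_run <- i - params$persistence + 1L
      stg <- if (stage1[i]) "ufed1" else "ufed2"  # stage at the trigger frame
      events <- rbind(events, data.frame(
        onset_frame = history$frame[start_run],
        end_frame = history$frame[j], stage = stg))
      i <- j + 1L
    } else i <- i + 1L
  }
  frames <- data.frame(frame = history$frame, ratio = ratio,
                       velocity = velocity, delta_z = delta_z,
                       stage = ifelse(stage1, "ufed1",
                                      ifelse(stage2, "ufed2", "none")),
                       fall = fall)
  structure(list(events = events, frames = frames, params = params),
            class = "fall_events")
}

#' @export
print.fall_events <- function(x, ...) {
  if (nrow(x$events) == 0L) {
    cat("No fall events detected over", nrow(x$frames), "frames.\n")
  } else {
    cat(nrow(x$events), "fall event(s):\n")
    for (r in seq_len(nrow(x$events)))
      cat(sprintf("  Fall Detect: frames %d-%d (stage %s)\n",
                  x$events$onset_frame[r], x$events$end_frame[r],
                  x$events$stage[r]))
  }
  invisible(x)
}

#' Sequence-level confusion matrix
#'
#' A sequence counts as a true positive when its ground-truth label is fall
#' and at least one fall event was emitted for it.
#'
#' @param truth,predicted character vectors of `"fall"` / `"normal"` labels,
#'   one per sequence.
#' @return Object of class `fall_confusion`: named integer vector
#'   `(tp, fp, fn, tn)`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  lv <- c("fall", "normal")
  if (!all(truth %in% lv) || !all(predicted %in% lv))
    stop("labels must be 'fall' or 'normal'")
  structure(c(tp = sum(truth == "fall" & predicted == "fall"),
              fp = sum(truth == "normal" & predicted == "fall"),
              fn = sum(truth == "fall" & predicted == "normal"),
              tn = sum(truth == "normal" & predicted == "normal")),
            class = "fall_confusion")
}

#' Detection performance rates
#'
#' Sensitivity = TP / (TP + FN) x 100, specificity = TN / (FP + TN) x 100,
#' accuracy = (TP + TN) / total x 100, false-positive rate =
#' FP / (FP + TN) x 100. A rate whose denominator is zero is `NA`.
#'
#' @param cm a [confusion_matrix()] result or named vector with `tp`, `fp`,
#'   `fn`, `tn`.
#' @return Object of class `fall_metrics`: named vector `(sensitivity,
#'   specificity, accuracy, false_positive_rate)` in percent, with the
#'   counts attached as an attribute.
#' @export
fall_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- c(sensitivity = rate(tp, tp + fn),
           specificity = rate(tn, fp + tn),
           accuracy = rate(tp + tn, tp + fp + fn + tn),
           false_positive_rate = rate(fp, fp + tn))
  structure(out, counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "fall_metrics")
}

#' @export
print.fall_metrics <- function(x, digits = 2, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("Confusion counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              cts[["tp"]], cts[["fp"]], cts[["fn"]], cts[["tn"]], sum(cts)))
  for (nm in names(unclass(x)))
    cat(sprintf("  %-20s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA",
                       formatC(x[[nm]], digits = digits, format = "f"))))
  invisible(x)
}
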