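#' Write a rendered sequence to standard frame directories
#'
#' Writes 8-bit RGB PNGs (`frame_%04d.png`), 16-bit depth TIFFs
#' (`depth_%04d.tif`), ground-truth label PNGs (`label_%04d.png`, pixel
#' values 0 = background, 1 = object, 2 = shadow scaled into the 8-bit
#' range as 0/128/255 for visibility) and a `manifest.json` describing the
#' sequence.
#'
#' @param scene output of [render_sequence()].
#' @param dir output directory (created if needed).
#' @param config the [scene_config()] used (stored in the manifest).
#' @return The directory, invisibly.
#' @export
write_sequence <- function(scene, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(scene$frames)
  for (i in seq_len(n)) {
    f <- scene$frames[[i]]
    png::writePNG(f$rgb, file.path(dir, sprintf("frame_%04d.png", i - 1L)))
    if (!is.null(f$depth))
      tiff::writeTIFF(f$depth, file.path(dir, sprintf("depth_%04d.tif", i - 1L)),
                      bits.per.sample = 16)
    lab <- scene$truth$labels[[i]]
    png::writePNG(matrix(c(0, 128, 255)[lab + 1L] / 255, nrow(lab), ncol(lab)),
                  file.path(dir, sprintf("label_%04d.png", i - 1L)))
  }
  manifest <- list(n_frames = n, label = scene$truth$label,
                   activity = scene$truth$activity,
                   fall_onset = scene$truth$fall_onset)
  if (!is.null(config)) manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Resize a frame by a scale factor
#'
#' Bilinear resize of the RGB raster and depth plane; used to trade accuracy
#' for speed on large input frames.
#'
#' @param frame a [vframe].
#' @param factor scale factor in (0, 1].
#' @return The resized [vframe].
#' @export
resize_frame <- function(frame, factor) {
  if (factor == 1) return(frame)
  if (factor <= 0 || factor > 1) stop("'factor' must lie in (0, 1]")
  d <- frame_dim(frame)
  h2 <- max(round(d[1L] * factor), 2L); w2 <- max(round(d[2L] * factor), 2L)
  rgb <- array(0, c(h2, w2, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- as.matrix(EBImage::resize(frame$rgb[, , ch], w = h2, h = w2))
  rgb <- pmin(pmax(rgb, 0), 1)
  depth <- NULL
  if (!is.null(frame$depth))
    depth <- pmin(pmax(as.matrix(EBImage::resize(frame$depth, w = h2, h = w2)),
                       0), 1)
  vframe(rgb, depth, index = frame$index, fps = 1)
}

#' Simulate scene directories for each activity
#'
#' Delegates to [render_sequence()] for `n_per_activity` variants of every
#' activity and writes each to its own directory under `out_dir`.
#'
#' @param out_dir output root directory.
#' @param n_per_activity sequences per activity (>= 1).
#' @param seed master seed.
#' @param ... forwarded to [generate_benchmark_suite()].
#' @return Character vector of sequence directories, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_per_activity = 1, seed = 1, ...) {
  bench <- generate_benchmark_suite(n_per_activity, seed, ...)
  dirs <- character(0)
  for (sq in bench) {
    d <- file.path(out_dir, sq$id)
    write_sequence(render_sequence(sq$config), d, config = sq$config)
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}

load_and_resize <- function(input_dir, depth_dir, config) {
  # a write_sequence() directory mixes frame_/depth_/label_ files: select by
  # prefix, and pick up the colocated depth planes automatically
  has_frames <- length(list.files(input_dir, pattern = "^frame_.*\\.png$")) > 0
  prefix <- if (has_frames) "frame_" else NULL
  depth_prefix <- NULL
  if (is.null(depth_dir) &&
      length(list.files(input_dir, pattern = "^depth_.*\\.(tif|tiff|png)$"))) {
    depth_dir <- input_dir
    depth_prefix <- "depth_"
  } else if (!is.null(depth_dir) &&
             length(list.files(depth_dir, pattern = "^depth_"))) {
    depth_prefix <- "depth_"
  }
  frames <- load_frame_sequence(input_dir, depth_dir, fps = config$fps,
                                prefix = prefix, depth_prefix = depth_prefix)
  if (config$resize != 1)
    frames <- lapply(frames, resize_frame, factor = config$resize)
  frames
}

#' Segment an on-disk sequence and write label masks
#'
#' Runs foreground segmentation plus shadow removal over a frame directory
#' and writes one label PNG per frame (0 = background, 128 = object,
#' 255 = shadow) together with a log of per-frame pixel counts and the
#' resolved parameter set.
#'
#' @param input_dir directory of numbered RGB frames.
#' @param out_dir output directory.
#' @param config a `fall_config`.
#' @param depth_dir optional directory of depth frames.
#' @return data.frame of per-frame object/shadow pixel counts, invisibly.
#' @export
cmd_segment <- function(input_dir, out_dir, config = run_config(),
                        depth_dir = NULL) {
  frames <- load_and_resize(input_dir, depth_dir, config)
  seg <- segment_sequence(frames, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(frame = integer(0), object_px = integer(0),
                       shadow_px = integer(0))
  for (i in seq_along(seg$labels)) {
    lab <- seg$labels[[i]]
    png::writePNG(matrix(c(0, 128, 255)[lab + 1L] / 255, nrow(lab), ncol(lab)),
                  file.path(out_dir, sprintf("label_%04d.png", i - 1L)))
    counts <- rbind(counts, data.frame(frame = i - 1L,
                                       object_px = sum(lab == 1L),
                                       shadow_px = sum(lab == 2L)))
  }
  utils::write.csv(counts, file.path(out_dir, "segment_log.csv"),
                   row.names = FALSE)
  save_config(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(counts)
}

#' Detect falls in an on-disk sequence
#'
#' Runs the full pipeline over a frame directory, writes the events CSV
#' (`sequence_id, frame, stage, ratio, velocity, delta_z, verdict`), prints
#' a "Fall Detect" line per event, and — when the directory carries a
#' ground-truth `manifest.json` — writes a metrics JSON scoring this
#' sequence's verdict.
#'
#' @param input_dir directory of numbered RGB frames (a [write_sequence()]
#'   directory works unchanged).
#' @param out_dir output directory.
#' @param config a `fall_config`.
#' @param depth_dir optional depth directory; defaults to `input_dir` when
#'   it contains depth files.
#' @return The `fall_run`, invisibly.
#' @export
cmd_detect <- function(input_dir, out_dir, config = run_config(),
                       depth_dir = NULL) {
  frames <- load_and_resize(input_dir, depth_dir, config)
  run <- process_sequence(frames, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(names(run$per_object), function(id) {
    fr <- run$per_object[[id]]$frames
    data.frame(sequence_id = basename(input_dir), object_id = id,
               frame = fr$frame, stage = fr$stage, ratio = fr$ratio,
               velocity = fr$velocity, delta_z = fr$delta_z,
               verdict = ifelse(fr$fall, "fall", "normal"))
  }))
  if (is.null(rows))
    rows <- data.frame(sequence_id = character(0), object_id = character(0),
                       frame = integer(0), stage = character(0),
                       ratio = numeric(0), velocity = numeric(0),
                       delta_z = numeric(0), verdict = character(0))
  utils::write.csv(rows, file.path(out_dir, "events.csv"), row.names = FALSE)
  save_config(config, file.path(out_dir, "resolved_config.yaml"))
  print(run)
  manifest_file <- file.path(input_dir, "manifest.json")
  if (file.exists(manifest_file)) {
    manifest <- jsonlite::read_json(manifest_file)
    cm <- confusion_matrix(manifest$label, run$verdict)
    m <- fall_metrics(cm)
    jsonlite::write_json(
      c(as.list(unclass(m)), as.list(attr(m, "counts"))),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(run)
}
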