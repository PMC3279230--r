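#' Synthetic indoor-scene configuration
#'
#' Describes one rendered sequence: a static background (flat color with an
#' optional vertical brightness gradient; the gradient scales all channels
#' equally so chromaticity is preserved), a moving actor drawn as a filled
#' ellipse, a cast shadow drawn as a displaced ellipse where the background
#' RGB is multiplied by `shadow_attenuation` (chroma preserved exactly), an
#' aligned depth plane, and i.i.d. Gaussian pixel noise added last. The
#' first `lead_in` frames contain background only, emulating the camera
#' running before the person enters; they seed the background model.
#'
#' @param width,height frame size in pixels.
#' @param fps frame rate.
#' @param n_frames number of actor frames (>= 10); total length is
#'   `lead_in + n_frames`.
#' @param lead_in number of background-only frames prepended.
#' @param activity one of `"walk"`, `"stand"`, `"crouch_stand"` (crouch then
#'   rise), `"crouch_down"`, `"stand_up"`, `"fall_backward"`,
#'   `"fall_forward"`, `"fall_left"`, `"fall_right"`.
#' @param background RGB triple of the base background color.
#' @param bg_gradient relative vertical brightness span (0 = flat).
#' @param noise_sigma per-channel Gaussian noise standard deviation.
#' @param shadow_attenuation value multiplier k in (0, 1) for shadow pixels.
#' @param shadow_offset pixel offset `(dx, dy)` of the shadow ellipse
#'   (down-right of the actor).
#' @param actor_color RGB triple of the actor.
#' @param actor_height actor height as a fraction of the frame height.
#' @param bg_depth constant background depth in \[0, 1\].
#' @param z0 actor depth at the start of the script.
#' @param fall_start actor-frame index at which a fall script begins.
#' @param fall_duration fall length in frames.
#' @param seed RNG seed; sequences are bit-identical given the seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 160, height = 120, fps = 30, n_frames = 60,
                         lead_in = 10, activity = "walk",
                         background = c(0.35, 0.45, 0.55), bg_gradient = 0.1,
                         noise_sigma = 0.01, shadow_attenuation = 0.6,
                         shadow_offset = NULL,
                         actor_color = c(0.75, 0.30, 0.25),
                         actor_height = 0.55, bg_depth = 0.9, z0 = 0.45,
                         fall_start = 20, fall_duration = 14, seed = 1) {
  activity <- match.arg(activity, c("walk", "stand", "crouch_stand",
                                    "crouch_down", "stand_up",
                                    "fall_backward", "fall_forward",
                                    "fall_left", "fall_right"))
  if (shadow_attenuation <= 0 || shadow_attenuation >= 1)
    stop("'shadow_attenuation' must lie in (0, 1)")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (n_frames < 10) stop("'n_frames' must be >= 10")
  if (is.null(shadow_offset))
    shadow_offset <- c(round(0.06 * width), round(0.03 * height))
  structure(list(width = width, height = height, fps = fps,
                 n_frames = as.integer(n_frames), lead_in = as.integer(lead_in),
                 activity = activity, background = background,
                 bg_gradient = bg_gradient, noise_sigma = noise_sigma,
                 shadow_attenuation = shadow_attenuation,
                 shadow_offset = shadow_offset, actor_color = actor_color,
                 actor_height = actor_height, bg_depth = bg_depth, z0 = z0,
                 fall_start = as.integer(fall_start),
                 fall_duration = as.integer(fall_duration),
                 seed = as.integer(seed)),
            class = "scene_config")
}

fall_activities <- c("fall_backward", "fall_forward", "fall_left", "fall_right")

# evaluate a block of code under a temporary RNG seed, restoring global state
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Per-frame actor geometry for a scripted activity
#'
#' Returns the ellipse center, semi-axes and depth of the actor for each
#' frame of the activity. Shapes are designed to the detector's feature
#' space: walking keeps the aspect ratio (w/h of the bounding box,
#' = ax / ay) near 0.5; crouch/stand raises it toward ~0.9 at slow vertical
#' velocity; sideways falls push it monotonically past 2.0; backward and
#' forward falls peak near 1.35 while the centroid drops fast and the mean
#' depth moves by >= 0.25 (up for backward, down for forward).
#'
#' @param activity activity name (see [scene_config()]).
#' @param n_frames number of frames (>= 10).
#' @param geometry list with `width` and `height` in pixels.
#' @param actor_height actor height as a fraction of the frame height.
#' @param z0 starting depth.
#' @param fall_start,fall_duration fall timing in frames.
#' @param walk_dir +1 (rightward) or -1.
#' @return data.frame with columns `frame` (0-based), `cx`, `cy`, `ax`,
#'   `ay`, `zc`.
#' @export
activity_script <- function(activity, n_frames, geometry,
                            actor_height = 0.55, z0 = 0.45,
                            fall_start = 20, fall_duration = 14,
                            walk_dir = 1) {
  if (n_frames < 10) stop("'n_frames' must be >= 10")
  activity <- match.arg(activity, c("walk", "stand", "crouch_stand",
                                    "crouch_down", "stand_up",
                                    fall_activities))
  w <- geometry$width; h <- geometry$height
  ay0 <- actor_height * h / 2
  ax0 <- 0.5 * ay0
  floor_y <- 0.9 * h
  t <- seq_len(n_frames) - 1L
  cx <- rep(0.5 * w, n_frames)
  ax <- rep(ax0, n_frames); ay <- rep(ay0, n_frames)
  zc <- rep(z0, n_frames)
  if (activity == "walk") {
    span <- 0.5 * w * walk_dir
    cx <- 0.5 * w - span / 2 + span * t / (n_frames - 1L)
  } else if (activity == "crouch_stand") {
    dip <- sin(pi * t / (n_frames - 1L))^2
    ay <- ay0 * (1 - 0.44 * dip)
  } else if (activity %in% c("crouch_down", "stand_up")) {
    # smoothstep transition over the middle of the script; slow enough that
    # the vertical velocity stays well below the fall threshold
    t0 <- round(0.25 * n_frames); d <- round(0.4 * n_frames)
    p <- pmin(pmax((t - t0) / d, 0), 1)
    p <- p^2 * (3 - 2 * p)
    if (activity == "stand_up") p <- 1 - p
    ay <- ay0 * (1 - 0.44 * p)
  } else if (activity %in% fall_activities) {
    f0 <- min(fall_start, n_frames - fall_duration - 5L)
    p <- pmin(pmax((t - f0) / fall_duration, 0), 1)
    if (activity %in% c("fall_left", "fall_right")) {
      ay_f <- 0.42 * ay0; ax_f <- 0.95 * ay0   # final aspect ~2.26
      ax <- ax0 + (ax_f - ax0) * p
      ay <- ay0 + (ay_f - ay0) * p
      cx <- cx + (if (activity == "fall_right") 1 else -1) * 0.12 * w * p
    } else {
      ay_f <- 0.35 * ay0
      aspect <- 0.5 + (1.25 - 0.5) * sqrt(p)   # crosses 1.0 early in the fall
      ay <- ay0 + (ay_f - ay0) * p             # constant-rate centroid drop
      ax <- aspect * ay
      dz <- if (activity == "fall_backward") 0.4 else -0.4
      zc <- pmin(pmax(z0 + dz * p, 0.02), 0.98)
    }
  }
  cy <- floor_y - ay
  data.frame(frame = t, cx = cx, cy = cy, ax = ax, ay = ay, zc = zc)
}

ellipse_mask <- function(xg, yg, cx, cy, ax, ay) {
  ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1
}

#' Render a synthetic sequence with per-pixel ground truth
#'
#' Draws the actor ellipse along the activity script, a chroma-preserving
#' attenuated cast shadow displaced down-right, and the depth plane
#' (constant background depth, actor pixels at the scripted depth). Ground
#' truth (labels, tight actor bounding box, centroid, depth) is recorded
#' before noise is added. Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @return List with `frames` (list of [vframe]) and `truth`: list with
#'   per-frame `labels` (0 = background, 1 = actor, 2 = shadow), `mbr`
#'   (x, y, w, h; NA on background-only frames), `centroid`, `zc`, plus
#'   sequence-level `label` ("fall"/"normal"), `activity` and `fall_onset`
#'   (0-based frame index, NA for normal activities).
#' @export
render_sequence <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, function() {
    w <- config$width; h <- config$height
    script <- activity_script(config$activity, config$n_frames,
                              list(width = w, height = h),
                              actor_height = config$actor_height,
                              z0 = config$z0, fall_start = config$fall_start,
                              fall_duration = config$fall_duration)
    xg <- matrix(rep(0:(w - 1L), each = h), h, w)
    yg <- matrix(rep(0:(h - 1L), w), h, w)
    vfac <- 1 - config$bg_gradient + config$bg_gradient * yg / max(h - 1L, 1L)
    bg <- array(0, c(h, w, 3L))
    for (ch in 1:3) bg[, , ch] <- config$background[ch] * vfac
    n_total <- config$lead_in + config$n_frames
    frames <- vector("list", n_total)
    labels <- vector("list", n_total)
    mbr <- matrix(NA_real_, n_total, 4L,
                  dimnames = list(NULL, c("x", "y", "w", "h")))
    centroid <- matrix(NA_real_, n_total, 2L,
                       dimnames = list(NULL, c("x", "y")))
    zc <- rep(NA_real_, n_total)
    for (i in seq_len(n_total)) {
      img <- bg
      depth <- matrix(config$bg_depth, h, w)
      lab <- matrix(0L, h, w)
      if (i > config$lead_in) {
        s <- script[i - config$lead_in, ]
        actor <- ellipse_mask(xg, yg, s$cx, s$cy, s$ax, s$ay)
        shadow <- ellipse_mask(xg, yg, s$cx + config$shadow_offset[1L],
                               s$cy + config$shadow_offset[2L], s$ax, s$ay) &
          !actor
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[shadow] <- pl[shadow] * config$shadow_attenuation
          pl[actor] <- config$actor_color[ch]
          img[, , ch] <- pl
        }
        depth[actor] <- s$zc
        lab[shadow] <- 2L
        lab[actor] <- 1L
        if (any(actor)) {
          px <- which(actor, arr.ind = TRUE)
          xs <- px[, 2L] - 1L; ys <- px[, 1L] - 1L
          mbr[i, ] <- c(min(xs), min(ys), max(xs) - min(xs) + 1L,
                        max(ys) - min(ys) + 1L)
          centroid[i, ] <- c(mean(xs), mean(ys))
          zc[i] <- s$zc
        }
      }
      if (config$noise_sigma > 0) {
        img <- img + array(stats::rnorm(length(img), 0, config$noise_sigma),
                           dim(img))
        img <- pmin(pmax(img, 0), 1)
      }
      frames[[i]] <- vframe(img, depth, index = i - 1L, fps = config$fps)
      labels[[i]] <- lab
    }
    is_fall <- config$activity %in% fall_activities
    onset <- if (is_fall)
      config$lead_in + min(config$fall_start,
                           config$n_frames - config$fall_duration - 5L)
    else NA_integer_
    list(frames = frames,
         truth = list(labels = labels, mbr = mbr, centroid = centroid,
                      zc = zc, activity = config$activity,
                      label = if (is_fall) "fall" else "normal",
                      fall_onset = onset))
  })
}

#' Generate a deterministic benchmark suite of scene configurations
#'
#' Spans all 8 activities with `n_per_activity` variants each, randomizing
#' actor height, fall timing, walk direction and actor color within bounds.
#' Returns configurations rather than rendered frames so sequences can be
#' rendered, processed and discarded one at a time; [render_sequence()] on
#' any element reproduces its frames bit-identically.
#'
#' @param n_per_activity sequences per activity (>= 1).
#' @param seed master seed; the whole suite is deterministic given it.
#' @param width,height,n_frames,lead_in,noise_sigma passed to
#'   [scene_config()].
#' @return Object of class `fall_benchmark`: list of elements with `id`,
#'   `activity`, `label` and `config`.
#' @export
generate_benchmark_suite <- function(n_per_activity = 5, seed = 1,
                                     width = 160, height = 120,
                                     n_frames = 60, lead_in = 10,
                                     noise_sigma = 0.01) {
  if (n_per_activity < 1) stop("'n_per_activity' must be >= 1")
  activities <- c("walk", "stand", "crouch_down", "stand_up", fall_activities)
  with_seed(seed, function() {
    out <- list()
    for (act in activities) for (i in seq_len(n_per_activity)) {
      cfg <- scene_config(
        width = width, height = height, n_frames = n_frames,
        lead_in = lead_in, activity = act, noise_sigma = noise_sigma,
        actor_height = stats::runif(1, 0.50, 0.60),
        actor_color = pmin(pmax(c(0.75, 0.30, 0.25) +
                                  stats::runif(3, -0.08, 0.08), 0), 1),
        z0 = stats::runif(1, 0.40, 0.50),
        fall_start = sample(15:22, 1),
        seed = sample.int(.Machine$integer.max - 1L, 1))
      out[[length(out) + 1L]] <- list(
        id = sprintf("%s_%02d", act, i), activity = act,
        label = if (act %in% fall_activities) "fall" else "normal",
        config = cfg)
    }
    structure(out, class = "fall_benchmark")
  })
}

#' @export
print.fall_benchmark <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<fall_benchmark: %d sequences (%d fall, %d normal)>\n",
              length(x), sum(labs == "fall"), sum(labs == "normal")))
  invisible(x)
}
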