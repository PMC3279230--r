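#' Extract object blobs from a label mask
#'
#' One blob per 8-connected object-labelled component with area >= `min_area`.
#' Coordinates follow the package convention: 0-based `(x, y)`, rectangles
#' half-open `[x, x + w) x [y, y + h)`. The 3-D centroid normalizes x by the
#' frame width and y by the frame height; `z` is the median depth over the
#' component's pixels (0 when no depth plane is given) — the median rather
#' than the mean so that background pixels swept into the component by
#' motion-edge artifacts cannot bias the depth estimate.
#'
#' @param labels integer label matrix (0 = background, 1 = object, 2 = shadow)
#'   or a 0/1 mask.
#' @param depth optional `H x W` depth plane in \[0, 1\].
#' @param frame optional [vframe] or rgb array used for the blob mean color.
#' @param min_area minimum component area in pixels.
#' @return List of blobs; each blob is a list with `mbr` (x, y, w, h),
#'   `centroid_2d`, `centroid_3d`, `area`, `binary_map`, `mean_color`.
#' @export
extract_blobs <- function(labels, depth = NULL, frame = NULL, min_area = 1) {
  obj <- matrix(as.integer(labels == 1L), nrow(labels), ncol(labels))
  lab <- label_components(obj)
  n <- max(lab)
  if (n == 0L) return(list())
  h <- nrow(lab); w <- ncol(lab)
  rgb <- if (!is.null(frame)) { if (inherits(frame, "vframe")) frame$rgb else frame }
  blobs <- list()
  for (id in seq_len(n)) {
    px <- which(lab == id, arr.ind = TRUE)  # (row = y+1, col = x+1)
    if (nrow(px) < min_area) next
    ys <- px[, 1L] - 1L; xs <- px[, 2L] - 1L
    mbr <- c(x = min(xs), y = min(ys),
             w = max(xs) - min(xs) + 1L, h = max(ys) - min(ys) + 1L)
    c2 <- c(x = mean(xs), y = mean(ys))
    zc <- if (is.null(depth)) 0 else stats::median(depth[px])
    c3 <- c(x = c2[["x"]] / w, y = c2[["y"]] / h, z = zc)
    bmap <- lab[(mbr[["y"]] + 1L):(mbr[["y"]] + mbr[["h"]]),
                (mbr[["x"]] + 1L):(mbr[["x"]] + mbr[["w"]]), drop = FALSE]
    bmap <- matrix(as.integer(bmap == id), mbr[["h"]], mbr[["w"]])
    mcol <- if (is.null(rgb)) c(NA_real_, NA_real_, NA_real_) else
      c(mean(rgb[, , 1L][px]), mean(rgb[, , 2L][px]), mean(rgb[, , 3L][px]))
    blobs[[length(blobs) + 1L]] <- list(
      mbr = mbr, centroid_2d = c2, centroid_3d = c3,
      area = nrow(px), binary_map = bmap, mean_color = mcol)
  }
  blobs
}

#' Fixed-gain alpha-beta-gamma filter state
#'
#' Recursive position/velocity/acceleration estimator per axis with fixed
#' gains; it has zero steady-state error on constant-acceleration targets.
#' The gains are named `g_alpha`, `g_beta`, `g_gamma` to avoid collision with
#' the shadow-test bounds. Stability of the gain triple is asserted at
#' construction: the closed-loop error transition matrix `(I - K H) F` must
#' have spectral radius < 1.
#'
#' @param x,y initial position.
#' @param dt inter-frame interval in seconds (> 0).
#' @param g_alpha,g_beta,g_gamma filter gains in (0, 1].
#' @return An object of class `abg_state`.
#' @export
abg_state <- function(x, y, dt = 1 / 30, g_alpha = 0.5, g_beta = 0.4,
                      g_gamma = 0.1) {
  if (dt <= 0) stop("'dt' must be > 0")
  g <- c(g_alpha, g_beta, g_gamma)
  if (any(g <= 0) || any(g > 1)) stop("gains must lie in (0, 1]")
  f_mat <- matrix(c(1, 0, 0, dt, 1, 0, dt^2 / 2, dt, 1), 3L, 3L)
  k_vec <- c(g_alpha, g_beta / dt, 2 * g_gamma / dt^2)
  a_cl <- (diag(3) - k_vec %*% t(c(1, 0, 0))) %*% f_mat
  if (max(Mod(eigen(a_cl, only.values = TRUE)$values)) >= 1)
    stop("unstable alpha-beta-gamma gain triple for dt = ", dt)
  structure(list(pos = c(x = x, y = y), vel = c(x = 0, y = 0),
                 acc = c(x = 0, y = 0), dt = dt,
                 g_alpha = g_alpha, g_beta = g_beta, g_gamma = g_gamma),
            class = "abg_state")
}

#' Predict position one frame ahead
#'
#' Constant-acceleration extrapolation over one `dt`; the state itself is
#' not modified.
#'
#' @param state an [abg_state].
#' @return Named vector `(x, y)` of the predicted position.
#' @export
abg_predict <- function(state) {
  state$pos + state$vel * state$dt + 0.5 * state$acc * state$dt^2
}

#' Update the filter with a measured position
#'
#' With residual `r = z - x_pred`: position <- `x_pred + g_alpha * r`,
#' velocity <- `v_pred + (g_beta / dt) * r`, acceleration <-
#' `a + (2 * g_gamma / dt^2) * r`, per axis.
#'
#' @param state an [abg_state].
#' @param measured named or plain numeric vector `(x, y)`.
#' @return The updated `abg_state`.
#' @export
abg_update <- function(state, measured) {
  z <- as.numeric(measured)[1:2]
  pred <- abg_predict(state)
  vpred <- state$vel + state$acc * state$dt
  r <- z - as.numeric(pred)
  state$pos <- pred + state$g_alpha * r
  state$vel <- vpred + (state$g_beta / state$dt) * r
  state$acc <- state$acc + (2 * state$g_gamma / state$dt^2) * r
  state
}

#' Greedy nearest-neighbour track/blob association
#'
#' Repeatedly pairs the globally closest (predicted track centroid, blob
#' centroid) couple within `gate_radius`; ties broken by lower track index.
#' Unmatched blobs will spawn new tracks, unmatched tracks are reported lost
#' for this frame.
#'
#' @param predicted list or n x 2 matrix of predicted track positions.
#' @param blobs list of blobs as from [extract_blobs()].
#' @param gate_radius maximum pairing distance in pixels (> 0).
#' @return List with `matches` (two-column matrix: track index, blob index),
#'   `unmatched_tracks`, `unmatched_blobs`.
#' @export
associate <- function(predicted, blobs, gate_radius) {
  if (gate_radius <= 0) stop("'gate_radius' must be > 0")
  pm <- if (is.matrix(predicted)) predicted else
    do.call(rbind, lapply(predicted, as.numeric))
  nt <- if (is.null(pm)) 0L else nrow(pm)
  nb <- length(blobs)
  matches <- matrix(integer(0), 0L, 2L)
  if (nt > 0L && nb > 0L) {
    bm <- do.call(rbind, lapply(blobs, function(b) as.numeric(b$centroid_2d)))
    d <- outer(seq_len(nt), seq_len(nb), Vectorize(function(i, j)
      sqrt(sum((pm[i, 1:2] - bm[j, ])^2))))
    d <- matrix(d, nt, nb)
    free_t <- rep(TRUE, nt); free_b <- rep(TRUE, nb)
    repeat {
      dd <- d
      dd[!free_t, ] <- Inf; dd[, !free_b] <- Inf
      if (all(!is.finite(dd)) || min(dd) > gate_radius) break
      ij <- which(dd == min(dd), arr.ind = TRUE)
      ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]
      matches <- rbind(matches, ij)
      free_t[ij[1L]] <- FALSE; free_b[ij[2L]] <- FALSE
      if (!any(free_t) || !any(free_b)) break
    }
  }
  dimnames(matches) <- list(NULL, c("track", "blob"))
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1L]),
       unmatched_blobs = setdiff(seq_len(nb), matches[, 2L]))
}

new_track <- function(id, blob, frame_idx, dt, gains) {
  state <- abg_state(blob$centroid_2d[["x"]], blob$centroid_2d[["y"]], dt,
                     gains[1L], gains[2L], gains[3L])
  list(object_id = id, state = state, mbr = blob$mbr,
       mean_color = blob$mean_color, binary_map = blob$binary_map,
       missed = 0L, last_frame = frame_idx,
       history = data.frame(frame = frame_idx,
                            x = blob$mbr[["x"]], y = blob$mbr[["y"]],
                            w = blob$mbr[["w"]], h = blob$mbr[["h"]],
                            x_c = blob$centroid_2d[["x"]],
                            y_c = blob$centroid_2d[["y"]],
                            X_c = blob$centroid_3d[["x"]],
                            Y_c = blob$centroid_3d[["y"]],
                            Z_c = blob$centroid_3d[["z"]]))
}

#' Track blobs across a sequence of label masks
#'
#' Maintains per-object identity with the alpha-beta-gamma predictor and
#' greedy gated association; unmatched tracks persist (coasting on the
#' predictor) for `max_missed` frames, then close. Re-appearing blobs get
#' fresh ids.
#'
#' @param blob_frames list (one element per frame) of blob lists as from
#'   [extract_blobs()].
#' @param fps frame rate (sets the filter `dt`).
#' @param gains numeric triple `(g_alpha, g_beta, g_gamma)`.
#' @param gate_radius association gate in pixels.
#' @param max_missed frames a track survives without a matched blob.
#' @param frame_indices optional 0-based indices of the supplied frames.
#' @return An object of class `track_set`: list with `history` (one
#'   data.frame row per track per frame: frame, object_id, x, y, w, h, x_c,
#'   y_c, X_c, Y_c, Z_c) and `tracks` (closed + open track records).
#' @export
track_blobs <- function(blob_frames, fps = 30, gains = c(0.5, 0.4, 0.1),
                        gate_radius = NULL, max_missed = 10,
                        frame_indices = NULL) {
  dt <- 1 / fps
  if (is.null(frame_indices)) frame_indices <- seq_along(blob_frames) - 1L
  active <- list()
  closed <- list()
  next_id <- 1L
  for (fi in seq_along(blob_frames)) {
    blobs <- blob_frames[[fi]]
    idx <- frame_indices[fi]
    preds <- lapply(active, function(tr) abg_predict(tr$state))
    gr <- gate_radius
    if (is.null(gr)) {
      hh <- if (length(blobs)) max(vapply(blobs, function(b)
        b$mbr[["y"]] + b$mbr[["h"]], numeric(1))) else 100
      gr <- max(0.15 * hh, 20)
    }
    asc <- associate(preds, blobs, gr)
    if (nrow(asc$matches)) for (r in seq_len(nrow(asc$matches))) {
      ti <- asc$matches[r, 1L]; bi <- asc$matches[r, 2L]
      tr <- active[[ti]]; b <- blobs[[bi]]
      tr$state <- abg_update(tr$state, b$centroid_2d)
      tr$mbr <- b$mbr; tr$binary_map <- b$binary_map
      tr$mean_color <- b$mean_color
      tr$missed <- 0L; tr$last_frame <- idx
      tr$history <- rbind(tr$history, data.frame(
        frame = idx, x = b$mbr[["x"]], y = b$mbr[["y"]],
        w = b$mbr[["w"]], h = b$mbr[["h"]],
        x_c = b$centroid_2d[["x"]], y_c = b$centroid_2d[["y"]],
        X_c = b$centroid_3d[["x"]], Y_c = b$centroid_3d[["y"]],
        Z_c = b$centroid_3d[["z"]]))
      active[[ti]] <- tr
    }
    for (ti in asc$unmatched_tracks) {
      tr <- active[[ti]]
      tr$state <- abg_update(tr$state, abg_predict(tr$state))  # coast
      tr$missed <- tr$missed + 1L
      active[[ti]] <- tr
    }
    for (bi in asc$unmatched_blobs) {
      active[[length(active) + 1L]] <- new_track(next_id, blobs[[bi]], idx,
                                                 dt, gains)
      next_id <- next_id + 1L
    }
    drop <- vapply(active, function(tr) tr$missed > max_missed, logical(1))
    closed <- c(closed, active[drop])
    active <- active[!drop]
  }
  tracks <- c(closed, active)
  hist <- do.call(rbind, lapply(tracks, function(tr)
    cbind(object_id = tr$object_id, tr$history)))
  if (!is.null(hist)) {
    hist <- hist[order(hist$frame, hist$object_id), ]
    rownames(hist) <- NULL
    hist <- hist[, c("frame", "object_id", "x", "y", "w", "h",
                     "x_c", "y_c", "X_c", "Y_c", "Z_c")]
  } else {
    hist <- data.frame(frame = integer(0), object_id = integer(0),
                       x = numeric(0), y = numeric(0), w = numeric(0),
                       h = numeric(0), x_c = numeric(0), y_c = numeric(0),
                       X_c = numeric(0), Y_c = numeric(0), Z_c = numeric(0))
  }
  structure(list(history = hist, tracks = tracks, fps = fps),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$history$object_id)
  cat(sprintf("<track_set: %d object(s) over %d frame row(s)>\n",
              length(ids), nrow(x$history)))
  invisible(x)
}
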