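#' Gaussian mixture background model
#'
#' Per-pixel mixture of `k` Gaussians over RGB with a shared per-component
#' variance (Stauffer--Grimson style). Components are ranked by weight/sigma;
#' the smallest prefix of that ranking whose cumulative weight exceeds
#' `bg_threshold` is taken as the background processes. The derived reference
#' background image B (used by the shadow masks) is each pixel's
#' dominant-weight component mean.
#'
#' @param frames list of [vframe]s (or `H x W x 3` arrays) used to initialize
#'   the model; the first component of every pixel is seeded with their
#'   sample mean and variance.
#' @param k number of Gaussians per pixel.
#' @param learning_rate online adaptation rate in (0, 1).
#' @param match_threshold match gate in standard deviations.
#' @param bg_threshold cumulative weight defining background components.
#' @param min_variance variance floor (keeps the match gate finite under
#'   noise-free input).
#' @param update_mode `"background_only"` (default) freezes the model at
#'   pixels classified foreground, so a person who stops moving is not
#'   absorbed into the background; `"full"` is the classic
#'   Stauffer--Grimson update of every pixel.
#' @return An object of class `background_model`.
#' @export
init_background <- function(frames, k = 3, learning_rate = 0.01,
                            match_threshold = 2.5, bg_threshold = 0.7,
                            min_variance = 1e-3,
                            update_mode = c("background_only", "full")) {
  update_mode <- match.arg(update_mode)
  if (length(frames) < 1L) stop("need at least one frame to initialize")
  if (k < 1L) stop("mixture size 'k' must be >= 1")
  if (learning_rate <= 0 || learning_rate >= 1)
    stop("'learning_rate' must lie in (0, 1)")
  arrs <- lapply(frames, function(f) if (inherits(f, "vframe")) f$rgb else f)
  d <- dim(arrs[[1L]])[1:2]
  n <- prod(d)
  x <- vapply(arrs, function(a) as.vector(a), numeric(n * 3L))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  mu1 <- matrix(rowMeans(x), n, 3L)
  if (ncol(x) > 1L) {
    v <- rowMeans((x - rowMeans(x))^2) * ncol(x) / (ncol(x) - 1L)
    var1 <- rowMeans(matrix(v, n, 3L))
  } else {
    var1 <- rep(min_variance, n)
  }
  w  <- matrix(0.01, n, k)
  mu <- array(0.5, c(n, 3L, k))
  vv <- matrix(0.25, n, k)
  w[, 1L]   <- 1 - 0.01 * (k - 1L)
  mu[, , 1L] <- mu1
  vv[, 1L]  <- pmax(var1, min_variance)
  structure(
    list(w = w, mu = mu, var = vv, dim = d, k = as.integer(k),
         learning_rate = learning_rate, match_threshold = match_threshold,
         bg_threshold = bg_threshold, min_variance = min_variance,
         update_mode = update_mode, n_seen = length(frames)),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model: %d x %d px, K = %d, lr = %g, %d frame(s) seen>\n",
              x$dim[2L], x$dim[1L], x$k, x$learning_rate, x$n_seen))
  invisible(x)
}

# per-pixel component ranking by weight / sigma (descending); ties broken by
# component index so the ranking is always a permutation
component_ranks <- function(w, vv) {
  k <- ncol(w)
  ratio <- w / sqrt(vv)
  rank <- matrix(1L, nrow(w), k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    beats <- if (b < a) ratio[, b] >= ratio[, a] else ratio[, b] > ratio[, a]
    rank[, a] <- rank[, a] + beats
  }
  rank
}

#' Reference background image
#'
#' @param model a `background_model`.
#' @return `H x W x 3` array: each pixel's dominant-weight component mean.
#' @export
reference_background <- function(model) {
  n <- prod(model$dim)
  kstar <- max.col(model$w, ties.method = "first")
  b <- array(0, c(model$dim, 3L))
  idx <- seq_len(n)
  for (ch in 1:3)
    b[, , ch] <- matrix(model$mu[cbind(idx, ch, kstar)], model$dim[1L])
  b
}

#' GMM foreground mask with online model update
#'
#' A pixel is foreground iff its value is not within `match_threshold`
#' standard deviations of any background-labelled Gaussian. The model is
#' updated online with the configured learning rate; unmatched pixels replace
#' their lowest-ranked component.
#'
#' @param model a `background_model`.
#' @param frame a [vframe] or `H x W x 3` array of matching dimensions.
#' @param update update the model online (default TRUE).
#' @return List with `mask` (H x W 0/1 matrix) and the (possibly updated)
#'   `model`.
#' @export
gmm_foreground <- function(model, frame, update = TRUE) {
  rgb <- if (inherits(frame, "vframe")) frame$rgb else frame
  if (!all(dim(rgb)[1:2] == model$dim))
    stop("frame dimensions do not match the background model")
  n <- prod(model$dim); k <- model$k
  x <- matrix(as.vector(rgb), n, 3L)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k))
    d2[, j] <- rowSums((x - model$mu[, , j])^2)
  gate <- model$match_threshold^2 * 3 * model$var
  matched <- d2 <= gate
  rank <- component_ranks(model$w, model$var)
  cumw_before <- matrix(0, n, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    cumw_before[, a] <- cumw_before[, a] + model$w[, b] * (rank[, b] < rank[, a])
  }
  is_bg <- cumw_before < model$bg_threshold
  fg <- rowSums(matched & is_bg) == 0
  mask <- matrix(as.integer(fg), model$dim[1L], model$dim[2L])

  if (update) {
    lr <- model$learning_rate
    has_match <- rowSums(matched) > 0
    rk <- rank; rk[!matched] <- k + 1L
    kbest <- max.col(-rk, ties.method = "first")
    # selective update: foreground pixels keep their model untouched, so a
    # target that stops moving is not absorbed into the background
    touch <- if (model$update_mode == "background_only") !fg else rep(TRUE, n)
    i_m <- which(has_match & touch)
    i_all <- which(touch)
    model$w[i_all, ] <- (1 - lr) * model$w[i_all, , drop = FALSE]
    if (length(i_m)) {
      ib <- cbind(i_m, kbest[i_m])
      model$w[ib] <- model$w[ib] + lr
      for (ch in 1:3) {
        im3 <- cbind(i_m, ch, kbest[i_m])
        model$mu[im3] <- model$mu[im3] + lr * (x[cbind(i_m, ch)] - model$mu[im3])
      }
      model$var[ib] <- pmax((1 - lr) * model$var[ib] + lr * d2[ib] / 3,
                            model$min_variance)
    }
    i_u <- which(!has_match & touch)
    if (length(i_u)) {
      kworst <- max.col(rank, ties.method = "first")
      iw <- cbind(i_u, kworst[i_u])
      model$w[iw] <- 0.05
      for (ch in 1:3)
        model$mu[cbind(i_u, ch, kworst[i_u])] <- x[cbind(i_u, ch)]
      model$var[iw] <- 0.01
    }
    model$w <- model$w / rowSums(model$w)
    model$n_seen <- model$n_seen + 1L
  }
  list(mask = mask, model = model)
}

#' Weighted three-frame difference mask
#'
#' Marks pixels where `w1 * |curr - prev| + w2 * |next - curr|` (taken
#' per channel, then the per-pixel maximum over channels) exceeds
#' `diff_threshold`. With `w2 = 0` this reduces to plain two-frame
#' differencing.
#'
#' @param prev,curr,nxt three consecutive frames ([vframe] or array).
#' @param w1,w2 non-negative weights of the two difference images.
#' @param diff_threshold decision threshold on the weighted difference.
#' @return `H x W` 0/1 matrix.
#' @export
weighted_frame_difference <- function(prev, curr, nxt, w1 = 0.5, w2 = 0.5,
                                      diff_threshold = 0.1) {
  if (w1 < 0 || w2 < 0) stop("difference weights must be non-negative")
  p <- if (inherits(prev, "vframe")) prev$rgb else prev
  c_ <- if (inherits(curr, "vframe")) curr$rgb else curr
  n <- if (inherits(nxt, "vframe")) nxt$rgb else nxt
  if (!all(dim(p) == dim(c_)) || !all(dim(c_) == dim(n)))
    stop("frames must share dimensions")
  d <- w1 * abs(c_ - p) + w2 * abs(n - c_)
  m <- pmax(d[, , 1L], d[, , 2L], d[, , 3L])
  matrix(as.integer(m > diff_threshold), dim(m)[1L], dim(m)[2L])
}

#' Combine two binary masks
#'
#' @param gmm,diff 0/1 matrices of equal dimensions.
#' @param mode `"union"` (pixelwise OR) or `"intersection"` (AND).
#' @return `H x W` 0/1 matrix.
#' @export
combine_masks <- function(gmm, diff, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!all(dim(gmm) == dim(diff))) stop("masks must share dimensions")
  out <- if (mode == "union") (gmm | diff) else (gmm & diff)
  matrix(as.integer(out), nrow(gmm), ncol(gmm))
}

#' Morphological cleanup of a binary mask
#'
#' Opening then closing with disc structuring elements, followed by removal
#' of 8-connected components smaller than `min_area` pixels.
#'
#' @param mask `H x W` 0/1 matrix.
#' @param open_radius,close_radius disc radii in pixels (0 skips the step).
#' @param min_area minimum surviving component area in pixels.
#' @return Cleaned `H x W` 0/1 matrix.
#' @export
morphological_cleanup <- function(mask, open_radius = 1, close_radius = 2,
                                  min_area = 50) {
  if (open_radius < 0 || close_radius < 0) stop("radii must be >= 0")
  m <- mask
  storage.mode(m) <- "double"
  if (open_radius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * open_radius + 1L, "disc"))
  if (close_radius > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * close_radius + 1L, "disc"))
  m <- matrix(as.integer(as.matrix(m) > 0.5), nrow(mask), ncol(mask))
  if (min_area > 1 && any(m > 0)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    m <- matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
  }
  m
}

#' 8-connected component labelling
#'
#' Wraps 4-connected labelling with a union-find merge across diagonal
#' neighbours, yielding 8-connectivity with dense labels 1..n.
#'
#' @param mask `H x W` 0/1 matrix.
#' @return Integer `H x W` matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- mask
  storage.mode(m) <- "double"
  lab <- as.matrix(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # (y, x) vs (y+1, x+1)
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # (y, x+1) vs (y+1, x)
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}
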