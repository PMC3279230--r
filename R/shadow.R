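#' Shadow-test parameters
#'
#' Thresholds of the two-stage spectral shadow test. The first mask (FSD)
#' accepts a pixel whose HSV value ratio against the background lies in
#' `[alpha, beta]` with bounded saturation and circular-hue differences;
#' the second mask (SSD) additionally requires the pixel to be darker than
#' the background in R and G with a bounded normalized-rg chromaticity
#' change. All thresholds are empirically set constants.
#'
#' @param alpha,beta lower/upper bound on the value ratio I_V / B_V, both in
#'   \[0, 1\] with `alpha <= beta`.
#' @param t_s saturation-difference threshold.
#' @param t_h circular hue-distance threshold (hue on \[0, 1)).
#' @param t_n normalized-rg chromaticity threshold of the second mask.
#' @param sat_floor saturation below which hue is treated as meaningless:
#'   when both pixels are this unsaturated the hue test passes.
#' @param ssd_chroma_mode `"as_printed"` applies the test
#'   `|dr| - |dg| <= t_n`; `"both_bounded"` applies
#'   `|dr| <= t_n & |dg| <= t_n`.
#' @return An object of class `shadow_params`.
#' @export
shadow_params <- function(alpha = 0.4, beta = 0.9, t_s = 0.1, t_h = 0.1,
                          t_n = 0.05, sat_floor = 0.05,
                          ssd_chroma_mode = c("as_printed", "both_bounded")) {
  ssd_chroma_mode <- match.arg(ssd_chroma_mode)
  if (alpha < 0 || beta > 1 || alpha > beta)
    stop("need 0 <= alpha <= beta <= 1")
  if (t_s < 0 || t_h < 0 || t_n < 0) stop("thresholds must be >= 0")
  structure(list(alpha = alpha, beta = beta, t_s = t_s, t_h = t_h, t_n = t_n,
                 sat_floor = sat_floor, ssd_chroma_mode = ssd_chroma_mode),
            class = "shadow_params")
}

#' First shadow mask (HSV test)
#'
#' Within the moving region, a pixel is flagged as shadow candidate iff
#' `alpha <= I_V / B_V <= beta`, `|I_S - B_S| <= t_s` and the circular hue
#' distance `|I_H - B_H| <= t_h`. Pixels with `B_V = 0` are never flagged
#' (a shadow cannot darken black); the hue test passes when both pixels are
#' effectively achromatic (saturation below `sat_floor`), since hue carries
#' no information there.
#'
#' @param current_hsv,background_hsv HSV plane lists as from [rgb_to_hsv()].
#' @param region `H x W` 0/1 moving-region mask.
#' @param params a [shadow_params] object.
#' @return `H x W` 0/1 matrix.
#' @export
fsd_mask <- function(current_hsv, background_hsv, region, params = shadow_params()) {
  if (!inherits(params, "shadow_params")) stop("'params' must be shadow_params")
  bv <- background_hsv$v
  ok <- bv > 0
  ratio <- ifelse(ok, current_hsv$v / ifelse(ok, bv, 1), Inf)
  cond_v <- ok & ratio >= params$alpha & ratio <= params$beta
  cond_s <- abs(current_hsv$s - background_hsv$s) <= params$t_s
  achrom <- current_hsv$s < params$sat_floor & background_hsv$s < params$sat_floor
  cond_h <- achrom | hue_distance(current_hsv$h, background_hsv$h) <= params$t_h
  matrix(as.integer(region > 0 & cond_v & cond_s & cond_h),
         nrow(region), ncol(region))
}

#' Second shadow mask (normalized-rg test)
#'
#' Within the moving region, a pixel is flagged iff it is strictly darker
#' than the background in both R and G and its normalized-rg chromaticity
#' change is bounded: `|dr| - |dg| <= t_n` as printed, or
#' `|dr| <= t_n & |dg| <= t_n` in `both_bounded` mode.
#'
#' @param current,background [vframe]s or `H x W x 3` arrays.
#' @param current_chroma,background_chroma chroma lists as from
#'   [normalized_rg()]; computed from the frames when NULL.
#' @param region `H x W` 0/1 moving-region mask.
#' @param params a [shadow_params] object.
#' @return `H x W` 0/1 matrix.
#' @export
ssd_mask <- function(current, background, region, params = shadow_params(),
                     current_chroma = NULL, background_chroma = NULL) {
  if (!inherits(params, "shadow_params")) stop("'params' must be shadow_params")
  cur <- if (inherits(current, "vframe")) current$rgb else current
  bg <- if (inherits(background, "vframe")) background$rgb else background
  if (is.null(current_chroma)) current_chroma <- normalized_rg(cur)
  if (is.null(background_chroma)) background_chroma <- normalized_rg(bg)
  darker <- cur[, , 1L] < bg[, , 1L] & cur[, , 2L] < bg[, , 2L]
  dr <- abs(current_chroma$r - background_chroma$r)
  dg <- abs(current_chroma$g - background_chroma$g)
  chroma_ok <- if (params$ssd_chroma_mode == "as_printed")
    (dr - dg) <= params$t_n else (dr <= params$t_n & dg <= params$t_n)
  matrix(as.integer(region > 0 & darker & chroma_ok),
         nrow(region), ncol(region))
}

#' Classify a moving region into object and shadow pixels
#'
#' Runs the cascade: each region pixel is tested with the first (HSV) shadow
#' mask; only pixels passing it are tested with the second (normalized-rg)
#' mask. A pixel is labelled shadow iff both fire; every other region pixel
#' is labelled object; pixels outside the region stay background.
#'
#' @param frame current [vframe].
#' @param background a `background_model` (its reference background is used
#'   as B) or an `H x W x 3` background array.
#' @param region `H x W` 0/1 moving-region mask.
#' @param params a [shadow_params] object.
#' @return Integer `H x W` label matrix: 0 = background, 1 = object,
#'   2 = shadow.
#' @export
classify_moving_region <- function(frame, background, region,
                                   params = shadow_params()) {
  bg <- if (inherits(background, "background_model"))
    reference_background(background) else background
  cur <- if (inherits(frame, "vframe")) frame$rgb else frame
  fsd <- fsd_mask(rgb_to_hsv(cur), rgb_to_hsv(bg), region, params)
  ssd <- ssd_mask(cur, bg, fsd, params)  # cascade: SSD evaluated inside FSD
  shadow <- fsd & ssd
  labels <- matrix(0L, nrow(region), ncol(region))
  labels[region > 0] <- 1L
  labels[shadow] <- 2L
  labels
}

#' Render a label mask as an RGB debug image
#'
#' Object pixels red, shadow pixels blue, background black.
#'
#' @param labels integer label matrix (0/1/2).
#' @return `H x W x 3` array in \[0, 1\].
#' @export
render_labels <- function(labels) {
  out <- array(0, c(dim(labels), 3L))
  r <- out[, , 1L]; b <- out[, , 3L]
  r[labels == 1L] <- 1
  b[labels == 2L] <- 1
  out[, , 1L] <- r; out[, , 3L] <- b
  out
}
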