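# shared fixture builders; everything is generated in code at test time

flat_rgb <- function(h, w, col) {
  a <- array(0, c(h, w, 3L))
  for (ch in 1:3) a[, , ch] <- col[ch]
  a
}

# per-pixel reference evaluation of the first (HSV) shadow test
fsd_oracle <- function(cur_hsv, bg_hsv, region, p) {
  h <- nrow(region); w <- ncol(region)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (region[i, j] == 0) next
    bv <- bg_hsv$v[i, j]
    if (bv <= 0) next
    ratio <- cur_hsv$v[i, j] / bv
    if (ratio < p$alpha || ratio > p$beta) next
    if (abs(cur_hsv$s[i, j] - bg_hsv$s[i, j]) > p$t_s) next
    achrom <- cur_hsv$s[i, j] < p$sat_floor && bg_hsv$s[i, j] < p$sat_floor
    dh <- abs(cur_hsv$h[i, j] - bg_hsv$h[i, j])
    dh <- min(dh, 1 - dh)
    if (!achrom && dh > p$t_h) next
    out[i, j] <- 1L
  }
  out
}

# per-pixel reference evaluation of the second (normalized-rg) shadow test
ssd_oracle <- function(cur, bg, region, p) {
  h <- nrow(region); w <- ncol(region)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (region[i, j] == 0) next
    if (!(cur[i, j, 1] < bg[i, j, 1] && cur[i, j, 2] < bg[i, j, 2])) next
    nr <- function(px) {
      s <- sum(px)
      if (s == 0) c(1 / 3, 1 / 3) else c(px[1] / s, px[2] / s)
    }
    ci <- nr(cur[i, j, ]); bi <- nr(bg[i, j, ])
    dr <- abs(ci[1] - bi[1]); dg <- abs(ci[2] - bi[2])
    ok <- if (p$ssd_chroma_mode == "as_printed") (dr - dg) <= p$t_n
          else (dr <= p$t_n && dg <= p$t_n)
    if (ok) out[i, j] <- 1L
  }
  out
}

# standard hexcone HSV -> RGB inverse, used to check the forward conversion
hsv_to_rgb_oracle <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  switch(as.character(i),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

# small pipeline config for synthetic scenes (no file-input resize)
scene_run_config <- function(...) {
  cfg <- run_config(...)
  cfg$resize <- 1
  cfg
}
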