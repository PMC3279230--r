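test_that("shadow parameter validation enforces the documented bounds", {
  expect_error(shadow_params(alpha = 0.9, beta = 0.4), "alpha")
  expect_error(shadow_params(beta = 1.2), "alpha")
  expect_error(shadow_params(t_s = -0.1), ">= 0")
  expect_s3_class(shadow_params(), "shadow_params")
})

test_that("first shadow mask applies the value-ratio and chroma gates", {
  p <- shadow_params(alpha = 0.4, beta = 0.9, t_s = 0.1, t_h = 0.1)
  region <- matrix(1L, 1, 1)
  mk <- function(h, s, v) list(h = matrix(h, 1, 1), s = matrix(s, 1, 1),
                               v = matrix(v, 1, 1))
  # ratio 0.6, small dS and dH -> shadow candidate
  expect_equal(fsd_mask(mk(0.31, 0.52, 0.48), mk(0.30, 0.50, 0.80),
                        region, p)[1, 1], 1L)
  # identical pixel: ratio 1 > beta -> not shadow
  expect_equal(fsd_mask(mk(0.3, 0.5, 0.8), mk(0.3, 0.5, 0.8),
                        region, p)[1, 1], 0L)
  # hue veto regardless of a valid value ratio
  expect_equal(fsd_mask(mk(0.7, 0.5, 0.48), mk(0.3, 0.5, 0.8),
                        region, p)[1, 1], 0L)
  # black background pixel can not be shaded
  expect_equal(fsd_mask(mk(0, 0, 0), mk(0, 0, 0), region, p)[1, 1], 0L)
})

test_that("second shadow mask requires darkening with stable chromaticity", {
  p <- shadow_params(t_n = 0.05)
  region <- matrix(1L, 1, 1)
  bg <- flat_rgb(1, 1, c(0.5, 0.6, 0.7))
  expect_equal(ssd_mask(0.6 * bg, bg, region, p)[1, 1], 1L)   # ideal shadow
  brighter <- flat_rgb(1, 1, c(0.6, 0.7, 0.8))
  expect_equal(ssd_mask(brighter, bg, region, p)[1, 1], 0L)
  # darker but with a large normalized-r shift
  off <- flat_rgb(1, 1, c(0.45, 0.15, 0.15))
  expect_equal(ssd_mask(off, bg, region, p)[1, 1], 0L)
})

test_that("region classification follows the cascade and conserves labels", {
  set.seed(19)
  bg <- array(runif(16 * 16 * 3, 0.2, 0.9), c(16, 16, 3))
  cur <- bg
  cur[1:8, , ] <- 0.6 * cur[1:8, , ]           # shaded half
  cur[9:16, , ] <- array(runif(8 * 16 * 3), c(8, 16, 3))
  region <- matrix(1L, 16, 16)
  p <- shadow_params()
  labels <- classify_moving_region(cur, bg, region, p)
  fsd <- fsd_mask(rgb_to_hsv(cur), rgb_to_hsv(bg), region, p)
  expect_true(all(fsd[labels == 2] == 1))      # shadow set inside FSD set
  expect_equal(sum(labels == 1) + sum(labels == 2), sum(region))
  # empty region -> everything background
  expect_true(all(classify_moving_region(cur, bg, matrix(0L, 16, 16), p) == 0))
  # degenerate thresholds admit no shadow at all
  tight <- shadow_params(alpha = 1, beta = 1, t_s = 0, t_h = 0)
  lab2 <- classify_moving_region(cur, bg, region, tight)
  expect_true(all(lab2[region > 0] == 1))
})

test_that("uniform illumination scaling inside [alpha, beta] reads as shadow", {
  set.seed(5)
  bg <- array(runif(12 * 12 * 3, 0.25, 0.95), c(12, 12, 3))
  region <- matrix(1L, 12, 12)
  p <- shadow_params()
  for (k in c(0.45, 0.6, 0.85)) {
    labels <- classify_moving_region(k * bg, bg, region, p)
    expect_true(all(labels == 2L), info = paste("attenuation", k))
  }
})

test_that("vectorized masks equal brute-force evaluation on random frames", {
  set.seed(123)
  for (trial in 1:25) {
    bg <- array(runif(16 * 16 * 3), c(16, 16, 3))
    cur <- array(runif(16 * 16 * 3), c(16, 16, 3))
    region <- matrix(rbinom(256, 1, 0.7), 16, 16)
    p <- shadow_params(ssd_chroma_mode = sample(c("as_printed",
                                                  "both_bounded"), 1))
    expect_identical(fsd_mask(rgb_to_hsv(cur), rgb_to_hsv(bg), region, p),
                     fsd_oracle(rgb_to_hsv(cur), rgb_to_hsv(bg), region, p))
    expect_identical(ssd_mask(cur, bg, region, p),
                     ssd_oracle(cur, bg, region, p))
  }
})

test_that("rendered shadows classify perfectly without noise", {
  scene <- render_sequence(scene_config(activity = "walk", noise_sigma = 0,
                                        width = 120, height = 90,
                                        n_frames = 30, seed = 9))
  bg <- reference_background(init_background(scene$frames[1:10]))
  p <- shadow_params()
  for (i in c(20, 30, 40)) {
    gt <- scene$truth$labels[[i]]
    region <- matrix(as.integer(gt > 0), nrow(gt), ncol(gt))
    lab <- classify_moving_region(scene$frames[[i]], bg, region, p)
    expect_equal(mean(lab[gt == 2] == 2), 1)   # every shadow pixel found
    expect_equal(mean(lab[gt == 1] == 1), 1)   # every actor pixel kept
  }
})
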