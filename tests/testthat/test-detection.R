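test_that("bounding-box aspect ratio rises as the body goes horizontal", {
  expect_equal(mbr_ratio(c(x = 0, y = 0, w = 50, h = 100)), 0.5)
  expect_equal(mbr_ratio(c(x = 0, y = 0, w = 60, h = 60)), 1)
  expect_equal(mbr_ratio(c(x = 0, y = 0, w = 100, h = 40)), 2.5)
  expect_error(mbr_ratio(c(x = 0, y = 0, w = 10, h = 0)), "height")
})

test_that("vertical velocity is window-normalized centroid motion", {
  expect_equal(vertical_velocity(rep(100, 10), 4, 480), 0)
  expect_equal(vertical_velocity(c(100, 112, 124, 136, 148), 4, 480), 0.025)
  expect_true(is.na(vertical_velocity(c(1, 2), 4, 480)))
  # per-second units scale by fps
  expect_equal(vertical_velocity(c(100, 112, 124, 136, 148), 4, 480,
                                 fps = 30), 0.75)
})

test_that("depth variation is the signed change over the window", {
  expect_equal(depth_variation(rep(0.4, 8), 5), 0)
  expect_equal(depth_variation(seq(0.3, 0.6, length.out = 6), 5), 0.3)
  expect_true(is.na(depth_variation(c(0.3, 0.4), 5)))
})

test_that("the two detector stages apply their printed conditions", {
  p <- detector_params(th1 = 1.5, th2 = 1.0, th_velocity = 0.3,
                       th_depth = 0.1)
  expect_equal(ufed1(1.8, p), "fall")
  expect_equal(ufed1(1.2, p), "escalate")
  expect_equal(ufed1(1.5, p), "fall")          # >= is inclusive
  expect_equal(ufed2(1.2, 0.35, 0.2, p), "fall")
  expect_equal(ufed2(1.2, 0.1, 0.2, p), "normal")
  expect_equal(ufed2(0.8, 0.5, 0.2, p), "normal")
  expect_equal(ufed2(1.2, -0.35, -0.2, p), "fall")  # magnitudes count
  expect_error(detector_params(th1 = 1.0, th2 = 1.5), "th2 < th1")
})

make_history <- function(ratio, y_c = NULL, z_c = NULL, frame_height = 100) {
  n <- length(ratio)
  data.frame(frame = 0:(n - 1), w = ratio * 50, h = 50,
             y_c = if (is.null(y_c)) rep(50, n) else y_c,
             Z_c = if (is.null(z_c)) rep(0.5, n) else z_c)
}

test_that("the cascade emits events only after persistent conditions", {
  p <- detector_params()
  # steady walking-like track: nothing fires
  ev <- detect_events(make_history(rep(0.5, 40)), 100, p, fps = 30)
  expect_equal(nrow(ev$events), 0)
  # ratio crossing th1 and staying: exactly one ufed1 event
  ratio <- c(rep(0.5, 15), seq(0.5, 2.2, length.out = 10), rep(2.2, 15))
  ev <- detect_events(make_history(ratio), 100, p, fps = 30)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$stage, "ufed1")
  # ratio capped below th1 with fast drop and depth change: one ufed2 event
  n <- 40
  y <- c(rep(20, 15), seq(20, 70, length.out = 10), rep(70, 15))
  z <- c(rep(0.4, 15), seq(0.4, 0.8, length.out = 10), rep(0.8, 15))
  ratio <- c(rep(0.5, 15), seq(0.5, 1.3, length.out = 10), rep(1.3, 15))
  ev <- detect_events(make_history(ratio, y, z), 100, p, fps = 30)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$stage, "ufed2")
  # ufed1 dominates: ratio above th1 fires with no velocity or depth change
  ratio <- c(rep(0.5, 10), rep(1.8, 30))
  ev <- detect_events(make_history(ratio), 100, p, fps = 30)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$stage, "ufed1")
  # a transient shorter than the persistence window is ignored
  ratio <- c(rep(0.5, 18), rep(1.8, 3), rep(0.5, 19))
  ev <- detect_events(make_history(ratio), 100, p, fps = 30)
  expect_equal(nrow(ev$events), 0)
})

test_that("raising thresholds never creates additional fall events", {
  set.seed(77)
  base <- detector_params()
  for (trial in 1:10) {
    n <- 60
    ratio <- pmax(cumsum(rnorm(n, 0, 0.15)) + 0.8, 0.1)
    y <- cumsum(rnorm(n, 1, 4)) + 30
    z <- pmin(pmax(cumsum(rnorm(n, 0, 0.04)) + 0.5, 0), 1)
    hist <- make_history(ratio, y, z)
    n_base <- nrow(detect_events(hist, 100, base, fps = 30)$events)
    stricter <- detector_params(th1 = base$th1 + 0.4, th2 = base$th2,
                                th_velocity = base$th_velocity + 0.2,
                                th_depth = base$th_depth + 0.1)
    n_strict <- nrow(detect_events(hist, 100, stricter, fps = 30)$events)
    expect_lte(n_strict, n_base)
  }
})

test_that("confusion counts and rates follow their definitions", {
  cm <- confusion_matrix(c("fall", "fall"), c("fall", "normal"))
  expect_equal(cm[["tp"]], 1); expect_equal(cm[["fn"]], 1)
  cm <- confusion_matrix(rep("normal", 5), rep("normal", 5))
  expect_equal(cm[["tn"]], 5)
  expect_error(confusion_matrix("fall", c("fall", "fall")), "equal length")

  m <- fall_metrics(c(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(unclass(m)[1:4], c(sensitivity = 100, specificity = 100,
                                  accuracy = 100, false_positive_rate = 0))
  m <- fall_metrics(c(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m[["sensitivity"]]))
  # complements: sensitivity + FNR = 100, specificity + FPR = 100
  m <- fall_metrics(c(tp = 7, fp = 3, fn = 2, tn = 11))
  fnr <- 100 * 2 / (7 + 2)
  expect_equal(m[["sensitivity"]] + fnr, 100)
  expect_equal(m[["specificity"]] + m[["false_positive_rate"]], 100)
  expect_true(all(unclass(m) >= 0 & unclass(m) <= 100))
})
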