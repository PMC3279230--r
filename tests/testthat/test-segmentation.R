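test_that("background initialization recovers a stationary scene", {
  img <- flat_rgb(6, 8, c(0.2, 0.5, 0.7))
  model <- init_background(rep(list(img), 10))
  expect_equal(reference_background(model), img, tolerance = 1e-3)
  expect_equal(rowSums(model$w), rep(1, 48), tolerance = 1e-6)
  expect_error(init_background(list(img), k = 0), "k")
  expect_error(init_background(list()), "at least one")
})

test_that("background means track the underlying image under noise", {
  set.seed(11)
  img <- array(runif(6 * 8 * 3, 0.2, 0.8), c(6, 8, 3))
  frames <- lapply(1:20, function(i)
    pmin(pmax(img + array(rnorm(length(img), 0, 0.02), dim(img)), 0), 1))
  model <- init_background(frames)
  # dominant means equal the per-pixel sample mean of the frames ...
  sample_mean <- Reduce(`+`, frames) / length(frames)
  expect_equal(reference_background(model), sample_mean, tolerance = 1e-12)
  # ... which sits within sampling error (sd/sqrt(n) ~ 0.0045) of the image
  expect_lt(max(abs(reference_background(model) - img)), 0.02)
})

test_that("gmm foreground flags departures from the background", {
  img <- flat_rgb(20, 20, c(0.3, 0.4, 0.5))
  model <- init_background(rep(list(img), 5))
  res <- gmm_foreground(model, img)
  expect_true(all(res$mask == 0))
  moved <- img
  for (ch in 1:3) moved[5:14, 5:14, ch] <- pmin(img[5:14, 5:14, ch] + 0.5, 1)
  res <- gmm_foreground(model, moved, update = FALSE)
  expected <- matrix(0L, 20, 20); expected[5:14, 5:14] <- 1L
  expect_equal(res$mask, expected)
  expect_error(gmm_foreground(model, flat_rgb(4, 4, c(0, 0, 0))), "dimensions")
})

test_that("selective update does not absorb a static foreground object", {
  img <- flat_rgb(16, 16, c(0.3, 0.4, 0.5))
  model <- init_background(rep(list(img), 5))
  occupied <- img
  for (ch in 1:3) occupied[4:12, 4:12, ch] <- c(0.9, 0.2, 0.1)[ch]
  for (i in 1:60) {
    res <- gmm_foreground(model, occupied)
    model <- res$model
  }
  expect_true(all(res$mask[4:12, 4:12] == 1))   # still foreground after 60 frames
  # full Stauffer-Grimson update absorbs the same object
  model_full <- init_background(rep(list(img), 5), update_mode = "full")
  for (i in 1:60) {
    res_full <- gmm_foreground(model_full, occupied)
    model_full <- res_full$model
  }
  expect_true(mean(res_full$mask[4:12, 4:12]) < 0.5)
})

test_that("weighted frame difference matches per-pixel brute force", {
  set.seed(3)
  p <- array(runif(5 * 6 * 3), c(5, 6, 3))
  c_ <- array(runif(5 * 6 * 3), c(5, 6, 3))
  n <- array(runif(5 * 6 * 3), c(5, 6, 3))
  got <- weighted_frame_difference(p, c_, n, 0.3, 0.6, 0.25)
  exp_mask <- matrix(0L, 5, 6)
  for (i in 1:5) for (j in 1:6) {
    d <- max(0.3 * abs(c_[i, j, ] - p[i, j, ]) + 0.6 * abs(n[i, j, ] - c_[i, j, ]))
    if (d > 0.25) exp_mask[i, j] <- 1L
  }
  expect_equal(got, exp_mask)
  expect_true(all(weighted_frame_difference(p, p, p) == 0))
  # w2 = 0 reduces to two-frame differencing
  expect_equal(weighted_frame_difference(p, c_, n, 1, 0, 0.2),
               weighted_frame_difference(p, c_, p, 1, 0, 0.2))
  # symmetric weights make the mask invariant under swapping prev/next
  expect_equal(weighted_frame_difference(p, c_, n, 0.5, 0.5, 0.1),
               weighted_frame_difference(n, c_, p, 0.5, 0.5, 0.1))
  expect_error(weighted_frame_difference(p, c_, n, -1, 0.5, 0.1), "non-negative")
})

test_that("mask combination is set arithmetic", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(combine_masks(a, a, "union"), a)               # idempotent
  expect_equal(combine_masks(a, b, "union"), combine_masks(b, a, "union"))
  expect_equal(sum(combine_masks(a, b, "union")), sum(a) + sum(b))
  expect_equal(sum(combine_masks(a, b, "intersection")), 0)
  expect_error(combine_masks(a, b, "xor"), "arg")
})

test_that("morphological cleanup removes specks and keeps solid blocks", {
  m <- matrix(0L, 30, 30)
  m[5, 5] <- 1L                      # isolated pixel
  m[10:29, 10:29] <- 1L              # 20x20 block
  out <- morphological_cleanup(m, open_radius = 1, close_radius = 1,
                               min_area = 5)
  expect_equal(out[5, 5], 0L)
  expect_lt(abs(sum(out) - 400) / 400, 0.15)
  empty <- matrix(0L, 10, 10)
  expect_equal(morphological_cleanup(empty), empty)
})

test_that("component labelling is 8-connected with dense labels", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L       # touch only diagonally
  m[6, 6] <- 1L                      # separate component
  lab <- label_components(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
})

test_that("the moving-region mask covers the actor and its shadow", {
  scene <- render_sequence(scene_config(activity = "walk", noise_sigma = 0,
                                        width = 120, height = 90,
                                        n_frames = 30, seed = 3))
  seg <- segment_sequence(scene$frames, scene_run_config())
  covered <- total <- 0
  for (i in 15:30) {
    gt <- scene$truth$labels[[i]]
    covered <- covered + sum(seg$regions[[i]][gt > 0] > 0)
    total <- total + sum(gt > 0)
  }
  expect_gte(covered / total, 0.95)
  # gmm mask alone covers the actor with little spurious area
  model <- seg$model
  i <- 25
  res <- gmm_foreground(model, scene$frames[[i]], update = FALSE)
  gt <- scene$truth$labels[[i]]
  expect_gte(mean(res$mask[gt == 1] == 1), 0.99)
  expect_lte(sum(res$mask == 1 & gt == 0) / sum(gt == 1), 0.05)
})
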