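test_that("blob extraction reports exact geometry", {
  lab <- matrix(0L, 40, 40)
  lab[6:25, 6:15] <- 1L             # 10 wide x 20 tall block at (5, 5)
  blobs <- extract_blobs(lab)
  expect_length(blobs, 1)
  expect_equal(blobs[[1]]$mbr, c(x = 5, y = 5, w = 10, h = 20))
  expect_equal(blobs[[1]]$centroid_2d, c(x = 9.5, y = 14.5))
  expect_equal(blobs[[1]]$area, 200)

  lab[35:38, 35:38] <- 1L
  expect_length(extract_blobs(lab), 2)
  expect_length(extract_blobs(lab, min_area = 50), 1)

  depth <- matrix(0.7, 40, 40)
  blobs <- extract_blobs(lab, depth = depth)
  expect_equal(blobs[[1]]$centroid_3d[["z"]], 0.7)

  # area bookkeeping: blob areas sum to the object-labelled pixel count
  expect_equal(sum(vapply(extract_blobs(lab), `[[`, numeric(1), "area")),
               sum(lab == 1L))
})

test_that("filter prediction follows constant-acceleration kinematics", {
  st <- abg_state(5, 0, dt = 1)
  expect_equal(abg_predict(st)[["x"]], 5)
  st$vel <- c(x = 2, y = 0)
  expect_equal(abg_predict(st)[["x"]], 7)
  st2 <- abg_state(0, 0, dt = 0.5)
  st2$vel <- c(x = 1, y = 0); st2$acc <- c(x = 2, y = 0)
  expect_equal(abg_predict(st2)[["x"]], 0.75)
})

test_that("a measurement equal to the prediction leaves the state unchanged", {
  st <- abg_state(3, 4, dt = 1)
  st$vel <- c(x = 1, y = -1); st$acc <- c(x = 0.2, y = 0)
  pred <- abg_predict(st)
  st2 <- abg_update(st, pred)
  expect_equal(st2$pos, pred)
  expect_equal(st2$vel, st$vel + st$acc * st$dt)
  expect_equal(st2$acc, st$acc)
})

test_that("tracking error vanishes on polynomial trajectories", {
  # constant velocity: x_k = 2k
  st <- abg_state(0, 0, dt = 1)
  errs <- numeric(300)
  for (k in 1:300) {
    st <- abg_update(st, c(2 * k, 0))
    errs[k] <- abs(st$pos[["x"]] - 2 * k)
  }
  expect_lt(errs[300], 1e-6)
  expect_lt(errs[300], errs[150])
  # constant acceleration: x_k = 0.1 k^2 -- zero steady-state error
  st <- abg_state(0, 0, dt = 1)
  for (k in 1:200) st <- abg_update(st, c(0.1 * k^2, 0))
  expect_lt(abs(st$pos[["x"]] - 0.1 * 200^2), 1e-4)
})

test_that("unstable gain triples are rejected at construction", {
  expect_error(abg_state(0, 0, dt = 1, 1, 1, 1), "unstable")
  expect_error(abg_state(0, 0, dt = 1, 0.9, 0.9, 0.9), "unstable")
  expect_s3_class(abg_state(0, 0, dt = 1 / 30), "abg_state")
  expect_error(abg_state(0, 0, dt = 0), "dt")
  expect_error(abg_state(0, 0, g_alpha = 0), "gains")
})

test_that("association pairs nearest neighbours inside the gate", {
  blob_at <- function(x, y) list(centroid_2d = c(x = x, y = y),
                                 mbr = c(x = x - 2, y = y - 2, w = 5, h = 5))
  a <- associate(list(c(50, 50)), list(blob_at(52, 51)), gate_radius = 20)
  expect_equal(nrow(a$matches), 1)
  a <- associate(list(c(50, 50)), list(blob_at(200, 200)), gate_radius = 20)
  expect_equal(nrow(a$matches), 0)
  expect_equal(a$unmatched_blobs, 1)
  # two tracks, two blobs: brute force over both assignments picks the
  # pairing with the smaller summed distance
  preds <- list(c(10, 10), c(90, 90))
  blobs <- list(blob_at(12, 11), blob_at(88, 92))
  d <- function(p, b) sqrt(sum((p - as.numeric(b$centroid_2d))^2))
  direct <- d(preds[[1]], blobs[[1]]) + d(preds[[2]], blobs[[2]])
  crossed <- d(preds[[1]], blobs[[2]]) + d(preds[[2]], blobs[[1]])
  best <- if (direct <= crossed) cbind(track = 1:2, blob = 1:2) else
    cbind(track = 1:2, blob = 2:1)
  a <- associate(preds, blobs, gate_radius = 50)
  expect_equal(a$matches[order(a$matches[, 1]), ], best)
  expect_error(associate(preds, blobs, gate_radius = 0), "gate_radius")
})

test_that("well-separated objects keep their identities across frames", {
  # two blobs translating on parallel paths, far apart relative to the gate
  frames <- lapply(0:29, function(t) {
    lab <- matrix(0L, 100, 200)
    x1 <- 20 + t; x2 <- 150 + t
    lab[10:29, x1:(x1 + 9)] <- 1L
    lab[70:89, x2:(x2 + 9)] <- 1L
    extract_blobs(lab)
  })
  ts <- track_blobs(frames, fps = 30, gate_radius = 15)
  h <- ts$history
  expect_equal(length(unique(h$object_id)), 2)
  for (id in unique(h$object_id)) {
    hi <- h[h$object_id == id, ]
    expect_equal(nrow(hi), 30)                      # present every frame
    expect_lt(max(abs(diff(hi$y_c))), 1e-6)         # stays on its own path
  }
})
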