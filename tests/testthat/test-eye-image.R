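# Eye-region extraction, iris segmentation, and moment centroids.

make_landmarks <- function(left_eye, right_eye) {
  # minimal valid 68-point set: filler grid plus the two 6-point eyes
  pts <- cbind(rep(seq(10, 90, length.out = 17), 4)[1:68],
               rep(seq(10, 90, length.out = 17), each = 4)[1:68])
  pts[37:42, ] <- left_eye
  pts[43:48, ] <- right_eye
  face_landmarks(pts)
}

std_eye <- function(x0, x1, y_up, y_lo) {
  yc <- (mean(y_up) + mean(y_lo)) / 2
  rbind(c(x0, yc),
        c(x0 + (x1 - x0) / 3, y_up[1]), c(x0 + 2 * (x1 - x0) / 3, y_up[2]),
        c(x1, yc),
        c(x0 + 2 * (x1 - x0) / 3, y_lo[2]), c(x0 + (x1 - x0) / 3, y_lo[1]))
}

test_that("eye regions carry the corner and eyelid reference coordinates", {
  img <- matrix(128, 200, 200)
  lm <- make_landmarks(std_eye(100, 140, c(118, 120), c(130, 132)),
                       std_eye(150, 190, c(118, 120), c(130, 132)))
  regs <- extract_eye_regions(img, lm)
  expect_equal(regs$left$corner_x_min, 100)
  expect_equal(regs$left$corner_x_max, 140)
  expect_equal(regs$left$eyelid_y_min, 119) # mean of the two upper-lid ys
  expect_equal(regs$left$eyelid_y_max, 131) # mean of the two lower-lid ys
  expect_equal(regs$right$corner_x_min, 150)
  # crop sits inside the frame and its origin is recorded
  expect_true(all(dim(regs$left$crop) > 0))
  expect_true(all(regs$left$origin >= 0))
})

test_that("crops are clamped at the frame edge with the origin recorded", {
  img <- matrix(128, 60, 60)
  lm <- make_landmarks(std_eye(1, 30, c(6, 7), c(14, 15)),
                       std_eye(35, 58, c(6, 7), c(14, 15)))
  lm$points[, 1] <- clamp(lm$points[, 1], 0, 59)
  lm$points[, 2] <- clamp(lm$points[, 2], 0, 59)
  regs <- extract_eye_regions(img, lm, margin = 10)
  expect_identical(regs$left$origin, c(0, 0))
  expect_lte(ncol(regs$right$crop), 60)

  out <- lm
  out$points[1, ] <- c(-5, 10)
  expect_error(extract_eye_regions(img, out), "outside image bounds")
})

test_that("degenerate eye hulls are rejected", {
  pts <- cbind(rep(seq(10, 90, length.out = 17), 4)[1:68],
               rep(seq(10, 90, length.out = 17), each = 4)[1:68])
  pts[37:42, ] <- cbind(seq(20, 40, length.out = 6), rep(30, 6)) # collinear
  pts[43:48, ] <- std_eye(50, 70, c(28, 29), c(33, 34))
  expect_error(face_landmarks(pts), "degenerate")
})

test_that("segmentation matches direct classification up to the erosion margin", {
  sp <- eye_image_spec(iris_intensity = 40, sclera_intensity = 220,
                       iris_center = c(32, 20), iris_radius = 5)
  eye <- generate_eye_image(sp)
  mask <- segment_iris(eye$image, iris_seg_params(binary_threshold = 128))
  # oracle: classify raw pixels at the threshold
  raw_fg <- eye$image < 128
  expect_true(all(mask[raw_fg])) # erosion only grows the dark region
  # every extra foreground pixel lies within the erosion+filter margin of
  # the true disc (3 iterations of a 3x3 min filter + 1 px of smoothing)
  margin <- 3 + 1
  xs <- matrix(0:(ncol(mask) - 1), nrow(mask), ncol(mask), byrow = TRUE)
  ys <- matrix(0:(nrow(mask) - 1), nrow(mask), ncol(mask))
  d <- sqrt((xs - sp$iris_center[1])^2 + (ys - sp$iris_center[2])^2)
  expect_true(all(d[mask] <= sp$iris_radius + margin + 0.5))
})

test_that("uniform crops signal a segmentation failure", {
  expect_error(segment_iris(matrix(120, 30, 40)),
               class = "segmentation_failure")
})

test_that("auto threshold equals fixed thresholds between the two modes", {
  eye <- generate_eye_image(eye_image_spec())
  m_auto <- segment_iris(eye$image, iris_seg_params(binary_threshold = "auto"))
  for (thr in c(100, 128, 160)) {
    m_fix <- segment_iris(eye$image, iris_seg_params(binary_threshold = thr))
    expect_identical(m_auto, m_fix)
  }
})

test_that("auto-threshold segmentation is invariant to a gray-level shift", {
  sp <- eye_image_spec(noise_sd = 6, seed = 2L)
  eye <- generate_eye_image(sp)
  m1 <- segment_iris(eye$image)
  m2 <- segment_iris(eye$image + 20)
  expect_identical(m1, m2)
})

test_that("pupil_center equals the brute-force foreground mean", {
  # worked examples
  disc <- matrix(FALSE, 60, 60)
  xs <- matrix(0:59, 60, 60, byrow = TRUE); ys <- matrix(0:59, 60, 60)
  disc[(xs - 25)^2 + (ys - 30)^2 <= 100] <- TRUE
  expect_equal(pupil_center(disc, origin = c(100, 50)), c(125, 80))

  two <- matrix(FALSE, 25, 45)
  two[(xs[1:25, 1:45] - 10)^2 + (ys[1:25, 1:45] - 10)^2 <= 9] <- TRUE
  two[(xs[1:25, 1:45] - 30)^2 + (ys[1:25, 1:45] - 10)^2 <= 9] <- TRUE
  expect_equal(pupil_center(two), brute_force_centroid(two))
  expect_equal(pupil_center(two)[1], 20) # symmetric discs at x = 10 and 30
  expect_equal(pupil_center(two)[2], 10)

  single <- matrix(FALSE, 10, 12); single[4, 8] <- TRUE # (x,y) = (7,3)
  expect_equal(pupil_center(single, origin = c(2, 5)), c(9, 8))

  # property: exhaustive equivalence on random masks
  withr::with_seed(1, {
    for (i in 1:50) {
      m <- random_mask(sample(3:12, 1), sample(3:12, 1))
      org <- c(sample(0:50, 1), sample(0:50, 1))
      expect_equal(pupil_center(m, org), brute_force_centroid(m, org))
    }
  })
  expect_error(pupil_center(matrix(FALSE, 5, 5)), class = "no_pupil_detected")
})

test_that("recovery error grows monotonically (on average) with image noise", {
  specs <- visible_iris_specs(20)
  err_at <- function(ns) {
    mean(vapply(specs, function(sp) {
      sp$noise_sd <- ns
      eye <- generate_eye_image(sp)
      m <- segment_iris(eye$image)
      sqrt(sum((pupil_center(m) - sp$iris_center)^2))
    }, numeric(1)))
  }
  e <- vapply(c(0, 30, 60), err_at, numeric(1))
  expect_true(all(diff(e) >= 0))
  expect_lt(e[1], 0.75)
})
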