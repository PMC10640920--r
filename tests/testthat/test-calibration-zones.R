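# One-point calibration and five-zone classification.

const_stream <- function(h, v, n = 61, rate = 30) {
  data.frame(timestamp = (seq_len(n) - 1) / rate,
             h_ratio = rep(h, n), v_ratio = rep(v, n),
             valid = rep(TRUE, n))
}

test_that("calibration on a constant stream returns that constant", {
  cal <- run_one_point_calibration(const_stream(0.56, 0.51))
  expect_equal(cal$h_c, 0.56)
  expect_equal(cal$v_c, 0.51)
  expect_equal(cal$w, 0.4)
  expect_equal(cal$l, 0.2)
  expect_equal(cal$sample_sd, 0)
})

test_that("blink samples are excluded from the calibration average", {
  st <- const_stream(0.5, 0.5)
  st$valid[10] <- FALSE
  st$h_ratio[10] <- NA
  st$v_ratio[10] <- NA
  cal <- run_one_point_calibration(st)
  expect_equal(cal$h_c, 0.5)
  expect_equal(cal$n_samples, nrow(st) - 1L)
})

test_that("an outlier saccade sample is rejected before averaging", {
  st <- const_stream(0.5, 0.5)
  st$h_ratio[20] <- 0.95 # stray saccade
  cal <- run_one_point_calibration(st)
  expect_equal(cal$h_c, 0.5)
})

test_that("jittered calibration recovers the center within 3 sd / sqrt(n)", {
  n <- 60
  withr::with_seed(7, {
    st <- data.frame(timestamp = (0:(n - 1)) / 30,
                     h_ratio = 0.56 + rnorm(n, 0, 0.02),
                     v_ratio = 0.51 + rnorm(n, 0, 0.02),
                     valid = TRUE)
  })
  cal <- run_one_point_calibration(st)
  bound <- 3 * 0.02 / sqrt(n)
  expect_lt(abs(cal$h_c - 0.56), bound)
  expect_lt(abs(cal$v_c - 0.51), bound)
  expect_gt(cal$sample_sd, 0)
})

test_that("too-short or too-sparse streams fail calibration", {
  expect_error(run_one_point_calibration(const_stream(0.5, 0.5, n = 20)),
               class = "calibration_failed")
  st <- const_stream(0.5, 0.5)
  st$valid <- FALSE
  expect_error(run_one_point_calibration(st), class = "calibration_failed")
})

test_that("zone worked examples follow the rectangle arithmetic", {
  cal <- calibration_state(0.56, 0.51, 0.4, 0.2)
  expect_identical(classify_zone(c(0.56, 0.51), cal), "center")
  expect_identical(classify_zone(c(0.86, 0.51), cal), "left")  # h excess 0.30
  expect_identical(classify_zone(c(0.56, 0.71), cal), "down")  # v excess 0.20
  expect_identical(classify_zone(c(0.26, 0.51), cal), "right")
  expect_identical(classify_zone(c(0.56, 0.31), cal), "up")
  # closed boundary: exactly on the rectangle edge is center
  expect_identical(classify_zone(c(0.56 + 0.2, 0.51), cal), "center")
  expect_identical(classify_zone(c(0.56, 0.51 + 0.1), cal), "center")
})

test_that("classification partitions the unit square totally and disjointly", {
  sizes <- c(central_area_sizes(), list(pilot = c(0.4, 0.2)))
  grid <- expand.grid(h = seq(0, 1, by = 0.01), v = seq(0, 1, by = 0.01))
  for (wl in sizes) {
    cal <- calibration_state(0.5, 0.5, wl[1], wl[2])
    labs <- apply(grid, 1, classify_zone, calib = cal)
    expect_true(all(labs %in% c("center", "up", "down", "left", "right")))
    # center region is exactly the closed rectangle
    inside <- abs(grid$h - 0.5) <= wl[1] / 2 + 1e-12 &
      abs(grid$v - 0.5) <= wl[2] / 2 + 1e-12
    expect_identical(labs == "center", unname(inside))
  }
})

test_that("reflecting h about the center swaps left and right", {
  cal <- calibration_state(0.5, 0.5, 0.2, 0.12)
  withr::with_seed(2, {
    pts <- cbind(runif(300), runif(300))
  })
  flip <- function(lab) switch(lab, left = "right", right = "left", lab)
  for (i in seq_len(nrow(pts))) {
    a <- classify_zone(pts[i, ], cal)
    b <- classify_zone(c(2 * cal$h_c - pts[i, 1], pts[i, 2]), cal)
    expect_identical(b, flip(a))
  }
})

test_that("classify_events matches classify_zone and flags blinks", {
  cal <- calibration_state(0.5, 0.5, 0.2, 0.12)
  withr::with_seed(8, {
    st <- data.frame(timestamp = (0:199) / 30,
                     h_ratio = runif(200), v_ratio = runif(200),
                     valid = runif(200) > 0.1)
  })
  st$h_ratio[!st$valid] <- NA
  ev <- classify_events(st, cal)
  expect_identical(ev$label[!st$valid], rep("missing", sum(!st$valid)))
  ok <- which(st$valid)
  ref <- vapply(ok, function(i) classify_zone(c(st$h_ratio[i], st$v_ratio[i]), cal),
                character(1))
  expect_identical(ev$label[ok], ref)
})

test_that("calibration state round-trips through JSON", {
  cal <- calibration_state(0.562, 0.508, 0.2, 0.12, n_samples = 55,
                           sample_sd = 0.013)
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$h_c, cal$h_c)
  expect_equal(back$n_samples, cal$n_samples)
})
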