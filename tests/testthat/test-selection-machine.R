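# Dwell-based two-stage selection machine.

test_that("item-stage layout keeps left/right, moves middle down, back on top", {
  menu <- test_menu()
  lay <- expand_cluster(menu, "down")
  expect_identical(lay$left, "drumstick")
  expect_identical(lay$down, "chips")
  expect_identical(lay$right, "popcorn")
  expect_identical(lay$up, "back")
  for (dir in c("up", "down", "left", "right")) {
    expect_identical(expand_cluster(menu, dir)$up, "back")
  }
})

test_that("menus load from YAML and reject malformed cluster sets", {
  menu <- read_menu(system.file("extdata", "menu.yaml", package = "gazedwell"))
  expect_s3_class(menu, "menu_model")
  expect_identical(menu$clusters$down, c("drumstick", "chips", "popcorn"))
  expect_error(menu_model(c("a", "b"), c("c", "d", "e"), c("f", "g", "h"),
                          c("i", "j", "k")), "exactly 3")
  expect_error(menu_model(c("a", "b", "c"), c("a", "d", "e"), c("f", "g", "h"),
                          c("i", "j", "k")), "unique")
})

test_that("dwelling past the threshold confirms a cluster", {
  menu <- test_menu()
  ev <- events_df(c(0, 0.5, 1.0), c("down", "down", "down"))
  res <- run_stream(menu, 1.0, ev)
  expect_identical(res$actions$kind, "cluster_selected")
  expect_identical(res$actions$payload, "down")
  expect_equal(res$actions$timestamp, 1.0)
  expect_identical(res$state$stage, "item")
  # gray focus feedback precedes the red confirm
  expect_identical(res$log$kind, c("feedback_focus", "feedback_confirm",
                                   "cluster_selected"))
})

test_that("leaving the arrow resets the dwell timer", {
  menu <- test_menu()
  ev <- events_df(c(0, 0.6, 0.8, 1.7, 1.9),
                  c("down", "center", "down", "down", "down"))
  res <- run_stream(menu, 1.0, ev)
  # dwell restarted at 0.8; nothing can confirm before 1.8
  expect_identical(res$actions$kind, "cluster_selected")
  expect_equal(res$actions$timestamp, 1.9)
})

test_that("switching arrows restarts the dwell on the new arrow", {
  menu <- test_menu()
  ev <- events_df(c(0, 0.4, 0.9, 1.5), c("down", "left", "left", "left"))
  res <- run_stream(menu, 1.0, ev)
  expect_identical(res$actions$payload, "left")
  expect_equal(res$actions$timestamp, 1.5) # 0.4 + >= 1.0
})

test_that("ten seconds without a confirm yields exactly one missed reset", {
  menu <- test_menu()
  ev <- held_events("center", 10.5, rate = 30)
  res <- run_stream(menu, 1.0, ev)
  expect_identical(res$actions$kind, "reset_missed")
  expect_equal(nrow(res$actions), 1L)
  expect_gt(res$actions$timestamp, 10)
  expect_identical(res$state$stage, "cluster")
})

test_that("back navigation returns to the cluster stage", {
  menu <- test_menu()
  ev <- rbind(held_events("down", 1.3, rate = 10),
              held_events("up", 1.4, rate = 10, t0 = 1.3))
  res <- run_stream(menu, 1.0, ev)
  expect_identical(res$actions$kind, c("cluster_selected", "back"))
  expect_identical(res$state$stage, "cluster")
  expect_true(is.na(res$state$active_cluster))
})

test_that("a blink resets an ongoing dwell unless within the grace period", {
  menu <- test_menu()
  # 30 Hz stream: dwell on "down" with a 0.1 s blink from 0.4 to 0.5
  ts <- (0:50) / 30
  lab <- rep("down", length(ts))
  lab[ts >= 0.4 & ts < 0.5] <- "missing"
  ev <- events_df(ts, lab)
  strict <- run_stream(menu, 1.0, ev) # any gap resets: dwell restarts at 0.5
  conf <- strict$actions[strict$actions$kind == "cluster_selected", ]
  expect_gte(conf$timestamp, 1.5)
  lenient <- run_stream(menu, 1.0, ev, grace_period = 0.2)
  conf <- lenient$actions[lenient$actions$kind == "cluster_selected", ]
  expect_equal(conf$timestamp, 1.0) # blink tolerated, dwell unbroken from 0
})

test_that("out-of-order events are rejected", {
  menu <- test_menu()
  st <- selection_state(1.0)
  st <- selection_step(st, "down", 1.0, menu)$state
  expect_error(selection_step(st, "down", 0.5, menu), "out-of-order")
})

test_that("confirms never fire early and are late by at most one interval", {
  menu <- test_menu()
  for (thr in c(0.5, 0.8, 1.0, 1.2)) {
    for (rate in c(15, 30, 60)) {
      dt <- 1 / rate
      ev <- rbind(held_events("center", 0.5, rate),
                  held_events("left", thr + 0.5, rate, t0 = 0.5))
      res <- run_stream(menu, thr, ev)
      conf <- res$actions[res$actions$kind == "cluster_selected", ]
      expect_equal(nrow(conf), 1L)
      first_focus <- min(ev$timestamp[ev$timestamp >= 0.5])
      dwell <- conf$timestamp - first_focus
      expect_gte(dwell, thr)
      expect_lte(dwell, thr + dt + 1e-9)
    }
  }
})

test_that("every item selection is preceded by exactly one cluster selection", {
  menu <- test_menu()
  labels <- c("up", "down", "left", "right", "center", "missing")
  n_items <- 0L
  withr::with_seed(21, {
    for (rep in 1:10) {
      # block-structured random gaze: directions held 0.2-1.2 s at 30 Hz
      lab <- character(0)
      while (length(lab) < 400) {
        lab <- c(lab, rep(sample(labels, 1, prob = c(2, 2, 2, 2, 1, 0.3)),
                          sample(6:36, 1)))
      }
      ev <- events_df((seq_along(lab) - 1) / 30, lab)
      res <- run_stream(menu, 0.5, ev)
      acts <- res$actions$kind
      open <- 0L
      for (a in acts) {
        if (a == "cluster_selected") {
          expect_identical(open, 0L)
          open <- 1L
        } else if (a %in% c("item_selected", "back")) {
          expect_identical(open, 1L)
          open <- 0L
        } else if (a == "reset_missed") {
          open <- 0L
        }
      }
      n_items <- n_items + sum(acts == "item_selected")
    }
  })
  expect_gt(n_items, 0L) # the random streams really exercised both stages
})

test_that("replay is deterministic", {
  menu <- test_menu()
  withr::with_seed(3, {
    ev <- events_df((0:299) / 30,
                    sample(c("up", "down", "left", "right", "center"), 300,
                           replace = TRUE))
  })
  a <- run_stream(menu, 0.5, ev)
  b <- run_stream(menu, 0.5, ev)
  expect_identical(a$actions, b$actions)
  expect_identical(a$log, b$log)
})

test_that("empty streams change nothing", {
  menu <- test_menu()
  res <- run_stream(menu, 1.0, events_df(numeric(0), character(0)))
  expect_equal(nrow(res$actions), 0L)
  expect_identical(res$state$stage, "cluster")
})
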