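# Simulation harness reproducing the study design: a 3 (central-area size)
# x 3 (viewing distance) x 4 (dwell threshold) within-subjects factorial,
# with task completion time and an error rate decomposed into false
# detections (wrong item confirmed) and missed detections (per-stage
# timeout). Human performance numbers are not reproduction targets — the
# harness reproduces the definitions, the design structure, and the
# qualitative trade-offs under an explicit simulated-user model.

#' Central-area sizes used in the study
#'
#' Width x height of the classification dead zone, as ratios of the screen:
#' small 0.16 x 0.09, medium 0.2 x 0.12, large 0.24 x 0.16. The pilot value
#' 0.4 x 0.2 remains the out-of-experiment default elsewhere.
#'
#' @return named list of `c(w, l)` pairs.
#' @export
central_area_sizes <- function() {
  list(small = c(0.16, 0.09), medium = c(0.2, 0.12), large = c(0.24, 0.16))
}

#' An experimental condition
#'
#' @param central_area `"small"`, `"medium"` or `"large"` (see
#'   [central_area_sizes()]), or a numeric `c(w, l)`.
#' @param distance_cm user-to-screen distance in cm (45, 55 or 65 in the
#'   study; any positive value accepted).
#' @param dwell_threshold dwell threshold in seconds (0.5, 0.8, 1.0 or 1.2
#'   in the study; any positive value accepted).
#' @return object of class `"condition"` with fields `size` (label or
#'   `"custom"`), `w`, `l`, `distance_cm`, `dwell_threshold`.
#' @export
condition <- function(central_area = "medium", distance_cm = 45,
                      dwell_threshold = 1.0) {
  if (is.character(central_area)) {
    wl <- central_area_sizes()[[match.arg(central_area,
                                          names(central_area_sizes()))]]
    size <- central_area
  } else {
    stopifnot(is.numeric(central_area), length(central_area) == 2L)
    wl <- central_area
    size <- "custom"
  }
  stopifnot(distance_cm > 0, dwell_threshold > 0)
  structure(list(size = size, w = wl[1], l = wl[2],
                 distance_cm = distance_cm,
                 dwell_threshold = dwell_threshold),
            class = "condition")
}

#' Build the factorial condition grid
#'
#' Full cross of 3 central-area sizes x 3 distances x 4 dwell thresholds
#' (36 conditions), each repeated `reps` times per participant. Block
#' structure mirrors the study: distance is the outer block, run far-to-near
#' for odd-numbered participants and near-to-far for even-numbered ones;
#' within a distance block the 12 size x dwell combinations are shuffled
#' per participant (seeded), with a condition's repetitions kept
#' consecutive.
#'
#' @param participants number of participants (>= 1).
#' @param reps repetitions per condition (>= 1).
#' @param seed RNG seed for the per-participant shuffles.
#' @return data.frame with columns `participant`, `order` (presentation
#'   index within participant), `size`, `distance_cm`, `dwell_s`, `rep`.
#' @export
#' @examples
#' nrow(build_condition_grid(1, 1))   # 36
#' nrow(build_condition_grid(22, 4))  # 3168
build_condition_grid <- function(participants, reps, seed = 1L) {
  stopifnot(participants >= 1, reps >= 1)
  sizes <- names(central_area_sizes())
  distances <- c(45, 55, 65)
  dwells <- c(0.5, 0.8, 1.0, 1.2)
  combos <- expand.grid(size = sizes, dwell_s = dwells,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, paste0("p", seq_len(participants)))
  out <- vector("list", participants)
  for (p in seq_len(participants)) {
    dist_order <- if (p %% 2L == 1L) rev(distances) else distances
    rows <- with_seed(seeds[[p]], {
      do.call(rbind, lapply(dist_order, function(d) {
        sh <- combos[sample.int(nrow(combos)), , drop = FALSE]
        sh <- sh[rep(seq_len(nrow(sh)), each = reps), , drop = FALSE]
        sh$rep <- rep(seq_len(reps), times = nrow(combos))
        sh$distance_cm <- d
        sh
      }))
    })
    rows$participant <- p
    rows$order <- seq_len(nrow(rows))
    out[[p]] <- rows
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  grid[, c("participant", "order", "size", "distance_cm", "dwell_s", "rep")]
}

# What the simulated user wants to look at given the machine's state.
desired_direction <- function(state, target_loc) {
  if (state$stage == "cluster") {
    target_loc$cluster
  } else if (identical(state$active_cluster, target_loc$cluster)) {
    target_loc$item_direction
  } else {
    "up" # wrong cluster open: go back
  }
}

#' Run one simulated trial
#'
#' Closed loop of the simulated user, the zone classifier and the selection
#' machine. At every sample the user gazes at the currently needed control
#' (the target's cluster arrow, then its item position; the back arrow if
#' the wrong cluster was opened), with AR(1) fixation drift, per-sample
#' jitter and blink dropouts from the scenario's noise model. After every
#' confirm the user keeps gazing at the just-confirmed arrow for a
#' per-reaction latency drawn from a Gamma distribution with mean
#' `reaction_latency` and sd `latency_sd` before re-orienting — the mechanism by
#' which short dwell thresholds produce false selections. Viewing distance
#' scales the noise sds by `distance_cm / 45`, an explicit modeling
#' assumption (farther faces are smaller on the sensor, so ratio estimates
#' are noisier).
#'
#' The trial ends at the first item confirmation (`success` if it is the
#' target, otherwise `false_detection`) or at the first per-stage timeout
#' (`missed`, no completion time).
#'
#' @param scenario a [gaze_scenario()] whose `target_sequence` holds the
#'   single target item.
#' @param cond a [condition()].
#' @param menu a [menu_model()] containing the target.
#' @param seed integer seed for this trial's noise draws.
#' @return one-row data.frame: `target`, `outcome`, `selected`,
#'   `completion_time` (seconds, `NA` when missed), `n_samples`.
#' @export
run_trial <- function(scenario, cond, menu, seed = scenario$seed) {
  stopifnot(inherits(scenario, "gaze_scenario"), inherits(cond, "condition"),
            length(scenario$target_sequence) == 1L)
  target <- scenario$target_sequence[1]
  loc <- locate_item(menu, target)
  calib <- calibration_state(scenario$true_center[1], scenario$true_center[2],
                             w = cond$w, l = cond$l)
  noise_scale <- cond$distance_cm / 45
  jitter_sd <- scenario$jitter_sd * noise_scale
  drift_sd <- scenario$drift_sd * noise_scale
  dt <- 1 / scenario$sample_rate
  max_t <- 3 * (cond$dwell_threshold + scenario$reaction_latency) +
    2 * selection_state(cond$dwell_threshold)$timeout + 5
  n_max <- ceiling(max_t / dt) + 1L

  seeds <- derive_seeds(seed, c("jitter", "drift", "blinks", "latency"))
  jit <- with_seed(seeds[["jitter"]], {
    if (jitter_sd > 0) matrix(stats::rnorm(2 * n_max, 0, jitter_sd), n_max, 2)
    else matrix(0, n_max, 2)
  })
  drift <- with_seed(seeds[["drift"]],
                     cbind(ar1_drift(n_max, dt, drift_sd, scenario$drift_tau),
                           ar1_drift(n_max, dt, drift_sd, scenario$drift_tau)))
  blinks <- with_seed(seeds[["blinks"]],
                      blink_intervals(max_t, scenario$blink_rate,
                                      scenario$blink_duration))
  # pre-drawn per-reaction latencies (first = initial orienting at t = 0)
  latencies <- with_seed(seeds[["latency"]], {
    mu <- scenario$reaction_latency
    s <- scenario$latency_sd
    if (mu > 0 && s > 0) {
      stats::rgamma(64, shape = (mu / s)^2, rate = mu / s^2)
    } else rep(mu, 64)
  })

  state <- selection_state(cond$dwell_threshold, t0 = 0)
  gaze_at <- "center"                 # where the eyes currently rest
  switch_at <- latencies[1]           # when the user re-orients next
  lat_i <- 1L
  outcome <- NA_character_; selected <- NA_character_; t_done <- NA_real_

  for (i in seq_len(n_max)) {
    t <- (i - 1) * dt
    if (t >= switch_at) {
      gaze_at <- desired_direction(state, loc)
      switch_at <- Inf
    }
    off <- direction_vector(gaze_at) * scenario$direction_offsets
    h <- clamp(scenario$true_center[1] + off[1] + drift[i, 1] + jit[i, 1])
    v <- clamp(scenario$true_center[2] + off[2] + drift[i, 2] + jit[i, 2])
    label <- if (in_any_interval(t, blinks)) "missing"
             else classify_zone(c(h, v), calib)
    res <- selection_step(state, label, t, menu)
    state <- res$state
    if (res$action == "item_selected") {
      outcome <- if (res$payload == target) "success" else "false_detection"
      selected <- res$payload
      t_done <- t
      break
    }
    if (res$action == "reset_missed") {
      outcome <- "missed"
      t_done <- NA_real_
      break
    }
    if (res$action %in% c("cluster_selected", "back")) {
      # user notices the stage change after a fresh reaction latency
      lat_i <- min(lat_i + 1L, length(latencies))
      switch_at <- t + latencies[lat_i]
    }
  }
  if (is.na(outcome)) { # safety net; unreachable under the timeout rule
    outcome <- "missed"
  }
  data.frame(target = target, outcome = outcome,
             selected = if (is.na(selected)) NA_character_ else selected,
             completion_time = t_done, n_samples = i,
             stringsAsFactors = FALSE)
}

#' Run a batch of simulated trials over a condition grid
#'
#' @param grid data.frame from [build_condition_grid()] (or any subset with
#'   the same columns).
#' @param menu a [menu_model()].
#' @param scenario_template a [gaze_scenario()] providing the noise model;
#'   its target is replaced per trial.
#' @param targets item identifiers to cycle through (default: all 12 menu
#'   items in order).
#' @param seed master seed; each trial gets an independent derived seed.
#' @return data.frame: grid columns plus `target`, `outcome`, `selected`,
#'   `completion_time`.
#' @export
run_design <- function(grid, menu, scenario_template = gaze_scenario("x"),
                       targets = unlist(menu$clusters, use.names = FALSE),
                       seed = 1L) {
  n <- nrow(grid)
  seeds <- derive_seeds(seed, paste0("trial", seq_len(n)))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- condition(grid$size[i], grid$distance_cm[i], grid$dwell_s[i])
    sc <- scenario_template
    sc$target_sequence <- targets[((i - 1) %% length(targets)) + 1]
    rec <- run_trial(sc, cond, menu, seed = seeds[[i]])
    res[[i]] <- cbind(grid[i, , drop = FALSE], rec, row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Descriptive metrics per condition
#'
#' For each size x distance x dwell cell: number of trials, mean and sd of
#' completion time over successful trials (sd is 0 for a single success, by
#' convention), and the error, false-detection and missed-detection rates,
#' each a fraction of all trials in the cell, so that
#' `false_rate + missed_rate == error_rate` exactly.
#'
#' @param records trial records from [run_design()] / [run_trial()], with
#'   columns `size`, `distance_cm`, `dwell_s`, `outcome`,
#'   `completion_time`.
#' @return data.frame, one row per condition cell present in `records`.
#' @export
compute_metrics <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("size", "distance_cm", "dwell_s", "outcome",
                  "completion_time") %in% names(records)))
  key <- interaction(records$size, records$distance_cm, records$dwell_s,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    n <- nrow(g)
    succ <- g$completion_time[g$outcome == "success"]
    data.frame(
      size = g$size[1], distance_cm = g$distance_cm[1], dwell_s = g$dwell_s[1],
      n_trials = n,
      mean_time = if (length(succ)) mean(succ) else NA_real_,
      sd_time = if (length(succ) > 1) stats::sd(succ)
                else if (length(succ) == 1) 0 else NA_real_,
      error_rate = mean(g$outcome != "success"),
      false_rate = mean(g$outcome == "false_detection"),
      missed_rate = mean(g$outcome == "missed"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$distance_cm, out$dwell_s, out$size), ]
  rownames(out) <- NULL
  out
}

#' Display geometry
#'
#' @param diagonal_in screen diagonal in inches.
#' @param resolution `c(width, height)` in pixels.
#' @param viewing_distance_cm user-to-screen distance in cm.
#' @return object of class `"display_geometry"`.
#' @export
display_geometry <- function(diagonal_in = 15.6,
                             resolution = c(1920, 1080),
                             viewing_distance_cm = 45) {
  stopifnot(diagonal_in > 0, length(resolution) == 2L, all(resolution > 0),
            viewing_distance_cm > 0)
  structure(list(diagonal_in = diagonal_in, resolution = resolution,
                 viewing_distance_cm = viewing_distance_cm),
            class = "display_geometry")
}

#' Pixels per degree of visual angle
#'
#' Physical screen width follows from the diagonal and the aspect ratio
#' implied by the resolution; the pixel pitch is width divided by
#' horizontal resolution; one degree then subtends
#' `2 * d * tan(0.5 deg) / pitch` pixels. For a 15.6-inch 1920x1080 screen
#' at 45 cm this is 43.7, i.e. 44 to the nearest pixel.
#'
#' @param geom a [display_geometry()].
#' @return pixels per degree (not rounded).
#' @export
#' @examples
#' round(pixels_per_degree(display_geometry(15.6, c(1920, 1080), 45)))
pixels_per_degree <- function(geom) {
  res <- geom$resolution
  width_cm <- geom$diagonal_in * 2.54 * res[1] / sqrt(sum(res^2))
  pitch_cm <- width_cm / res[1]
  2 * geom$viewing_distance_cm * tan(0.5 * pi / 180) / pitch_cm
}
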