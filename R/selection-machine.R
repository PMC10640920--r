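# Dwell-based two-stage hierarchical selection.
#
# Stage 1 (cluster): four clusters of three items sit in the four
# directions; dwelling on an arrow past the threshold selects that cluster.
# Stage 2 (item): the chosen cluster's items expand — the item originally
# on the right stays right, the left item stays left, the middle item moves
# down, and the top position becomes a back control returning to stage 1.
# Feedback is a gray "focus" circle while dwelling and a red "confirm" at
# selection. If 10 s pass within one stage without a confirm, the machine
# resets to the cluster screen and reports a missed selection.

#' Menu model: four clusters of three items
#'
#' @param up,down,left,right character vectors of length 3: the cluster's
#'   items in on-screen order (left, middle, right). All 12 identifiers
#'   must be unique.
#' @return object of class `"menu_model"`.
#' @export
#' @examples
#' menu <- menu_model(
#'   up    = c("pizza", "burger", "hotdog"),
#'   down  = c("drumstick", "chips", "popcorn"),
#'   left  = c("coffee", "tea", "cocoa"),
#'   right = c("cola", "water", "juice"))
menu_model <- function(up, down, left, right) {
  clusters <- list(up = as.character(up), down = as.character(down),
                   left = as.character(left), right = as.character(right))
  if (any(lengths(clusters) != 3L)) {
    stop("each cluster must hold exactly 3 items", call. = FALSE)
  }
  items <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(items)) stop("item identifiers must be unique", call. = FALSE)
  structure(list(clusters = clusters), class = "menu_model")
}

#' Item-stage layout for a cluster
#'
#' Maps each gaze direction to what a confirm selects at the item stage:
#' the cluster's left item on the left, its right item on the right, its
#' middle item at the bottom, and the back control at the top.
#'
#' @param menu a [menu_model()].
#' @param direction cluster key, one of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return named list with entries `left`, `down`, `right` (item ids) and
#'   `up = "back"`.
#' @export
expand_cluster <- function(menu, direction) {
  assert_direction(direction)
  cl <- menu$clusters[[direction]]
  list(left = cl[1], down = cl[2], right = cl[3], up = "back")
}

# Cluster direction and item-stage direction for a target item.
locate_item <- function(menu, target) {
  for (dir in names(menu$clusters)) {
    pos <- match(target, menu$clusters[[dir]])
    if (!is.na(pos)) {
      return(list(cluster = dir,
                  item_direction = c("left", "down", "right")[pos]))
    }
  }
  stop("target not in menu: ", target, call. = FALSE)
}

#' Initial selection-machine state
#'
#' @param dwell_threshold dwell time in seconds required to confirm; the
#'   study used 0.5, 0.8, 1.0 and 1.2 s, but any positive value is valid.
#' @param timeout per-stage timeout in seconds (default 10): exceeding it
#'   without a confirm resets to the cluster screen as a missed selection.
#' @param grace_period blink tolerance in seconds: a run of missing samples
#'   shorter than this neither advances nor resets an ongoing dwell
#'   (default 0, i.e. any gap resets — the strictest reading of
#'   "continuously focuses").
#' @param t0 timestamp at which the first stage is displayed.
#' @return object of class `"selection_state"`.
#' @export
selection_state <- function(dwell_threshold, timeout = 10,
                            grace_period = 0, t0 = 0) {
  stopifnot(dwell_threshold > 0, timeout > 0, grace_period >= 0)
  structure(list(stage = "cluster", active_cluster = NA_character_,
                 focused = NA_character_, dwell_start = NA_real_,
                 stage_start = t0, dwell_threshold = dwell_threshold,
                 timeout = timeout, grace_period = grace_period,
                 last_ts = -Inf, gap_accum = 0),
            class = "selection_state")
}

#' Advance the selection machine by one gaze event
#'
#' Semantics: a `"center"` event clears any focus; a direction event equal
#' to the current focus confirms once `timestamp - dwell_start >=
#' dwell_threshold` (cluster selection, item selection, or back, depending
#' on stage and direction), resetting the stage clock; a different
#' direction moves the focus and restarts the dwell timer; a `"missing"`
#' event (blink) resets the focus unless the gap since the last non-missing
#' event is within `grace_period`. If no confirm occurs and the event's
#' timestamp exceeds `stage_start + timeout`, the machine emits
#' `reset_missed` and reinitializes to the cluster stage.
#'
#' @param state a [selection_state()].
#' @param label event label: `"center"`, `"up"`, `"down"`, `"left"`,
#'   `"right"`, or `"missing"`.
#' @param timestamp event time in seconds; must be non-decreasing.
#' @param menu a [menu_model()] (needed to resolve item-stage confirms).
#' @return list with `state` (updated), `feedback` (`"none"`, `"focus"` or
#'   `"confirm"`), `focus_direction`, `action` (`"none"`,
#'   `"cluster_selected"`, `"item_selected"`, `"back"`, `"reset_missed"`)
#'   and `payload` (direction or item id, `NA` otherwise).
#' @export
selection_step <- function(state, label, timestamp, menu) {
  if (timestamp < state$last_ts) {
    stop("out-of-order event: timestamp decreases", call. = FALSE)
  }
  prev_ts <- state$last_ts
  state$last_ts <- timestamp
  feedback <- "none"
  focus_direction <- NA_character_
  action <- "none"
  payload <- NA_character_

  if (identical(label, "missing")) {
    # accumulate blink time across the current run of missing samples;
    # reset the dwell only once it outlasts the grace period
    state$gap_accum <- state$gap_accum +
      if (is.finite(prev_ts)) timestamp - prev_ts else 0
    if (state$gap_accum > state$grace_period) {
      state$focused <- NA_character_
      state$dwell_start <- NA_real_
    }
  } else {
    state$gap_accum <- 0
    if (identical(label, "center")) {
      state$focused <- NA_character_
      state$dwell_start <- NA_real_
    } else {
      assert_direction(label)
      if (!is.na(state$focused) && state$focused == label) {
        if (timestamp - state$dwell_start >= state$dwell_threshold) {
          feedback <- "confirm"
          focus_direction <- label
          if (state$stage == "cluster") {
            action <- "cluster_selected"
            payload <- label
            state$active_cluster <- label
            state$stage <- "item"
          } else {
            layout <- expand_cluster(menu, state$active_cluster)
            if (label == "up") {
              action <- "back"
              payload <- state$active_cluster
            } else {
              action <- "item_selected"
              payload <- layout[[label]]
            }
            state$stage <- "cluster"
            state$active_cluster <- NA_character_
          }
          state$stage_start <- timestamp
          state$focused <- NA_character_
          state$dwell_start <- NA_real_
        } else {
          feedback <- "focus"
          focus_direction <- label
        }
      } else {
        state$focused <- label
        state$dwell_start <- timestamp
        feedback <- "focus"
        focus_direction <- label
      }
    }
  }

  if (action == "none" && timestamp - state$stage_start > state$timeout) {
    action <- "reset_missed"
    feedback <- "none"
    focus_direction <- NA_character_
    state$stage <- "cluster"
    state$active_cluster <- NA_character_
    state$focused <- NA_character_
    state$dwell_start <- NA_real_
    state$stage_start <- timestamp
  }

  list(state = state, feedback = feedback, focus_direction = focus_direction,
       action = action, payload = payload)
}

#' Replay a gaze-event stream through the selection machine
#'
#' Deterministic fold of [selection_step()] over time-ordered events,
#' logging every feedback transition and every action.
#'
#' @param menu a [menu_model()].
#' @param dwell_threshold dwell threshold in seconds.
#' @param events data.frame with columns `timestamp`, `label` (as produced
#'   by [classify_events()]).
#' @param timeout,grace_period passed to [selection_state()].
#' @return list with `actions` (data.frame `timestamp`, `kind`, `payload`),
#'   `log` (feedback transitions and actions) and `state` (final state).
#' @export
run_stream <- function(menu, dwell_threshold, events,
                       timeout = 10, grace_period = 0) {
  stopifnot(is.data.frame(events),
            all(c("timestamp", "label") %in% names(events)))
  t0 <- if (nrow(events) > 0) events$timestamp[1] else 0
  state <- selection_state(dwell_threshold, timeout = timeout,
                           grace_period = grace_period, t0 = t0)
  log_ts <- numeric(0); log_kind <- character(0); log_payload <- character(0)
  last_feedback <- "none"
  for (i in seq_len(nrow(events))) {
    res <- selection_step(state, events$label[i], events$timestamp[i], menu)
    state <- res$state
    fb <- if (res$feedback == "none") "none" else {
      paste0(res$feedback, ":", res$focus_direction)
    }
    if (fb != last_feedback) {
      log_ts <- c(log_ts, events$timestamp[i])
      log_kind <- c(log_kind, paste0("feedback_", res$feedback))
      log_payload <- c(log_payload,
                       if (is.na(res$focus_direction)) "" else res$focus_direction)
      last_feedback <- fb
    }
    if (res$action != "none") {
      log_ts <- c(log_ts, events$timestamp[i])
      log_kind <- c(log_kind, res$action)
      log_payload <- c(log_payload, if (is.na(res$payload)) "" else res$payload)
    }
  }
  log <- data.frame(timestamp = log_ts, kind = log_kind, payload = log_payload,
                    stringsAsFactors = FALSE)
  actions <- log[!startsWith(log$kind, "feedback_"), , drop = FALSE]
  rownames(actions) <- NULL
  list(actions = actions, log = log, state = state)
}
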