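# Internal helpers shared across modules.

#' Clamp values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Expand one user-facing seed into named per-component substreams, so that
# adding a new noise source to a generator never perturbs draws made by the
# existing ones. Returns a named integer vector of derived seeds < 2^31.
derive_seeds <- function(seed, components) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(components))
  names(s) <- components
  s
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Gaze direction vocabulary. "missing" marks blink/undetected samples.
.directions <- c("up", "down", "left", "right")
.zone_labels <- c("center", .directions)

assert_direction <- function(x) {
  if (!(is.character(x) && length(x) == 1L && x %in% .directions)) {
    stop("expected one of ", paste(.directions, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
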