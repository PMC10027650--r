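#' Monotonic clocks
#'
#' All timing inside the pipeline is measured on a monotonic millisecond
#' clock injected as a dependency, so that tests and calibration runs can use
#' a deterministic simulated clock instead of wall time.
#'
#' `sim_clock()` returns a simulated clock starting at `start_ms` that only
#' advances when `clock_advance()` (or `clock_set()`) is called.
#' `monotonic_clock()` wraps the process's elapsed-time counter, which is
#' monotone and unaffected by wall-clock adjustments.
#'
#' @param start_ms Initial time of the simulated clock, in milliseconds.
#' @return An object of class `mirror_clock` with elements `now`, `advance`
#'   and `set` (functions).
#' @examples
#' clk <- sim_clock()
#' clock_now(clk)            # 0
#' clock_advance(clk, 250)
#' clock_now(clk)            # 250
#' @export
sim_clock <- function(start_ms = 0) {
  t <- start_ms
  clk <- list(
    now = function() t,
    advance = function(ms) {
      stopifnot(ms >= 0)
      t <<- t + ms
      invisible(t)
    },
    set = function(ms) {
      if (ms < t) stop("monotonic clock cannot move backwards")
      t <<- ms
      invisible(t)
    },
    simulated = TRUE
  )
  class(clk) <- "mirror_clock"
  clk
}

#' @rdname sim_clock
#' @export
monotonic_clock <- function() {
  origin <- proc.time()[["elapsed"]]
  clk <- list(
    now = function() (proc.time()[["elapsed"]] - origin) * 1000,
    advance = function(ms) invisible(NULL),
    set = function(ms) invisible(NULL),
    simulated = FALSE
  )
  class(clk) <- "mirror_clock"
  clk
}

#' @rdname sim_clock
#' @param clock A `mirror_clock`.
#' @export
clock_now <- function(clock) clock$now()

#' @rdname sim_clock
#' @param ms Milliseconds to advance (simulated clocks only).
#' @export
clock_advance <- function(clock, ms) clock$advance(ms)

#' @rdname sim_clock
#' @export
clock_set <- function(clock, ms) clock$set(ms)
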