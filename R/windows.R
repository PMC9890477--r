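#' Sliding-window geometry
#'
#' Defines the sliding analysis window used throughout the pipeline.  The
#' window for a center `c` is the half-open interval `[c - width/2,
#' c + width/2)` in milliseconds, so adjacent non-overlapping windows
#' partition time.  Centers below `width/2` span both the prestimulus and
#' poststimulus periods.
#'
#' @param width Window width in ms (default 50).
#' @param step Step between consecutive centers in ms (default 1).
#' @param from,to Inclusive range of window centers in ms.  Defaults cover
#'   -100 to 500 ms around stimulus onset.
#' @param centers Optional explicit vector of centers; overrides
#'   `from`/`to`/`step` spacing (`step` is still recorded).
#'
#' @return An object of class `window_spec`: a list with elements `width`,
#'   `step` and `centers`.
#' @examples
#' window_spec()
#' window_spec(width = 50, from = 25, to = 250, step = 5)
#' @export
window_spec <- function(width = 50, step = 1, from = -100, to = 500,
                        centers = NULL) {
  if (width <= 0) abort("`width` must be positive.")
  if (step <= 0) abort("`step` must be positive.")
  if (is.null(centers)) centers <- seq(from, to, by = step)
  if (length(centers) == 0) abort("`centers` must be nonempty.")
  structure(
    list(width = width, step = step, centers = as.numeric(centers)),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf(
    "<window_spec> width %g ms, step %g ms, %d centers in [%g, %g] ms\n",
    x$width, x$step, length(x$centers), min(x$centers), max(x$centers)
  ))
  invisible(x)
}

# half-open window bounds [lo, hi) for a center
window_bounds <- function(center, width) {
  list(lo = center - width / 2, hi = center + width / 2)
}

#' The early analysis window
#'
#' A single 50-ms window centered at 55 ms after stimulus onset (30--80 ms),
#' where the earliest expression-dependent responses are expected given the
#' ~30 ms shortest latency of pulvinar face responses.
#'
#' @return A `window_spec` with a single center at 55 ms.
#' @export
early_window <- function() {
  window_spec(width = 50, step = 1, centers = 55)
}
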