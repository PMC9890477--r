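#' Count spikes in one sliding window
#'
#' Counts, for every trial of every neuron, the spikes falling in the
#' half-open window `[center - width/2, center + width/2)`.
#'
#' @param dataset A spike dataset.
#' @param center Window center in ms; must be one of `spec$centers`.
#' @param spec A [window_spec()].
#' @return A tibble (`response_matrix`) with columns `neuron_id`, `area`,
#'   `trial_id`, `image_id`, `expression`, `count`, and attributes `center`
#'   and `width`.
#' @examples
#' ds <- tibble::tibble(
#'   neuron_id = "n1", area = "amygdala", trial_id = 1L, image_id = 1L,
#'   spike_times = list(c(30, 55, 79.9))
#' )
#' count_spikes(ds, center = 55, spec = window_spec())
#' @export
count_spikes <- function(dataset, center, spec = window_spec()) {
  if (!any(abs(spec$centers - center) < 1e-9)) {
    abort(sprintf("Center %g ms is not among the window centers of `spec`.", center))
  }
  b <- window_bounds(center, spec$width)
  out <- tibble::tibble(
    neuron_id = dataset$neuron_id,
    area = dataset$area,
    trial_id = dataset$trial_id,
    image_id = dataset$image_id,
    expression = expression_of(dataset$image_id),
    count = vapply(
      dataset$spike_times,
      function(s) sum(s >= b$lo & s < b$hi),
      numeric(1)
    )
  )
  attr(out, "center") <- center
  attr(out, "width") <- spec$width
  class(out) <- union("response_matrix", class(out))
  out
}

#' Convert window spike counts to firing rates
#'
#' @param counts A `response_matrix` from [count_spikes()], or any tibble
#'   with a `count` column (then `width` must be given).
#' @param width Window width in ms; defaults to the `width` attribute.
#' @return The input with an added `rate` column in spikes/s.
#' @examples
#' ds <- tibble::tibble(
#'   neuron_id = "n1", area = "amygdala", trial_id = 1L, image_id = 1L,
#'   spike_times = list(c(30, 55, 79.9))
#' )
#' firing_rate(count_spikes(ds, 55, window_spec()))
#' @export
firing_rate <- function(counts, width = attr(counts, "width")) {
  if (is.null(width)) abort("Window `width` is unknown; pass it explicitly.")
  counts$rate <- counts$count / (width / 1000)
  counts
}

# Counts for every trial at every center: returns a numeric matrix with one
# row per dataset row (trial) and one column per center.  Half-open windows;
# O(n_centers * log n_spikes) per trial via sorted search.
count_matrix_all_centers <- function(dataset, centers, width) {
  lo <- centers - width / 2
  hi <- centers + width / 2
  edges <- c(rbind(lo, hi))
  nC <- length(centers)
  m <- matrix(0, nrow = nrow(dataset), ncol = nC)
  for (i in seq_len(nrow(dataset))) {
    s <- dataset$spike_times[[i]]
    if (length(s) == 0) next
    # number of spikes strictly below each edge
    below <- findInterval(edges, s, left.open = TRUE)
    m[i, ] <- below[seq(2, 2 * nC, by = 2)] - below[seq(1, 2 * nC, by = 2)]
  }
  m
}

# Mean firing rate (sp/s) per dataset row in an arbitrary half-open epoch.
epoch_rate <- function(dataset, lo, hi) {
  n <- vapply(dataset$spike_times, function(s) sum(s >= lo & s < hi), numeric(1))
  n / ((hi - lo) / 1000)
}
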