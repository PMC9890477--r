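#' Preferred spatial frequency at one stimulus size
#'
#' Estimates the preferred image-based SF from the 7-point tuning curve at
#' one size by least-squares fitting a Gaussian in log2(SF) (sub-grid
#' precision); if the fit fails to converge the argmax grid SF is used.
#' The preferred value is clamped to the tested span `[2, 16]`
#' cycles/image (extrapolation beyond the grid is not trusted).
#'
#' @param surface A tuning surface tibble (`sf`, `size`, `rate`).
#' @param size One of the 5 stimulus sizes present in `surface`.
#' @return A list: `preferred` (cycles/image, NA for an all-zero curve),
#'   `clamped`, `method` (`"gaussian"` or `"argmax"`).
#' @export
preferred_sf_per_size <- function(surface, size) {
  cur <- surface[abs(surface$size - size) < 1e-9, ]
  if (nrow(cur) < 7) abort(sprintf("Size %g lacks the full 7-SF tuning curve.", size))
  cur <- dplyr::arrange(cur, .data$sf)
  if (all(cur$rate == 0)) {
    return(list(preferred = NA_real_, clamped = FALSE, method = "none"))
  }
  l <- log2(cur$sf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ a * exp(-(l - mu)^2 / (2 * s^2)),
      data = data.frame(rate = cur$rate, l = l),
      start = list(a = max(cur$rate), mu = l[which.max(cur$rate)], s = 1),
      lower = c(a = 0, mu = min(l) - 2, s = 0.05),
      upper = c(a = Inf, mu = max(l) + 2, s = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pref <- cur$sf[which.max(cur$rate)]
    method <- "argmax"
  } else {
    pref <- 2^coef(fit)[["mu"]]
    method <- "gaussian"
  }
  clamped <- pref < min(cur$sf) || pref > max(cur$sf)
  pref <- min(max(pref, min(cur$sf)), max(cur$sf))
  list(preferred = pref, clamped = clamped, method = method)
}

#' Spatial-frequency reference-frame shift index
#'
#' Quantifies how a neuron's preferred image-based SF shifts with stimulus
#' size, as the least-squares slope of log2(preferred SF) regressed on
#' log2(size) across the sizes with a defined preference (>= 3 required).
#' By construction the index is 1 when the preferred image-based SF scales
#' proportionally with size (constant retina-based preference), 0 when it
#' is constant across sizes (image-based frame), negative when the shift
#' opposes the retina-based prediction, and above 1 when the shift exceeds
#' it.  Responses are expected to come from a fixed 500-ms window.
#'
#' @param surface A tuning surface tibble (`sf`, `size`, `rate`) on the
#'   7 x 5 grid.
#' @return A list of class `shift_index_result`: `shift_index`,
#'   `preferred` (tibble `size`, `preferred`, `clamped`, `method`),
#'   `n_valid`.
#' @export
shift_index <- function(surface) {
  sizes <- sort(unique(surface$size))
  pref <- purrr::map_dfr(sizes, function(s) {
    r <- preferred_sf_per_size(surface, s)
    tibble::tibble(size = s, preferred = r$preferred,
                   clamped = r$clamped, method = r$method)
  })
  valid <- !is.na(pref$preferred)
  if (sum(valid) < 3) {
    warn("Fewer than 3 sizes with a defined SF preference; shift index undefined.")
    si <- NA_real_
  } else {
    fit <- lm(log2(preferred) ~ log2(size), data = pref[valid, ])
    si <- unname(coef(fit)[2])
  }
  structure(
    list(shift_index = si, preferred = pref, n_valid = sum(valid)),
    class = "shift_index_result"
  )
}

#' @export
print.shift_index_result <- function(x, ...) {
  cat(sprintf("<shift_index_result> shift index = %s (%d/5 sizes valid)\n",
              format(x$shift_index, digits = 3), x$n_valid))
  invisible(x)
}

#' @method tidy shift_index_result
#' @export
tidy.shift_index_result <- function(x, ...) x$preferred

#' @method glance shift_index_result
#' @export
glance.shift_index_result <- function(x, ...) {
  tibble::tibble(shift_index = x$shift_index, n_valid = x$n_valid)
}

#' Shift indices for many neurons
#'
#' @param surfaces A tibble with columns `neuron_id`, `sf`, `size`, `rate`
#'   stacking one tuning surface per neuron.
#' @return A tibble `neuron_id`, `shift_index`, `n_valid`.
#' @export
shift_indices <- function(surfaces) {
  surfaces |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(g, key) {
      r <- shift_index(g)
      tibble::tibble(shift_index = r$shift_index, n_valid = r$n_valid)
    }) |>
    dplyr::ungroup()
}

#' Correlate shift indices with classifier weights or response signs
#'
#' Spearman rank correlation (shared with the weight analysis) between
#' per-neuron shift indices and a paired covariate (early-peak classifier
#' weight, or early-response FR difference), plus the ordinary
#' least-squares regression line for reporting.
#'
#' @param shift Numeric vector of shift indices.
#' @param value Paired numeric covariate (same length, >= 3 pairs).
#' @return An `amyg_htest` with extra elements `slope` and `intercept`
#'   (regression of `shift` on `value`).
#' @export
shift_weight_correlation <- function(shift, value) {
  keep <- !is.na(shift) & !is.na(value)
  if (sum(keep) < 3) abort("Need >= 3 paired values.")
  ht <- spearman_rank(value[keep], shift[keep])
  fit <- lm(shift[keep] ~ value[keep])
  ht$slope <- unname(coef(fit)[2])
  ht$intercept <- unname(coef(fit)[1])
  ht
}
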