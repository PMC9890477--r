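#' Stimulus catalog for the 3 identities x 3 expressions face set
#'
#' The face stimulus set crosses 3 monkey identities with 3 facial
#' expressions (open-mouth, neutral, pout-lips), giving 9 images with ids
#' 1--9.  Image ids are assigned identity-major: images 1--3 are identity M1
#' showing open-mouth, neutral and pout-lips, and so on.
#'
#' @return A tibble with columns `image_id`, `identity` and `expression`.
#' @examples
#' stimulus_catalog()
#' @export
stimulus_catalog <- function() {
  tibble::tibble(
    image_id = 1:9,
    identity = rep(IDENTITIES, each = 3),
    expression = factor(rep(EXPRESSIONS, times = 3), levels = EXPRESSIONS)
  )
}

#' Spatial-frequency by size stimulus grid
#'
#' The bandpass-filtered face set crosses 7 center spatial frequencies
#' (cycles/image) with 5 stimulus sizes (degrees of visual angle), giving a
#' 35-cell grid.
#'
#' @return A tibble with columns `sf` (cycles/image) and `size` (degrees),
#'   one row per grid cell (35 rows).
#' @examples
#' sf_size_grid()
#' @export
sf_size_grid <- function() {
  tidyr::expand_grid(
    sf = SF_CENTERS,
    size = STIMULUS_SIZES
  )
}

# center SFs in cycles/image and sizes in degrees for the SF x size set
SF_CENTERS <- c(2.0, 2.8, 4.0, 5.7, 8.0, 11.3, 16.0)
STIMULUS_SIZES <- c(3.8, 5.4, 7.7, 11.0, 15.3)

# map image ids to expressions / identities
expression_of <- function(image_id) {
  factor(EXPRESSIONS[(image_id - 1L) %% 3L + 1L], levels = EXPRESSIONS)
}

identity_of <- function(image_id) {
  IDENTITIES[(image_id - 1L) %/% 3L + 1L]
}
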