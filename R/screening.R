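#' Screen neurons for face responsiveness
#'
#' For each neuron and each of the 9 face images, the per-trial firing rate
#' in the 500 ms before stimulus onset (`[-500, 0)`) is compared with the
#' rate in the 500 ms after onset (`[0, 500)`) by the two-sided Wilcoxon
#' signed-rank test.  A neuron is face responsive when at least one image
#' shows a significant *increase*: p < `alpha` and median post rate above
#' median pre rate.  Neurons with fewer than `min_trials` trials for any
#' image are flagged excluded.
#'
#' @param dataset A spike dataset.
#' @param alpha Significance criterion (default 0.05).
#' @param min_trials Minimum trials per image (default 6).
#' @return A tibble with one row per neuron: `neuron_id`, `excluded`,
#'   `responsive`, `min_p`, `best_image` (the image attaining `min_p` among
#'   increases; NA when none).
#' @export
face_responsiveness <- function(dataset, alpha = 0.05, min_trials = 6) {
  dataset <- validate_spike_dataset(dataset)
  pre <- epoch_rate(dataset, -500, 0)
  post <- epoch_rate(dataset, 0, 500)
  d <- tibble::tibble(
    neuron_id = dataset$neuron_id,
    image_id = dataset$image_id,
    pre = pre, post = post
  )
  d |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(g, key) {
      counts <- table(factor(g$image_id, levels = 1:9))
      if (any(counts < min_trials)) {
        return(tibble::tibble(
          excluded = TRUE, responsive = NA, min_p = NA_real_,
          best_image = NA_integer_
        ))
      }
      per_image <- purrr::map_dfr(1:9, function(img) {
        gi <- g[g$image_id == img, ]
        ht <- suppressWarnings(wilcoxon_signed_rank(gi$post, gi$pre))
        tibble::tibble(
          image_id = img,
          p = ht$p.value,
          increase = median(gi$post) > median(gi$pre)
        )
      })
      hits <- per_image[per_image$p < alpha & per_image$increase, ]
      tibble::tibble(
        excluded = FALSE,
        responsive = nrow(hits) > 0,
        min_p = if (nrow(hits) > 0) min(hits$p) else min(per_image$p),
        best_image = if (nrow(hits) > 0) {
          as.integer(hits$image_id[which.min(hits$p)])
        } else NA_integer_
      )
    }) |>
    dplyr::ungroup()
}
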