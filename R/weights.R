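#' Extract per-neuron classifier weights at a reference window
#'
#' Averages one classifier's weight for each neuron across decoding reps
#' (reps where the neuron was not subsampled are excluded from its mean)
#' and assigns the excitation/suppression group by weight sign.  A neuron
#' never subsampled yields no record (warning); a neuron whose mean weight
#' is exactly zero is excluded from the sign groups.
#'
#' @param window_reps Result of [decode_window()] run with
#'   `keep_weights = TRUE` at the reference (early-peak) center.
#' @param classifier Which one-vs-rest classifier's weights to use
#'   (default `"open_mouth"`).
#' @return A tibble `neuron_id`, `weight`, `group` with `group` one of
#'   `"positive"`, `"negative"`, `"excluded_zero"`.
#' @export
extract_weights <- function(window_reps, classifier = "open_mouth") {
  classifier <- match.arg(classifier, EXPRESSIONS)
  w <- attr(window_reps, "weights")
  if (is.null(w)) {
    abort("`window_reps` carries no weights; rerun decode_window(keep_weights = TRUE).")
  }
  wk <- w[, , classifier, drop = FALSE][, , 1]
  if (is.null(dim(wk))) wk <- matrix(wk, nrow = dim(w)[1])
  n_seen <- colSums(!is.na(wk))
  if (any(n_seen == 0)) {
    warn(sprintf("%d neuron(s) never subsampled; no weight record for them.",
                 sum(n_seen == 0)))
  }
  mean_w <- unname(colMeans(wk, na.rm = TRUE))
  out <- tibble::tibble(
    neuron_id = dimnames(w)[[2]],
    weight = mean_w,
    group = dplyr::case_when(
      mean_w > 0 ~ "positive",
      mean_w < 0 ~ "negative",
      TRUE ~ "excluded_zero"
    )
  )
  out[n_seen > 0, ]
}

# per-neuron FR difference used by the weight correlations
weight_fr_difference <- function(dataset, center, spec, mode, baseline = c(-50, 0)) {
  b <- window_bounds(center, spec$width)
  expr <- expression_of(dataset$image_id)
  win_rate <- epoch_rate(dataset, b$lo, b$hi)
  if (mode == "preference") {
    om <- tapply(win_rate[expr == "open_mouth"],
                 dataset$neuron_id[expr == "open_mouth"], mean)
    other <- tapply(win_rate[expr != "open_mouth"],
                    dataset$neuron_id[expr != "open_mouth"], mean)
    tibble::tibble(neuron_id = names(om),
                   fr_diff = as.numeric(om) - as.numeric(other[names(om)]))
  } else {
    base_rate <- epoch_rate(dataset, baseline[1], baseline[2])
    sel <- expr == "open_mouth"
    om <- tapply(win_rate[sel], dataset$neuron_id[sel], mean)
    bs <- tapply(base_rate[sel], dataset$neuron_id[sel], mean)
    tibble::tibble(neuron_id = names(om),
                   fr_diff = as.numeric(om) - as.numeric(bs[names(om)]))
  }
}

#' Correlate classifier weights with firing-rate differences
#'
#' Spearman rank correlation between each neuron's mean open-mouth
#' classifier weight and either its open-mouth *preference* (mean FR to
#' open-mouth faces minus mean FR to the other faces at the reference
#' window) or its early open-mouth *excitation* (open-mouth FR at the
#' reference window minus the prestimulus `[-50, 0)` ms window).
#'
#' @param weights Weight table from [extract_weights()].
#' @param dataset The spike dataset the weights came from.
#' @param center Reference window center, ms (the early peak).
#' @param spec A [window_spec()].
#' @param mode `"preference"` or `"excitation"`.
#' @param baseline Prestimulus window for `"excitation"`, ms.
#' @return An `amyg_htest` (Spearman rs, p, n) with the paired table in
#'   attribute `data`.
#' @export
weight_response_correlation <- function(weights, dataset, center,
                                        spec = window_spec(),
                                        mode = c("preference", "excitation"),
                                        baseline = c(-50, 0)) {
  mode <- match.arg(mode)
  fr <- weight_fr_difference(dataset, center, spec, mode, baseline)
  d <- dplyr::inner_join(weights, fr, by = "neuron_id")
  if (nrow(d) < 3) abort("Need >= 3 neurons with both weight and FR records.")
  ht <- spearman_rank(d$weight, d$fr_diff)
  attr(ht, "data") <- d
  ht
}

#' Weighted-sum time course per weight-sign group
#'
#' The open-mouth classifier's weighted sum of normalized responses,
#' evaluated with the weights fixed at the early-peak reference window and
#' probed at every window center, separately per facial expression.
#' Responses are max-normalized per neuron within each window (maximum over
#' all of that neuron's trials), and the per-expression mean response is
#' combined as `sum_n w_n * xbar_n(expression)`.
#'
#' @param dataset A spike dataset.
#' @param weights Weight table from [extract_weights()].
#' @param group `"positive"` or `"negative"`: which weight-sign group to sum.
#' @param spec A [window_spec()] defining the probed centers.
#' @return A tibble `center`, `expression`, `weighted_sum`, classed
#'   `weighted_sum_timecourse`.
#' @export
weighted_sum_timecourse <- function(dataset, weights, group,
                                    spec = window_spec()) {
  group <- match.arg(group, c("positive", "negative"))
  wg <- weights[weights$group == group, ]
  if (nrow(wg) == 0) abort(sprintf("The %s-weight group is empty.", group))
  dataset <- validate_spike_dataset(dataset)
  sub <- dataset[dataset$neuron_id %in% wg$neuron_id, ]
  X <- count_matrix_all_centers(sub, spec$centers, spec$width)
  expr <- expression_of(sub$image_id)
  nid <- factor(sub$neuron_id, levels = wg$neuron_id)
  # per window: normalize each neuron by its max count over all trials
  mx <- do.call(rbind, lapply(split(seq_len(nrow(X)), nid), function(i) {
    apply(X[i, , drop = FALSE], 2, max)
  }))
  mx[mx == 0] <- 1
  out <- purrr::map_dfr(EXPRESSIONS, function(e) {
    sel <- expr == e
    xbar <- rowsum(X[sel, , drop = FALSE], nid[sel]) /
      as.vector(table(nid[sel]))
    xnorm <- xbar / mx
    tibble::tibble(
      center = spec$centers,
      expression = e,
      weighted_sum = as.numeric(crossprod(wg$weight, xnorm))
    )
  })
  out$expression <- factor(out$expression, levels = EXPRESSIONS)
  class(out) <- union("weighted_sum_timecourse", class(out))
  out
}

#' Mean firing-rate time course of a neuron group
#'
#' Unweighted mean firing rate across the group's neurons and the selected
#' trials at each window center.
#'
#' @param dataset A spike dataset.
#' @param neurons Character vector of neuron ids forming the group.
#' @param stimulus_filter Restrict to one expression (default
#'   `"open_mouth"`); `NULL` uses all trials.
#' @param spec A [window_spec()].
#' @return A tibble `center`, `mean_fr`, `se` (SEM across neurons).
#' @export
group_mean_fr_timecourse <- function(dataset, neurons,
                                     stimulus_filter = "open_mouth",
                                     spec = window_spec()) {
  if (length(neurons) == 0) abort("Empty neuron group.")
  dataset <- validate_spike_dataset(dataset)
  sub <- dataset[dataset$neuron_id %in% neurons, ]
  if (!is.null(stimulus_filter)) {
    sub <- sub[expression_of(sub$image_id) == stimulus_filter, ]
  }
  X <- count_matrix_all_centers(sub, spec$centers, spec$width)
  nid <- factor(sub$neuron_id)
  per_neuron <- rowsum(X, nid) / as.vector(table(nid)) / (spec$width / 1000)
  tibble::tibble(
    center = spec$centers,
    mean_fr = colMeans(per_neuron),
    se = apply(per_neuron, 2, sd) / sqrt(nrow(per_neuron))
  )
}

#' Response latency of a weight-sign group
#'
#' At each window center, the distribution of per-neuron mean firing rates
#' (to the filtered stimuli) is compared with the same neurons' rates in
#' the prestimulus baseline window by the paired two-sided Wilcoxon
#' signed-rank test.  The latency is the first window center at which the
#' p-value drops below `alpha` (optionally requiring `sustained`
#' consecutive significant centers); `NA` if the curve never crosses.
#'
#' @param dataset A spike dataset.
#' @param neurons Character vector of neuron ids (>= 6 for usable power).
#' @param spec A [window_spec()]; centers at and above 25 ms are typical
#'   since lower centers span the prestimulus period.
#' @param baseline Baseline window, ms (default `[-50, 0)`).
#' @param alpha Crossing criterion (default 0.05).
#' @param stimulus_filter Restrict to one expression (default
#'   `"open_mouth"`); `NULL` uses all trials.
#' @param sustained Number of consecutive significant centers required
#'   (default 1: the first crossing).
#' @return A list of class `latency_result`: `latency` (ms or NA),
#'   `pvalues` (tibble `center`, `p`), `alpha`, `n_neurons`.
#' @export
group_latency <- function(dataset, neurons, spec = window_spec(from = 25, to = 500),
                          baseline = c(-50, 0), alpha = 0.05,
                          stimulus_filter = "open_mouth", sustained = 1) {
  if (length(neurons) < 6) abort("Group too small for the signed-rank latency test (need >= 6).")
  dataset <- validate_spike_dataset(dataset)
  sub <- dataset[dataset$neuron_id %in% neurons, ]
  if (!is.null(stimulus_filter)) {
    sub <- sub[expression_of(sub$image_id) == stimulus_filter, ]
  }
  X <- count_matrix_all_centers(sub, spec$centers, spec$width)
  nid <- factor(sub$neuron_id)
  per_neuron <- rowsum(X, nid) / as.vector(table(nid)) / (spec$width / 1000)
  base <- tapply(epoch_rate(sub, baseline[1], baseline[2]), nid, mean)
  base <- as.numeric(base[rownames(per_neuron)])
  p <- vapply(seq_along(spec$centers), function(ci) {
    suppressWarnings(wilcoxon_signed_rank(per_neuron[, ci], base)$p.value)
  }, numeric(1))
  sig <- p < alpha
  latency <- NA_real_
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  hit <- which(run$values & run$lengths >= sustained)
  if (length(hit) > 0) latency <- spec$centers[starts[hit[1]]]
  structure(
    list(latency = latency,
         pvalues = tibble::tibble(center = spec$centers, p = p),
         alpha = alpha, n_neurons = length(unique(neurons))),
    class = "latency_result"
  )
}

#' @export
print.latency_result <- function(x, ...) {
  cat(sprintf("<latency_result> latency %s ms (alpha = %g, %d neurons)\n",
              ifelse(is.na(x$latency), "undefined", format(x$latency)),
              x$alpha, x$n_neurons))
  invisible(x)
}

#' @method tidy latency_result
#' @export
tidy.latency_result <- function(x, ...) x$pvalues

#' @method glance latency_result
#' @export
glance.latency_result <- function(x, ...) {
  tibble::tibble(latency = x$latency, alpha = x$alpha, n_neurons = x$n_neurons)
}
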