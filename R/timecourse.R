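# Shared preparation for the sliding-window Friedman analyses: per neuron,
# trials are truncated to the per-image minimum repetition count using
# presentation order (trial_id), so blocks stay paired; neurons below
# `min_reps` repetitions are dropped.  Returns the retained trial rows, a
# counts matrix (row = retained trial, column = window center) and indexing
# vectors used by the batched rank computations.
friedman_prep <- function(dataset, spec, min_reps = 6) {
  dataset <- validate_spike_dataset(dataset)
  dataset <- dplyr::arrange(dataset, .data$neuron_id, .data$trial_id)
  dataset <- dataset |>
    dplyr::group_by(.data$neuron_id, .data$image_id) |>
    dplyr::mutate(repetition = dplyr::row_number()) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(n_reps = min(table(factor(.data$image_id, levels = 1:9)))) |>
    dplyr::ungroup()
  kept <- dataset |>
    dplyr::filter(.data$n_reps >= min_reps, .data$repetition <= .data$n_reps) |>
    dplyr::arrange(.data$neuron_id, .data$image_id, .data$repetition)
  if (nrow(kept) == 0) abort("No neuron has enough repetitions per image.")
  neurons <- unique(kept$neuron_id)
  X <- count_matrix_all_centers(kept, spec$centers, spec$width)
  list(
    rows = kept,
    X = X,
    centers = spec$centers,
    neurons = neurons,
    nid = match(kept$neuron_id, neurons),
    n_reps = vapply(split(kept$n_reps, kept$neuron_id), function(x) x[1],
                    numeric(1))[neurons]
  )
}

# Batched tie-corrected Friedman chi-square for 3 treatments across many
# (neuron, center) cells.  x1, x2, x3: one row per block, one column per
# center; `block_nid` maps block rows to neuron index; `n_blocks` gives
# blocks per neuron.  Returns list(chi2, p): neurons x centers matrices.
friedman_batch3 <- function(x1, x2, x3, block_nid, n_blocks) {
  eq12 <- x1 == x2; eq13 <- x1 == x3; eq23 <- x2 == x3
  r1 <- 1 + (x1 > x2) + (x1 > x3) + 0.5 * (eq12 + eq13)
  r2 <- 1 + (x2 > x1) + (x2 > x3) + 0.5 * (eq12 + eq23)
  r3 <- 1 + (x3 > x1) + (x3 > x2) + 0.5 * (eq13 + eq23)
  s1 <- rowsum(r1, block_nid)
  s2 <- rowsum(r2, block_nid)
  s3 <- rowsum(r3, block_nid)
  all_eq <- eq12 & eq13
  pair_only <- (eq12 + eq13 + eq23 == 1)
  tie_term <- rowsum(24 * all_eq + 6 * pair_only, block_nid)
  nb <- as.numeric(n_blocks[as.integer(rownames(s1))])
  chi_raw <- sweep(s1^2 + s2^2 + s3^2, 1, nb, "/") - 12 * nb
  cc <- 1 - sweep(tie_term, 1, 24 * nb, "/")
  chi2 <- ifelse(cc <= 1e-12, 0, chi_raw / cc)
  p <- pchisq(chi2, df = 2, lower.tail = FALSE)
  list(chi2 = chi2, p = p)
}

# Assemble the three per-expression block-value matrices from a (possibly
# permuted) counts matrix, then run the batched Friedman computation.
friedman_pvalues_from_counts <- function(prep, X, block_mode) {
  rows <- prep$rows
  if (block_mode == "repetition") {
    # block = repetition index; value = mean count across the 3 identities
    key <- prep$nid * 1000L + rows$repetition
    xs <- lapply(EXPRESSIONS, function(e) {
      sel <- expression_of(rows$image_id) == e
      rowsum(X[sel, , drop = FALSE], key[sel]) / 3
    })
    block_key <- sort(unique(key))
    block_nid <- block_key %/% 1000L
    n_blocks <- tapply(rep(1, length(block_nid)), block_nid, sum)
  } else {
    # block = identity x repetition; value = raw count
    key <- prep$nid * 10000L + match(identity_of(rows$image_id), IDENTITIES) *
      1000L + rows$repetition
    xs <- lapply(EXPRESSIONS, function(e) {
      sel <- expression_of(rows$image_id) == e
      rowsum(X[sel, , drop = FALSE], key[sel])
    })
    block_key <- sort(unique(key))
    block_nid <- block_key %/% 10000L
    n_blocks <- tapply(rep(1, length(block_nid)), block_nid, sum)
  }
  friedman_batch3(xs[[1]], xs[[2]], xs[[3]], block_nid, n_blocks)
}

#' Build the expression Friedman table for one neuron and window
#'
#' Blocks-by-expression table feeding [friedman_statistic()].  In the
#' default `"repetition"` mode, block b holds, for each expression, the mean
#' spike count over the 3 identities at repetition index b (repetitions in
#' presentation order, truncated to the per-image minimum); the number of
#' blocks equals the repetition count.  The `"identity_repetition"` mode
#' uses one block per identity-repetition pair with raw counts.
#'
#' @param dataset A spike dataset.
#' @param neuron One `neuron_id` present in `dataset`.
#' @param center Window center, ms.
#' @param spec A [window_spec()] (defines the width).
#' @param block_mode `"repetition"` (default) or `"identity_repetition"`.
#' @param min_reps Minimum repetitions per image (default 6).
#' @return A numeric matrix, blocks x 3 expressions.
#' @export
expression_table <- function(dataset, neuron, center, spec = window_spec(),
                             block_mode = c("repetition", "identity_repetition"),
                             min_reps = 6) {
  block_mode <- match.arg(block_mode)
  sub <- dataset[dataset$neuron_id == neuron, ]
  if (nrow(sub) == 0) abort(sprintf("Neuron %s not found.", neuron))
  spec1 <- window_spec(width = spec$width, centers = center)
  prep <- tryCatch(friedman_prep(sub, spec1, min_reps = min_reps),
                   error = function(e) abort(sprintf(
                     "Neuron %s excluded: fewer than %d repetitions per image.",
                     neuron, min_reps)))
  rows <- prep$rows
  X <- prep$X[, 1]
  if (block_mode == "repetition") {
    tab <- vapply(EXPRESSIONS, function(e) {
      sel <- expression_of(rows$image_id) == e
      as.numeric(rowsum(X[sel], rows$repetition[sel]) / 3)
    }, numeric(prep$n_reps[[1]]))
  } else {
    tab <- vapply(EXPRESSIONS, function(e) {
      sel <- expression_of(rows$image_id) == e
      key <- match(identity_of(rows$image_id[sel]), IDENTITIES) * 1000L +
        rows$repetition[sel]
      as.numeric(rowsum(X[sel], key))
    }, numeric(3 * prep$n_reps[[1]]))
  }
  colnames(tab) <- EXPRESSIONS
  tab
}

#' Sliding-window Friedman p-value time course per neuron
#'
#' For every neuron and window center, tests the effect of facial
#' expression on spike counts with the tie-corrected Friedman test
#' (df = 2).
#'
#' @inheritParams expression_table
#' @param spec A [window_spec()].
#' @return A tibble `neuron_id`, `center`, `chi2`, `p`.
#' @export
expression_pvalue_timecourse <- function(dataset, spec = window_spec(),
                                         block_mode = c("repetition", "identity_repetition"),
                                         min_reps = 6) {
  block_mode <- match.arg(block_mode)
  prep <- friedman_prep(dataset, spec, min_reps = min_reps)
  res <- friedman_pvalues_from_counts(prep, prep$X, block_mode)
  tibble::tibble(
    neuron_id = rep(prep$neurons, times = length(prep$centers)),
    center = rep(prep$centers, each = length(prep$neurons)),
    chi2 = as.vector(res$chi2),
    p = as.vector(res$p)
  )
}

#' Count expression-differentiating neurons per window
#'
#' The population summary of the sliding-window Friedman analysis: the
#' number of neurons with p below each criterion at every window center.
#'
#' @inheritParams expression_pvalue_timecourse
#' @param alpha Significance criteria (default both 0.05 and 0.01).
#' @return A tibble `center`, `alpha`, `count`, classed `sig_counts`.
#' @export
significant_neuron_counts <- function(dataset, spec = window_spec(),
                                      alpha = c(0.05, 0.01),
                                      block_mode = c("repetition", "identity_repetition"),
                                      min_reps = 6) {
  block_mode <- match.arg(block_mode)
  tc <- expression_pvalue_timecourse(dataset, spec, block_mode, min_reps)
  out <- purrr::map_dfr(alpha, function(a) {
    tc |>
      dplyr::group_by(center = .data$center) |>
      dplyr::summarise(count = sum(.data$p < a), .groups = "drop") |>
      dplyr::mutate(alpha = a, .before = "count")
  })
  class(out) <- union("sig_counts", class(out))
  out
}

#' Shuffle-calibrated null percentiles for significant-neuron counts
#'
#' Builds the null distribution of the per-window count of
#' expression-differentiating neurons by permuting the stimulus-response
#' relationship: within each neuron, image labels are permuted across
#' trials (one permutation per neuron per shuffle, applied consistently
#' across all windows), and the Friedman counts are recomputed.  The 95th
#' and 99th percentiles of the null count distribution are taken per window
#' and, since the null shows no systematic time trend, averaged across
#' windows into the reported thresholds.
#'
#' @inheritParams significant_neuron_counts
#' @param alpha The Friedman significance criterion the counts use.
#' @param n_shuffles Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return A list with scalars `p95` and `p99` (window-averaged), a tibble
#'   `per_center` of per-window percentiles, and the `null_counts` matrix
#'   (shuffles x centers).
#' @export
shuffle_null_percentiles <- function(dataset, spec = window_spec(),
                                     alpha = 0.05, n_shuffles = 1000, seed = 1,
                                     block_mode = c("repetition", "identity_repetition"),
                                     min_reps = 6) {
  block_mode <- match.arg(block_mode)
  if (n_shuffles < 1) abort("`n_shuffles` must be >= 1.")
  prep <- friedman_prep(dataset, spec, min_reps = min_reps)
  row_groups <- split(seq_len(nrow(prep$X)), prep$nid)
  raw <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- unlist(lapply(row_groups, sample), use.names = FALSE)
      Xp <- prep$X
      Xp[unlist(row_groups, use.names = FALSE), ] <- prep$X[perm, , drop = FALSE]
      res <- friedman_pvalues_from_counts(prep, Xp, block_mode)
      colSums(res$p < alpha)
    }, numeric(length(prep$centers)))
  })
  # shuffles in rows, centers in columns (vapply drops the center axis when
  # the spec has a single center)
  null_counts <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = 1)
  per_center <- tibble::tibble(
    center = prep$centers,
    p95 = apply(null_counts, 2, quantile, probs = 0.95, names = FALSE),
    p99 = apply(null_counts, 2, quantile, probs = 0.99, names = FALSE)
  )
  list(
    p95 = mean(per_center$p95),
    p99 = mean(per_center$p99),
    per_center = per_center,
    null_counts = null_counts
  )
}
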