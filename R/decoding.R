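#' Max-normalize spike-count response vectors
#'
#' Each neuron's counts are divided by that neuron's maximum count over the
#' reference set, so the maximum response maps to 1 (counts
#' `[0, 1, 2, 3, 4]` become `[0, 0.25, 0.5, 0.75, 1]`).  A neuron whose
#' reference maximum is 0 maps to all zeros.
#'
#' @param reference Numeric matrix, samples x neurons: the set defining each
#'   neuron's maximum (normally the training fold).
#' @param x Matrix to normalize (same neuron columns); defaults to
#'   `reference`.
#' @return `x` with each column divided by the reference column maximum.
#' @examples
#' normalize_responses(matrix(0:4, ncol = 1))
#' @export
normalize_responses <- function(reference, x = reference) {
  if (ncol(reference) != ncol(x)) abort("Neuron sets differ between matrices.")
  mx <- apply(reference, 2, max)
  mx[mx == 0] <- 1  # all-zero neurons stay all-zero
  sweep(x, 2, mx, "/")
}

# one binary soft-margin linear SVM via LIBSVM (e1071); returns w (per
# neuron) and b oriented so f(x) = x.w + b is positive for the target class
svm_binary <- function(x, is_target, cost) {
  if (all(is_target) || !any(is_target)) {
    abort("A class is absent from the training set.")
  }
  y <- factor(ifelse(is_target, "target", "rest"), levels = c("rest", "target"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = 1e-6)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- as.numeric(x %*% w) + b
  mt <- mean(f[is_target]); mr <- mean(f[!is_target])
  flip <- if (abs(mt - mr) > 1e-12) {
    mt < mr
  } else {
    # degenerate geometry (identical samples): orient the constant decision
    # value toward the majority side
    if (mean(is_target) >= 0.5) mean(f) < 0 else mean(f) > 0
  }
  if (flip) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Train the one-vs-rest linear classifier ensemble
#'
#' Fits, for each facial expression, a soft-margin linear support-vector
#' classifier (C-SVC, linear kernel, cost 0.125 by default) separating that
#' expression from the other two.  The decision function of classifier k is
#' `f_k(x) = w_k . x + b_k`, oriented so the target expression scores
#' positive.
#'
#' @param x Training matrix, samples x neurons, normally max-normalized.
#' @param labels Expression label per row of `x`.
#' @param cost Soft-margin cost parameter (default 0.125).
#' @return A `classifier_ensemble`: list with `w` (3 x neurons matrix,
#'   rows named by expression), `b` (length-3 offsets) and `cost`.
#' @export
train_ovr <- function(x, labels, cost = 0.125) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), EXPRESSIONS)
  if (length(bad) > 0) abort(paste0("Unknown expression label: ", bad[1]))
  fits <- lapply(EXPRESSIONS, function(e) svm_binary(x, labels == e, cost))
  w <- do.call(rbind, lapply(fits, `[[`, "w"))
  rownames(w) <- EXPRESSIONS
  structure(
    list(w = w, b = vapply(fits, `[[`, numeric(1), "b"), cost = cost),
    class = "classifier_ensemble"
  )
}

#' Decision values of a classifier ensemble
#'
#' @param ensemble A `classifier_ensemble` from [train_ovr()].
#' @param x Matrix of response vectors, samples x neurons.
#' @return Matrix samples x 3 of weighted sums `f_k(x)`.
#' @export
decision_values <- function(ensemble, x) {
  if (ncol(x) != ncol(ensemble$w)) abort("Response-vector dimension mismatch.")
  sweep(x %*% t(ensemble$w), 2, ensemble$b, "+")
}

#' Classify response vectors
#'
#' The predicted expression maximizes the weighted sum `f_k(x)`; ties are
#' broken by the fixed expression order (open-mouth, neutral, pout-lips).
#'
#' @inheritParams decision_values
#' @return Factor of predicted expressions, one per row of `x`.
#' @export
classify <- function(ensemble, x) {
  f <- decision_values(ensemble, x)
  factor(EXPRESSIONS[max.col(f, ties.method = "first")], levels = EXPRESSIONS)
}

#' @method tidy classifier_ensemble
#' @export
tidy.classifier_ensemble <- function(x, ...) {
  neurons <- colnames(x$w) %||% as.character(seq_len(ncol(x$w)))
  tibble::tibble(
    expression = rep(EXPRESSIONS, each = ncol(x$w)),
    neuron_id = rep(neurons, times = 3),
    weight = as.vector(t(x$w)),
    offset = rep(x$b, each = ncol(x$w))
  )
}

# Build the per-neuron counts array [neuron, image, repetition] at each
# requested center; neurons must have exactly `n_trials` trials per image
# (the cross-validation bookkeeping requires it); others are dropped with a
# message.  Returns list(arr: 4-d array [N, 9, T, nC], neurons, excluded).
decode_prep <- function(dataset, centers, width, n_trials = 10) {
  dataset <- validate_spike_dataset(dataset)
  dataset <- dplyr::arrange(dataset, .data$neuron_id, .data$trial_id)
  tc <- trial_counts(dataset)
  ok <- tc |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      ok = dplyr::n() == 9 && all(.data$n_trials == .env$n_trials),
      .groups = "drop"
    )
  excluded <- ok$neuron_id[!ok$ok]
  if (length(excluded) > 0) {
    rlang::inform(sprintf(
      "Excluding %d neuron(s) without exactly %d trials per image: %s",
      length(excluded), n_trials,
      paste(head(excluded, 5), collapse = ", ")
    ))
  }
  neurons <- ok$neuron_id[ok$ok]
  if (length(neurons) == 0) abort("No neuron meets the trial-count requirement.")
  kept <- dataset |>
    dplyr::filter(.data$neuron_id %in% neurons) |>
    dplyr::group_by(.data$neuron_id, .data$image_id) |>
    dplyr::mutate(repetition = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$neuron_id, .data$image_id, .data$repetition)
  X <- count_matrix_all_centers(kept, centers, width)
  arr <- array(0, dim = c(length(neurons), 9, n_trials, length(centers)))
  nid <- match(kept$neuron_id, neurons)
  arr[cbind(
    rep(nid, times = length(centers)),
    rep(kept$image_id, times = length(centers)),
    rep(kept$repetition, times = length(centers)),
    rep(seq_along(centers), each = nrow(kept))
  )] <- as.vector(X)
  list(arr = arr, neurons = neurons, excluded = excluded)
}

# within-group random permutations for many groups in one order() call:
# returns an integer vector where positions of group g hold a random
# permutation of 1..size, laid out group-major
block_permutations <- function(n_groups, size) {
  o <- order(rep(seq_len(n_groups), each = size), runif(n_groups * size))
  o - (rep(seq_len(n_groups), each = size) - 1L) * size
}

# Core repeated-split decoding at one center.  `m3`: array [N, 9, T].
# Assumes the RNG state is already controlled by the caller.
decode_core <- function(m3, n_reps, n_neurons, train_frac, cost,
                        shuffle_labels, normalization, cv, keep_weights) {
  N <- dim(m3)[1]; Timg <- dim(m3)[3]
  n_train <- round(train_frac * Timg)
  n_test <- Timg - n_train
  if (n_train < 1 || n_test < 1) abort("`train_frac` leaves an empty fold.")
  if (is.null(n_neurons)) n_neurons <- N
  if (n_neurons > N) abort("`n_neurons` exceeds the population size.")
  train_lab <- expression_of(rep(1:9, each = n_train))
  test_lab <- expression_of(rep(1:9, each = n_test))
  train_img <- rep(1:9, each = n_train)
  test_img <- rep(1:9, each = n_test)
  acc <- matrix(NA_real_, n_reps, 4)
  weights <- if (keep_weights) {
    array(NA_real_, dim = c(n_reps, N, 3),
          dimnames = list(NULL, NULL, EXPRESSIONS))
  }
  if (cv == "kfold") {
    fold_sets <- split(seq_len(Timg), rep(seq_len(Timg %/% n_test), each = n_test))
  }
  flat <- as.vector(m3)  # index = n + (img-1)*N + (trial-1)*N*9
  rep_i <- 1L
  while (rep_i <= n_reps) {
    sel <- if (n_neurons < N) sort(sample.int(N, n_neurons)) else seq_len(N)
    ns <- length(sel)
    fold_span <- if (cv == "kfold") length(fold_sets) else 1L
    if (shuffle_labels) {
      # permute the (image, trial) assignment within each selected neuron
      shuf <- block_permutations(ns, 9L * Timg)
      cell <- rep(sel, each = 9 * Timg) +
        ((shuf - 1L) %% 9L) * N + ((shuf - 1L) %/% 9L) * (N * 9L)
      # lay shuffled cells back image-major: neuron-block j holds its 9*T cells
      flat_view <- flat
      dest <- rep(sel, each = 9 * Timg) +
        rep((rep(1:9, times = Timg) - 1L) * N, times = ns) +
        rep((rep(seq_len(Timg), each = 9) - 1L) * (N * 9L), times = ns)
      flat_view[dest] <- flat[cell]
    } else {
      flat_view <- flat
    }
    # per (neuron, image) trial permutation: arbitrary pseudo-trial pairing,
    # one order() call for all of them
    perm <- block_permutations(ns * 9L, Timg)
    # perm laid out (neuron, image)-major: slot k = ((j-1)*9 + (img-1))*T + t
    for (fold in seq_len(fold_span)) {
      if (rep_i > n_reps) break
      if (cv == "kfold") {
        test_rows <- fold_sets[[fold]]
        train_rows <- setdiff(seq_len(Timg), test_rows)
      } else {
        train_rows <- seq_len(n_train)
        test_rows <- n_train + seq_len(n_test)
      }
      pick <- function(rows) {
        # rows: positions in the per-(neuron,image) permutation
        take <- perm[rep(seq(0, ns * 9L - 1L) * Timg, each = length(rows)) +
                       rep(rows, times = ns * 9L)]
        idx <- rep(sel, each = 9 * length(rows)) +
          rep(rep((1:9 - 1L) * N, each = length(rows)), times = ns) +
          (take - 1L) * (N * 9L)
        matrix(flat_view[idx], nrow = 9 * length(rows), ncol = ns)
      }
      train_x <- pick(train_rows)
      test_x <- pick(test_rows)
      ref <- if (normalization == "train") train_x else rbind(train_x, test_x)
      train_n <- normalize_responses(ref, train_x)
      test_n <- normalize_responses(ref, test_x)
      ens <- train_ovr(train_n, train_lab, cost)
      pred <- classify(ens, test_n)
      correct <- pred == test_lab
      acc[rep_i, ] <- c(
        mean(correct),
        vapply(EXPRESSIONS, function(e) mean(correct[test_lab == e]), numeric(1))
      )
      if (keep_weights) weights[rep_i, sel, ] <- t(ens$w)
      rep_i <- rep_i + 1L
    }
  }
  out <- tibble::tibble(
    rep = seq_len(n_reps),
    accuracy = acc[, 1],
    acc_open_mouth = acc[, 2],
    acc_neutral = acc[, 3],
    acc_pout_lips = acc[, 4]
  )
  if (keep_weights) attr(out, "weights") <- weights
  out
}

#' Decode facial expression at one window center
#'
#' Repeated stratified random-split decoding of the 9 face images' pseudo-
#' population responses at one window.  In each of `n_reps` simulations:
#' (i) if the population exceeds `n_neurons`, neurons are subsampled
#' without replacement; (ii) for every neuron and image, `train_frac` of
#' the trials (8 of 10) are drawn for training and the rest (2) for
#' testing, independently per neuron (neurons were not recorded
#' simultaneously, so trial pairing across neurons is arbitrary and
#' re-randomized per rep); (iii) counts are max-normalized per neuron over
#' the training fold and the one-vs-rest ensemble is trained on the 72
#' training vectors; (iv) the 18 test vectors are classified and the
#' overall and per-expression correct fractions recorded.
#'
#' @param dataset A spike dataset.
#' @param center Window center, ms.
#' @param spec A [window_spec()] (defines the width).
#' @param n_reps Number of random-split simulations (default 100).
#' @param n_neurons Neuron count to equalize to; `NULL` uses all.
#' @param train_frac Training fraction (default 0.8).
#' @param cost SVM cost (default 0.125).
#' @param seed Integer seed.
#' @param shuffle_labels Permute image labels within each neuron first
#'   (chance estimation).
#' @param normalization `"train"` (per-neuron max over the training fold,
#'   applied to both folds; default) or `"all"` (max over all trials).
#' @param cv `"random"` (repeated 80/20 splits; default) or `"kfold"`
#'   (exact 5-fold partitions, refreshed until `n_reps` folds are run).
#' @param n_trials Required trial count per image (default 10); neurons
#'   differing on any image are excluded with a message.
#' @param keep_weights Retain the per-rep weight vectors (as an `weights`
#'   attribute: array reps x neurons x expression, NA where a neuron was
#'   not subsampled).
#' @return A tibble with one row per rep: `rep`, `accuracy`,
#'   `acc_open_mouth`, `acc_neutral`, `acc_pout_lips`; attributes `center`,
#'   `neurons`, `excluded` (and `weights` if requested).
#' @export
decode_window <- function(dataset, center, spec = window_spec(), n_reps = 100,
                          n_neurons = NULL, train_frac = 0.8, cost = 0.125,
                          seed = 1, shuffle_labels = FALSE,
                          normalization = c("train", "all"),
                          cv = c("random", "kfold"),
                          n_trials = 10, keep_weights = FALSE) {
  normalization <- match.arg(normalization)
  cv <- match.arg(cv)
  prep <- decode_prep(dataset, center, spec$width, n_trials)
  out <- withr::with_seed(seed, {
    decode_core(prep$arr[, , , 1, drop = TRUE] |>
                  array(dim = dim(prep$arr)[1:3]),
                n_reps, n_neurons, train_frac, cost, shuffle_labels,
                normalization, cv, keep_weights)
  })
  if (keep_weights) {
    dimnames(attr(out, "weights"))[[2]] <- prep$neurons
  }
  attr(out, "center") <- center
  attr(out, "neurons") <- prep$neurons
  attr(out, "excluded") <- prep$excluded
  out
}

#' Decoding-accuracy time course
#'
#' Applies [decode_window()] independently at every window center of
#' `spec`, with an optional chance curve from label-shuffled runs.
#'
#' @inheritParams decode_window
#' @param chance Also estimate chance accuracy by label shuffling at each
#'   center (default TRUE).
#' @param detail Keep the per-rep results as a list-column `reps`.
#' @return A `decoding_timecourse` tibble: `center`, `accuracy`, `se`
#'   (SEM across reps), per-expression accuracies, and `chance` (NA when
#'   not estimated).
#' @export
decode_timecourse <- function(dataset, spec = window_spec(), n_reps = 100,
                              n_neurons = NULL, train_frac = 0.8, cost = 0.125,
                              seed = 1, normalization = c("train", "all"),
                              cv = c("random", "kfold"), n_trials = 10,
                              chance = TRUE, detail = FALSE) {
  normalization <- match.arg(normalization)
  cv <- match.arg(cv)
  prep <- decode_prep(dataset, spec$centers, spec$width, n_trials)
  rows <- withr::with_seed(seed, {
    lapply(seq_along(spec$centers), function(ci) {
      m3 <- array(prep$arr[, , , ci], dim = dim(prep$arr)[1:3])
      reps <- decode_core(m3, n_reps, n_neurons, train_frac, cost,
                          FALSE, normalization, cv, FALSE)
      ch <- if (chance) {
        mean(decode_core(m3, n_reps, n_neurons, train_frac, cost,
                         TRUE, normalization, cv, FALSE)$accuracy)
      } else NA_real_
      row <- tibble::tibble(
        center = spec$centers[ci],
        accuracy = mean(reps$accuracy),
        se = sd(reps$accuracy) / sqrt(nrow(reps)),
        acc_open_mouth = mean(reps$acc_open_mouth),
        acc_neutral = mean(reps$acc_neutral),
        acc_pout_lips = mean(reps$acc_pout_lips),
        chance = ch
      )
      if (detail) row$reps <- list(reps)
      row
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "neurons") <- prep$neurons
  attr(out, "n_reps") <- n_reps
  class(out) <- union("decoding_timecourse", class(out))
  out
}

#' Pairwise AUC profile of per-expression decoding accuracy
#'
#' Reflected rank-based AUC between the per-rep correct-rate distributions
#' of each expression pair at one window, quantifying how separated the
#' classifiers' performance is across expressions.
#'
#' @param window_reps Per-rep tibble from [decode_window()] (or one element
#'   of a detailed time course).
#' @return A tibble `pair`, `auc` with the three expression pairs.
#' @export
pairwise_auc_profile <- function(window_reps) {
  pairs <- list(
    c("open_mouth", "neutral"),
    c("open_mouth", "pout_lips"),
    c("neutral", "pout_lips")
  )
  purrr::map_dfr(pairs, function(pr) {
    a <- window_reps[[paste0("acc_", pr[1])]]
    b <- window_reps[[paste0("acc_", pr[2])]]
    tibble::tibble(
      pair = paste(pr, collapse = "_vs_"),
      auc = reflect_auc(auc(a, b))
    )
  })
}
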