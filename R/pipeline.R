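#' Locate the early peak, trough and global peak of an accuracy curve
#'
#' The global peak is the curve maximum (for tied maxima, the later one;
#' the earlier tied maximum then qualifies as the early peak).  The early
#' peak is the highest local maximum preceding the global peak and
#' separated from it by a local minimum; the trough is the lowest point
#' between the two peaks.  The peak delay is the difference of the two
#' peak centers.  A unimodal curve has no early peak; a flat curve has no
#' peaks at all.
#'
#' @param timecourse A [decode_timecourse()] result, or any data frame with
#'   `center` and `accuracy` columns.
#' @param smooth_window Odd number of centers for a running-mean smoothing
#'   of the curve before peak detection (1 = no smoothing).  Monte-Carlo
#'   wiggle between neighboring windows otherwise creates spurious local
#'   extrema.
#' @param min_prominence Minimum depth (accuracy units) by which the
#'   intervening minimum must fall below the lower of the two peaks for an
#'   early-peak candidate to count (0 = any local minimum).
#' @return A one-row tibble: `early_peak`, `trough`, `global_peak`,
#'   `delay` (all window centers in ms, NA where undefined) and the
#'   accuracies at each.
#' @export
find_peaks_and_trough <- function(timecourse, smooth_window = 1,
                                  min_prominence = 0) {
  acc <- timecourse$accuracy
  centers <- timecourse$center
  if (length(acc) < 3) abort("Need a curve on >= 3 centers.")
  if (smooth_window > 1) {
    k <- floor(smooth_window / 2)
    acc <- vapply(seq_along(acc), function(i) {
      mean(acc[max(1, i - k):min(length(acc), i + k)])
    }, numeric(1))
  }
  out <- tibble::tibble(
    early_peak = NA_real_, trough = NA_real_, global_peak = NA_real_,
    delay = NA_real_, early_accuracy = NA_real_, trough_accuracy = NA_real_,
    global_accuracy = NA_real_
  )
  if (max(acc) == min(acc)) {
    warn("Flat accuracy curve; peaks undefined.")
    return(out)
  }
  g <- max(which(acc == max(acc)))
  out$global_peak <- centers[g]
  out$global_accuracy <- acc[g]
  if (g >= 3) {
    n <- length(acc)
    is_locmax <- vapply(seq_len(g - 1), function(i) {
      left_ok <- i == 1 || acc[i] >= acc[i - 1]
      right_ok <- acc[i] >= acc[i + 1]
      left_ok && right_ok && (i == 1 || acc[i] > acc[i - 1] || acc[i] > acc[i + 1])
    }, logical(1))
    cand <- which(is_locmax)
    # require a strictly lower point between candidate and global peak
    cand <- cand[vapply(cand, function(e) {
      between <- acc[(e + 1):(g - 1)]
      length(between) > 0 &&
        min(between) < min(acc[e], acc[g]) - max(min_prominence, 0)
    }, logical(1))]
    if (length(cand) > 0) {
      e <- cand[which.max(acc[cand])]
      t_idx <- e + which.min(acc[(e + 1):(g - 1)])
      out$early_peak <- centers[e]
      out$early_accuracy <- acc[e]
      out$trough <- centers[t_idx]
      out$trough_accuracy <- acc[t_idx]
      out$delay <- centers[g] - centers[e]
    }
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles every stage setting of [run_pipeline()] with the analysis
#' defaults used throughout the package: 50-ms windows, significance
#' criteria 0.05 and 0.01, 1000 shuffles, 100 decoding simulations, SVM
#' cost 0.125 and an 80/20 train/test split.  Window ranges and counts can
#' be scaled down for quick runs; any override is echoed in the report.
#'
#' @param dataset A spike dataset, or `NULL` to simulate one from
#'   `population`.
#' @param population A [population_config()] used when simulating.
#' @param timecourse_spec,decode_spec,latency_spec [window_spec()]s for the
#'   Friedman time course, the decoding time course and the latency
#'   analysis.
#' @param alphas Significance criteria for the Friedman counts.
#' @param n_shuffles Shuffle repetitions for the null percentiles.
#' @param n_reps Decoding simulations per window.
#' @param cost,train_frac SVM cost and training fraction.
#' @param n_trials Required trials per image for decoding.
#' @param reference_center Early-peak center for the weight analysis;
#'   `NULL` locates it from the decoding curve.
#' @param peak_smooth,peak_prominence Peak-detection settings passed to
#'   [find_peaks_and_trough()] (running-mean span in centers and minimum
#'   trough depth); the defaults suppress Monte-Carlo micro-extrema.
#' @param stages Character vector of stages to run, in order, among
#'   `"screen"`, `"timecourse"`, `"decode"`, `"weights"`, `"sfshift"`.
#' @param seed Integer master seed; per-stage seeds are derived from it by
#'   fixed offsets so stages can be reproduced singly.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = NULL,
                            population = population_config(),
                            timecourse_spec = window_spec(from = -100, to = 500, step = 5),
                            decode_spec = window_spec(from = -50, to = 300, step = 5),
                            latency_spec = window_spec(from = 25, to = 300, step = 1),
                            alphas = c(0.05, 0.01),
                            n_shuffles = 1000, n_reps = 100,
                            cost = 0.125, train_frac = 0.8, n_trials = 10,
                            reference_center = NULL,
                            peak_smooth = 5, peak_prominence = 0.02,
                            stages = c("screen", "timecourse", "decode",
                                       "weights", "sfshift"),
                            seed = 1) {
  structure(
    list(dataset = dataset, population = population,
         timecourse_spec = timecourse_spec, decode_spec = decode_spec,
         latency_spec = latency_spec, alphas = alphas,
         n_shuffles = n_shuffles, n_reps = n_reps, cost = cost,
         train_frac = train_frac, n_trials = n_trials,
         reference_center = reference_center, peak_smooth = peak_smooth,
         peak_prominence = peak_prominence, stages = stages, seed = seed),
    class = "pipeline_config"
  )
}

# fixed per-stage seed derivation (kept well below 2^31)
stage_seed <- function(seed, k) (seed %% 1000000L) * 100L + k

#' Run the full analysis pipeline
#'
#' Executes simulate (when no dataset is supplied), screening, the
#' sliding-window Friedman time course with shuffle-calibrated null
#' percentiles, population decoding with peak/trough detection, the
#' early-peak weight analysis (groups, correlations, weighted-sum time
#' courses, group latencies), and — when the dataset carries generator
#' group labels — a spatial-frequency shift-index stage on simulated
#' tuning surfaces (retina-based for early-excited neurons, image-based
#' otherwise).  All randomness derives from the single seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list of stage tables; see [glance.pipeline_report()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  report <- list(config = config, seed = config$seed)
  dataset <- config$dataset
  if (is.null(dataset)) {
    dataset <- simulate_population(config$population,
                                   seed = stage_seed(config$seed, 1))
  }
  report$n_neurons <- length(unique(dataset$neuron_id))
  if ("screen" %in% stages) {
    report$screening <- face_responsiveness(dataset, alpha = 0.05)
  }
  if ("timecourse" %in% stages) {
    report$sig_counts <- significant_neuron_counts(
      dataset, config$timecourse_spec, alpha = config$alphas
    )
    nulls <- shuffle_null_percentiles(
      dataset, config$timecourse_spec, alpha = config$alphas[1],
      n_shuffles = config$n_shuffles, seed = stage_seed(config$seed, 2)
    )
    report$null_percentiles <- tibble::tibble(p95 = nulls$p95, p99 = nulls$p99)
  }
  if ("decode" %in% stages) {
    report$decoding <- decode_timecourse(
      dataset, config$decode_spec, n_reps = config$n_reps,
      train_frac = config$train_frac, cost = config$cost,
      n_trials = config$n_trials, seed = stage_seed(config$seed, 3)
    )
    report$peaks <- find_peaks_and_trough(report$decoding,
                                          smooth_window = config$peak_smooth,
                                          min_prominence = config$peak_prominence)
  }
  if ("weights" %in% stages) {
    ref <- config$reference_center
    if (is.null(ref)) {
      if (is.null(report$decoding)) {
        abort("The weights stage needs the decode stage (or a `reference_center`).")
      }
      ref <- report$peaks$early_peak
      if (is.na(ref)) ref <- report$peaks$global_peak
    }
    spec_ref <- window_spec(width = config$decode_spec$width, centers = ref)
    reps <- decode_window(
      dataset, ref, spec_ref, n_reps = config$n_reps,
      train_frac = config$train_frac, cost = config$cost,
      n_trials = config$n_trials, seed = stage_seed(config$seed, 4),
      keep_weights = TRUE
    )
    report$reference_center <- ref
    report$weights <- extract_weights(reps)
    report$auc_profile <- pairwise_auc_profile(reps)
    report$weight_correlations <- purrr::map_dfr(
      c("preference", "excitation"),
      function(m) {
        ht <- weight_response_correlation(report$weights, dataset, ref,
                                          spec_ref, mode = m)
        tibble::tibble(mode = m, rs = ht$statistic, p = ht$p.value, n = ht$n)
      }
    )
    report$weighted_sums <- purrr::map_dfr(c("positive", "negative"), function(g) {
      dplyr::mutate(
        weighted_sum_timecourse(dataset, report$weights, g, config$decode_spec),
        group = g, .before = 1
      )
    })
    report$latencies <- purrr::map_dfr(c("positive", "negative"), function(g) {
      ids <- report$weights$neuron_id[report$weights$group == g]
      if (length(ids) < 6) {
        return(tibble::tibble(group = g, latency = NA_real_, n_neurons = length(ids)))
      }
      lat <- group_latency(dataset, ids, config$latency_spec)
      tibble::tibble(group = g, latency = lat$latency, n_neurons = lat$n_neurons)
    })
  }
  if ("sfshift" %in% stages && "group" %in% names(dataset) &&
      !is.null(report$weights)) {
    neurons <- dataset |>
      dplyr::distinct(.data$neuron_id, .data$group)
    surfaces <- withr::with_seed(stage_seed(config$seed, 5), {
      purrr::map_dfr(seq_len(nrow(neurons)), function(i) {
        frame <- if (neurons$group[i] == "positive") "retina_based" else "image_based"
        preferred <- if (frame == "retina_based") {
          2^runif(1, log2(0.6), log2(1.6))   # cycles/degree
        } else {
          2^runif(1, log2(3), log2(10))      # cycles/image
        }
        s <- simulate_tuning_surface(frame, preferred, noise_sd = 1.5,
                                     seed = sample.int(1e6, 1))
        dplyr::mutate(s, neuron_id = neurons$neuron_id[i], .before = 1)
      })
    })
    report$shift <- shift_indices(surfaces)
    paired <- dplyr::inner_join(report$shift, report$weights, by = "neuron_id")
    ht <- shift_weight_correlation(paired$shift_index, paired$weight)
    report$shift_correlation <- tibble::tibble(
      rs = ht$statistic, p = ht$p.value, n = ht$n,
      slope = ht$slope, intercept = ht$intercept
    )
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  neurons: %d, seed: %d\n", x$n_neurons, x$seed))
  if (!is.null(x$peaks)) {
    cat(sprintf("  early peak %s ms, trough %s ms, global peak %s ms (delay %s ms)\n",
                format(x$peaks$early_peak), format(x$peaks$trough),
                format(x$peaks$global_peak), format(x$peaks$delay)))
  }
  if (!is.null(x$latencies)) {
    for (i in seq_len(nrow(x$latencies))) {
      cat(sprintf("  %s-weight latency: %s ms\n", x$latencies$group[i],
                  format(x$latencies$latency[i])))
    }
  }
  invisible(x)
}

#' Pipeline report summary
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities: peak/trough
#'   centers and accuracies, peak delay, group latencies and sizes.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  out <- tibble::tibble(n_neurons = x$n_neurons, seed = x$seed)
  if (!is.null(x$peaks)) out <- dplyr::bind_cols(out, x$peaks)
  if (!is.null(x$weights)) {
    out$n_positive <- sum(x$weights$group == "positive")
    out$n_negative <- sum(x$weights$group == "negative")
  }
  if (!is.null(x$latencies)) {
    out$latency_positive <- x$latencies$latency[x$latencies$group == "positive"]
    out$latency_negative <- x$latencies$latency[x$latencies$group == "negative"]
  }
  out
}
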