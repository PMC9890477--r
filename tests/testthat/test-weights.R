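test_that("weight extraction averages across reps and groups by sign", {
  reps <- tibble::tibble(rep = 1:3, accuracy = 0.5,
                         acc_open_mouth = 0.5, acc_neutral = 0.5,
                         acc_pout_lips = 0.5)
  w <- array(NA_real_, dim = c(3, 4, 3),
             dimnames = list(NULL, c("a", "b", "c", "d"),
                             c("open_mouth", "neutral", "pout_lips")))
  w[, 1, 1] <- c(0.2, 0.4, 0.6)    # positive
  w[, 2, 1] <- c(-0.1, -0.3, NA)   # negative, absent one rep
  w[, 3, 1] <- 0                   # exactly zero
  # neuron d never subsampled
  attr(reps, "weights") <- w
  expect_warning(out <- extract_weights(reps), "never subsampled")
  expect_equal(nrow(out), 3)
  expect_equal(out$weight[out$neuron_id == "a"], 0.4)
  expect_equal(out$weight[out$neuron_id == "b"], -0.2)
  expect_equal(out$group, c("positive", "negative", "excluded_zero"))
  expect_error(extract_weights(tibble::tibble(rep = 1)), "no weights")
})

test_that("weight-response correlations recover monotone structure", {
  ds <- simulate_population(population_config(), seed = 71)
  dw <- decode_window(ds, 60, window_spec(), n_reps = 30, seed = 9,
                      keep_weights = TRUE)
  w <- extract_weights(dw)
  for (mode in c("preference", "excitation")) {
    ht <- weight_response_correlation(w, ds, 60, window_spec(), mode = mode)
    expect_gt(ht$statistic, 0.3)
    expect_lt(ht$p.value, 0.01)
  }
})

test_that("weighted sums are linear in the weights and need a nonempty group", {
  ds <- simulate_population(
    population_config(n_positive = 3, n_negative = 3, n_nonselective = 2),
    seed = 72
  )
  w <- tibble::tibble(
    neuron_id = sprintf("n%03d", 1:6),
    weight = c(0.5, 0.3, 0.2, -0.4, -0.2, -0.1),
    group = rep(c("positive", "negative"), each = 3)
  )
  spec <- window_spec(width = 50, centers = c(0, 55, 150))
  ws <- weighted_sum_timecourse(ds, w, "positive", spec)
  w2 <- dplyr::mutate(w, weight = weight * 2)
  ws2 <- weighted_sum_timecourse(ds, w2, "positive", spec)
  expect_equal(ws2$weighted_sum, 2 * ws$weighted_sum, tolerance = 1e-12)
  expect_equal(nrow(ws), 9)  # 3 centers x 3 expressions
  empty <- dplyr::filter(w, group == "nonexistent")
  expect_error(weighted_sum_timecourse(ds, empty, "positive", spec), "empty")
})

test_that("group mean firing rates track the generating profiles", {
  cfg <- population_config(
    n_positive = 6, n_negative = 0, n_nonselective = 0,
    positive = rate_profile_params(baseline = 18),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 73)
  spec <- window_spec(width = 50, centers = seq(-100, 400, by = 100))
  fr <- group_mean_fr_timecourse(ds, unique(ds$neuron_id), spec = spec)
  expect_true(all(abs(fr$mean_fr - 18) < 6))

  # suppression dips below baseline, rebound rises above it
  neg <- simulate_population(population_config(), seed = 74)
  negids <- unique(neg$neuron_id[neg$group == "negative"])
  spec2 <- window_spec(width = 50, centers = c(-100, 65, 300))
  fr2 <- group_mean_fr_timecourse(neg, negids, spec = spec2)
  expect_lt(fr2$mean_fr[2], fr2$mean_fr[1])   # early suppression
  expect_gt(fr2$mean_fr[3], fr2$mean_fr[1])   # late rebound
})

test_that("group latency is the first sub-alpha crossing of the p curve", {
  ds <- simulate_population(population_config(), seed = 75)
  pos <- unique(ds$neuron_id[ds$group == "positive"])
  spec <- window_spec(width = 50, from = 25, to = 150, step = 5)
  lat <- group_latency(ds, pos, spec)
  expect_s3_class(lat, "latency_result")
  expect_false(is.na(lat$latency))
  expect_equal(lat$latency, lat$pvalues$center[min(which(lat$pvalues$p < 0.05))])
  # alpha = 1: every window crosses, so latency is the first center
  lat1 <- group_latency(ds, pos, spec, alpha = 1)
  expect_equal(lat1$latency, 25)
  expect_error(group_latency(ds, pos[1:3], spec), "too small")
  expect_equal(nrow(tidy(lat)), length(spec$centers))
})
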