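test_that("expression tables have the documented block structure", {
  # deterministic counts: expression effect e adds e spikes
  ds <- deterministic_dataset(10, function(img, t) {
    expr <- (img - 1) %% 3 + 1
    2 + expr
  })
  tab <- expression_table(ds, "n1", 255, window_spec(width = 500, centers = 255))
  expect_equal(dim(tab), c(10, 3))
  expect_true(all(tab[, "open_mouth"] < tab[, "neutral"]))
  expect_true(all(tab[, "neutral"] < tab[, "pout_lips"]))

  # identical responses to everything -> fully tied -> p = 1
  flat <- deterministic_dataset(10, function(img, t) 3)
  tabf <- expression_table(flat, "n1", 255, window_spec(width = 500, centers = 255))
  ht <- friedman_statistic(tabf)
  expect_equal(ht$p.value, 1)

  # identity_repetition mode has 3x the blocks with raw counts
  tab2 <- expression_table(ds, "n1", 255, window_spec(width = 500, centers = 255),
                           block_mode = "identity_repetition")
  expect_equal(dim(tab2), c(30, 3))

  expect_error(
    expression_table(deterministic_dataset(4, function(i, t) 1), "n1", 255,
                     window_spec(width = 500, centers = 255)),
    "excluded"
  )
})

test_that("expression-selective neurons are detected in the early window only", {
  cfg <- population_config(
    n_positive = 12, n_negative = 0, n_nonselective = 0,
    positive = rate_profile_params(
      baseline = 10, early_onset = 30, early_offset = 80,
      early_amp = c(open_mouth = 30, neutral = 5, pout_lips = 5)
    ),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 51)
  spec <- window_spec(width = 50, centers = c(-100, 55))
  tc <- expression_pvalue_timecourse(ds, spec)
  early <- tc$p[tc$center == 55]
  pre <- tc$p[tc$center == -100]
  expect_gt(mean(early < 0.05), 0.8)   # high power at the configured amplitude
  expect_lt(mean(pre < 0.05), 0.35)    # prestimulus windows are null
})

test_that("significant-neuron counts are calibrated on null data", {
  nullds <- simulate_population(null_population_config(80), seed = 52)
  spec <- window_spec(width = 50, centers = seq(-75, 475, by = 50))
  sc <- significant_neuron_counts(nullds, spec, alpha = c(0.05, 0.01))
  m05 <- mean(sc$count[sc$alpha == 0.05]) / 80
  expect_lt(abs(m05 - 0.05), 0.03)
  # monotone in alpha on every window
  wide <- tidyr::pivot_wider(sc, names_from = "alpha", values_from = "count")
  expect_true(all(wide[["0.01"]] <= wide[["0.05"]]))
  sc0 <- significant_neuron_counts(nullds, spec, alpha = 0)
  expect_true(all(sc0$count == 0))
})

test_that("shuffle percentiles calibrate the count null", {
  nullds <- simulate_population(null_population_config(60), seed = 53)
  spec <- window_spec(width = 50, centers = c(30, 130, 230))
  np <- shuffle_null_percentiles(nullds, spec, n_shuffles = 150, seed = 54)
  # the unshuffled null counts should respect the shuffled thresholds
  sc <- significant_neuron_counts(nullds, spec, alpha = 0.05)
  expect_true(all(sc$count <= np$p99 + 2))
  # binomial expectation: count distribution centered near 60 * 0.05
  expect_gt(np$p95, 3)
  expect_lt(np$p95, 12)

  # a single shuffle: percentiles equal that shuffle's counts
  np1 <- shuffle_null_percentiles(nullds, spec, n_shuffles = 1, seed = 55)
  expect_equal(np1$per_center$p95, np1$per_center$p99)
  expect_equal(np1$p95, mean(np1$null_counts[1, ]))
})

test_that("carried signal lifts counts above the shuffle threshold", {
  ds <- simulate_population(population_config(), seed = 56)
  spec <- window_spec(width = 50, centers = c(55))
  sc <- significant_neuron_counts(ds, spec, alpha = 0.05)
  np <- shuffle_null_percentiles(ds, spec, n_shuffles = 150, seed = 57)
  expect_gt(sc$count[1], np$p95)
})
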