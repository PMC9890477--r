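test_that("max-normalization matches the worked example and edge cases", {
  expect_equal(as.numeric(normalize_responses(matrix(0:4, ncol = 1))),
               c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(as.numeric(normalize_responses(matrix(0, 3, 1))), c(0, 0, 0))
  expect_equal(as.numeric(normalize_responses(matrix(5, 3, 1))), c(1, 1, 1))
  # idempotence: renormalizing a normalized matrix is the identity
  m <- matrix(c(0, 1, 2, 3, 0, 2, 4, 8), ncol = 2)
  n1 <- normalize_responses(m)
  expect_equal(normalize_responses(n1), n1)
  # per-neuron scale is removed entirely
  expect_equal(normalize_responses(sweep(m, 2, c(3, 0.5), "*")), n1)
  # train-fold reference applies to held-out data
  expect_equal(as.numeric(normalize_responses(matrix(0:4, ncol = 1),
                                              matrix(8, 1, 1))), 2)
})

test_that("the one-vs-rest ensemble separates a linearly separable toy set", {
  # neuron 1 fires only for open-mouth, neuron 2 only for neutral
  x <- rbind(
    matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE)
  )
  labels <- rep(c("open_mouth", "neutral", "pout_lips"), each = 3)
  # hard-margin regime so the separating geometry is exact
  ens <- train_ovr(x, labels, cost = 100)
  expect_equal(dim(ens$w), c(3L, 2L))
  f <- decision_values(ens, x)
  expect_true(all(f[1:3, 1] > 0))       # open-mouth side of its hyperplane
  expect_true(all(f[4:9, 1] < 0))
  expect_equal(as.character(classify(ens, x)), labels)
  # the soft-margin default still classifies the toy set perfectly by argmax
  ens_soft <- train_ovr(x, labels)
  expect_equal(as.character(classify(ens_soft, x)), labels)

  # duplicating the training set leaves the hard-margin hyperplane unchanged
  ens2 <- train_ovr(rbind(x, x), rep(labels, 2), cost = 100)
  expect_equal(ens2$w, ens$w, tolerance = 1e-6)
  expect_equal(ens2$b, ens$b, tolerance = 1e-6)

  # degenerate geometry: identical samples with mixed labels still trains,
  # and decision values tie across classes
  xd <- matrix(1, 9, 2)
  ensd <- train_ovr(xd, labels)
  fd <- decision_values(ensd, xd)
  expect_lt(max(fd) - min(fd), 1e-8)
  expect_error(train_ovr(x[1:6, ], labels[1:6]), "absent")
})

test_that("classification follows argmax with the documented tie-break", {
  ens <- structure(
    list(w = diag(3), b = c(0, 0, 0), cost = 0.125),
    class = "classifier_ensemble"
  )
  rownames(ens$w) <- c("open_mouth", "neutral", "pout_lips")
  expect_equal(as.character(classify(ens, matrix(c(2, -1, -1), 1))), "open_mouth")
  expect_equal(as.character(classify(ens, matrix(c(0.5, 0.5, -1), 1))), "open_mouth")
  expect_equal(as.character(classify(ens, matrix(c(-1, 0.5, 0.5), 1))), "neutral")
  expect_error(classify(ens, matrix(1, 1, 2)), "dimension")
})

test_that("decode_window splits 72/18 and is seed-deterministic", {
  cfg <- population_config(n_positive = 4, n_negative = 4, n_nonselective = 8)
  ds <- simulate_population(cfg, seed = 61)
  dw <- decode_window(ds, 55, window_spec(), n_reps = 12, seed = 3)
  expect_equal(nrow(dw), 12)
  # 18 test vectors: overall accuracy moves in 1/18 steps; 6 per class
  expect_true(all(abs(dw$accuracy * 18 - round(dw$accuracy * 18)) < 1e-9))
  for (col in c("acc_open_mouth", "acc_neutral", "acc_pout_lips")) {
    expect_true(all(abs(dw[[col]] * 6 - round(dw[[col]] * 6)) < 1e-9))
  }
  dw2 <- decode_window(ds, 55, window_spec(), n_reps = 12, seed = 3)
  expect_identical(dw, dw2)
  # neuron with a missing trial is excluded with a message
  drop1 <- ds[-5, ]
  expect_message(
    dw3 <- decode_window(drop1, 55, window_spec(), n_reps = 2, seed = 1),
    "Excluding 1 neuron"
  )
  expect_equal(length(attr(dw3, "neurons")), 15)
})

test_that("label-shuffled decoding sits at chance", {
  cfg <- population_config(n_positive = 8, n_negative = 8, n_nonselective = 14)
  ds <- simulate_population(cfg, seed = 62)
  ch <- decode_window(ds, 55, window_spec(), n_reps = 80, seed = 4,
                      shuffle_labels = TRUE)
  se <- sd(ch$accuracy) / sqrt(nrow(ch))
  expect_lt(abs(mean(ch$accuracy) - 1 / 3), 3 * se + 0.02)
})

test_that("early open-mouth signal yields the expected per-class profile", {
  ds <- simulate_population(population_config(), seed = 63)
  dw <- decode_window(ds, 60, window_spec(), n_reps = 40, seed = 5)
  m <- colMeans(dw[, c("acc_open_mouth", "acc_neutral", "acc_pout_lips")])
  expect_gt(m[["acc_open_mouth"]], m[["acc_neutral"]])
  expect_gt(m[["acc_open_mouth"]], m[["acc_pout_lips"]])
  pa <- pairwise_auc_profile(dw)
  expect_true(all(pa$auc >= 0.5 & pa$auc <= 1))
  expect_gt(pa$auc[pa$pair == "open_mouth_vs_neutral"],
            pa$auc[pa$pair == "neutral_vs_pout_lips"])
})

test_that("decoding accuracy grows with the early-component amplitude", {
  accs <- vapply(c(4, 25), function(amp) {
    cfg <- population_config(
      n_positive = 10, n_negative = 0, n_nonselective = 10,
      positive = rate_profile_params(
        baseline = 10, early_onset = 30, early_offset = 80,
        early_amp = c(open_mouth = amp, neutral = 0, pout_lips = 0)
      ),
      identity_gain_sdlog = 0, amp_jitter = c(1, 1)
    )
    ds <- simulate_population(cfg, seed = 64)
    mean(decode_window(ds, 55, window_spec(), n_reps = 30,
                       seed = 6)$acc_open_mouth)
  }, numeric(1))
  expect_gt(accs[2], accs[1])
})

test_that("neuron-count equalization subsamples without replacement", {
  cfg <- population_config(n_positive = 3, n_negative = 3, n_nonselective = 6)
  ds <- simulate_population(cfg, seed = 65)
  dw <- decode_window(ds, 55, window_spec(), n_reps = 6, seed = 7,
                      n_neurons = 5, keep_weights = TRUE)
  w <- attr(dw, "weights")
  per_rep <- apply(!is.na(w[, , 1]), 1, sum)
  expect_true(all(per_rep == 5))
  expect_error(decode_window(ds, 55, window_spec(), n_reps = 2, n_neurons = 13),
               "exceeds")
})

test_that("exact k-fold partitions cover every trial once per cycle", {
  cfg <- population_config(n_positive = 3, n_negative = 0, n_nonselective = 5)
  ds <- simulate_population(cfg, seed = 66)
  dw <- decode_window(ds, 150, window_spec(), n_reps = 10, seed = 8, cv = "kfold")
  expect_equal(nrow(dw), 10)
  expect_true(all(dw$accuracy >= 0 & dw$accuracy <= 1))
})

test_that("degenerate rep counts give degenerate AUC values", {
  reps <- tibble::tibble(
    rep = 1L, accuracy = 0.5, acc_open_mouth = 0.6,
    acc_neutral = 0.4, acc_pout_lips = 0.4
  )
  pa <- pairwise_auc_profile(reps)
  expect_true(all(pa$auc %in% c(0.5, 1)))
})
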