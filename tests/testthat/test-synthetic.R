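test_that("rate profiles combine baseline, components, clipping and gain", {
  flat <- rate_profile_params(baseline = 10)
  expect_equal(rate_profile(flat, "neutral", c(-400, 0, 55, 300)), rep(10, 4))

  sup <- rate_profile_params(baseline = 5, early_sign = -1,
                             early_amp = c(open_mouth = 8))
  expect_equal(rate_profile(sup, "open_mouth", 55), 0)  # clipped at zero
  expect_equal(rate_profile(sup, "neutral", 55), 5)

  exc <- rate_profile_params(baseline = 10, early_amp = c(open_mouth = 20))
  expect_equal(rate_profile(exc, "open_mouth", 55), 30)
  expect_equal(rate_profile(exc, "open_mouth", 55, identity_gain = 1.2), 36)

  ramped <- rate_profile_params(baseline = 0, late_onset = 100,
                                late_amp = c(neutral = 10), late_ramp = 100)
  expect_equal(rate_profile(ramped, "neutral", c(100, 150, 200, 300)),
               c(0, 5, 10, 10))
  expect_error(rate_profile(exc, "open_mouth", 1000), "1000")
})

test_that("simulation is seed-deterministic and trial counts are honored", {
  cfg <- population_config(n_positive = 2, n_negative = 2, n_nonselective = 2)
  a <- simulate_population(cfg, seed = 9)
  b <- simulate_population(cfg, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_population(cfg, seed = 10)))
  tc <- trial_counts(a)
  expect_true(all(tc$n_trials == 10))
  expect_equal(nrow(tc), 6 * 9)
})

test_that("simulated spike counts match the rate profile integral", {
  cfg <- population_config(
    n_positive = 0, n_negative = 0, n_nonselective = 1, n_trials = 25,
    nonselective = rate_profile_params(baseline = 20),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 6)
  # integral of 20 sp/s over [0, 500): expect 10 spikes/trial
  post <- vapply(ds$spike_times, function(s) sum(s >= 0 & s < 500), numeric(1))
  n <- length(post)
  expect_lt(abs(mean(post) - 10), 3.5 * sqrt(10 / n))
})

test_that("the early excitatory component raises open-mouth rates as configured", {
  cfg <- population_config(
    n_positive = 1, n_negative = 0, n_nonselective = 0, n_trials = 120,
    positive = rate_profile_params(
      baseline = 10, early_onset = 30, early_offset = 80,
      early_amp = c(open_mouth = 20, neutral = 0, pout_lips = 0)
    ),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 7)
  rate_in <- function(expr) {
    sel <- (ds$image_id - 1) %% 3 + 1 == match(expr, c("open_mouth", "neutral", "pout_lips"))
    mean(vapply(ds$spike_times[sel], function(s) sum(s >= 30 & s < 80), numeric(1))) / 0.05
  }
  diff_obs <- rate_in("open_mouth") - rate_in("neutral")
  # SE of each mean rate: sqrt(rate/(0.05 * n_trials)); 360 trials/expression
  se <- sqrt(30 / (0.05 * 360)) + sqrt(10 / (0.05 * 360))
  expect_lt(abs(diff_obs - 20), 3.5 * se)
})

test_that("the empirical PSTH converges to the generating rate profile", {
  params <- rate_profile_params(
    baseline = 12, early_onset = 40, early_offset = 80,
    early_amp = c(open_mouth = 15), late_onset = 90,
    late_amp = c(open_mouth = 8), late_ramp = 0
  )
  cfg <- population_config(
    n_positive = 1, n_negative = 0, n_nonselective = 0, n_trials = 400,
    positive = params, identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 13)
  om <- ds[(ds$image_id - 1) %% 3 == 0, ]  # open-mouth trials (1200)
  segments <- list(c(-200, 0), c(40, 80), c(90, 500))
  for (seg in segments) {
    dur_s <- (seg[2] - seg[1]) / 1000
    obs <- mean(vapply(om$spike_times,
                       function(s) sum(s >= seg[1] & s < seg[2]), numeric(1)))
    expected <- sum(rate_profile(params, "open_mouth",
                                 seq(seg[1], seg[2] - 1))) / 1000
    se <- sqrt(expected / nrow(om))
    expect_lt(abs(obs - expected), 3.5 * se)
  }
})

test_that("tuning surfaces realize the stated reference frames", {
  ret <- simulate_tuning_surface("retina_based", preferred = 1.0, noise_sd = 0)
  expect_equal(nrow(ret), 35)
  # retina frame: the image-based argmax scales with size
  argmax <- vapply(split(ret, ret$size), function(g) g$sf[which.max(g$rate)],
                   numeric(1))
  expect_true(all(diff(argmax) > 0))

  img <- simulate_tuning_surface("image_based", preferred = 5.7, noise_sd = 0)
  argmax_img <- vapply(split(img, img$size), function(g) g$sf[which.max(g$rate)],
                       numeric(1))
  expect_true(all(argmax_img == 5.7))

  expect_warning(simulate_tuning_surface("image_based", preferred = 30),
                 "outside the representable span")
  noisy1 <- simulate_tuning_surface("image_based", 5.7, noise_sd = 2, seed = 3)
  noisy2 <- simulate_tuning_surface("image_based", 5.7, noise_sd = 2, seed = 3)
  expect_identical(noisy1, noisy2)
})
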