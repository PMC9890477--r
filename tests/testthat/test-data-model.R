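test_that("spike dataset files parse, validate and roundtrip losslessly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "neuron_id\tarea\ttrial_id\timage_id\tspike_times",
    "n1\tamygdala\t1\t1\t12.5;40"
  ), path)
  ds <- read_spike_dataset(path)
  expect_equal(ds$spike_times[[1]], c(12.5, 40))

  # roundtrip on a simulated population, field by field
  sim <- simulate_population(
    population_config(n_positive = 2, n_negative = 2, n_nonselective = 2),
    seed = 4
  )
  out <- withr::local_tempfile(fileext = ".tsv")
  write_spike_dataset(sim, out)
  back <- read_spike_dataset(out)
  expect_equal(back$neuron_id, sim$neuron_id)
  expect_equal(back$trial_id, as.integer(sim$trial_id))
  expect_equal(back$image_id, as.integer(sim$image_id))
  expect_equal(back$spike_times, sim$spike_times, tolerance = 1e-12)

  # empty trials survive the roundtrip
  ds2 <- trial_row("n1", 1, 1, numeric(0))
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_spike_dataset(ds2, out2)
  expect_identical(read_spike_dataset(out2)$spike_times[[1]], numeric(0))
})

test_that("invalid datasets are rejected on read and write", {
  expect_error(validate_spike_dataset(trial_row("n1", 1, 1, 1500)), "out of range")
  expect_error(validate_spike_dataset(trial_row("n1", 1, 12, 10)), "image_id")
  expect_error(
    validate_spike_dataset(dplyr::bind_rows(trial_row("n1", 1, 1, 10),
                                            trial_row("n1", 1, 2, 20))),
    "trial_id"
  )
  out <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_spike_dataset(trial_row("n1", 1, 1, -900), out), "out of range")
  expect_error(read_spike_dataset("/nonexistent/file.tsv"), "No such file")
})

test_that("window counting honors the half-open convention", {
  ds <- trial_row("n1", 1, 1, c(30, 55, 79.9))
  spec <- window_spec()
  expect_equal(count_spikes(ds, 55, spec)$count, 3)

  # a spike exactly at the upper edge is excluded
  ds_edge <- trial_row("n1", 1, 1, 80)
  expect_equal(count_spikes(ds_edge, 55, spec)$count, 0)
  expect_equal(count_spikes(ds_edge, 105, spec)$count, 1)

  # adjacent non-overlapping windows partition the union
  set.seed(8)
  spikes <- sort(runif(200, -100, 200))
  dsr <- trial_row("n1", 1, 1, spikes)
  spec50 <- window_spec(width = 50, centers = c(-75, -25, 25, 75, 125, 175))
  parts <- vapply(spec50$centers, function(ctr) count_spikes(dsr, ctr, spec50)$count,
                  numeric(1))
  expect_equal(sum(parts), sum(spikes >= -100 & spikes < 200))

  # counting is invariant to input spike order
  shuffled <- trial_row("n1", 1, 1, sample(spikes))
  expect_equal(count_spikes(shuffled, 25, spec50)$count,
               count_spikes(dsr, 25, spec50)$count)
})

test_that("counts convert to firing rates by the window width", {
  ds <- trial_row("n1", 1, 1, c(30, 55, 79.9))
  fr <- firing_rate(count_spikes(ds, 55, window_spec()))
  expect_equal(fr$rate, 60)
  expect_equal(firing_rate(tibble::tibble(count = 0), width = 50)$rate, 0)
  expect_equal(firing_rate(tibble::tibble(count = 10), width = 500)$rate, 20)
})

test_that("window counts of a homogeneous Poisson process match the rate", {
  # 20 sp/s over a 50-ms window: expected count 1.0
  cfg <- population_config(
    n_positive = 0, n_negative = 0, n_nonselective = 1, n_trials = 60,
    nonselective = rate_profile_params(baseline = 20),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
  ds <- simulate_population(cfg, seed = 5)
  counts <- count_spikes(ds, 255, window_spec())$count
  n <- length(counts)  # 540 trials
  se <- sqrt(1 / n)    # Poisson variance = mean = 1
  expect_lt(abs(mean(counts) - 1), 3.5 * se)
})

test_that("the stimulus catalog and SF grid have the full crossings", {
  cat <- stimulus_catalog()
  expect_equal(nrow(cat), 9)
  expect_equal(as.character(sort(unique(cat$identity))), c("M1", "M2", "M3"))
  expect_equal(nrow(dplyr::distinct(cat, identity, expression)), 9)
  expect_equal(nrow(sf_size_grid()), 35)
})
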