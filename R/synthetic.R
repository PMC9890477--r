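#' Piecewise-constant firing-rate profile parameters
#'
#' Parameterizes the rate profile of a simulated neuron as a baseline plus an
#' early transient component (excitatory or suppressive, expression
#' dependent) and a later sustained component, all in spikes/s.  The realized
#' rate is clipped at zero after summing components and then scaled by a
#' per-identity gain:
#' `rate(t) = max(0, baseline + sign * early_amp[expr] * 1[early] +
#' late_amp[expr] * 1[late]) * identity_gain`.
#'
#' @param baseline Baseline rate, sp/s.
#' @param early_onset,early_offset Early-component interval `[onset, offset)` in ms.
#' @param early_sign `+1` (excitation) or `-1` (suppression).
#' @param early_amp Named vector of early amplitudes (sp/s) per expression.
#' @param late_onset Late-component onset, ms.
#' @param late_duration Late-component duration, ms.
#' @param late_amp Named vector of late amplitudes (sp/s) per expression.
#' @param late_ramp Linear rise time of the late component, ms (0 for a
#'   step): the amplitude grows linearly from `late_onset` to
#'   `late_onset + late_ramp`, emulating gradually building sustained input.
#' @return A `rate_profile_params` list.
#' @export
rate_profile_params <- function(baseline = 10,
                                early_onset = 40, early_offset = 80,
                                early_sign = 1,
                                early_amp = c(open_mouth = 0, neutral = 0, pout_lips = 0),
                                late_onset = 90, late_duration = 410,
                                late_amp = c(open_mouth = 0, neutral = 0, pout_lips = 0),
                                late_ramp = 0) {
  if (baseline < 0) abort("`baseline` must be >= 0.")
  if (early_onset >= early_offset) abort("`early_onset` must be < `early_offset`.")
  if (!early_sign %in% c(-1, 1)) abort("`early_sign` must be +1 or -1.")
  if (late_ramp < 0) abort("`late_ramp` must be >= 0.")
  early_amp <- fill_expression_amps(early_amp)
  late_amp <- fill_expression_amps(late_amp)
  structure(
    list(baseline = baseline,
         early_onset = early_onset, early_offset = early_offset,
         early_sign = early_sign, early_amp = early_amp,
         late_onset = late_onset, late_duration = late_duration,
         late_amp = late_amp, late_ramp = late_ramp),
    class = "rate_profile_params"
  )
}

fill_expression_amps <- function(amp) {
  out <- c(open_mouth = 0, neutral = 0, pout_lips = 0)
  if (is.null(names(amp)) && length(amp) == 3) {
    names(amp) <- EXPRESSIONS
  }
  bad <- setdiff(names(amp), EXPRESSIONS)
  if (length(bad) > 0) abort(paste0("Unknown expression: ", bad[1]))
  out[names(amp)] <- amp
  out
}

#' Evaluate a rate profile
#'
#' @param params A [rate_profile_params()].
#' @param expression One of `"open_mouth"`, `"neutral"`, `"pout_lips"`.
#' @param t Time(s) in ms relative to stimulus onset, in `[-500, 1000)`.
#' @param identity_gain Multiplicative gain for the stimulus identity.
#' @return Rate(s) in spikes/s, deterministic in all arguments.
#' @examples
#' p <- rate_profile_params(baseline = 10, early_amp = c(open_mouth = 20))
#' rate_profile(p, "open_mouth", t = 55)  # 30 sp/s
#' @export
rate_profile <- function(params, expression, t, identity_gain = 1) {
  expression <- match.arg(expression, EXPRESSIONS)
  if (any(t < EPOCH_MS[1] | t >= EPOCH_MS[2])) {
    abort("`t` must lie in [-500, 1000) ms.")
  }
  early <- t >= params$early_onset & t < params$early_offset
  late <- t >= params$late_onset & t < params$late_onset + params$late_duration
  ramp <- if (params$late_ramp > 0) {
    pmin(1, (t - params$late_onset) / params$late_ramp)
  } else 1
  r <- params$baseline +
    params$early_sign * params$early_amp[[expression]] * early +
    params$late_amp[[expression]] * late * ramp
  pmax(0, r) * identity_gain
}

#' Simulated population configuration
#'
#' Group sizes, trial counts and per-group rate profiles for
#' [simulate_population()].  The default preset emulates the response
#' structure the downstream analyses assume: an early-excited group
#' preferring open-mouth faces (onset 40 ms), an early-suppressed group
#' (suppression onset 50 ms, strongest for open-mouth) with a late
#' neutral-preferring rebound (onset 90 ms), and a nonselective group with a
#' flat rate.  Amplitudes are stated assumptions, not measured values; see
#' the methods vignette for the power reasoning behind them.
#'
#' @param n_positive,n_negative,n_nonselective Group sizes (default 20/20/60).
#' @param n_trials Trials per image per neuron (default 10).
#' @param positive,negative,nonselective Per-group [rate_profile_params()].
#' @param identity_gain_sdlog Log-normal sdlog of the per-neuron per-identity
#'   gains (identities modulate rate without carrying expression signal).
#' @param amp_jitter Two-element range of a per-neuron multiplicative factor
#'   applied to all component amplitudes (response-strength heterogeneity).
#' @return A `population_config` list.
#' @export
population_config <- function(n_positive = 20, n_negative = 20, n_nonselective = 60,
                              n_trials = 10,
                              positive = rate_profile_params(
                                baseline = 10,
                                early_onset = 40, early_offset = 80, early_sign = 1,
                                early_amp = c(open_mouth = 15, neutral = 6, pout_lips = 6),
                                late_onset = 90, late_duration = 410,
                                late_amp = c(open_mouth = 6, neutral = 6, pout_lips = 6),
                                late_ramp = 100
                              ),
                              negative = rate_profile_params(
                                baseline = 15,
                                early_onset = 50, early_offset = 80, early_sign = -1,
                                early_amp = c(open_mouth = 12, neutral = 0, pout_lips = 3),
                                late_onset = 90, late_duration = 410,
                                late_amp = c(open_mouth = 8, neutral = 22, pout_lips = 6),
                                late_ramp = 100
                              ),
                              nonselective = rate_profile_params(baseline = 10),
                              identity_gain_sdlog = 0.1,
                              amp_jitter = c(0.75, 1.25)) {
  sizes <- c(n_positive, n_negative, n_nonselective)
  if (any(sizes < 0)) abort("Group sizes must be >= 0.")
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  structure(
    list(n_positive = n_positive, n_negative = n_negative,
         n_nonselective = n_nonselective, n_trials = n_trials,
         positive = positive, negative = negative, nonselective = nonselective,
         identity_gain_sdlog = identity_gain_sdlog, amp_jitter = amp_jitter),
    class = "population_config"
  )
}

#' A fully null population configuration
#'
#' Flat-rate neurons with no expression signal, no identity gain spread and
#' no amplitude heterogeneity; used for type-I calibration.
#'
#' @param n_neurons Number of neurons.
#' @param n_trials Trials per image.
#' @param baseline Flat rate in sp/s.
#' @return A `population_config`.
#' @export
null_population_config <- function(n_neurons = 104, n_trials = 10, baseline = 10) {
  population_config(
    n_positive = 0, n_negative = 0, n_nonselective = n_neurons,
    n_trials = n_trials,
    nonselective = rate_profile_params(baseline = baseline),
    identity_gain_sdlog = 0, amp_jitter = c(1, 1)
  )
}

# scale the component amplitudes of a rate_profile_params by a factor
scale_amps <- function(params, f) {
  params$early_amp <- params$early_amp * f
  params$late_amp <- params$late_amp * f
  params
}

#' Simulate a spike dataset
#'
#' Draws every trial from an inhomogeneous Poisson process: the rate profile
#' is piecewise constant at 1-ms resolution, each 1-ms bin receives a
#' Poisson spike count, and spikes are placed uniformly within their bin.
#' Trials are independent; presentation order interleaves the 9 images in
#' shuffled blocks.  Identical seeds give identical datasets.
#'
#' @param config A [population_config()].
#' @param catalog The stimulus catalog (fixed 9-image set).
#' @param seed Integer seed.
#' @param area Area tag for all neurons.
#' @return A validated `spike_dataset` tibble with an extra `group` column
#'   (`"positive"`, `"negative"` or `"nonselective"`) recording the
#'   generator's ground truth.
#' @export
simulate_population <- function(config, catalog = stimulus_catalog(), seed = 1,
                                area = "amygdala") {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(seed, {
    groups <- rep(c("positive", "negative", "nonselective"),
                  c(config$n_positive, config$n_negative, config$n_nonselective))
    n_neurons <- length(groups)
    if (n_neurons == 0) abort("Empty population.")
    n_trials <- config$n_trials
    bins <- seq(EPOCH_MS[1], EPOCH_MS[2] - 1)  # 1-ms bin left edges
    nb <- length(bins)
    rows <- vector("list", n_neurons)
    for (i in seq_len(n_neurons)) {
      params <- scale_amps(config[[groups[i]]],
                           runif(1, config$amp_jitter[1], config$amp_jitter[2]))
      gains <- exp(rnorm(3, 0, config$identity_gain_sdlog))
      names(gains) <- IDENTITIES
      # presentation schedule: shuffled block of the 9 images per repetition
      schedule <- unlist(lapply(seq_len(n_trials), function(r) sample(1:9)))
      trial_of_slot <- seq_along(schedule)
      spike_lists <- vector("list", length(schedule))
      for (img in 1:9) {
        lam <- rate_profile(params, as.character(expression_of(img)), bins,
                            gains[[identity_of(img)]]) / 1000
        slots <- which(schedule == img)
        counts <- matrix(rpois(nb * length(slots), lam), nrow = nb)
        for (j in seq_along(slots)) {
          k <- counts[, j]
          occ <- which(k > 0)
          if (length(occ) == 0) {
            spike_lists[[slots[j]]] <- numeric(0)
          } else {
            spike_lists[[slots[j]]] <-
              sort(rep(bins[occ], k[occ]) + runif(sum(k[occ])))
          }
        }
      }
      rows[[i]] <- tibble::tibble(
        neuron_id = sprintf("n%03d", i),
        area = area,
        group = groups[i],
        trial_id = trial_of_slot,
        image_id = schedule,
        spike_times = spike_lists
      )
    }
    out <- dplyr::bind_rows(rows)
    validate_spike_dataset(out)
  })
}

#' Simulate a spatial-frequency by size tuning surface
#'
#' Mean firing rate on the 7 center-SF x 5 size grid for a neuron tuned
#' either in the retina-based frame (preferred SF in cycles/degree; the
#' effective SF of a grid cell is `sf / size`) or the image-based frame
#' (preferred SF in cycles/image; effective SF is `sf` itself).  Tuning is a
#' unit-height Gaussian in log2 SF with full width at half maximum
#' `bandwidth_octaves`, scaled by `peak_rate`, plus optional Gaussian noise
#' (truncated at zero rate).
#'
#' @param frame `"retina_based"` or `"image_based"`.
#' @param preferred Preferred SF: cycles/degree (retina-based) or
#'   cycles/image (image-based).
#' @param bandwidth_octaves Tuning FWHM in octaves (default 1.5).
#' @param peak_rate Peak rate, sp/s.
#' @param grid The SF x size grid (default [sf_size_grid()]).
#' @param noise_sd Gaussian noise sd in sp/s (default 0).
#' @param seed Seed (used only when `noise_sd > 0`).
#' @return A `tuning_surface` tibble with columns `sf`, `size`, `rate`.
#' @export
simulate_tuning_surface <- function(frame = c("retina_based", "image_based"),
                                    preferred, bandwidth_octaves = 1.5,
                                    peak_rate = 30, grid = sf_size_grid(),
                                    noise_sd = 0, seed = 1) {
  frame <- match.arg(frame)
  if (bandwidth_octaves <= 0) abort("`bandwidth_octaves` must be positive.")
  eff <- if (frame == "retina_based") grid$sf / grid$size else grid$sf
  span <- range(eff)
  if (preferred < span[1] || preferred > span[2]) {
    warn(sprintf(
      "Preferred SF %g is outside the representable span [%g, %g] for this frame.",
      preferred, span[1], span[2]
    ))
  }
  sigma <- bandwidth_octaves / (2 * sqrt(2 * log(2)))
  g <- exp(-(log2(eff) - log2(preferred))^2 / (2 * sigma^2))
  rate <- peak_rate * g
  if (noise_sd > 0) {
    rate <- withr::with_seed(seed, pmax(0, rate + rnorm(length(rate), 0, noise_sd)))
  }
  out <- tibble::tibble(sf = grid$sf, size = grid$size, rate = rate)
  class(out) <- union("tuning_surface", class(out))
  out
}
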