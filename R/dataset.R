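#' Validate a spike dataset
#'
#' A spike dataset is a tibble with one row per trial and columns
#' `neuron_id`, `area`, `trial_id`, `image_id` and `spike_times` (a
#' list-column of numeric vectors, in ms relative to stimulus onset).
#' Validation enforces the container invariants: spike times within
#' `[-500, 1000)` ms and strictly increasing within a trial (spike times are
#' sorted first, so input ordering is immaterial), known image ids, known
#' areas, and unique trial ids within a neuron.
#'
#' @param dataset A spike dataset tibble.
#' @return The validated dataset (spike times sorted), invisibly classed as
#'   `spike_dataset`.
#' @export
validate_spike_dataset <- function(dataset) {
  required <- c("neuron_id", "area", "trial_id", "image_id", "spike_times")
  missing <- setdiff(required, names(dataset))
  if (length(missing) > 0) {
    abort(paste0("Dataset is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!is.list(dataset$spike_times)) {
    abort("`spike_times` must be a list-column of numeric vectors.")
  }
  bad_area <- setdiff(unique(dataset$area), AREAS)
  if (length(bad_area) > 0) {
    abort(paste0("Unknown area: ", paste(bad_area, collapse = ", ")))
  }
  bad_img <- !dataset$image_id %in% 1:9
  if (any(bad_img)) {
    abort(sprintf("Unknown image_id in row %d: %s",
                  which(bad_img)[1], dataset$image_id[which(bad_img)[1]]))
  }
  dataset$spike_times <- lapply(dataset$spike_times, function(s) {
    s <- as.numeric(s)
    sort(s[!is.na(s)])
  })
  for (i in seq_len(nrow(dataset))) {
    s <- dataset$spike_times[[i]]
    if (length(s) > 0 && (min(s) < EPOCH_MS[1] || max(s) >= EPOCH_MS[2])) {
      abort(sprintf(
        "Spike time out of range [-500, 1000) ms in row %d (neuron %s, trial %s).",
        i, dataset$neuron_id[i], dataset$trial_id[i]
      ))
    }
    if (anyDuplicated(s)) {
      abort(sprintf(
        "Duplicated spike times in row %d (neuron %s, trial %s); times must be strictly increasing.",
        i, dataset$neuron_id[i], dataset$trial_id[i]
      ))
    }
  }
  dup <- dataset |>
    dplyr::count(.data$neuron_id, .data$trial_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicated trial_id %s within neuron %s.",
                  dup$trial_id[1], dup$neuron_id[1]))
  }
  class(dataset) <- union("spike_dataset", class(dataset))
  dataset
}

#' Trial counts per image for each neuron
#'
#' @param dataset A spike dataset.
#' @return A tibble `neuron_id`, `image_id`, `n_trials`.
#' @export
trial_counts <- function(dataset) {
  dataset |>
    dplyr::count(.data$neuron_id, .data$image_id, name = "n_trials") |>
    tibble::as_tibble()
}

#' Read a spike dataset from delimited text
#'
#' The on-disk dialect is UTF-8 tab-separated text with a header row and one
#' row per trial: `neuron_id`, `area`, `trial_id`, `image_id`,
#' `spike_times` (semicolon-separated spike times in ms; empty string for a
#' trial with no spikes).  A sidecar YAML file `<path>.meta.yaml`, when
#' present, records the stimulus catalog and is checked against the built-in
#' catalog.
#'
#' @param path Path to the dataset file.
#' @return A validated `spike_dataset` tibble.
#' @seealso [write_spike_dataset()]
#' @export
read_spike_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      neuron_id = readr::col_character(),
      area = readr::col_character(),
      trial_id = readr::col_integer(),
      image_id = readr::col_integer(),
      spike_times = readr::col_character()
    )
  )
  problems <- readr::problems(raw)
  if (nrow(problems) > 0) {
    abort(sprintf("Malformed dataset file %s at line %d: %s",
                  path, problems$row[1] + 1L, problems$expected[1]))
  }
  raw$spike_times <- lapply(raw$spike_times, function(s) {
    if (is.na(s) || s == "") return(numeric(0))
    out <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
    if (anyNA(out)) abort(paste0("Malformed spike time list: ", s))
    out
  })
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$images) && length(meta$images) != 9) {
      abort("Sidecar metadata must list exactly 9 face images.")
    }
  }
  validate_spike_dataset(raw)
}

#' Write a spike dataset to delimited text
#'
#' Writes the tab-separated dialect read by [read_spike_dataset()], plus a
#' sidecar YAML metadata file listing the stimulus catalog.  The dataset is
#' validated first; invalid datasets are refused.  Roundtrips are lossless
#' up to numeric formatting (times are written with full precision).
#'
#' @param dataset A spike dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_dataset <- function(dataset, path) {
  dataset <- validate_spike_dataset(dataset)
  out <- tibble::tibble(
    neuron_id = as.character(dataset$neuron_id),
    area = dataset$area,
    trial_id = as.integer(dataset$trial_id),
    image_id = as.integer(dataset$image_id),
    spike_times = vapply(
      dataset$spike_times,
      function(s) paste(format(s, digits = 15, trim = TRUE, scientific = FALSE),
                        collapse = ";"),
      character(1)
    )
  )
  out$spike_times[lengths(dataset$spike_times) == 0] <- ""
  readr::write_tsv(out, path)
  catalog <- stimulus_catalog()
  meta <- list(
    format = "amygdecode spike dataset v1",
    images = lapply(seq_len(nrow(catalog)), function(i) {
      list(image_id = catalog$image_id[i],
           identity = catalog$identity[i],
           expression = as.character(catalog$expression[i]))
    })
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
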