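# Independent brute-force oracles and small fixture builders.

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments over the realized mid-ranks (zero differences removed first).
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}

# Monte-Carlo within-block permutation null of the Friedman chi-square.
oracle_friedman_perm <- function(tab, stat_fn, n_perm = 4000) {
  obs <- stat_fn(tab)
  stats <- replicate(n_perm, {
    p <- t(apply(tab, 1, sample))
    stat_fn(p)
  })
  mean(stats >= obs - 1e-9)
}

# O(n*m) pairwise AUC enumeration.
oracle_auc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# Exact Spearman permutation p by looping over all n! pairings with cor().
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- gen_perms(n)
  ps <- apply(perms, 1, function(p) abs(cor(rx, ry[p])))
  mean(ps >= obs - 1e-9)
}

gen_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- gen_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# One trial row of a spike dataset.
trial_row <- function(neuron, trial, image, spikes, area = "amygdala") {
  tibble::tibble(
    neuron_id = neuron, area = area, trial_id = as.integer(trial),
    image_id = as.integer(image), spike_times = list(spikes)
  )
}

# A deterministic dataset: each neuron has `n_trials` trials per image with
# spike counts given by count_fn(image_id, repetition) placed in [0, 500).
deterministic_dataset <- function(n_trials, count_fn, neuron = "n1") {
  rows <- list()
  tid <- 0
  for (img in 1:9) for (t in seq_len(n_trials)) {
    tid <- tid + 1
    k <- count_fn(img, t)
    spikes <- if (k > 0) seq(10, 490, length.out = k) else numeric(0)
    rows[[tid]] <- trial_row(neuron, tid, img, spikes)
  }
  dplyr::bind_rows(rows)
}
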