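#' Two-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the conventions fixed throughout the
#' pipeline: zero differences are discarded (Wilcoxon's original treatment,
#' not Pratt's), tied absolute differences receive mid-ranks, and the
#' two-sided p-value is exact for n <= 25 effective pairs (the full null
#' distribution of the positive-rank sum is built by dynamic programming
#' over the realized mid-ranks, so ties are handled exactly) and a normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param a,b Paired numeric samples of equal length.
#' @return A list of class `amyg_htest` with elements `statistic` (positive
#'   rank sum V), `p.value`, `n` (pairs after zero removal) and `method`.
#' @examples
#' wilcoxon_signed_rank(1:6, 2:7)  # exact p = 0.03125
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 1) abort("Samples must be nonempty.")
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All differences are zero; p = 1.")
    return(new_amyg_htest(NA_real_, 1, 0, "Wilcoxon signed rank (degenerate)"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null of V over sign flips, via DP on doubled mid-ranks
    f <- signed_rank_null(r)
    w2 <- round(2 * v)
    cdf_lo <- sum(f[seq_len(w2 + 1)])
    cdf_hi <- sum(f[seq(w2 + 1, length(f))])
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    method <- "Wilcoxon signed rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "Wilcoxon signed rank (normal approximation)"
  }
  new_amyg_htest(v, p, n, method)
}

# exact distribution of 2*V (doubled ranks are integers even with mid-ranks);
# returns probability vector over 0..sum(2r)
signed_rank_null <- function(r) {
  r2 <- round(2 * r)
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (x in r2) {
    g <- f
    g[(x + 1):(total + 1)] <- g[(x + 1):(total + 1)] + f[1:(total + 1 - x)]
    f <- g
  }
  f / 2^length(r2)
}

new_amyg_htest <- function(statistic, p, n, method, extra = list()) {
  structure(
    c(list(statistic = statistic, p.value = p, n = n, method = method), extra),
    class = "amyg_htest"
  )
}

#' @export
print.amyg_htest <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %s, n = %d, p = %.4g\n",
              x$method, format(x$statistic, digits = 4), x$n, x$p.value))
  invisible(x)
}

#' @method tidy amyg_htest
#' @export
tidy.amyg_htest <- function(x, ...) {
  tibble::tibble(
    statistic = as.numeric(x$statistic),
    p.value = x$p.value,
    n = x$n,
    method = x$method
  )
}

#' Friedman test for a blocks-by-treatments table
#'
#' Rank-based test of treatment effects with repeated measures: values are
#' mid-ranked within each block and the chi-square statistic is computed
#' with the standard tie correction.  A block with all-equal values simply
#' contributes tied mid-ranks.  When every block is fully tied the statistic
#' is 0 and p = 1.
#'
#' @param table Numeric matrix, blocks in rows, treatments in columns
#'   (>= 2 blocks, >= 2 treatments; the expression analysis uses 3 columns,
#'   df = 2).
#' @return An `amyg_htest` list with `statistic` (chi-square), `df`,
#'   `p.value` and `n` (blocks).
#' @examples
#' friedman_statistic(matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE))
#' @export
friedman_statistic <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2) abort("Need >= 2 blocks.")
  if (k < 2) abort("Need >= 2 treatments.")
  r <- t(apply(table, 1, rank))
  rs <- colSums(r)
  chi_raw <- 12 / (n * k * (k + 1)) * sum((rs - n * (k + 1) / 2)^2)
  ties <- apply(table, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  cc <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (cc <= 0) {
    chi2 <- 0
  } else {
    chi2 <- chi_raw / cc
  }
  p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  new_amyg_htest(chi2, p, n, "Friedman rank sum (tie-corrected)",
                 extra = list(df = k - 1))
}

#' Spearman rank correlation
#'
#' Spearman's rs with mid-ranks for ties.  The two-sided p-value is by
#' exact permutation enumeration for n <= 9 and by the t approximation
#' otherwise.  Constant input gives rs = NA with a warning.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return An `amyg_htest` list with `statistic` (rs), `p.value` and `n`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need >= 3 paired values.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input; Spearman correlation undefined.")
    return(new_amyg_htest(NA_real_, NA_real_, n, "Spearman rank correlation (degenerate)"))
  }
  rx <- rank(x); ry <- rank(y)
  rs <- cor(rx, ry)
  if (n <= 9) {
    pm <- permutations_of(n)
    # rs is monotone in sum(rx * ry[perm]); compare |centered sums| over all
    # n! pairings of the observed (mid-)rank vectors
    mu <- mean(ry) * sum(rx)
    obs <- sum(rx * ry)
    ref <- matrix(ry[pm], nrow = nrow(pm)) %*% rx
    p <- mean(abs(ref - mu) >= abs(obs - mu) - 1e-9)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  new_amyg_htest(rs, p, n, method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = nrow(sub) * n, ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE],
      n,
      if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE]
    )
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Rank-based area under the ROC curve
#'
#' The probability that a random draw from `a` exceeds a random draw from
#' `b`, with ties counted half (the Mann-Whitney U statistic divided by
#' `n * m`).
#'
#' @param a,b Nonempty numeric samples.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(2, 3, 4), c(0, 1))  # 1: fully separated
#' @export
auc <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be nonempty.")
  r <- rank(c(a, b))
  n <- length(a); m <- length(b)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u / (n * m)
}

#' Reflect an AUC about 0.5
#'
#' Maps AUC values below 0.5 to their mirror image above 0.5, so the result
#' measures separation irrespective of direction.
#'
#' @param a AUC value(s) in `[0, 1]`.
#' @return `max(a, 1 - a)`, in `[0.5, 1]`.
#' @examples
#' reflect_auc(0.45)  # 0.55
#' @export
reflect_auc <- function(a) {
  if (any(a < 0 | a > 1)) abort("AUC must lie in [0, 1].")
  pmax(a, 1 - a)
}
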