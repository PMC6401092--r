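# Rank-based comparison statistics, implemented from first principles.
# (base R equivalents exist and are used as independent cross-checks in the
# test suite; these implementations expose exact small-n behaviour and the
# tie conventions the error-profile comparisons rely on.)

average_ranks <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with exact small-n p-value
#'
#' Computes rho as the Pearson correlation of average ranks (so ties are
#' handled by mid-ranks). The two-sided p-value is exact (full enumeration
#' of rank permutations) for n <= 8 and uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom above.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list with `rho`, `p.value`, `n`, `method`
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    stopf("spearman_cor needs two equal-length vectors with n >= 3")
  rx <- average_ranks(x); ry <- average_ranks(y)
  rho <- rank_pearson(rx, ry)
  if (is.na(rho)) stopf("correlation undefined: a vector is constant")
  if (n <= 8L) {
    perms <- permutations(n)
    rhos <- apply(perms, 1L, function(p) rank_pearson(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(1, p)
    method <- "t approximation"
  }
  list(rho = rho, p.value = p, n = n, method = method)
}

rank_pearson <- function(rx, ry) {
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# All permutations of 1..n as a matrix (n! rows); n is capped small.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- cbind(k, sub + (sub >= k))
    out[[k]] <- m
  }
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test
#'
#' Paired test on `a - b` (or a single vector of differences). Zero
#' differences are dropped; |differences| are ranked with average ranks and
#' the statistic V is the rank sum of the positive differences. The null
#' distribution is exact for n <= 25 (sign-flip convolution over doubled
#' mid-ranks, so tied |differences| are handled exactly); above that a
#' normal approximation with tie correction and continuity correction is
#' used. When every difference is zero the result is degenerate
#' (statistic 0, p-value 1, flagged).
#'
#' @param a,b numeric vectors; `b` may be omitted to pass differences in `a`
#' @param alternative `"two.sided"`, `"greater"` (a tends above b) or
#'   `"less"`
#' @return list with `statistic` (V), `p.value`, `n_used` (non-zero
#'   differences), `method`, `degenerate`
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(b)) a else {
    if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
    a - b
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- average_ranks(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of V by convolution over sign flips; mid-ranks
    # are multiples of 1/2, so doubling makes every rank an integer
    r2 <- as.integer(round(2 * r))
    V2 <- as.integer(round(2 * V))
    maxV <- sum(r2)
    f <- numeric(maxV + 1L); f[1L] <- 1
    for (k in r2) {
      g <- f
      g[(k + 1L):(maxV + 1L)] <- g[(k + 1L):(maxV + 1L)] + f[1L:(maxV - k + 1L)]
      f <- g
    }
    f <- f / 2^n
    p_ge <- sum(f[(V2 + 1L):(maxV + 1L)])
    p_le <- sum(f[1L:(V2 + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_ge <- (V - mu - cc) / sqrt(sigma2)
    z_le <- (V - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE),
                                           pnorm(z_le))),
                greater = pnorm(z_ge, lower.tail = FALSE),
                less = pnorm(z_le))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n_used = n, method = method,
       degenerate = FALSE)
}
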