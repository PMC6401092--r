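# Independent oracles used to validate the package implementations.
# These are deliberately naive: exhaustive dynamic programming, full
# enumeration of sign flips / permutations. They share only documented
# conventions (scores, tie-break priority) with the implementations.

# Exhaustive (unbanded) global Needleman-Wunsch with the same scoring and
# tie-break priority (diagonal, then deletion, then insertion) as
# anchor_align, written as a plain full-matrix DP.
oracle_nw <- function(insert, reference, match = 1, mismatch = -1,
                      gap = -2) {
  x <- strsplit(insert, "")[[1]]
  y <- strsplit(reference, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * (0:m)
  S[, 1] <- gap * (0:n)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(x[i] == y[j], match, mismatch),
                           S[i, j + 1] + gap,
                           S[i + 1, j] + gap)
  }
  calls <- character(m); ins <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    sc <- S[i + 1, j + 1]
    if (i > 0 && j > 0 &&
        sc == S[i, j] + ifelse(x[i] == y[j], match, mismatch)) {
      calls[j] <- x[i]; i <- i - 1; j <- j - 1
    } else if (j > 0 && sc == S[i + 1, j] + gap) {
      calls[j] <- "-"; j <- j - 1
    } else {
      ins[[length(ins) + 1]] <- c(j, x[i]); i <- i - 1
    }
  }
  list(score = S[n + 1, m + 1], calls = calls)
}

# Exact Wilcoxon signed-rank p-value by full enumeration of the 2^n sign
# assignments of the observed |differences|.
oracle_wilcoxon <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  p_ge <- mean(Vs >= V - 1e-9)
  p_le <- mean(Vs <= V + 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}

# Spearman rho by the textbook formula on mid-ranks, and an exact two-sided
# permutation p-value for tiny n.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  perms <- gtools_permutations(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  list(rho = rho, p.value = mean(abs(rhos) >= abs(rho) - 1e-12))
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Enumerate the barcoding doubling tree by explicit recursion: returns the
# synthesis-depth of every product strand after `cycles` cycles at
# efficiency 1 (founder synthesised in cycle 1).
oracle_doubling_tree_depths <- function(cycles) {
  depths <- c(1L)  # founder copy, made in cycle 1
  for (cy in seq_len(cycles)[-1]) depths <- c(depths, depths + 1L)
  depths
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
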