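#' @import data.table
#' @importFrom stats rbinom rbeta runif rmultinom ppois pt pnorm cor setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")
DEL_CHAR <- "-"
CALL_LEVELS <- c(DNA_BASES, DEL_CHAR)  # integer codes 1..5, 5 = deletion

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequences
#'
#' Draws `n` independent sequences of length `len`, uniform over A/C/G/T.
#'
#' @param n number of sequences
#' @param len sequence length
#' @return character vector of length `n`
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Split fixed-width strings into a character matrix (one row per string).
seq_char_matrix <- function(x, width) {
  n <- length(x)
  if (n == 0L) return(matrix(character(0), nrow = 0, ncol = width))
  out <- matrix("", nrow = n, ncol = width)
  for (j in seq_len(width)) out[, j] <- substr(x, j, j)
  out
}

# Count mismatches between each string's segment [start, start+len-1] and a
# fixed anchor sequence. Vectorised over reads; loops only over anchor bases.
segment_mismatches <- function(x, start, anchor) {
  len <- nchar(anchor)
  mm <- integer(length(x))
  for (j in seq_len(len)) {
    mm <- mm + (substr(x, start + j - 1L, start + j - 1L) !=
                  substr(anchor, j, j))
  }
  mm
}

# Apply single-base substitutions to strings in place. `idx` indexes into `x`,
# `pos` is the 1-based position within the string, `base` the replacement.
# Grouped by position so each group is one vectorised substr<- call.
apply_substitutions <- function(x, idx, pos, base) {
  if (length(idx) == 0L) return(x)
  for (p in unique(pos)) {
    sel <- pos == p
    i <- idx[sel]
    s <- x[i]
    substr(s, p, p) <- base[sel]
    x[i] <- s
  }
  x
}

# Uniformly pick a base different from `from` (vectorised).
other_base <- function(from) {
  k <- sample.int(3L, length(from), replace = TRUE)
  vapply(seq_along(from), function(i) setdiff(DNA_BASES, from[i])[k[i]], "",
         USE.NAMES = FALSE)
}

# Fast variant of other_base: precomputed alternatives table.
OTHER_BASE_TAB <- local({
  tab <- matrix("", nrow = 4, ncol = 3, dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) tab[b, ] <- setdiff(DNA_BASES, b)
  tab
})

other_base_fast <- function(from) {
  n <- length(from)
  if (n == 0L) return(character(0))
  k <- sample.int(3L, n, replace = TRUE)
  fi <- match(from, DNA_BASES)
  # characters not in A/C/G/T (should not occur) mutate to a random base
  out <- OTHER_BASE_TAB[cbind(pmax(fi, 1L, na.rm = TRUE), k)]
  out[is.na(fi)] <- sample(DNA_BASES, sum(is.na(fi)), replace = TRUE)
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}
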