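#' Banded primer-anchored global alignment
#'
#' Global Needleman-Wunsch alignment of an extracted insert against its
#' amplicon reference, restricted to a diagonal band. Scores: match +1,
#' mismatch -1, gap -2 per base. Returns one call per reference position
#' (`A`/`C`/`G`/`T` or `-` for a deleted reference base); inserted bases are
#' recorded separately with the reference position they follow. Ties between
#' optimal paths are broken by preferring a diagonal step, then a deletion,
#' then an insertion (evaluated during traceback from the alignment end).
#'
#' @param insert insert sequence (character scalar)
#' @param reference amplicon reference insert
#' @param match,mismatch,gap alignment scores
#' @param band half-width of the diagonal band; length differences beyond the
#'   band raise an `unalignable` error
#' @return list with `calls` (character vector, one per reference position),
#'   `insertions` (data.table `after_pos`, `bases`; `after_pos` is 1-based,
#'   0 = before the first reference base) and `score`
#' @export
anchor_align <- function(insert, reference, match = 1, mismatch = -1,
                         gap = -2, band = 10) {
  Li <- nchar(insert); Lr <- nchar(reference)
  if (Li == 0L || Lr == 0L) stopf("anchor_align: empty sequence")
  if (abs(Li - Lr) > band)
    stop(structure(class = c("unalignable", "error", "condition"),
                   list(message = sprintf(
                     "insert length %d outside band %d of reference length %d",
                     Li, band, Lr), call = NULL)))
  xi <- strsplit(insert, "", fixed = TRUE)[[1]]
  yr <- strsplit(reference, "", fixed = TRUE)[[1]]

  # feasible diagonal offsets j - i: the corridor [0, Lr-Li] widened by band
  lo <- min(0L, Lr - Li) - band
  hi <- max(0L, Lr - Li) + band
  NEG <- -1e9
  S <- matrix(NEG, Li + 1L, Lr + 1L)
  S[1L, 1L] <- 0
  for (j in seq_len(Lr)) if (j <= hi) S[1L, j + 1L] <- gap * j
  for (i in seq_len(Li)) if (-i >= lo) S[i + 1L, 1L] <- gap * i
  for (i in seq_len(Li)) {
    jmin <- max(1L, i + lo); jmax <- min(Lr, i + hi)
    for (j in seq.int(jmin, length.out = max(0L, jmax - jmin + 1L))) {
      d <- S[i, j] + if (xi[i] == yr[j]) match else mismatch
      u <- S[i, j + 1L] + gap      # insert base unmatched -> insertion
      l <- S[i + 1L, j] + gap      # reference base skipped -> deletion
      S[i + 1L, j + 1L] <- max(d, u, l)
    }
  }
  score <- S[Li + 1L, Lr + 1L]
  if (score <= NEG / 2)
    stop(structure(class = c("unalignable", "error", "condition"),
                   list(message = "no alignment within band", call = NULL)))

  calls <- character(Lr)
  ins_after <- integer(0); ins_base <- character(0)
  i <- Li; j <- Lr
  while (i > 0L || j > 0L) {
    sc <- S[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        sc == S[i, j] + (if (xi[i] == yr[j]) match else mismatch)) {
      calls[j] <- xi[i]; i <- i - 1L; j <- j - 1L
    } else if (j > 0L && sc == S[i + 1L, j] + gap) {
      calls[j] <- DEL_CHAR; j <- j - 1L
    } else {
      ins_after <- c(ins_after, j); ins_base <- c(ins_base, xi[i])
      i <- i - 1L
    }
  }
  insertions <- if (length(ins_after)) {
    dt <- data.table(after_pos = rev(ins_after), base = rev(ins_base))
    dt[, .(bases = paste(base, collapse = "")), by = after_pos]
  } else data.table(after_pos = integer(0), bases = character(0))
  list(calls = calls, insertions = insertions, score = score)
}
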