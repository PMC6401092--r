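# Read validation and insert extraction.
#
# A read is valid when its hairpin-stem and targeting-primer segments match
# exactly one panel amplicon with at most `max_anchor_mismatches` mismatches
# each; the 12-mer at the start is then its barcode and the following window
# its insert. Equal-length inserts with <= 2 mismatches are called
# positionally: with gap penalty -2, any alignment containing a gap pair
# scores at most L - 5 < L - 2k for k <= 2, so the gap-free alignment is the
# unique NW optimum and the banded aligner is only invoked for the rare
# remainder.

#' Validate and parse reads against a panel
#'
#' @param reads a `sim_reads` table, any data.frame with `read_id` and `seq`
#'   columns, or a FASTQ path
#' @param layout a [read_layout()]
#' @param panel the [amplicon_panel()] the layout was built from
#' @return object of class `valid_reads`: `$reads` (read_id, amplicon,
#'   barcode, row index into the per-amplicon call matrix), `$calls` (per
#'   amplicon, an integer matrix of per-position calls coded A=1, C=2, G=3,
#'   T=4, deletion=5), `$insertions`, and `$rejects` (read_id, reason; one
#'   reason per rejected read)
#' @export
parse_reads <- function(reads, layout, panel) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  reads <- as.data.table(reads)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  n <- nrow(reads)
  sq <- reads$seq
  len <- nchar(sq)
  namp <- length(layout$amplicon)

  reason <- rep(NA_character_, n)
  anchor_extent <- layout$primer_start - 1L + nchar(layout$primer)
  too_short <- len < min(anchor_extent)
  reason[too_short] <- "short_read"

  barcode <- substr(sq, 1L, layout$barcode_length)
  bad_bc <- is.na(reason) & grepl("[^ACGT]", barcode)
  reason[bad_bc] <- "invalid_barcode"

  live <- which(is.na(reason))
  ok <- matrix(FALSE, n, namp)
  for (a in seq_len(namp)) {
    mm <- segment_mismatches(sq[live], layout$stem_start, layout$stem[a])
    pm <- segment_mismatches(sq[live], layout$primer_start[a],
                             layout$primer[a])
    ok[live, a] <- mm <= layout$max_anchor_mismatches &
      pm <= layout$max_anchor_mismatches
  }
  nok <- rowSums(ok)
  reason[is.na(reason) & nok == 0L] <- "no_anchor"
  reason[is.na(reason) & nok > 1L] <- "ambiguous_amplicon"

  amp_idx <- rep(NA_integer_, n)
  sel <- is.na(reason)
  amp_idx[sel] <- max.col(ok[sel, , drop = FALSE], "first")
  short2 <- sel & len < layout$core_len[amp_idx]
  reason[short2] <- "short_read"
  amp_idx[!is.na(reason)] <- NA_integer_

  calls <- vector("list", namp)
  names(calls) <- layout$amplicon
  rows <- rep(NA_integer_, n)
  ins_all <- list()
  for (a in seq_len(namp)) {
    idx <- which(amp_idx == a & is.na(reason))
    L <- layout$insert_len[a]
    ref <- panel$insert[a]
    win <- substr(sq[idx], layout$insert_start[a],
                  layout$insert_start[a] + L - 1L)
    mm <- segment_mismatches(win, 1L, ref)
    M <- matrix(NA_integer_, length(idx), L)
    easy <- mm <= 2L
    for (j in seq_len(L)) {
      M[easy, j] <- match(substr(win[easy], j, j), CALL_LEVELS)
    }
    hard <- which(!easy)
    drop_rows <- integer(0)
    for (h in hard) {
      al <- tryCatch(anchor_align(win[h], ref), unalignable = function(e) NULL)
      if (is.null(al)) {
        reason[idx[h]] <- "unalignable"
        drop_rows <- c(drop_rows, h)
      } else {
        M[h, ] <- match(al$calls, CALL_LEVELS)
        if (nrow(al$insertions))
          ins_all[[length(ins_all) + 1L]] <-
            data.table(read_id = reads$read_id[idx[h]],
                       amplicon = layout$amplicon[a],
                       after_pos = al$insertions$after_pos,
                       bases = al$insertions$bases)
      }
    }
    if (length(drop_rows)) {
      M <- M[-drop_rows, , drop = FALSE]
      idx <- idx[-drop_rows]
    }
    calls[[a]] <- M
    rows[idx] <- seq_along(idx)
  }

  valid <- is.na(reason)
  out <- list(
    reads = data.table(read_id = reads$read_id[valid],
                       amplicon = layout$amplicon[amp_idx[valid]],
                       barcode = barcode[valid],
                       row = rows[valid]),
    calls = calls,
    insertions = if (length(ins_all)) rbindlist(ins_all) else
      data.table(read_id = character(0), amplicon = character(0),
                 after_pos = integer(0), bases = character(0)),
    rejects = data.table(read_id = reads$read_id[!valid],
                         reason = reason[!valid]),
    panel = panel, layout = layout
  )
  structure(out, class = "valid_reads")
}

#' Parse a single read
#'
#' Single-read convenience wrapper around [parse_reads()].
#'
#' @param read a character scalar (the read sequence) or a one-row data.frame
#'   with `read_id` and `seq`
#' @inheritParams parse_reads
#' @return for a valid read, a list with `read_id`, `amplicon_id`, `barcode`,
#'   `calls` (character vector over A/C/G/T/-) and `insertions`; otherwise a
#'   list with `rejected = <reason>`
#' @export
parse_read <- function(read, layout, panel) {
  if (is.character(read)) read <- data.frame(read_id = "read1", seq = read)
  vr <- parse_reads(read, layout, panel)
  if (nrow(vr$rejects)) return(list(rejected = vr$rejects$reason[1L]))
  a <- vr$reads$amplicon[1L]
  list(read_id = vr$reads$read_id[1L], amplicon_id = a,
       barcode = vr$reads$barcode[1L],
       calls = CALL_LEVELS[vr$calls[[a]][vr$reads$row[1L], ]],
       insertions = vr$insertions)
}

#' @export
print.valid_reads <- function(x, ...) {
  cat(sprintf("valid_reads: %d valid, %d rejected\n",
              nrow(x$reads), nrow(x$rejects)))
  if (nrow(x$rejects))
    print(x$rejects[, .N, by = reason])
  invisible(x)
}

#' Per-read parse status table
#'
#' One row per input read: its status (`valid` or the rejection reason) and,
#' for valid reads, the assigned amplicon and barcode.
#'
#' @param valid a `valid_reads` object
#' @return data.table with columns read_id, status, amplicon, barcode
#' @export
parse_summary <- function(valid) {
  rbind(
    valid$reads[, .(read_id, status = "valid", amplicon, barcode)],
    valid$rejects[, .(read_id, status = reason, amplicon = NA_character_,
                      barcode = NA_character_)]
  )
}
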