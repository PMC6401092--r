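# Shared fixtures, built in code.

test_panel <- function() default_panel()

# A single-amplicon panel (keeps family counts per amplicon high in
# detection simulations).
kit_panel <- function() {
  p <- default_panel()
  amplicon_panel(id = "KIT", insert = p$insert[p$amplicon == "KIT"],
                 primer = p$primer[p$amplicon == "KIT"],
                 stem = p$stem[p$amplicon == "KIT"],
                 targets = data.frame(amplicon = "KIT", pos = 6L,
                                      alt = "T"))
}

quiet_config <- function(...) {
  # all error sources off unless overridden
  sim_config(taq_error_rate = 0, seq_error_rate = 0, ...)
}

# Consensus-read character matrix for a hand-built family: `n` reads of the
# reference with substitutions injected at (read, pos) -> base.
family_matrix <- function(reference, n, subs = NULL) {
  L <- nchar(reference)
  M <- matrix(rep(strsplit(reference, "")[[1]], each = n), nrow = n)
  if (!is.null(subs))
    for (k in seq_len(nrow(subs)))
      M[subs$read[k], subs$pos[k]] <- subs$base[k]
  M
}

# Rebuild each read's expected sequence from its template and logged events
# and compare with the emitted read (ground-truth consistency).
check_divergences <- function(sim) {
  truth <- attr(sim$reads, "truth")
  ev <- attr(sim$reads, "events")
  layout <- sim$layout
  rl <- layout$read_length
  amp_idx <- match(truth$amplicon, layout$amplicon)
  base <- substr(paste0(truth$barcode, layout$stem[amp_idx],
                        layout$primer[amp_idx],
                        sim$templates$insert[truth$template_id],
                        layout$tail), 1, rl)
  allev <- rbind(
    data.frame(read_id = ev$pcr$read_id, pos = ev$pcr$pos, to = ev$pcr$to,
               cycle = ev$pcr$cycle),
    data.frame(read_id = ev$sequencer$read_id, pos = ev$sequencer$pos,
               to = ev$sequencer$to, cycle = 1e6)
  )
  allev <- allev[allev$pos <= rl, ]
  allev <- allev[order(match(allev$read_id, truth$read_id), allev$cycle), ]
  idx <- match(allev$read_id, truth$read_id)
  for (k in seq_len(nrow(allev)))
    substr(base[idx[k]], allev$pos[k], allev$pos[k]) <- allev$to[k]
  testthat::expect_identical(base, sim$reads$seq)
  testthat::expect_gt(nrow(allev), 0)
}
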