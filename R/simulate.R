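# Generative simulator of barcoded library construction.
#
# The generative model, stage by stage:
#   templates  -> barcoding PCR (few cycles; a random 12-mer barcode is
#                 attached to each successfully primed template, copies then
#                 double per cycle, every newly synthesised strand picks up
#                 polymerase substitutions)
#              -> adapter PCR (many cycles; each family amplifies with its own
#                 efficiency drawn from a Beta distribution, modelling
#                 amplification bias)
#              -> sequencing (multinomial sampling of the final pool, uniform
#                 substitution noise per base).
#
# Polymerase errors are drawn in two steps: candidate events at the Taq base
# rate, each kept with probability 1/fidelity. The kept set has exactly the
# Binomial(L, rate/fidelity) law, and because the candidate stream does not
# depend on fidelity, runs that share a seed but differ in fidelity see nested
# error sets (a higher-fidelity run keeps a subset of a lower-fidelity run's
# errors). Fidelity sweeps at a fixed seed are therefore exactly coupled.

# Draw polymerase errors for the strands indexed by `idx` into `seqs`.
# `Lc` gives each strand's construct length. Returns updated seqs plus the
# kept events. RNG consumption depends on cand_rate but not on keep_prob.
draw_strand_errors <- function(seqs, idx, Lc, cand_rate, keep_prob, cycle) {
  empty <- data.table(idx = integer(0), cycle = integer(0), pos = integer(0),
                      from = character(0), to = character(0))
  n <- length(idx)
  if (n == 0L || cand_rate <= 0)
    return(list(seqs = seqs, events = empty))
  k <- rbinom(n, Lc, cand_rate)
  aff <- which(k > 0L)
  if (length(aff) == 0L) return(list(seqs = seqs, events = empty))
  pos <- unlist(lapply(aff, function(j) sample.int(Lc[j], k[j])),
                use.names = FALSE)
  sid <- idx[rep(aff, k[aff])]
  from <- substr(seqs[sid], pos, pos)
  to <- other_base_fast(from)
  keep <- runif(length(pos)) < keep_prob
  if (any(keep))
    seqs <- apply_substitutions(seqs, sid[keep], pos[keep], to[keep])
  list(seqs = seqs,
       events = data.table(idx = sid, cycle = cycle, pos = pos,
                           from = from, to = to)[keep])
}

#' Generate template molecules
#'
#' Draws `n_templates` haploid template molecules per amplicon. Spiked
#' variants from `config$vaf_spec` are assigned binomially with probability
#' VAF, or as an exact `round(n_templates * vaf)` count in `"fixed"` mode.
#' Optional tandem (dinucleotide) damage from `config$tandem_spec` is placed
#' afterwards. Ground-truth labels are retained.
#'
#' @param panel an [amplicon_panel()]
#' @param config a [sim_config()]
#' @return data.table of class `template_molecules` with columns
#'   `template_id`, `amplicon`, `insert`, `is_variant`, `variant_desc`
#' @export
generate_templates <- function(panel, config) {
  vs <- config$vaf_spec
  if (!is.null(vs)) {
    bad <- !vs$amplicon %in% panel$amplicon
    if (any(bad)) stopf("vaf_spec amplicon '%s' not in panel",
                        vs$amplicon[bad][1])
    len <- panel$insert_len[match(vs$amplicon, panel$amplicon)]
    if (any(vs$pos < 1L | vs$pos > len))
      stopf("vaf_spec position outside insert bounds")
  }
  n <- config$n_templates
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    a <- panel$amplicon[i]
    dt <- data.table(amplicon = a,
                     insert = rep(panel$insert[i], n),
                     is_variant = FALSE,
                     variant_desc = NA_character_)
    if (!is.null(vs)) {
      for (r in which(vs$amplicon == a)) {
        vaf <- vs$vaf[r]
        hit <- if (config$vaf_mode == "fixed") {
          kk <- round(n * vaf)
          if (kk > 0L) sample.int(n, kk) else integer(0)
        } else {
          which(runif(n) < vaf)
        }
        if (length(hit)) {
          s <- dt$insert[hit]
          substr(s, vs$pos[r], vs$pos[r]) <- vs$alt[r]
          dt$insert[hit] <- s
          dt$is_variant[hit] <- TRUE
          dt$variant_desc[hit] <- sprintf("%s:%d%s", a, vs$pos[r], vs$alt[r])
        }
      }
    }
    ts <- config$tandem_spec
    if (!is.null(ts)) {
      for (r in which(ts$amplicon == a)) {
        hit <- which(runif(n) < ts$rate[r])
        if (length(hit)) {
          s <- dt$insert[hit]
          substr(s, ts$pos[r], ts$pos[r] + 1L) <- ts$to[r]
          dt$insert[hit] <- s
          dt$variant_desc[hit] <- paste0(
            ifelse(is.na(dt$variant_desc[hit]), "",
                   paste0(dt$variant_desc[hit], ";")),
            sprintf("%s:%d..%s(tandem)", a, ts$pos[r], ts$to[r]))
        }
      }
    }
    out[[i]] <- dt
  }
  res <- rbindlist(out)
  res[, template_id := .I]
  setcolorder(res, "template_id")
  setattr(res, "class", c("template_molecules", class(res)))
  res[]
}

#' Run the barcoding PCR
#'
#' Each template is successfully primed with probability
#' `barcoding_efficiency`, founding one barcode family with a barcode drawn
#' uniformly from the 4^12 12-mer space; the founder copy is synthesised in
#' cycle 1 (its errors are inherited by the whole family and flagged as
#' uncorrectable ground truth), and every strand then duplicates in each
#' remaining cycle with probability `barcoding_efficiency`. Newly synthesised
#' strands acquire substitutions at rate `taq_error_rate / fidelity` per base
#' over the whole construct (barcode, anchors, insert and tail), recorded
#' with their cycle number.
#'
#' @param templates output of [generate_templates()]
#' @param config a [sim_config()]
#' @param layout a [read_layout()]
#' @return object of class `tagged_pool`: strand table, construct sequences
#'   and the cumulative per-strand error log
#' @export
run_barcoding_pcr <- function(templates, config, layout) {
  eff <- config$barcoding_efficiency
  founded <- which(runif(nrow(templates)) < eff)
  nfam <- length(founded)
  barcodes <- random_dna(nfam, layout$barcode_length)
  amp_idx <- match(templates$amplicon[founded], layout$amplicon)
  Lc_all <- construct_length(layout)

  families <- data.table(family_id = seq_len(nfam),
                         template_id = templates$template_id[founded],
                         amplicon = templates$amplicon[founded],
                         barcode = barcodes)

  # cycle 1: the founder copy of each family
  seqs <- render_construct(layout, amp_idx, barcodes,
                           templates$insert[founded])
  strands <- data.table(strand_id = seq_len(nfam),
                        family_id = seq_len(nfam),
                        created_cycle = 1L)
  Lc <- Lc_all[amp_idx]

  rate1 <- config$cycle1_error_rate
  if (is.null(rate1)) {
    cand1 <- config$taq_error_rate; keep1 <- 1 / config$fidelity
  } else {
    cand1 <- rate1; keep1 <- 1
  }
  er <- draw_strand_errors(seqs, seq_len(nfam), Lc, cand1, keep1, 1L)
  seqs <- er$seqs
  events <- setnames(er$events, "idx", "strand_id")

  for (cy in seq_len(config$barcoding_cycles)[-1]) {
    nstr <- nrow(strands)
    dup <- which(runif(nstr) < eff)
    if (length(dup) == 0L) next
    new_ids <- nrow(strands) + seq_along(dup)
    strands <- rbind(strands,
                     data.table(strand_id = new_ids,
                                family_id = strands$family_id[dup],
                                created_cycle = cy))
    seqs <- c(seqs, seqs[dup])
    Lc <- c(Lc, Lc[dup])
    # children inherit their parent's accumulated error log
    if (nrow(events)) {
      par_ev <- events[data.table(strand_id = strands$strand_id[dup],
                                  new_id = new_ids),
                       on = "strand_id", nomatch = NULL]
      if (nrow(par_ev)) {
        par_ev[, strand_id := new_id][, new_id := NULL]
        events <- rbind(events, par_ev)
      }
    }
    er <- draw_strand_errors(seqs, new_ids, Lc[new_ids],
                             config$taq_error_rate, 1 / config$fidelity, cy)
    seqs <- er$seqs
    events <- rbind(events, setnames(er$events, "idx", "strand_id"))
  }

  strands[, template_id := families$template_id[family_id]]
  strands[, amplicon := families$amplicon[family_id]]
  strands[, barcode := families$barcode[family_id]]
  setkey(events, strand_id)
  structure(list(strands = strands[], seqs = seqs, Lc = Lc,
                 events = events, families = families, layout = layout,
                 n_input_templates = nrow(templates)),
            class = "tagged_pool")
}

#' Run the adapter PCR
#'
#' Each barcode family draws one amplification efficiency from the configured
#' Beta distribution (the amplification-bias model); every molecule then
#' duplicates per cycle with that efficiency, newly synthesised strands
#' acquiring errors at rate `taq_error_rate / adapter_fidelity`. With
#' `materialize = "never"` (the default for realistic cycle counts) molecules
#' are tracked at the count level per barcoding strand and adapter errors are
#' drawn per sampled read in [sequence_reads()]; with materialised tracking
#' every molecule and its error log is explicit.
#'
#' @param tagged output of [run_barcoding_pcr()]
#' @param config a [sim_config()]
#' @return object of class `amplified_pool`
#' @export
run_adapter_pcr <- function(tagged, config) {
  nfam <- nrow(tagged$families)
  fe <- config$family_efficiency
  eff <- rbeta(nfam, fe[1], fe[2])
  cyc <- config$adapter_cycles
  nstr <- nrow(tagged$strands)

  expected <- nstr * (1 + mean(eff))^cyc
  mode <- switch(config$materialize,
                 always = "materialized",
                 never = "virtual",
                 auto = if (expected <= 2e5) "materialized" else "virtual")

  if (mode == "virtual") {
    counts <- rep(1, nstr)  # the barcoding strand itself plus its descendants
    p <- eff[tagged$strands$family_id]
    for (t in seq_len(cyc)) counts <- counts + rbinom(nstr, counts, p)
    return(structure(list(mode = "virtual", tagged = tagged,
                          weights = counts, family_eff = eff,
                          adapter_cycles = cyc,
                          molecules = NULL, seqs = tagged$seqs,
                          events = tagged$events, layout = tagged$layout),
                     class = "amplified_pool"))
  }

  if (expected > 2e6)
    stopf("materialized adapter PCR would create ~%.0f molecules; use materialize = 'never'",
          expected)
  # materialized: extend the strand tree through the adapter cycles
  mol <- data.table(molecule_id = seq_len(nstr),
                    root_strand_id = tagged$strands$strand_id,
                    family_id = tagged$strands$family_id,
                    created_cycle = tagged$strands$created_cycle,
                    adapter_product = FALSE)
  seqs <- tagged$seqs
  Lc <- tagged$Lc
  events <- copy(tagged$events)
  setnames(events, "strand_id", "molecule_id")
  base_cycle <- config$barcoding_cycles
  for (t in seq_len(cyc)) {
    n <- nrow(mol)
    dup <- which(runif(n) < eff[mol$family_id])
    if (length(dup) == 0L) next
    new_ids <- n + seq_along(dup)
    mol <- rbind(mol, data.table(molecule_id = new_ids,
                                 root_strand_id = mol$root_strand_id[dup],
                                 family_id = mol$family_id[dup],
                                 created_cycle = base_cycle + t,
                                 adapter_product = TRUE))
    seqs <- c(seqs, seqs[dup])
    Lc <- c(Lc, Lc[dup])
    if (nrow(events)) {
      par_ev <- events[data.table(molecule_id = mol$molecule_id[dup],
                                  new_id = new_ids),
                       on = "molecule_id", nomatch = NULL]
      if (nrow(par_ev)) {
        par_ev[, molecule_id := new_id][, new_id := NULL]
        events <- rbind(events, par_ev)
      }
    }
    er <- draw_strand_errors(seqs, new_ids, Lc[new_ids],
                             config$taq_error_rate,
                             1 / config$adapter_fidelity, base_cycle + t)
    seqs <- er$seqs
    events <- rbind(events, setnames(er$events, "idx", "molecule_id"))
  }
  setkey(events, molecule_id)
  structure(list(mode = "materialized", tagged = tagged, weights = NULL,
                 family_eff = eff, adapter_cycles = cyc,
                 molecules = mol[], seqs = seqs, events = events,
                 layout = tagged$layout),
            class = "amplified_pool")
}

#' Sample sequencing reads from an amplified pool
#'
#' Renders `depth` single-end reads: molecules are sampled multinomially from
#' the final pool, the construct is truncated to `read_length`, and each base
#' is flipped to a uniformly chosen different base with probability
#' `seq_error_rate`. Quality strings are constant "I". Read names encode the
#' ground-truth lineage (`r<i>|f<family>|s<strand>|t<template>`).
#'
#' @param pool output of [run_adapter_pcr()] (or of [run_barcoding_pcr()],
#'   which is treated as an unamplified pool)
#' @param layout a [read_layout()]
#' @param config a [sim_config()]
#' @param depth total reads to sample (default `config$depth`, or 15 per
#'   family)
#' @return data.table of class `sim_reads` with columns `read_id`, `seq`,
#'   `qual`; ground truth in `attr(, "truth")` and `attr(, "events")`
#' @export
sequence_reads <- function(pool, layout, config, depth = NULL) {
  if (inherits(pool, "tagged_pool"))
    pool <- structure(list(mode = "virtual", tagged = pool,
                           weights = rep(1, nrow(pool$strands)),
                           family_eff = rep(1, nrow(pool$families)),
                           adapter_cycles = 0L, molecules = NULL,
                           seqs = pool$seqs, events = pool$events,
                           layout = pool$layout),
                      class = "amplified_pool")
  tagged <- pool$tagged
  rl <- layout$read_length
  depth <- depth %||% config$depth %||% (15L * nrow(tagged$families))
  depth <- check_count(depth, "depth", 1L)

  if (pool$mode == "virtual") {
    units <- tagged$strands
    unit_strand <- units$strand_id
    weights <- pool$weights
    unit_events <- pool$events   # keyed by strand_id
    ev_key <- "strand_id"
  } else {
    units <- pool$molecules
    unit_strand <- units$root_strand_id
    weights <- rep(1, nrow(units))
    unit_events <- pool$events   # keyed by molecule_id
    ev_key <- "molecule_id"
  }
  if (nrow(units) == 0L) stopf("cannot sequence an empty pool")

  cnt <- as.vector(rmultinom(1L, depth, weights))
  u <- rep(seq_len(nrow(units)), cnt)
  n <- length(u)
  fam <- units$family_id[u]
  amp <- tagged$families$amplicon[fam]
  amp_idx <- match(amp, layout$amplicon)
  Lc <- construct_length(layout)[amp_idx]

  reads <- substr(pool$seqs[u], 1L, rl)

  # adapter-PCR errors for the virtual mode: each read's lineage passes
  # through Binomial(cycles, e/(1+e)) synthesis events
  adapter_events <- data.table(read = integer(0), cycle = integer(0),
                               pos = integer(0), from = character(0),
                               to = character(0))
  adepth <- rep(0L, n)
  if (pool$mode == "virtual" && pool$adapter_cycles > 0L) {
    e <- pool$family_eff[fam]
    adepth <- rbinom(n, pool$adapter_cycles, e / (1 + e))
    if (config$taq_error_rate > 0) {
      k <- pmin(rbinom(n, adepth * Lc, config$taq_error_rate), Lc)
      aff <- which(k > 0L)
      if (length(aff)) {
        pos <- unlist(lapply(aff, function(j) sample.int(Lc[j], k[j])),
                      use.names = FALSE)
        rd <- rep(aff, k[aff])
        cyc <- config$barcoding_cycles +
          floor(runif(length(pos)) * pool$adapter_cycles) + 1L
        from <- substr(pool$seqs[u[rd]], pos, pos)
        to <- other_base_fast(from)
        keep <- runif(length(pos)) < 1 / config$adapter_fidelity
        if (any(keep)) {
          sel <- keep & pos <= rl
          reads <- apply_substitutions(reads, rd[sel], pos[sel], to[sel])
          adapter_events <- data.table(read = rd, cycle = as.integer(cyc),
                                       pos = pos, from = from, to = to)[keep]
        }
      }
    }
  }

  # sequencer noise
  seq_events <- data.table(read = integer(0), pos = integer(0),
                           from = character(0), to = character(0))
  if (config$seq_error_rate > 0) {
    k <- rbinom(n, rl, config$seq_error_rate)
    aff <- which(k > 0L)
    if (length(aff)) {
      pos <- unlist(lapply(aff, function(j) sample.int(rl, k[j])),
                    use.names = FALSE)
      rd <- rep(aff, k[aff])
      from <- substr(reads[rd], pos, pos)
      to <- other_base_fast(from)
      reads <- apply_substitutions(reads, rd, pos, to)
      seq_events <- data.table(read = rd, pos = pos, from = from, to = to)
    }
  }

  read_id <- sprintf("r%07d|f%d|s%d|t%d", seq_len(n), fam,
                     unit_strand[u], units_template(units, tagged, u))
  truth <- data.table(read_id = read_id, family_id = fam,
                      strand_id = unit_strand[u],
                      template_id = units_template(units, tagged, u),
                      amplicon = amp,
                      barcode = tagged$families$barcode[fam],
                      adapter_depth = adepth)

  # per-read PCR error log: inherited strand/molecule events + adapter events
  pcr <- unit_events[data.table(uid = if (pool$mode == "virtual")
    unit_strand[u] else units$molecule_id[u], read = seq_len(n)),
    on = setNames("uid", ev_key), nomatch = NULL, allow.cartesian = TRUE]
  pcr <- pcr[, .(read, cycle, pos, from, to)]
  if (nrow(adapter_events))
    pcr <- rbind(pcr, adapter_events)
  events <- list(pcr = pcr[order(read, cycle, pos)],
                 sequencer = seq_events[order(read, pos)])
  events$pcr[, read_id := read_id[read]]
  events$sequencer[, read_id := read_id[read]]

  out <- data.table(read_id = read_id, seq = reads,
                    qual = strrep("I", rl))
  setattr(out, "truth", truth)
  setattr(out, "events", events)
  setattr(out, "class", c("sim_reads", class(out)))
  out[]
}

units_template <- function(units, tagged, u) {
  if ("root_strand_id" %in% names(units)) {
    tagged$strands$template_id[match(units$root_strand_id[u],
                                     tagged$strands$strand_id)]
  } else {
    units$template_id[u]
  }
}

#' Simulate a complete barcoded library
#'
#' Runs the full generative chain (templates, barcoding PCR, adapter PCR,
#' sequencing) under one seed. Identical panel + config + seed gives
#' bit-identical output.
#'
#' @param panel an [amplicon_panel()]
#' @param config a [sim_config()]
#' @param layout optional [read_layout()] (default built from the panel with
#'   `config$read_length`)
#' @param depth total reads to sample (default `config$depth` or 15/family)
#' @return list of class `sim_library` with elements `reads` (a `sim_reads`
#'   table), `templates`, `tagged`, `pool`, `panel`, `layout`, `config`
#' @export
simulate_library <- function(panel, config, layout = NULL, depth = NULL) {
  set.seed(config$seed)
  layout <- layout %||% read_layout(panel, read_length = config$read_length)
  templates <- generate_templates(panel, config)
  tagged <- run_barcoding_pcr(templates, config, layout)
  pool <- run_adapter_pcr(tagged, config)
  reads <- sequence_reads(pool, layout, config, depth = depth)
  structure(list(reads = reads, templates = templates, tagged = tagged,
                 pool = pool, panel = panel, layout = layout,
                 config = config),
            class = "sim_library")
}

#' Ground-truth uncorrectable (cycle-1) errors within the insert
#'
#' Maps every cycle-1 polymerase error of the founded families to insert
#' coordinates. These errors are carried by the whole family and cannot be
#' removed by consensus calling.
#'
#' @param sim a `sim_library`
#' @return data.table with columns `family_id`, `amplicon`, `insert_pos`,
#'   `from`, `to`
#' @export
truth_cycle1_errors <- function(sim) {
  ev <- sim$tagged$events[cycle == 1L]
  if (nrow(ev) == 0L)
    return(data.table(family_id = integer(0), amplicon = character(0),
                      insert_pos = integer(0), from = character(0),
                      to = character(0)))
  st <- sim$tagged$strands
  ev[, family_id := st$family_id[match(strand_id, st$strand_id)]]
  ev[, amplicon := sim$tagged$families$amplicon[family_id]]
  ai <- match(ev$amplicon, sim$layout$amplicon)
  ev[, insert_pos := pos - sim$layout$insert_start[ai] + 1L]
  ev <- ev[insert_pos >= 1L & insert_pos <= sim$layout$insert_len[ai]]
  ev[, .(family_id, amplicon, insert_pos, from, to)]
}
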