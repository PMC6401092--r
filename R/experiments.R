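# Whole-experiment drivers: simulate full arms and summarise them the way
# the downstream comparisons need. These are the computational core behind
# the numbered analysis scripts.

#' Polymerase fidelity sweep
#'
#' Simulates one library per (seed, fidelity) at otherwise identical
#' conditions and summarises raw and consensus error. Because polymerase
#' errors are realised by thinning a fidelity-independent candidate stream
#' (see [sim_config()]), arms sharing a seed see nested error sets: the
#' sweep is exactly coupled and consensus error is non-increasing in
#' fidelity by construction.
#'
#' @param fidelities fidelity multipliers to sweep (default the 1x-100x
#'   ladder of commercially common enzymes)
#' @param seeds one simulation per seed and fidelity
#' @param panel an [amplicon_panel()]
#' @param n_templates,depth library size per arm
#' @param taq_error_rate,seq_error_rate error rates (defaults as in
#'   [sim_config()])
#' @param ... further arguments passed to [sim_config()]
#' @return data.table with one row per (seed, fidelity): read/family
#'   accounting, raw and consensus error counts, call totals and mean
#'   frequencies
#' @export
fidelity_sweep <- function(fidelities = c(1, 2, 9, 52, 100),
                           seeds = 1L,
                           panel = default_panel(),
                           n_templates = 1600L, depth = 65000L,
                           taq_error_rate = 1e-4, seq_error_rate = 0.001,
                           ...) {
  out <- list()
  for (seed in seeds) for (fid in fidelities) {
    cfg <- sim_config(taq_error_rate = taq_error_rate, fidelity = fid,
                      seq_error_rate = seq_error_rate,
                      n_templates = n_templates, depth = depth,
                      seed = seed, ...)
    pl <- run_pipeline(panel, cfg, keep_sim = FALSE)
    out[[length(out) + 1L]] <- data.table(
      seed = seed, fidelity = fid,
      n_valid = nrow(pl$valid$reads),
      n_families = nrow(pl$families$families),
      n_consensus = nrow(pl$consensus$families),
      raw_errors = sum(pl$raw_profile$nonref),
      raw_calls = sum(pl$raw_profile$depth),
      cons_errors = sum(pl$cons_profile$nonref),
      cons_calls = sum(pl$cons_profile$depth),
      raw_err = sum(pl$raw_profile$nonref) / sum(pl$raw_profile$depth),
      cons_err = sum(pl$cons_profile$nonref) / sum(pl$cons_profile$depth))
  }
  rbindlist(out)
}

#' Pooled arm summary of a fidelity sweep
#'
#' @param sweep output of [fidelity_sweep()]
#' @return data.table per fidelity: pooled raw and consensus error rates
#' @export
sweep_summary <- function(sweep) {
  sweep[, .(raw_err = sum(raw_errors) / sum(raw_calls),
            cons_err = sum(cons_errors) / sum(cons_calls),
            n_consensus = sum(n_consensus)), by = fidelity]
}

#' Adapter-PCR amplification-bias comparison
#'
#' Simulates paired low-bias and high-bias adapter-PCR arms at matched mean
#' yield (identical sequencing depth) for each seed and counts the unique
#' barcodes represented by at least `min_family_size` reads.
#'
#' @param seeds one simulation pair per seed
#' @param panel an [amplicon_panel()]
#' @param n_templates,depth library size per arm
#' @param min_family_size family-size floor for a barcode to count
#' @param ... further arguments passed to [sim_config()]
#' @return data.table with one row per (seed, preset): barcode counts and
#'   consensus depth
#' @export
bias_comparison <- function(seeds = 1:20, panel = default_panel(),
                            n_templates = 400L, depth = 13000L,
                            min_family_size = 10L, ...) {
  out <- list()
  for (seed in seeds) for (preset in c("low_bias", "high_bias")) {
    cfg <- sim_config(family_efficiency = preset,
                      n_templates = n_templates, depth = depth,
                      seed = seed, ...)
    pl <- run_pipeline(panel, cfg, keep_sim = FALSE,
                       min_family_size = min_family_size)
    cnt <- count_unique_barcodes(pl$families, min_family_size)
    out[[length(out) + 1L]] <- data.table(
      seed = seed, preset = preset,
      n_families = nrow(pl$families$families),
      n_barcodes10 = attr(cnt, "total"),
      n_consensus = nrow(pl$consensus$families))
  }
  rbindlist(out)
}

#' Monte-Carlo detection power at spiked VAFs
#'
#' Simulates libraries with a variant spiked at each VAF (binomial template
#' assignment), runs the pipeline and the background-based detector, and
#' records the per-seed detection decision for each panel target.
#'
#' @param vafs variant allele frequencies to test (0 = no spike, the
#'   false-detection arm)
#' @param seeds one simulation per (vaf, seed)
#' @param panel an [amplicon_panel()]; its targets receive the spike
#' @param n_templates,depth library size per arm
#' @param fidelity barcoding-enzyme fidelity (default 100, the
#'   highest-fidelity arm)
#' @param min_alt_count detector count floor
#' @param ... further arguments passed to [sim_config()]
#' @return data.table with one row per (vaf, seed, target): detection
#'   decision, observed VAF, alternate count and background summary
#' @export
detection_power <- function(vafs = c(0.00125, 0.000625, 0.0003125, 0),
                            seeds = 1:20, panel = default_panel(),
                            n_templates = 8000L, depth = 129600L,
                            fidelity = 100, min_alt_count = 3L, ...) {
  tg <- panel_targets(panel)
  out <- list()
  for (vaf in vafs) for (seed in seeds) {
    vs <- if (vaf > 0)
      data.frame(amplicon = tg$amplicon, pos = tg$pos, alt = tg$alt,
                 vaf = vaf)
    cfg <- sim_config(fidelity = fidelity, n_templates = n_templates,
                      depth = depth, seed = seed, vaf_spec = vs, ...)
    pl <- run_pipeline(panel, cfg, keep_sim = FALSE)
    rep <- detect_variants(pl$cons_profile, panel,
                           min_alt_count = min_alt_count)
    out[[length(out) + 1L]] <- data.table(
      vaf = vaf, seed = seed, amplicon = rep$amplicon, pos = rep$pos,
      detected = rep$detected, observed_vaf = rep$observed_vaf,
      alt_count = rep$alt_count, depth = rep$depth,
      background_max = rep$background_max)
  }
  rbindlist(out)
}

#' Detection power summary per VAF
#' @param power output of [detection_power()]
#' @return data.table per vaf: detection rate over seeds (targets pooled)
#' @export
power_summary <- function(power) {
  power[, .(power = mean(detected), n = .N), by = vaf][order(-vaf)]
}
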