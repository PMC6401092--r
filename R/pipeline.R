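#' Run the full simulation-to-profile pipeline
#'
#' Convenience driver chaining [simulate_library()], [parse_reads()],
#' [group_families()], [call_consensus()], [raw_error_profile()] and
#' [consensus_error_profile()] under one seed.
#'
#' @param panel an [amplicon_panel()]
#' @param config a [sim_config()]
#' @param depth total reads to sample (default `config$depth` or 15/family)
#' @param min_family_size consensus family-size floor (default 10)
#' @param rule consensus rule dialect (see [call_consensus()])
#' @param keep_sim keep the full `sim_library` (ground truth) in the result
#' @return list of class `umi_pipeline` with elements `valid`, `families`,
#'   `consensus`, `raw_profile`, `cons_profile` and (optionally) `sim`
#' @export
run_pipeline <- function(panel, config, depth = NULL, min_family_size = 10L,
                         rule = c("methods", "simple90"), keep_sim = TRUE) {
  rule <- match.arg(rule)
  sim <- simulate_library(panel, config, depth = depth)
  valid <- parse_reads(sim$reads, sim$layout, panel)
  fams <- group_families(valid)
  cons <- call_consensus(fams, min_family_size = min_family_size,
                         rule = rule)
  raw <- raw_error_profile(fams, panel)
  cp <- consensus_error_profile(cons, panel)
  structure(list(sim = if (keep_sim) sim,
                 valid = valid, families = fams, consensus = cons,
                 raw_profile = raw, cons_profile = cp,
                 panel = panel, config = config),
            class = "umi_pipeline")
}

#' @export
print.umi_pipeline <- function(x, ...) {
  cat(sprintf(
    "umi pipeline: %d valid reads (%d rejected), %d families, %d consensus reads\n",
    nrow(x$valid$reads), nrow(x$valid$rejects),
    nrow(x$families$families), nrow(x$consensus$families)))
  cat(sprintf("  mean raw error %.4g, mean consensus error %.4g\n",
              mean_error(x$raw_profile), mean_error(x$cons_profile)))
  invisible(x)
}

#' Summary of a pipeline run as a list (JSON-ready)
#'
#' @param x a `umi_pipeline`
#' @return list with read accounting, per-amplicon family and consensus
#'   counts, and mean raw/consensus error
#' @export
pipeline_summary <- function(x) {
  list(
    n_reads = nrow(x$valid$reads) + nrow(x$valid$rejects),
    n_valid = nrow(x$valid$reads),
    rejects = as.list(table(x$valid$rejects$reason)),
    n_families = nrow(x$families$families),
    consensus_per_amplicon = {
      d <- consensus_depth(x$consensus)
      stats::setNames(as.list(d$n_consensus), d$amplicon)
    },
    mean_raw_error = mean_error(x$raw_profile),
    mean_consensus_error = mean_error(x$cons_profile)
  )
}
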