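#' Expected mutant copies from DNA mass and VAF
#'
#' Converts an input DNA mass and variant allele frequency into the expected
#' number of mutant template copies entering the barcoding reaction, under
#' the convention that 1 ng of genomic DNA contains 278 haploid genomes.
#'
#' @param mass_ng DNA mass in nanograms (vectorised)
#' @param vaf variant allele frequency in [0, 1] (vectorised)
#' @param haploid_genomes_per_ng haploid genome copies per ng (default 278)
#' @return data.table with columns mass_ng, vaf, haploid_genomes, copies
#'   (unrounded) and copies_rounded
#' @export
expected_mutant_copies <- function(mass_ng, vaf,
                                   haploid_genomes_per_ng = 278) {
  if (any(mass_ng < 0)) stopf("'mass_ng' must be >= 0")
  if (any(vaf < 0 | vaf > 1)) stopf("'vaf' must be in [0, 1]")
  if (haploid_genomes_per_ng < 0) stopf("negative copy density")
  copies <- mass_ng * haploid_genomes_per_ng * vaf
  data.table(mass_ng = mass_ng, vaf = vaf,
             haploid_genomes = mass_ng * haploid_genomes_per_ng,
             copies = copies, copies_rounded = round(copies))
}

#' Detect target variants above the panel background
#'
#' For every target position of the panel, compares the consensus
#' alternate-allele frequency with the background consensus error
#' distribution over all non-target positions. The default decision
#' criterion: detected iff (a) the observed alternate VAF exceeds the
#' maximum background non-reference frequency anywhere in the panel, and
#' (b) the alternate consensus count is at least `min_alt_count`. A
#' one-sided Poisson tail probability of the observed count under the mean
#' background rate (scaled to the target depth) is reported as a score so
#' alternative decision rules can be applied.
#'
#' @param cons_profile a consensus `error_profile` from
#'   [consensus_error_profile()]
#' @param panel the [amplicon_panel()] (its target table defines the
#'   positions and expected alternate bases)
#' @param min_alt_count minimum alternate consensus count (default 3)
#' @param exclude_positions optional data.frame (amplicon, pos) of known
#'   recurrent-artifact positions to drop from the background
#' @return data.table of class `detection_report`: per target, the amplicon,
#'   position, expected alternate base, alternate consensus count, consensus
#'   depth, observed VAF, background max and mean frequencies, the Poisson
#'   tail score and the detection decision (`NA` when the target depth is 0)
#' @export
detect_variants <- function(cons_profile, panel, min_alt_count = 3L,
                            exclude_positions = NULL) {
  targets <- panel_targets(panel)
  if (nrow(targets) == 0L) stopf("panel has no target positions")
  prof <- as.data.table(cons_profile)
  prof[, is_target := FALSE]
  prof[targets, is_target := TRUE, on = c("amplicon", "pos")]
  bg <- prof[!(is_target)]
  if (!is.null(exclude_positions)) {
    ex <- as.data.table(exclude_positions)
    bg <- bg[!ex, on = c("amplicon", "pos")]
  }
  bg <- bg[depth > 0]
  bg_max <- if (nrow(bg)) max(bg$freq) else 0
  bg_mean <- if (nrow(bg)) sum(bg$nonref) / sum(bg$depth) else 0

  out <- targets[, {
    row <- prof[amplicon == .BY$amplicon & pos == .BY$pos]
    alt_col <- paste0("to_", alt)
    alt_count <- as.integer(row[[alt_col]])
    depth <- row$depth
    vaf <- if (depth > 0) alt_count / depth else NA_real_
    score <- if (depth > 0)
      ppois(alt_count - 1L, bg_mean * depth, lower.tail = FALSE) else
        NA_real_
    detected <- if (depth > 0)
      (vaf > bg_max) && (alt_count >= min_alt_count) else NA
    .(ref = ref, alt = alt, alt_count = alt_count, depth = depth,
      observed_vaf = vaf, background_max = bg_max,
      background_mean = bg_mean, score = score, detected = detected)
  }, by = .(amplicon, pos)]
  setattr(out, "class", c("detection_report", class(out)))
  out[]
}

#' Write a detection report as TSV and JSON
#' @param report a `detection_report`
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`)
#' @export
write_detection_report <- function(report, prefix) {
  data.table::fwrite(report, paste0(prefix, ".tsv"), sep = "\t")
  jsonlite::write_json(report, paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}
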