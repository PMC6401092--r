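#' Simulation configuration
#'
#' All generative parameters of the library-construction simulator. The
#' defaults emulate the study conditions of the experiments the package is
#' built around: a 3-cycle barcoding PCR incorporating random 12-mer barcodes,
#' a 25-cycle adapter PCR run with a high-fidelity enzyme, single-end 150 bp
#' reads with uniform substitution noise of 1e-3 per base, and a Taq-relative
#' polymerase fidelity scale.
#'
#' @param taq_error_rate polymerase substitution rate for standard Taq, in
#'   errors per base per duplication. The effective rate of the barcoding
#'   enzyme is `taq_error_rate / fidelity`.
#' @param fidelity fidelity multiplier (relative to Taq, >= 1) of the
#'   barcoding-PCR enzyme
#' @param adapter_fidelity fidelity multiplier of the adapter-PCR enzyme
#'   (default 100, i.e. an ultra-high-fidelity enzyme)
#' @param cycle1_error_rate optional override of the error rate used in the
#'   first barcoding cycle only (`NULL` = use `taq_error_rate / fidelity`).
#'   First-cycle errors are inherited by the whole barcode family and are
#'   flagged as uncorrectable ground truth.
#' @param barcoding_cycles number of barcoding PCR cycles (>= 1)
#' @param adapter_cycles number of adapter PCR cycles (>= 0)
#' @param barcoding_efficiency per-molecule per-cycle amplification
#'   probability during the barcoding PCR; also the probability that a
#'   template is successfully primed and founds a barcode family
#' @param family_efficiency adapter-PCR per-family efficiency model: either a
#'   preset name (`"low_bias"` = Beta(50, 5), `"high_bias"` = Beta(2, 1)) or a
#'   numeric `c(shape1, shape2)` of a Beta distribution
#' @param seq_error_rate sequencer substitution probability per sequenced base
#' @param read_length sequenced read length (bases)
#' @param n_templates haploid genome copies per amplicon entering the
#'   barcoding reaction
#' @param vaf_spec `NULL`, or a data.frame with columns `amplicon`, `pos`,
#'   `alt`, `vaf` describing spiked variants (positions must be panel targets
#'   or valid insert positions)
#' @param vaf_mode `"binomial"` (each template is a variant with probability
#'   VAF) or `"fixed"` (exactly `round(n_templates * vaf)` variant templates)
#' @param tandem_spec `NULL`, or a data.frame with columns `amplicon`, `pos`,
#'   `to` (2-base string), `rate`: dinucleotide damage placed on templates
#'   before any PCR (e.g. CA->TT tandem changes)
#' @param depth total number of reads to sample from the final pool
#'   (`NULL` = 15 reads per founded family on average)
#' @param materialize adapter-PCR molecule tracking: `"auto"` materialises
#'   every molecule when the expected final pool is small (<= 2e5), `"always"`
#'   forces full tracking, `"never"` uses the count-level model
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output
#' @return object of class `sim_config`
#' @export
sim_config <- function(taq_error_rate = 1e-4,
                       fidelity = 1,
                       adapter_fidelity = 100,
                       cycle1_error_rate = NULL,
                       barcoding_cycles = 3L,
                       adapter_cycles = 25L,
                       barcoding_efficiency = 0.9,
                       family_efficiency = "low_bias",
                       seq_error_rate = 0.001,
                       read_length = 150L,
                       n_templates = 1000L,
                       vaf_spec = NULL,
                       vaf_mode = c("binomial", "fixed"),
                       tandem_spec = NULL,
                       depth = NULL,
                       materialize = c("auto", "always", "never"),
                       seed = 1L) {
  vaf_mode <- match.arg(vaf_mode)
  materialize <- match.arg(materialize)
  check_prob(barcoding_efficiency, "barcoding_efficiency")
  check_prob(seq_error_rate, "seq_error_rate")
  check_prob(taq_error_rate, "taq_error_rate")
  if (!is.null(cycle1_error_rate)) check_prob(cycle1_error_rate,
                                              "cycle1_error_rate")
  if (fidelity < 1) stopf("'fidelity' must be >= 1 (Taq = 1)")
  if (adapter_fidelity < 1) stopf("'adapter_fidelity' must be >= 1")
  barcoding_cycles <- check_count(barcoding_cycles, "barcoding_cycles", 1L)
  adapter_cycles <- check_count(adapter_cycles, "adapter_cycles", 0L)
  n_templates <- check_count(n_templates, "n_templates", 1L)
  read_length <- check_count(read_length, "read_length", 1L)
  seed <- check_count(seed, "seed")
  if (is.character(family_efficiency)) {
    family_efficiency <- switch(
      family_efficiency,
      low_bias = c(50, 5),
      high_bias = c(2, 1),
      stopf("unknown family_efficiency preset '%s'", family_efficiency))
  }
  stopifnot(is.numeric(family_efficiency), length(family_efficiency) == 2L,
            all(family_efficiency > 0))
  if (!is.null(vaf_spec)) {
    vaf_spec <- as.data.table(vaf_spec)
    stopifnot(all(c("amplicon", "pos", "alt", "vaf") %in% names(vaf_spec)))
    if (any(vaf_spec$vaf < 0 | vaf_spec$vaf > 1))
      stopf("VAF values must be in [0, 1]")
  }
  if (!is.null(tandem_spec)) {
    tandem_spec <- as.data.table(tandem_spec)
    stopifnot(all(c("amplicon", "pos", "to", "rate") %in% names(tandem_spec)))
    if (any(nchar(tandem_spec$to) != 2L))
      stopf("tandem_spec$to must be 2-base strings")
  }
  structure(list(
    taq_error_rate = taq_error_rate,
    fidelity = fidelity,
    adapter_fidelity = adapter_fidelity,
    cycle1_error_rate = cycle1_error_rate,
    barcoding_cycles = barcoding_cycles,
    adapter_cycles = adapter_cycles,
    barcoding_efficiency = barcoding_efficiency,
    family_efficiency = family_efficiency,
    seq_error_rate = seq_error_rate,
    read_length = read_length,
    n_templates = n_templates,
    vaf_spec = vaf_spec,
    vaf_mode = vaf_mode,
    tandem_spec = tandem_spec,
    depth = depth,
    materialize = materialize,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d templates/amplicon, %d+%d cycles, taq %.2g (fidelity %gx barcoding / %gx adapter), seq %.2g, seed %d\n",
    x$n_templates, x$barcoding_cycles, x$adapter_cycles, x$taq_error_rate,
    x$fidelity, x$adapter_fidelity, x$seq_error_rate, x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param config a [sim_config()]
#' @param file path to a YAML file
#' @export
write_sim_config <- function(config, file) {
  obj <- unclass(config)
  obj$vaf_spec <- if (!is.null(obj$vaf_spec)) as.data.frame(obj$vaf_spec)
  obj$tandem_spec <- if (!is.null(obj$tandem_spec))
    as.data.frame(obj$tandem_spec)
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  obj <- yaml::read_yaml(file)
  if (!is.null(obj$vaf_spec)) obj$vaf_spec <- as.data.frame(obj$vaf_spec)
  if (!is.null(obj$tandem_spec))
    obj$tandem_spec <- as.data.frame(obj$tandem_spec)
  obj$family_efficiency <- unlist(obj$family_efficiency)
  do.call(sim_config, obj)
}
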