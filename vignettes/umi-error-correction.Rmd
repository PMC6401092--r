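---
title: "Barcode-consensus error correction: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-consensus error correction: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umiconsensus)
```

## The problem

Detecting single-nucleotide variants below ~0.1% allele frequency in
amplicon sequencing is limited not by depth but by background error:
polymerase misincorporations during library construction, DNA damage, and
sequencer miscalls all masquerade as low-frequency variants. Unique
molecular identifiers (UMIs, "barcodes") attached to individual template
molecules let every read be traced back to its founder molecule; aligning
the reads of one barcode family and requiring near-unanimity removes every
error that arose *after* the barcode was attached. What survives is the
error floor this package is built to study: errors from the very first
barcoding-PCR cycle (inherited by the entire family) and template damage.

`umiconsensus` implements the full analysis chain — structural read
validation, primer-anchored alignment, barcode-family grouping,
family-size-dependent consensus calling, raw/consensus error profiling,
and background-based variant detection — together with a generative
simulator of barcoded library construction, so every stage can be tested
at desk scale against a fully known ground truth.

## The generative model

The simulator follows the library-construction chain of a hairpin-protected
barcoding protocol:

1. **Templates.** Per amplicon, `n_templates` haploid genome copies.
   Spiked variants are assigned per template either binomially with
   probability VAF or as an exact `round(n * vaf)` count. Optional
   dinucleotide ("tandem") damage can be placed on templates before any
   PCR to emulate damage-like artifacts that no consensus threshold can
   remove.
2. **Barcoding PCR** (default 3 cycles). Each template is successfully
   primed with probability `barcoding_efficiency` and founds one barcode
   family under a random 12-mer drawn uniformly from the 4^12 space. The
   founder copy is synthesised in cycle 1; strands then duplicate per cycle
   with the same efficiency, giving the familiar doubling tree (2^(c-1)
   strands per family at full efficiency, synthesis depths {1,2,2,3} for
   c = 3). Every newly synthesised strand acquires substitutions at
   `taq_error_rate / fidelity` per base over the *whole* construct —
   barcode, anchors, insert and tail — so barcode hits found spurious
   singleton families and anchor hits cost reads at parsing, as in real
   data. Cycle-1 events are flagged as uncorrectable ground truth.
3. **Adapter PCR** (default 25 cycles). Each family draws one
   amplification efficiency from a Beta distribution — the bias model. The
   presets `low_bias` Beta(50, 5) and `high_bias` Beta(2, 1) have very
   different shapes: after 25 cycles a family's yield scales as
   (1+e)^25, so a heavy low-efficiency tail translates into orders of
   magnitude of yield spread and, at matched sequencing depth, into
   starved barcode families.
4. **Sequencing.** `depth` reads are sampled multinomially from the final
   pool; each base flips to a uniformly chosen different base with
   probability `seq_error_rate` (default 1e-3). Quality strings are a
   constant "I"; read names encode the ground-truth lineage.

### Fidelity as thinning (coupled sweeps)

Polymerase errors are drawn in two steps: candidate events at the Taq base
rate, each *kept* with probability `1/fidelity`. The kept set has exactly
the Binomial(L, rate/fidelity) law the model calls for, but because the
candidate stream does not depend on fidelity, two runs that share a seed
and differ only in fidelity see **nested** error sets. A fidelity sweep at
a fixed seed is therefore exactly coupled: consensus error is
non-increasing in fidelity by construction, and arm differences are not
clouded by Monte-Carlo noise. This is the package's realisation of a
"fixed seeds" sweep and is what makes desk-scale monotonicity checks
decisive.

### The count-level adapter model

Materialising 2^25 molecules per family is neither feasible nor
informative. By default (`materialize = "never"`/"auto" at realistic cycle
counts) the adapter PCR tracks exact per-strand descendant counts by
branching simulation, and adapter-polymerase errors are drawn per *sampled
read* from its lineage-depth law, depth ~ Binomial(cycles, e/(1+e)). This
drops the within-family correlation of adapter errors: two reads of one
family can no longer share an adapter-PCR error. At the 90%/100% consensus
thresholds a shared adapter error would need to reach >= 90% of a family
of >= 10 reads — an event whose probability is negligible (of order
10^-20 at default rates) — so the approximation does not affect any
quantity the package reports. A fully materialised mode exists
(`materialize = "always"`) and is used in the tests for the small-pool
molecule-count identities and ground-truth consistency.

### What the simulator does not model

Polymerase processivity, GC-dependent efficiency, chimera formation,
hairpin secondary-structure kinetics, sequencer indels, paired-end reads,
and per-cycle efficiency drift are all out of scope. Passing tests
therefore demonstrate the correctness of the error-correction logic under
a substitution-dominated noise model, not the full messiness of real
libraries; in particular, real consensus error floors include DNA damage,
which here appears only if tandem damage is explicitly configured.

## The analysis chain

**Validation.** A read is valid when its hairpin-stem and targeting-primer
segments match exactly one panel amplicon with at most
`max_anchor_mismatches` (default 1) each; the leading 12-mer is its
barcode. Failures carry exactly one reason (`short_read`,
`invalid_barcode`, `no_anchor`, `ambiguous_amplicon`, `unalignable`), and
counts always conserve the input. Barcodes containing N are rejected.
Reads are single-end in fixed orientation; reverse-complement scanning is
not performed.

**Alignment.** The insert is aligned to the amplicon reference by banded
global Needleman-Wunsch (match +1, mismatch -1, gap -2, band 10), with
ties broken diagonal-first, then deletion, then insertion. Equal-length
inserts with at most 2 mismatches are called positionally: with these
scores any alignment containing a gap pair scores at most L-5 < L-2k for
k <= 2, so the gap-free alignment is provably the unique optimum and the
dynamic program is only run for the rare remainder. Insertions are
recorded separately; per reference position there is exactly one call in
{A, C, G, T, deletion}. Coordinates are 1-based in all reports.

**Families and consensus.** Families are exact groups on
(amplicon, barcode): no merging, no UMI network correction — barcodes at
edit distance 1 stay distinct. The default consensus dialect
(`rule = "methods"`) reports a non-reference base when it composes 100% of
reads in families of 10–20 reads ("10–20" inclusive on both ends) or at
least 90% in families of more than 20; the alternative dialect
(`rule = "simple90"`) applies >= 90% at every family of at least 10 reads.
Both appear in practice and the choice is explicit. When the threshold is
unmet the consensus call is the reference base (not N, not the modal
base), matching the framing of error as non-reference content. Ties
between two non-reference bases fall back to the reference; at the >= 90%
thresholds a tie cannot satisfy the rule anyway. Insertions are kept as
metadata but excluded from per-position flags, so spectra enumerate base
changes and deletions only. The floor of 10 reads ("consensus_10") is the
default and configurable.

**Error statistics.** Error frequencies are per-base-call fractions
(count/depth); report writers express them as percentages. Fold reduction
of consensus over raw error uses a pseudo-count of 0.5 flagged calls when
the consensus cell is exactly zero and flags the value as censored — small
simulations regularly produce zero surviving consensus errors, and an
honest "at least x-fold" beats an infinity. Relative consensus depth
divides each arm's per-amplicon count by the mean over the arms being
compared. The Wilcoxon signed-rank and Spearman utilities are implemented
from first principles (exact sign-flip convolution over doubled mid-ranks
for n <= 25; exact permutation p for n <= 8) and are cross-checked in the
tests against full-enumeration oracles and against base R; no multiple
testing correction is applied by default. Factorial depth comparisons
(two-way ANOVA with post hoc contrasts) are deliberately left to standard
statistical tooling rather than wrapped here.

**Detection.** The visual criterion "clearly seen above background" is
formalised as: detected iff the target's consensus alternate VAF exceeds
the maximum consensus non-reference frequency over all non-target
positions of the panel *and* the alternate count reaches
`min_alt_count = 3`; a one-sided Poisson tail score under the mean
background rate is reported alongside, so users can substitute their own
rule. Known recurrent-artifact positions can be excluded from the
background. Detection operates on consensus profiles only. The
copy-number helper converts mass x VAF into expected mutant copies at 278
haploid genomes per ng; both unrounded and rounded values are reported
because published round-offs differ from the raw arithmetic.

## Defaults and their rationale

| parameter | default | why |
|---|---|---|
| `taq_error_rate` | 1e-4 /base/duplication | order-of-magnitude literature value for Taq; all comparisons here are relative |
| `fidelity` | 1 (barcoding), 100 (adapter) | Taq-relative scale; the adapter arm is run with an ultra-high-fidelity enzyme |
| `barcoding_cycles` | 3 | the barcoding protocol's short first PCR |
| `adapter_cycles` | 25 | typical second-round amplification; unstated in protocols, configurable |
| `barcoding_efficiency` | 0.9 | a well-behaved triplex assay; also the priming probability |
| `family_efficiency` | Beta(50, 5) | "low bias" enzyme; `high_bias` Beta(2, 1) models a biased one |
| `seq_error_rate` | 1e-3 /base | substitution-dominated short-read noise |
| `read_length` | 150 | single-end 150 bp layout |
| `min_family_size` | 10 | the consensus_10 convention |
| `min_alt_count` | 3 | a single consensus family is never called a variant |

One modelling consequence worth stating explicitly: every sequenced read
passes through at least one barcoding synthesis event (the cycle-1 founder
copy) and on average about two, so the PCR contribution to *raw* error is
roughly `2 x taq_error_rate / fidelity` per base. With the defaults
(seq 1e-3, taq 1e-4) that contribution is ~20% of the raw error at
fidelity 1, and a fidelity sweep moves raw error by about that much.
Raw-error insensitivity to fidelity — in the sense of a <10% relative
spread — holds once sequencer noise dominates the *lineage* PCR burden by
an order of magnitude (e.g. seq error >= 2.5e-3 at taq 1e-4), and the test
suite demonstrates it under that condition.

## Problem sizes used in the checks

The shipped experiments are scaled for a single CPU: the
sequencer-suppression check uses ~10,600 consensus families (~238,000
reads); the fidelity sweep 2 seeds x 5 arms of ~4,300 families; the bias
comparison 20 seed-pairs of ~1,080 families; the detection-power series 20
seeds per VAF with 8,000 KIT templates (~130,000 reads each), chosen so
the three dilution arms sit at clearly separated expected mutant-family
counts (~7, ~3.5, ~1.75) while the VAF-0 arm stays at zero. The analysis
scripts under `analysis/` use the same machinery at similar sizes and
write their tables under `results/`.

## Worked example

```{r example}
panel <- default_panel()
cfg <- sim_config(fidelity = 9, n_templates = 600, depth = 24000,
                  seed = 42,
                  vaf_spec = data.frame(amplicon = "KIT", pos = 6,
                                        alt = "T", vaf = 0.02))
pl <- run_pipeline(panel, cfg)
pl
head(pl$cons_profile[order(-freq)], 3)
detect_variants(pl$cons_profile, panel)[, .(amplicon, pos, alt_count,
                                            depth, observed_vaf, detected)]
```

## Known limitations

* The simulator's independence approximation for adapter errors (above)
  makes coordinated adapter artifacts impossible rather than merely
  astronomically rare.
* Spiked indels and sequencer indels are not generated; the aligner and
  consensus caller handle deletion calls, but indel-rich data would
  require widening the insert extraction window.
* One barcode per successfully primed template: the real 3-cycle protocol
  can found several families per template. Family multiplicity dilutes
  depth but does not change the consensus logic under test.
* Detection treats the panel background as exchangeable across positions;
  sequence-context-specific error models are out of scope.
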