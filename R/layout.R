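# Constant downstream filler appended after the insert so that a single-end
# read of the configured length is always fully defined (in the real library
# this region is the reverse primer plus sequencing adapter).
DEFAULT_TAIL <- paste0(
  "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACGTACTGACCT",
  "GAACTCCAGTCACATCACGATCTCGTATGCCGTCTTCTGCTTGAAAAAA",
  "CGTATGCCGTCTTCTGCTTGAAAAAACGTATGCCGTCTTCTGCTTG"
)

#' Read layout
#'
#' Describes the structural layout every read is expected to follow:
#' a 12-mer barcode at the 5' end, then the amplicon-specific hairpin stem,
#' then the targeting primer, then the insert, then a constant tail. The
#' stem and primer act as anchors that identify the amplicon.
#'
#' @param panel an [amplicon_panel()]
#' @param barcode_length barcode length in bases (12)
#' @param max_anchor_mismatches mismatches tolerated in each anchor segment
#' @param read_length sequenced read length in bases
#' @param tail constant filler sequence appended after the insert
#' @return object of class `read_layout`
#' @export
read_layout <- function(panel, barcode_length = 12L,
                        max_anchor_mismatches = 1L,
                        read_length = 150L, tail = DEFAULT_TAIL) {
  barcode_length <- check_count(barcode_length, "barcode_length", 1L)
  max_anchor_mismatches <- check_count(max_anchor_mismatches,
                                       "max_anchor_mismatches", 0L)
  read_length <- check_count(read_length, "read_length", 1L)
  stem_start <- barcode_length + 1L
  primer_start <- stem_start + nchar(panel$stem)
  insert_start <- primer_start + nchar(panel$primer)
  core_len <- insert_start + panel$insert_len - 1L
  if (read_length < max(core_len))
    stopf("read_length %d is shorter than the layout overhead plus the %s insert (%d bases)",
          read_length, panel$amplicon[which.max(core_len)], max(core_len))
  if (min(core_len) + nchar(tail) < read_length)
    stopf("tail too short: core (%d) + tail (%d) < read_length %d",
          min(core_len), nchar(tail), read_length)
  structure(list(
    barcode_length = barcode_length,
    max_anchor_mismatches = max_anchor_mismatches,
    read_length = read_length,
    tail = tail,
    amplicon = panel$amplicon,
    stem = panel$stem,
    primer = panel$primer,
    stem_start = stem_start,
    primer_start = primer_start,
    insert_start = insert_start,
    insert_len = panel$insert_len,
    core_len = core_len
  ), class = "read_layout")
}

# Full construct (core + tail) length for each amplicon; the construct is what
# the polymerase copies, so PCR errors are drawn over this length. Constructs
# are truncated/padded so that they are exactly long enough to render a read.
construct_length <- function(layout) {
  pmax(layout$core_len + nchar(layout$tail), layout$read_length)
}

# Render the error-free construct for given amplicon indices and parts.
render_construct <- function(layout, amp_idx, barcode, insert) {
  core <- paste0(barcode, layout$stem[amp_idx], layout$primer[amp_idx], insert)
  full <- paste0(core, layout$tail)
  substr(full, 1L, construct_length(layout)[amp_idx])
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("read layout: %d-mer barcode | stem | primer | insert | tail; %d bp reads\n",
              x$barcode_length, x$read_length))
  for (i in seq_along(x$amplicon))
    cat(sprintf("  %-8s stem %d bp, primer %d bp, insert %d bp (read pos %d-%d)\n",
                x$amplicon[i], nchar(x$stem[i]), nchar(x$primer[i]),
                x$insert_len[i], x$insert_start[i],
                x$insert_start[i] + x$insert_len[i] - 1L))
  invisible(x)
}
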