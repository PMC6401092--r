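#' Amplicon panel definition
#'
#' An amplicon panel describes, per assay: the reference insert sequence (the
#' bases interrogated for errors and variants), the targeting primer and
#' hairpin-stem anchor sequences that sit between the 12-mer barcode and the
#' insert on every read, a genomic coordinate for reporting, and the target
#' variant position(s) with their expected alternate base.
#'
#' @param id character vector of unique amplicon identifiers
#' @param insert reference insert sequences (A/C/G/T only)
#' @param primer targeting-primer anchor sequences
#' @param stem hairpin-stem anchor sequences
#' @param chrom,insert_start genomic location of the first insert base
#'   (reporting only; 1-based)
#' @param targets a data.frame with columns `amplicon`, `pos` (1-based insert
#'   position), `ref`, `alt` listing the expected variants, or `NULL`
#' @return an object of class `amplicon_panel` (a data.table, one row per
#'   amplicon, with the target table in `attr(, "targets")`)
#' @export
amplicon_panel <- function(id, insert, primer, stem,
                           chrom = NA_character_, insert_start = NA_integer_,
                           targets = NULL) {
  if (anyDuplicated(id)) stopf("amplicon ids must be unique")
  for (s in c(insert, primer, stem)) {
    if (grepl("[^ACGT]", s)) stopf("panel sequences must be over {A,C,G,T}")
  }
  panel <- data.table(
    amplicon = as.character(id),
    insert = as.character(insert),
    primer = as.character(primer),
    stem = as.character(stem),
    insert_len = nchar(insert),
    chrom = chrom,
    insert_start = as.integer(insert_start)
  )
  if (is.null(targets)) {
    targets <- data.table(amplicon = character(0), pos = integer(0),
                          ref = character(0), alt = character(0))
  } else {
    targets <- as.data.table(targets)
    stopifnot(all(c("amplicon", "pos", "alt") %in% names(targets)))
    bad <- !targets$amplicon %in% panel$amplicon
    if (any(bad)) stopf("target amplicon '%s' not in panel",
                        targets$amplicon[bad][1])
    len <- panel$insert_len[match(targets$amplicon, panel$amplicon)]
    if (any(targets$pos < 1L | targets$pos > len))
      stopf("target position outside insert bounds")
    ref <- substr(panel$insert[match(targets$amplicon, panel$amplicon)],
                  targets$pos, targets$pos)
    if (!is.null(targets$ref) && any(targets$ref != ref))
      stopf("target ref base disagrees with the insert sequence")
    targets <- data.table(amplicon = targets$amplicon,
                          pos = as.integer(targets$pos),
                          ref = ref, alt = as.character(targets$alt))
  }
  setattr(panel, "targets", targets)
  setattr(panel, "class", c("amplicon_panel", class(panel)))
  panel[]
}

#' Target variant table of a panel
#' @param panel an [amplicon_panel()]
#' @return data.table with columns amplicon, pos, ref, alt
#' @export
panel_targets <- function(panel) attr(panel, "targets")

#' Built-in synthetic three-amplicon panel
#'
#' A synthetic stand-in for a triplex hotspot panel targeting BRAF V600E,
#' KIT D816V and PIK3CA H1047R. Insert sequences are built around the real
#' hotspot codons with base composition chosen so that the KIT and PIK3CA
#' inserts are A-rich and the BRAF insert is T-heavier; primer and hairpin
#' stem sequences are invented. The three inserts cover 59 bases in total.
#'
#' @return an [amplicon_panel()] with amplicons `BRAF`, `KIT`, `PIK3CA`
#' @export
default_panel <- function() {
  amplicon_panel(
    id = c("BRAF", "KIT", "PIK3CA"),
    insert = c(
      "CTACAGTGAAATCTCGATGG",   # codon 600 GTG at 6-8; V600E = T>A at pos 7
      "CAGAGACATCAAGAATGAT",    # codon 816 GAC at 5-7; D816V = A>T at pos 6
      "TGCACATCATGAAATAAACA"    # codon 1047 CAT at 5-7; H1047R = A>G at pos 6
    ),
    primer = c("GGTGATTTTGGTCTAGCT",
               "AGTTCAGCGGATCACAAT",
               "CAAAGCAATTTCTACACG"),
    stem = c("ACGCTGAGTC", "TCGAGCATGT", "GATCCGTAAC"),
    chrom = c("chr7", "chr4", "chr3"),
    insert_start = c(140453130L, 55599250L, 178952070L),
    targets = data.frame(
      amplicon = c("BRAF", "KIT", "PIK3CA"),
      pos = c(7L, 6L, 6L),
      alt = c("A", "T", "G")
    )
  )
}

#' Write / read a panel as a YAML file
#'
#' @param panel an [amplicon_panel()]
#' @param file path to a YAML file
#' @export
write_panel <- function(panel, file) {
  tg <- panel_targets(panel)
  obj <- lapply(seq_len(nrow(panel)), function(i) {
    a <- panel$amplicon[i]
    t <- tg[tg$amplicon == a]
    list(id = a, insert = panel$insert[i], primer = panel$primer[i],
         stem = panel$stem[i], chrom = panel$chrom[i],
         insert_start = panel$insert_start[i],
         targets = if (nrow(t)) lapply(seq_len(nrow(t)), function(j)
           list(pos = t$pos[j], ref = t$ref[j], alt = t$alt[j])) else list())
  })
  yaml::write_yaml(list(amplicons = obj), file)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  obj <- yaml::read_yaml(file)$amplicons
  tg <- rbindlist(lapply(obj, function(a) {
    if (length(a$targets) == 0) return(NULL)
    data.table(amplicon = a$id,
               pos = vapply(a$targets, function(t) as.integer(t$pos), 1L),
               alt = vapply(a$targets, function(t) t$alt, ""))
  }))
  amplicon_panel(
    id = vapply(obj, `[[`, "", "id"),
    insert = vapply(obj, `[[`, "", "insert"),
    primer = vapply(obj, `[[`, "", "primer"),
    stem = vapply(obj, `[[`, "", "stem"),
    chrom = vapply(obj, function(a) a$chrom %||% NA_character_, ""),
    insert_start = vapply(obj, function(a)
      as.integer(a$insert_start %||% NA_integer_), 1L),
    targets = if (nrow(tg)) tg else NULL
  )
}
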