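#' Write reads to a FASTQ file
#'
#' @param reads a `sim_reads` table (or any data.frame with `read_id`, `seq`
#'   and optionally `qual` columns)
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  rec <- rbind(paste0("@", reads$read_id), reads$seq, "+", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rec), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; qualities are not
#' retained (the pipeline does not use them).
#'
#' @param path a FASTQ file, plain or gzip
#' @return data.table with columns `read_id`, `seq`
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = names(x), seq = as.character(x))
}

#' Write the ground-truth table of a simulated library as TSV
#'
#' One row per read: lineage identifiers plus a compact encoding of the
#' read's cycle-labelled PCR error list and its sequencer flips
#' (`cycle:pos:from>to` and `pos:from>to`, `;`-separated, construct/read
#' coordinates).
#'
#' @param sim a `sim_library`
#' @param path output TSV path
#' @export
write_ground_truth <- function(sim, path) {
  truth <- copy(attr(sim$reads, "truth"))
  ev <- attr(sim$reads, "events")
  pcr <- ev$pcr[, .(s = paste(sprintf("%d:%d:%s>%s", cycle, pos, from, to),
                              collapse = ";")), by = read_id]
  sq <- ev$sequencer[, .(s = paste(sprintf("%d:%s>%s", pos, from, to),
                                   collapse = ";")), by = read_id]
  truth[, pcr_errors := pcr$s[match(read_id, pcr$read_id)]]
  truth[, seq_errors := sq$s[match(read_id, sq$read_id)]]
  data.table::fwrite(truth, path, sep = "\t", na = "")
  invisible(path)
}
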