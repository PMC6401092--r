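#' Group valid reads into barcode families
#'
#' Families are exact groups on the (amplicon, barcode) pair: no barcode
#' error correction or merging is performed, so barcodes at edit distance 1
#' form distinct families. The sum of family sizes equals the number of
#' valid reads.
#'
#' @param valid a `valid_reads` object from [parse_reads()]
#' @return object of class `barcode_families`: `$families` (family_id,
#'   amplicon, barcode, size) plus the valid reads annotated with their
#'   family
#' @export
group_families <- function(valid) {
  reads <- copy(valid$reads)
  if (nrow(reads)) {
    reads[, family_id := .GRP, by = .(amplicon, barcode)]
    families <- reads[, .(amplicon = amplicon[1L], barcode = barcode[1L],
                          size = .N), by = family_id]
  } else {
    families <- data.table(family_id = integer(0), amplicon = character(0),
                           barcode = character(0), size = integer(0))
  }
  structure(list(reads = reads[], families = families[],
                 calls = valid$calls, panel = valid$panel,
                 layout = valid$layout),
            class = "barcode_families")
}

# The family-size-dependent non-reference rule, on integer counts.
# rule "methods": sizes 10-20 (inclusive) require 100% agreement, sizes > 20
# require >= 90%; rule "simple90": >= 90% for every family >= the size floor.
consensus_rule_met <- function(count, size, rule) {
  if (rule == "methods") {
    (size <= 20L & count == size) | (size > 20L & count * 10L >= size * 9L)
  } else {
    count * 10L >= size * 9L
  }
}

#' Call the consensus of a single barcode family
#'
#' Reference implementation operating on one family. Per position the modal
#' non-reference call (including deletion) is reported if its fraction of the
#' family satisfies the size-dependent rule; otherwise the consensus call is
#' the reference base. Ties between two non-reference calls fall back to the
#' reference.
#'
#' @param calls the family's reads: a character matrix (one row per read, one
#'   column per reference position, over A/C/G/T/-) or a character vector of
#'   aligned read sequences
#' @param reference the amplicon reference insert
#' @param min_family_size families below this size return `NULL`
#'   (the consensus_10 floor)
#' @param rule `"methods"` (100% for sizes 10-20, >= 90% above 20) or
#'   `"simple90"` (>= 90% for every family at or above the floor)
#' @return `NULL`, or a list with `consensus` (character vector),
#'   `nonref` (logical flags), `variant_base_count` and `family_size`
#' @export
call_family_consensus <- function(calls, reference, min_family_size = 10L,
                                  rule = c("methods", "simple90")) {
  rule <- match.arg(rule)
  if (is.character(calls) && is.null(dim(calls)))
    calls <- seq_char_matrix(calls, nchar(reference))
  size <- nrow(calls)
  if (size < min_family_size) return(NULL)
  L <- nchar(reference)
  stopifnot(ncol(calls) == L)
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  cons <- ref
  flag <- logical(L)
  for (j in seq_len(L)) {
    tab <- table(calls[, j])
    tab <- tab[names(tab) != ref[j]]
    if (length(tab) == 0L) next
    best <- max(tab)
    if (sum(tab == best) > 1L) next        # tie -> reference
    if (consensus_rule_met(as.integer(best), size, rule)) {
      cons[j] <- names(tab)[which.max(tab)]
      flag[j] <- TRUE
    }
  }
  list(consensus = cons, nonref = flag,
       variant_base_count = sum(flag), family_size = size)
}

#' Call consensus reads for all families
#'
#' Vectorised consensus calling over every barcode family of at least
#' `min_family_size` reads (the "consensus_10" set for the default floor of
#' 10). Agrees exactly with [call_family_consensus()] applied per family.
#'
#' @param fams a `barcode_families` object from [group_families()]
#' @inheritParams call_family_consensus
#' @return object of class `consensus_reads`: `$families` (family_id,
#'   amplicon, barcode, size, variant_base_count), `$calls` and `$flags`
#'   (per-amplicon matrices, one row per consensus read)
#' @export
call_consensus <- function(fams, min_family_size = 10L,
                           rule = c("methods", "simple90")) {
  rule <- match.arg(rule)
  panel <- fams$panel
  out_fam <- list(); out_calls <- list(); out_flags <- list()
  for (a in panel$amplicon) {
    L <- panel$insert_len[panel$amplicon == a]
    rr <- match(strsplit(panel$insert[panel$amplicon == a], "",
                         fixed = TRUE)[[1]], CALL_LEVELS)
    rd <- fams$reads[amplicon == a]
    keep_fam <- fams$families[amplicon == a & size >= min_family_size]
    if (nrow(keep_fam) == 0L) {
      out_fam[[a]] <- keep_fam[, .(family_id, amplicon, barcode, size,
                                   variant_base_count = integer(0))]
      out_calls[[a]] <- matrix(integer(0), 0L, L)
      out_flags[[a]] <- matrix(FALSE, 0L, L)
      next
    }
    rd <- rd[family_id %in% keep_fam$family_id]
    fidx <- match(rd$family_id, keep_fam$family_id)
    M <- fams$calls[[a]][rd$row, , drop = FALSE]
    Fn <- nrow(keep_fam)
    sizes <- keep_fam$size
    grp <- factor(fidx, levels = seq_len(Fn))
    best <- matrix(-1L, Fn, L)
    arg <- matrix(0L, Fn, L)
    nties <- matrix(0L, Fn, L)
    for (b in seq_along(CALL_LEVELS)) {
      Cb <- rowsum((M == b) + 0L, grp)
      Cb[, rr == b] <- 0L
      upd <- Cb > best
      arg[upd] <- b
      best[upd] <- Cb[upd]
      # recount ties at the (possibly new) maximum
      nties <- (nties * (!upd)) + (Cb == best)
    }
    met <- consensus_rule_met(best, matrix(sizes, Fn, L), rule)
    flag <- met & best > 0L & nties == 1L
    cons <- matrix(rr, Fn, L, byrow = TRUE)
    cons[flag] <- arg[flag]
    keep_fam[, variant_base_count := rowSums(flag)]
    out_fam[[a]] <- keep_fam
    out_calls[[a]] <- cons
    out_flags[[a]] <- flag
  }
  fam_all <- rbindlist(out_fam)
  if (nrow(fam_all)) fam_all[, row := seq_len(.N), by = amplicon]
  else fam_all[, row := integer(0)]
  structure(list(families = fam_all[], calls = out_calls,
                 flags = out_flags, panel = panel, layout = fams$layout,
                 rule = rule, min_family_size = as.integer(min_family_size)),
            class = "consensus_reads")
}

#' Consensus sequencing depth per amplicon
#'
#' @param cons a `consensus_reads` object
#' @return data.table with the number of consensus reads per amplicon
#' @export
consensus_depth <- function(cons) {
  base <- data.table(amplicon = cons$panel$amplicon)
  n <- cons$families[, .N, by = amplicon]
  base[, n_consensus := ifelse(is.na(match(amplicon, n$amplicon)), 0L,
                               n$N[match(amplicon, n$amplicon)])]
  base[]
}

#' Relative consensus depths across experimental arms
#'
#' Divides each arm's per-amplicon consensus depth by the mean depth of that
#' amplicon over all arms in the comparison (the unitless cross-arm view).
#'
#' @param arms a named list of `consensus_reads` objects
#' @return data.table with columns arm, amplicon, n_consensus, relative
#' @export
relative_consensus_depth <- function(arms) {
  stopifnot(is.list(arms), !is.null(names(arms)))
  dt <- rbindlist(lapply(names(arms), function(nm)
    cbind(arm = nm, consensus_depth(arms[[nm]]))))
  dt[, relative := n_consensus / mean(n_consensus), by = amplicon]
  dt[]
}

#' Write consensus reads as TSV
#'
#' Columns: amplicon, barcode, family_size, consensus sequence (deletions as
#' `-`), and the 1-based flagged (non-reference) positions.
#'
#' @param cons a `consensus_reads` object
#' @param path output path
#' @export
write_consensus_tsv <- function(cons, path) {
  rows <- lapply(cons$panel$amplicon, function(a) {
    f <- cons$families[amplicon == a]
    if (nrow(f) == 0L) return(NULL)
    M <- cons$calls[[a]][f$row, , drop = FALSE]
    seqs <- apply(M, 1L, function(r) paste(CALL_LEVELS[r], collapse = ""))
    flags <- apply(cons$flags[[a]][f$row, , drop = FALSE], 1L,
                   function(r) paste(which(r), collapse = ","))
    data.table(amplicon = a, barcode = f$barcode, family_size = f$size,
               consensus = seqs, flagged_positions = flags)
  })
  data.table::fwrite(rbindlist(rows), path, sep = "\t")
  invisible(path)
}
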