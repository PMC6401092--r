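# Raw and consensus error profiles, substitution spectra and summaries.
#
# Error frequencies are per-base-call fractions (count / depth); report
# writers express them as percentages.

profile_from_matrix <- function(M, nonref_mask, panel, type) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    a <- panel$amplicon[i]
    L <- panel$insert_len[i]
    ref <- strsplit(panel$insert[i], "", fixed = TRUE)[[1]]
    m <- M[[a]]
    msk <- nonref_mask[[a]]
    depth <- rep(nrow(m), L)
    counts <- matrix(0L, length(CALL_LEVELS), L,
                     dimnames = list(CALL_LEVELS, NULL))
    if (nrow(m)) {
      for (b in seq_along(CALL_LEVELS)) {
        hit <- (m == b) & msk
        counts[b, ] <- colSums(hit)
      }
    }
    nonref <- colSums(counts)
    data.table(amplicon = a, pos = seq_len(L), ref = ref,
               depth = depth, nonref = as.integer(nonref),
               to_A = counts["A", ], to_C = counts["C", ],
               to_G = counts["G", ], to_T = counts["T", ],
               del = counts["-", ],
               freq = ifelse(depth > 0, nonref / depth, 0))
  })
  res <- rbindlist(out)
  setattr(res, "profile_type", type)
  setattr(res, "class", c("error_profile", class(res)))
  res[]
}

#' Raw per-position error profile
#'
#' Counts, per amplicon position, the calls differing from the reference
#' across all valid reads, with no family-based filtering, split by
#' substitution target base and deletion.
#'
#' @param valid a `valid_reads` object (or a `barcode_families` object)
#' @param panel the [amplicon_panel()]
#' @return data.table of class `error_profile` with columns amplicon, pos,
#'   ref, depth, nonref, to_A..to_T, del, freq
#' @export
raw_error_profile <- function(valid, panel = valid$panel) {
  M <- valid$calls
  # restrict to rows actually retained as valid reads
  rd <- if (inherits(valid, "barcode_families")) valid$reads else valid$reads
  M <- lapply(panel$amplicon, function(a)
    M[[a]][rd[amplicon == a]$row, , drop = FALSE])
  names(M) <- panel$amplicon
  mask <- nonref_masks(M, panel)
  profile_from_matrix(M, mask, panel, "raw")
}

#' Consensus per-position error profile
#'
#' Counts flagged non-reference consensus calls over the consensus depth,
#' split by substitution target base and deletion.
#'
#' @param cons a `consensus_reads` object
#' @param panel the [amplicon_panel()]
#' @return data.table of class `error_profile`
#' @export
consensus_error_profile <- function(cons, panel = cons$panel) {
  M <- cons$calls
  mask <- cons$flags
  profile_from_matrix(M, mask, panel, "consensus")
}

nonref_masks <- function(M, panel) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    rr <- match(strsplit(panel$insert[i], "", fixed = TRUE)[[1]],
                CALL_LEVELS)
    m <- M[[panel$amplicon[i]]]
    m != matrix(rr, nrow(m), length(rr), byrow = TRUE)
  })
  names(out) <- panel$amplicon
  out
}

#' Mean error frequency of a profile
#' @param profile an `error_profile`
#' @return mean of per-position frequencies (positions with zero depth
#'   excluded)
#' @export
mean_error <- function(profile) {
  p <- profile[depth > 0]
  if (nrow(p) == 0L) return(NA_real_)
  mean(p$freq)
}

#' Fold reduction of consensus over raw error
#'
#' Ratio of mean raw frequency to mean consensus frequency. Scopes: overall,
#' per amplicon, or per position. When the consensus error is exactly zero
#' the ratio is computed against a pseudo-count of 0.5 flagged calls over the
#' total consensus depth and the result is flagged `censored`; when both
#' terms are zero the ratio is reported as 1 with a `degenerate` flag.
#'
#' @param raw,cons `error_profile` objects over the same panel
#' @param scope `"overall"`, `"amplicon"` or `"position"`
#' @return data.table with columns scope id(s), raw_err, cons_err,
#'   fold_reduction, censored, degenerate
#' @export
fold_reduction <- function(raw, cons, scope = c("overall", "amplicon",
                                                "position")) {
  scope <- match.arg(scope)
  stopifnot(nrow(raw) == nrow(cons))
  by <- switch(scope, overall = character(0), amplicon = "amplicon",
               position = c("amplicon", "pos"))
  r <- copy(raw)[, cons_nonref := cons$nonref][, cons_depth := cons$depth]
  agg <- r[, .(raw_err = sum(nonref) / max(1, sum(depth)),
               cons_err = sum(cons_nonref) / max(1, sum(cons_depth)),
               cons_depth_total = sum(cons_depth)), by = by]
  agg[, degenerate := raw_err == 0 & cons_err == 0]
  agg[, censored := cons_err == 0 & !degenerate]
  agg[, fold_reduction := ifelse(
    degenerate, 1,
    raw_err / ifelse(cons_err > 0, cons_err,
                     0.5 / pmax(1, cons_depth_total)))]
  agg[, cons_depth_total := NULL]
  agg[]
}

#' Distribution of variant-base counts per consensus read
#'
#' Fraction of consensus reads carrying 0, 1, 2 or 3+ flagged
#' (non-reference) bases, per amplicon. Fractions sum to 1.
#'
#' @param cons a `consensus_reads` object
#' @return data.table with columns amplicon, n_variant_bases
#'   ("0","1","2","3+"), fraction
#' @export
variant_base_count_distribution <- function(cons) {
  f <- cons$families
  lev <- c("0", "1", "2", "3+")
  out <- lapply(cons$panel$amplicon, function(a) {
    x <- f[amplicon == a]$variant_base_count
    cat_ <- factor(ifelse(x >= 3L, "3+", as.character(x)), levels = lev)
    n <- length(x)
    data.table(amplicon = a, n_variant_bases = lev,
               fraction = if (n) as.vector(table(cat_)) / n else
                 rep(NA_real_, 4L))
  })
  rbindlist(out)
}

#' Substitution spectrum and base composition
#'
#' Per amplicon: the base composition of the reference strand, and the mean
#' error by substitution target base -- the fraction of base calls changed
#' to an A/C/G/T from any other base, plus deleted bases.
#'
#' @param profile an `error_profile` (typically the consensus profile)
#' @return list with `composition` (amplicon, base, fraction; fractions sum
#'   to 1 per amplicon) and `spectrum` (amplicon, change = errorA..errorT,
#'   errorD, rate)
#' @export
substitution_spectrum <- function(profile) {
  comp <- profile[, {
    tb <- table(factor(ref, levels = DNA_BASES))
    .(base = DNA_BASES, fraction = as.vector(tb) / sum(tb))
  }, by = amplicon]
  spec <- profile[, .(
    errorA = sum(to_A) / max(1, sum(depth)),
    errorC = sum(to_C) / max(1, sum(depth)),
    errorG = sum(to_G) / max(1, sum(depth)),
    errorT = sum(to_T) / max(1, sum(depth)),
    errorD = sum(del) / max(1, sum(depth))
  ), by = amplicon]
  spec <- melt(spec, id.vars = "amplicon", variable.name = "change",
               value.name = "rate")
  list(composition = comp[], spectrum = spec[])
}

#' Spearman correlation of per-position error frequencies
#'
#' Rank correlation (average ranks for ties) between the per-position error
#' frequencies of two profiles over the same panel positions.
#'
#' @param profile_a,profile_b `error_profile` objects over the same panel
#' @return list with `rho` and `p.value` (see [spearman_cor()])
#' @export
positionwise_correlation <- function(profile_a, profile_b) {
  stopifnot(nrow(profile_a) == nrow(profile_b),
            all(profile_a$amplicon == profile_b$amplicon),
            all(profile_a$pos == profile_b$pos))
  spearman_cor(profile_a$freq, profile_b$freq)
}

#' Paired per-position error comparison (Wilcoxon signed-rank)
#'
#' Compares two equal-length per-position error vectors with the
#' signed-rank test; zero differences are dropped (Wilcoxon convention).
#'
#' @param errors_a,errors_b numeric vectors of per-position error
#'   frequencies, equal length >= 6
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (for a; i.e.
#'   `"greater"` tests whether `errors_a` exceeds `errors_b`)
#' @return list with `statistic` (V), `p.value`, `n_used`, `method` and
#'   `degenerate` (TRUE when every difference is zero)
#' @export
paired_error_test <- function(errors_a, errors_b,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (length(errors_a) != length(errors_b) || length(errors_a) < 6L)
    stopf("paired_error_test needs two equal-length vectors of length >= 6")
  wilcoxon_signed_rank(errors_a, errors_b, alternative = alternative)
}

#' Count unique barcodes represented by large families
#'
#' The number of barcode families with at least `min_family_size` reads, per
#' amplicon -- the "unique barcodes represented by at least 10 reads" view
#' used to quantify amplification bias.
#'
#' @param x a `barcode_families` or `consensus_reads` object
#' @param min_family_size size floor (default 10)
#' @return data.table with columns amplicon, n_families, plus a `total`
#'   attribute
#' @export
count_unique_barcodes <- function(x, min_family_size = 10L) {
  f <- x$families
  if (inherits(x, "consensus_reads")) {
    # consensus families already satisfy the floor used at calling time
    f <- f[size >= min_family_size]
  } else {
    f <- f[size >= min_family_size]
  }
  base <- data.table(amplicon = x$panel$amplicon)
  n <- f[, .N, by = amplicon]
  base[, n_families := ifelse(is.na(match(amplicon, n$amplicon)), 0L,
                              n$N[match(amplicon, n$amplicon)])]
  setattr(base, "total", sum(base$n_families))
  base[]
}

#' Write the per-position error table as TSV
#'
#' Columns follow the reporting convention: 1-based position, reference
#' base, raw depth and percent error, consensus depth and percent error, and
#' the consensus substitution spectrum (percent changed to each base and
#' percent deleted).
#'
#' @param raw,cons `error_profile` objects over the same panel
#' @param path output path
#' @export
write_error_profile_tsv <- function(raw, cons, path) {
  stopifnot(nrow(raw) == nrow(cons))
  out <- data.table(
    amplicon = raw$amplicon, pos_1based = raw$pos, ref = raw$ref,
    rawDepth = raw$depth, rawErr = 100 * raw$freq,
    consDepth = cons$depth, consErr = 100 * cons$freq,
    consErrorA = 100 * cons$to_A / pmax(1, cons$depth),
    consErrorC = 100 * cons$to_C / pmax(1, cons$depth),
    consErrorG = 100 * cons$to_G / pmax(1, cons$depth),
    consErrorT = 100 * cons$to_T / pmax(1, cons$depth),
    consErrorD = 100 * cons$del / pmax(1, cons$depth)
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
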