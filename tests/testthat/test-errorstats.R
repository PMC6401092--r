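make_profiles <- function(seed = 111, ...) {
  p <- test_panel()
  cfg <- sim_config(seed = seed, ...)
  run_pipeline(p, cfg, keep_sim = FALSE)
}

test_that("raw and consensus profile arithmetic on constructed inputs", {
  p <- kit_panel()
  L <- p$insert_len[1]
  rr <- match(strsplit(p$insert[1], "")[[1]], c("A", "C", "G", "T", "-"))
  # 10 reads, one carries G at reference position 2 (ref A)
  M <- matrix(rr, 10, L, byrow = TRUE)
  expect_equal(p$insert[1], "CAGAGACATCAAGAATGAT")
  M[3, 2] <- 3L  # G
  vr <- structure(list(
    reads = data.table::data.table(read_id = sprintf("r%d", 1:10),
                                   amplicon = "KIT", barcode = "B",
                                   row = 1:10),
    calls = list(KIT = M), panel = p, layout = NULL),
    class = "valid_reads")
  prof <- raw_error_profile(vr, p)
  expect_equal(prof$depth, rep(10, L))
  expect_equal(prof$freq[2], 0.1)
  expect_equal(prof$to_G[2], 1)
  expect_equal(sum(prof$nonref), 1)
  # substitution-type counts decompose the non-reference count everywhere
  expect_equal(prof$nonref,
               prof$to_A + prof$to_C + prof$to_G + prof$to_T + prof$del)
})

test_that("zero-error simulation gives exactly zero raw and consensus error", {
  p <- test_panel()
  cfg <- quiet_config(n_templates = 60, depth = 1500, seed = 121)
  pl <- run_pipeline(p, cfg, keep_sim = FALSE)
  expect_equal(sum(pl$raw_profile$nonref), 0)
  expect_equal(sum(pl$cons_profile$nonref), 0)
  expect_equal(mean_error(pl$raw_profile), 0)
  expect_gt(nrow(pl$consensus$families), 0)
})

test_that("raw error matches the sequencer rate when PCR is error-free", {
  pl <- make_profiles(taq_error_rate = 0, seq_error_rate = 0.001,
                      n_templates = 1200, depth = 25000, seed = 131)
  calls <- sum(pl$raw_profile$depth)
  errs <- sum(pl$raw_profile$nonref)
  expect_gt(calls, 4e5)
  rate <- errs / calls
  se <- sqrt(0.001 * 0.999 / calls)
  expect_lt(abs(rate - 0.001), 3 * se)
})

test_that("fold reduction handles arithmetic, censoring and degeneracy", {
  p <- kit_panel()
  L <- p$insert_len[1]
  mk <- function(nonref, depth, cons = FALSE) {
    data.table::data.table(amplicon = "KIT", pos = seq_len(L),
                           ref = strsplit(p$insert[1], "")[[1]],
                           depth = depth, nonref = nonref,
                           to_A = nonref, to_C = 0L, to_G = 0L, to_T = 0L,
                           del = 0L, freq = nonref / depth)
  }
  # raw 0.1% vs consensus 0.01% -> 10-fold
  raw <- mk(rep(1L, L), 1000L)
  cons <- mk(rep(1L, L), 10000L)
  fr <- fold_reduction(raw, cons)
  expect_equal(fr$fold_reduction, 10)
  expect_false(fr$censored); expect_false(fr$degenerate)
  # identical profiles -> 1
  expect_equal(fold_reduction(raw, raw)$fold_reduction, 1)
  # zero consensus error -> pseudo-count 0.5 and censoring flag
  cons0 <- mk(rep(0L, L), 10000L)
  fr0 <- fold_reduction(raw, cons0)
  expect_true(fr0$censored)
  expect_equal(fr0$fold_reduction, 0.001 / (0.5 / (10000 * L)))
  # both zero -> degenerate, ratio 1
  raw0 <- mk(rep(0L, L), 1000L)
  frd <- fold_reduction(raw0, cons0)
  expect_true(frd$degenerate)
  expect_equal(frd$fold_reduction, 1)
})

test_that("variant-base-count distribution sums to one and sees tandem damage", {
  p <- test_panel()
  f <- 0.05
  cfg <- quiet_config(
    n_templates = 800, depth = 24000, seed = 141,
    tandem_spec = data.frame(amplicon = "BRAF", pos = 4, to = "TT",
                             rate = f))  # ref CA at 4-5 -> both bases change
  pl <- run_pipeline(p, cfg)
  dist <- variant_base_count_distribution(pl$consensus)
  sums <- tapply(dist$fraction, dist$amplicon, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # the tandem arm produces two-variant consensus reads at ~ the damage rate
  two <- dist[dist$amplicon == "BRAF" & dist$n_variant_bases == "2"]$fraction
  n_braf <- nrow(pl$consensus$families[
    pl$consensus$families$amplicon == "BRAF"])
  se <- sqrt(f * (1 - f) / n_braf)
  expect_lt(abs(two - f), 4 * se + 1e-9)
  # other amplicons are error-free here
  expect_equal(dist[dist$amplicon == "KIT" &
                      dist$n_variant_bases == "0"]$fraction, 1)
})

test_that("substitution spectrum decomposes the total error mass", {
  # pure A->G injection: all consensus error mass lands in errorG
  p <- kit_panel()
  cfg <- quiet_config(
    n_templates = 300, depth = 9000, seed = 151,
    vaf_spec = data.frame(amplicon = "KIT", pos = 12, alt = "G",
                          vaf = 0.3))  # ref A at pos 12
  expect_equal(substr(p$insert[1], 12, 12), "A")
  pl <- run_pipeline(p, cfg)
  spec <- substitution_spectrum(pl$cons_profile)
  rates <- spec$spectrum[spec$spectrum$amplicon == "KIT"]
  expect_gt(rates[rates$change == "errorG"]$rate, 0.005)
  expect_equal(sum(rates[rates$change != "errorG"]$rate), 0)
  # conservation at every scope: spectrum sums to total error
  tot <- sum(pl$cons_profile$nonref) / sum(pl$cons_profile$depth)
  expect_equal(sum(rates$rate) * nrow(pl$cons_profile) /
                 nrow(pl$cons_profile), sum(rates$rate))
  expect_equal(sum(rates$rate), tot)
  # base composition sums to 1 and matches the reference strand
  comp <- spec$composition
  expect_equal(sum(comp$fraction), 1)
  expect_equal(comp[comp$base == "A"]$fraction,
               mean(strsplit(p$insert[1], "")[[1]] == "A"))
})

test_that("spearman_cor matches hand computation and the exhaustive oracle", {
  # worked 5-point set: ranks differ by d = (1,1,1,1,0), rho = 1 - 24/120
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  s <- spearman_cor(x, y)
  expect_equal(s$rho, 0.8)
  expect_equal(s$rho, stats::cor(x, y, method = "spearman"))
  # self and reversed orderings
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # exhaustive-permutation oracle agreement (rho and exact p), small n
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    a <- rnorm(n); b <- rnorm(n)
    s <- spearman_cor(a, b)
    o <- oracle_spearman(a, b)
    expect_equal(s$rho, o$rho)
    expect_equal(s$p.value, o$p.value)
    expect_equal(s$rho, stats::cor(a, b, method = "spearman"))
  }
  # ties handled by average ranks, as in cor(method = "spearman")
  a <- c(1, 1, 2, 3, 5, 5, 7, 8, 9, 10)
  b <- c(2, 1, 2, 4, 4, 6, 7, 7, 10, 9)
  expect_equal(spearman_cor(a, b)$rho,
               stats::cor(a, b, method = "spearman"))
  expect_error(spearman_cor(1:2, 1:2))
})

test_that("positionwise_correlation works on profiles and rejects tiny input", {
  pl1 <- make_profiles(seed = 161, n_templates = 150, depth = 4000,
                       seq_error_rate = 0.01)
  pl2 <- make_profiles(seed = 162, n_templates = 150, depth = 4000,
                       seq_error_rate = 0.01)
  r <- positionwise_correlation(pl1$raw_profile, pl2$raw_profile)
  expect_true(is.finite(r$rho))
  expect_equal(positionwise_correlation(pl1$raw_profile,
                                        pl1$raw_profile)$rho, 1)
  expect_error(positionwise_correlation(pl1$raw_profile[1:2],
                                        pl2$raw_profile[1:2]))
})

test_that("wilcoxon signed-rank: exact small-n behaviour and oracles", {
  # identical lists -> degenerate
  w <- wilcoxon_signed_rank(1:10, 1:10)
  expect_true(w$degenerate)
  expect_equal(w$p.value, 1)
  # a shifted copy of 10 distinct values: one-sided exact p = 1/2^10
  a <- c(3, 1, 4, 1.5, 5, 9, 2.6, 6, 5.3, 5.9)
  b <- a + 1
  w <- wilcoxon_signed_rank(b, a, alternative = "greater")
  expect_equal(w$method, "exact")
  expect_equal(w$p.value, 1 / 2^10)
  expect_equal(w$statistic, 55)
  # agreement with the sign-flip enumeration oracle
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    for (alt in c("two.sided", "greater", "less")) {
      w <- wilcoxon_signed_rank(d, alternative = alt)
      expect_equal(w$p.value, oracle_wilcoxon(d, alt),
                   info = paste(alt, paste(d, collapse = ",")))
    }
    # and with base R's implementation
    wb <- stats::wilcox.test(d, exact = TRUE)
    w2 <- wilcoxon_signed_rank(d)
    expect_equal(w2$p.value, wb$p.value)
    expect_equal(unname(w2$statistic), unname(wb$statistic))
  }
  # tied |differences| still take the exact path at small n, agreeing with
  # full enumeration
  d <- c(1, 1, -2, 3, 3, -4, 5, 5)
  w <- wilcoxon_signed_rank(d)
  expect_equal(w$method, "exact")
  expect_equal(w$p.value, oracle_wilcoxon(d, "two.sided"))
  # normal approximation above n = 25 matches wilcox.test's corrected z test
  set.seed(29)
  d30 <- round(rnorm(30), 1); d30 <- d30[d30 != 0]
  w <- wilcoxon_signed_rank(d30)
  wb <- stats::wilcox.test(d30, exact = FALSE, correct = TRUE)
  expect_equal(w$method, "normal approximation")
  expect_equal(w$p.value, unname(wb$p.value), tolerance = 1e-10)
  # paired_error_test guards its preconditions
  expect_error(paired_error_test(1:3, 1:3))
})

test_that("raw error is fidelity-insensitive when sequencer noise dominates", {
  # every read passes through ~2 barcoding synthesis events, so the PCR
  # contribution to raw error is ~2x taq_error_rate at fidelity 1; when the
  # sequencer rate dominates that burden >= 10x, raw error moves < 10%
  # relative across the fidelity extremes
  s <- sweep_summary(fidelity_sweep(fidelities = c(1, 100), seeds = 401,
                                    n_templates = 1200L, depth = 48000L,
                                    taq_error_rate = 1e-4,
                                    seq_error_rate = 0.003))
  spread <- (max(s$raw_err) - min(s$raw_err)) / min(s$raw_err)
  expect_lt(spread, 0.10)
  # while consensus error still collapses
  expect_gt(s$cons_err[s$fidelity == 1],
            2 * s$cons_err[s$fidelity == 100])
})

test_that("unique barcode counting applies the family-size floor", {
  p <- kit_panel()
  fams <- structure(list(
    families = data.table::data.table(
      family_id = 1:5, amplicon = "KIT", barcode = sprintf("B%d", 1:5),
      size = c(12L, 10L, 9L, 50L, 3L)),
    panel = p), class = "barcode_families")
  cnt <- count_unique_barcodes(fams)
  expect_equal(cnt$n_families, 3)
  expect_equal(attr(cnt, "total"), 3)
  empty <- structure(list(
    families = fams$families[0], panel = p), class = "barcode_families")
  expect_equal(count_unique_barcodes(empty)$n_families, 0)
})
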