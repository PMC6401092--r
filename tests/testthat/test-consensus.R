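test_that("families are exact groups on (amplicon, barcode)", {
  p <- test_panel()
  cfg <- quiet_config(n_templates = 50, depth = 1200, seed = 91)
  sim <- simulate_library(p, cfg)
  vr <- parse_reads(sim$reads, sim$layout, p)
  fams <- group_families(vr)
  # conservation
  expect_equal(sum(fams$families$size), nrow(vr$reads))
  # zero sequencer error: grouping reconstructs exactly the ground-truth
  # families present in the sampled reads
  truth <- attr(sim$reads, "truth")
  expect_equal(nrow(fams$families), length(unique(truth$family_id)))
  expect_true(all(fams$families$barcode %in% sim$tagged$families$barcode))
  merged <- merge(fams$reads, truth[, c("read_id", "family_id")],
                  by = "read_id", suffixes = c("", ".truth"))
  expect_equal(length(unique(paste(merged$family_id,
                                   merged$family_id.truth))),
               nrow(fams$families))

  # edit-distance-1 barcodes are never merged
  dummy <- structure(list(
    reads = data.table::data.table(
      read_id = sprintf("r%d", 1:10),
      amplicon = "KIT",
      barcode = c(rep("AAAAAAAAAAAA", 7), rep("AAAAAAAAAAAT", 3)),
      row = 1:10),
    calls = list(KIT = matrix(1L, 10, 19)),
    panel = kit_panel(), layout = NULL), class = "valid_reads")
  f2 <- group_families(dummy)
  expect_equal(sort(f2$families$size), c(3L, 7L))
  # empty input
  empty <- structure(list(
    reads = dummy$reads[0], calls = list(KIT = matrix(1L, 0, 19)),
    panel = kit_panel(), layout = NULL), class = "valid_reads")
  expect_equal(nrow(group_families(empty)$families), 0)
})

test_that("family-size consensus thresholds follow the size-dependent rule", {
  ref <- "ACGTACGTAC"
  refv <- strsplit(ref, "")[[1]]
  # size 15, all reads carry T at reference-A position 1 -> flagged T
  M <- family_matrix(ref, 15, data.frame(read = 1:15, pos = 1, base = "T"))
  cc <- call_family_consensus(M, ref)
  expect_equal(cc$consensus[1], "T")
  expect_true(cc$nonref[1])
  expect_equal(cc$variant_base_count, 1)
  # size 15, 14/15 (93%) -> reference, not flagged (100% required at 10-20)
  M <- family_matrix(ref, 15, data.frame(read = 1:14, pos = 1, base = "T"))
  cc <- call_family_consensus(M, ref)
  expect_equal(cc$consensus[1], "A")
  expect_false(any(cc$nonref))
  # size 25: 23/25 (92%) flagged, 22/25 (88%) not
  M <- family_matrix(ref, 25, data.frame(read = 1:23, pos = 1, base = "T"))
  cc <- call_family_consensus(M, ref)
  expect_equal(cc$consensus[1], "T")
  expect_true(cc$nonref[1])
  M <- family_matrix(ref, 25, data.frame(read = 1:22, pos = 1, base = "T"))
  cc <- call_family_consensus(M, ref)
  expect_equal(cc$consensus[1], "A")
  expect_false(any(cc$nonref))
  # size 9 -> excluded from consensus_10
  M <- family_matrix(ref, 9, data.frame(read = 1:9, pos = 1, base = "T"))
  expect_null(call_family_consensus(M, ref))
  # boundary sizes: 20 is still in the 100% branch, 21 in the 90% branch
  M <- family_matrix(ref, 20, data.frame(read = 1:19, pos = 1, base = "T"))
  expect_false(any(call_family_consensus(M, ref)$nonref))
  M <- family_matrix(ref, 21, data.frame(read = 1:19, pos = 1, base = "T"))
  expect_true(call_family_consensus(M, ref)$nonref[1])  # 19/21 = 90.5%
  # deletions count as non-reference calls
  M <- family_matrix(ref, 12, data.frame(read = 1:12, pos = 3, base = "-"))
  cc <- call_family_consensus(M, ref)
  expect_equal(cc$consensus[3], "-")
  expect_true(cc$nonref[3])
})

test_that("simple90 dialect flags >=90% at any family >= the floor", {
  ref <- "ACGTACGTAC"
  M <- family_matrix(ref, 15, data.frame(read = 1:14, pos = 1, base = "T"))
  cc <- call_family_consensus(M, ref, rule = "simple90")
  expect_true(cc$nonref[1])    # 14/15 = 93% passes under simple90
  cc <- call_family_consensus(M, ref, rule = "methods")
  expect_false(cc$nonref[1])   # but not under the size-dependent rule
})

test_that("bulk consensus equals the per-family reference implementation", {
  p <- test_panel()
  cfg <- sim_config(taq_error_rate = 5e-3, fidelity = 1,
                    adapter_fidelity = 1, seq_error_rate = 0.02,
                    n_templates = 40, adapter_cycles = 4,
                    materialize = "always", depth = 1500, seed = 101)
  sim <- simulate_library(p, cfg)
  vr <- parse_reads(sim$reads, sim$layout, p)
  fams <- group_families(vr)
  for (rule in c("methods", "simple90")) {
    cons <- call_consensus(fams, min_family_size = 10, rule = rule)
    checked <- 0L
    for (a in p$amplicon) {
      ref <- p$insert[p$amplicon == a]
      fa <- cons$families[cons$families$amplicon == a]
      for (i in seq_len(nrow(fa))) {
        rd <- fams$reads[fams$reads$family_id == fa$family_id[i]]
        M <- matrix(c("A", "C", "G", "T", "-")[fams$calls[[a]][rd$row, ]],
                    nrow = nrow(rd))
        single <- call_family_consensus(M, ref, min_family_size = 10,
                                        rule = rule)
        bulk_calls <- c("A", "C", "G", "T", "-")[
          cons$calls[[a]][fa$row[i], ]]
        expect_equal(bulk_calls, single$consensus)
        expect_equal(as.vector(cons$flags[[a]][fa$row[i], ]),
                     single$nonref)
        checked <- checked + 1L
      }
    }
    expect_gt(checked, 20)
    # families below the floor are absent
    small <- fams$families[fams$families$size < 10]
    expect_false(any(small$family_id %in% cons$families$family_id))
  }
})

test_that("consensus depth and relative depth arithmetic", {
  p <- test_panel()
  mk <- function(n_per_amp) {
    structure(list(
      families = data.table::data.table(
        family_id = seq_len(sum(n_per_amp)),
        amplicon = rep(p$amplicon, n_per_amp),
        barcode = "X", size = 12L,
        variant_base_count = 0L,
        row = unlist(lapply(n_per_amp, seq_len))),
      panel = p), class = "consensus_reads")
  }
  arms <- list(arm1 = mk(c(100, 100, 100)), arm2 = mk(c(200, 100, 100)))
  d <- consensus_depth(arms$arm1)
  expect_equal(d$n_consensus, c(100, 100, 100))
  rel <- relative_consensus_depth(arms)
  expect_equal(rel[rel$amplicon == "BRAF"]$relative, c(100, 200) / 150)
  expect_equal(rel[rel$amplicon == "KIT"]$relative, c(1, 1))
  # symmetric arms give relative depth 1 everywhere
  rel1 <- relative_consensus_depth(list(a = arms$arm1, b = arms$arm1))
  expect_true(all(rel1$relative == 1))
})
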