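test_that("template generation respects VAF in both modes", {
  p <- test_panel()
  vs <- data.frame(amplicon = "KIT", pos = 6, alt = "T", vaf = 0)
  cfg <- quiet_config(n_templates = 50, vaf_spec = vs, seed = 1)
  set.seed(1)
  tm <- generate_templates(p, cfg)
  expect_equal(sum(tm$is_variant), 0)

  # fixed-count mode: 22240 templates at VAF 6.25e-4 -> round(13.9) = 14
  vs$vaf <- 0.000625
  cfg <- quiet_config(n_templates = 22240, vaf_spec = vs, vaf_mode = "fixed",
                      seed = 1)
  set.seed(1)
  tm <- generate_templates(p, cfg)
  expect_equal(sum(tm$is_variant), 14)
  expect_equal(sum(tm$is_variant & tm$amplicon == "KIT"), 14)
  # the variant base is written into the template insert
  v <- tm[tm$is_variant == TRUE]
  expect_true(all(substr(v$insert, 6, 6) == "T"))

  # binomial mode concentrates near n * vaf
  vs$vaf <- 0.5
  cfg <- quiet_config(n_templates = 1000, vaf_spec = vs, seed = 7)
  set.seed(7)
  tm <- generate_templates(p, cfg)
  n_var <- sum(tm$is_variant)
  expect_gte(n_var, 400)
  expect_lte(n_var, 600)
})

test_that("barcoding PCR builds the doubling tree with correct error logs", {
  p <- kit_panel()
  layout <- read_layout(p)
  cfg <- quiet_config(n_templates = 30, barcoding_cycles = 3,
                      barcoding_efficiency = 1, seed = 3)
  set.seed(3)
  tm <- generate_templates(p, cfg)
  tg <- run_barcoding_pcr(tm, cfg, layout)
  # efficiency 1: every template founds a family of 2^(3-1) = 4 strands
  expect_equal(nrow(tg$families), 30)
  sizes <- table(tg$strands$family_id)
  expect_true(all(sizes == 4))
  # creation cycles follow the doubling tree: founder in cycle 1, one copy
  # in cycle 2, two in cycle 3
  expect_equal(sort(tg$strands[tg$strands$family_id == 1]$created_cycle),
               c(1L, 2L, 3L, 3L))
  # and the enumerated tree has 2^(c-1) strands for any cycle count
  expect_equal(length(oracle_doubling_tree_depths(3)), 4L)
  expect_equal(length(oracle_doubling_tree_depths(5)), 16L)
  # zero error rate: strands equal their rendered template; log empty
  expect_equal(nrow(tg$events), 0)
  expect_equal(length(unique(tg$seqs[tg$strands$family_id == 1])), 1)
})

test_that("huge fidelity behaves as a zero error rate", {
  p <- kit_panel()
  layout <- read_layout(p)
  cfg <- sim_config(taq_error_rate = 1e-2, fidelity = 1e12,
                    seq_error_rate = 0, n_templates = 200, seed = 11)
  set.seed(11)
  tm <- generate_templates(p, cfg)
  tg <- run_barcoding_pcr(tm, cfg, layout)
  expect_equal(nrow(tg$events), 0)
})

test_that("adapter PCR: identity at 0 cycles, 2^c molecules at efficiency 1", {
  p <- kit_panel()
  layout <- read_layout(p)
  cfg <- quiet_config(n_templates = 1, barcoding_cycles = 1,
                      barcoding_efficiency = 1, adapter_cycles = 0,
                      materialize = "always", seed = 5)
  set.seed(5)
  tg <- run_barcoding_pcr(generate_templates(p, cfg), cfg, layout)
  pool0 <- run_adapter_pcr(tg, cfg)
  expect_equal(nrow(pool0$molecules), nrow(tg$strands))
  expect_equal(pool0$seqs, tg$seqs)

  # one tagged molecule through 3 cycles at efficiency 1 -> 8 molecules
  cfg3 <- quiet_config(n_templates = 1, barcoding_cycles = 1,
                       barcoding_efficiency = 1, adapter_cycles = 3,
                       family_efficiency = c(1e6, 1e-6),  # Beta -> ~1
                       materialize = "always", seed = 5)
  set.seed(5)
  tg <- run_barcoding_pcr(generate_templates(p, cfg3), cfg3, layout)
  expect_equal(nrow(tg$strands), 1)
  pool <- run_adapter_pcr(tg, cfg3)
  expect_equal(nrow(pool$molecules), 8)
})

test_that("sequencer noise has the configured binomial rate", {
  p <- kit_panel()
  cfg <- sim_config(taq_error_rate = 0, seq_error_rate = 0.001,
                    n_templates = 700, read_length = 150,
                    depth = 10000, seed = 17)
  sim <- simulate_library(p, cfg)
  ev <- attr(sim$reads, "events")
  mean_flips <- nrow(ev$sequencer) / nrow(sim$reads)
  # mean per-read flips: 150 * 0.001 = 0.15, +/- 3 SE over 10,000 reads
  expect_lt(abs(mean_flips - 0.15), 0.012)
  expect_equal(nrow(ev$pcr), 0)
})

test_that("identical seed and config give bit-identical FASTQ output", {
  p <- test_panel()
  cfg <- sim_config(n_templates = 60, seed = 23, depth = 1500,
                    vaf_spec = data.frame(amplicon = "BRAF", pos = 7,
                                          alt = "A", vaf = 0.01))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_library(p, cfg)$reads, f1)
  write_fastq(simulate_library(p, cfg)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
  # a different seed changes the bytes
  cfg2 <- sim_config(n_templates = 60, seed = 24, depth = 1500)
  f3 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_library(p, cfg2)$reads, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("every read's divergence from its template equals its error log", {
  p <- test_panel()
  # materialized run with aggressive error rates so logs are non-trivial
  cfg <- sim_config(taq_error_rate = 0.002, fidelity = 1,
                    adapter_fidelity = 1, seq_error_rate = 0.005,
                    n_templates = 25, adapter_cycles = 3,
                    materialize = "always", depth = 800, seed = 31)
  sim <- simulate_library(p, cfg)
  check_divergences(sim)
  # virtual adapter mode, same property
  cfg2 <- sim_config(taq_error_rate = 0.002, fidelity = 1,
                     adapter_fidelity = 2, seq_error_rate = 0.005,
                     n_templates = 25, adapter_cycles = 10,
                     materialize = "never", depth = 800, seed = 32)
  sim2 <- simulate_library(p, cfg2)
  check_divergences(sim2)
})

test_that("lineage conservation: every read maps to exactly one template", {
  p <- test_panel()
  cfg <- sim_config(n_templates = 40, depth = 900, seed = 41)
  sim <- simulate_library(p, cfg)
  truth <- attr(sim$reads, "truth")
  expect_equal(nrow(truth), nrow(sim$reads))
  expect_true(all(truth$template_id %in% sim$templates$template_id))
  # the read name encodes the same lineage
  expect_true(all(sprintf("f%d", truth$family_id) ==
                    sub("^r\\d+\\|(f\\d+)\\|.*$", "\\1", truth$read_id)))
})

test_that("first-cycle errors are carried by every read of the family", {
  p <- kit_panel()
  cfg <- sim_config(taq_error_rate = 0, cycle1_error_rate = 0.05,
                    seq_error_rate = 0, n_templates = 60,
                    depth = 1500, seed = 51)
  sim <- simulate_library(p, cfg)
  ev <- attr(sim$reads, "events")$pcr
  truth <- attr(sim$reads, "truth")
  expect_true(all(ev$cycle == 1))
  # for each family with a cycle-1 error within the read window, every read
  # of that family carries it
  rl <- sim$layout$read_length
  fam_ev <- unique(ev[ev$pos <= rl, c("read_id", "pos", "to")])
  fam_ev$family_id <- truth$family_id[match(fam_ev$read_id, truth$read_id)]
  fam_pos <- unique(fam_ev[, c("family_id", "pos", "to")])
  for (k in seq_len(nrow(fam_pos))) {
    rds <- truth$read_id[truth$family_id == fam_pos$family_id[k]]
    seqs <- sim$reads$seq[match(rds, sim$reads$read_id)]
    expect_true(all(substr(seqs, fam_pos$pos[k], fam_pos$pos[k]) ==
                      fam_pos$to[k]))
  }
  expect_gt(nrow(fam_pos), 0)
})
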