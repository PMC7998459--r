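# Synthetic-data generator: determinism, the truncated-ppm error model,
# scan-range clipping, and expression bookkeeping.

test_that("all generators are reproducible under a fixed seed", {
  cfg <- sim_config(seed = 101, n_genes = 3, background_length = 5e4)
  p1 <- generate_precursor(cfg, index = 2)
  p2 <- generate_precursor(cfg, index = 2)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_precursor(cfg, index = 3)))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  s1 <- simulate_ms2("AWDSKHP", cfg)
  s2 <- simulate_ms2("AWDSKHP", cfg)
  expect_identical(s1$peaks, s2$peaks)
  m1 <- simulate_ms1(enumerate_candidates("TFLPPLFVPP"), cfg)
  m2 <- simulate_ms1(enumerate_candidates("TFLPPLFVPP"), cfg)
  expect_identical(m1, m2)
})

test_that("precursors use reference templates around the supplied core", {
  cfg <- sim_config(seed = 1)
  g <- generate_precursor(cfg, core = "IWGIGCNP")
  expect_match(g$leader, "^M")
  expect_equal(nchar(g$leader), 10)
  expect_match(g$recognition, "^[CS]")
  expect_equal(g$protein, paste0(g$leader, "IWGIGCNP", g$recognition))
  expect_error(generate_precursor(cfg, core = "IWXGP"), "invalid residue")
})

test_that("simulated MS1 errors follow the truncated-ppm model", {
  m <- peptide_mass("TFLPPLFVPP", "cyclic")
  cfg <- sim_config(seed = 211, ms1_ppm_sd = 1.5, ms1_noise_peaks = 0,
                    adduct_probabilities = c(H = 1))
  cand <- data.frame(neutral_mass = rep(m, 10000))
  pk <- simulate_ms1(cand, cfg)
  errs <- (pk$mz - adduct_mz(m, "H")) / adduct_mz(m, "H") * 1e6
  expect_equal(nrow(pk), 10000)
  expect_lt(abs(mean(errs)), 0.1)
  expect_lt(abs(sd(errs) - 1.5), 0.15) # within 10% of the nominal sd
  expect_lte(max(abs(errs)), 4.5)      # hard truncation at 3 sd
  # noiseless limit
  cfg0 <- sim_config(seed = 211, ms1_ppm_sd = 0, ms1_noise_peaks = 0,
                     adduct_probabilities = c(H = 1))
  pk0 <- simulate_ms1(data.frame(neutral_mass = m), cfg0)
  expect_equal(pk0$mz, adduct_mz(m, "H"))
})

test_that("MS1 peaks are clipped to the scan range", {
  cfg <- sim_config(seed = 3, ms1_noise_peaks = 0)
  pk <- simulate_ms1(enumerate_candidates("GG"), cfg) # all species < 500 m/z
  expect_equal(nrow(pk), 0)
})

test_that("MS/MS emission controls drive the assignment verdict", {
  cfg <- sim_config(seed = 19)
  sp <- simulate_ms2("AFFPPFFIPP", cfg)
  a <- assign_spectrum("AFFPPFFIPP", sp)
  expect_equal(a$verdict, "confirmed")
  expect_equal(a$residue_coverage, 1.0)
  # without immonium emission the immonium requirement fails
  cfg_no_imm <- sim_config(seed = 19, p_immonium = 0)
  sp2 <- simulate_ms2("AFFPPFFIPP", cfg_no_imm)
  expect_equal(assign_spectrum("AFFPPFFIPP", sp2)$verdict, "rejected")
})

test_that("transcriptome bookkeeping rounds the expressed fraction", {
  cfg <- sim_config(seed = 5, n_genes = 22, background_length = 3e5,
                    expressed_fraction = 18 / 22)
  g <- generate_genome(cfg)
  tx <- generate_transcriptome(g$truth, cfg)
  expect_equal(sum(tx$truth$expressed), 18)
  cfg_all <- sim_config(seed = 5, n_genes = 10, background_length = 2e5,
                        expressed_fraction = 1)
  g2 <- generate_genome(cfg_all)
  expect_true(all(generate_transcriptome(g2$truth, cfg_all)$truth$expressed))
})

test_that("overcrowded genomes are rejected", {
  cfg <- sim_config(seed = 1, n_genes = 50, background_length = 5e3)
  expect_error(generate_genome(cfg), "overcrowding")
})
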