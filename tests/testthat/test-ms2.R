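# MS/MS fragment generation, spectrum matching, the most-or-all-residues
# assignment rule, and natural-vs-synthetic spectrum comparison.

test_that("y, b and immonium ion m/z values are correct", {
  ions <- theoretical_ions("TFLPPLFVPP")
  y <- ions[ions$series == "y", ]
  expect_equal(round(y$mz[y$index == 1], 4), 116.0706) # P + H2O + proton
  expect_equal(round(y$mz[y$index == 2], 4), 213.1234)
  imm <- ions[ions$series == "immonium", ]
  expect_setequal(imm$span, c("T", "F", "L", "P", "V"))
  expect_equal(round(imm$mz[imm$span == "F"], 4), 120.0808)
  b <- theoretical_ions("GGG", "b")
  expect_equal(round(b$mz[b$index == 1], 4), 58.0287)
  expect_equal(round(b$mz[b$index == 2], 4), 115.0502)
  expect_error(theoretical_ions("GG"), "at least 3")
})

test_that("y/b complementarity holds on all reference cores", {
  for (core in unique(msdin_reference()$core)) {
    n <- nchar(core)
    ions <- theoretical_ions(core, c("y", "b"))
    y <- ions$mz[ions$series == "y"][order(ions$index[ions$series == "y"])]
    b <- ions$mz[ions$series == "b"][order(ions$index[ions$series == "b"])]
    lin_mh <- adduct_mz(peptide_mass(core, "linear"), "H")
    for (k in 1:(n - 1))
      expect_equal(y[k] + b[n - k], lin_mh + 1.007276, tolerance = 1e-4)
  }
})

test_that("ring-opened b-ion set is rotation invariant", {
  core <- "AFFPPFFIPP"
  ring <- theoretical_ions(core, "ring_b")
  for (j in c(3, 7)) {
    rot <- paste0(substr(core, j + 1, nchar(core)), substr(core, 1, j))
    ring_j <- theoretical_ions(rot, "ring_b")
    expect_equal(ring$mz, ring_j$mz, tolerance = 1e-6)
  }
})

test_that("spectrum matching is greedy, one-to-one and nearest-first", {
  ions <- theoretical_ions("GGG", "b")
  # two peaks within tolerance of b1: only the nearest is taken
  sp <- ms2_spectrum(data.frame(mz = c(58.030, 58.042), intensity = c(1, 2)))
  m <- match_spectrum(sp, ions, tol = 0.02)
  expect_equal(nrow(m[m$label == "b1", ]), 1)
  expect_equal(m$peak_mz[m$label == "b1"], 58.030)
  # noise-only spectrum: nothing matches
  far <- ms2_spectrum(data.frame(mz = ions$mz + 1, intensity = 1))
  expect_equal(nrow(match_spectrum(far, ions, tol = 0.02)), 0)
})

test_that("noiseless spectra confirm their own core and reject decoys", {
  sp <- noiseless_spectrum("AFFPPFFIPP")
  a <- assign_spectrum("AFFPPFFIPP", sp)
  expect_equal(a$verdict, "confirmed")
  expect_equal(a$residue_coverage, 1.0)
  expect_setequal(a$matched_immonium, c("A", "F", "P", "I"))
  # decoy of different composition
  d <- assign_spectrum("GGSGGSGGSG", sp)
  expect_equal(d$verdict, "rejected")
  expect_equal(d$residue_coverage, 0)
})

test_that("sparse y-ion evidence is rejected at the default threshold", {
  core <- "TFLPPLFVPP"
  ions <- theoretical_ions(core)
  keep <- ions$series == "y" & ions$index %in% c(2, 3)
  sp <- ms2_spectrum(data.frame(mz = ions$mz[keep], intensity = 1))
  a <- assign_spectrum(core, sp)
  expect_equal(a$verdict, "rejected")
  expect_lt(a$residue_coverage, 0.8)
})

test_that("assignment rule matches the reported y2-y9 + immonium evidence", {
  # spectrum holding y2..y9 of the core plus immonium ions for P, L, F:
  # the published evidence pattern for cyclo(TFLPPLFVPP)
  core <- "TFLPPLFVPP"
  ions <- theoretical_ions(core)
  keep <- (ions$series == "y" & ions$index %in% 2:9) |
    (ions$series == "immonium" & ions$span %in% c("P", "L", "F"))
  sp <- ms2_spectrum(data.frame(mz = ions$mz[keep], intensity = 1))
  a <- assign_spectrum(core, sp)
  expect_equal(a$verdict, "confirmed")
  expect_equal(a$matched_y, 2:9)
  expect_equal(a$residue_coverage, 0.9) # only the N-terminal Thr unexplained
})

test_that("I/L substitutions are indistinguishable and flagged", {
  sp <- noiseless_spectrum("FIPLGIITILP")
  a1 <- assign_spectrum("FIPLGIITILP", sp)
  a2 <- assign_spectrum("FLPIGLLTLIP", sp)
  expect_equal(a1$verdict, a2$verdict)
  expect_equal(a1$residue_coverage, a2$residue_coverage)
  expect_equal(a1$matched_y, a2$matched_y)
  expect_true(a1$il_ambiguous)
})

test_that("spectrum comparison counts shared ions one-to-one", {
  sp <- noiseless_spectrum("TFLPPLFVPP")
  self <- compare_spectra(sp, sp, tol = 0.02)
  expect_equal(self$shared, nrow(sp$peaks))
  off <- ms2_spectrum(data.frame(mz = sp$peaks$mz + 5,
                                 intensity = sp$peaks$intensity))
  expect_equal(compare_spectra(sp, off)$shared, 0)
  # replicate spectra with small jitter share nearly all ions, symmetrically
  cfg <- sim_config(seed = 13, ms2_jitter_sd = 0.005)
  r1 <- simulate_ms2("TFLPPLFVPP", cfg, index = 1)
  r2 <- simulate_ms2("TFLPPLFVPP", cfg, index = 2)
  res <- compare_spectra(r1, r2, tol = 0.02)
  expect_gte(res$shared, 0.9 * nrow(r1$peaks))
  expect_equal(res$shared, compare_spectra(r2, r1, tol = 0.02)$shared)
  expect_error(compare_spectra(sp, ms2_spectrum(
    data.frame(mz = numeric(), intensity = numeric()))), "non-empty")
})
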