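# Elemental compositions, monoisotopic masses, modifications, adducts,
# ppm arithmetic, immonium ions and isotope envelopes.

test_that("peptide compositions match known molecular formulas", {
  expect_equal(format_formula(peptide_composition("TFLPPLFVPP", "cyclic")),
               "C59H84N10O11")
  expect_equal(format_formula(peptide_composition("MHILAPPP", "cyclic")),
               "C41H64N10O8S")
  expect_equal(format_formula(peptide_composition("GG", "linear")),
               "C4H8N2O3")
  # cyclic = linear minus one water
  lin <- peptide_composition("AWDSKHP", "linear")
  cyc <- peptide_composition("AWDSKHP", "cyclic")
  expect_equal(unclass(comp_subtract(lin, cyc)),
               unclass(composition(H = 2, O = 1)))
})

test_that("invalid sequences are rejected with position information", {
  expect_error(peptide_composition("GABG", "linear"),
               "invalid residue 'B' at position 3")
  expect_error(peptide_composition("G", "linear"), "at least 2")
  expect_error(immonium_mz("Z"), "unknown residue")
})

test_that("composition arithmetic is element-wise and guards negatives", {
  a <- composition(C = 2, H = 5, N = 1)
  b <- composition(C = 1, H = 2, O = 3)
  expect_equal(unclass(comp_add(a, b)),
               unclass(composition(C = 3, H = 7, N = 1, O = 3)))
  expect_error(comp_subtract(a, b), "negative")
  expect_error(composition(C = -1), "non-negative")
  expect_equal(parse_formula("C41H64N10O8S"),
               composition(C = 41, H = 64, N = 10, O = 8, S = 1))
})

test_that("monoisotopic masses reproduce reference cyclic peptide values", {
  expect_equal(peptide_mass("TFLPPLFVPP", "cyclic"), 1108.6321,
               tolerance = 5e-8)
  expect_equal(peptide_mass("AWDSKHP", "cyclic"), 821.3820, tolerance = 5e-8)
  # frozen from the brute-force oracle (7 glycine residues)
  expect_equal(round(peptide_mass("GGGGGGG", "cyclic"), 4), 399.1502)
})

test_that("mass additivity and water-loss invariants hold", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_peptide()
    expect_equal(peptide_mass(p, "linear") - peptide_mass(p, "cyclic"),
                 18.010565, tolerance = 1e-6)
  }
  a <- peptide_composition("FNFFRFPYP", "cyclic")
  b <- peptide_composition("SSVLPRP", "linear")
  expect_identical(monoisotopic_mass(comp_add(a, b)),
                   monoisotopic_mass(a) + monoisotopic_mass(b))
})

test_that("mass calculator agrees with per-atom brute-force summation", {
  set.seed(23)
  for (i in 1:300) {
    p <- random_peptide()
    topo <- sample(c("linear", "cyclic"), 1)
    expect_equal(peptide_mass(p, topo), oracle_mass(p, topo),
                 tolerance = 1e-12)
  }
})

test_that("modification states shift compositions as expected", {
  # fully modified amatoxin state: 4 OH + sulfoxide + tryptathionine bridge
  m <- monoisotopic_mass(apply_modifications(
    peptide_composition("IWGIGCNP", "cyclic"), "IWGIGCNP",
    n_hydroxyl = 4, sulfoxide = TRUE, bridge = TRUE))
  expect_equal(m, 918.3541, tolerance = 5e-4)
  m2 <- monoisotopic_mass(apply_modifications(
    peptide_composition("AWLVDCP", "cyclic"), "AWLVDCP",
    n_hydroxyl = 4, bridge = TRUE))
  expect_equal(m2, 846.3217, tolerance = 5e-4)
  # identity state
  comp <- peptide_composition("AWDSKHP", "cyclic")
  expect_identical(apply_modifications(comp, "AWDSKHP"), comp)
  # Cys+Trp gate
  expect_error(apply_modifications(peptide_composition("GGG", "linear"),
                                   "GGG", sulfoxide = TRUE),
               "require both Cys and Trp")
  expect_error(apply_modifications(comp, "AWDSKHP", bridge = TRUE),
               "require both Cys and Trp")
  expect_error(apply_modifications(comp, "AWDSKHP", n_hydroxyl = 5), "0..4")
})

test_that("adduct m/z uses fixed cation offsets", {
  expect_equal(round(adduct_mz(1108.6321, "H"), 4), 1109.6394)
  expect_equal(round(adduct_mz(1213.6284, "H"), 4), 1214.6357)
  expect_equal(round(adduct_mz(1108.6321, "Na"), 4), 1131.6213)
  expect_equal(adduct_mz(1000, "H", charge = 2), (1000 + 2 * 1.007276) / 2)
  expect_error(adduct_mz(-5, "H"))
})

test_that("ppm discrepancy is symmetric, non-negative and zero at identity", {
  expect_equal(round(ppm_delta(1109.6394, 1109.6398), 2), 0.36)
  expect_equal(round(ppm_delta(1161.6132, 1161.6161), 2), 2.50)
  expect_identical(ppm_delta(845.4039, 845.4039), 0)
  set.seed(5)
  for (i in 1:20) {
    t <- runif(1, 500, 1700); e <- runif(1, -0.01, 0.01)
    expect_equal(ppm_delta(t, t + e), ppm_delta(t, t - e))
    expect_gte(ppm_delta(t, t + e), 0)
  }
})

test_that("immonium ions follow residue - CO + proton", {
  expect_equal(round(immonium_mz("P"), 4), 70.0651)
  expect_equal(round(immonium_mz("F"), 4), 120.0808)
  expect_equal(round(immonium_mz("L"), 4), 86.0964)
  expect_identical(immonium_mz("I"), immonium_mz("L"))
})

test_that("isotopic distributions are normalized and start monoisotopic", {
  c1 <- isotopic_distribution(composition(C = 1))
  expect_equal(c1$mass, c(12.000000, 13.0033548), tolerance = 1e-6)
  expect_equal(c1$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  water <- isotopic_distribution(composition(H = 2, O = 1))
  expect_equal(round(water$mass[which.max(water$abundance)], 4), 18.0106)
  set.seed(31)
  for (i in 1:10) {
    comp <- peptide_composition(random_peptide(5, 11), "cyclic")
    d <- isotopic_distribution(comp)
    expect_equal(sum(d$abundance), 1, tolerance = 1e-9)
    expect_equal(d$mass[1], monoisotopic_mass(comp), tolerance = 1e-4)
    expect_true(!is.unsorted(d$mass))
  }
})
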