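# Precursor mining: six-frame translation, leader scanning, Pro-anchored
# core candidate ranking, genome round trips and the expression cross-check.

test_that("six-frame translation follows the standard code and conventions", {
  fr <- six_frame_translate("ATGTCA")
  expect_equal(fr$protein[fr$strand == "+" & fr$frame == 0], "MS")
  fr2 <- six_frame_translate("TGACAT")
  expect_equal(fr2$protein[fr2$strand == "-" & fr2$frame == 0], "MS")
  # stops and fuzzy codons
  fr3 <- six_frame_translate("ATGTAANNG")
  expect_equal(fr3$protein[fr3$strand == "+" & fr3$frame == 0], "M*X")
  expect_error(six_frame_translate("ATGQCA"), "illegal character 'Q' at position 4")
  expect_error(six_frame_translate("AT"), "shorter")
})

test_that("reverse-translated precursors translate back to themselves", {
  cfg <- sim_config(seed = 3)
  for (i in 1:5) {
    g <- generate_precursor(cfg, index = i)
    fr <- six_frame_translate(g$dna)
    expect_equal(fr$protein[fr$strand == "+" & fr$frame == 0], g$protein)
  }
})

test_that("core candidates are Pro-anchored and ranked by the cleavage cues", {
  cfg <- mining_config()
  # Pro at 10 followed by C beats Pro at 9 followed by P
  cand <- extract_core_candidates("TFLPPLFVPPCVSDDIEMVLTRGESLC", cfg)
  expect_equal(cand$core[1], "TFLPPLFVPP")
  expect_true("TFLPPLFVP" %in% cand$core)
  cand2 <- extract_core_candidates("AWLVDCPCVGDDISRLLTRGEK", cfg)
  expect_equal(cand2$core[1], "AWLVDCP")
  # no Pro in range: full-window candidates, flagged non-canonical
  cand3 <- extract_core_candidates("LILVANGMAYVSDDVSPTLTRGE", cfg)
  expect_true(all(cand3$non_canonical))
  expect_equal(cand3$core[1], "LILVANGMAYV") # the one with C/S recognition
  # tail too short
  expect_equal(nrow(extract_core_candidates("AWLVDCP", cfg)), 0)
})

test_that("leader scanning finds reference precursors in protein context", {
  cfg <- mining_config()
  rec <- find_precursors("MSDINSTRLPIWGIGCNPSVGDEVTALLTRGEA", cfg)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$core, "IWGIGCNP")
  expect_equal(rec$leader, "MSDINSTRLP")
  rec2 <- find_precursors("MSDINTARLPAFFPPFFIPPCVSDDIEMVLTRGESLC", cfg)
  expect_equal(rec2$core, "AFFPPFFIPP")
  # leader + core + recognition always reconstructs the matched substring
  prot <- paste0("GAV", "MSDINATRLPAWDSKHPCVGDDVSRLLTRGE", "KLM")
  rec3 <- find_precursors(prot, cfg)
  expect_equal(substr(prot, rec3$start + 1, rec3$end), rec3$full_sequence)
  expect_equal(rec3$full_sequence,
               paste0(rec3$leader, rec3$core, rec3$recognition))
})

test_that("random background yields no spurious precursors", {
  set.seed(17)
  prot <- paste(sample(names(residue_table()), 10000, replace = TRUE),
                collapse = "")
  rec <- find_precursors(prot, mining_config())
  # any hit must still satisfy the leader pattern
  if (nrow(rec) > 0) {
    expect_true(all(substr(rec$leader, 1, 1) == "M"))
    expect_true(all(substr(rec$leader, 10, 10) == "P"))
  }
  expect_lte(nrow(rec), 1)
})

test_that("genome mining round-trips embedded genes with exact coordinates", {
  cfg <- sim_config(seed = 42, n_genes = 8, background_length = 1.2e5)
  g <- generate_genome(cfg)
  rec <- mine_genome(g$genome, mining_config())
  expect_equal(nrow(rec), nrow(g$truth))
  key <- function(d) sort(paste(d$core, d$start, d$end, d$strand))
  expect_equal(key(rec), key(g$truth))
  expect_true(any(rec$strand == "-") || any(rec$strand == "+"))
})

test_that("mining is strand-symmetric", {
  cfg <- sim_config(seed = 9, n_genes = 5, background_length = 8e4)
  g <- generate_genome(cfg)
  rec_f <- mine_genome(g$genome, mining_config())
  rc <- Biostrings::reverseComplement(g$genome)
  names(rc) <- names(g$genome)
  rec_r <- mine_genome(rc, mining_config())
  expect_equal(sort(rec_f$core), sort(rec_r$core))
  flip <- c("+" = "-", "-" = "+")
  expect_equal(sort(paste(rec_f$core, flip[rec_f$strand])),
               sort(paste(rec_r$core, rec_r$strand)))
})

test_that("empty FASTA input errors", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">empty", ""), f)
  expect_error(mine_genome(f), "empty")
  expect_error(mine_genome(tempfile()), "cannot read")
})

test_that("expression cross-check counts exact transcript matches", {
  cfg <- sim_config(seed = 77, n_genes = 24, background_length = 3e5,
                    expressed_fraction = 0.75)
  g <- generate_genome(cfg)
  tx <- generate_transcriptome(g$truth, cfg)
  expect_equal(sum(tx$truth$expressed), 18) # round(0.75 * 24)
  rec <- mine_genome(g$genome, mining_config())
  res <- compare_to_transcripts(rec, tx$transcripts)
  expect_equal(res$n_expressed, 18)
  expect_equal(res$percent_expressed, 75.0)
  # no transcripts at all
  none <- generate_transcriptome(g$truth, sim_config(seed = 77, n_genes = 24,
                                                     expressed_fraction = 0))
  res0 <- compare_to_transcripts(rec, none$transcripts)
  expect_equal(res0$percent_expressed, 0)
  expect_error(compare_to_transcripts(rec[0, ], tx$transcripts), "empty")
})
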