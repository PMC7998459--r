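# Seeded synthetic-data generator: MSDIN genes embedded in random genomic
# background, partially-expressed transcriptomes, and centroided MS1/MS2
# peak lists with ppm-scale mass error, adduct peaks and noise. Every
# stage of the pipeline can therefore be exercised round-trip against a
# recorded truth table without any external data.

# run a block with a private, restorable RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# residue sampling weights for synthetic cores: Pro, Phe and Ile dominate
# the residue usage of known Amanita cyclic peptides
.CORE_RESIDUE_WEIGHTS <- c(
  P = 5, F = 4, I = 3, L = 2, V = 2, A = 1.5, G = 1, T = 1, S = 1,
  Y = 0.8, W = 0.5, H = 0.5, N = 0.5, D = 0.5, E = 0.5, Q = 0.5,
  K = 0.5, R = 0.5, M = 0.5, C = 0.3
)

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: a fungal
#' genome background at GC 0.46, 7-11 residue cores rich in Pro/Phe/Ile,
#' MS1 mass error of 1.5 ppm (truncated at three standard deviations, so
#' all simulated errors stay inside a 5 ppm matching tolerance), and clean
#' (noise-free, jitter-free) MS/MS spectra; MS/MS imperfections are opt-in
#' via the jitter/noise/emission fields.
#'
#' @param seed Integer seed fixing all downstream randomness.
#' @param n_genes Number of MSDIN genes embedded in the synthetic genome.
#' @param background_length Genome background length in bp.
#' @param background_gc Background GC fraction (default 0.46).
#' @param core_len_range Range of sampled core lengths (default 7-11).
#' @param expressed_fraction Fraction of genes present in the synthetic
#'   transcriptome (default 18/22, the observed expression fraction).
#' @param ms1_ppm_sd MS1 mass-error standard deviation in ppm (default 1.5).
#' @param ms1_noise_peaks Uniform decoy peaks added to MS1 lists.
#' @param adduct_probabilities Emission probability per adduct; \[M+H\]+ is
#'   always emitted.
#' @param scan_range MS1 scan range in m/z (default `c(500, 1700)`).
#' @param ms2_jitter_sd Gaussian m/z jitter (Da) on MS/MS peaks (default 0).
#' @param ms2_noise_peaks Noise peaks per MS/MS spectrum (default 0).
#' @param p_y,p_b,p_immonium Emission probabilities for y-ions other than
#'   the guaranteed y2..y(n-1), b-ions, and immonium ions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, background_length = 1e6,
                       background_gc = 0.46, core_len_range = c(7L, 11L),
                       expressed_fraction = 18 / 22,
                       ms1_ppm_sd = 1.5, ms1_noise_peaks = 50L,
                       adduct_probabilities = c(H = 1, Na = 0.3, K = 0.2),
                       scan_range = c(500, 1700),
                       ms2_jitter_sd = 0, ms2_noise_peaks = 0L,
                       p_y = 1, p_b = 1, p_immonium = 1) {
  stopifnot(expressed_fraction >= 0, expressed_fraction <= 1,
            background_gc >= 0, background_gc <= 1,
            ms1_ppm_sd >= 0, ms2_jitter_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# sample a core: biased residues, terminal Pro (the POPB cleavage anchor)
.sample_core <- function(config) {
  len <- sample(seq(config$core_len_range[1], config$core_len_range[2]), 1)
  body <- sample(names(.CORE_RESIDUE_WEIGHTS), len - 1, replace = TRUE,
                 prob = .CORE_RESIDUE_WEIGHTS)
  paste(c(body, "P"), collapse = "")
}

# codon table grouped by amino acid, for uniform-synonymous reverse
# translation (built from Biostrings' standard genetic code)
.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- .CODONS_BY_AA[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Generate one synthetic MSDIN precursor
#'
#' Leader and recognition sequences are sampled from the built-in reference
#' templates (recognition restricted to the canonical C/S-initial ones, as
#' POPB-processed precursors carry); the core is supplied or sampled with
#' the residue bias of known Amanita cyclic peptides and a terminal Pro.
#' The DNA is a uniform-synonymous-codon reverse translation.
#'
#' @param config A [sim_config()]; its seed (offset by `index`) fixes the
#'   output.
#' @param core Core sequence, or `NULL` to sample one.
#' @param index Integer offset so successive calls under one config yield
#'   distinct, reproducible precursors.
#' @return A list with `leader`, `core`, `recognition`, `protein`, `dna`.
#' @export
generate_precursor <- function(config = sim_config(), core = NULL, index = 0L) {
  if (!is.null(core)) .check_sequence(core)
  .with_seed(config$seed + 7919L * index, {
    ref <- msdin_reference()
    recog_pool <- unique(ref$recognition[substr(ref$recognition, 1, 1) %in%
                                           c("C", "S")])
    leader <- sample(unique(ref$leader), 1)
    recognition <- sample(recog_pool, 1)
    if (is.null(core)) core <- .sample_core(config)
    protein <- paste0(leader, core, recognition)
    list(leader = leader, core = core, recognition = recognition,
         protein = protein, dna = .reverse_translate(protein))
  })
}

#' Generate a synthetic genome with embedded MSDIN genes
#'
#' `n_genes` precursor coding sequences (each followed by a stop codon) are
#' embedded at non-overlapping random positions and strands in i.i.d.
#' GC-weighted background sequence.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a `DNAStringSet` of one sequence named
#'   `synthetic_genome`) and `truth` (data.frame `id`, `core`, `leader`,
#'   `recognition`, `protein`, `start`, `end`, `strand`; coordinates are
#'   0-based half-open forward-strand positions of the coding region,
#'   excluding the stop codon).
#' @export
generate_genome <- function(config = sim_config()) {
  n <- config$n_genes
  L <- as.integer(config$background_length)
  genes <- lapply(seq_len(max(n, 0)), function(i)
    generate_precursor(config, index = i))
  lens <- vapply(genes, function(g) nchar(g$dna) + 3L, integer(1))
  if (n > 0 && L < sum(lens) * 2)
    stop("background too short for ", n, " genes (overcrowding)",
         call. = FALSE)
  .with_seed(config$seed, {
    gcw <- c(A = (1 - config$background_gc) / 2, C = config$background_gc / 2,
             G = config$background_gc / 2, T = (1 - config$background_gc) / 2)
    background <- sample(names(gcw), L, replace = TRUE, prob = gcw)
    truth <- list()
    occupied <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      g <- genes[[i]]
      cassette <- paste0(g$dna, "TAA") # coding region then stop
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") cassette else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cassette)))
      w <- nchar(ins)
      placed <- FALSE
      for (try in 1:1000) {
        s0 <- sample.int(L - w + 1L, 1) - 1L # 0-based start
        clash <- nrow(occupied) > 0 &&
          any(s0 < occupied[, 2] & s0 + w > occupied[, 1])
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place gene ", i, " (overcrowding)",
                        call. = FALSE)
      occupied <- rbind(occupied, c(s0, s0 + w))
      background[(s0 + 1):(s0 + w)] <- strsplit(ins, "")[[1]]
      # forward-strand span of the coding region (stop codon excluded)
      cds <- if (strand == "+") c(s0, s0 + w - 3L) else c(s0 + 3L, s0 + w)
      truth[[i]] <- data.frame(
        id = sprintf("gene%02d", i), core = g$core, leader = g$leader,
        recognition = g$recognition, protein = g$protein,
        start = cds[1], end = cds[2], strand = strand,
        stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(paste(background, collapse = ""))
    names(genome) <- "synthetic_genome"
    list(genome = genome,
         truth = if (n > 0) do.call(rbind, truth) else
           data.frame(id = character(), core = character(),
                      leader = character(), recognition = character(),
                      protein = character(), start = integer(),
                      end = integer(), strand = character()))
  })
}

#' Generate a synthetic transcriptome for a genome truth table
#'
#' `round(expressed_fraction * n_genes)` genes are marked expressed; each
#' expressed gene yields one transcript containing its full coding sequence
#' flanked by random UTRs.
#'
#' @param truth Truth table from [generate_genome()].
#' @param config A [sim_config()] (supplies `expressed_fraction` and seed).
#' @return A list with `transcripts` (`DNAStringSet`) and `truth` (input
#'   table plus a logical `expressed` column).
#' @export
generate_transcriptome <- function(truth, config = sim_config()) {
  n <- nrow(truth)
  k <- round(config$expressed_fraction * n)
  .with_seed(config$seed + 104729L, {
    expressed_idx <- if (k > 0) sort(sample.int(n, k)) else integer(0)
    utr <- function() paste(sample(c("A", "C", "G", "T"),
                                   sample(50:150, 1), replace = TRUE),
                            collapse = "")
    txs <- vapply(expressed_idx, function(i) {
      cds <- .reverse_translate(truth$protein[i])
      paste0(utr(), cds, "TAA", utr())
    }, character(1))
    transcripts <- Biostrings::DNAStringSet(txs)
    if (length(txs))
      names(transcripts) <- paste0("transcript_", truth$id[expressed_idx])
    truth$expressed <- seq_len(n) %in% expressed_idx
    list(transcripts = transcripts, truth = truth)
  })
}

# one truncated-normal ppm error (rejection at +/- 3 sd)
.trunc_ppm_error <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      e <- stats::rnorm(1, 0, sd)
      if (abs(e) <= 3 * sd) break
    }
    out[i] <- e
  }
  out
}

#' Simulate an MS1 peak list for a set of candidates
#'
#' Each candidate emits its \[M+H\]+ peak (and Na/K adduct peaks with the
#' configured probabilities) with multiplicative mass error drawn from a
#' Normal(0, `ms1_ppm_sd` ppm) truncated at three standard deviations.
#' Peaks whose theoretical m/z falls outside the scan range are dropped;
#' uniform noise peaks are added across the scan range.
#'
#' @param candidates Candidate data.frame (needs `neutral_mass`).
#' @param config A [sim_config()].
#' @return A peak data.frame (`mz`, `intensity`, `rt`), sorted by mz.
#' @export
simulate_ms1 <- function(candidates, config = sim_config()) {
  .with_seed(config$seed + 224737L, {
    mz <- numeric(0); int <- numeric(0)
    for (i in seq_len(nrow(candidates))) {
      m <- candidates$neutral_mass[i]
      for (ad in names(config$adduct_probabilities)) {
        if (stats::runif(1) > config$adduct_probabilities[[ad]]) next
        t <- adduct_mz(m, ad)
        if (t < config$scan_range[1] || t > config$scan_range[2]) next
        err <- .trunc_ppm_error(1, config$ms1_ppm_sd)
        mz <- c(mz, t * (1 + err * 1e-6))
        int <- c(int, stats::rlnorm(1, log(1e5), 0.5) *
                   if (ad == "H") 1 else 0.2)
      }
    }
    nn <- config$ms1_noise_peaks
    if (nn > 0) {
      mz <- c(mz, stats::runif(nn, config$scan_range[1], config$scan_range[2]))
      int <- c(int, stats::rlnorm(nn, log(1e3), 1))
    }
    df <- data.frame(mz = mz, intensity = int,
                     rt = stats::runif(length(mz), 60, 600))
    df <- df[order(df$mz), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Simulate an MS/MS spectrum of a cyclic core peptide
#'
#' Emits peaks at the theoretical y-ions (y2..y(n-1) always; y1 with
#' probability `p_y`), b-ions (`p_b`) and immonium ions (`p_immonium`) of
#' the written core, with optional Gaussian m/z jitter and uniform noise
#' peaks. Intensities follow a decorative exponential-rank model. The
#' precursor m/z is the cyclic \[M+H\]+.
#'
#' @param core Core sequence (length >= 3).
#' @param config A [sim_config()].
#' @param index Offset decoupling the RNG stream of successive spectra.
#' @return An [ms2_spectrum()].
#' @export
simulate_ms2 <- function(core, config = sim_config(), index = 0L) {
  ions <- theoretical_ions(core, c("y", "b", "immonium"))
  n <- nchar(core)
  .with_seed(config$seed + 350377L + 31L * index, {
    keep <- logical(nrow(ions))
    for (i in seq_len(nrow(ions))) {
      p <- switch(ions$series[i],
                  y = if (ions$index[i] >= 2) 1 else config$p_y,
                  b = config$p_b,
                  immonium = config$p_immonium)
      keep[i] <- stats::runif(1) <= p
    }
    mz <- ions$mz[keep]
    if (config$ms2_jitter_sd > 0)
      mz <- mz + stats::rnorm(length(mz), 0, config$ms2_jitter_sd)
    int <- 1e4 * exp(-rank(-mz) / 6) + stats::runif(length(mz), 0, 100)
    if (config$ms2_noise_peaks > 0) {
      prec <- adduct_mz(peptide_mass(core, "cyclic"), "H")
      mz <- c(mz, stats::runif(config$ms2_noise_peaks, 60, prec))
      int <- c(int, stats::runif(config$ms2_noise_peaks, 0, 500))
    }
    ms2_spectrum(data.frame(mz = mz, intensity = int),
                 precursor_mz = adduct_mz(peptide_mass(core, "cyclic"), "H"),
                 title = paste0("sim:", core))
  })
}
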