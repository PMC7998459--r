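# Pipeline orchestration: a single round-trippable configuration object
# and file-to-file runners binding the stages together (mine -> enumerate
# -> match MS1 -> assign MS/MS), plus the synthetic-dataset runner. All
# tabular outputs are TSV with '#' metadata header lines (tool version,
# config hash, seed); m/z is printed to 4 decimals and ppm to 2.

.pkg_version <- function() {
  as.character(utils::packageVersion("msdinmine"))
}

# small deterministic content hash (djb2 over the JSON serialization)
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.meta <- function(config, extra = NULL) {
  c(tool = paste0("msdinmine/", .pkg_version()),
    config_hash = .config_hash(config),
    seed = as.character(config$sim$seed),
    extra)
}

#' Pipeline configuration
#'
#' One object holding the per-stage settings, round-trippable to and from a
#' JSON file. Unknown keys in a file are rejected.
#'
#' @param mining A [mining_config()].
#' @param max_hydroxyl Enumeration hydroxylation ceiling.
#' @param ms1_tol_ppm MS1 matching tolerance (ppm).
#' @param scan_range MS1 scan range, m/z.
#' @param ms2_tol MS/MS fragment tolerance (Da).
#' @param coverage_threshold,min_immonium MS/MS assignment rule settings.
#' @param sim A [sim_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mining = mining_config(), max_hydroxyl = 4,
                            ms1_tol_ppm = 5, scan_range = c(500, 1700),
                            ms2_tol = 0.02, coverage_threshold = 0.8,
                            min_immonium = 1, sim = sim_config()) {
  structure(list(mining = mining, max_hydroxyl = max_hydroxyl,
                 ms1_tol_ppm = ms1_tol_ppm, scan_range = scan_range,
                 ms2_tol = ms2_tol, coverage_threshold = coverage_threshold,
                 min_immonium = min_immonium, sim = sim),
            class = "pipeline_config")
}

#' Write a pipeline configuration to JSON
#' @param config A [pipeline_config()].
#' @param path Output JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$mining <- unclass(x$mining)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path JSON file written by [write_pipeline_config()].
#' @return A [pipeline_config()]; unknown keys raise an error.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$mining)) {
    mk <- names(formals(mining_config))
    bad <- setdiff(names(x$mining), mk)
    if (length(bad))
      stop("unknown mining config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    x$mining <- do.call(mining_config, x$mining)
  }
  if (!is.null(x$sim)) {
    sk <- names(formals(sim_config))
    bad <- setdiff(names(x$sim), sk)
    if (length(bad))
      stop("unknown sim config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    x$sim <- do.call(sim_config, x$sim)
  }
  do.call(pipeline_config, x)
}

#' Mine precursors from a FASTA file and write a precursor TSV
#'
#' @param input Genome (DNA) or protein FASTA path.
#' @param output Output TSV path.
#' @param config A [pipeline_config()].
#' @param type `"dna"` or `"protein"` input.
#' @param known_cores Optional character vector; the summary counts mined
#'   cores absent from it as novel.
#' @return The precursor data.frame, invisibly; prints a one-line summary.
#' @export
run_mine <- function(input, output, config = pipeline_config(),
                     type = c("dna", "protein"), known_cores = NULL) {
  type <- match.arg(type)
  rec <- if (type == "dna") mine_genome(input, config$mining)
         else mine_proteins(input, config$mining)
  .write_tsv(rec, output, .meta(config, c(input = input)))
  novel <- if (is.null(known_cores)) NA_integer_
           else sum(!unique(rec$core) %in% known_cores)
  message(sprintf("mined %d precursor(s), %d unique core(s)%s",
                  nrow(rec), length(unique(rec$core)),
                  if (is.na(novel)) "" else sprintf(", %d novel", novel)))
  invisible(rec)
}

#' Enumerate candidates for a precursor TSV
#'
#' @param input Precursor TSV from [run_mine()].
#' @param output Candidate TSV path.
#' @param config A [pipeline_config()].
#' @return The candidate data.frame, invisibly.
#' @export
run_enumerate <- function(input, output, config = pipeline_config()) {
  prec <- .read_tsv(input)
  if (!nrow(prec)) stop("empty precursor table: ", input, call. = FALSE)
  cand <- candidate_table(prec, config$max_hydroxyl)
  num <- c("neutral_mass", "mz_H", "mz_Na", "mz_K")
  out <- cand
  out[num] <- lapply(out[num], round, 4)
  .write_tsv(out, output, .meta(config))
  invisible(cand)
}

#' Match a candidate TSV against an MS1 peak list
#'
#' @param candidates Candidate TSV from [run_enumerate()].
#' @param peaks MS1 peak list (CSV or MGF).
#' @param output Match TSV path.
#' @param config A [pipeline_config()].
#' @return The match data.frame, invisibly.
#' @export
run_match_ms1 <- function(candidates, peaks, output,
                          config = pipeline_config()) {
  cand <- read_candidates(candidates)
  pk <- read_peaklist(peaks)
  m <- match_ms1(pk, cand, config$ms1_tol_ppm, config$scan_range)
  out <- m
  for (cc in c("theoretical_mz", "measured_mz"))
    out[[cc]] <- round(out[[cc]], 4)
  .write_tsv(out, output, .meta(config, c(peaks = peaks)))
  invisible(m)
}

#' Assign MS/MS spectra to MS1-matched cores
#'
#' Each spectrum in the MGF is assigned against every distinct matched core
#' whose cyclic \[M+H\]+ lies within the MS1 tolerance of the spectrum
#' precursor m/z (all cores are tried when a spectrum has no precursor).
#'
#' @param matches MS1 match TSV from [run_match_ms1()].
#' @param msms MS/MS MGF path.
#' @param output Assignment TSV path.
#' @return The assignment data.frame, invisibly.
#' @param config A [pipeline_config()].
#' @export
run_assign_ms2 <- function(matches, msms, output,
                           config = pipeline_config()) {
  m <- .read_tsv(matches)
  spectra <- read_mgf(msms)
  cores <- unique(m$core)
  rows <- list()
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    for (core in cores) {
      if (!is.na(sp$precursor_mz)) {
        t <- adduct_mz(peptide_mass(core, "cyclic"), "H")
        if (ppm_delta(t, sp$precursor_mz) > config$ms1_tol_ppm) next
      }
      a <- assign_spectrum(core, sp, config$ms2_tol,
                           config$coverage_threshold, config$min_immonium)
      rows[[length(rows) + 1]] <- data.frame(
        spectrum = si,
        title = if (is.null(sp$title)) NA_character_ else sp$title,
        core = core, verdict = a$verdict,
        residue_coverage = round(a$residue_coverage, 3),
        n_y = length(a$matched_y), n_b = length(a$matched_b),
        immonium = paste(a$matched_immonium, collapse = ","),
        il_ambiguous = a$il_ambiguous, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum = integer(), title = character(), core = character(),
               verdict = character(), residue_coverage = numeric(),
               n_y = integer(), n_b = integer(), immonium = character(),
               il_ambiguous = logical())
  .write_tsv(res, output, .meta(config, c(msms = msms)))
  invisible(res)
}

#' Generate a complete synthetic dataset directory
#'
#' Writes a genome FASTA, a transcriptome FASTA, an MS1 peak list (MGF
#' precursor mode), one MS/MS MGF holding a spectrum per embedded core,
#' truth tables, and a JSON run manifest recording the seed and paths.
#'
#' @param dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return A list with the truth tables and the file paths, invisibly.
#' @export
run_simulate <- function(dir, config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  gen <- generate_genome(sim)
  tx <- generate_transcriptome(gen$truth, sim)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    transcriptome = file.path(dir, "transcriptome.fasta"),
    ms1 = file.path(dir, "ms1.mgf"),
    ms2 = file.path(dir, "ms2.mgf"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(gen$genome, paths$genome)
  Biostrings::writeXStringSet(tx$transcripts, paths$transcriptome)
  # MS1: unmodified cyclic species of every embedded core
  cand <- candidate_table(data.frame(id = gen$truth$id, core = gen$truth$core,
                                     stringsAsFactors = FALSE),
                          config$max_hydroxyl)
  cyc <- cand[cand$topology == "cyclic" & cand$n_hydroxyl == 0 &
                !cand$sulfoxide & !cand$bridge, ]
  pk <- simulate_ms1(cyc, sim)
  ms1_spectra <- lapply(seq_len(nrow(pk)), function(i)
    ms2_spectrum(data.frame(mz = pk$mz[i], intensity = pk$intensity[i]),
                 precursor_mz = pk$mz[i],
                 title = sprintf("ms1_scan_%04d", i)))
  write_mgf(ms1_spectra, paths$ms1)
  ms2 <- lapply(seq_len(nrow(gen$truth)), function(i)
    simulate_ms2(gen$truth$core[i], sim, index = i))
  write_mgf(ms2, paths$ms2)
  .write_tsv(tx$truth, paths$truth, .meta(config))
  jsonlite::write_json(
    list(seed = sim$seed, n_genes = sim$n_genes,
         expressed_fraction = sim$expressed_fraction,
         config_hash = .config_hash(config),
         tool = paste0("msdinmine/", .pkg_version()),
         files = lapply(paths, basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = tx$truth, paths = paths))
}
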