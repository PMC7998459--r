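# MSDIN precursor mining: degenerate-motif scan for the 10-residue leader,
# Pro-anchored core extraction with ranked candidates, six-frame genome
# scanning, and an expression cross-check against transcript sequences.
# The leader motif replaces the homology search used on real genomes: the
# leader is near-invariant across published precursors, so a per-position
# residue-set scan is deterministic and parameter-free.

#' Build a degenerate leader pattern from a set of leader sequences
#'
#' Positions 1 and 10 are fixed to Met and Pro (the leader always starts
#' with M and the POPB cleavage site requires a terminal Pro); positions
#' 2-9 allow the union of residues observed at that position.
#'
#' @param leaders Character vector of 10-residue leader sequences.
#' @return A list of 10 character vectors (allowed residues per position).
#' @export
leader_pattern_from <- function(leaders) {
  stopifnot(all(nchar(leaders) == 10))
  mat <- do.call(rbind, strsplit(leaders, ""))
  pat <- lapply(seq_len(10), function(j) sort(unique(mat[, j])))
  pat[[1]] <- "M"
  pat[[10]] <- "P"
  pat
}

#' Mining configuration
#'
#' @param leader_pattern List of 10 character vectors of allowed residues
#'   per leader position; default: derived from the built-in reference
#'   leader set via [leader_pattern_from()].
#' @param core_len_range Integer vector `c(min, max)` of core lengths
#'   (default 7-11).
#' @param min_recognition_len Minimum recognition-sequence length kept after
#'   the core (default 2).
#' @param max_recognition_len Recognition is truncated at a stop codon or at
#'   this many residues, whichever comes first (default 25).
#' @param allow_non_pro_core Also emit full-window candidates (flagged
#'   `non_canonical_core`) when no Pro falls inside the core length range
#'   (default TRUE).
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(leader_pattern = NULL,
                          core_len_range = c(7L, 11L),
                          min_recognition_len = 2L,
                          max_recognition_len = 25L,
                          allow_non_pro_core = TRUE) {
  if (is.null(leader_pattern))
    leader_pattern <- leader_pattern_from(msdin_reference()$leader)
  stopifnot(length(leader_pattern) == 10,
            length(core_len_range) == 2,
            core_len_range[1] >= 2, core_len_range[1] <= core_len_range[2],
            min_recognition_len >= 1)
  structure(list(leader_pattern = leader_pattern,
                 core_len_range = as.integer(core_len_range),
                 min_recognition_len = as.integer(min_recognition_len),
                 max_recognition_len = as.integer(max_recognition_len),
                 allow_non_pro_core = isTRUE(allow_non_pro_core)),
            class = "mining_config")
}

.leader_regex <- function(pattern) {
  paste0(vapply(pattern, function(set) {
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Six-frame translation of a DNA sequence
#'
#' Translates all three frames of both strands with the standard genetic
#' code. Stop codons are rendered `*`; codons containing N are rendered `X`.
#'
#' @param dna A DNA string over A, C, G, T, N (length >= 3).
#' @return A data.frame with columns `strand` (`+`/`-`), `frame` (0-2) and
#'   `protein`.
#' @export
six_frame_translate <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1)
  dna <- toupper(dna)
  bad <- regexpr("[^ACGTN]", dna)
  if (bad > 0)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(dna, bad, bad), bad), call. = FALSE)
  if (nchar(dna) < 3) stop("sequence shorter than one codon", call. = FALSE)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, f) {
    len <- (length(s) - f) %/% 3 * 3
    if (len < 3) return("")
    as.character(Biostrings::translate(s[(f + 1):(f + len)],
                                       if.fuzzy.codon = "X"))
  }
  data.frame(
    strand = rep(c("+", "-"), each = 3),
    frame = rep(0:2, 2),
    protein = c(vapply(0:2, function(f) one(fwd, f), character(1)),
                vapply(0:2, function(f) one(rev, f), character(1))),
    stringsAsFactors = FALSE
  )
}

#' Rank core/recognition candidates for the tail after a leader
#'
#' POPB cleaves at Pro, so one candidate is emitted per Pro whose position
#' falls inside the allowed core length range (the core ends at that Pro).
#' When no Pro lies in range and `allow_non_pro_core` is set, one
#' full-window candidate per allowed length is emitted and flagged
#' `non_canonical_core`. Candidates are ranked by: (1) recognition starts
#' with C or S, (2) core ends with Pro, (3) longer core.
#'
#' @param tail The residues following the 10-residue leader.
#' @param config A [mining_config()].
#' @return A data.frame (possibly empty) with columns `core`, `recognition`,
#'   `ends_pro`, `rec_cs`, `non_canonical`, `rank`, ordered by rank.
#' @export
extract_core_candidates <- function(tail, config = mining_config()) {
  rng <- config$core_len_range
  minrec <- config$min_recognition_len
  n <- nchar(tail)
  empty <- data.frame(core = character(), recognition = character(),
                      ends_pro = logical(), rec_cs = logical(),
                      non_canonical = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (n < rng[1] + minrec) return(empty)
  kmax <- min(rng[2], n - minrec)
  ks <- seq(rng[1], kmax)
  if (length(ks) == 0) return(empty)
  aa <- strsplit(tail, "")[[1]]
  pro_ks <- ks[aa[ks] == "P"]
  if (length(pro_ks)) {
    ks_use <- pro_ks
    noncan <- rep(FALSE, length(ks_use))
  } else if (config$allow_non_pro_core) {
    ks_use <- ks
    noncan <- rep(TRUE, length(ks_use))
  } else {
    return(empty)
  }
  core <- substr(rep(tail, length(ks_use)), 1, ks_use)
  recog <- substring(tail, ks_use + 1)
  # drop candidates whose core crosses a stop or ambiguous residue
  ok <- !grepl("[*X]", core)
  core <- core[ok]; recog <- recog[ok]; noncan <- noncan[ok]
  if (!length(core)) return(empty)
  ends_pro <- substr(core, nchar(core), nchar(core)) == "P"
  rec_cs <- substr(recog, 1, 1) %in% c("C", "S")
  o <- order(-rec_cs, -ends_pro, -nchar(core))
  data.frame(core = core[o], recognition = recog[o],
             ends_pro = ends_pro[o], rec_cs = rec_cs[o],
             non_canonical = noncan[o], rank = seq_along(o),
             stringsAsFactors = FALSE)
}

# truncate a tail string at the first stop codon and cap its length
.clip_tail <- function(tail, config) {
  stop_at <- regexpr("*", tail, fixed = TRUE)
  if (stop_at > 0) tail <- substr(tail, 1, stop_at - 1)
  cap <- config$core_len_range[2] + config$max_recognition_len
  substr(tail, 1, cap)
}

#' Find MSDIN precursors in a protein sequence
#'
#' Scans for 10-residue windows matching the leader pattern and extracts
#' the top-ranked core/recognition candidate after each. Coordinates are
#' 0-based half-open in residue space of `protein`.
#'
#' @param protein Protein string (20-letter alphabet plus `*` and `X`).
#' @param config A [mining_config()].
#' @param source_id Identifier recorded in the `source_id` column.
#' @return A data.frame of precursor records with columns `id`, `source_id`,
#'   `start`, `end`, `strand`, `frame`, `leader`, `core`, `recognition`,
#'   `full_sequence`, `flags`, `n_candidates`, sorted by `start`. Zero rows
#'   when nothing matches.
#' @export
find_precursors <- function(protein, config = mining_config(),
                            source_id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1)
  rx <- paste0("(?=", .leader_regex(config$leader_pattern), ")")
  hits <- gregexpr(rx, protein, perl = TRUE)[[1]]
  out <- list()
  if (hits[1] != -1) {
    for (i in as.integer(hits)) {
      leader <- substr(protein, i, i + 9)
      if (grepl("[*X]", leader)) next
      tail <- .clip_tail(substring(protein, i + 10), config)
      cand <- extract_core_candidates(tail, config)
      if (!nrow(cand)) next
      top <- cand[1, ]
      flags <- c(if (top$ends_pro) "core_ends_pro",
                 if (top$rec_cs) "recognition_starts_CS",
                 if (top$non_canonical) "non_canonical_core")
      full <- paste0(leader, top$core, top$recognition)
      out[[length(out) + 1]] <- data.frame(
        id = sprintf("%s:%d", source_id, i - 1),
        source_id = source_id,
        start = i - 1L,
        end = i - 1L + nchar(full),
        strand = "+", frame = NA_integer_,
        leader = leader, core = top$core, recognition = top$recognition,
        full_sequence = full,
        flags = paste(flags, collapse = ";"),
        n_candidates = nrow(cand),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), source_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), leader = character(),
                      core = character(), recognition = character(),
                      full_sequence = character(), flags = character(),
                      n_candidates = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# map an aa-space record to nucleotide coordinates on the forward strand
.aa_to_nt <- function(rec, frame, strand, seq_len_nt) {
  aa_start <- rec$start
  aa_end <- rec$end
  nt_start_local <- frame + 3L * aa_start
  nt_end_local <- frame + 3L * aa_end
  if (strand == "+") {
    c(nt_start_local, nt_end_local)
  } else {
    c(seq_len_nt - nt_end_local, seq_len_nt - nt_start_local)
  }
}

#' Mine MSDIN precursors from a genome FASTA
#'
#' Six-frame-translates every sequence and scans each frame with
#' [find_precursors()]. Record coordinates are 0-based half-open nucleotide
#' positions on the forward strand of the source sequence.
#'
#' @param fasta Path to a DNA FASTA file (gzip allowed), or a
#'   `Biostrings::DNAStringSet`.
#' @param config A [mining_config()].
#' @return A precursor data.frame as in [find_precursors()] (with `strand`
#'   and `frame` filled in), ordered by source then start.
#' @export
mine_genome <- function(fasta, config = mining_config()) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else {
    if (!file.exists(fasta)) stop("cannot read FASTA: ", fasta, call. = FALSE)
    Biostrings::readDNAStringSet(fasta)
  }
  if (length(seqs) == 0 || any(Biostrings::width(seqs) == 0))
    stop("empty sequence in FASTA input", call. = FALSE)
  out <- list()
  for (s in seq_along(seqs)) {
    sid <- sub("\\s.*", "", names(seqs)[s])
    frames <- six_frame_translate(as.character(seqs[[s]]))
    L <- Biostrings::width(seqs)[s]
    for (r in seq_len(nrow(frames))) {
      rec <- find_precursors(frames$protein[r], config, source_id = sid)
      if (!nrow(rec)) next
      for (j in seq_len(nrow(rec))) {
        nt <- .aa_to_nt(rec[j, ], frames$frame[r], frames$strand[r], L)
        rec$start[j] <- nt[1]
        rec$end[j] <- nt[2]
      }
      rec$strand <- frames$strand[r]
      rec$frame <- frames$frame[r]
      rec$id <- sprintf("%s:%d:%s%d", sid, rec$start, rec$strand, rec$frame)
      out[[length(out) + 1]] <- rec
    }
  }
  if (!length(out)) return(find_precursors("", config)[0, ])
  res <- do.call(rbind, out)
  res <- res[order(res$source_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine MSDIN precursors from a protein FASTA
#'
#' @param fasta Path to a protein FASTA file or an `AAStringSet`.
#' @param config A [mining_config()].
#' @return A precursor data.frame as in [find_precursors()].
#' @export
mine_proteins <- function(fasta, config = mining_config()) {
  seqs <- if (inherits(fasta, "AAStringSet")) fasta else {
    if (!file.exists(fasta)) stop("cannot read FASTA: ", fasta, call. = FALSE)
    Biostrings::readAAStringSet(fasta)
  }
  if (length(seqs) == 0) stop("empty FASTA input", call. = FALSE)
  out <- lapply(seq_along(seqs), function(s) {
    find_precursors(as.character(seqs[[s]]), config,
                    source_id = sub("\\s.*", "", names(seqs)[s]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-check precursor expression against transcript sequences
#'
#' A precursor counts as expressed when its full sequence (leader + core +
#' recognition) occurs verbatim in any of the three forward-frame
#' translations of any transcript.
#'
#' @param precursors Precursor data.frame from [mine_genome()] /
#'   [find_precursors()] (non-empty).
#' @param transcripts Path to a transcript FASTA or a `DNAStringSet`.
#' @return A list with `records` (the input plus a logical `expressed`
#'   column), `n_expressed`, `n_total`, and `percent_expressed` (one
#'   decimal).
#' @export
compare_to_transcripts <- function(precursors, transcripts) {
  if (!is.data.frame(precursors) || nrow(precursors) == 0)
    stop("empty precursor list", call. = FALSE)
  seqs <- if (inherits(transcripts, "DNAStringSet")) transcripts else {
    if (!file.exists(transcripts))
      stop("cannot read FASTA: ", transcripts, call. = FALSE)
    Biostrings::readDNAStringSet(transcripts)
  }
  frames <- character(0)
  for (s in seq_along(seqs)) {
    tr <- six_frame_translate(as.character(seqs[[s]]))
    frames <- c(frames, tr$protein[tr$strand == "+"])
  }
  expressed <- vapply(precursors$full_sequence, function(p) {
    any(vapply(frames, function(f) grepl(p, f, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  precursors$expressed <- expressed
  list(records = precursors,
       n_expressed = sum(expressed),
       n_total = length(expressed),
       percent_expressed = round(100 * mean(expressed), 1))
}
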