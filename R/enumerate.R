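# Expansion of each core peptide into candidate species: topology x
# modification state x adduct, with molecular formula and theoretical m/z.
# Mirrors the try-all-combinations strategy used to screen LC-HRMS data:
# how many modifications occur, and in what order, is unknown a priori, so
# every state up to the ceiling is enumerated.

#' Enumerate candidate species for one core peptide
#'
#' States are the Cartesian product of topology (linear, cyclic), number of
#' hydroxylations (0..`max_hydroxyl`), and - only for cores containing both
#' Cys and Trp - sulfoxidation and tryptathionine bridge formation. Each
#' state carries its molecular formula, neutral monoisotopic mass, and
#' singly-charged \[M+H\]+, \[M+Na\]+, \[M+K\]+ m/z.
#'
#' @param core Core peptide sequence.
#' @param max_hydroxyl Hydroxylation ceiling (default 4, the maximum known
#'   for amatoxins).
#' @param provenance Identifier(s) of the precursor(s) the core came from.
#' @return A data.frame with one row per state: `core`, `topology`,
#'   `n_hydroxyl`, `sulfoxide`, `bridge`, `formula`, `neutral_mass`,
#'   `mz_H`, `mz_Na`, `mz_K`, `provenance`. 10 rows for cores without
#'   Cys+Trp, 40 with.
#' @export
enumerate_candidates <- function(core, max_hydroxyl = 4,
                                 provenance = NA_character_) {
  aa <- .check_sequence(core)
  has_cw <- "C" %in% aa && "W" %in% aa
  states <- expand.grid(
    topology = c("linear", "cyclic"),
    n_hydroxyl = 0:max_hydroxyl,
    sulfoxide = if (has_cw) c(FALSE, TRUE) else FALSE,
    bridge = if (has_cw) c(FALSE, TRUE) else FALSE,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- list(linear = peptide_composition(core, "linear"),
               cyclic = peptide_composition(core, "cyclic"))
  rows <- lapply(seq_len(nrow(states)), function(i) {
    st <- states[i, ]
    comp <- apply_modifications(base[[st$topology]], core, st$n_hydroxyl,
                                st$sulfoxide, st$bridge)
    m <- monoisotopic_mass(comp)
    data.frame(core = core, topology = st$topology,
               n_hydroxyl = st$n_hydroxyl, sulfoxide = st$sulfoxide,
               bridge = st$bridge, formula = format_formula(comp),
               neutral_mass = m,
               mz_H = adduct_mz(m, "H"), mz_Na = adduct_mz(m, "Na"),
               mz_K = adduct_mz(m, "K"),
               provenance = paste(provenance, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Candidate table for a set of precursors
#'
#' Enumerates every unique core and deduplicates on (core, topology,
#' modification state); duplicate precursor genes (identical cores) collapse
#' to one row whose `provenance` lists all contributing precursor ids.
#'
#' @param precursors Precursor data.frame with at least `id` and `core`
#'   columns (from the mining stage), or a character vector of cores.
#' @param max_hydroxyl Hydroxylation ceiling passed to
#'   [enumerate_candidates()].
#' @return A flat candidate data.frame; zero rows for empty input.
#' @export
candidate_table <- function(precursors, max_hydroxyl = 4) {
  if (is.character(precursors))
    precursors <- data.frame(id = precursors, core = precursors,
                             stringsAsFactors = FALSE)
  if (!nrow(precursors))
    return(enumerate_candidates("GG")[0, ])
  cores <- unique(precursors$core)
  out <- lapply(cores, function(co) {
    ids <- precursors$id[precursors$core == co]
    enumerate_candidates(co, max_hydroxyl, provenance = ids)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a candidate table as TSV
#' @param candidates Candidate data.frame.
#' @param path Output file.
#' @param meta Optional named character vector written as `# key=value`
#'   header comments.
#' @export
write_candidates <- function(candidates, path, meta = NULL) {
  .write_tsv(candidates, path, meta)
}

#' Read a candidate table written by [write_candidates()]
#' @param path TSV file.
#' @return Candidate data.frame.
#' @export
read_candidates <- function(path) {
  .read_tsv(path)
}
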