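# MS/MS fragment ion generation and spectrum assignment. The core is
# annotated in its written orientation with linear-peptide y- and b-series
# plus residue-diagnostic immonium ions - the convention that explains
# Amanita cyclic-peptide spectra well in practice - with an optional
# ring-opened b-series (union of b-ions over all ring openings) available
# for principled cyclic fragmentation.

#' Theoretical fragment ions of a core peptide
#'
#' y_k is the C-terminal k-residue fragment (`mass + H2O + proton`); b_k the
#' N-terminal k-residue fragment (`mass + proton`); immonium ions are
#' emitted once per distinct residue; `ring_b` is the union of b-series over
#' all n ring openings of the cyclic peptide, deduplicated at 1e-4 Da.
#'
#' @param core Core sequence (length >= 3).
#' @param series Subset of `c("y", "b", "immonium", "ring_b")`.
#' @return A data.frame with columns `series`, `index`, `label`, `mz`,
#'   `span` (the stretch of `core` the ion covers; the residue letter for
#'   immonium ions).
#' @export
theoretical_ions <- function(core, series = c("y", "b", "immonium")) {
  aa <- .check_sequence(core)
  n <- length(aa)
  if (n < 3) stop("core must have at least 3 residues", call. = FALSE)
  series <- match.arg(series, c("y", "b", "immonium", "ring_b"),
                      several.ok = TRUE)
  res_mass <- vapply(aa, function(a) monoisotopic_mass(.RESIDUE_TABLE[[a]]),
                     numeric(1))
  out <- list()
  if ("y" %in% series) {
    csum <- cumsum(rev(res_mass)) # k C-terminal residues
    out$y <- data.frame(
      series = "y", index = 1:(n - 1),
      label = paste0("y", 1:(n - 1)),
      mz = csum[1:(n - 1)] + .WATER_MASS + .PROTON_MASS,
      span = vapply(1:(n - 1), function(k)
        paste(aa[(n - k + 1):n], collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  if ("b" %in% series) {
    csum <- cumsum(res_mass)
    out$b <- data.frame(
      series = "b", index = 1:(n - 1),
      label = paste0("b", 1:(n - 1)),
      mz = csum[1:(n - 1)] + .PROTON_MASS,
      span = vapply(1:(n - 1), function(k)
        paste(aa[1:k], collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  if ("immonium" %in% series) {
    uaa <- unique(aa)
    out$imm <- data.frame(
      series = "immonium", index = NA_integer_,
      label = paste0("imm:", uaa),
      mz = unname(immonium_mz(uaa)),
      span = uaa, stringsAsFactors = FALSE)
  }
  if ("ring_b" %in% series) {
    ring <- list()
    for (r in 0:(n - 1)) {
      rot <- if (r == 0) aa else c(aa[(r + 1):n], aa[1:r])
      csum <- unname(cumsum(vapply(rot, function(a)
        monoisotopic_mass(.RESIDUE_TABLE[[a]]), numeric(1))))
      for (k in 1:(n - 1)) {
        ring[[length(ring) + 1]] <- data.frame(
          series = "ring_b", index = k,
          label = sprintf("rb%d.%d", r, k),
          mz = csum[k] + .PROTON_MASS,
          span = paste(rot[1:k], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    ring <- do.call(rbind, ring)
    ring <- ring[order(ring$mz), , drop = FALSE]
    keep <- c(TRUE, diff(ring$mz) > 1e-4)
    out$ring <- ring[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# global nearest-first greedy one-to-one matching between two mz vectors;
# returns a data.frame of (i, j, delta) pairs within tol
.greedy_match <- function(mz_a, mz_b, tol) {
  if (!length(mz_a) || !length(mz_b))
    return(data.frame(i = integer(), j = integer(), delta = numeric()))
  d <- abs(outer(mz_a, mz_b, `-`))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(i = integer(), j = integer(), delta = numeric()))
  deltas <- d[cand]
  # deterministic order: by |delta|, then by position
  o <- order(deltas, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  deltas <- deltas[o]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  data.frame(i = cand[keep, 1], j = cand[keep, 2], delta = deltas[keep])
}

#' Match theoretical ions against an MS/MS spectrum
#'
#' Nearest-first greedy one-to-one matching: each theoretical ion matches at
#' most one peak and each peak at most one ion, within `tol` Da.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param ions Ion data.frame from [theoretical_ions()].
#' @param tol Fragment tolerance in Da (> 0, default 0.02).
#' @return The `ions` rows that matched, with `peak_mz`, `peak_intensity`
#'   and `delta` columns appended (zero rows when nothing matches).
#' @export
match_spectrum <- function(spectrum, ions, tol = 0.02) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol > 0)
  pk <- spectrum$peaks
  m <- .greedy_match(ions$mz, pk$mz, tol)
  res <- ions[m$i, , drop = FALSE]
  res$peak_mz <- pk$mz[m$j]
  res$peak_intensity <- pk$intensity[m$j]
  res$delta <- res$peak_mz - res$mz
  res <- res[order(res$mz), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign a candidate core sequence to an MS/MS spectrum
#'
#' Implements the acceptance rule used for Amanita cyclic peptides: a
#' candidate is deemed real only when most or all of its residues are
#' explained by the spectrum. Residues are counted as covered when flanked
#' by consecutive matched y-ions (the mass differential identifies the
#' residue; y1 alone identifies the C-terminal residue) or when their
#' residue type has a matched immonium ion. The verdict is `confirmed` when
#' coverage reaches `coverage_threshold` and at least `min_immonium`
#' immonium ions matched.
#'
#' Because Ile and Leu are isobaric, assignments are identical for cores
#' differing only by I/L substitutions; `il_ambiguous` flags cores where
#' this caveat applies.
#'
#' @param core Candidate core sequence.
#' @param spectrum An [ms2_spectrum()].
#' @param tol Fragment tolerance in Da (default 0.02).
#' @param coverage_threshold Minimum residue coverage (default 0.8).
#' @param min_immonium Minimum matched immonium ions (default 1).
#' @param series Ion series to use (default y, b and immonium; b matches
#'   are reported but only y differentials and immonium count towards
#'   coverage).
#' @return A list of class `ms2_assignment` with fields `core`, `verdict`
#'   (`"confirmed"`/`"rejected"`), `residue_coverage`, `covered` (logical
#'   per residue), `matched_y`, `matched_b`, `matched_immonium`,
#'   `il_ambiguous`, `matches` (the matched-ion table).
#' @export
assign_spectrum <- function(core, spectrum, tol = 0.02,
                            coverage_threshold = 0.8, min_immonium = 1,
                            series = c("y", "b", "immonium")) {
  aa <- .check_sequence(core)
  n <- length(aa)
  ions <- theoretical_ions(core, series)
  matches <- match_spectrum(spectrum, ions, tol)
  y_idx <- sort(matches$index[matches$series == "y"])
  b_idx <- sort(matches$index[matches$series == "b"])
  imm <- matches$span[matches$series == "immonium"]
  covered <- logical(n)
  # y_k and y_{k+1} differ by residue n-k; y0 (bare C-terminus) is implicit,
  # so a matched y1 identifies residue n
  for (k in 0:(n - 2)) {
    if ((k == 0 || k %in% y_idx) && (k + 1) %in% y_idx)
      covered[n - k] <- TRUE
  }
  covered[aa %in% imm] <- TRUE
  coverage <- mean(covered)
  verdict <- if (coverage >= coverage_threshold && length(imm) >= min_immonium)
    "confirmed" else "rejected"
  structure(list(core = core, verdict = verdict,
                 residue_coverage = coverage, covered = covered,
                 matched_y = y_idx, matched_b = b_idx,
                 matched_immonium = imm,
                 il_ambiguous = any(aa %in% c("I", "L")),
                 matches = matches),
            class = "ms2_assignment")
}

#' @export
print.ms2_assignment <- function(x, ...) {
  cat(sprintf("cyclo(%s): %s  [coverage %.2f; y: %s; immonium: %s%s]\n",
              x$core, x$verdict, x$residue_coverage,
              if (length(x$matched_y))
                paste0("y", paste(x$matched_y, collapse = ",y")) else "none",
              if (length(x$matched_immonium))
                paste(x$matched_immonium, collapse = ",") else "none",
              if (x$il_ambiguous) "; I/L indistinguishable" else ""))
  invisible(x)
}

#' Compare two MS/MS spectra
#'
#' Counts peaks of `spec_a` having a one-to-one partner in `spec_b` within
#' `tol` Da (nearest-first greedy matching), as used to compare natural
#' versus synthetic peptide spectra.
#'
#' @param spec_a,spec_b [ms2_spectrum()] objects (non-empty).
#' @param tol Tolerance in Da (default 0.02).
#' @return A list with `shared` (count) and `aligned` (data.frame `mz_a`,
#'   `mz_b`, `delta`).
#' @export
compare_spectra <- function(spec_a, spec_b, tol = 0.02) {
  stopifnot(inherits(spec_a, "ms2_spectrum"), inherits(spec_b, "ms2_spectrum"))
  if (!nrow(spec_a$peaks) || !nrow(spec_b$peaks))
    stop("both spectra must be non-empty", call. = FALSE)
  m <- .greedy_match(spec_a$peaks$mz, spec_b$peaks$mz, tol)
  list(shared = nrow(m),
       aligned = data.frame(mz_a = spec_a$peaks$mz[m$i],
                            mz_b = spec_b$peaks$mz[m$j],
                            delta = spec_b$peaks$mz[m$j] - spec_a$peaks$mz[m$i]))
}
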