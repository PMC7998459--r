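# Elemental-composition and monoisotopic-mass arithmetic for linear and
# cyclic peptides, their modification states, adducts, fragments and
# isotope envelopes. Everything downstream (enumeration, MS1 matching,
# MS/MS annotation) is built on these primitives.

.ELEMENTS <- c("C", "H", "N", "O", "S")

# principal-isotope (monoisotopic) masses, Da
.ELEMENT_MASS <- c(
  C = 12.000000000,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.007276466
.WATER_MASS <- 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]] # 18.010565
.CO_MASS <- .ELEMENT_MASS[["C"]] + .ELEMENT_MASS[["O"]]        # 27.994915

# singly-charged cation mass offsets, Da per charge
.ADDUCT_OFFSET <- c(
  H = 1.007276,
  Na = 22.989218,
  K = 38.963158
)

# IUPAC 2021 isotopic abundances (mass, fraction), principal isotope first
.ISOTOPES <- list(
  C = list(mass = c(12.000000, 13.0033548), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503, 2.01410178), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.00307401, 15.00010890), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491462, 16.99913176, 17.99915961),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Monoisotopic element masses
#'
#' Principal-isotope masses (Da) of the five elements occurring in the 20
#' standard amino acid residues.
#'
#' @return Named numeric vector with elements C, H, N, O, S.
#' @export
element_masses <- function() .ELEMENT_MASS

#' Construct an elemental composition
#'
#' An elemental composition is a named integer vector over the fixed element
#' set C, H, N, O, S. All counts must be non-negative.
#'
#' @param C,H,N,O,S Non-negative integer atom counts.
#' @return An object of class `elem_comp` (named integer vector).
#' @examples
#' composition(C = 4, H = 8, N = 2, O = 3) # linear Gly-Gly
#' @export
composition <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  x <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers", call. = FALSE)
  structure(as.integer(round(x)), names = .ELEMENTS, class = "elem_comp")
}

.as_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  if (is.numeric(x) && !is.null(names(x)) && all(names(x) %in% .ELEMENTS)) {
    full <- stats::setNames(integer(5), .ELEMENTS)
    full[names(x)] <- as.integer(round(x))
    return(structure(full, class = "elem_comp"))
  }
  stop("not an elemental composition", call. = FALSE)
}

#' Add two elemental compositions element-wise
#' @param a,b `elem_comp` objects.
#' @return The element-wise sum as an `elem_comp`.
#' @export
comp_add <- function(a, b) {
  a <- .as_comp(a); b <- .as_comp(b)
  structure(as.integer(unclass(a) + unclass(b)), names = .ELEMENTS,
            class = "elem_comp")
}

#' Subtract one elemental composition from another
#'
#' Errors if any resulting count would be negative: compositions are counts
#' of physical atoms, so a deficit indicates an invalid operation.
#'
#' @param a,b `elem_comp` objects; `b` is removed from `a`.
#' @return The element-wise difference as an `elem_comp`.
#' @export
comp_subtract <- function(a, b) {
  a <- .as_comp(a); b <- .as_comp(b)
  d <- unclass(a) - unclass(b)
  if (any(d < 0))
    stop("composition subtraction would give a negative ",
         paste(.ELEMENTS[d < 0], collapse = ","), " count", call. = FALSE)
  structure(as.integer(d), names = .ELEMENTS, class = "elem_comp")
}

#' Format an elemental composition as a molecular formula string
#'
#' @param comp An `elem_comp`.
#' @return A string such as `"C59H84N10O11"`; elements with zero count are
#'   omitted, order is fixed C, H, N, O, S.
#' @export
format_formula <- function(comp) {
  comp <- .as_comp(comp)
  nz <- which(comp > 0)
  paste(paste0(.ELEMENTS[nz], ifelse(comp[nz] > 1, comp[nz], "")),
        collapse = "")
}

#' Parse a molecular formula string into an elemental composition
#' @param x A formula string over C, H, N, O, S, e.g. `"C41H64N10O8S"`.
#' @return An `elem_comp`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- gregexpr("([CHNOS])([0-9]*)", x)
  parts <- regmatches(x, m)[[1]]
  if (nchar(paste(parts, collapse = "")) != nchar(x) || length(parts) == 0)
    stop("cannot parse formula: ", x, call. = FALSE)
  out <- stats::setNames(integer(5), .ELEMENTS)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    out[el] <- out[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  structure(out, class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat(format_formula(x), sprintf("(monoisotopic %.4f Da)\n", monoisotopic_mass(x)))
  invisible(x)
}

# residue formulas (amino acid minus water), one row per one-letter code
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Residue composition table
#'
#' Elemental compositions of the 20 standard amino acid residues
#' (residue = amino acid minus one water, i.e. the in-chain unit).
#'
#' @return Named list of `elem_comp` objects keyed by one-letter code.
#' @export
residue_table <- function() .RESIDUE_TABLE

# built once at load
.RESIDUE_TABLE <- lapply(.RESIDUE_FORMULA, parse_formula)

.check_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  aa <- strsplit(seq, "")[[1]]
  bad <- which(!aa %in% names(.RESIDUE_FORMULA))
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 aa[bad[1]], bad[1], seq), call. = FALSE)
  aa
}

#' Elemental composition of a peptide
#'
#' A linear peptide is the sum of its residue compositions plus one water
#' (the terminal H and OH); head-to-tail macrocyclization condenses out that
#' water, so a cyclic peptide is the plain residue sum.
#'
#' @param seq Peptide sequence (uppercase one-letter codes, length >= 2).
#' @param topology `"linear"` or `"cyclic"`.
#' @return An `elem_comp`.
#' @examples
#' format_formula(peptide_composition("TFLPPLFVPP", "cyclic")) # C59H84N10O11
#' @export
peptide_composition <- function(seq, topology = c("linear", "cyclic")) {
  topology <- match.arg(topology)
  aa <- .check_sequence(seq)
  if (length(aa) < 2)
    stop("peptide must have at least 2 residues", call. = FALSE)
  tot <- stats::setNames(integer(5), .ELEMENTS)
  for (a in aa) tot <- tot + unclass(.RESIDUE_TABLE[[a]])
  if (topology == "linear") {
    tot["H"] <- tot["H"] + 2L
    tot["O"] <- tot["O"] + 1L
  }
  structure(as.integer(tot), names = .ELEMENTS, class = "elem_comp")
}

#' Monoisotopic mass of an elemental composition
#' @param comp An `elem_comp` (or a peptide sequence plus `topology`, via
#'   [peptide_mass()]).
#' @return Mass in Da (full double precision; round only for display).
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_comp(comp)
  sum(unclass(comp) * .ELEMENT_MASS)
}

#' Monoisotopic mass of a peptide sequence
#' @inheritParams peptide_composition
#' @return Mass in Da.
#' @examples
#' peptide_mass("AWDSKHP", "cyclic") # 821.3820
#' @export
peptide_mass <- function(seq, topology = c("linear", "cyclic")) {
  monoisotopic_mass(peptide_composition(seq, topology))
}

#' Apply posttranslational modification state to a composition
#'
#' The modification chemistry of Amanita cyclic peptides is treated at the
#' composition level: each hydroxylation adds one O; sulfoxidation adds one
#' O; formation of the Trp-Cys tryptathionine cross-bridge removes two H.
#' Sulfoxidation and the bridge are only permitted when the sequence
#' contains both Cys and Trp.
#'
#' @param comp `elem_comp` of the (cyclic or linear) peptide.
#' @param seq The peptide sequence the composition came from (used to gate
#'   the Cys/Trp-dependent modifications).
#' @param n_hydroxyl Number of hydroxylations, 0-4.
#' @param sulfoxide Logical; add one O at the thioether.
#' @param bridge Logical; remove two H for the tryptathionine bridge.
#' @return Modified `elem_comp`.
#' @export
apply_modifications <- function(comp, seq, n_hydroxyl = 0, sulfoxide = FALSE,
                                bridge = FALSE) {
  comp <- .as_comp(comp)
  if (!is.numeric(n_hydroxyl) || n_hydroxyl < 0 || n_hydroxyl > 4 ||
      n_hydroxyl != round(n_hydroxyl))
    stop("n_hydroxyl must be an integer in 0..4", call. = FALSE)
  if (isTRUE(sulfoxide) || isTRUE(bridge)) {
    aa <- .check_sequence(seq)
    if (!("C" %in% aa && "W" %in% aa))
      stop("sulfoxide/bridge modifications require both Cys and Trp in '",
           seq, "'", call. = FALSE)
  }
  out <- unclass(comp)
  out["O"] <- out["O"] + as.integer(n_hydroxyl) + as.integer(isTRUE(sulfoxide))
  if (isTRUE(bridge)) {
    if (out["H"] < 2) stop("bridge would give negative H count", call. = FALSE)
    out["H"] <- out["H"] - 2L
  }
  structure(as.integer(out), names = .ELEMENTS, class = "elem_comp")
}

#' m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct `"H"`, `"Na"` or `"K"` (for \[M+H\]+, \[M+Na\]+, \[M+K\]+).
#' @param charge Positive integer charge state (default 1).
#' @return m/z = (neutral_mass + charge * cation mass) / charge.
#' @examples
#' adduct_mz(1108.6321, "H") # 1109.6394
#' @export
adduct_mz <- function(neutral_mass, adduct = c("H", "Na", "K"), charge = 1L) {
  adduct <- match.arg(adduct)
  stopifnot(all(neutral_mass > 0), charge >= 1, charge == round(charge))
  (neutral_mass + charge * .ADDUCT_OFFSET[[adduct]]) / charge
}

#' Mass discrepancy in parts per million
#'
#' @param theoretical Theoretical m/z (> 0).
#' @param measured Measured m/z.
#' @return Non-negative ppm value, `|measured - theoretical| / theoretical * 1e6`,
#'   at full precision. Report layers round to 2 decimals.
#' @examples
#' round(ppm_delta(1109.6394, 1109.6398), 2) # 0.36
#' @export
ppm_delta <- function(theoretical, measured) {
  stopifnot(all(theoretical > 0))
  abs(measured - theoretical) / theoretical * 1e6
}

#' Immonium ion m/z of a residue
#'
#' Immonium ions are low-mass residue-diagnostic fragments produced by
#' combined loss of CO from the acylium; m/z = residue mass - CO + proton.
#'
#' @param residue One-letter residue code (single character, vectorised).
#' @return m/z value(s).
#' @examples
#' immonium_mz("P") # 70.0651
#' @export
immonium_mz <- function(residue) {
  vapply(residue, function(r) {
    if (!r %in% names(.RESIDUE_FORMULA))
      stop("unknown residue '", r, "'", call. = FALSE)
    monoisotopic_mass(.RESIDUE_TABLE[[r]]) - .CO_MASS + .PROTON_MASS
  }, numeric(1), USE.NAMES = !is.null(names(residue)) || length(residue) > 1)
}

# convolve two (mass, abundance) peak lists, merging peaks within mass_bin
.convolve_peaks <- function(a, b, mass_bin, prune = 1e-12) {
  mass <- as.vector(outer(a$mass, b$mass, `+`))
  ab <- as.vector(outer(a$abundance, b$abundance, `*`))
  keep <- ab > 0
  mass <- mass[keep]; ab <- ab[keep]
  o <- order(mass)
  mass <- mass[o]; ab <- ab[o]
  # group peaks closer than mass_bin to their running cluster
  grp <- cumsum(c(TRUE, diff(mass) > mass_bin))
  mass <- vapply(split(mass * ab, grp), sum, 0) /
    vapply(split(ab, grp), sum, 0)
  ab <- vapply(split(ab, grp), sum, 0)
  keep <- ab > prune
  list(mass = unname(mass[keep]), abundance = unname(ab[keep]))
}

#' Isotopic distribution of a composition
#'
#' Computes the fine isotope envelope by element-wise convolution of the
#' per-element isotope distributions, aggregating peaks into bins of width
#' `mass_bin` and renormalizing so abundances sum to one.
#'
#' @param comp An `elem_comp`.
#' @param mass_bin Aggregation bin width in Da (default 0.01).
#' @return A data.frame with columns `mass` and `abundance`, sorted by mass;
#'   the first row is the monoisotopic peak.
#' @export
isotopic_distribution <- function(comp, mass_bin = 0.01) {
  comp <- .as_comp(comp)
  stopifnot(mass_bin > 0)
  dist <- list(mass = 0, abundance = 1)
  for (el in .ELEMENTS) {
    n <- comp[[el]]
    if (n == 0) next
    iso <- list(mass = .ISOTOPES[[el]]$mass, abundance = .ISOTOPES[[el]]$abundance)
    for (i in seq_len(n)) dist <- .convolve_peaks(dist, iso, mass_bin)
  }
  ab <- dist$abundance / sum(dist$abundance)
  data.frame(mass = dist$mass, abundance = ab)
}
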