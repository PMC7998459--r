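# Peak-list and spectrum I/O: CSV peak lists (mz[,intensity[,rt]]), the
# Mascot generic format (MGF), and the package's commented-TSV convention.
# The MGF dialect supported is the standard BEGIN IONS / TITLE / PEPMASS /
# RTINSECONDS / peak-line / END IONS block structure.

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Construct an MS/MS spectrum object
#'
#' @param peaks data.frame with columns `mz` and `intensity` (sorted by mz
#'   on construction).
#' @param precursor_mz Precursor m/z (optional, `NA` allowed).
#' @param title Optional spectrum title.
#' @param collision_energy Optional collision energy (eV), metadata only.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(peaks, precursor_mz = NA_real_, title = NULL,
                         collision_energy = NA_real_) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0)) stop("non-positive m/z in spectrum", call. = FALSE)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(precursor_mz = precursor_mz, peaks = peaks, title = title,
                 collision_energy = collision_energy),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("ms2_spectrum: %d peaks, precursor %.4f%s\n",
              nrow(x$peaks), x$precursor_mz,
              if (is.null(x$title)) "" else paste0(" (", x$title, ")")))
  invisible(x)
}

#' Read an MGF file
#'
#' @param path MGF file path.
#' @return A list of [ms2_spectrum()] objects (one per BEGIN IONS block).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF: ", path, call. = FALSE)
  lines <- readLines(path)
  spectra <- list()
  inblock <- FALSE
  pep <- NA_real_; title <- NULL; ce <- NA_real_
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (inblock) stop("line ", i, ": nested BEGIN IONS", call. = FALSE)
      inblock <- TRUE
      pep <- NA_real_; title <- NULL; ce <- NA_real_
      mz <- numeric(0); int <- numeric(0)
    } else if (ln == "END IONS") {
      if (!inblock) stop("line ", i, ": END IONS without BEGIN", call. = FALSE)
      inblock <- FALSE
      spectra[[length(spectra) + 1]] <- ms2_spectrum(
        data.frame(mz = mz, intensity = int), pep, title, ce)
    } else if (grepl("^[A-Z]+=", ln)) {
      key <- sub("=.*", "", ln)
      val <- sub("^[A-Z]+=", "", ln)
      if (key == "PEPMASS") pep <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      if (key == "TITLE") title <- val
      if (key == "COLLISIONENERGY") ce <- as.numeric(val)
    } else if (inblock) {
      parts <- strsplit(ln, "[ \t,]+")[[1]]
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) < 1 || any(is.na(v[seq_len(min(2, length(v)))])))
        stop("line ", i, ": malformed peak line '", ln, "'", call. = FALSE)
      mz <- c(mz, v[1])
      int <- c(int, if (length(v) >= 2) v[2] else 0)
    } else {
      stop("line ", i, ": content outside BEGIN IONS block", call. = FALSE)
    }
  }
  if (inblock) stop("unterminated BEGIN IONS block", call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of [ms2_spectrum()] objects.
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz))
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$collision_energy))
      writeLines(sprintf("COLLISIONENERGY=%g", sp$collision_energy), con)
    writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an MS1 peak list
#'
#' CSV input is `mz[,intensity[,rt]]` with an optional header line. MGF
#' input in `"precursor"` mode yields one peak per BEGIN IONS block (the
#' PEPMASS value, as written by MS1-mode exports); `"fragments"` mode pools
#' every fragment peak of every block.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @param mode For MGF input: `"precursor"` or `"fragments"`.
#' @return A data.frame with columns `mz`, `intensity`, `rt`, sorted by mz.
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "mgf"),
                          mode = c("precursor", "fragments")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  if (format == "mgf") {
    spectra <- read_mgf(path)
    if (mode == "precursor") {
      df <- data.frame(
        mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
        intensity = vapply(spectra, function(s)
          if (nrow(s$peaks)) max(s$peaks$intensity) else 0, numeric(1)),
        rt = NA_real_)
    } else {
      df <- do.call(rbind, lapply(spectra, function(s)
        data.frame(mz = s$peaks$mz, intensity = s$peaks$intensity,
                   rt = NA_real_)))
    }
  } else {
    if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    start <- 1L
    if (length(lines) &&
        is.na(suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))))
      start <- 2L # header line
    rows <- lapply(seq(start, length.out = max(0, length(lines) - start + 1)),
                   function(i) {
      v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
      if (length(v) < 1 || is.na(v[1]))
        stop("line ", i, ": malformed CSV peak line", call. = FALSE)
      c(v[1],
        if (length(v) >= 2 && !is.na(v[2])) v[2] else 0,
        if (length(v) >= 3) v[3] else NA_real_)
    })
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("mz", "intensity", "rt")
  }
  if (any(df$mz <= 0, na.rm = TRUE) || any(is.na(df$mz)))
    stop("non-positive or missing m/z in peak list", call. = FALSE)
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  df
}
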