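# MS1 matching: candidate theoretical m/z against measured peak lists at
# ppm accuracy, restricted to the instrument scan range. The reported
# discrepancy is computed against the 4-decimal theoretical m/z, the
# precision at which theoretical values are reported.

#' Match candidates against an MS1 peak list
#'
#' Every (candidate, adduct, peak) combination whose ppm discrepancy is at
#' most `tol_ppm` and whose theoretical m/z lies inside `scan_range` is
#' reported. One peak may match several candidates and vice versa;
#' ambiguity is resolved downstream at the MS/MS stage. The reported
#' `delta_ppm` is computed from the theoretical m/z rounded to 4 decimals
#' (the reporting precision for m/z), which is also the matching criterion.
#'
#' @param peaks Peak data.frame from [read_peaklist()] (columns `mz`,
#'   optionally `intensity`, `rt`).
#' @param candidates Candidate data.frame from [candidate_table()] /
#'   [enumerate_candidates()] (non-empty).
#' @param tol_ppm Tolerance in ppm (> 0, default 5).
#' @param scan_range Instrument scan range in m/z (default `c(500, 1700)`).
#' @return A data.frame with one row per match: candidate descriptor
#'   columns, `adduct`, `theoretical_mz` (4 decimals), `measured_mz`,
#'   `intensity`, `rt`, `delta_ppm` (2 decimals), sorted by `delta_ppm`.
#' @export
match_ms1 <- function(peaks, candidates, tol_ppm = 5,
                      scan_range = c(500, 1700)) {
  stopifnot(tol_ppm > 0, length(scan_range) == 2)
  if (!is.data.frame(candidates) || nrow(candidates) == 0)
    stop("empty candidate list", call. = FALSE)
  if (!is.data.frame(peaks) || !"mz" %in% names(peaks))
    stop("peaks must be a data.frame with an mz column", call. = FALSE)
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  if (!"rt" %in% names(peaks)) peaks$rt <- NA_real_
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  pmz <- peaks$mz
  out <- list()
  for (ad in c("H", "Na", "K")) {
    col <- paste0("mz_", ad)
    if (!col %in% names(candidates)) next
    theo <- round(candidates[[col]], 4)
    in_range <- theo >= scan_range[1] & theo <= scan_range[2]
    for (i in which(in_range)) {
      t <- theo[i]
      lo <- t * (1 - tol_ppm * 1e-6)
      hi <- t * (1 + tol_ppm * 1e-6)
      j0 <- findInterval(lo, pmz) + 1L
      j1 <- findInterval(hi, pmz)
      if (j1 < j0) next
      for (j in j0:j1) {
        d <- ppm_delta(t, pmz[j])
        if (d > tol_ppm) next
        row <- candidates[i, setdiff(names(candidates),
                                     c("mz_H", "mz_Na", "mz_K")),
                          drop = FALSE]
        row$adduct <- ad
        row$theoretical_mz <- t
        row$measured_mz <- pmz[j]
        row$intensity <- peaks$intensity[j]
        row$rt <- peaks$rt[j]
        row$delta_ppm <- round(d, 2)
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (!length(out)) {
    res <- candidates[0, setdiff(names(candidates),
                                 c("mz_H", "mz_Na", "mz_K")), drop = FALSE]
    res$adduct <- character(0)
    res$theoretical_mz <- res$measured_mz <- numeric(0)
    res$intensity <- res$rt <- res$delta_ppm <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$delta_ppm, res$theoretical_mz, res$adduct), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
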