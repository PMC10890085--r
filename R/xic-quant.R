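#' Extract an ion chromatogram at ppm tolerance
#'
#' For every MS1 spectrum, sums the intensities of centroids whose
#' deviation from the target satisfies
#' `|mz - target| / target * 1e6 <= ppm_tol` (symmetric, inclusive,
#' computed against the target m/z). Spectra with no matching centroid
#' contribute intensity 0, so the chromatogram always spans the full run.
#'
#' @param run An [ms_run()] with at least one MS1 spectrum.
#' @param target_mz Target m/z (> 0).
#' @param ppm_tol Mass tolerance in ppm (> 0); the method default is 5.
#' @return A `chromatogram` object: list with ascending `rt` (minutes)
#'   and `intensity` vectors of equal length.
#' @export
extract_xic <- function(run, target_mz, ppm_tol = 5) {
  stopifnot(inherits(run, "ms_run"),
            is.numeric(target_mz), length(target_mz) == 1L, target_mz > 0,
            is.numeric(ppm_tol), length(ppm_tol) == 1L, ppm_tol > 0)
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  if (!length(ms1)) stop("run has no MS1 spectra", call. = FALSE)
  half <- target_mz * ppm_tol * 1e-6
  lo <- target_mz - half
  hi <- target_mz + half
  rt <- vapply(ms1, `[[`, numeric(1), "rt")
  intensity <- vapply(ms1, function(s) {
    if (!length(s$mz)) return(0)
    i1 <- findInterval(lo, s$mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, s$mz)
    if (i2 < i1) 0 else sum(s$intensity[i1:i2])
  }, numeric(1))
  structure(list(rt = rt, intensity = intensity), class = "chromatogram")
}

# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Integrate a chromatographic peak inside a retention-time window
#'
#' Locates the apex (maximum intensity) within
#' `[expected_rt - rt_tol, expected_rt + rt_tol]`; when two apices tie,
#' the one closer to the expected RT wins, exact ties resolve to the
#' earlier RT. Integration bounds extend from the apex outwards to the
#' nearest local minima (or the window edges), and the area is the
#' trapezoidal integral of intensity over RT with no baseline
#' subtraction.
#'
#' @param chrom A `chromatogram` from [extract_xic()].
#' @param expected_rt Expected retention time, minutes.
#' @param rt_tol Window half-width, minutes (> 0).
#' @param compound_id Optional id attached to the result.
#' @return An `integrated_peak` (fields `compound_id`, `rt_apex`,
#'   `rt_lo`, `rt_hi`, `area` in intensity x minutes, `apex_intensity`),
#'   or `NULL` when the window is empty or contains no signal.
#' @export
integrate_peak <- function(chrom, expected_rt, rt_tol,
                           compound_id = NA_character_) {
  stopifnot(inherits(chrom, "chromatogram"),
            is.numeric(expected_rt), length(expected_rt) == 1L,
            is.numeric(rt_tol), length(rt_tol) == 1L, rt_tol > 0)
  if (!length(chrom$rt)) return(NULL)
  idx <- which(chrom$rt >= expected_rt - rt_tol &
                 chrom$rt <= expected_rt + rt_tol)
  if (!length(idx)) return(NULL)
  y <- chrom$intensity[idx]
  x <- chrom$rt[idx]
  if (max(y) <= 0) return(NULL)
  apex_candidates <- which(y == max(y))
  if (length(apex_candidates) > 1L) {
    d <- abs(x[apex_candidates] - expected_rt)
    apex_candidates <- apex_candidates[d == min(d)]
  }
  apex <- apex_candidates[1L]  # earliest RT on exact tie
  lo <- apex
  while (lo > 1L && y[lo - 1L] <= y[lo]) lo <- lo - 1L
  hi <- apex
  while (hi < length(y) && y[hi + 1L] <= y[hi]) hi <- hi + 1L
  structure(list(compound_id = compound_id,
                 rt_apex = x[apex],
                 rt_lo = x[lo], rt_hi = x[hi],
                 area = .trapz(x[lo:hi], y[lo:hi]),
                 apex_intensity = y[apex]),
            class = "integrated_peak")
}

#' Quantify one run against a compound library
#'
#' Runs [extract_xic()] then [integrate_peak()] for every library entry
#' and returns one peak area (or `NA` for missing) per compound — one
#' row of the study peak table.
#'
#' @param run An [ms_run()].
#' @param library Compound-library data.frame (validated via
#'   [validate_compound_library()]); must be non-empty with unique ids.
#' @param config A [default_config()]-style list supplying `ppm_tol` and
#'   the fallback `rt_tol` for entries without their own.
#' @return Named numeric vector of areas, names = compound ids, `NA`
#'   where no peak was found.
#' @export
quantify_run <- function(run, library, config = default_config()) {
  if (is.null(library) || !nrow(library)) {
    stop("compound library is empty", call. = FALSE)
  }
  library <- validate_compound_library(library)
  areas <- vapply(seq_len(nrow(library)), function(i) {
    chrom <- extract_xic(run, library$target_mz[i], config$ppm_tol)
    tol <- library$rt_tol[i]
    if (is.na(tol)) tol <- config$rt_tol
    pk <- integrate_peak(chrom, library$rt_expected[i], tol,
                         compound_id = library$compound_id[i])
    if (is.null(pk)) NA_real_ else pk$area
  }, numeric(1))
  names(areas) <- library$compound_id
  areas
}

#' Cosine similarity between two MS2 spectra
#'
#' Fragments are matched one-to-one within `frag_tol` Da, greedily in
#' order of decreasing intensity product (ties broken by smaller m/z
#' difference), each fragment used at most once. The score is the cosine
#' of the matched intensity vectors, with unmatched fragments entering as
#' zero-paired entries, so it is symmetric and bounded in [0, 1].
#'
#' @param a,b `ms_spectrum` objects with `ms_level == 2`.
#' @param frag_tol Fragment match tolerance in Da (> 0).
#' @return Similarity in [0, 1]; empty spectra give 0 with a warning.
#' @export
ms2_cosine <- function(a, b, frag_tol = 0.01) {
  stopifnot(inherits(a, "ms_spectrum"), inherits(b, "ms_spectrum"),
            is.numeric(frag_tol), frag_tol > 0)
  if (a$ms_level != 2L || b$ms_level != 2L) {
    stop("ms2_cosine requires MS2 spectra", call. = FALSE)
  }
  if (!length(a$mz) || !length(b$mz)) {
    warning("empty MS2 spectrum; similarity 0", call. = FALSE)
    return(0)
  }
  cand <- which(abs(outer(a$mz, b$mz, "-")) <= frag_tol, arr.ind = TRUE)
  dot <- 0
  if (nrow(cand)) {
    prod <- a$intensity[cand[, 1L]] * b$intensity[cand[, 2L]]
    dmz <- abs(a$mz[cand[, 1L]] - b$mz[cand[, 2L]])
    ord <- order(-prod, dmz, cand[, 1L], cand[, 2L])
    used_a <- logical(length(a$mz))
    used_b <- logical(length(b$mz))
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- used_b[j] <- TRUE
        dot <- dot + a$intensity[i] * b$intensity[j]
      }
    }
  }
  denom <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  if (denom == 0) return(0)
  min(1, dot / denom)
}
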