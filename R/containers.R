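#' A single centroided mass spectrum
#'
#' @param rt Retention time in minutes (>= 0).
#' @param mz Numeric vector of centroid m/z values, strictly ascending.
#' @param intensity Numeric vector of intensities, same length, >= 0.
#' @param ms_level 1 (survey) or 2 (fragmentation).
#' @param precursor_mz,collision_energy Optional MS2 metadata.
#' @return An `ms_spectrum` object.
#' @export
ms_spectrum <- function(rt, mz, intensity, ms_level = 1L,
                        precursor_mz = NULL, collision_energy = NULL) {
  stopifnot(is.numeric(rt), length(rt) == 1L, is.finite(rt), rt >= 0,
            is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity),
            ms_level %in% c(1L, 2L))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("spectrum m/z values must be strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("spectrum intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(rt = as.numeric(rt), mz = as.numeric(mz),
                 intensity = as.numeric(intensity),
                 ms_level = as.integer(ms_level),
                 precursor_mz = precursor_mz,
                 collision_energy = collision_energy),
            class = "ms_spectrum")
}

#' An ordered LC-MS run of centroided spectra
#'
#' @param spectra List of [ms_spectrum()] objects with non-decreasing RT.
#' @param run_id Run identifier string.
#' @param polarity `"positive"` or `"negative"`.
#' @param scan_range Optional numeric length-2 acquired m/z range, e.g.
#'   `c(70, 1000)` for a full scan or `c(600, 800)` for the narrow thyroid
#'   hormone scan.
#' @return An `ms_run` object.
#' @export
ms_run <- function(spectra, run_id = "run", polarity = "positive",
                   scan_range = NULL) {
  stopifnot(is.list(spectra),
            polarity %in% c("positive", "negative"))
  if (!length(spectra)) stop("no spectra", call. = FALSE)
  ok <- vapply(spectra, inherits, logical(1), "ms_spectrum")
  if (!all(ok)) stop("all elements must be ms_spectrum objects", call. = FALSE)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (length(rts) > 1L && any(diff(rts) < 0)) {
    stop("spectrum retention times must be non-decreasing", call. = FALSE)
  }
  if (!is.null(scan_range)) {
    stopifnot(is.numeric(scan_range), length(scan_range) == 2L,
              scan_range[1] < scan_range[2])
  }
  structure(list(spectra = spectra, run_id = run_id, polarity = polarity,
                 scan_range = scan_range),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run '%s'> %d spectra (%d MS1, %d MS2), %s mode\n",
              x$run_id, length(x$spectra), sum(lv == 1L), sum(lv == 2L),
              x$polarity))
  rng <- range(vapply(x$spectra, `[[`, numeric(1), "rt"))
  cat(sprintf("  RT %.3f-%.3f min", rng[1], rng[2]))
  if (!is.null(x$scan_range)) {
    cat(sprintf("; scan range m/z %g-%g", x$scan_range[1], x$scan_range[2]))
  }
  cat("\n")
  invisible(x)
}

.sample_types <- c("study", "pool", "pool_dilution", "blank", "mock",
                   "standard")

#' Validate a sample-metadata table
#'
#' Required columns: `sample_id`, `group`, `sample_type` (one of study,
#' pool, pool_dilution, blank, mock, standard), `dilution_factor` in
#' (0, 1] (1 = undiluted; pool_dilution requires < 1). Optional:
#' `injection_order`, `volume_ul`, `storage`.
#'
#' @param meta A data.frame.
#' @return The validated data.frame (invisibly unchanged apart from type
#'   coercion of `dilution_factor`).
#' @export
validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "group", "sample_type", "dilution_factor")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(meta$sample_type), .sample_types)
  if (length(bad)) {
    stop("unknown sample_type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta$dilution_factor <- as.numeric(meta$dilution_factor)
  df <- meta$dilution_factor
  if (any(!is.finite(df)) || any(df <= 0) || any(df > 1)) {
    stop("dilution_factor must lie in (0, 1]", call. = FALSE)
  }
  if (any(meta$sample_type == "pool_dilution" & df >= 1)) {
    stop("pool_dilution samples require dilution_factor < 1", call. = FALSE)
  }
  meta
}

#' Validate a compound-library table
#'
#' Required columns: `compound_id`, `name`, `rt_expected` (minutes, > 0),
#' and either `formula` + `adduct` or a precomputed `target_mz`. Optional:
#' `rt_tol` (minutes), `is_internal_standard` (logical), `is_pair`
#' (compound_id of the paired internal standard for isotope-dilution
#' analytes). When both `formula` and `target_mz` are present,
#' `target_mz` wins and a warning is issued; otherwise `target_mz` is
#' filled in from the formula and adduct.
#'
#' @param lib A data.frame.
#' @return The validated data.frame with a resolved `target_mz` column.
#' @export
validate_compound_library <- function(lib) {
  stopifnot(is.data.frame(lib))
  need <- c("compound_id", "name", "rt_expected")
  miss <- setdiff(need, names(lib))
  if (length(miss)) {
    stop("compound library missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$compound_id)) {
    stop("duplicate compound ids: ",
         paste(unique(lib$compound_id[duplicated(lib$compound_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!"is_internal_standard" %in% names(lib)) {
    lib$is_internal_standard <- FALSE
  }
  lib$is_internal_standard <- as.logical(lib$is_internal_standard)
  if (!"is_pair" %in% names(lib)) lib$is_pair <- NA_character_
  if (!"rt_tol" %in% names(lib)) lib$rt_tol <- NA_real_
  if (any(!is.finite(lib$rt_expected)) || any(lib$rt_expected <= 0)) {
    stop("rt_expected must be finite and > 0 (minutes)", call. = FALSE)
  }
  has_formula <- "formula" %in% names(lib) &&
    any(!is.na(lib$formula) & nzchar(lib$formula))
  has_mz <- "target_mz" %in% names(lib) && any(!is.na(lib$target_mz))
  if (!"target_mz" %in% names(lib)) lib$target_mz <- NA_real_
  lib$target_mz <- as.numeric(lib$target_mz)
  both <- if (has_formula && has_mz) {
    !is.na(lib$target_mz) & !is.na(lib$formula) & nzchar(lib$formula)
  } else rep(FALSE, nrow(lib))
  if (any(both)) {
    # warn only on a real conflict so that re-validating an
    # already-resolved library stays quiet
    if (!all(c("adduct") %in% names(lib))) lib$adduct <- NA_character_
    conflict <- vapply(which(both), function(i) {
      if (is.na(lib$adduct[i]) || !nzchar(lib$adduct[i])) return(FALSE)
      comp <- tryCatch(adduct_mz(monoisotopic_mass(lib$formula[i]),
                                 lib$adduct[i]),
                       error = function(e) NA_real_)
      is.na(comp) || abs(comp - lib$target_mz[i]) > 1e-3
    }, logical(1))
    if (any(conflict)) {
      warning("both formula and target_mz present and disagree for: ",
              paste(lib$compound_id[which(both)[conflict]],
                    collapse = ", "), "; target_mz wins", call. = FALSE)
    }
  }
  fill <- is.na(lib$target_mz)
  if (any(fill)) {
    if (!all(c("formula", "adduct") %in% names(lib))) {
      stop("compounds without target_mz need formula and adduct columns",
           call. = FALSE)
    }
    bad <- fill & (is.na(lib$formula) | !nzchar(lib$formula) |
                     is.na(lib$adduct) | !nzchar(lib$adduct))
    if (any(bad)) {
      stop("compound(s) with neither target_mz nor formula+adduct: ",
           paste(lib$compound_id[bad], collapse = ", "), call. = FALSE)
    }
    lib$target_mz[fill] <- vapply(which(fill), function(i) {
      adduct_mz(monoisotopic_mass(lib$formula[i]), lib$adduct[i])
    }, numeric(1))
  }
  if (any(!is.finite(lib$target_mz)) || any(lib$target_mz <= 0)) {
    stop("resolved target_mz must be finite and > 0", call. = FALSE)
  }
  pair <- lib$is_pair[!is.na(lib$is_pair) & nzchar(lib$is_pair)]
  if (length(pair)) {
    unknown <- setdiff(pair, lib$compound_id)
    if (length(unknown)) {
      stop("is_pair references unknown compound(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(pair, lib$compound_id)
    if (!all(lib$is_internal_standard[idx])) {
      stop("is_pair must reference internal-standard-flagged compounds",
           call. = FALSE)
    }
  }
  lib
}

#' Samples-by-compounds table of integrated peak areas
#'
#' The central container of the pipeline: a numeric matrix with samples
#' in rows and compounds in columns, `NA` marking missing peaks, plus the
#' attached sample metadata and compound library. Literal zeros are kept
#' on input but treated as missing by every analysis step.
#'
#' @param areas Numeric matrix with unique row (sample) and column
#'   (compound) names; entries `NA` or >= 0.
#' @param samples Sample-metadata data.frame (see
#'   [validate_sample_meta()]); defaults to a minimal `study` frame built
#'   from the row names.
#' @param compounds Compound-library data.frame (see
#'   [validate_compound_library()]); optional.
#' @return A `peak_table` object with elements `areas`, `samples`,
#'   `compounds`.
#' @export
peak_table <- function(areas, samples = NULL, compounds = NULL) {
  stopifnot(is.matrix(areas), is.numeric(areas))
  if (is.null(rownames(areas)) || is.null(colnames(areas))) {
    stop("areas matrix needs sample row names and compound column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(areas))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(areas)[duplicated(rownames(areas))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(areas))) {
    stop("duplicate compound ids: ",
         paste(unique(colnames(areas)[duplicated(colnames(areas))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(areas < 0, na.rm = TRUE)) {
    stop("peak areas must be >= 0 where present", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(areas), group = "study",
                          sample_type = "study", dilution_factor = 1,
                          stringsAsFactors = FALSE)
  }
  samples <- validate_sample_meta(samples)
  if (!setequal(samples$sample_id, rownames(areas)) ||
      nrow(samples) != nrow(areas)) {
    stop("sample metadata ids must match area matrix row names",
         call. = FALSE)
  }
  samples <- samples[match(rownames(areas), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(compounds)) {
    compounds <- validate_compound_library(compounds)
    if (!setequal(compounds$compound_id, colnames(areas)) ||
        nrow(compounds) != ncol(areas)) {
      stop("compound library ids must match area matrix column names",
           call. = FALSE)
    }
    compounds <- compounds[match(colnames(areas), compounds$compound_id), ,
                           drop = FALSE]
    rownames(compounds) <- NULL
  }
  structure(list(areas = areas, samples = samples, compounds = compounds),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d samples x %d compounds; %d missing cells\n",
              nrow(x$areas), ncol(x$areas), sum(is.na(x$areas))))
  tab <- table(x$samples$sample_type)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$compounds)) {
    cat(sprintf("  compounds: %d internal standards, %d analytes\n",
                sum(x$compounds$is_internal_standard),
                sum(!x$compounds$is_internal_standard)))
  }
  invisible(x)
}

#' Subset a peak table
#'
#' @param x A `peak_table`.
#' @param i Sample selector (names, indices or logical).
#' @param j Compound selector.
#' @param ... Ignored.
#' @return A `peak_table` with metadata subset in step.
#' @export
`[.peak_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$areas))
  if (missing(j)) j <- seq_len(ncol(x$areas))
  areas <- x$areas[i, j, drop = FALSE]
  samples <- x$samples[match(rownames(areas), x$samples$sample_id), ,
                       drop = FALSE]
  rownames(samples) <- NULL
  compounds <- x$compounds
  if (!is.null(compounds)) {
    compounds <- compounds[match(colnames(areas), compounds$compound_id), ,
                           drop = FALSE]
    rownames(compounds) <- NULL
    # pairings to compounds that were subset away are cleared
    gone <- !is.na(compounds$is_pair) &
      !(compounds$is_pair %in% compounds$compound_id)
    compounds$is_pair[gone] <- NA_character_
  }
  peak_table(areas, samples, compounds)
}

# Analysis view of the area matrix: literal zeros count as missing
# (zeros are excluded from every downstream computation).
.analysis_areas <- function(table) {
  a <- table$areas
  a[!is.na(a) & a == 0] <- NA_real_
  a
}

.is_ids <- function(table) {
  if (is.null(table$compounds)) return(character(0))
  table$compounds$compound_id[table$compounds$is_internal_standard]
}
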