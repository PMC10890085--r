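#' A standard dilution series
#'
#' @param compound_id Compound identifier.
#' @param concentration Concentrations in nM, >= 0 (0 rows are blanks).
#' @param area Measured peak areas (same length).
#' @param replicate Optional replicate index per row.
#' @return A `dilution_series` data.frame.
#' @export
dilution_series <- function(compound_id, concentration, area,
                            replicate = NULL) {
  stopifnot(is.numeric(concentration), is.numeric(area),
            length(concentration) == length(area))
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(concentration, concentration, FUN = seq_along)
  }
  structure(data.frame(compound_id = compound_id,
                       concentration_nM = concentration,
                       replicate = replicate, area = area,
                       stringsAsFactors = FALSE),
            class = c("dilution_series", "data.frame"))
}

#' Read a dilution-series CSV
#'
#' Columns: `compound`, `concentration_nM`, `replicate`, `area`.
#'
#' @param path CSV path.
#' @return Named list of `dilution_series`, one per compound.
#' @export
read_dilution_series <- function(path) {
  df <- .read_csv(path)
  need <- c("compound", "concentration_nM", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dilution series CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$compound), function(d) {
    dilution_series(d$compound[1], d$concentration_nM, d$area,
                    replicate = if ("replicate" %in% names(d)) d$replicate)
  })
}

#' Estimate linear dynamic range and limit of detection
#'
#' Anchored at the highest concentration, finds the longest contiguous
#' run of non-zero concentration levels (>= 4 levels) whose ordinary
#' least-squares fit of mean area versus concentration reaches
#' `R^2 >= rsq_min`. The limit of detection (LOD) is the lowest
#' concentration inside that linear segment whose mean area exceeds the
#' blank mean + 3 x blank standard deviation — i.e. the conventional
#' 3-sigma criterion constrained to the linear range. The lowest linear
#' level is reported alongside (`linear_range[1]`) since "linear limit of
#' detection" is also used in that sense.
#'
#' @param series A [dilution_series()] with >= 4 non-zero levels and
#'   >= 2 blank (concentration 0) replicates.
#' @param rsq_min Minimum R-squared of the linear segment (default 0.99).
#' @return A `calibration_result`: `slope`, `intercept`, `r_squared`,
#'   `lod` (nM, `NA` with status `"above range"` when no in-range level
#'   clears the blank threshold), `blank_threshold`, `linear_range`
#'   (length-2, nM), `level_cv` (per-level CV percent), `status`
#'   (`"ok"` or `"no linear range"`).
#' @export
fit_linear_range <- function(series, rsq_min = 0.99) {
  stopifnot(inherits(series, "dilution_series") || is.data.frame(series),
            is.numeric(rsq_min), rsq_min > 0, rsq_min <= 1)
  conc <- series$concentration_nM
  area <- series$area
  blanks <- area[conc == 0]
  if (length(blanks) < 2L) {
    stop("LOD requires >= 2 blank replicates (concentration 0), found ",
         length(blanks), call. = FALSE)
  }
  levels <- sort(unique(conc[conc > 0]))
  if (length(levels) < 4L) {
    stop("need >= 4 non-zero concentration levels, found ", length(levels),
         call. = FALSE)
  }
  means <- vapply(levels, function(l) mean(area[conc == l]), numeric(1))
  cvs <- vapply(levels, function(l) {
    v <- area[conc == l]
    if (length(v) < 2L || mean(v) == 0) NA_real_
    else 100 * stats::sd(v) / mean(v)
  }, numeric(1))
  names(cvs) <- format(levels)
  k <- length(levels)
  chosen <- NULL
  for (start in seq_len(k - 3L)) {       # longest run first
    x <- levels[start:k]
    y <- means[start:k]
    if (stats::sd(y) == 0) next
    r2 <- stats::cor(x, y)^2
    if (r2 >= rsq_min) {
      fit <- stats::lm.fit(cbind(1, x), y)
      chosen <- list(start = start, slope = fit$coefficients[2],
                     intercept = fit$coefficients[1], r2 = r2)
      break
    }
  }
  blank_mean <- mean(blanks)
  blank_sd <- stats::sd(blanks)
  threshold <- blank_mean + 3 * blank_sd
  if (is.null(chosen)) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, lod = NA_real_,
                          blank_threshold = threshold,
                          linear_range = c(NA_real_, NA_real_),
                          level_cv = cvs, status = "no linear range"),
                     class = "calibration_result"))
  }
  in_run <- chosen$start:k
  above <- in_run[means[in_run] > threshold]
  lod <- if (length(above)) levels[min(above)] else NA_real_
  structure(list(slope = unname(chosen$slope),
                 intercept = unname(chosen$intercept),
                 r_squared = chosen$r2,
                 lod = lod,
                 blank_threshold = threshold,
                 linear_range = c(levels[chosen$start], levels[k]),
                 level_cv = cvs,
                 status = if (is.na(lod)) "above range" else "ok"),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  if (x$status == "no linear range") {
    cat("<calibration_result> no linear range\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<calibration_result> linear %g-%g nM (R^2 %.4f); LOD %s nM [%s]\n",
    x$linear_range[1], x$linear_range[2], x$r_squared,
    if (is.na(x$lod)) "-" else format(x$lod), x$status))
  invisible(x)
}

#' Write calibration results to JSON
#'
#' @param results A `calibration_result` or named list of them.
#' @param path Output JSON path.
#' @export
write_calibration <- function(results, path) {
  if (inherits(results, "calibration_result")) results <- list(results)
  jsonlite::write_json(lapply(results, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
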