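# Four-step normalization / QC chain (applied in this fixed order):
#   1. assemble peak areas            -> peak_table (msdata_io)
#   2. internal-standard factors      -> is_factors() / apply_factors()
#   3. pooled-QC filtering            -> pooled_cv(), dilution_linearity(),
#                                        qc_filter()
#   4. total-signal normalization     -> total_signal_normalize()
# plus isotope-dilution thyroid-hormone ratios: th_relative_abundance().

# Samples that can receive a normalization factor; blanks and mocks carry
# no biological material and (for blanks) no internal standards.
.normalizable_types <- c("study", "pool", "pool_dilution", "standard")

#' Per-sample internal-standard normalization factors
#'
#' For each usable internal standard (IS) s and sample j, the
#' mean-centered area is `r_sj = area_sj / mean_over_reference(area_s.)`;
#' the sample factor is the arithmetic mean of `r_sj` over all usable IS.
#' Dividing every raw area in sample j by `f_j` removes per-sample
#' multiplicative technical/matrix distortions. IS with any missing value
#' across the factor-receiving samples are dropped with a warning; blanks
#' and mocks neither receive factors nor contribute to IS means.
#'
#' @param table A [peak_table()] with an attached compound library whose
#'   `is_internal_standard` column flags the IS panel.
#' @param reference_types Sample types whose mean defines the centering
#'   denominator (default study + undiluted pool).
#' @return A `norm_factors` object: `factors` (named, one per
#'   factor-receiving sample), `is_used`, `is_means`.
#' @export
is_factors <- function(table, reference_types = c("study", "pool")) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(table$compounds)) {
    stop("peak table has no compound library; cannot identify internal ",
         "standards", call. = FALSE)
  }
  is_ids <- .is_ids(table)
  if (!length(is_ids)) stop("no internal-standard compounds", call. = FALSE)
  a <- .analysis_areas(table)
  norm_samples <- table$samples$sample_id[
    table$samples$sample_type %in% .normalizable_types]
  ref_samples <- table$samples$sample_id[
    table$samples$sample_type %in% reference_types &
      table$samples$dilution_factor == 1]
  if (!length(ref_samples)) {
    stop("no reference samples of type ",
         paste(reference_types, collapse = "/"), call. = FALSE)
  }
  sub <- a[norm_samples, is_ids, drop = FALSE]
  usable <- colSums(is.na(sub)) == 0L
  if (any(!usable)) {
    warning("dropping internal standard(s) with missing values: ",
            paste(is_ids[!usable], collapse = ", "), call. = FALSE)
  }
  if (!any(usable)) {
    stop("no usable internal standards (all have missing values)",
         call. = FALSE)
  }
  used <- is_ids[usable]
  is_means <- colMeans(a[ref_samples, used, drop = FALSE])
  centered <- sweep(a[norm_samples, used, drop = FALSE], 2L, is_means, "/")
  factors <- rowMeans(centered)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("normalization factors must be finite and positive", call. = FALSE)
  }
  structure(list(factors = factors, is_used = used, is_means = is_means),
            class = "norm_factors")
}

#' Apply internal-standard normalization factors
#'
#' Divides each factor-receiving sample's areas by its factor; samples
#' without a factor (blanks, mocks) pass through unchanged.
#'
#' @param table A [peak_table()].
#' @param factors A `norm_factors` object; computed from `table` when
#'   omitted.
#' @return The normalized [peak_table()] with the factors stored in
#'   `attr(, "norm_factors")`.
#' @export
apply_factors <- function(table, factors = is_factors(table)) {
  stopifnot(inherits(table, "peak_table"), inherits(factors, "norm_factors"))
  a <- table$areas
  f <- factors$factors
  keep <- intersect(names(f), rownames(a))
  a[keep, ] <- a[keep, , drop = FALSE] / f[keep]
  out <- peak_table(a, table$samples, table$compounds)
  attr(out, "norm_factors") <- factors
  out
}

#' Per-compound coefficient of variation over pool reinjections
#'
#' CV percent = 100 * unbiased sample standard deviation / mean over the
#' undiluted pool injections. Missing values (and literal zeros) are
#' excluded; the CV is undefined (`NA`, compound fails QC) when fewer
#' than two values remain or the mean is zero.
#'
#' @param table A [peak_table()] (normally IS-normalized) containing at
#'   least two undiluted `pool` samples.
#' @return Named numeric vector of CV percentages per compound.
#' @export
pooled_cv <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  pools <- table$samples$sample_id[table$samples$sample_type == "pool" &
                                     table$samples$dilution_factor == 1]
  if (length(pools) < 2L) {
    stop("need >= 2 undiluted pool injections, found ", length(pools),
         call. = FALSE)
  }
  a <- .analysis_areas(table)[pools, , drop = FALSE]
  apply(a, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
}

#' Per-compound linearity of response across pool dilutions
#'
#' Ordinary least squares (with intercept) of peak area on relative
#' concentration across pool and pool-dilution samples, where the
#' relative concentration of a pool dilution is its dilution factor
#' (1, 1/3, 1/10 in the reference design). Returns the coefficient of
#' determination R-squared; `NA` when areas are constant or fewer than
#' three points with at least three distinct levels remain.
#'
#' @param table A [peak_table()] (normally IS-normalized) containing pool
#'   and pool-dilution samples at >= 3 distinct relative concentrations.
#' @return Named numeric vector of R-squared per compound.
#' @export
dilution_linearity <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  sel <- table$samples$sample_type %in% c("pool", "pool_dilution")
  ids <- table$samples$sample_id[sel]
  conc <- table$samples$dilution_factor[sel]
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct relative concentrations among pool and ",
         "pool_dilution samples, found ", length(unique(conc)),
         call. = FALSE)
  }
  a <- .analysis_areas(table)[ids, , drop = FALSE]
  apply(a, 2L, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 3L || length(unique(conc[ok])) < 3L) return(NA_real_)
    if (stats::sd(v[ok]) == 0) return(NA_real_)
    stats::cor(conc[ok], v[ok])^2
  })
}

#' Filter compounds on pooled CV and dilution linearity
#'
#' Keeps exactly the compounds with `rsq > rsq_cutoff` AND
#' `cv < cv_cutoff` (strict inequalities; a compound with an undefined
#' metric fails). Internal standards are always retained for bookkeeping
#' but flagged in the report.
#'
#' @param table A [peak_table()] (IS-normalized).
#' @param cv,rsq Optional precomputed [pooled_cv()] / [dilution_linearity()]
#'   vectors over the same compound set.
#' @param cv_cutoff CV cutoff in percent (default 30).
#' @param rsq_cutoff R-squared cutoff (default 0.95).
#' @return List with `table` (kept compounds) and `report` (`qc_report`:
#'   per-compound metrics data.frame, cutoffs, kept/dropped counts).
#' @export
qc_filter <- function(table, cv = NULL, rsq = NULL,
                      cv_cutoff = 30, rsq_cutoff = 0.95) {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(cv)) cv <- pooled_cv(table)
  if (is.null(rsq)) rsq <- dilution_linearity(table)
  ids <- colnames(table$areas)
  if (!identical(names(cv), ids) || !identical(names(rsq), ids)) {
    cv <- cv[ids]
    rsq <- rsq[ids]
    names(cv) <- names(rsq) <- ids
  }
  is_flag <- ids %in% .is_ids(table)
  pass <- !is.na(cv) & !is.na(rsq) & cv < cv_cutoff & rsq > rsq_cutoff
  reason <- rep("pass", length(ids))
  reason[!pass] <- vapply(which(!pass), function(i) {
    why <- c(
      if (is.na(cv[i])) "CV undefined"
      else if (cv[i] >= cv_cutoff) sprintf("CV %.1f%% >= %g%%", cv[i],
                                           cv_cutoff),
      if (is.na(rsq[i])) "RSQ undefined"
      else if (rsq[i] <= rsq_cutoff) sprintf("RSQ %.3f <= %g", rsq[i],
                                             rsq_cutoff))
    paste(why, collapse = "; ")
  }, character(1))
  keep <- pass | is_flag
  metrics <- data.frame(compound_id = ids, cv = unname(cv),
                        rsq = unname(rsq), pass = unname(pass),
                        internal_standard = is_flag, reason = reason,
                        stringsAsFactors = FALSE)
  report <- structure(list(
    metrics = metrics,
    cutoffs = list(cv = cv_cutoff, rsq = rsq_cutoff),
    n_kept = sum(pass & !is_flag),
    n_dropped = sum(!pass & !is_flag),
    n_internal_standard = sum(is_flag)
  ), class = "qc_report")
  list(table = table[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> kept %d / dropped %d metabolites (CV < %g%%, RSQ > %g); %d IS retained\n",
    x$n_kept, x$n_dropped, x$cutoffs$cv, x$cutoffs$rsq,
    x$n_internal_standard))
  invisible(x)
}

#' Normalize for biological material by total signal
#'
#' Computes per-sample totals `t_j` of the kept (QC-passing, non-IS)
#' compound areas and rescales each targeted sample by `mean(t) / t_j`,
#' so post-normalization totals are equal across the targeted samples.
#' Samples with zero total are flagged and excluded (left unscaled, ids
#' in `attr(, "excluded_samples")`).
#'
#' @param table A [peak_table()] after [qc_filter()].
#' @param kept Compound ids defining the total (default: all non-IS
#'   compounds of `table`).
#' @param types Sample types to rescale (default `"study"`; pool
#'   dilutions are deliberately never rescaled — equalizing their totals
#'   would erase the dilution response).
#' @return The rescaled [peak_table()] with scale factors in
#'   `attr(, "total_signal_factors")`.
#' @export
total_signal_normalize <- function(table, kept = NULL, types = "study") {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(kept)) {
    kept <- setdiff(colnames(table$areas), .is_ids(table))
  }
  kept <- intersect(kept, colnames(table$areas))
  if (!length(kept)) stop("no kept non-IS compounds", call. = FALSE)
  targets <- table$samples$sample_id[table$samples$sample_type %in% types]
  if (!length(targets)) stop("no samples of type ",
                             paste(types, collapse = "/"), call. = FALSE)
  a <- .analysis_areas(table)
  totals <- rowSums(a[targets, kept, drop = FALSE], na.rm = TRUE)
  zero <- totals == 0
  if (any(zero)) {
    warning("excluding sample(s) with zero total signal: ",
            paste(targets[zero], collapse = ", "), call. = FALSE)
  }
  use <- targets[!zero]
  scale <- mean(totals[!zero]) / totals[!zero]
  out_areas <- table$areas
  out_areas[use, ] <- out_areas[use, , drop = FALSE] * scale
  out <- peak_table(out_areas, table$samples, table$compounds)
  attr(out, "total_signal_factors") <- scale
  attr(out, "excluded_samples") <- targets[zero]
  out
}

#' Isotope-dilution relative abundance of paired analytes
#'
#' For every analyte with a paired isotope-labeled internal standard
#' (library `is_pair` column — T3 and T4 in the reference design), the
#' per-sample relative abundance is `area(analyte) / area(paired IS)`
#' computed on raw areas, which cancels any per-sample multiplicative
#' matrix/technical distortion. Zeros count as missing; a missing or zero
#' IS area flags the ratio as undefined rather than 0. Sample volumes
#' must be equal across the compared samples (equal-volume comparison).
#'
#' @param table A [peak_table()] whose library pairs analytes to IS.
#' @param types Sample types to report (default `"study"`).
#' @return Data frame: `sample_id`, `group`, then one ratio column per
#'   paired analyte (NA = undefined).
#' @export
th_relative_abundance <- function(table, types = "study") {
  stopifnot(inherits(table, "peak_table"))
  if (is.null(table$compounds)) {
    stop("peak table has no compound library", call. = FALSE)
  }
  lib <- table$compounds
  paired <- which(!is.na(lib$is_pair) & nzchar(lib$is_pair) &
                    !lib$is_internal_standard)
  if (!length(paired)) {
    stop("no analyte has a paired internal standard (is_pair)",
         call. = FALSE)
  }
  sel <- table$samples$sample_type %in% types
  if ("volume_ul" %in% names(table$samples)) {
    vols <- table$samples$volume_ul[sel]
    vols <- vols[!is.na(vols)]
    if (length(unique(vols)) > 1L) {
      stop("equal-volume comparison requires identical sample volumes; got ",
           paste(unique(vols), collapse = ", "), call. = FALSE)
    }
  }
  a <- .analysis_areas(table)[table$samples$sample_id[sel], , drop = FALSE]
  out <- data.frame(sample_id = table$samples$sample_id[sel],
                    group = table$samples$group[sel],
                    stringsAsFactors = FALSE)
  for (i in paired) {
    analyte <- lib$compound_id[i]
    is_id <- lib$is_pair[i]
    ratio <- a[, analyte] / a[, is_id]
    ratio[is.na(a[, is_id])] <- NA_real_
    out[[analyte]] <- unname(ratio)
  }
  out
}
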