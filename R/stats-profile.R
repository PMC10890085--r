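# Downstream profiling statistics, mirroring the MetaboAnalyst defaults
# the processed tables feed into: half-minimum imputation, log10,
# Pareto scaling, PCA, Welch comparisons with BH correction.

.stats_matrix <- function(table, types = "study") {
  if (inherits(table, "peak_table")) {
    sel <- table$samples$sample_type %in% types
    m <- .analysis_areas(table)[table$samples$sample_id[sel], , drop = FALSE]
    list(m = m, groups = table$samples$group[sel])
  } else {
    stopifnot(is.matrix(table))
    m <- table
    m[!is.na(m) & m == 0] <- NA_real_
    list(m = m, groups = NULL)
  }
}

#' Log-transform and Pareto-scale a peak table
#'
#' Zeros and missing values are imputed as half the compound's minimum
#' positive value (compounds entirely missing are dropped with a
#' warning), areas are log10-transformed, and each compound is Pareto
#' scaled: `(x - mean) / sqrt(sd)` with the unbiased sample standard
#' deviation. Constant compounds map to all-zero columns with a warning.
#' The retained parameters make the transform invertible back to the
#' imputed logged matrix.
#'
#' @param table A QC-filtered, normalized [peak_table()] (study samples
#'   are used) or a plain samples x compounds matrix.
#' @param types Sample types used when `table` is a `peak_table`.
#' @return A `scaled_matrix`: `x` (scaled matrix), `center` (per-compound
#'   log mean), `scale_sd` (per-compound log sd).
#' @export
log_pareto <- function(table, types = "study") {
  inp <- .stats_matrix(table, types)
  m <- inp$m
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    warning("dropping compound(s) with no observed values: ",
            paste(colnames(m)[all_missing], collapse = ", "), call. = FALSE)
    m <- m[, !all_missing, drop = FALSE]
  }
  if (!ncol(m)) stop("no compounds with observed values", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- min(m[!miss, j]) / 2
  }
  lm10 <- log10(m)
  center <- colMeans(lm10)
  scale_sd <- apply(lm10, 2L, stats::sd)
  const <- scale_sd == 0
  if (any(const)) {
    warning("constant compound(s) map to zero columns: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  x <- sweep(lm10, 2L, center, "-")
  x[, !const] <- sweep(x[, !const, drop = FALSE], 2L,
                       sqrt(scale_sd[!const]), "/")
  x[, const] <- 0
  structure(list(x = x, center = center, scale_sd = scale_sd,
                 groups = inp$groups),
            class = "scaled_matrix")
}

#' Invert a Pareto-scaled matrix back to the logged matrix
#'
#' @param sm A `scaled_matrix` from [log_pareto()].
#' @return The imputed log10 matrix.
#' @export
pareto_inverse <- function(sm) {
  stopifnot(inherits(sm, "scaled_matrix"))
  y <- sm$x
  nz <- sm$scale_sd > 0
  y[, nz] <- sweep(y[, nz, drop = FALSE], 2L, sqrt(sm$scale_sd[nz]), "*")
  sweep(y, 2L, sm$center, "+")
}

#' Principal component analysis of a scaled matrix
#'
#' Column-centered singular value decomposition. The sign convention
#' makes the largest-magnitude loading of each component positive.
#'
#' @param sm A `scaled_matrix` (or plain numeric matrix).
#' @param k Number of components, `k <= min(samples - 1, compounds)`.
#' @return List: `scores` (samples x k), `loadings` (compounds x k),
#'   `explained_variance` (length-k fractions, non-increasing).
#' @export
pca_scores <- function(sm, k = 2L) {
  x <- if (inherits(sm, "scaled_matrix")) sm$x else sm
  stopifnot(is.matrix(x), all(is.finite(x)))
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k > kmax) {
    stop("k = ", k, " exceeds min(samples - 1, compounds) = ", kmax,
         call. = FALSE)
  }
  xc <- sweep(x, 2L, colMeans(x), "-")
  dec <- svd(xc)
  ev <- dec$d^2 / sum(dec$d^2)
  scores <- dec$u[, seq_len(k), drop = FALSE] %*%
    diag(dec$d[seq_len(k)], nrow = k)
  loadings <- dec$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)])
}

#' Two-group comparison per compound
#'
#' Welch's unequal-variance t-test on log10 values, fold change as the
#' log2 ratio of unlogged group means, Benjamini-Hochberg adjustment
#' across the tested compounds. Zeros count as missing; compounds with
#' fewer than two observed values in either group are skipped and
#' flagged.
#'
#' @param table A [peak_table()] (study samples) or samples x compounds
#'   matrix.
#' @param labels Group labels, one per sample; defaults to the sample
#'   metadata `group` column. Exactly two distinct labels required.
#' @return Data frame: `compound_id`, `log2fc` (group1 over group2, in
#'   label sort order), `p`, `q`, `n1`, `n2`, `skipped`.
#' @export
group_compare <- function(table, labels = NULL) {
  inp <- .stats_matrix(table)
  m <- inp$m
  if (is.null(labels)) labels <- inp$groups
  if (is.null(labels) || length(labels) != nrow(m)) {
    stop("need one group label per sample", call. = FALSE)
  }
  gs <- sort(unique(as.character(labels)))
  if (length(gs) != 2L) {
    stop("group_compare requires exactly two groups, got ",
         length(gs), call. = FALSE)
  }
  i1 <- labels == gs[1]
  i2 <- labels == gs[2]
  res <- lapply(seq_len(ncol(m)), function(j) {
    v1 <- m[i1, j]; v1 <- v1[!is.na(v1)]
    v2 <- m[i2, j]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2L || length(v2) < 2L) {
      return(data.frame(log2fc = NA_real_, p = NA_real_,
                        n1 = length(v1), n2 = length(v2), skipped = TRUE))
    }
    p <- if (stats::sd(v1) == 0 && stats::sd(v2) == 0 &&
             mean(v1) == mean(v2)) {
      1
    } else {
      tryCatch(stats::t.test(log10(v1), log10(v2),
                             var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    }
    data.frame(log2fc = log2(mean(v1) / mean(v2)), p = p,
               n1 = length(v1), n2 = length(v2), skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(compound_id = colnames(m),
                          stringsAsFactors = FALSE), out)
  out$q <- NA_real_
  tested <- !out$skipped & !is.na(out$p)
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  rownames(out) <- NULL
  attr(out, "groups") <- gs
  out
}

#' Rank the most-changed compounds
#'
#' Compounds are ranked by ascending p-value — Welch t for two groups,
#' one-way ANOVA on log10 values for more — with ties broken by
#' descending absolute log2 fold change (max/min group mean for > 2
#' groups) and then by compound id, so the ordering is deterministic.
#'
#' @param table A [peak_table()] or samples x compounds matrix.
#' @param labels Group labels (>= 2 groups, >= 2 samples each).
#' @param n Number of compounds to return (default 25; capped at the
#'   number of rankable compounds).
#' @return Data frame of the top `n` compounds with `rank`, `p`, `q`,
#'   `log2fc`.
#' @export
top_changed <- function(table, labels = NULL, n = 25L) {
  inp <- .stats_matrix(table)
  m <- inp$m
  if (is.null(labels)) labels <- inp$groups
  gs <- sort(unique(as.character(labels)))
  if (length(gs) == 2L) {
    cmp <- group_compare(m, labels)
    df <- cmp[, c("compound_id", "log2fc", "p", "q")]
    df <- df[!cmp$skipped & !is.na(df$p), , drop = FALSE]
  } else {
    res <- lapply(seq_len(ncol(m)), function(j) {
      v <- m[, j]
      ok <- !is.na(v)
      counts <- table(labels[ok])
      if (length(counts) < 2L || any(counts < 2L)) return(NULL)
      fit <- stats::oneway.test(log10(v[ok]) ~ factor(labels[ok]),
                                var.equal = TRUE)
      gm <- tapply(v[ok], labels[ok], mean)
      data.frame(compound_id = colnames(m)[j],
                 log2fc = log2(max(gm) / min(gm)),
                 p = fit$p.value, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    if (is.null(df) || !nrow(df)) {
      stop("no compound is testable across groups", call. = FALSE)
    }
    df$q <- stats::p.adjust(df$p, method = "BH")
  }
  ord <- order(df$p, -abs(df$log2fc), df$compound_id)
  df <- df[ord, , drop = FALSE]
  df <- utils::head(df, n)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "compound_id", "log2fc", "p", "q")]
}
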