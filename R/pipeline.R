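# End-to-end orchestration: quantified areas -> IS normalization -> QC
# metrics -> filter -> total-signal normalization -> profiling stats.
# The stage order is fixed and recorded in the run manifest.

.stop_input <- function(...) {
  stop(structure(class = c("thq_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the full processing chain
#'
#' Executes, in fixed order: input assembly (either a simulated scenario
#' or supplied peak-table/metadata/library CSVs), internal-standard
#' normalization, pooled-QC metrics and filtering, total-signal
#' normalization, and profiling statistics (log/Pareto, PCA, group
#' comparison, top-changed ranking, isotope-dilution TH ratios). All
#' outputs carry the tool version, config hash and seed; a JSON
#' `MANIFEST` records stage timings, record counts and completeness.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for simulation (recorded regardless).
#' @param config A [default_config()]-style `pipeline_config`.
#' @param scenario A [scenario_config()] used when no `peaks` input is
#'   given.
#' @param peaks,meta,library Optional paths to a peak-table CSV, sample
#'   metadata CSV and compound library CSV to process instead of
#'   simulating.
#' @return The manifest list, invisibly. Stage failure raises an error
#'   after writing a manifest with `complete = FALSE`.
#' @export
run_all <- function(out_dir, seed = 1L, config = default_config(),
                    scenario = scenario_config(),
                    peaks = NULL, meta = NULL, library = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(tool = "thquant", version = .thquant_version(),
                     config_hash = .config_hash(config), seed = seed)
  manifest <- list(tool = "thquant", version = .thquant_version(),
                   config_hash = provenance$config_hash,
                   seed = as.integer(seed), complete = FALSE,
                   stages = list())
  write_config(config, file.path(out_dir, "config.json"))
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- fun()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      records = res$records)
    res$value
  }
  finish <- function() {
    manifest$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  on.exit(finish())

  table <- stage("input", function() {
    if (!is.null(peaks)) {
      for (p in c(peaks, meta, library)) {
        if (!is.null(p) && !file.exists(p)) {
          .stop_input("input file not found: ", p)
        }
      }
      tab <- read_peak_table(
        peaks,
        samples = if (!is.null(meta)) read_sample_meta(meta),
        compounds = if (!is.null(library)) read_compound_library(library))
    } else {
      sim <- simulate_study(scenario, seed = seed)
      write_truth(sim$truth, file.path(out_dir, "truth.json"))
      write_peak_table(sim$table, file.path(out_dir, "peaks_raw.csv"),
                       provenance)
      write_sample_meta(sim$table$samples,
                        file.path(out_dir, "samples.csv"), provenance)
      write_compound_library(sim$table$compounds,
                             file.path(out_dir, "library.csv"), provenance)
      tab <- sim$table
    }
    list(value = tab, records = c(samples = nrow(tab$areas),
                                  compounds = ncol(tab$areas)))
  })

  normalized <- stage("is_normalization", function() {
    nf <- is_factors(table)
    list(value = apply_factors(table, nf),
         records = c(is_used = length(nf$is_used)))
  })

  qc <- stage("qc_filter", function() {
    res <- qc_filter(normalized, cv_cutoff = config$cv_cutoff,
                     rsq_cutoff = config$rsq_cutoff)
    write_qc_report(res$report, file.path(out_dir, "qc_report.json"))
    list(value = res, records = c(kept = res$report$n_kept,
                                  dropped = res$report$n_dropped))
  })

  final <- stage("total_signal", function() {
    out <- total_signal_normalize(qc$table)
    write_peak_table(out, file.path(out_dir, "norm.csv"), provenance)
    list(value = out, records = c(samples = nrow(out$areas)))
  })

  stage("stats", function() {
    study <- final$samples$sample_type == "study"
    groups <- final$samples$group[study]
    analytes <- setdiff(colnames(final$areas), .is_ids(final))
    sm <- suppressWarnings(log_pareto(final[, analytes]))
    k <- min(2L, min(sum(study) - 1L, ncol(sm$x)))
    pca <- pca_scores(sm, k = k)
    .write_csv(data.frame(sample_id = rownames(pca$scores),
                          group = groups, pca$scores,
                          check.names = FALSE),
               file.path(out_dir, "pca_scores.csv"), provenance)
    .write_csv(data.frame(compound_id = rownames(pca$loadings),
                          pca$loadings, check.names = FALSE),
               file.path(out_dir, "pca_loadings.csv"), provenance)
    tab <- sort(table(groups), decreasing = TRUE)
    if (length(tab) >= 2L) {
      pair <- sort(names(tab)[1:2])
      m <- .analysis_areas(final[, analytes])
      m <- m[final$samples$sample_id[study], , drop = FALSE]
      sel <- groups %in% pair
      cmp <- group_compare(m[sel, , drop = FALSE], groups[sel])
      .write_csv(cmp, file.path(out_dir, "comparison.csv"), provenance)
      top <- top_changed(final[, analytes], labels = NULL, n = 25L)
      .write_csv(top, file.path(out_dir, "top_changed.csv"), provenance)
    }
    if (!is.null(final$compounds) &&
        any(!is.na(final$compounds$is_pair) &
              nzchar(final$compounds$is_pair))) {
      th <- th_relative_abundance(qc$table)  # raw-ratio table, pre-scaling
      .write_csv(th, file.path(out_dir, "th_ratios.csv"), provenance)
    }
    list(value = NULL, records = c(groups = length(tab)))
  })

  manifest$complete <- TRUE
  invisible(manifest)
}
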