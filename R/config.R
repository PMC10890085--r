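#' Default pipeline configuration
#'
#' Defaults mirror the acquisition and processing settings of the
#' underlying method: 5 ppm mass tolerance for targeted extraction,
#' dilution-linearity cutoff R-squared > 0.95 and pooled CV < 30 percent,
#' full scan m/z 70-1000 and narrow thyroid-hormone scan m/z 600-800.
#' Retention-time units are minutes everywhere.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    ppm_tol = 5,              # mass window half-width, ppm of target m/z
    rt_tol = 0.5,             # RT search window half-width, minutes
    frag_tol = 0.01,          # MS2 fragment match tolerance, Da
    cv_cutoff = 30,           # pooled CV cutoff, percent (strict <)
    rsq_cutoff = 0.95,        # dilution linearity cutoff (strict >)
    lod_rsq_min = 0.99,       # calibration linear-segment R^2 floor
    scan_range_full = c(70, 1000),
    scan_range_narrow = c(600, 800),
    log_base = 10,
    seed = NULL
  ), class = "pipeline_config")
}

#' Read / write pipeline configuration JSON
#'
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  stopifnot(cfg$ppm_tol > 0, cfg$rt_tol > 0, cfg$cv_cutoff > 0,
            cfg$rsq_cutoff > 0, cfg$rsq_cutoff < 1)
  cfg
}

#' @rdname read_config
#' @param config A `pipeline_config` list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Stable md5 hash of a config (used for output provenance).
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.thquant_version <- function() {
  as.character(utils::packageVersion("thquant"))
}
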