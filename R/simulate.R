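# Synthetic-data generator with known ground truth, emulating the study
# structure the pipeline was built for: CSF cohorts (embryo, adult male,
# adult female, pregnant dam), spiked isotope-labeled internal standards,
# pooled QC reinjections with 3- and 10-fold dilutions, blanks and mocks,
# per-sample matrix factors, and fresh-vs-frozen lability of
# nucleotide-salvage metabolites.

.salvage_compounds <- c("guanosine", "cytosine", "adenosine", "inosine",
                        "UMP", "CMP", "guanine", "cytidine", "uridine",
                        "hypoxanthine")

#' Scenario configuration for the study simulator
#'
#' Defaults encode the reference study design: four CSF groups (>= 4-6
#' samples each), a ~200-compound metabolite panel plus a 40-compound
#' internal-standard panel, five undiluted pool reinjections plus 3- and
#' 10-fold pool dilutions in duplicate, two blanks and two mocks.
#' Noise levels: `noise_cv` 0.05 is the technical (reinjection)
#' coefficient of variation of an abundant targeted compound;
#' `matrix_sdlog` 0.2 is the log-sd of the per-sample multiplicative
#' matrix/recovery factor that internal standards are spiked to correct;
#' planted non-compliant compounds get `noise_cv_bad` (near-LOD
#' variability) or a saturating detector response.
#'
#' @param groups Named integer vector of study-group sizes.
#' @param n_metabolites Number of compliant metabolites (includes T3, T4
#'   and the ten nucleotide-salvage compounds).
#' @param n_is Internal-standard panel size (includes the 13C T3/T4
#'   standards paired to the analytes).
#' @param n_pool Undiluted pool reinjections.
#' @param pool_dilution_factors Relative concentrations of the pool
#'   dilutions (3- and 10-fold).
#' @param pool_dilution_replicates Injections per dilution level.
#' @param n_blank,n_mock Blank and mock (empty-tube) sample counts.
#' @param frozen_fraction Fraction of each study group acutely frozen
#'   before extraction.
#' @param noise_cv Multiplicative (lognormal) technical CV.
#' @param noise_cv_bad CV planted into high-CV non-compliant compounds.
#' @param baseline Scale of the small additive baseline (area units).
#' @param matrix_sdlog Log-sd of per-sample matrix factors.
#' @param missing_rate Fraction of study metabolite cells dropped as
#'   missing.
#' @param t3_effects,t4_effects Named per-group relative concentration
#'   multipliers for T3 and T4 (embryo-elevated T3, pregnancy-elevated
#'   T4).
#' @param frozen_labile_fold Fold elevation of the nucleotide-salvage
#'   compounds in frozen embryo samples.
#' @param n_group_effect Number of additional metabolites given random
#'   embryo-vs-adult effects.
#' @param n_bad_cv,n_bad_nonlinear Planted non-compliant compound counts
#'   (added on top of `n_metabolites`).
#' @param peak_sigma Gaussian elution sigma in minutes (raw-run writer).
#' @param scan_dt MS1 scan spacing in minutes (raw-run writer).
#' @param volume_ul Extracted volume per sample.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(groups = c(embryo = 6L, adult_male = 5L,
                                       adult_female = 5L, pregnant = 4L),
                            n_metabolites = 200L,
                            n_is = 40L,
                            n_pool = 5L,
                            pool_dilution_factors = c(1 / 3, 1 / 10),
                            pool_dilution_replicates = 2L,
                            n_blank = 2L, n_mock = 2L,
                            frozen_fraction = 0.5,
                            noise_cv = 0.05,
                            noise_cv_bad = 1.0,
                            baseline = 50,
                            matrix_sdlog = 0.2,
                            missing_rate = 0.02,
                            t3_effects = c(embryo = 4, adult_male = 1,
                                           adult_female = 0.8,
                                           pregnant = 1.5),
                            t4_effects = c(embryo = 1.5, adult_male = 1,
                                           adult_female = 0.8,
                                           pregnant = 3),
                            frozen_labile_fold = 2.5,
                            n_group_effect = 40L,
                            n_bad_cv = 0L, n_bad_nonlinear = 0L,
                            peak_sigma = 0.05, scan_dt = 0.01,
                            volume_ul = 5) {
  stopifnot(length(groups) >= 1L, all(groups >= 1L),
            !is.null(names(groups)),
            n_metabolites >= 2L, n_is >= 2L, n_pool >= 2L,
            all(pool_dilution_factors > 0),
            all(pool_dilution_factors <= 1),
            noise_cv >= 0, matrix_sdlog >= 0, baseline >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "scenario_config")
}

# Deterministic compound library for a scenario.
.scenario_library <- function(config) {
  n_sal <- min(length(.salvage_compounds), config$n_metabolites - 2L)
  met_names <- c("T3", "T4", .salvage_compounds[seq_len(n_sal)])
  n_generic <- config$n_metabolites - length(met_names)
  if (n_generic > 0) {
    met_names <- c(met_names, sprintf("met_%03d", seq_len(n_generic)))
  }
  bad <- c(if (config$n_bad_cv > 0) sprintf("bad_cv_%02d",
                                            seq_len(config$n_bad_cv)),
           if (config$n_bad_nonlinear > 0)
             sprintf("bad_nl_%02d", seq_len(config$n_bad_nonlinear)))
  met_names <- c(met_names, bad)
  is_names <- c("IS_13C_T3", "IS_13C_T4",
                sprintf("IS_%02d", seq_len(config$n_is - 2L)))
  n_met <- length(met_names)
  n_is <- length(is_names)
  # spread compounds over the gradient and the acquired mass range
  rt <- round(seq(1, 17, length.out = n_met + n_is), 3)
  mz <- round(seq(85, 995, length.out = n_met + n_is) +
                stats::runif(n_met + n_is, -0.35, 0.35), 4)
  lib <- data.frame(
    compound_id = c(met_names, is_names),
    name = c(met_names, is_names),
    formula = NA_character_,
    adduct = "[M+H]+",
    target_mz = mz,
    rt_expected = rt,
    rt_tol = 0.3,
    is_internal_standard = c(rep(FALSE, n_met), rep(TRUE, n_is)),
    is_pair = NA_character_,
    stringsAsFactors = FALSE)
  # the thyroid hormones resolve from composition; everything else keeps
  # a precomputed target m/z as a real in-house library would
  lib$formula[lib$compound_id == "T3"] <- "C15H12I3NO4"
  lib$formula[lib$compound_id == "T4"] <- "C15H11I4NO4"
  lib$target_mz[lib$compound_id %in% c("T3", "T4")] <- NA_real_
  # isotope-labeled standards co-elute with their analytes
  lib$rt_expected[lib$compound_id == "IS_13C_T3"] <-
    lib$rt_expected[lib$compound_id == "T3"]
  lib$rt_expected[lib$compound_id == "IS_13C_T4"] <-
    lib$rt_expected[lib$compound_id == "T4"]
  lib$is_pair[lib$compound_id == "T3"] <- "IS_13C_T3"
  lib$is_pair[lib$compound_id == "T4"] <- "IS_13C_T4"
  validate_compound_library(lib)
}

.scenario_samples <- function(config) {
  rows <- list()
  for (g in names(config$groups)) {
    n <- config$groups[[g]]
    n_frozen <- floor(n * config$frozen_fraction)
    storage <- c(rep("fresh", n - n_frozen), rep("frozen", n_frozen))
    rows[[g]] <- data.frame(
      sample_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g, sample_type = "study", dilution_factor = 1,
      storage = storage, stringsAsFactors = FALSE)
  }
  rows$pool <- data.frame(
    sample_id = sprintf("pool_%02d", seq_len(config$n_pool)),
    group = "pool", sample_type = "pool", dilution_factor = 1,
    storage = "fresh", stringsAsFactors = FALSE)
  for (f in config$pool_dilution_factors) {
    tag <- paste0("pool_d", round(1 / f))
    rows[[tag]] <- data.frame(
      sample_id = sprintf("%s_%02d", tag,
                          seq_len(config$pool_dilution_replicates)),
      group = "pool", sample_type = "pool_dilution", dilution_factor = f,
      storage = "fresh", stringsAsFactors = FALSE)
  }
  if (config$n_blank > 0) {
    rows$blank <- data.frame(
      sample_id = sprintf("blank_%02d", seq_len(config$n_blank)),
      group = "blank", sample_type = "blank", dilution_factor = 1,
      storage = "fresh", stringsAsFactors = FALSE)
  }
  if (config$n_mock > 0) {
    rows$mock <- data.frame(
      sample_id = sprintf("mock_%02d", seq_len(config$n_mock)),
      group = "mock", sample_type = "mock", dilution_factor = 1,
      storage = "fresh", stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  meta$injection_order <- seq_len(nrow(meta))
  meta$volume_ul <- config$volume_ul
  validate_sample_meta(meta)
}

#' Simulate a complete study peak table with known ground truth
#'
#' Areas are generated as
#' `true_concentration x dilution x matrix_factor x lognormal_noise +
#' baseline`; analytes and their paired internal standards share the
#' sample's matrix factor, the embryo group gets elevated T3, the
#' pregnant group elevated T4, frozen embryo samples get elevated
#' nucleotide-salvage metabolites, and planted non-compliant compounds
#' get high-CV noise or a saturating (nonlinear) dilution response.
#' Fully reproducible for a given seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed (recorded in the truth object).
#' @param matrix_factors Optional named per-sample factors overriding the
#'   lognormal draw (handy for exact-recovery tests).
#' @return List: `table` (a [peak_table()] with metadata and library),
#'   `truth` (a `study_truth`: per-compound base concentrations, group
#'   multipliers, matrix factors, IS spikes, labile set, non-compliant
#'   ids, expected noise-free signal matrix, seed, config).
#' @export
simulate_study <- function(config = scenario_config(), seed = 1L,
                           matrix_factors = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(as.integer(seed), {
    lib <- .scenario_library(config)
    meta <- .scenario_samples(config)
    met_ids <- lib$compound_id[!lib$is_internal_standard]
    is_ids <- lib$compound_id[lib$is_internal_standard]
    n_met <- length(met_ids)
    bad_cv_ids <- grep("^bad_cv_", met_ids, value = TRUE)
    bad_nl_ids <- grep("^bad_nl_", met_ids, value = TRUE)
    labile <- intersect(.salvage_compounds, met_ids)

    base_conc <- stats::setNames(10^stats::runif(n_met, 4.3, 6.3), met_ids)
    is_spike <- stats::setNames(10^stats::runif(length(is_ids), 4.8, 5.8),
                                is_ids)

    groups <- names(config$groups)
    gm <- matrix(1, nrow = length(groups), ncol = n_met,
                 dimnames = list(groups, met_ids))
    common <- intersect(groups, names(config$t3_effects))
    gm[common, "T3"] <- config$t3_effects[common]
    common <- intersect(groups, names(config$t4_effects))
    gm[common, "T4"] <- config$t4_effects[common]
    candidates <- setdiff(met_ids, c("T3", "T4", bad_cv_ids, bad_nl_ids))
    eff <- sample(candidates, min(config$n_group_effect, length(candidates)))
    if ("embryo" %in% groups && length(eff)) {
      gm["embryo", eff] <- 2^stats::rnorm(length(eff), 0, 1)
    }
    if ("pregnant" %in% groups && length(eff)) {
      gm["pregnant", eff] <- 2^stats::rnorm(length(eff), 0, 0.5)
    }

    mf <- if (is.null(matrix_factors)) {
      stats::setNames(exp(stats::rnorm(nrow(meta), 0, config$matrix_sdlog)),
                      meta$sample_id)
    } else {
      stopifnot(all(meta$sample_id %in% names(matrix_factors)))
      matrix_factors[meta$sample_id]
    }
    mf[meta$sample_type %in% c("blank", "mock")] <- 1

    # per-sample true metabolite concentration (area units)
    study <- meta$sample_type == "study"
    conc <- matrix(0, nrow = nrow(meta), ncol = n_met,
                   dimnames = list(meta$sample_id, met_ids))
    for (i in which(study)) {
      ci <- base_conc * gm[meta$group[i], ]
      if (meta$storage[i] == "frozen" && meta$group[i] == "embryo" &&
          length(labile)) {
        ci[labile] <- ci[labile] * config$frozen_labile_fold
      }
      conc[i, ] <- ci
    }
    pool_conc <- colMeans(conc[study, , drop = FALSE])
    pools <- meta$sample_type %in% c("pool", "pool_dilution")
    conc[pools, ] <- matrix(pool_conc, nrow = sum(pools), ncol = n_met,
                            byrow = TRUE) * meta$dilution_factor[pools]

    # saturating detector response for planted nonlinear compounds
    for (id in bad_nl_ids) {
      vmax <- 1.05 * pool_conc[id]
      k <- 0.05 * pool_conc[id]
      pos <- conc[, id] > 0
      conc[pos, id] <- vmax * conc[pos, id] / (k + conc[pos, id])
    }

    expected <- cbind(conc,
                      matrix(is_spike, nrow = nrow(meta),
                             ncol = length(is_ids), byrow = TRUE,
                             dimnames = list(meta$sample_id, is_ids)))
    expected[meta$sample_type == "blank", is_ids] <- 0
    expected <- expected * mf[rownames(expected)]

    sdlog <- sqrt(log(1 + config$noise_cv^2))
    sdlog_bad <- sqrt(log(1 + config$noise_cv_bad^2))
    noise <- matrix(exp(stats::rnorm(length(expected), 0, sdlog)),
                    nrow = nrow(expected))
    if (length(bad_cv_ids)) {
      jbad <- match(bad_cv_ids, colnames(expected))
      noise[, jbad] <- exp(stats::rnorm(nrow(expected) * length(jbad),
                                        0, sdlog_bad))
    }
    if (config$noise_cv == 0) noise[] <- 1  # exact in the noise-free world
    areas <- expected * noise
    if (config$baseline > 0) {
      areas <- areas + matrix(abs(stats::rnorm(length(areas), 0,
                                               config$baseline)),
                              nrow = nrow(areas))
    }
    if (config$missing_rate > 0) {
      cells <- which(study)  # rows eligible for dropout
      drop <- matrix(stats::runif(length(cells) * n_met) <
                       config$missing_rate,
                     nrow = length(cells))
      areas[cells, seq_len(n_met)][drop] <- NA_real_
    }

    tab <- peak_table(areas[, lib$compound_id, drop = FALSE], meta, lib)
    truth <- structure(list(
      seed = as.integer(seed),
      base_conc = base_conc,
      is_spike = is_spike,
      group_multipliers = gm,
      matrix_factors = mf,
      labile_compounds = labile,
      frozen_labile_fold = config$frozen_labile_fold,
      noncompliant = list(high_cv = bad_cv_ids, nonlinear = bad_nl_ids),
      expected_signal = expected,
      config = unclass(config)
    ), class = "study_truth")
    list(table = tab, truth = truth)
  })
}

#' Serialize / restore simulator ground truth as JSON
#'
#' @param truth A `study_truth` from [simulate_study()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "study_truth"))
  x <- unclass(truth)
  flatten <- function(m, rowkey) {
    out <- list(colnames(m), lapply(seq_len(nrow(m)),
                                    function(i) unname(m[i, ])))
    names(out) <- c("compounds", "values")
    out[[rowkey]] <- rownames(m)
    out[c(rowkey, "compounds", "values")]
  }
  x$group_multipliers <- flatten(truth$group_multipliers, "groups")
  x$expected_signal <- flatten(truth$expected_signal, "samples")
  named <- function(v) list(names = names(v), values = unname(v))
  x$base_conc <- named(truth$base_conc)
  x$is_spike <- named(truth$is_spike)
  x$matrix_factors <- named(truth$matrix_factors)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the `study_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(block) {
    m <- if (is.matrix(block$values)) block$values
         else do.call(rbind, lapply(block$values, unlist))
    dimnames(m) <- list(block[[1]], block$compounds)
    m
  }
  x$group_multipliers <- rebuild(x$group_multipliers)
  x$expected_signal <- rebuild(x$expected_signal)
  renamed <- function(block) {
    stats::setNames(as.numeric(unlist(block$values)),
                    as.character(unlist(block$names)))
  }
  x$base_conc <- renamed(x$base_conc)
  x$is_spike <- renamed(x$is_spike)
  x$matrix_factors <- renamed(x$matrix_factors)
  x$noncompliant <- lapply(x$noncompliant,
                           function(v) as.character(unlist(v)))
  x$labile_compounds <- as.character(unlist(x$labile_compounds))
  structure(x, class = "study_truth")
}

#' Simulate a standard dilution series with a planted detection limit
#'
#' Mean signal is `slope x concentration` at and above the planted LOD
#' and collapses to the blank level below it; every measurement gets
#' additive Gaussian noise of standard deviation `noise_sd`.
#'
#' @param lod_nM Planted limit of detection in nM.
#' @param noise_sd Additive noise sd in area units.
#' @param levels Non-zero concentrations (default: 2-fold ladder
#'   `lod_nM * 2^(-2..5)` spanning below and above the LOD).
#' @param replicates Replicates per level and blank replicates.
#' @param seed RNG seed.
#' @param slope Response slope in area units per nM.
#' @param blank_level Mean blank area. The default is a nonzero
#'   instrument background well above the zero floor so that the
#'   additive Gaussian noise model is not truncated.
#' @return A [dilution_series()] including `replicates` blank rows at
#'   concentration 0.
#' @export
simulate_dilution_series <- function(lod_nM = 0.5, noise_sd = 20,
                                     levels = NULL, replicates = 3L,
                                     seed = 1L, slope = 1000,
                                     blank_level = 100) {
  if (is.null(levels)) levels <- lod_nM * 2^seq(-2, 5)
  levels <- sort(unique(levels))
  if (length(levels) < 5L || min(levels) >= lod_nM || max(levels) < lod_nM) {
    stop("need >= 5 levels spanning below and above the planted LOD",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    conc <- c(rep(0, replicates), rep(levels, each = replicates))
    mu <- ifelse(conc == 0, blank_level,
                 ifelse(conc >= lod_nM, blank_level + slope * conc,
                        blank_level))
    area <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
    ds <- dilution_series("synthetic", conc, area)
    attr(ds, "planted_lod") <- lod_nM
    ds
  })
}

#' Write a centroided raw run realizing a set of peak areas
#'
#' Places one Gaussian elution profile per compound on a uniform MS1
#' scan grid such that the trapezoidal area of its extracted ion
#' chromatogram matches the requested area (within ~2 percent for
#' `scan_dt <= peak_sigma`). Optionally appends two MS2 spectra per
#' compound at collision energies 20 and 40 for annotation tests. A
#' warning is issued when two compounds overlap within 5 ppm and in RT
#' (planted isomer stress test).
#'
#' @param areas Named numeric vector of requested areas (names must match
#'   library compound ids; zero-area compounds are omitted from the
#'   spectra entirely).
#' @param library Compound library with `target_mz` and `rt_expected`.
#' @param peak_sigma Gaussian sigma in minutes.
#' @param scan_dt Scan spacing in minutes.
#' @param seed RNG seed (mass jitter, noise peaks).
#' @param mz_jitter_ppm Uniform per-centroid mass error half-width, ppm.
#' @param noise_peaks Random low-intensity noise centroids per scan.
#' @param noise_intensity Mean intensity of noise centroids.
#' @param ms2 Also emit MS2 spectra per compound.
#' @param run_id Run identifier.
#' @return An [ms_run()].
#' @export
simulate_run_from_areas <- function(areas, library, peak_sigma = 0.05,
                                    scan_dt = 0.01, seed = 1L,
                                    mz_jitter_ppm = 1, noise_peaks = 0L,
                                    noise_intensity = 10, ms2 = FALSE,
                                    run_id = "sim") {
  library <- validate_compound_library(library)
  stopifnot(!is.null(names(areas)),
            all(names(areas) %in% library$compound_id))
  lib <- library[match(names(areas), library$compound_id), , drop = FALSE]
  keep <- areas > 0
  lib <- lib[keep, , drop = FALSE]
  areas <- areas[keep]
  if (nrow(lib) >= 2L) {
    for (i in seq_len(nrow(lib) - 1L)) {
      dmz <- abs(lib$target_mz[-seq_len(i)] - lib$target_mz[i]) /
        lib$target_mz[i] * 1e6
      drt <- abs(lib$rt_expected[-seq_len(i)] - lib$rt_expected[i])
      if (any(dmz < 5 & drt < 4 * peak_sigma)) {
        warning("compounds overlap within 5 ppm and in RT: ",
                lib$compound_id[i], call. = FALSE)
      }
    }
  }
  withr::with_seed(as.integer(seed), {
    rt_lo <- max(0, min(c(lib$rt_expected, 1)) - 8 * peak_sigma)
    rt_hi <- max(c(lib$rt_expected, 1)) + 8 * peak_sigma
    grid <- seq(rt_lo, rt_hi, by = scan_dt)
    spectra <- vector("list", length(grid))
    for (s in seq_along(grid)) {
      rt <- grid[s]
      sel <- which(abs(lib$rt_expected - rt) <= 6 * peak_sigma)
      mz <- ints <- numeric(0)
      if (length(sel)) {
        ints <- areas[sel] * stats::dnorm(rt, lib$rt_expected[sel],
                                          peak_sigma)
        jit <- stats::runif(length(sel), -mz_jitter_ppm, mz_jitter_ppm)
        mz <- lib$target_mz[sel] * (1 + jit * 1e-6)
      }
      if (noise_peaks > 0L) {
        mz <- c(mz, stats::runif(noise_peaks, 70, 1000))
        ints <- c(ints, stats::rexp(noise_peaks, 1 / noise_intensity))
      }
      ord <- order(mz)
      mz <- mz[ord]; ints <- ints[ord]
      if (length(mz) > 1L) {       # centroids must be strictly ascending
        while (any(diff(mz) <= 0)) {
          i <- which(diff(mz) <= 0)[1] + 1L
          mz[i] <- mz[i - 1L] * (1 + 1e-9)
        }
      }
      spectra[[s]] <- ms_spectrum(rt, mz, ints, ms_level = 1L)
    }
    if (ms2) {
      for (i in seq_len(nrow(lib))) {
        frac <- sort(stats::runif(6, 0.15, 0.95))
        fmz <- lib$target_mz[i] * frac
        for (ce in c(20, 40)) {
          fint <- stats::rexp(6, 1 / 100) * (if (ce == 40) rev(frac)
                                             else frac)
          spectra[[length(spectra) + 1L]] <-
            ms_spectrum(lib$rt_expected[i], fmz, fint, ms_level = 2L,
                        precursor_mz = lib$target_mz[i],
                        collision_energy = ce)
        }
      }
      rts <- vapply(spectra, `[[`, numeric(1), "rt")
      spectra <- spectra[order(rts)]
    }
    ms_run(spectra, run_id = run_id, polarity = "positive",
           scan_range = c(70, 1000))
  })
}
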