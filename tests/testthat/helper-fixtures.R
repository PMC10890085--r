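# Shared in-code fixtures for the suite; everything is generated, no
# binary files.

# A tiny compound library: two analytes with paired labeled standards
# plus one free-standing metabolite.
tiny_library <- function() {
  validate_compound_library(data.frame(
    compound_id = c("T3", "T4", "alanine", "IS_13C_T3", "IS_13C_T4"),
    name = c("triiodothyronine", "thyroxine", "alanine",
             "13C-T3", "13C-T4"),
    formula = c("C15H12I3NO4", "C15H11I4NO4", NA, NA, NA),
    adduct = "[M+H]+",
    target_mz = c(NA, NA, 90.055, 660.8275, 786.7242),
    rt_expected = c(8.1, 8.6, 2.2, 8.1, 8.6),
    rt_tol = 0.3,
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    is_pair = c("IS_13C_T3", "IS_13C_T4", NA, NA, NA),
    stringsAsFactors = FALSE))
}

# A minimal peak table: `areas` is samples x compounds; metadata derived
# from the sample-id prefix (study/pool/dil3/dil10/blank/mock).
make_table <- function(areas, lib = NULL, groups = NULL) {
  ids <- rownames(areas)
  type <- rep("study", length(ids))
  dil <- rep(1, length(ids))
  type[startsWith(ids, "pool")] <- "pool"
  type[startsWith(ids, "dil3")] <- "pool_dilution"
  dil[startsWith(ids, "dil3")] <- 1 / 3
  type[startsWith(ids, "dil10")] <- "pool_dilution"
  dil[startsWith(ids, "dil10")] <- 1 / 10
  type[startsWith(ids, "blank")] <- "blank"
  type[startsWith(ids, "mock")] <- "mock"
  meta <- data.frame(sample_id = ids,
                     group = if (is.null(groups)) type else groups,
                     sample_type = type, dilution_factor = dil,
                     stringsAsFactors = FALSE)
  peak_table(areas, meta, lib)
}

# Random centroided run for round-trip tests.
random_run <- function(n_spectra = 10L, seed = 1L, ms2 = FALSE) {
  withr::with_seed(seed, {
    sp <- lapply(seq_len(n_spectra), function(i) {
      n <- sample(3:40, 1)
      ms_spectrum(rt = i / 10, mz = sort(runif(n, 70, 1000)),
                  intensity = runif(n, 0, 1e6))
    })
    if (ms2) {
      sp[[length(sp) + 1L]] <- ms_spectrum(
        rt = n_spectra / 10, mz = c(91.05, 130.1, 250.2),
        intensity = c(10, 100, 40), ms_level = 2L,
        precursor_mz = 651.7973, collision_energy = 35)
      sp[[length(sp) + 1L]] <- ms_spectrum(
        rt = n_spectra / 10, mz = c(105.07, 330.1),
        intensity = c(55, 5), ms_level = 2L,
        precursor_mz = 777.694, collision_energy = 70)
    }
    ms_run(sp, run_id = "fixture", polarity = "positive",
           scan_range = c(70, 1000))
  })
}
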