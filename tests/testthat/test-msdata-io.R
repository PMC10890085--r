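test_that("mzML round-trips spectra, RTs and MS2 metadata", {
  run <- random_run(10, seed = 3, ms2 = TRUE)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_mzml(path)
  expect_length(back$spectra, 12)
  expect_identical(back$run_id, "fixture")
  expect_identical(back$polarity, "positive")
  for (i in seq_along(run$spectra)) {
    expect_equal(back$spectra[[i]]$rt, run$spectra[[i]]$rt)
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz)
    expect_equal(back$spectra[[i]]$intensity, run$spectra[[i]]$intensity)
    expect_identical(back$spectra[[i]]$ms_level, run$spectra[[i]]$ms_level)
  }
  ms2 <- Filter(function(s) s$ms_level == 2L, back$spectra)
  expect_length(ms2, 2)
  expect_equal(ms2[[1]]$precursor_mz, 651.7973)
  expect_equal(ms2[[1]]$collision_energy, 35)
  expect_equal(ms2[[2]]$collision_energy, 70)
})

test_that("mzML round-trip is stable over randomized runs", {
  for (seed in c(11, 12, 13)) {
    run <- random_run(n_spectra = 5L, seed = seed)
    path <- withr::local_tempfile(fileext = ".mzML")
    write_mzml(run, path)
    back <- read_mzml(path)
    expect_equal(lapply(back$spectra, `[`, c("rt", "mz", "intensity")),
                 lapply(run$spectra, `[`, c("rt", "mz", "intensity")))
  }
})

test_that("mzML reader rejects degenerate and unsupported input", {
  expect_error(ms_run(list()), "no spectra")
  path <- withr::local_tempfile(fileext = ".mzML")
  # hand-written profile-mode spectrum must be rejected
  writeLines(c(
    '<?xml version="1.0"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml"><run id="p">',
    '<spectrumList count="1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="0">',
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>',
    '<scanList><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="1" unitName="minute"/></scan></scanList>',
    '</spectrum></spectrumList></run></mzML>'), path)
  expect_error(read_mzml(path), "profile")
  # truncated document
  writeLines('<?xml version="1.0"?><mzML><run>', path)
  expect_error(read_mzml(path), "truncated|invalid")
  expect_error(read_mzml(file.path(tempdir(), "absent.mzML")), "not found")
})

test_that("second-based scan times are converted to minutes", {
  run <- random_run(2, seed = 5)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  txt <- gsub('unitName="minute"', 'unitName="second"', readLines(path))
  writeLines(txt, path)
  back <- read_mzml(path)
  expect_equal(vapply(back$spectra, `[[`, numeric(1), "rt"),
               vapply(run$spectra, `[[`, numeric(1), "rt") / 60)
})

test_that("peak tables round-trip with missing kept distinct from zero", {
  m <- matrix(c(1.5, NA, 0, 42.25), nrow = 2,
              dimnames = list(c("s1", "s2"), c("c1", "c2")))
  tab <- peak_table(m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(tab, path)
  back <- read_peak_table(path)
  expect_equal(back$areas, m)
  expect_true(is.na(back$areas["s2", "c1"]))    # empty cell -> NA
  expect_identical(back$areas["s1", "c2"], 0)   # literal zero survives IO
})

test_that("peak-table reader rejects duplicate ids, naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,c1,c1", "s1,1,2"), path)
  expect_error(read_peak_table(path), "duplicate compound ids.*c1")
  writeLines(c("sample_id,c1,c2", "s1,1,2", "s1,3,4"), path)
  expect_error(read_peak_table(path), "duplicate sample ids.*s1")
})

test_that("a full-width 40 IS + 226 metabolite table is preserved", {
  ids <- c(sprintf("IS_%02d", 1:40), sprintf("met_%03d", 1:226))
  withr::with_seed(21, {
    m <- matrix(round(runif(3 * 266, 1e3, 1e6), 3), nrow = 3,
                dimnames = list(paste0("s", 1:3), ids))
  })
  m[2, 100] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(peak_table(m), path)
  back <- read_peak_table(path)
  expect_identical(dim(back$areas), c(3L, 266L))
  expect_equal(back$areas, m)
})

test_that("library validation resolves target m/z and flags conflicts", {
  lib <- tiny_library()
  expect_equal(round(lib$target_mz[lib$compound_id == "T3"], 4), 651.7973)
  expect_equal(round(lib$target_mz[lib$compound_id == "T4"], 4), 777.6940)
  # disagreeing precomputed target wins, with a warning
  lib2 <- data.frame(compound_id = "x", name = "x", formula = "C6H12O6",
                     adduct = "[M+H]+", target_mz = 200.0,
                     rt_expected = 5, stringsAsFactors = FALSE)
  expect_warning(out <- validate_compound_library(lib2), "target_mz wins")
  expect_equal(out$target_mz, 200.0)
  # broken pairing is rejected
  lib3 <- tiny_library()
  lib3$is_pair[3] <- "nonexistent"
  expect_error(validate_compound_library(lib3), "unknown compound")
  lib4 <- tiny_library()
  lib4$is_pair[1] <- "alanine"  # not IS-flagged
  expect_error(validate_compound_library(lib4), "internal-standard")
})

test_that("sample metadata validation enforces dilution-factor rules", {
  meta <- data.frame(sample_id = c("a", "b"), group = "g",
                     sample_type = c("study", "pool_dilution"),
                     dilution_factor = c(1, 1 / 3))
  expect_silent(validate_sample_meta(meta))
  meta$dilution_factor[2] <- 1
  expect_error(validate_sample_meta(meta), "pool_dilution")
  meta$dilution_factor <- c(0, 0.5)
  expect_error(validate_sample_meta(meta), "\\(0, 1\\]")
  meta$dilution_factor <- c(1, 0.5)
  meta$sample_type[1] <- "mystery"
  expect_error(validate_sample_meta(meta), "unknown sample_type")
})

test_that("config round-trips and rejects unknown keys", {
  cfg <- default_config()
  expect_equal(cfg$ppm_tol, 5)
  expect_equal(cfg$cv_cutoff, 30)
  expect_equal(cfg$rsq_cutoff, 0.95)
  expect_equal(cfg$scan_range_full, c(70, 1000))
  expect_equal(cfg$scan_range_narrow, c(600, 800))
  path <- withr::local_tempfile(fileext = ".json")
  cfg$ppm_tol <- 7.5
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$ppm_tol, 7.5)
  expect_equal(back$scan_range_narrow, c(600, 800))
  writeLines('{"ppm_tolerance": 5}', path)
  expect_error(read_config(path), "unknown config key")
})
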