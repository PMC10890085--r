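two_is_lib <- function(n_met = 1L) {
  validate_compound_library(data.frame(
    compound_id = c(sprintf("m%d", seq_len(n_met)), "IS1", "IS2"),
    name = "x", target_mz = seq(100, by = 10,
                                length.out = n_met + 2L),
    rt_expected = 5, is_internal_standard = c(rep(FALSE, n_met), TRUE,
                                              TRUE),
    stringsAsFactors = FALSE))
}

test_that("is_factors matches hand-computed mean-centered means", {
  # IS1 areas (100, 200), IS2 areas (10, 30):
  # r1 = (100/150, 200/150), r2 = (10/20, 30/20)
  # f  = ((2/3 + 1/2)/2, (4/3 + 3/2)/2) = (0.58333, 1.41667)
  m <- matrix(c(50, 70, 100, 200, 10, 30), nrow = 2,
              dimnames = list(c("s1", "s2"), c("m1", "IS1", "IS2")))
  tab <- make_table(m, two_is_lib())
  nf <- is_factors(tab)
  expect_equal(unname(nf$factors), c(7 / 12, 17 / 12), tolerance = 1e-12)
  expect_identical(nf$is_used, c("IS1", "IS2"))
  # identical IS across samples -> all factors 1
  m2 <- m; m2[, c("IS1", "IS2")] <- rep(c(100, 10), each = 2)
  expect_equal(unname(is_factors(make_table(m2, two_is_lib()))$factors),
               c(1, 1))
  # doubling every IS in one sample doubles its factor
  m3 <- m; m3[2, c("IS1", "IS2")] <- 2 * m3[1, c("IS1", "IS2")]
  f3 <- is_factors(make_table(m3, two_is_lib()))$factors
  expect_equal(unname(f3[2] / f3[1]), 2)
})

test_that("is_factors drops IS with missing values and can run dry", {
  m <- matrix(c(5, 6, 100, NA, 10, 30), nrow = 2,
              dimnames = list(c("s1", "s2"), c("m1", "IS1", "IS2")))
  expect_warning(nf <- is_factors(make_table(m, two_is_lib())), "IS1")
  expect_identical(nf$is_used, "IS2")
  m[, "IS2"] <- c(0, 5)  # zero counts as missing too
  expect_error(suppressWarnings(is_factors(make_table(m, two_is_lib()))),
               "no usable internal standards")
})

test_that("normalization factors undo planted matrix distortion exactly", {
  withr::with_seed(51, {
    true <- matrix(10^runif(4 * 6, 3, 6), nrow = 4,
                   dimnames = list(paste0("s", 1:4),
                                   c(sprintf("m%d", 1:4), "IS1", "IS2")))
    true[, c("IS1", "IS2")] <- rep(c(2e4, 5e4), each = 4)
    mfac <- c(0.5, 1, 1.5, 3)
    distorted <- true * mfac
    tab <- make_table(distorted, two_is_lib(4))
    nf <- is_factors(tab)
    expect_equal(unname(nf$factors / nf$factors[2]), mfac / mfac[2],
                 tolerance = 1e-12)
    normed <- apply_factors(tab, nf)
    ratio <- normed$areas / true
    expect_lt(diff(range(ratio)), 1e-10)  # equal up to one global constant
  })
})

test_that("pooled_cv matches hand sd/mean and handles degeneracy", {
  m <- matrix(c(100, 100, 100, 90, 110, 120, 100, NA, NA),
              nrow = 3, dimnames = list(c("pool1", "pool2", "pool3"),
                                        c("c1", "c2", "c3")))
  tab <- make_table(m)
  cv <- pooled_cv(tab)
  expect_equal(unname(cv["c1"]), 0)
  expect_equal(unname(cv["c2"]), 100 * sd(c(90, 110, 120)) /
                 mean(c(90, 110, 120)))
  expect_true(is.na(cv["c3"]))          # single value -> undefined
  # the frozen two-injection example: (90, 110) -> 14.14%
  m2 <- m[1:2, , drop = FALSE]; m2[, "c2"] <- c(90, 110)
  expect_equal(unname(pooled_cv(make_table(m2))["c2"]), 14.14213,
               tolerance = 1e-5)
  expect_error(pooled_cv(make_table(m[1, , drop = FALSE])), ">= 2")
})

test_that("dilution_linearity reproduces oracle OLS R-squared", {
  m <- matrix(c(1000, 1000 / 3, 100, 1000, 350, 120, 7, 7, 7),
              nrow = 3, dimnames = list(c("pool1", "dil3_1", "dil10_1"),
                                        c("prop", "nearlin", "flat")))
  tab <- make_table(m)
  rsq <- dilution_linearity(tab)
  expect_equal(unname(rsq["prop"]), 1, tolerance = 1e-12)
  # independent oracle: squared Pearson correlation
  expect_equal(unname(rsq["nearlin"]),
               cor(c(1, 1 / 3, 1 / 10), c(1000, 350, 120))^2,
               tolerance = 1e-12)
  expect_true(is.na(rsq["flat"]))       # constant areas -> undefined
  expect_error(dilution_linearity(make_table(m[1:2, , drop = FALSE])),
               "3 distinct")
})

test_that("qc_filter applies strict cutoffs and matches brute force", {
  ids <- c("borderline_keep", "cv_at_cut", "rsq_at_cut", "good")
  cv <- c(29.9, 30.0, 10, 5)
  rsq <- c(0.951, 0.99, 0.95, 0.999)
  names(cv) <- names(rsq) <- ids
  m <- matrix(1, nrow = 3, ncol = 4,
              dimnames = list(c("pool1", "dil3_1", "dil10_1"), ids))
  res <- qc_filter(make_table(m), cv = cv, rsq = rsq)
  expect_identical(colnames(res$table$areas), c("borderline_keep", "good"))
  brute <- ids[cv < 30 & rsq > 0.95]
  expect_identical(res$report$metrics$compound_id[res$report$metrics$pass],
                   brute)
  expect_equal(res$report$n_kept, 2L)
  expect_match(res$report$metrics$reason[2], "CV 30.0% >= 30")
  # idempotence: filtering the kept table again changes nothing
  res2 <- qc_filter(res$table, cv = cv[brute], rsq = rsq[brute])
  expect_identical(colnames(res2$table$areas), colnames(res$table$areas))
})

test_that("internal standards are retained through qc_filter but flagged", {
  m <- matrix(c(5, 1, 2), nrow = 1, dimnames = list("s1",
                                                    c("m1", "IS1", "IS2")))
  cv <- c(m1 = 50, IS1 = 50, IS2 = 1)
  rsq <- c(m1 = 0.5, IS1 = 0.5, IS2 = 0.999)
  res <- qc_filter(make_table(m, two_is_lib()), cv = cv, rsq = rsq)
  expect_identical(colnames(res$table$areas), c("IS1", "IS2"))
  expect_true(all(res$report$metrics$internal_standard[2:3]))
  expect_equal(res$report$n_dropped, 1L)
})

test_that("total_signal_normalize equalizes totals of targeted samples", {
  m <- matrix(c(40, 80, 160, 60, 120, 240), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("c1", "c2")))
  out <- total_signal_normalize(make_table(m))
  expect_equal(unname(attr(out, "total_signal_factors")),
               c(7 / 3, 7 / 6, 7 / 12), tolerance = 1e-12)
  expect_equal(unname(rowSums(out$areas)),
               rep(mean(c(100, 200, 400)), 3))
  # sample B = 2 x sample A -> identical after normalization
  expect_equal(out$areas[1, ], out$areas[2, ])
  # single sample passes through unchanged
  one <- total_signal_normalize(make_table(m[1, , drop = FALSE]))
  expect_equal(one$areas, m[1, , drop = FALSE])
  # zero-total sample flagged and excluded
  m0 <- rbind(m, s4 = c(0, 0))
  expect_warning(z <- total_signal_normalize(make_table(m0)), "s4")
  expect_identical(attr(z, "excluded_samples"), "s4")
  expect_equal(z$areas["s4", ], m0["s4", ])
})

test_that("th_relative_abundance forms analyte/IS ratios and flags gaps", {
  lib <- tiny_library()
  m <- matrix(c(500, 900, 0,      # T3
                100, NA, 70,      # T4
                5, 5, 5,          # alanine
                1000, 1800, 40,   # IS_13C_T3
                200, 210, NA),    # IS_13C_T4
              nrow = 3,
              dimnames = list(paste0("s", 1:3), lib$compound_id))
  th <- th_relative_abundance(make_table(m, lib))
  expect_equal(th$T3, c(0.5, 0.5, NA))   # zero analyte -> missing, not 0
  expect_equal(th$T4, c(0.5, NA, NA))    # missing analyte / missing IS
  # invariance to joint per-sample multiplicative distortion
  m2 <- m * c(3, 0.25, 10)
  th2 <- th_relative_abundance(make_table(m2, lib))
  expect_equal(th2$T3, th$T3)
  expect_equal(th2$T4, th$T4)
})

test_that("th_relative_abundance demands equal volumes", {
  lib <- tiny_library()
  m <- matrix(1, nrow = 2, ncol = 5,
              dimnames = list(c("s1", "s2"), lib$compound_id))
  tab <- make_table(m, lib)
  tab$samples$volume_ul <- c(5, 7)
  expect_error(th_relative_abundance(tab), "equal-volume")
})
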