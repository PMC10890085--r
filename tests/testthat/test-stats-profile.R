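test_that("log_pareto matches hand computation and handles constants", {
  m <- matrix(c(1, 3, 7, 7), nrow = 2,
              dimnames = list(c("s1", "s2"), c("v", "const")))
  expect_warning(sm <- log_pareto(m), "constant")
  # log10(1, 3) = (0, 0.47712); mean 0.23856; sd 0.33738;
  # sqrt(sd) 0.58084 -> scaled (-0.41072, +0.41072)
  expect_equal(sm$x[, "v"], c(s1 = -0.4107162, s2 = 0.4107162),
               tolerance = 1e-6)
  expect_equal(unname(sm$x[, "const"]), c(0, 0))
  expect_equal(unname(sm$center["v"]), mean(log10(c(1, 3))))
})

test_that("zeros and missing values are imputed as half-minimum", {
  m <- matrix(c(10, 0, 40, 100, NA, 400), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  sm <- log_pareto(m)
  logged <- pareto_inverse(sm)
  expect_equal(unname(10^logged[2, "a"]), 5)    # half of min positive 10
  expect_equal(unname(10^logged[2, "b"]), 50)
  # a compound with no observed values is dropped with a warning
  m2 <- cbind(m, empty = c(0, NA, 0))
  expect_warning(sm2 <- log_pareto(m2), "empty")
  expect_identical(colnames(sm2$x), c("a", "b"))
})

test_that("Pareto identity: scaled column variance equals logged sd", {
  withr::with_seed(61, {
    m <- matrix(10^runif(200, 2, 6), nrow = 10,
                dimnames = list(paste0("s", 1:10), paste0("c", 1:20)))
    sm <- log_pareto(m)
    logged_sd <- apply(log10(m), 2, sd)
    expect_equal(unname(apply(sm$x, 2, var)), unname(logged_sd),
                 tolerance = 1e-10)
    # inverse transform recovers the imputed logged matrix
    expect_equal(pareto_inverse(sm), log10(m), tolerance = 1e-10)
  })
})

test_that("pca_scores: geometry, orthogonality, reconstruction", {
  withr::with_seed(63, {
    # samples on a 1-D line -> PC1 carries all the variance
    direction <- rnorm(6)
    line <- outer(seq(-2, 2, length.out = 5), direction)
    dimnames(line) <- list(paste0("s", 1:5), paste0("c", 1:6))
    p1 <- pca_scores(line, k = 2)
    expect_equal(p1$explained_variance[1], 1, tolerance = 1e-12)
    # random matrix: orthogonal scores, non-increasing variance,
    # full-rank reconstruction
    x <- matrix(rnorm(8 * 5), nrow = 8,
                dimnames = list(paste0("s", 1:8), paste0("c", 1:5)))
    k <- 5
    p <- pca_scores(x, k = k)
    expect_lt(abs(sum(p$scores[, 1] * p$scores[, 2])), 1e-8)
    expect_true(all(diff(p$explained_variance) <= 1e-12))
    xc <- sweep(x, 2, colMeans(x))
    expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-8)
    # sign convention: dominant loading positive
    for (j in 1:k) {
      expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    }
    expect_error(pca_scores(x, k = 8), "exceeds")
  })
})

test_that("planted group separation dominates PC1", {
  withr::with_seed(65, {
    n_per <- 6; p <- 30
    shift <- rnorm(p, 0, 1)
    x <- rbind(
      matrix(rnorm(n_per * p, 0, 0.1), n_per, p),
      matrix(rnorm(n_per * p, 0, 0.1), n_per, p) +
        matrix(shift, n_per, p, byrow = TRUE))
    dimnames(x) <- list(paste0("s", 1:(2 * n_per)), paste0("c", 1:p))
    sc <- pca_scores(x, k = 2)$scores[, 1]
    g <- rep(c("a", "b"), each = n_per)
    gap <- abs(mean(sc[g == "a"]) - mean(sc[g == "b"]))
    within_sd <- max(sd(sc[g == "a"]), sd(sc[g == "b"]))
    expect_gt(gap, 3 * within_sd)
  })
})

test_that("group_compare: identical groups give log2FC 0 and q near 1", {
  m <- matrix(rep(c(10, 12, 9, 10, 12, 9), 3), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:3)))
  res <- group_compare(m, rep(c("a", "b"), each = 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$q > 0.95))
})

test_that("BH adjustment matches the hand-computed example", {
  # p = (.01,.02,.03,.04), m = 4 -> q all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # group_compare's q column is BH over its own p column
  withr::with_seed(67, {
    m <- matrix(10^rnorm(12 * 20, 4, 0.2), nrow = 12,
                dimnames = list(paste0("s", 1:12), paste0("c", 1:20)))
    res <- group_compare(m, rep(c("a", "b"), each = 6))
    expect_equal(res$q, p.adjust(res$p, method = "BH"))
  })
})

test_that("group_compare skips and flags undersized groups", {
  m <- matrix(c(1, NA, NA, 4, 5, 6,     # one observed value in group a
                1, 2, 3, 4, 5, 6), nrow = 6,
              dimnames = list(paste0("s", 1:6), c("gappy", "full")))
  res <- group_compare(m, rep(c("a", "b"), each = 3))
  expect_true(res$skipped[res$compound_id == "gappy"])
  expect_false(res$skipped[res$compound_id == "full"])
  expect_true(is.na(res$p[res$compound_id == "gappy"]))
})

test_that("a planted 4x effect is detected with high power", {
  hits <- 0L
  reps <- 50L
  for (seed in seq_len(reps)) {
    withr::with_seed(70 + seed, {
      base <- 10^4
      m <- cbind(
        effect = c(base * 4 * (1 + rnorm(6, 0, 0.1)),
                   base * (1 + rnorm(6, 0, 0.1))),
        matrix(base * (1 + rnorm(12 * 19, 0, 0.1)), nrow = 12))
      colnames(m)[-1] <- paste0("null", 1:19)
      rownames(m) <- paste0("s", 1:12)
      res <- group_compare(m, rep(c("a", "b"), each = 6))
      if (res$q[res$compound_id == "effect"] < 0.05) hits <- hits + 1L
    })
  }
  expect_gte(hits / reps, 0.95)
})

test_that("top_changed ranks the planted hit first, deterministically", {
  withr::with_seed(77, {
    m <- matrix(10^rnorm(12 * 30, 4, 0.05), nrow = 12,
                dimnames = list(paste0("s", 1:12), paste0("c", 1:30)))
    m[1:6, "c7"] <- m[1:6, "c7"] * 10       # planted 10x hit
    labels <- rep(c("a", "b"), each = 6)
    top <- top_changed(m, labels, n = 5)
    expect_identical(top$compound_id[1], "c7")
    expect_identical(top$rank, 1:5)
    expect_identical(top, top_changed(m, labels, n = 5))
    # n larger than compound count returns everything, ranked
    all_ranked <- top_changed(m, labels, n = 1000)
    expect_equal(nrow(all_ranked), 30)
  })
})

test_that("top_changed uses ANOVA across more than two groups", {
  withr::with_seed(79, {
    m <- matrix(10^rnorm(12 * 10, 4, 0.05), nrow = 12,
                dimnames = list(paste0("s", 1:12), paste0("c", 1:10)))
    labels <- rep(c("a", "b", "c"), each = 4)
    m[labels == "c", "c3"] <- m[labels == "c", "c3"] * 8
    top <- top_changed(m, labels, n = 3)
    expect_identical(top$compound_id[1], "c3")
    expect_lt(top$p[1], 1e-4)
  })
})
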