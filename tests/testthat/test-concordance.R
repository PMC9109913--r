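# Naive from-definition recomputations used as independent oracles.
naive_kappa <- function(m, weighting = "none") {
  k <- nrow(m)
  n <- sum(m)
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j)
    w[i, j] <- switch(weighting,
                      none = as.numeric(d == 0),
                      linear = 1 - d / (k - 1),
                      quadratic = 1 - (d / (k - 1))^2)
  }
  p_o <- 0; p_e <- 0
  for (i in 1:k) for (j in 1:k) {
    p_o <- p_o + w[i, j] * m[i, j] / n
    p_e <- p_e + w[i, j] * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
  }
  (p_o - p_e) / (1 - p_e)
}

naive_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

naive_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

test_that("kappa on the exon VIII pathogenicity table is substantial", {
  res <- cohen_kappa(crosstab_2x2(a = 71, b = 1, c = 7, d = 19))
  expect_equal(round(res$kappa, 3), 0.774)
  expect_equal(res$band, "substantial")
  expect_lt(res$p_value, 1e-5)
})

test_that("kappa on the exon IV pathogenicity table follows the standard formula", {
  # The standard formula gives 0.352 for this table (58, 6, 20, 14);
  # see the methods vignette for the documented discrepancy with the
  # originally reported 0.388.
  res <- cohen_kappa(crosstab_2x2(a = 58, b = 6, c = 20, d = 14))
  expect_equal(round(res$kappa, 3), 0.352)
  expect_equal(res$band, "fair")
})

test_that("kappa basics: perfect agreement, degenerate tables, 2x2 weightings", {
  expect_equal(cohen_kappa(diag(c(10, 20, 5)))$kappa, 1)
  expect_error(cohen_kappa(matrix(c(7, 0, 0, 0), 2, 2)), "degenerate")
  expect_error(cohen_kappa(matrix(1:6, 2, 3)), "square")
  m <- matrix(c(40, 5, 8, 30), 2, 2)
  expect_equal(cohen_kappa(m, "linear")$kappa, cohen_kappa(m, "none")$kappa)
  expect_equal(cohen_kappa(m, "quadratic")$kappa, cohen_kappa(m, "none")$kappa)
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  set.seed(8)
  m <- matrix(rpois(16, 10), 4, 4)
  perm <- sample(4)
  expect_equal(cohen_kappa(m)$kappa, cohen_kappa(m[perm, perm])$kappa,
               tolerance = 1e-12)
  # kappa = 1 iff off-diagonal mass is zero
  expect_lt(cohen_kappa(m + diag(4))$kappa, 1)
})

test_that("kappa, r and slope match brute-force recomputation on random data", {
  set.seed(99)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 6), k, k) + diag(k)  # keep marginals non-degenerate
    for (wt in c("none", "linear", "quadratic")) {
      expect_equal(cohen_kappa(m, wt)$kappa, naive_kappa(m, wt),
                   tolerance = 1e-10)
    }
    n <- sample(10:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    expect_equal(pearson_r(x, y)$estimate, naive_pearson(x, y),
                 tolerance = 1e-10)
    expect_equal(ols_fit(x, y)$estimate, naive_slope(x, y),
                 tolerance = 1e-10)
  }
})

test_that("unweighted kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 8), 3, 3) + diag(3)
    expect_equal(cohen_kappa(m)$kappa,
                 e1071::classAgreement(m)$kappa, tolerance = 1e-10)
  }
})

test_that("permutation p-values broadly agree with asymptotic ones", {
  m <- matrix(c(30, 8, 6, 25), 2, 2)
  asym <- cohen_kappa(m)$p_value
  perm <- cohen_kappa(m, p_method = "permutation",
                      n_permutations = 4000)$p_value
  expect_lt(perm, 0.01)
  expect_lt(asym, 0.01)
})

test_that("agreement bands follow the conventional scale", {
  expect_equal(agreement_band(0.774), "substantial")
  expect_equal(agreement_band(0.558), "moderate")
  expect_equal(agreement_band(0.15), "slight")
  expect_equal(agreement_band(c(0.81, 0.61, 0.41, 0.21, 0.2, -0.5)),
               c("almost perfect", "substantial", "moderate", "fair",
                 "slight", "slight"))
  expect_error(agreement_band(1.2), "\\[-1, 1\\]")
})

test_that("pearson_r handles exact linear relations and degenerate input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  expect_error(pearson_r(x, rep(3, 10)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  # invariance under positive affine transforms
  set.seed(4)
  y <- rnorm(10)
  expect_equal(pearson_r(x, y)$estimate,
               pearson_r(3 * x + 7, 0.5 * y - 2)$estimate, tolerance = 1e-12)
})

test_that("ols_fit reports slope, R-squared and broom-style summaries", {
  x <- c(5, 6, 7, 8, 9, 10)
  f <- suppressWarnings(ols_fit(x, x))  # exact fit warns in summary.lm
  expect_equal(f$estimate, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  td <- suppressWarnings(tidy(f))
  expect_setequal(td$term, c("(Intercept)", "x"))
  gl <- glance(f)
  expect_equal(gl$estimate, 1, tolerance = 1e-12)
  expect_lte(f$adj_r_squared, f$r_squared)

  # independent noise: slope within 3 SEs of zero over seeded replicates
  set.seed(21)
  slopes_ok <- vapply(1:20, function(i) {
    xx <- rnorm(30)
    yy <- rnorm(30)
    fit <- ols_fit(xx, yy)
    se <- tidy(fit)$std_error[2]
    abs(fit$estimate) < 3 * se
  }, logical(1))
  expect_gte(mean(slopes_ok), 0.9)
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "Degenerate")
})

test_that("pathogenicity cross-tabs count the four label combinations", {
  calls <- tibble::tibble(ddpcr_label = rep("benign", 3),
                          acgh_label = rep("benign", 3))
  ct <- build_pathogenicity_crosstab(calls)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(3, 0, 0, 0))

  mixed <- tibble::tibble(
    ddpcr_label = c("benign", "benign", "pathogenic", "pathogenic", NA),
    acgh_label = c("benign", "pathogenic", "benign", "pathogenic", "benign")
  )
  expect_warning(ct2 <- build_pathogenicity_crosstab(mixed), "Skipping 1")
  expect_equal(c(ct2$a, ct2$b, ct2$c, ct2$d), c(1, 1, 1, 1))
  expect_equal(ct2$n_skipped, 1)

  expect_error(build_pathogenicity_crosstab(calls[0, ]), "n = 0")
})

test_that("cn_concordance assembles the full battery coherently", {
  set.seed(77)
  acgh <- rep(c(5L, 6L, 7L, 8L, 10L), times = c(8, 16, 5, 3, 3))
  est <- acgh + rnorm(length(acgh), 0, 0.35)
  samples <- tibble::tibble(sample_id = paste0("S", seq_along(acgh)),
                            cn_estimate = est, acgh_cn = acgh)
  cc <- cn_concordance(samples)
  expect_gt(cc$pearson$estimate, 0.9)
  expect_equal(cc$ols$estimate, 1, tolerance = 0.15)
  expect_s3_class(cc$kappa_cn_linear, "kappa_result")
  expect_s3_class(cc$kappa_cn_quadratic, "kappa_result")
  expect_equal(cc$crosstab$n, length(acgh))
  gl <- glance(cc)
  expect_equal(gl$n, length(acgh))
  expect_gte(cc$kappa_pathogenicity$kappa, -1)
})
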