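test_that("percent CV matches the closed form and is scale invariant", {
  expect_equal(percent_cv(c(6.0, 6.0)), 0)
  # sd(c(6, 6.2)) = 0.1414214 (n-1), mean 6.1
  expect_equal(percent_cv(c(6.0, 6.2)), 100 * sd(c(6, 6.2)) / 6.1,
               tolerance = 1e-12)
  expect_equal(round(percent_cv(c(6.0, 6.2)), 3), 2.318)
  expect_error(percent_cv(6.0), "two values")
  expect_error(percent_cv(c(-1, 1)), "mean is zero")
  x <- c(5.5, 6.1, 6.4)
  expect_equal(percent_cv(3 * x), percent_cv(x), tolerance = 1e-12)
  # population denominator option
  expect_equal(percent_cv(c(6, 6.2), denominator = "n"),
               100 * (0.1 / 6.1), tolerance = 1e-12)
})

test_that("intra-assay pairs come from within one experiment", {
  runs <- make_runs(
    make_run(well = "A01", sample_id = "S1", experiment_id = "E1",
             cn_estimate = 6.0),
    make_run(well = "A02", sample_id = "S1", experiment_id = "E1",
             cn_estimate = 6.2),
    make_run(well = "A03", sample_id = "S2", experiment_id = "E1",
             cn_estimate = 5.9),
    make_run(well = "A04", sample_id = "S2", experiment_id = "E2",
             cn_estimate = 6.1)
  )
  res <- intra_assay(runs)
  expect_equal(nrow(res$pairs), 1)  # S2 runs span experiments: no intra pair
  expect_equal(res$pairs$sample_id, "S1")
  expect_equal(round(res$pairs$pct_cv, 3), 2.318)
  expect_equal(res$summary$mean_pct_cv, res$pairs$pct_cv)
})

test_that("triplicates keep the two highest-droplet runs; assay CV averages pairs", {
  runs <- make_runs(
    make_run(well = "A01", sample_id = "S1", experiment_id = "E1",
             n_pp = 1500, n_pn = 4500, n_np = 1500, n_nn = 4500,
             cn_estimate = 6.0),                                   # 12,000
    make_run(well = "A02", sample_id = "S1", experiment_id = "E1",
             cn_estimate = 6.0),                                   # 15,000
    make_run(well = "A03", sample_id = "S1", experiment_id = "E1",
             n_pp = 2000, n_pn = 6000, n_np = 2000, n_nn = 6000,
             cn_estimate = 6.0),                                   # 16,000
    make_run(well = "B01", sample_id = "S2", experiment_id = "E1",
             cn_estimate = 6.0),
    make_run(well = "B02", sample_id = "S2", experiment_id = "E1",
             cn_estimate = 6.2)
  )
  res <- intra_assay(runs)
  s1 <- res$pairs[res$pairs$sample_id == "S1", ]
  expect_setequal(c(s1$well_a, s1$well_b), c("A03", "A02"))
  expect_equal(s1$pct_cv, 0)
  # assay mean %CV = unweighted mean of pair CVs {0, 2.318}
  expect_equal(res$summary$mean_pct_cv,
               mean(c(0, percent_cv(c(6.0, 6.2)))))
})

test_that("inter-assay selection maximizes droplets across experiments", {
  runs <- make_runs(
    make_run(well = "A01", sample_id = "S1", experiment_id = "E1",
             n_pp = 1200, n_pn = 3600, n_np = 1200, n_nn = 6000),  # 12,000
    make_run(well = "A02", sample_id = "S1", experiment_id = "E1",
             n_pp = 1400, n_pn = 4200, n_np = 1400, n_nn = 7000),  # 14,000
    make_run(well = "A03", sample_id = "S1", experiment_id = "E2",
             n_pp = 1300, n_pn = 3900, n_np = 1300, n_nn = 6500)   # 13,000
  )
  sel <- select_inter_assay_runs(runs)
  expect_setequal(sel$well, c("A02", "A03"))
  expect_true(sel$experiment_id[1] != sel$experiment_id[2])

  # exhaustive check: best (min, sum) over all cross-experiment pairs
  combos <- t(utils::combn(nrow(runs), 2))
  cross <- combos[runs$experiment_id[combos[, 1]] !=
                    runs$experiment_id[combos[, 2]], , drop = FALSE]
  mins <- pmin(runs$n_total[cross[, 1]], runs$n_total[cross[, 2]])
  best <- cross[which.max(mins), ]
  expect_setequal(sel$well, runs$well[best])

  # all in one experiment -> none
  one_exp <- dplyr::mutate(runs, experiment_id = "E1")
  expect_null(select_inter_assay_runs(one_exp))

  # exactly one run per experiment -> that pair
  two <- runs[c(1, 3), ]
  expect_setequal(select_inter_assay_runs(two)$well, c("A01", "A03"))
})

test_that("inter-assay %CV falls with droplet count on simulated duplicates", {
  mean_cv <- vapply(c(5000, 10000, 20000), function(n) {
    cvs <- vapply(1:30, function(i) {
      a <- simulate_and_quantify(sim_config(n_droplets = n, true_cn = 6,
                                            seed = 6000 + n + i))
      b <- simulate_and_quantify(sim_config(n_droplets = n, true_cn = 6,
                                            seed = 7000 + n + i))
      percent_cv(c(a$cn_estimate, b$cn_estimate))
    }, numeric(1))
    mean(cvs)
  }, numeric(1))
  expect_true(all(diff(mean_cv) < 0))
})

test_that("per-group summaries report range, mean, sd and %CV", {
  samples <- tibble::tibble(acgh_cn = c(6L, 6L, 8L, 8L, 10L),
                            cn_estimate = c(5.8, 6.2, 8.0, 8.0, 10.3))
  s <- cn_group_summary(samples)
  g6 <- s[s$acgh_cn == 6, ]
  expect_equal(g6$mean, 6)
  expect_equal(g6$sd, sqrt(0.08), tolerance = 1e-12)
  expect_equal(round(g6$pct_cv, 3), 4.714)
  g8 <- s[s$acgh_cn == 8, ]
  expect_equal(g8$sd, 0)
  expect_equal(g8$pct_cv, 0)
  expect_true(is.na(s$sd[s$acgh_cn == 10]))
  expect_equal(nrow(cn_group_summary(samples[0, ])), 0)
})

test_that("sample-level CN averages the selected inter-assay pair", {
  runs <- make_runs(
    make_run(well = "A01", sample_id = "S1", experiment_id = "E1",
             cn_estimate = 6.0),
    make_run(well = "A02", sample_id = "S1", experiment_id = "E2",
             cn_estimate = 6.4),
    make_run(well = "A03", sample_id = "S2", experiment_id = "E1",
             cn_estimate = 8.1)
  )
  s <- sample_cn(runs)
  expect_equal(s$cn_estimate[s$sample_id == "S1"], 6.2)
  # single-experiment sample falls back to its best run
  expect_equal(s$cn_estimate[s$sample_id == "S2"], 8.1)
  b <- sample_cn(runs, rule = "best_run")
  expect_true(b$cn_estimate[b$sample_id == "S1"] %in% c(6.0, 6.4))
})
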