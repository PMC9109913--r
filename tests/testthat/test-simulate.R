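test_that("simulator configuration is validated before sampling", {
  expect_error(sim_config(lambda_ref = 0), "lambda_ref")
  expect_error(sim_config(rain_fraction = 1), "rain_fraction")
  expect_error(sim_config(linkage_fraction = 1.2), "linkage_fraction")
  expect_error(sim_config(fam_pos = c(500, 50)), "exceed")
})

test_that("identical configs give bit-identical wells", {
  cfg <- sim_config(n_droplets = 5000, seed = 42, rain_fraction = 0.02)
  a <- simulate_well(cfg)
  b <- simulate_well(cfg)
  expect_identical(a$droplets, b$droplets)
  expect_identical(a$truth, b$truth)
})

test_that("zero target copy number yields no target-positive droplets", {
  cfg <- sim_config(n_droplets = 5000, true_cn = 0, seed = 3)
  sim <- simulate_well(cfg)
  expect_equal(sim$truth$n_target_positive, 0)
  # all FAM amplitudes from the negative cluster (well below midpoint)
  expect_true(all(sim$droplets$fam < 4500))
})

test_that("negative-droplet fraction matches the Poisson zero class", {
  # true_cn = 6, lambda_ref = 0.5 -> lambda_target = 1.5;
  # P(target-negative) = exp(-1.5).  99.9% binomial band around it.
  cfg <- sim_config(n_droplets = 20000, lambda_ref = 0.5, true_cn = 6,
                    seed = 11)
  sim <- simulate_well(cfg)
  p <- exp(-1.5)
  half <- qnorm(0.9995) * sqrt(p * (1 - p) / 20000)
  frac_neg <- 1 - sim$truth$n_target_positive / 20000
  expect_gt(frac_neg, p - half)
  expect_lt(frac_neg, p + half)
})

test_that("observed negative fractions converge to exp(-lambda) over many wells", {
  # Poisson consistency on both channels at >= 1e6 total droplets.
  n_wells <- 50
  n <- 20000
  neg_t <- neg_r <- 0
  for (i in seq_len(n_wells)) {
    s <- simulate_well(sim_config(n_droplets = n, lambda_ref = 0.4,
                                  true_cn = 5, seed = 1000 + i))
    neg_t <- neg_t + (n - s$truth$n_target_positive)
    neg_r <- neg_r + (n - s$truth$n_ref_positive)
  }
  total <- n_wells * n
  for (case in list(list(obs = neg_t / total, lambda = 0.4 * 5 / 2),
                    list(obs = neg_r / total, lambda = 0.4))) {
    p <- exp(-case$lambda)
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(case$obs - p), 4 * se)
  }
})

test_that("full linkage collapses the triplicate to allelic units", {
  # L = 1: six copies partition as two indivisible 3-copy blocks, so the
  # effective target rate equals the reference rate and the estimate
  # concentrates near CN 2.
  ests <- vapply(1:50, function(i) {
    q <- simulate_and_quantify(sim_config(n_droplets = 15000,
                                          true_cn = 6,
                                          linkage_fraction = 1,
                                          seed = 2000 + i))
    q$cn_estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.1)
})

test_that("estimated CN is non-increasing in the linkage fraction", {
  mean_cn <- vapply(c(0, 0.5, 1), function(L) {
    ests <- vapply(1:20, function(i) {
      simulate_and_quantify(sim_config(n_droplets = 10000, true_cn = 6,
                                       linkage_fraction = L,
                                       seed = 3000 + i))$cn_estimate
    }, numeric(1))
    mean(ests)
  }, numeric(1))
  expect_true(all(diff(mean_cn) < 0))
})

test_that("simulate_plate assembles wells, NTC and truth consistently", {
  configs <- list(A01 = sim_config(n_droplets = 2000, seed = 1),
                  A02 = sim_config(n_droplets = 2000, true_cn = 8, seed = 2))
  plate <- simulate_plate(configs, include_ntc = TRUE, ntc_n_droplets = 2000)
  expect_setequal(unique(plate$amplitudes$well), c("A01", "A02", "H12"))
  expect_equal(sum(plate$plate$is_ntc), 1)
  expect_equal(nrow(plate$truth), 2)

  # NTC with zero false-positive rate has no positives on either channel
  ntc_amp <- plate$amplitudes[plate$amplitudes$well == "H12", ]
  counts <- check_ntc(assign_clusters(ntc_amp, default_thresholds()))
  expect_equal(counts$n_fam_positive, 0)
  expect_equal(counts$n_hex_positive, 0)
  expect_true(counts$ntc_pass)

  # determinism of the whole plate
  plate2 <- simulate_plate(configs, include_ntc = TRUE, ntc_n_droplets = 2000)
  expect_identical(plate$amplitudes, plate2$amplitudes)

  expect_error(simulate_plate(list(A01 = configs[[1]], A1 = configs[[2]])),
               "Duplicate")
})
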