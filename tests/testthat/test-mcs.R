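# The four Monte Carlo variants, iteration allocation, convergence, and
# Spearman sensitivity.

whole_pop_config <- function(variant = "traditional", iterations = 30000,
                             seed = 1, ...) {
  p <- default_exposure_params()
  mcs_config(variant, conc = p$site_conc, bw = p$bw$whole, ir = p$ir$whole,
             iterations = iterations, seed = seed, ...)
}

test_that("iteration allocation conserves the total by largest remainder", {
  expect_equal(allocate_iterations(30000, rep(1 / 3, 3)),
               c(10000L, 10000L, 10000L))
  expect_equal(allocate_iterations(9, c(0.5, 0.3, 0.2)), c(4L, 3L, 2L))
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    w <- rexp(k); w <- w / sum(w)
    n <- sample(10:5000, 1)
    counts <- allocate_iterations(n, w)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - w * n) < 1))
  }
  expect_error(allocate_iterations(100, c(0.5, -0.5, 1)), "positive")
})

test_that("identical config and seed give bit-identical simulations", {
  for (variant in c("traditional", "age_stratified", "correlated")) {
    p <- default_exposure_params()
    cfg <- switch(variant,
      traditional = whole_pop_config(seed = 99, iterations = 2000),
      age_stratified = mcs_config("age_stratified", conc = p$site_conc,
                                  strata = p$strata, iterations = 2000,
                                  seed = 99),
      correlated = mcs_config("correlated", conc = p$site_conc,
                              bw = p$bw$whole, power_law = p$power_law,
                              iterations = 2000, seed = 99))
    expect_identical(run_mcs(cfg)$draws, run_mcs(cfg)$draws)
  }
})

test_that("zero-variance configurations collapse to the point estimate", {
  cfg <- mcs_config("traditional",
                    conc = lognormal_params(log(10), 0),
                    bw = lognormal_params(log(64), 0),
                    ir = lognormal_params(log(16), 0),
                    iterations = 50, seed = 3)
  res <- run_mcs(cfg)
  expect_equal(unique(res$draws$ilcr), compute_ilcr(10, 16, 64))
  expect_equal(res$summary$sd, 0)
})

test_that("the traditional variant matches the lognormal-product oracle", {
  cfg <- whole_pop_config(iterations = 30000, seed = 17)
  res <- run_mcs(cfg)
  oracle <- lognormal_product_moments(cfg$conc, cfg$ir, cfg$bw, cfg$constants)
  n <- cfg$iterations
  # arithmetic mean within 3 MC standard errors
  expect_lt(abs(res$summary$mean - oracle$mean), 3 * oracle$sd / sqrt(n))
  # the risk is itself lognormal: log-moments match the analytic sums
  lm_ <- mean(log(res$draws$ilcr)); ls_ <- sd(log(res$draws$ilcr))
  expect_lt(abs(lm_ - oracle$meanlog), 3 * oracle$sdlog / sqrt(n))
  expect_lt(abs(ls_ - oracle$sdlog), 3 * oracle$sdlog / sqrt(2 * n))
})

test_that("the correlated variant substitutes IR deterministically", {
  p <- default_exposure_params()
  cfg <- mcs_config("correlated", conc = p$site_conc, bw = p$bw$whole,
                    power_law = p$power_law, iterations = 5000, seed = 2)
  res <- run_mcs(cfg)
  expect_identical(res$draws$ir, predict_ir(p$power_law, res$draws$bw))
  # effective BW exponent in the risk is slope - 1: fix C, regress logs
  cfg0 <- mcs_config("correlated", conc = lognormal_params(2.21, 0),
                     bw = p$bw$whole, power_law = p$power_law,
                     iterations = 3000, seed = 2)
  res0 <- run_mcs(cfg0)
  eff <- unname(coef(lm(log(res0$draws$ilcr) ~ log(res0$draws$bw)))[2])
  expect_equal(eff, p$power_law$slope - 1, tolerance = 1e-10)
})

test_that("age stratification with identical strata reduces to traditional", {
  p <- default_exposure_params()
  same <- list(
    a = list(weight = 1 / 6, bw = p$bw$whole, ir = p$ir$whole),
    b = list(weight = 2 / 6, bw = p$bw$whole, ir = p$ir$whole),
    c = list(weight = 3 / 6, bw = p$bw$whole, ir = p$ir$whole))
  ks_ps <- vapply(1:6, function(s) {
    strat <- run_mcs(mcs_config("age_stratified", conc = p$site_conc,
                                strata = same, iterations = 6000, seed = s))
    trad <- run_mcs(whole_pop_config(iterations = 6000, seed = s + 100))
    suppressWarnings(
      ks.test(strat$draws$ilcr, trad$draws$ilcr)$p.value)
  }, numeric(1))
  # p-values behave like a uniform null: distributional equivalence
  expect_gte(sum(ks_ps > 0.01), 5)
  expect_true(all(ks_ps > 1e-4))
})

test_that("stratified allocation follows the census-proportional weights", {
  p <- default_exposure_params()
  res <- run_mcs(mcs_config("age_stratified", conc = p$site_conc,
                            strata = p$strata, iterations = 30000, seed = 4))
  counts <- table(res$draws$stratum)
  expect_equal(as.integer(counts[c("s18_44", "s45_59", "s60_70")]),
               c(19379L, 8172L, 2449L))
})

test_that("Spearman sensitivity identifies monotone drivers and signs", {
  p <- default_exposure_params()
  # constant concentration: correlation undefined for it, -1 for BW, and IR
  # (a monotone function of BW under the deterministic power law) ties BW
  cfg0 <- mcs_config("correlated", conc = lognormal_params(2.21, 0),
                     bw = p$bw$whole, power_law = p$power_law,
                     iterations = 2000, seed = 6)
  s0 <- sensitivity_spearman(run_mcs(cfg0))
  expect_true(is.na(s0$rho[s0$input == "conc"]))
  expect_equal(s0$rho[s0$input == "bw"], -1)
  expect_equal(s0$rho[s0$input == "ir"], -1)
  # independent-input variants: conc dominant, BW negative, IR positive
  for (variant in c("traditional", "concentration_adjusted")) {
    s <- sensitivity_spearman(run_mcs(whole_pop_config(variant,
                                                       iterations = 10000,
                                                       seed = 7)))
    expect_equal(s$input[s$rank == 1], "conc")
    expect_lt(s$rho[s$input == "bw"], 0)
    expect_gt(s$rho[s$input == "ir"], 0)
  }
  strat <- run_mcs(mcs_config("age_stratified",
                              conc = p$site_conc, strata = p$strata,
                              iterations = 10000, seed = 7))
  s <- sensitivity_spearman(strat)
  expect_equal(s$input[s$rank == 1], "conc")
  expect_lt(s$rho[s$input == "bw"], 0)
  expect_gt(s$rho[s$input == "ir"], 0)
})

test_that("sensitivity matches the bivariate-normal closed form", {
  cfg <- whole_pop_config(iterations = 30000, seed = 19)
  s <- sensitivity_spearman(run_mcs(cfg))
  sds <- c(cfg$conc$sdlog, cfg$bw$sdlog, cfg$ir$sdlog)
  for (input in c("conc", "bw", "ir")) {
    rho <- input_log_correlation(
      switch(input, conc = sds[1], bw = sds[2], ir = sds[3]),
      sds, sign = if (input == "bw") -1 else 1)
    expect_lt(abs(s$rho[s$input == input] - spearman_from_pearson(rho)),
              0.02)
  }
})

test_that("convergence checking flags stable means and respects tolerance", {
  p <- default_exposure_params()
  flat <- mcs_config("traditional",
                     conc = lognormal_params(2, 0),
                     bw = lognormal_params(4, 0),
                     ir = lognormal_params(2.7, 0), seed = 1)
  tab <- convergence_check(flat, grid = c(100, 200, 300))
  expect_true(attr(tab, "converged"))
  expect_true(all(tab$rel_change[-1] == 0))
  noisy <- whole_pop_config(seed = 23)
  expect_false(attr(convergence_check(noisy, grid = c(500, 1000, 1500),
                                      tol = 0), "converged"))
  expect_error(convergence_check(noisy, grid = 5000), "two points")
})

test_that("the mean's fluctuation shrinks like n^(-1/2) across seeds", {
  means_at <- function(n) {
    vapply(1:30, function(s) {
      run_mcs(whole_pop_config(iterations = n, seed = 1000 + s))$summary$mean
    }, numeric(1))
  }
  sd_small <- sd(means_at(1000))
  sd_large <- sd(means_at(9000))
  ratio <- sd_small / sd_large   # CLT predicts 3
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 6)
})

test_that("variant/parameter mismatches are rejected at config time", {
  p <- default_exposure_params()
  expect_error(mcs_config("traditional", conc = p$site_conc, bw = p$bw$whole),
               "requires")
  expect_error(mcs_config("correlated", conc = p$site_conc, bw = p$bw$whole),
               "power_law")
  bad <- p$strata
  bad$s18_44$weight <- bad$s18_44$weight + 0.1
  expect_error(mcs_config("age_stratified", conc = p$site_conc, strata = bad),
               "sum to 1")
})
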