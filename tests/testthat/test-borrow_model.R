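short_mcmc <- function(seed = 1, chains = 4, iter = 2000, burn = 500) {
  mcmc_config(n_chains = chains, n_iter = iter, n_burnin = burn, seed = seed)
}

test_that("conjugate test mode matches the closed-form Normal posterior", {
  set.seed(11)
  ctrl <- rnorm(10, 41, 5)
  trt <- rnorm(10, 30, 5)
  d <- make_two_group(ctrl, trt)
  fit <- fit_concurrent(d, "E1", mcmc = short_mcmc(seed = 4, iter = 6000, burn = 1000),
                        fixed_sigma = 5)
  bd <- beta_draws(fit, "drugA")
  # flat priors, known sigma: beta | data ~ N(mean(trt) - mean(ctrl), sigma^2 * 2/10)
  post_mean <- mean(trt) - mean(ctrl)
  post_sd <- 5 * sqrt(2 / 10)
  mcse_mean <- post_sd / sqrt(length(bd))
  expect_lt(abs(mean(bd) - post_mean), 3 * mcse_mean)
  mcse_sd <- post_sd / sqrt(2 * (length(bd) - 1))
  expect_lt(abs(sd(bd) - post_sd), 3 * mcse_sd)
})

test_that("the noiseless limit pins the treatment effect", {
  cfg <- sim_config(n_experiments = 4, beta_by_treatment = c(drugA = -20),
                    mu = 41.46, tau = 0, sigma = 1e-6, seed = 31)
  d <- simulate_trial(cfg)
  fit <- suppressWarnings(fit_pooled(d, mcmc = short_mcmc(seed = 5)))
  expect_lt(abs(median(beta_draws(fit, "drugA")) - (-20)), 0.5)
})

test_that("pooled fit recovers generating parameters with correct structure", {
  cfg <- sim_config(n_experiments = 10, treatments_per_experiment = 1,
                    control_group_size_range = c(10, 10),
                    treatment_group_size_range = c(10, 10),
                    beta_by_treatment = c(drugA = -15, drugB = 0),
                    mu = 41, tau = 5, sigma = 12, seed = 77)
  d <- simulate_trial(cfg)
  fit <- suppressWarnings(fit_pooled(d, mcmc = short_mcmc(seed = 6, iter = 3000, burn = 1000)))
  expect_equal(nrow(fit$draws), 4 * (3000 - 1000))
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(fit$draws[, "tau"] >= 0))
  sA <- posterior_summary(beta_draws(fit, "drugA"))
  expect_lt(sA$cri[["lower"]], -15 + 10)
  expect_gt(sA$cri[["upper"]], -15 - 10)
  # reproducibility: identical seed gives identical draws
  fit2 <- suppressWarnings(fit_pooled(d, mcmc = short_mcmc(seed = 6, iter = 3000, burn = 1000)))
  expect_identical(fit$draws, fit2$draws)
})

test_that("location-shift equivariance: +c moves mu, leaves beta alone", {
  cfg <- sim_config(n_experiments = 6, beta_by_treatment = c(drugA = -10),
                    mu = 45, tau = 4, sigma = 10, seed = 13)
  d <- simulate_trial(cfg)
  shifted <- as.data.frame(d)
  shifted$area_loss_pct <- shifted$area_loss_pct + 5
  d5 <- trial_dataset(shifted)
  f0 <- suppressWarnings(fit_pooled(d, mcmc = short_mcmc(seed = 21, iter = 4000, burn = 1000)))
  f5 <- suppressWarnings(fit_pooled(d5, mcmc = short_mcmc(seed = 22, iter = 4000, burn = 1000)))
  expect_equal(mean(f5$draws[, "mu"]) - mean(f0$draws[, "mu"]), 5, tolerance = 0.35)
  expect_equal(mean(beta_draws(f5, "drugA")), mean(beta_draws(f0, "drugA")),
               tolerance = 0.35)
})

test_that("with tau fixed at 0 posterior means agree with least squares", {
  cfg <- sim_config(n_experiments = 5, beta_by_treatment = c(drugA = -12),
                    mu = 42, tau = 3, sigma = 9, seed = 29)
  d <- simulate_trial(cfg)
  fit <- suppressWarnings(fit_pooled(d, mcmc = short_mcmc(seed = 9, iter = 4000, burn = 1000),
                                     fixed_tau = 0))
  ols <- lm(area_loss_pct ~ treatment, data = as.data.frame(d))
  expect_equal(mean(fit$draws[, "mu"]), unname(coef(ols)[1]), tolerance = 0.25)
  expect_equal(mean(beta_draws(fit, "drugA")),
               unname(coef(ols)["treatmentdrugA"]), tolerance = 0.35)
})

test_that("concurrent fit is exchangeable-safe and restriction-invariant", {
  set.seed(47)
  ctrl <- rnorm(12, 40, 8)
  d1 <- make_two_group(ctrl, ctrl)        # treated arm copies control
  fit <- fit_concurrent(d1, "E1", mcmc = short_mcmc(seed = 14, iter = 4000, burn = 1000))
  bd <- beta_draws(fit, "drugA")
  expect_lt(abs(median(bd)), 1)
  expect_lt(abs(prob_efficacy(bd) - 0.5), 0.05)

  # invariance to other experiments in the file
  extra <- make_experiment("E9", list(control = rnorm(8, 60, 5),
                                      drugZ = rnorm(8, 20, 5)))
  d2 <- trial_dataset(rbind(as.data.frame(d1), extra))
  fit2 <- fit_concurrent(d2, "E1", mcmc = short_mcmc(seed = 14, iter = 4000, burn = 1000))
  expect_identical(fit$draws, fit2$draws)

  expect_error(fit_concurrent(d1, "nope"), "unknown experiment")
  only_ctrl <- make_dataset(make_experiment("E3", list(control = rnorm(6, 40, 5))))
  expect_error(fit_concurrent(only_ctrl, "E3"), "no treated arm")
})

test_that("convergence diagnostics detect healthy and broken chains", {
  # well-mixed: iid draws in every chain
  make_fake_fit <- function(draws_matrix, n_chains) {
    structure(list(draws = draws_matrix,
                   chain = rep(seq_len(n_chains), each = nrow(draws_matrix) / n_chains),
                   treatments = character(0), experiments = character(0),
                   mcmc = mcmc_config(n_chains = n_chains,
                                      n_iter = nrow(draws_matrix) / n_chains + 1,
                                      n_burnin = 1, seed = 1)),
              class = "posterior_draws")
  }
  set.seed(97)
  iid <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "x"))
  dg <- convergence_diagnostics(make_fake_fit(iid, 4))
  expect_lt(abs(dg$rhat - 1), 0.01)
  expect_gt(dg$ess, 0.5 * 4000)

  # two chains 10 SDs apart: flagged
  apart <- matrix(c(rnorm(1000), rnorm(1000, 10)), ncol = 1,
                  dimnames = list(NULL, "x"))
  dg2 <- convergence_diagnostics(make_fake_fit(apart, 2))
  expect_gt(dg2$rhat, 1.1)
  expect_true(dg2$flag)

  # AR(1) with rho = 0.9: ESS well below 20% of draws, and in the same
  # ballpark as coda's spectral estimate (rank-normalisation and estimator
  # differences allow a wide band)
  ar <- matrix(as.numeric(arima.sim(list(ar = 0.9), 4000)), ncol = 1,
               dimnames = list(NULL, "x"))
  dg3 <- convergence_diagnostics(make_fake_fit(ar, 4))
  expect_lt(dg3$ess, 0.2 * 4000)
  ess_coda <- unname(coda::effectiveSize(coda::mcmc(as.vector(ar))))
  expect_gt(dg3$ess, ess_coda / 3)
  expect_lt(dg3$ess, ess_coda * 3)
})

test_that("half-Cauchy scale prior yields a working sampler", {
  cfg <- sim_config(n_experiments = 6, beta_by_treatment = c(drugA = -10),
                    mu = 41, tau = 5, sigma = 12, seed = 55)
  d <- simulate_trial(cfg)
  fit <- suppressWarnings(
    fit_pooled(d, prior = prior_config("half_cauchy", half_cauchy_scale = 10),
               mcmc = short_mcmc(seed = 33, iter = 3000, burn = 1000)))
  expect_true(all(is.finite(fit$draws)))
  s <- posterior_summary(beta_draws(fit, "drugA"))
  expect_lt(s$cri[["lower"]], 0)
  expect_gt(s$cri[["upper"]], -25)
})
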