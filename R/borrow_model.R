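# Bayesian linear mixed model with pooled-control borrowing.
#
# y_ij | alpha_i = mu + alpha_i + sum_k beta_k 1{Trt = k} + eps_ij,
# alpha_i ~ N(0, tau^2), eps_ij ~ N(0, sigma^2).
#
# Flat priors on mu and every beta_k; the scale prior on sigma and tau is
# flat-on-SD by default (proper posterior with several experiments) or
# half-Cauchy. Fit by blocked Gibbs: (mu, beta) jointly from the Normal full
# conditional, each alpha_i from its Normal full conditional, sigma^2 and
# tau^2 from inverse-gamma full conditionals (flat-on-SD) or by an
# independence Metropolis-Hastings step using that conditional as proposal
# (half-Cauchy).

#' Prior configuration
#'
#' @param scale_prior prior on the standard deviations sigma and tau:
#'   `"flat_on_sd"` (default; improper flat density on the SD scale) or
#'   `"half_cauchy"`.
#' @param half_cauchy_scale scale of the half-Cauchy prior, percent.
#' @return a `prior_config` list.
#' @export
prior_config <- function(scale_prior = c("flat_on_sd", "half_cauchy"),
                         half_cauchy_scale = 10) {
  scale_prior <- match.arg(scale_prior)
  if (half_cauchy_scale <= 0) stopf("half_cauchy_scale must be > 0")
  structure(list(location_prior = "flat",
                 scale_prior = scale_prior,
                 half_cauchy_scale = half_cauchy_scale),
            class = "prior_config")
}

#' MCMC configuration
#'
#' Defaults follow the trial's reporting protocol: four independent chains of
#' 10,000 iterations each with the first 5,000 discarded as burn-in, giving
#' 20,000 retained draws; no thinning.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain (< `n_iter`).
#' @param seed master seed; each chain runs on its own substream.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 10000L, n_burnin = 5000L,
                        seed = 1L) {
  cfg <- list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
              n_burnin = as.integer(n_burnin), seed = as.integer(seed))
  if (cfg$n_chains < 1L) stopf("n_chains must be >= 1")
  if (cfg$n_burnin < 0L || cfg$n_burnin >= cfg$n_iter) {
    stopf("n_burnin must satisfy 0 <= n_burnin < n_iter")
  }
  structure(cfg, class = "mcmc_config")
}

#' Fit the pooled-control borrowing model
#'
#' Fits the mixed model by blocked Gibbs sampling on all retained animals:
#' every control across every experiment informs the grand control mean `mu`
#' and the between-experiment SD `tau`, so each treatment is compared against
#' the pooled (non-concurrent) controls while experiment-to-experiment
#' baseline shifts are absorbed by the random effects. Treatments sharing a
#' label across experiments share one effect.
#'
#' @param dataset a [trial_dataset()]; needs >= 2 experiments.
#' @param prior a [prior_config()].
#' @param mcmc an [mcmc_config()].
#' @param fixed_sigma optional known residual SD; when given, sigma is held
#'   fixed instead of sampled (conjugate test mode: with flat location priors
#'   the draws of (mu, beta) then come from their exact Normal posterior).
#' @param fixed_tau optional known between-experiment SD, held fixed instead
#'   of sampled; `fixed_tau = 0` removes the random effect entirely, making
#'   the location posterior the flat-prior (OLS-centred) Normal.
#' @return a `posterior_draws` object: matrix of retained draws (columns
#'   `mu`, `beta.<treatment>`, `alpha.<experiment>`, `sigma`, `tau`), a chain
#'   index per draw, and convergence diagnostics (split R-hat, rank-normalized
#'   bulk ESS). A warning is raised if any R-hat exceeds 1.01.
#' @export
fit_pooled <- function(dataset, prior = prior_config(), mcmc = mcmc_config(),
                       fixed_sigma = NULL, fixed_tau = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  exps <- sort(unique(dataset$experiment_id))
  if (length(exps) < 2L) {
    stopf("fit_pooled needs >= 2 experiments; use fit_concurrent for a single experiment")
  }
  fit_lmm_gibbs(dataset, prior, mcmc, fixed_sigma, random_effect = TRUE,
                fixed_tau = fixed_tau)
}

#' Fit the concurrent-control model for one experiment
#'
#' Restricts the data to a single experiment and fits the same machinery
#' without the experiment random effect (unidentifiable with one experiment):
#' `y_j = mu + beta_trt + eps_j`. This is the per-experiment comparison of
#' each drug arm against its matched saline control.
#'
#' @param dataset a [trial_dataset()].
#' @param experiment_id the experiment to analyse; must contain a control arm
#'   and at least one treated arm.
#' @param prior,mcmc,fixed_sigma as in [fit_pooled()].
#' @return a `posterior_draws` object with columns `mu`, `beta.<treatment>`,
#'   `sigma`.
#' @export
fit_concurrent <- function(dataset, experiment_id, prior = prior_config(),
                           mcmc = mcmc_config(), fixed_sigma = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  sub <- dataset[dataset$experiment_id == experiment_id, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("unknown experiment '%s'", experiment_id)
  if (!any(sub$treatment == "control")) {
    stopf("experiment '%s' has no control arm", experiment_id)
  }
  if (length(unique(sub$treatment)) < 2L) {
    stopf("experiment '%s' has no treated arm", experiment_id)
  }
  sub <- trial_dataset(sub, provenance = sprintf("concurrent subset: %s", experiment_id))
  fit_lmm_gibbs(sub, prior, mcmc, fixed_sigma, random_effect = FALSE)
}

# Shared Gibbs engine. random_effect = FALSE drops alpha and tau.
fit_lmm_gibbs <- function(dataset, prior, mcmc, fixed_sigma, random_effect,
                          fixed_tau = NULL) {
  stopifnot(inherits(prior, "prior_config"), inherits(mcmc, "mcmc_config"))
  y <- dataset$area_loss_pct
  n <- length(y)
  treatments <- sort(setdiff(unique(dataset$treatment), "control"))
  if (length(treatments) == 0L) stopf("no treated arms in dataset")
  exps <- sort(unique(dataset$experiment_id))
  I <- length(exps)
  eidx <- match(dataset$experiment_id, exps)

  # Design for the location block: intercept + one column per treatment
  # (reference coding, beta_control = 0).
  X <- cbind(1, vapply(treatments,
                       function(k) as.numeric(dataset$treatment == k),
                       numeric(n)))
  colnames(X) <- c("mu", paste0("beta.", treatments))
  p <- ncol(X)
  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  A <- chol(XtX_inv)          # theta = theta_hat + sigma * t(A) %*% z
  XtX_inv_Xt <- XtX_inv %*% t(X)

  n_keep <- mcmc$n_iter - mcmc$n_burnin
  n_per_exp <- tabulate(eidx, nbins = I)

  # Moment-based starting values; chains are overdispersed around them.
  ctrl_mean <- mean(y[dataset$treatment == "control"])
  beta0 <- vapply(treatments, function(k) mean(y[dataset$treatment == k]) - ctrl_mean,
                  numeric(1))
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  sigma0 <- fixed_sigma %||% max(sd_y, 1e-3)
  exp_ctrl_means <- tapply(y[dataset$treatment == "control"],
                           dataset$experiment_id[dataset$treatment == "control"], mean)
  tau0 <- if (random_effect && length(exp_ctrl_means) > 1L) {
    max(stats::sd(exp_ctrl_means), 1e-3)
  } else {
    0
  }

  run_chain <- function(chain) {
    with_substream(mcmc$seed, chain, {
      theta <- c(ctrl_mean, beta0) + stats::rnorm(p, 0, 0.5 * sd_y)
      alpha <- if (random_effect && is.null(fixed_tau)) {
        stats::rnorm(I, 0, max(tau0, 0.5))
      } else {
        rep(0, I)
      }
      sigma2 <- (sigma0 * stats::runif(1, 0.5, 2))^2
      if (!is.null(fixed_sigma)) sigma2 <- fixed_sigma^2
      tau2 <- if (!random_effect) 0
      else if (!is.null(fixed_tau)) fixed_tau^2
      else (tau0 * stats::runif(1, 0.5, 2))^2 + 1e-6
      out <- matrix(NA_real_, n_keep, p + I + 2L)
      for (it in seq_len(mcmc$n_iter)) {
        # (mu, beta) | alpha, sigma2 : Normal around the GLS/OLS solution
        z <- y - alpha[eidx]
        theta_hat <- drop(XtX_inv_Xt %*% z)
        theta <- theta_hat + sqrt(sigma2) * drop(crossprod(A, stats::rnorm(p)))
        resid <- y - drop(X %*% theta)
        if (random_effect && tau2 > 0) {
          # alpha_i | rest : Normal(precision-weighted mean)
          prec <- n_per_exp / sigma2 + 1 / tau2
          m <- (rowsum(resid, eidx) / sigma2) / prec
          alpha <- drop(m) + stats::rnorm(I, 0, sqrt(1 / prec))
          if (is.null(fixed_tau)) {
            tau2 <- draw_variance(sum(alpha^2), I, prior, sqrt(tau2),
                                  min_shape_obs = 1L)
          }
        }
        eps <- resid - alpha[eidx]
        if (is.null(fixed_sigma)) {
          sigma2 <- draw_variance(sum(eps^2), n, prior, sqrt(sigma2),
                                  min_shape_obs = 1L)
        }
        if (it > mcmc$n_burnin) {
          out[it - mcmc$n_burnin, ] <- c(theta, alpha, sqrt(sigma2), sqrt(tau2))
        }
      }
      out
    })
  }

  chains <- lapply(seq_len(mcmc$n_chains), run_chain)
  draws <- do.call(rbind, chains)
  colnames(draws) <- c(colnames(X),
                       paste0("alpha.", exps),
                       "sigma", "tau")
  if (!random_effect) {
    draws <- draws[, !(colnames(draws) %in% c(paste0("alpha.", exps), "tau")),
                   drop = FALSE]
  }
  fit <- structure(list(
    draws = draws,
    chain = rep(seq_len(mcmc$n_chains), each = n_keep),
    treatments = treatments,
    experiments = if (random_effect) exps else character(0),
    random_effect = random_effect,
    prior = prior, mcmc = mcmc,
    fixed_sigma = fixed_sigma,
    n_obs = n), class = "posterior_draws")
  fit$diagnostics <- convergence_diagnostics(fit)
  bad <- fit$diagnostics$parameter[fit$diagnostics$flag]
  if (length(bad) > 0L && mcmc$n_chains >= 2L) {
    warnf("convergence flags (R-hat > 1.01 or ESS < 400) for: %s",
          paste(bad, collapse = ", "))
  }
  fit
}

# Draw a variance from its full conditional given the sum of squares `ss`
# over `m` effects. Flat-on-SD prior p(s) ~ 1 gives
# v ~ InvGamma((m - 1)/2, ss/2). Half-Cauchy uses that inverse-gamma as an
# independence MH proposal with acceptance ratio = prior ratio on the SD
# scale (the flat reference cancels).
draw_variance <- function(ss, m, prior, current_sd, min_shape_obs = 1L) {
  shape <- (m - 1) / 2
  if (shape <= 0) shape <- min_shape_obs / 2
  cand <- 1 / stats::rgamma(1, shape = shape, rate = ss / 2 + 1e-12)
  if (prior$scale_prior == "flat_on_sd") return(cand)
  s_new <- sqrt(cand)
  ratio <- stats::dcauchy(s_new, 0, prior$half_cauchy_scale) /
    stats::dcauchy(current_sd, 0, prior$half_cauchy_scale)
  if (stats::runif(1) < ratio) cand else current_sd^2
}

#' Extract draws of one treatment effect
#'
#' @param fit a `posterior_draws` object.
#' @param treatment treatment label.
#' @return numeric vector of retained draws of beta for that treatment.
#' @export
beta_draws <- function(fit, treatment) {
  stopifnot(inherits(fit, "posterior_draws"))
  col <- paste0("beta.", treatment)
  if (!col %in% colnames(fit$draws)) stopf("no such treatment in fit: '%s'", treatment)
  fit$draws[, col]
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d retained draws (%d chains), %d parameters\n",
              nrow(x$draws), x$mcmc$n_chains, ncol(x$draws)))
  cat(sprintf("  model: %s; prior on scales: %s\n",
              if (x$random_effect) "pooled (experiment random effect)" else "concurrent (single experiment)",
              x$prior$scale_prior))
  q <- t(apply(x$draws[, c("mu", paste0("beta.", x$treatments)), drop = FALSE], 2,
               stats::quantile, c(.025, .5, .975)))
  print(round(q, 2))
  invisible(x)
}

#' Convergence diagnostics for posterior draws
#'
#' Split R-hat and rank-normalized bulk effective sample size per parameter.
#' Each chain is split in half before the between/within variance comparison;
#' ESS uses rank-normalized draws and Geyer's initial-positive-sequence
#' truncation of the autocorrelation sum. Parameters with R-hat above 1.01 or
#' ESS below 400 are flagged.
#'
#' @param fit a `posterior_draws` object.
#' @return data frame with columns `parameter`, `rhat`, `ess`, `flag`.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  params <- colnames(fit$draws)
  n_chains <- fit$mcmc$n_chains
  if (n_chains < 2L) {
    warnf("single chain: R-hat unavailable, reporting ESS only")
  }
  res <- lapply(params, function(pp) {
    m <- matrix(fit$draws[, pp], ncol = n_chains)  # iterations x chains
    rhat <- if (n_chains >= 2L) split_rhat(m) else NA_real_
    ess <- rank_normalized_ess(m)
    data.frame(parameter = pp, rhat = rhat, ess = ess,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flag <- (!is.na(out$rhat) & out$rhat > 1.01) | out$ess < 400
  out
}

# Split R-hat on an iterations x chains matrix.
split_rhat <- function(m) {
  nn <- nrow(m) %/% 2L
  halves <- cbind(m[seq_len(nn), , drop = FALSE],
                  m[nn + seq_len(nn), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  B <- nn * stats::var(colMeans(halves))
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Rank-normalized bulk ESS with Geyer initial-positive-sequence truncation.
rank_normalized_ess <- function(m) {
  S <- length(m)
  z <- stats::qnorm((rank(m) - 3 / 8) / (S + 1 / 4))
  zm <- matrix(z, nrow = nrow(m))
  n_chains <- ncol(zm)
  nn <- nrow(zm)
  if (stats::var(z) == 0) return(S)
  chain_vars <- apply(zm, 2, stats::var)
  W <- mean(chain_vars)
  var_plus <- (nn - 1) / nn * W +
    (if (n_chains > 1L) stats::var(colMeans(zm)) else 0)
  max_lag <- min(nn - 1L, 1000L)
  acov <- sapply(seq_len(n_chains), function(cc) {
    a <- stats::acf(zm[, cc], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive
  tsum <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    tsum <- tsum + pair
    t <- t + 2L
  }
  ess <- S / (1 + 2 * tsum)
  min(ess, S)
}
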