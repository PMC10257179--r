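# Posterior decision summaries and per-experiment nonparametric comparisons.

#' Posterior probability of efficacy
#'
#' The Monte-Carlo probability that a treatment reduces the outcome: the
#' strict fraction of posterior draws of the treatment effect that fall below
#' zero. Draws exactly at zero count as non-efficacious.
#'
#' @param draws numeric vector of posterior draws of a treatment effect.
#' @return a probability in [0, 1] with resolution 1/length(draws).
#' @export
prob_efficacy <- function(draws) {
  if (length(draws) < 1L || anyNA(draws)) {
    stopf("prob_efficacy: need at least one non-missing draw")
  }
  mean(draws < 0)
}

#' Posterior median and 95% credible interval
#'
#' Sample 2.5th, 50th and 97.5th percentiles of the draws, using linear
#' interpolation between order statistics (the convention is recorded in the
#' result).
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param level credible level (default 0.95).
#' @return list with `median`, `cri` (lower, upper) and
#'   `percentile_convention`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  if (length(draws) < 2L || anyNA(draws)) {
    stopf("posterior_summary: need at least two non-missing draws")
  }
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  list(median = q[2], cri = c(lower = q[1], upper = q[3]),
       percentile_convention = "linear interpolation between order statistics (type 7)")
}

#' Two-sided rank-sum comparison of two groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test with midranks. For combined sample
#' sizes up to `exact_max_n` the null distribution is enumerated exactly over
#' all assignments of the pooled (possibly tied) values to the two groups;
#' the two-sided p-value is the fraction of assignments whose rank sum
#' deviates from its expectation at least as much as the observed one.
#' Larger samples use the Normal approximation with tie and continuity
#' correction. When every pooled value is identical the comparison is
#' degenerate and p = 1 is returned with a flag. A Welch t-test is available
#' as a sensitivity alternative.
#'
#' @param control,treated numeric vectors (each >= 2 values).
#' @param exact_max_n largest combined n for exact enumeration.
#' @param method `"rank_sum"` (default) or `"welch"`.
#' @return list with `p_value`, `method`, `degenerate`.
#' @export
rank_sum_comparison <- function(control, treated, exact_max_n = 20L,
                                method = c("rank_sum", "welch")) {
  method <- match.arg(method)
  if (length(control) < 2L || length(treated) < 2L) {
    stopf("rank_sum_comparison: both groups need >= 2 values")
  }
  if (method == "welch") {
    p <- stats::t.test(control, treated)$p.value
    return(list(p_value = p, method = "welch", degenerate = FALSE))
  }
  pooled <- c(control, treated)
  if (length(unique(pooled)) == 1L) {
    return(list(p_value = 1, method = "rank_sum_degenerate", degenerate = TRUE))
  }
  n1 <- length(control)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  if (n <= exact_max_n) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    tol <- 1e-9
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - tol)
    return(list(p_value = p, method = "rank_sum_exact", degenerate = FALSE))
  }
  p <- stats::wilcox.test(control, treated, exact = FALSE, correct = TRUE)$p.value
  list(p_value = p, method = "rank_sum_normal_approx", degenerate = FALSE)
}

#' Per-experiment group comparisons (medians, ranges, rank-sum p)
#'
#' For every treated arm, reports the matched control and treatment medians
#' with their ranges and a two-sided rank-sum p-value against the concurrent
#' control — the per-experiment summary table of the trial.
#'
#' @param dataset a [trial_dataset()].
#' @param ... passed to [rank_sum_comparison()].
#' @return data frame with one row per (experiment, treatment).
#' @export
group_comparisons <- function(dataset, ...) {
  stopifnot(inherits(dataset, "trial_dataset"))
  rows <- list()
  for (e in sort(unique(dataset$experiment_id))) {
    sub <- dataset[dataset$experiment_id == e, , drop = FALSE]
    ctrl <- sub$area_loss_pct[sub$treatment == "control"]
    for (k in sort(setdiff(unique(sub$treatment), "control"))) {
      trt <- sub$area_loss_pct[sub$treatment == k]
      cmp <- rank_sum_comparison(ctrl, trt, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = e, treatment = k,
        control_median = stats::median(ctrl),
        control_min = min(ctrl), control_max = max(ctrl),
        control_n = length(ctrl),
        treatment_median = stats::median(trt),
        treatment_min = min(trt), treatment_max = max(trt),
        treatment_n = length(trt),
        p_value = cmp$p_value,
        method = cmp$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Efficacy summary for one treatment
#'
#' @param draws numeric vector of posterior draws of the treatment effect.
#' @param treatment treatment label.
#' @param analysis `"pooled"` or `"concurrent"`.
#' @return one-row data frame: effect estimate (posterior median), 95% CrI,
#'   Pr(efficacy), and a significance flag (CrI excludes 0).
#' @export
efficacy_summary <- function(draws, treatment, analysis = c("pooled", "concurrent")) {
  analysis <- match.arg(analysis)
  s <- posterior_summary(draws)
  data.frame(treatment = treatment,
             analysis = analysis,
             effect_estimate = s$median,
             cri_lower = s$cri[["lower"]],
             cri_upper = s$cri[["upper"]],
             pr_efficacy = prob_efficacy(draws),
             significant = s$cri[["lower"]] > 0 | s$cri[["upper"]] < 0,
             stringsAsFactors = FALSE)
}

#' Ranked efficacy report
#'
#' Combines the pooled fit and the per-experiment concurrent fits into one
#' table, one row per treatment, with the concurrent and pooled effect
#' estimate, 95% credible interval and probability of efficacy side by side,
#' sorted by pooled Pr(efficacy) descending. Treatments without a concurrent
#' fit appear with NA concurrent columns.
#'
#' @param pooled_fit a `posterior_draws` from [fit_pooled()].
#' @param concurrent_fits named list of `posterior_draws` from
#'   [fit_concurrent()], keyed by experiment id (optional).
#' @return data frame of class `efficacy_report`.
#' @export
build_report <- function(pooled_fit, concurrent_fits = list()) {
  stopifnot(inherits(pooled_fit, "posterior_draws"))
  pooled_rows <- do.call(rbind, lapply(pooled_fit$treatments, function(k) {
    efficacy_summary(beta_draws(pooled_fit, k), k, "pooled")
  }))
  conc_rows <- list()
  for (fit in concurrent_fits) {
    for (k in fit$treatments) {
      conc_rows[[k]] <- efficacy_summary(beta_draws(fit, k), k, "concurrent")
    }
  }
  out <- data.frame(treatment = pooled_rows$treatment, stringsAsFactors = FALSE)
  pick <- function(rows, k, col) {
    if (is.null(rows[[k]])) NA_real_ else rows[[k]][[col]]
  }
  out$concurrent_effect <- vapply(out$treatment, pick, numeric(1), rows = conc_rows, col = "effect_estimate")
  out$concurrent_cri_lower <- vapply(out$treatment, pick, numeric(1), rows = conc_rows, col = "cri_lower")
  out$concurrent_cri_upper <- vapply(out$treatment, pick, numeric(1), rows = conc_rows, col = "cri_upper")
  out$concurrent_pr_efficacy <- vapply(out$treatment, pick, numeric(1), rows = conc_rows, col = "pr_efficacy")
  out$pooled_effect <- pooled_rows$effect_estimate
  out$pooled_cri_lower <- pooled_rows$cri_lower
  out$pooled_cri_upper <- pooled_rows$cri_upper
  out$pooled_pr_efficacy <- pooled_rows$pr_efficacy
  out$significant_pooled <- pooled_rows$significant
  out <- out[order(-out$pooled_pr_efficacy, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("efficacy_report", "data.frame")
  out
}

#' @export
print.efficacy_report <- function(x, digits = 2, ...) {
  cat(sprintf("efficacy_report: %d treatments, sorted by pooled Pr(efficacy)\n", nrow(x)))
  show <- data.frame(
    treatment = x$treatment,
    `effect (pooled)` = sprintf("%.1f (%.1f; %.1f)%s", x$pooled_effect,
                                x$pooled_cri_lower, x$pooled_cri_upper,
                                ifelse(x$significant_pooled, " *", "")),
    `Pr(eff) %` = sprintf("%.2f", 100 * x$pooled_pr_efficacy),
    `effect (concurrent)` = ifelse(is.na(x$concurrent_effect), "-",
                                   sprintf("%.1f (%.1f; %.1f)", x$concurrent_effect,
                                           x$concurrent_cri_lower, x$concurrent_cri_upper)),
    `Pr(eff concurrent) %` = ifelse(is.na(x$concurrent_pr_efficacy), "-",
                                    sprintf("%.2f", 100 * x$concurrent_pr_efficacy)),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(show, right = FALSE)
  invisible(x)
}
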