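# Iterative rank-based exclusion of outlier litters among control animals.
#
# The procedure loops: (1) Kruskal-Wallis gate across litters; (2) pick the
# most deviant litter by average rank; (3) a contrast statistic T for that
# litter against the rest, calibrated by permutation; (4) exclude and repeat.

#' Per-litter rank summary
#'
#' Pools all control values, assigns midranks, and returns per-litter sizes
#' and average ranks. The building block of the deviant-litter statistic.
#'
#' @param values_by_litter named list: litter label -> numeric vector of
#'   outcomes.
#' @return a `rank_summary` list with `labels`, `n_i`, `rbar` (average
#'   midrank per litter) and `n` (total animals).
#' @export
rank_summary <- function(values_by_litter) {
  check_litter_values(values_by_litter, min_litters = 1L)
  labels <- names(values_by_litter)
  sizes <- lengths(values_by_litter)
  pooled <- unlist(values_by_litter, use.names = FALSE)
  r <- rank(pooled)  # midranks for ties
  grp <- rep(seq_along(labels), sizes)
  rbar <- as.numeric(tapply(r, grp, mean))
  structure(list(labels = labels, n_i = as.integer(sizes),
                 rbar = rbar, n = length(pooled)),
            class = "rank_summary")
}

check_litter_values <- function(values_by_litter, min_litters = 2L) {
  if (!is.list(values_by_litter) || length(values_by_litter) < min_litters) {
    stopf("need at least %d litter(s) of values", min_litters)
  }
  if (is.null(names(values_by_litter)) || any(!nzchar(names(values_by_litter)))) {
    stopf("values_by_litter must be a named list (litter label -> values)")
  }
  if (any(lengths(values_by_litter) < 1L)) stopf("every litter must be non-empty")
  invisible(TRUE)
}

#' Kruskal-Wallis test across litters
#'
#' The gate of the exclusion loop: tests whether the distribution of the
#' outcome differs across litters. Uses midranks with the standard tie
#' correction and a chi-square reference with K - 1 degrees of freedom.
#'
#' @param values_by_litter named list: litter label -> numeric outcomes.
#' @return list with `H` (tie-corrected statistic), `p`, and `df`.
#' @export
kruskal_wallis <- function(values_by_litter) {
  check_litter_values(values_by_litter)
  pooled <- unlist(values_by_litter, use.names = FALSE)
  grp <- factor(rep(names(values_by_litter), lengths(values_by_litter)),
                levels = names(values_by_litter))
  if (length(unique(pooled)) == 1L) {
    # all observations equal: every midrank coincides, no evidence of
    # litter differences
    return(list(H = 0, p = 1, df = length(values_by_litter) - 1L))
  }
  kt <- stats::kruskal.test(pooled, grp)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

# Tie-corrected Kruskal-Wallis H from a midrank vector and group index;
# the permutation engine's fast path (ranks are permuted, not recomputed).
kw_H_from_ranks <- function(r, grp_sizes, grp, n) {
  rbar <- rowsum(r, grp) / grp_sizes
  h <- 12 / (n * (n + 1)) * sum(grp_sizes * (rbar - (n + 1) / 2)^2)
  h
}

#' Most deviant litter by average rank
#'
#' Identifies the litter whose average midrank deviates most from the overall
#' mean rank (n + 1)/2. The default uses the absolute deviation, catching
#' abnormally small or large litters alike; `one_sided = TRUE` takes the
#' literal argmax of the signed deviation instead. Ties are broken by larger
#' litter size, then by lexicographically smallest label.
#'
#' @param summary a [rank_summary()].
#' @param one_sided use the signed deviation (largest positive) instead of
#'   the absolute deviation.
#' @return the litter label.
#' @export
most_deviant_litter <- function(summary, one_sided = FALSE) {
  stopifnot(inherits(summary, "rank_summary"))
  if (length(summary$labels) < 2L) stopf("need at least 2 litters")
  dev <- summary$rbar - (summary$n + 1) / 2
  score <- if (one_sided) dev else abs(dev)
  ord <- order(-score, -summary$n_i, summary$labels)
  summary$labels[ord[1L]]
}

#' Deviant-litter contrast statistic
#'
#' The distance of litter `j` from the remaining litters on the rank scale:
#' contrasts c_i = -1 for the deviant litter and 1/(K - 1) otherwise,
#' standard error SE = sqrt(n(n+1)/12 * sum(c_i^2 / n_i)), and
#' T = (sum(c_i * rbar_i) / SE)^2. For K = 2 litters T coincides with the
#' Kruskal-Wallis H.
#'
#' @param summary a [rank_summary()].
#' @param j label of the deviant litter.
#' @return a `contrast_result` list with `j`, `contrasts`, `sum_c_rbar`,
#'   `SE` and `T`.
#' @export
contrast_statistic <- function(summary, j) {
  stopifnot(inherits(summary, "rank_summary"))
  K <- length(summary$labels)
  if (K < 2L) stopf("need at least 2 litters")
  jdx <- match(j, summary$labels)
  if (is.na(jdx)) stopf("unknown litter '%s'", j)
  cvec <- rep(1 / (K - 1), K)
  cvec[jdx] <- -1
  n <- summary$n
  se <- sqrt(n * (n + 1) / 12 * sum(cvec^2 / summary$n_i))
  if (!is.finite(se) || se <= 0) stopf("degenerate input: zero standard error (n <= 1?)")
  num <- sum(cvec * summary$rbar)
  structure(list(j = j, contrasts = stats::setNames(cvec, summary$labels),
                 sum_c_rbar = num, SE = se, T = (num / se)^2),
            class = "contrast_result")
}

# Full step-2 statistic from a midrank vector: (re-)select the deviant
# litter, then the contrast statistic. Vectorised internals for the
# permutation loop. grp is an integer group index aligned with r.
deviant_T_from_ranks <- function(r, grp, n_i, n, one_sided = FALSE,
                                 frozen_j = NULL, se_by_j = NULL) {
  rbar <- as.numeric(rowsum(r, grp)) / n_i
  K <- length(n_i)
  if (is.null(frozen_j)) {
    dev <- rbar - (n + 1) / 2
    score <- if (one_sided) dev else abs(dev)
    # tie-break: larger n_i, then smallest index (labels pre-sorted upstream)
    jdx <- order(-score, -n_i)[1L]
  } else {
    jdx <- frozen_j
  }
  cj <- rep(1 / (K - 1), K)
  cj[jdx] <- -1
  se <- if (is.null(se_by_j)) {
    sqrt(n * (n + 1) / 12 * sum(cj^2 / n_i))
  } else {
    se_by_j[jdx]
  }
  list(T = (sum(cj * rbar) / se)^2, jdx = jdx)
}

#' Permutation p-value for the deviant-litter statistic
#'
#' Calibrates the observed contrast statistic T by randomly reassigning the
#' pooled observations to litters of the original sizes. Within each permuted
#' dataset the full procedure is re-run by default: the deviant litter is
#' re-selected before T is computed, giving a valid null for a data-selected
#' contrast (`reselect = FALSE` freezes the observed litter instead). The
#' p-value is the strict fraction of permuted statistics exceeding the
#' observed one. Exhaustive mode enumerates every distinct assignment.
#'
#' @param values_by_litter named list: litter label -> numeric outcomes.
#' @param n_perm number of random permutations (random mode).
#' @param seed integer RNG seed (random mode).
#' @param mode `"random"` (default) or `"exhaustive"`.
#' @param reselect re-select the deviant litter within each permutation
#'   (default TRUE).
#' @param one_sided passed to [most_deviant_litter()].
#' @param max_exhaustive safety cap on the number of enumerated assignments.
#' @return a `permutation_result` list with the observed statistic and litter,
#'   `p_value`, `n_perm`, `mode`, and `tie_fraction` (share of permuted
#'   statistics tying the observed one; a warning is issued above 10%).
#' @export
permutation_pvalue <- function(values_by_litter, n_perm = 10000L, seed = 1L,
                               mode = c("random", "exhaustive"),
                               reselect = TRUE, one_sided = FALSE,
                               max_exhaustive = 2e6) {
  mode <- match.arg(mode)
  check_litter_values(values_by_litter)
  smry <- rank_summary(values_by_litter)
  j_obs <- most_deviant_litter(smry, one_sided = one_sided)
  obs <- contrast_statistic(smry, j_obs)

  pooled <- unlist(values_by_litter, use.names = FALSE)
  r0 <- rank(pooled)          # midranks are permutation-invariant as a multiset
  n <- smry$n
  n_i <- smry$n_i
  K <- length(n_i)
  grp <- rep(seq_len(K), n_i)
  frozen <- if (reselect) NULL else match(j_obs, smry$labels)
  se_by_j <- vapply(seq_len(K), function(jdx) {
    cj <- rep(1 / (K - 1), K); cj[jdx] <- -1
    sqrt(n * (n + 1) / 12 * sum(cj^2 / n_i))
  }, numeric(1))

  if (mode == "exhaustive") {
    perms <- enumerate_assignments(n, n_i, max_exhaustive)
    t_perm <- vapply(perms, function(idx) {
      deviant_T_from_ranks(r0[idx], grp, n_i, n, one_sided, frozen, se_by_j)$T
    }, numeric(1))
    n_used <- length(t_perm)
  } else {
    if (n_perm < 1L) stopf("n_perm must be >= 1")
    t_perm <- with_substream(seed, 0L, {
      vapply(seq_len(n_perm), function(b) {
        deviant_T_from_ranks(r0[sample.int(n)], grp, n_i, n,
                             one_sided, frozen, se_by_j)$T
      }, numeric(1))
    })
    n_used <- n_perm
  }
  tol <- 1e-10
  p <- mean(t_perm > obs$T + tol)
  tie_frac <- mean(abs(t_perm - obs$T) <= tol)
  if (tie_frac > 0.10) {
    warnf("permutation_pvalue: %.0f%% of permuted statistics tie the observed one; the strict-inequality p-value may be unstable", 100 * tie_frac)
  }
  structure(list(observed_T = obs$T, deviant_litter = j_obs,
                 p_value = p, n_perm = n_used, mode = mode,
                 tie_fraction = tie_frac,
                 permuted_T_summary = stats::quantile(t_perm, c(0, .5, .95, 1))),
            class = "permutation_result")
}

# All distinct assignments of n pooled observations to groups of fixed sizes,
# as a list of index permutations (positions of the pooled vector laid out
# group by group). Count = n! / prod(n_i!).
enumerate_assignments <- function(n, sizes, cap) {
  total <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (total > cap) {
    stopf("exhaustive mode would enumerate %.3g assignments (cap %g); use mode = 'random'",
          total, cap)
  }
  recurse <- function(remaining, sizes) {
    if (length(sizes) == 0L) return(list(integer(0)))
    if (length(sizes) == 1L) return(list(remaining))
    first <- utils::combn(remaining, sizes[1L], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- recurse(setdiff(remaining, f), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(f, r)))
    }
    out
  }
  recurse(seq_len(n), sizes)
}

#' Iterative exclusion of outlier litters
#'
#' Runs the full loop on control-animal outcomes grouped by litter: stop if
#' the Kruskal-Wallis gate is not significant at `alpha_kw`; otherwise pick
#' the most deviant litter, compute its contrast statistic, and calibrate it
#' by permutation. If the permutation p-value exceeds `alpha_perm`, stop;
#' otherwise exclude the litter and repeat on the remaining data. A single
#' remaining litter forces a stop, so at most K - 1 litters are ever excluded.
#'
#' @param values_by_litter named list: litter label -> numeric control
#'   outcomes.
#' @param alpha_kw significance level of the Kruskal-Wallis gate.
#' @param alpha_perm significance level of the permutation test.
#' @param n_perm permutations per iteration.
#' @param seed integer seed; each iteration uses a substream derived from it,
#'   so the whole trace is reproducible.
#' @param mode,reselect,one_sided passed to [permutation_pvalue()].
#' @return an `exclusion_trace` list: `iterations` (each with the KW gate,
#'   the deviant litter, the contrast statistic, the permutation result and
#'   the action taken) and `excluded` (litter labels in exclusion order).
#' @export
iterative_exclusion <- function(values_by_litter,
                                alpha_kw = 0.05, alpha_perm = 0.05,
                                n_perm = 10000L, seed = 1L,
                                mode = c("random", "exhaustive"),
                                reselect = TRUE, one_sided = FALSE) {
  mode <- match.arg(mode)
  check_litter_values(values_by_litter, min_litters = 1L)
  current <- values_by_litter
  iterations <- list()
  excluded <- character()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (length(current) < 2L) {
      iterations[[iter]] <- list(action = "stopped_single_litter",
                                 n_litters = length(current))
      break
    }
    kw <- kruskal_wallis(current)
    if (kw$p > alpha_kw) {
      iterations[[iter]] <- list(kw = kw, action = "stopped_at_kw",
                                 n_litters = length(current))
      break
    }
    smry <- rank_summary(current)
    j <- most_deviant_litter(smry, one_sided = one_sided)
    contrast <- contrast_statistic(smry, j)
    perm <- permutation_pvalue(current, n_perm = n_perm,
                               seed = derive_seed(seed, iter),
                               mode = mode, reselect = reselect,
                               one_sided = one_sided)
    if (perm$p_value > alpha_perm) {
      iterations[[iter]] <- list(kw = kw, deviant_litter = j,
                                 contrast = contrast, permutation = perm,
                                 action = "stopped_at_permutation",
                                 n_litters = length(current))
      break
    }
    iterations[[iter]] <- list(kw = kw, deviant_litter = j,
                               contrast = contrast, permutation = perm,
                               action = "excluded",
                               n_litters = length(current))
    excluded <- c(excluded, j)
    current <- current[names(current) != j]
  }
  structure(list(iterations = iterations, excluded = excluded,
                 retained = names(current),
                 alpha_kw = alpha_kw, alpha_perm = alpha_perm,
                 n_perm = n_perm, seed = seed, mode = mode),
            class = "exclusion_trace")
}

#' @export
print.exclusion_trace <- function(x, ...) {
  cat(sprintf("exclusion_trace: %d iteration(s), %d litter(s) excluded\n",
              length(x$iterations), length(x$excluded)))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    if (!is.null(it$kw)) {
      cat(sprintf("  [%d] KW H = %.3f (p = %.4g)", i, it$kw$H, it$kw$p))
      if (!is.null(it$permutation)) {
        cat(sprintf("; deviant = %s, T = %.3f, perm p = %.4g",
                    it$deviant_litter, it$contrast$T, it$permutation$p_value))
      }
      cat(sprintf(" -> %s\n", it$action))
    } else {
      cat(sprintf("  [%d] %s\n", i, it$action))
    }
  }
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Control outcomes grouped for the exclusion procedure
#'
#' Extracts control-animal outcomes from a trial dataset as a named list
#' keyed by litter (the default) or by experiment, the input format of
#' [iterative_exclusion()].
#'
#' @param dataset a [trial_dataset()].
#' @param group_by `"litter"` (litter within experiment) or `"experiment"`.
#' @return named list of numeric vectors.
#' @export
control_values_by_group <- function(dataset, group_by = c("litter", "experiment")) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(dataset, "trial_dataset"))
  ctrl <- dataset[dataset$treatment == "control", , drop = FALSE]
  key <- if (group_by == "litter") ctrl$litter_id else ctrl$experiment_id
  split(ctrl$area_loss_pct, key)
}

#' Drop excluded litters from a dataset
#'
#' Removes every animal (all arms) belonging to a litter named in an
#' exclusion trace, recording the action in provenance.
#'
#' @param dataset a [trial_dataset()].
#' @param trace an `exclusion_trace` from [iterative_exclusion()].
#' @return a [trial_dataset()].
#' @export
apply_exclusions <- function(dataset, trace) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(trace, "exclusion_trace"))
  if (length(trace$excluded) == 0L) return(dataset)
  keep <- !(dataset$litter_id %in% trace$excluded)
  trial_dataset(dataset[keep, , drop = FALSE],
                provenance = c(attr(dataset, "provenance"),
                               sprintf("apply_exclusions: removed litter(s) %s",
                                       paste(trace$excluded, collapse = ", "))))
}
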