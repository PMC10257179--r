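test_that("Kruskal-Wallis gate matches hand computation and rank properties", {
  kw <- kruskal_wallis(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  expect_equal(kw$H, 162 / 42, tolerance = 1e-12)
  expect_equal(kw$df, 1)

  # all observations equal: no evidence
  kw0 <- kruskal_wallis(list(A = c(5, 5), B = c(5, 5, 5)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)

  # invariance under strictly monotone transformation
  set.seed(31)
  vals <- split(rnorm(30), rep(1:3, each = 10))
  names(vals) <- c("a", "b", "c")
  h1 <- kruskal_wallis(vals)$H
  h2 <- kruskal_wallis(lapply(vals, function(v) exp(v) + 7))$H
  expect_equal(h1, h2, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(A = 1:3)), "at least 2")
})

test_that("most deviant litter uses absolute deviation with stated tie-breaks", {
  # R-bar = (2, 5), n = 6: |deviations| tie at 1.5, equal sizes -> first label
  s <- structure(list(labels = c("a", "b"), n_i = c(3L, 3L),
                      rbar = c(2, 5), n = 6L), class = "rank_summary")
  expect_equal(most_deviant_litter(s), "a")
  # one-sided literal reading picks the high litter
  expect_equal(most_deviant_litter(s, one_sided = TRUE), "b")

  # R-bar = (3, 3, 7.5), n = 9, mid rank 5: litter 3 wins (|2.5| > |2|)
  s3 <- structure(list(labels = c("L1", "L2", "L3"), n_i = c(3L, 3L, 3L),
                       rbar = c(3, 3, 7.5), n = 9L), class = "rank_summary")
  expect_equal(most_deviant_litter(s3), "L3")

  # tie on deviation broken by larger litter size
  s4 <- structure(list(labels = c("x", "y"), n_i = c(2L, 4L),
                       rbar = c(2, 5), n = 6L), class = "rank_summary")
  expect_equal(most_deviant_litter(s4), "y")

  # a far-shifted litter is always selected (brute force over litters)
  set.seed(41)
  for (rep in 1:10) {
    vals <- split(rnorm(40), rep(1:4, each = 10))
    names(vals) <- paste0("L", 1:4)
    shifted <- sample(4, 1)
    vals[[shifted]] <- vals[[shifted]] + 50
    expect_equal(most_deviant_litter(rank_summary(vals)),
                 paste0("L", shifted))
  }
})

test_that("contrast statistic matches the closed form and reduces to H at K = 2", {
  s <- rank_summary(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  ct <- contrast_statistic(s, "B")
  expect_equal(ct$sum_c_rbar, -3)
  expect_equal(ct$SE, sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(ct$T, 27 / 7, tolerance = 1e-12)
  expect_equal(sum(ct$contrasts), 0, tolerance = 1e-12)

  # all average ranks equal -> T = 0
  s0 <- rank_summary(list(A = c(5, 5), B = c(5, 5)))
  expect_equal(contrast_statistic(s0, "A")$T, 0)

  # K = 2 identity with the Kruskal-Wallis H (independent oracle:
  # stats::kruskal.test), exact up to 1e-10, 100 random instances with ties
  set.seed(53)
  for (rep in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- list(A = sample(1:6, n1, replace = TRUE),
                 B = sample(1:6, n2, replace = TRUE))
    if (length(unique(unlist(vals))) == 1L) next
    smry <- rank_summary(vals)
    j <- most_deviant_litter(smry)
    T <- contrast_statistic(smry, j)$T
    grp <- factor(rep(c("A", "B"), c(n1, n2)))
    H_oracle <- unname(stats::kruskal.test(unlist(vals), grp)$statistic)
    # the contrast statistic carries no tie correction; compare on the
    # uncorrected scale by undoing kruskal.test's tie divisor
    pooled <- unlist(vals)
    ties <- table(pooled)
    n <- length(pooled)
    tie_div <- 1 - sum(ties^3 - ties) / (n^3 - n)
    expect_equal(T, H_oracle * tie_div, tolerance = 1e-10)
  }
})

test_that("exhaustive permutation reproduces the enumeration oracle", {
  res <- suppressWarnings(
    permutation_pvalue(list(A = c(1, 2), B = c(9, 10)), mode = "exhaustive"))
  expect_equal(res$observed_T, 2.4, tolerance = 1e-12)
  expect_equal(res$n_perm, 6)  # C(4, 2) distinct assignments
  expect_equal(res$p_value, 0) # strict inequality: nothing exceeds 2.4
  expect_warning(
    permutation_pvalue(list(A = c(1, 2), B = c(9, 10)), mode = "exhaustive"),
    "tie")

  # degenerate: all values identical -> all T equal, strict p = 0, tie warning
  expect_warning(
    res0 <- permutation_pvalue(list(A = c(3, 3), B = c(3, 3)), mode = "exhaustive"),
    "tie")
  expect_equal(res0$p_value, 0)
  expect_equal(res0$tie_fraction, 1)

  # enumeration size guard
  big <- split(rnorm(40), rep(1:4, each = 10))
  names(big) <- paste0("L", 1:4)
  expect_error(permutation_pvalue(big, mode = "exhaustive", max_exhaustive = 100),
               "use mode = 'random'")
})

test_that("random and exhaustive permutation modes agree within binomial error", {
  set.seed(61)
  for (rep in 1:5) {
    vals <- list(A = round(rnorm(3, 0, 2), 1), B = round(rnorm(3, 1, 2), 1),
                 C = round(rnorm(3, -1, 2), 1))
    ex <- suppressWarnings(permutation_pvalue(vals, mode = "exhaustive"))
    rn <- suppressWarnings(permutation_pvalue(vals, mode = "random",
                                              n_perm = 10000, seed = rep))
    bound <- 3 * sqrt(max(ex$p_value * (1 - ex$p_value), 1e-4) / 10000)
    expect_lte(abs(rn$p_value - ex$p_value), max(bound, 0.015))
  }
})

test_that("every statistic in the procedure is rank-based (monotone invariant)", {
  set.seed(71)
  vals <- split(rgamma(40, 2), rep(1:4, each = 10))
  names(vals) <- paste0("L", 1:4)
  trans <- lapply(vals, function(v) log(v + 1) * 10 - 2)
  s1 <- rank_summary(vals); s2 <- rank_summary(trans)
  expect_equal(s1$rbar, s2$rbar)
  j <- most_deviant_litter(s1)
  expect_equal(j, most_deviant_litter(s2))
  expect_equal(contrast_statistic(s1, j)$T, contrast_statistic(s2, j)$T,
               tolerance = 1e-12)
  p1 <- permutation_pvalue(vals, n_perm = 300, seed = 8)
  p2 <- permutation_pvalue(trans, n_perm = 300, seed = 8)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("iterative exclusion stops on degenerate input and respects K - 1 cap", {
  tr <- iterative_exclusion(list(only = c(1, 2, 3)), seed = 1)
  expect_equal(length(tr$excluded), 0)
  expect_equal(tr$iterations[[1]]$action, "stopped_single_litter")

  # two wildly different litters: at most one exclusion ever
  tr2 <- iterative_exclusion(list(lo = 1:6, hi = 101:106),
                             n_perm = 200, seed = 2)
  expect_lte(length(tr2$excluded), 1)
})

test_that("a strongly shifted litter is excluded first and traces replay exactly", {
  set.seed(83)
  vals <- split(rnorm(50, 40, 5), rep(1:5, each = 10))
  names(vals) <- paste0("L", 1:5)
  vals$L3 <- vals$L3 + 20  # +4 sigma shift
  tr <- iterative_exclusion(vals, n_perm = 1000, seed = 19)
  expect_gte(length(tr$excluded), 1)
  expect_equal(tr$excluded[1], "L3")
  expect_false("L3" %in% tr$retained)

  # bit-for-bit replay under the same seed
  tr2 <- iterative_exclusion(vals, n_perm = 1000, seed = 19)
  expect_identical(tr, tr2)

  # applying the exclusions removes all arms of the litter from a dataset
  d <- simulate_trial(sim_config(n_experiments = 2, seed = 6))
  lit <- unique(d$litter_id[d$treatment == "control"])[1]
  fake <- structure(list(excluded = lit, iterations = list()),
                    class = "exclusion_trace")
  d2 <- apply_exclusions(d, fake)
  expect_false(lit %in% d2$litter_id)
})
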