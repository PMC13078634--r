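test_that("shapiro_gate reports W and gates at alpha", {
  # exact standard-normal quantiles look maximally normal
  x <- qnorm(ppoints(20))
  g <- shapiro_gate(x)
  expect_gt(g$statistic, 0.99)
  expect_equal(g$decision, "normal")

  # a two-point sample is flagged non-normal
  set.seed(15)
  y <- sample(c(0, 10), 20, replace = TRUE)
  expect_equal(shapiro_gate(y)$decision, "non-normal")
  expect_error(shapiro_gate(c(1, 2)), "\\[3, 5000\\]")
})

test_that("two_group_test gates between Student t and Mann-Whitney", {
  set.seed(16)
  xn <- rnorm(20); yn <- rnorm(20, 1)
  tn <- two_group_test(xn, yn)
  expect_equal(tn$gate, "normal")
  expect_equal(tn$test, "student-t")
  expect_equal(tn$p, t.test(xn, yn, var.equal = TRUE)$p.value)

  xs <- exp(rnorm(20, sd = 2)); ys <- exp(rnorm(20, sd = 2)) + 5
  ts <- two_group_test(xs, ys)
  expect_equal(ts$gate, "non-normal")
  expect_equal(ts$test, "mann-whitney-u")

  # identical groups: p ~ 1 whichever branch
  xi <- c(1.2, 3.4, 2.2, 4.1, 0.8)
  expect_gt(two_group_test(xi, xi)$p, 0.95)

  # 3-vs-3 fully separated ranks: exact two-sided MWU p = 2/C(6,3) = 0.1
  tsep <- two_group_test(c(101, 102, 103), c(1, 2, 3.5), alpha_gate = 1)
  expect_equal(tsep$test, "mann-whitney-u")
  expect_equal(tsep$p, 0.1, tolerance = 1e-9)

  # Bonferroni caps at 1
  tb <- two_group_test(xn, xn + 0.01, m_comparisons = 3)
  expect_equal(tb$p_adj, min(1, 3 * tb$p))
  expect_lte(tb$p_adj, 1)
  expect_error(two_group_test(xn, yn, m_comparisons = 0), "m_comparisons")

  # gate decision is a pure function of data and alpha
  expect_identical(two_group_test(xs, ys)$gate, two_group_test(xs, ys)$gate)
})

test_that("fisher_exact_2x2 equals full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))$p, 2 / 252,
               tolerance = 1e-12)

  # independent oracle: point-probability two-sided sum over dhyper
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(2, 24, 62, 40), 2),   # 2/64 vs 24/64 abnormal hearts
               matrix(c(1, 22, 59, 48), 2),   # 1/60 vs 22/70
               matrix(c(3, 1, 1, 3), 2),
               matrix(c(10, 25, 40, 12), 2),
               matrix(c(100, 50, 50, 100), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact_2x2(tab)$p, fisher_oracle(tab), tolerance = 1e-12)
  }
  expect_warning(pz <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(pz$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("paired_t matches the closed form and is shift invariant", {
  # differences [1, 2, 3]: t = 2 * sqrt(3), df 2
  before <- c(10, 20, 30)
  after <- before + c(1, 2, 3)
  pt <- paired_t(before, after)
  expect_equal(pt$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(pt$df, 2)
  # shift invariance
  pt2 <- paired_t(before + 100, after + 100)
  expect_equal(pt2$statistic, pt$statistic)
  expect_equal(pt2$p, pt$p)
  # degenerate: no change
  d0 <- paired_t(before, before)
  expect_true(d0$degenerate)
  expect_equal(d0$p, 1)
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("exceedance permutation test matches exhaustive enumeration", {
  # identical conditions in every trial: T = 0 and p = 1, exhaustively
  tr0 <- tibble::tibble(trial = rep(c("T1", "T2"), each = 6),
                        condition = rep(rep(c("control", "treatment"), each = 3), 2),
                        count = rep(c(4, 7, 9), 4))
  r0 <- exceedance_permutation_test(tr0)
  expect_true(r0$exact)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # single trial, brute-force oracle over all C(8,4) = 70 label assignments
  x <- c(1, 2, 1, 3, 9, 8, 9, 7)
  tr1 <- tibble::tibble(trial = "T1",
                        condition = rep(c("control", "treatment"), each = 4),
                        count = x)
  r1 <- exceedance_permutation_test(tr1)
  stat <- function(ctl, trt) {
    thr <- mean(ctl) + sd(ctl)
    mean(trt >= thr) - mean(ctl >= thr)
  }
  t_obs <- stat(x[1:4], x[5:8])
  t_null <- apply(combn(8, 4), 2, function(idx) stat(x[idx], x[-idx]))
  expect_true(r1$exact)
  expect_equal(r1$statistic, t_obs)
  expect_equal(r1$p, mean(t_null >= t_obs - 1e-12), tolerance = 1e-12)

  # Monte-Carlo p converges to the exhaustive p; never zero (add-one rule)
  r_mc <- exceedance_permutation_test(tr1, n_perm = 4000, seed = 3,
                                      exhaustive_limit = 1)
  expect_false(r_mc$exact)
  se <- sqrt(r1$p * (1 - r1$p) / 4000)
  expect_lt(abs(r_mc$p - r1$p), 3 * se + 2 / 4000)
  expect_gt(r_mc$p, 0)

  # row order of the input is irrelevant
  set.seed(17)
  shuffled <- tr1[sample(nrow(tr1)), ]
  expect_equal(exceedance_permutation_test(shuffled)$p, r1$p)

  expect_error(exceedance_permutation_test(
    tibble::tibble(trial = "T1", condition = c("control", "treatment", "treatment"),
                   count = c(1, 2, 3))), "SD is undefined")
  expect_error(exceedance_permutation_test(tr1, n_perm = 0), "n_perm")
})

test_that("permutation schemes and alternatives behave sensibly on a planted effect", {
  d <- generate_trial_counts(trial_config(
    n_trials = 3, n_control = 8, n_treatment = 8,
    effect = list(type = "exceeder", value = 0.6), seed = 18))
  p_within <- exceedance_permutation_test(d$trials, n_perm = 1000, seed = 1,
                                          exhaustive_limit = 1)$p
  p_pooled <- exceedance_permutation_test(d$trials, n_perm = 1000, seed = 1,
                                          scheme = "pooled")$p
  expect_lt(p_within, 0.01)
  expect_lt(p_pooled, 0.05)
  p_two <- exceedance_permutation_test(d$trials, n_perm = 1000, seed = 1,
                                       alternative = "two.sided",
                                       exhaustive_limit = 1)$p
  expect_gte(p_two, p_within)
})
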