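new_ul_test <- function(test, statistic, p, ..., p_adj = NULL) {
  structure(c(list(test = test, statistic = unname(statistic), p = unname(p),
                   p_adj = p_adj), list(...)),
            class = "ul_test")
}

#' @export
print.ul_test <- function(x, ...) {
  cat(sprintf("<ul_test> %s: statistic = %.6g, p = %.4g", x$test, x$statistic, x$p))
  if (!is.null(x$p_adj)) cat(sprintf(", p_adj = %.4g", x$p_adj))
  if (!is.null(x$gate)) cat(sprintf("  [gate: %s]", x$gate))
  cat("\n")
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and decides `normal` when p >= `alpha_gate`
#' (default 0.05), the gate the two-group ladder uses to choose between the
#' Student t and Mann-Whitney branches.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param alpha_gate significance level for the gate.
#' @return An `ul_test` with `statistic` (W), `p`, and `decision`
#'   (`"normal"` / `"non-normal"`).
#' @export
shapiro_gate <- function(x, alpha_gate = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("shapiro_gate: sample size must be in [3, 5000].")
  }
  sw <- shapiro.test(x)
  new_ul_test("shapiro-wilk", sw$statistic, sw$p.value,
              decision = if (sw$p.value >= alpha_gate) "normal" else "non-normal",
              n = length(x), alpha_gate = alpha_gate)
}

#' Normality-gated two-group comparison with Bonferroni correction
#'
#' The two-sample ladder: a Shapiro-Wilk gate is applied to the pooled
#' within-group-centered residuals; if they look normal a Student t test
#' (equal variances) is run, otherwise a Mann-Whitney U test. The p-value is
#' Bonferroni-corrected for `m_comparisons` comparisons
#' (`p_adj = min(1, m * p)`).
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha_gate gate level for the Shapiro-Wilk decision.
#' @param m_comparisons number of comparisons in the family (>= 1).
#' @return An `ul_test` with the branch taken in `test`, the `gate` decision
#'   and the gate's W and p.
#' @export
two_group_test <- function(x, y, alpha_gate = 0.05, m_comparisons = 1) {
  if (m_comparisons < 1) abort("two_group_test: m_comparisons must be >= 1.")
  if (length(x) < 3 || length(y) < 3) abort("two_group_test: both groups need n >= 3.")
  resid <- c(x - mean(x), y - mean(y))
  gate <- if (length(unique(resid)) < 3) {
    # degenerate residuals (e.g. identical constants): treat as non-normal
    list(statistic = NA_real_, p = 0)
  } else {
    sw <- shapiro.test(resid)
    list(statistic = unname(sw$statistic), p = sw$p.value)
  }
  normal <- gate$p >= alpha_gate
  if (normal) {
    ht <- t.test(x, y, var.equal = TRUE)
    test <- "student-t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    test <- "mann-whitney-u"
  }
  new_ul_test(test, ht$statistic, ht$p.value,
              p_adj = min(1, m_comparisons * ht$p.value),
              gate = if (normal) "normal" else "non-normal",
              gate_W = gate$statistic, gate_p = gate$p,
              n = c(length(x), length(y)), m_comparisons = m_comparisons)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test for association in a 2x2 contingency table, with the
#' point-probability rule: the p-value sums hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. A zero margin carries no information and returns p = 1 with a
#' warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return An `ul_test` with `statistic` = conditional odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_exact_2x2: need a 2x2 table of non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("fisher_exact_2x2: a margin is zero; association is undefined, p = 1.")
    return(new_ul_test("fisher-exact", NA_real_, 1, table = tab))
  }
  ft <- fisher.test(tab)
  new_ul_test("fisher-exact", ft$estimate, ft$p.value, table = tab)
}

#' Paired t test
#'
#' Student t test on paired differences (`after - before`), two-sided.
#' Zero-variance differences are flagged degenerate: p = 1 when all
#' differences are 0, otherwise p = 0 with `degenerate = TRUE` (a constant
#' nonzero shift).
#'
#' @param before,after equal-length paired samples, n >= 2.
#' @return An `ul_test` with `statistic` = t, `df`, and `degenerate` flag.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) abort("paired_t: arms must have equal length.")
  if (length(before) < 2) abort("paired_t: need n >= 2 pairs.")
  d <- after - before
  if (sd(d) < 1e-12) {
    p <- if (all(abs(d) < 1e-12)) 1 else 0
    return(new_ul_test("paired-t", if (p == 1) 0 else Inf, p,
                       df = length(d) - 1, degenerate = TRUE))
  }
  ht <- t.test(d)
  new_ul_test("paired-t", ht$statistic, ht$p.value,
              df = unname(ht$parameter), degenerate = FALSE)
}
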