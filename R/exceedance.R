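#' Trial-stratified permutation test on exceedance proportions
#'
#' The exceedance statistic summarises, per trial, the fraction of animals
#' whose count is at least one control standard deviation above the control
#' mean of that trial (count >= mean + 1*SD, sample SD), and takes the mean
#' over trials of the treatment fraction minus the control fraction. The
#' null distribution permutes condition labels *within* each trial (the
#' control mean and SD are recomputed from each permuted control group), so
#' the trial structure is preserved. When the number of distinct label
#' arrangements is small the null is enumerated exhaustively and the p-value
#' is exact; otherwise `n_perm` Monte-Carlo permutations are drawn and the
#' add-one rule `p = (1 + #\{T* >= T\}) / (1 + n_perm)` keeps p positive.
#' The default alternative is one-sided (treatment exceeds control), the
#' direction of the planted claim; `"two.sided"` compares |T*| with |T|.
#'
#' @param trials tibble with `trial`, `condition`, `count`; `condition` has
#'   a control and a treatment level.
#' @param n_perm Monte-Carlo permutations (ignored when exhaustive).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param control label of the control condition; the other label is the
#'   treatment.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param scheme `"within"` (trial-stratified, default) or `"pooled"`
#'   (labels permuted across the pooled animals, for sensitivity analysis).
#' @param exhaustive_limit enumerate exactly when the total number of
#'   within-trial arrangements is at most this.
#' @param sd_mult exceedance cutoff is mean + `sd_mult` * SD.
#' @return An `ul_test` with `statistic` = observed T, `p`, `exact`
#'   (exhaustive or not), `n_perm`, `per_trial` tibble of observed
#'   exceedance proportions, and `seed`.
#' @export
exceedance_permutation_test <- function(trials, n_perm = 10000, seed = 0,
                                        control = "control",
                                        alternative = c("greater", "two.sided"),
                                        scheme = c("within", "pooled"),
                                        exhaustive_limit = 1e6,
                                        sd_mult = 1) {
  alternative <- match.arg(alternative)
  scheme <- match.arg(scheme)
  stopifnot(all(c("trial", "condition", "count") %in% names(trials)))
  if (n_perm < 1) abort("exceedance_permutation_test: n_perm must be >= 1.")
  conds <- unique(trials$condition)
  if (!control %in% conds || length(conds) != 2) {
    abort("exceedance_permutation_test: need exactly two conditions including the control.")
  }
  treatment <- setdiff(conds, control)
  split_tr <- split(trials, trials$trial)
  for (tr in split_tr) {
    if (sum(tr$condition == control) < 2) {
      abort(sprintf("Trial %s has < 2 control animals; control SD is undefined.",
                    tr$trial[1]))
    }
    if (sum(tr$condition == treatment) < 1) {
      abort(sprintf("Trial %s has no treatment animals.", tr$trial[1]))
    }
  }

  # observed per-trial contributions
  contrib <- function(ctl, trt) {
    thr <- mean(ctl) + sd_mult * sd(ctl)
    mean(trt >= thr) - mean(ctl >= thr)
  }
  per_trial <- purrr::map_dfr(split_tr, function(tr) {
    ctl <- tr$count[tr$condition == control]
    trt <- tr$count[tr$condition == treatment]
    thr <- mean(ctl) + sd_mult * sd(ctl)
    tibble::tibble(trial = tr$trial[1],
                   threshold = thr,
                   prop_treatment = mean(trt >= thr),
                   prop_control = mean(ctl >= thr))
  })
  t_obs <- mean(per_trial$prop_treatment - per_trial$prop_control)

  n_arrangements <- prod(vapply(split_tr, function(tr) {
    choose(nrow(tr), sum(tr$condition == control))
  }, numeric(1)))
  exhaustive <- scheme == "within" && is.finite(n_arrangements) &&
    n_arrangements <= exhaustive_limit

  if (exhaustive) {
    # per-trial null contribution vectors, combined by outer sums
    d_list <- lapply(split_tr, function(tr) {
      x <- tr$count
      n_ctl <- sum(tr$condition == control)
      apply(utils::combn(length(x), n_ctl), 2, function(idx) {
        contrib(x[idx], x[-idx])
      })
    })
    t_null <- Reduce(function(a, b) as.vector(outer(a, b, "+")), d_list) /
      length(d_list)
    p <- switch(alternative,
                greater = mean(t_null >= t_obs - 1e-12),
                two.sided = mean(abs(t_null) >= abs(t_obs) - 1e-12))
    n_used <- length(t_null)
  } else {
    set.seed(seed)
    t_null <- if (scheme == "within") {
      null_sums <- numeric(n_perm)
      for (tr in split_tr) {
        x <- tr$count
        n <- length(x)
        n_ctl <- sum(tr$condition == control)
        idx <- replicate(n_perm, sample.int(n))
        xp <- matrix(x[idx], n, n_perm)
        ctl <- xp[seq_len(n_ctl), , drop = FALSE]
        trt <- xp[(n_ctl + 1):n, , drop = FALSE]
        mu <- colMeans(ctl)
        s <- sqrt(pmax(colSums(ctl^2) - n_ctl * mu^2, 0) / (n_ctl - 1))
        thr <- matrix(mu + sd_mult * s, 1)
        null_sums <- null_sums +
          (colMeans(trt >= thr[rep(1, nrow(trt)), , drop = FALSE]) -
             colMeans(ctl >= thr[rep(1, nrow(ctl)), , drop = FALSE]))
      }
      null_sums / length(split_tr)
    } else {
      # pooled scheme: permute counts across all animals, keep trial sizes
      all_counts <- trials$count
      vapply(seq_len(n_perm), function(i) {
        perm <- sample(all_counts)
        pos <- 0
        mean(vapply(split_tr, function(tr) {
          n <- nrow(tr)
          x <- perm[pos + seq_len(n)]
          pos <<- pos + n
          n_ctl <- sum(tr$condition == control)
          contrib(x[seq_len(n_ctl)], x[(n_ctl + 1):n])
        }, numeric(1)))
      }, numeric(1))
    }
    p <- switch(alternative,
                greater = (1 + sum(t_null >= t_obs - 1e-12)) / (1 + n_perm),
                two.sided = (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (1 + n_perm))
    n_used <- n_perm
  }
  new_ul_test("exceedance-permutation", t_obs, p,
              exact = exhaustive, n_perm = n_used, seed = seed,
              alternative = alternative, scheme = scheme,
              per_trial = per_trial)
}
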