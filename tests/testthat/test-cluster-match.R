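test_that("cluster_profiles computes centroids and abundances", {
  v <- tiny_counts(seq_len(20), 5, 4)
  e <- expr_matrix(v, stage = "log")
  lab <- labels_for(v, c(0, 0, 0, 1, 1))
  prof <- cluster_profiles(e, lab, colnames(v))
  expect_equal(unname(prof$centroids["0", ]), unname(colMeans(v[1:3, ])))
  expect_equal(prof$info$abundance, c(0.6, 0.4))
  expect_equal(sum(prof$info$abundance), 1)

  # single-cell cluster: centroid equals that cell's row
  lab1 <- labels_for(v, c(0, 1, 1, 1, 1))
  prof1 <- cluster_profiles(e, lab1, colnames(v))
  expect_equal(unname(prof1$centroids["0", ]), unname(v[1, ]))
  expect_error(cluster_profiles(e, lab, c("nope", colnames(v))), "absent")
})

test_that("profile_correlation matches closed forms and a brute-force oracle", {
  a <- profiles_from(rbind(c(1, 2, 3)), 10)
  b <- profiles_from(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 4)), c(5, 5, 5))
  r <- profile_correlation(a, b)$r
  expect_equal(unname(r[1, 1]), 1)
  expect_equal(unname(r[1, 2]), -1)
  expect_equal(unname(r[1, 3]), 0.9819805, tolerance = 1e-6)

  # brute-force Pearson loop oracle on random 8x6 profile pairs
  set.seed(9)
  A <- profiles_from(matrix(rnorm(8 * 15), 8), rep(2, 8))
  B <- profiles_from(matrix(rnorm(6 * 15), 6), rep(2, 6))
  colnames(A$centroids) <- colnames(B$centroids) <- A$hvg <- B$hvg <-
    sprintf("g%03d", 1:15)
  r2 <- profile_correlation(A, B)$r
  for (i in 1:8) for (j in 1:6) {
    x <- A$centroids[i, ]; y <- B$centroids[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r2[i, j]), oracle, tolerance = 1e-12)
  }

  # zero-variance centroid: NA with warning
  z <- profiles_from(rbind(c(2, 2, 2)), 3)
  expect_warning(rz <- profile_correlation(z, b), "zero-variance")
  expect_true(all(is.na(rz$r)))
})

test_that("calibrate_threshold picks the largest all-matched grid value", {
  # replicates that are copies: every self-match r = 1 -> top of grid
  p <- profiles_from(matrix(rnorm(4 * 10), 4), rep(5, 4))
  cal <- calibrate_threshold(list(p, p))
  expect_equal(cal$threshold, 0.9)
  expect_true(all(cal$curve$all_cross_matched))

  # planted: matched-pair r about 0.9, cross-state r low -> threshold in (low, 0.9]
  set.seed(10)
  base <- matrix(rnorm(3 * 40), 3)
  rep1 <- profiles_from(base, rep(5, 3))
  rep2 <- profiles_from(base + matrix(rnorm(3 * 40, sd = 0.3), 3), rep(5, 3))
  r12 <- profile_correlation(rep1, rep2)$r
  min_match <- min(diag(r12))
  max_cross <- max(r12[row(r12) != col(r12)])
  cal2 <- calibrate_threshold(list(rep1, rep2))
  expect_gt(cal2$threshold, max_cross)
  expect_lte(cal2$threshold, min_match + 0.05)
  expect_true(cal2$threshold %in% seq(0.1, 0.9, by = 0.05)) # grid member
  expect_error(calibrate_threshold(list(rep1)), "at least 2")
})

test_that("assign_contaminants applies threshold, review band, and abundance veto", {
  hv <- sprintf("g%03d", 1:20)
  set.seed(11)
  base <- matrix(rnorm(3 * 20), 3)
  # query cluster 0 correlates ~1 with ref 0; cluster 1 engineered near 0.494;
  # cluster 2 uncorrelated
  q <- profiles_from(rbind(base[1, ],
                           0.55 * scale(base[2, ])[, 1] + sqrt(1 - 0.55^2) * scale(base[3, ])[, 1],
                           rnorm(20)),
                     c(50, 30, 20))
  r <- profiles_from(base, c(40, 40, 20))
  colnames(q$centroids) <- colnames(r$centroids) <- q$hvg <- r$hvg <- hv
  m <- profile_correlation(q, r)
  # overwrite with exact correlations for a deterministic rule check
  m$r <- matrix(c(0.9, 0.1, 0.1,
                  0.1, 0.494, 0.1,
                  0.2, 0.1, 0.3), nrow = 3, byrow = TRUE,
                dimnames = list(0:2, 0:2))
  dec <- assign_contaminants(m, match_config(threshold = 0.5, band = 0.01))
  expect_equal(dec$verdict, c("contaminant", "needs_review", "retained"))
  expect_equal(dec$rules[2], "near_threshold")

  # abundance veto: reference cluster at 0.17% matched by query clusters
  # totalling 12.1% (71x discrepancy) is vetoed at the 10x limit
  qv <- profiles_from(rbind(base[1, ], base[1, ] + rnorm(20, sd = 0.05)),
                      c(60, 61))           # two similar query clusters, 12.1%-ish
  rv <- profiles_from(rbind(base[1, ], base[2, ]), c(1, 599)) # rare ref state
  colnames(qv$centroids) <- colnames(rv$centroids) <- qv$hvg <- rv$hvg <- hv
  mv <- profile_correlation(qv, rv)
  expect_true(all(mv$r[, 1] > 0.9))
  decv <- assign_contaminants(mv, match_config(threshold = 0.5, ratio_limit = 10))
  expect_equal(decv$verdict, c("retained", "retained"))
  expect_true(all(decv$rules == "abundance_discrepancy"))
  # with comparable abundances the same correlations convict
  rv2 <- profiles_from(rbind(base[1, ], base[2, ]), c(300, 300))
  colnames(rv2$centroids) <- rv2$hvg <- hv
  dec2 <- assign_contaminants(profile_correlation(qv, rv2),
                              match_config(threshold = 0.5))
  expect_true(all(dec2$verdict == "contaminant"))

  # manual overrides applied last and logged
  dec3 <- assign_contaminants(m, match_config(
    overrides = list(`2` = "contaminant")))
  expect_equal(dec3$verdict[3], "contaminant")
  expect_match(dec3$rules[3], "manual_override")
})

test_that("raising the threshold never enlarges the contaminant set", {
  for (s in 1:5) {
    pair <- generate_sc_pair(sc_sim_config(seed = s))
    res <- run_pipeline(pair$query$counts, pair$reference$counts,
                        pipeline_config(min_genes = 5, n_components = 20, seed = s))
    prev <- NULL
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      dec <- assign_contaminants(res$match, match_config(threshold = thr))
      cur <- dec$query_cluster[dec$verdict == "contaminant"]
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})
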