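test_that("generators are pure functions of (config, seed)", {
  cfg <- sc_sim_config(n_states = 3, shared_states = 1:2, contaminant_states = 1:2,
                       n_genes = 50, cells_per_state_query = 20,
                       cells_per_state_reference = 20, seed = 7)
  a <- generate_sc_pair(cfg)
  b <- generate_sc_pair(cfg)
  expect_identical(a$query$counts, b$query$counts)
  expect_identical(a$reference$counts, b$reference$counts)
  expect_identical(a$truth$query_contaminant, b$truth$query_contaminant)

  ec <- edu_sim_config(n_animals = 5, seed = 3)
  expect_identical(generate_edu_dataset(ec)$pulse, generate_edu_dataset(ec)$pulse)

  tc <- trial_config(seed = 11)
  expect_identical(generate_trial_counts(tc)$trials, generate_trial_counts(tc)$trials)

  rc <- read_set_config(n_reads = 100, seed = 5)
  expect_identical(generate_read_set(rc)$reads, generate_read_set(rc)$reads)
})

test_that("empty contaminant set yields zero contaminant cells and counts are integer", {
  cfg <- sc_sim_config(n_states = 3, shared_states = 1:2,
                       contaminant_states = integer(0), n_genes = 40,
                       cells_per_state_query = 15, cells_per_state_reference = 15,
                       seed = 2)
  pair <- generate_sc_pair(cfg)
  expect_false(any(pair$truth$query_contaminant))
  m <- as.matrix(pair$query$counts)
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(sort(unique(pair$reference$cells$replicate)), 1:2)
})

test_that("single-state counts match negative-binomial moments", {
  n_cells <- 600
  mu <- matrix(c(2, 8, 0.5, 20, 5), nrow = 1, ncol = 5)
  cfg <- sc_sim_config(n_states = 1, shared_states = 1, contaminant_states = 1,
                       n_genes = 5, cells_per_state_query = n_cells,
                       cells_per_state_reference = 10, nb_mean = mu,
                       nb_dispersion = 2, seed = 4)
  m <- as.matrix(generate_sc_pair(cfg)$query$counts)
  # NB(mu, size): var = mu + mu^2/size; observed mean within 3 SE
  for (j in 1:5) {
    se <- sqrt((mu[j] + mu[j]^2 / 2) / n_cells)
    expect_lt(abs(mean(m[, j]) - mu[j]), 3 * se + 1e-9)
  }
  v_expect <- mu + mu^2 / 2
  expect_equal(unname(apply(m, 2, var)), as.vector(v_expect), tolerance = 0.3)
})

test_that("config invariants are enforced", {
  expect_error(sc_sim_config(contaminant_states = 5, shared_states = 1:2),
               "subset")
  expect_error(sc_sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sc_sim_config(n_replicates_reference = 1), "replicates")
  expect_error(edu_sim_config(compartments = tibble::tibble(
    compartment = "x", cells = 10, label_prob = 1.5, rate = 1)), "label_prob")
  expect_error(edu_sim_config(chase_hours = -1), "chase_hours")
  expect_error(trial_config(n_control = 0), "at least one animal")
  expect_error(read_set_config(natural_indel_prevalence = 1.2), "fractions")
  expect_error(read_set_config(pam_position = 500, amplicon_length = 400),
               "outside the amplicon")
})

test_that("zero labeling probability yields all-zero EdU counts", {
  cfg <- edu_sim_config(n_animals = 10, compartments = tibble::tibble(
    compartment = "distal", cells = 100, label_prob = 0, rate = 1), seed = 6)
  d <- generate_edu_dataset(cfg)
  expect_true(all(d$pulse$edu_pos == 0))
  expect_true(all(d$chase$edu_pos == 0))
})

test_that("additive growth model reproduces the mean ratio 1 + r*t/24 (rate 0 gives 1)", {
  for (r in c(0, 1)) {
    cfg <- edu_sim_config(n_animals = 400, compartments = tibble::tibble(
      compartment = "midline", cells = 400, label_prob = 0.05, rate = r),
      chase_hours = 36, growth = "linear_plus_one", seed = 8)
    d <- generate_edu_dataset(cfg)
    ratio <- mean(d$chase$edu_pos) / mean(d$pulse$edu_pos)
    expect_equal(ratio, 1 + r * 36 / 24, tolerance = 0.05)
  }
})

test_that("trial generator plants effects as configured", {
  d0 <- generate_trial_counts(trial_config(n_trials = 6, n_control = 30,
                                           n_treatment = 30, seed = 9))
  m <- d0$trials |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(count))
  expect_equal(diff(m$m), 0, tolerance = 0.8) # no planted effect
  expect_true(all(d0$trials$count >= 0 & d0$trials$count == round(d0$trials$count)))

  d1 <- generate_trial_counts(trial_config(
    n_trials = 3, n_control = 20, n_treatment = 20,
    effect = list(type = "exceeder", value = 0.5), seed = 10))
  p <- exceedance_permutation_test(d1$trials, n_perm = 2000, seed = 1)$p
  expect_lt(p, 0.01)
})

test_that("read-set generator recovers configured prevalence within binomial CI", {
  cfg <- read_set_config(n_reads = 1500, natural_indel_prevalence = 0.67,
                         edit_rate = 0.17, seed = 12)
  rs <- generate_read_set(cfg)
  cls <- classify_natural_indel(rs$reads, weighting = "unique")
  ci_half <- 1.96 * sqrt(0.67 * 0.33 / 1500)
  expect_lt(abs(cls$prevalence - 0.67), ci_half + 0.01)

  # degenerate settings propagate exactly
  rs1 <- generate_read_set(read_set_config(n_reads = 200,
                                           natural_indel_prevalence = 1, seed = 1))
  expect_equal(classify_natural_indel(rs1$reads)$prevalence, 1)
  rs0 <- generate_read_set(read_set_config(n_reads = 200, edit_rate = 0, seed = 1))
  without <- classify_natural_indel(rs0$reads)$without
  expect_equal(mutagenesis_incidence(without, rs0$edits), 0)
})
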