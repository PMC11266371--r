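# fabricate an outcome whose cohort is a single diagnostic group
single_group_outcome <- function(params, true_state, amyloid, label,
                                 pathway = "SOC") {
  out <- evaluate_pathway(pathway, params)
  out$groups <- data.frame(true_state = true_state, amyloid = amyloid,
                           label = label, mass = 1, stringsAsFactors = FALSE)
  out
}

test_that("stage mortality combines the life-table rate with the hazard ratio", {
  expect_equal(combine_mortality(0.02, 1.0), 0.019801, tolerance = 1e-4)
  expect_equal(combine_mortality(0.0, 5.0), 0.0)
  expect_equal(combine_mortality(0.01, 1.82), 1 - exp(-0.0182))
  expect_equal(round(combine_mortality(0.01, 1.82), 6), 0.018035)
  expect_error(combine_mortality(-0.1, 1), class = "bbm_domain_error")
  expect_error(combine_mortality(0.1, -1), class = "bbm_domain_error")
})

test_that("treatment effect scales progression multiplicatively", {
  expect_equal(apply_treatment_effect(0.22, 0.27), 0.1606)
  expect_equal(apply_treatment_effect(0.22, 0), 0.22)
  expect_equal(apply_treatment_effect(0, 0.27), 0)
  expect_error(apply_treatment_effect(1.2, 0.1), class = "bbm_domain_error")
})

test_that("transition matrices are row-stochastic with an absorbing dead state", {
  p <- default_parameters()
  set.seed(99)
  for (i in 1:8) {
    f <- default_fixture_bundle()
    f$dementia_transitions <- generate_dementia_transition_fixture(
      seed = i, progression_level = runif(1, 0, 0.4),
      institutionalisation_level = runif(1, 0, 0.2),
      regression_level = runif(1, 0, 0.1))
    age <- sample(65:95, 1)
    amy <- sample(c("positive", "negative"), 1)
    eff <- runif(1, 0, 0.5)
    M <- build_transition_matrix(age, p, f, amy, eff)
    expect_equal(unname(rowSums(M)), rep(1, 13), tolerance = 1e-9)
    expect_true(all(M >= 0))
    expect_equal(unname(M["DEAD", ]), c(rep(0, 12), 1))
  }
})

test_that("certain death empties the pre-dementia states in one cycle", {
  p <- default_parameters()
  M <- build_transition_matrix(70, p, lethal_fixtures(), "positive", 0)
  for (s in c("SCD", "MCI", "MCI_T1", "MCI_T2")) {
    expect_equal(unname(M[s, "DEAD"]), 1)
    expect_equal(sum(M[s, colnames(M) != "DEAD"]), 0)
  }
})

test_that("a deathless two-state chain decays geometrically", {
  p <- single_mci_parameters(p_progress = 0.05)
  f <- immortal_fixtures()
  out <- evaluate_pathway("SOC", p)
  traj <- run_cohort(out, p, f)
  pooled <- apply(traj$occupancy, c(2, 3), sum)
  for (t in 0:30) {
    expect_equal(unname(pooled[t + 1, "MCI"]), 0.95^t, tolerance = 1e-12)
  }
  # with zero progression and zero mortality, occupancy is frozen
  p0 <- single_mci_parameters(p_progress = 0)
  traj0 <- run_cohort(evaluate_pathway("SOC", p0), p0, f)
  pooled0 <- apply(traj0$occupancy, c(2, 3), sum)
  for (t in 1:30) expect_equal(pooled0[t + 1, ], pooled0[1, ], tolerance = 1e-12)
})

test_that("cohort mass is conserved and death is monotone on the default bundle", {
  p <- default_parameters()
  f <- default_fixture_bundle()
  for (pw in c("SOC", "BBM_PHC")) {
    out <- evaluate_pathway(pw, p)
    traj <- run_cohort(out, p, f)
    for (g in seq_len(nrow(out$groups))) {
      sums <- rowSums(traj$occupancy[g, , ])
      expect_equal(sums, rep(out$groups$mass[g], 31), tolerance = 1e-9)
      expect_true(all(diff(traj$occupancy[g, , "DEAD"]) >= -1e-12))
    }
  }
})

test_that("treatment slows entry into dementia for responders only", {
  p <- default_parameters()
  f <- default_fixture_bundle()
  out <- single_group_outcome(p, "MCI", "positive", "AD_DIAGNOSED", "BBM_PHC")
  treated <- run_cohort(out, p, f)
  p0 <- p
  p0$treatment$effect <- 0
  untreated <- run_cohort(out, p0, f)
  mci_states <- c("MCI", "MCI_T1", "MCI_T2")
  for (t in 1:31) {
    expect_gte(sum(treated$occupancy[1, t, mci_states]),
               sum(untreated$occupancy[1, t, mci_states]) - 1e-12)
  }
  # strictly fewer have progressed by the end of treatment
  expect_gt(sum(treated$occupancy[1, 3, mci_states]),
            sum(untreated$occupancy[1, 3, mci_states]))
})

test_that("null treatment leaves trajectories identical to the untreated arm", {
  p <- default_parameters()
  f <- default_fixture_bundle()
  # effect = 0: every treated group equals its relabelled untreated twin
  p0 <- p
  p0$treatment$effect <- 0
  for (grp in list(c("MCI", "positive"), c("MILD_DEM", "positive"))) {
    tx <- run_cohort(single_group_outcome(p0, grp[1], grp[2], "AD_DIAGNOSED"),
                     p0, f)
    un <- run_cohort(single_group_outcome(p0, grp[1], grp[2], "NOT_AD"), p0, f)
    expect_equal(collapse_tunnels(tx), collapse_tunnels(un), tolerance = 1e-12)
  }
  # amyloid-negative treated (false positive) groups never respond
  tx <- run_cohort(single_group_outcome(p, "MCI", "negative", "AD_DIAGNOSED"),
                   p, f)
  un <- run_cohort(single_group_outcome(p, "MCI", "negative", "NOT_AD"), p, f)
  expect_equal(collapse_tunnels(tx), collapse_tunnels(un), tolerance = 1e-12)
})

test_that("higher stage hazard ratios bring death forward", {
  p <- default_parameters()
  f_lo <- default_fixture_bundle()
  f_lo$mortality_hrs <- generate_mortality_hr_fixture(step = 1)
  f_hi <- default_fixture_bundle()
  f_hi$mortality_hrs <- generate_mortality_hr_fixture(step = 1.8)
  out <- single_group_outcome(p, "MILD_DEM", "positive", "NOT_AD")
  dead_lo <- run_cohort(out, p, f_lo)$occupancy[1, , "DEAD"]
  dead_hi <- run_cohort(out, p, f_hi)$occupancy[1, , "DEAD"]
  expect_true(all(dead_hi[-1] >= dead_lo[-1]))
  expect_gt(dead_hi[15], dead_lo[15])
})

test_that("microsimulation is deterministic and converges on the cohort model", {
  p <- default_parameters()
  f <- default_fixture_bundle()
  out <- evaluate_pathway("SOC", p)
  one <- microsimulate(out, p, f, n_individuals = 1, seed = 3)
  expect_true(all(one$occupancy %in% c(0, 1)))
  ms1 <- microsimulate(out, p, f, n_individuals = 5000, seed = 5)
  ms2 <- microsimulate(out, p, f, n_individuals = 5000, seed = 5)
  expect_identical(ms1$occupancy, ms2$occupancy)
  ms3 <- microsimulate(out, p, f, n_individuals = 5000, seed = 6)
  expect_false(identical(ms1$occupancy, ms3$occupancy))

  traj <- run_cohort(out, p, f)
  ms <- microsimulate(out, p, f, n_individuals = 20000, seed = 7)
  expect_lt(max(abs(ms$occupancy - traj$occupancy)), 0.015)
})

test_that("median survival from mild dementia on F0 is epidemiologically plausible", {
  p <- default_parameters()
  f <- default_fixture_bundle()
  out <- single_group_outcome(p, "MILD_DEM", "positive", "NOT_AD")
  dead <- run_cohort(out, p, f)$occupancy[1, , "DEAD"]
  median_years <- which(dead >= 0.5)[1] - 1
  expect_gte(median_years, 3)
  expect_lte(median_years, 10)
})
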