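test_that("pathway evaluation agrees with the leaf-enumeration oracle", {
  for (dialect in c("text", "table1")) {
    p <- default_parameters(dialect)
    for (pw in c("SOC", "BBM_PHC", "BBM_MC")) {
      out <- evaluate_pathway(pw, p)
      ora <- oracle_pathway(pw, p)
      for (f in c("frac_referred", "frac_csf", "frac_tp", "frac_fp",
                  "frac_tn", "frac_fn")) {
        expect_equal(out[[f]], ora[[f]], tolerance = 1e-12, label = paste(pw, f))
      }
      expect_equal(out$diagnosis_cost_per_person, ora$diagnosis_cost,
                   tolerance = 1e-12)
      for (g in seq_len(nrow(out$groups))) {
        expect_equal(
          out$groups$mass[g],
          oracle_group_mass(ora, out$groups$true_state[g],
                            out$groups$amyloid[g], out$groups$label[g]),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("masses conserve and the confusion matrix closes for random inputs", {
  set.seed(42)
  for (i in 1:15) {
    p <- random_parameters()
    amypos <- with(p$population,
                   share_scd * amyloid_prev_scd + share_mci * amyloid_prev_mci +
                     share_mild_dem * amyloid_prev_dem)
    for (pw in c("SOC", "BBM_PHC", "BBM_MC")) {
      out <- evaluate_pathway(pw, p)
      expect_true(all(out$groups$mass >= 0))
      expect_equal(sum(out$groups$mass), 1, tolerance = 1e-9)
      expect_equal(out$frac_tp + out$frac_fn, amypos, tolerance = 1e-12)
      expect_equal(out$frac_tn + out$frac_fp, 1 - amypos, tolerance = 1e-12)
      expect_lte(out$frac_csf, out$frac_referred + 1e-12)
      expect_lte(out$frac_referred, 1)
      # oracle agreement as part of the property sweep
      ora <- oracle_pathway(pw, p)
      expect_equal(out$frac_tp, ora$frac_tp, tolerance = 1e-12)
      expect_equal(out$diagnosis_cost_per_person, ora$diagnosis_cost,
                   tolerance = 1e-12)
    }
    # BBM triage at the clinic can only reduce CSF examinations
    expect_lte(evaluate_pathway("BBM_MC", p)$frac_csf,
               evaluate_pathway("SOC", p)$frac_csf + 1e-12)
  }
})

test_that("false positives fall and true positives rise with test accuracy", {
  p <- default_parameters()
  grid <- c(0.5, 0.7, 0.9)
  for (pw in c("BBM_PHC", "BBM_MC")) {
    fp_bbm <- vapply(grid, function(v) {
      evaluate_pathway(pw, apply_param_value(p, "accuracy.bbm_specificity", v))$frac_fp
    }, numeric(1))
    expect_true(all(diff(fp_bbm) <= 1e-12))
    fp_csf <- vapply(grid, function(v) {
      evaluate_pathway(pw, apply_param_value(p, "accuracy.csf_specificity", v))$frac_fp
    }, numeric(1))
    expect_true(all(diff(fp_csf) <= 1e-12))
    tp_bbm <- vapply(grid, function(v) {
      evaluate_pathway(pw, apply_param_value(p, "accuracy.bbm_sensitivity", v))$frac_tp
    }, numeric(1))
    expect_true(all(diff(tp_bbm) >= -1e-12))
    tp_csf <- vapply(grid, function(v) {
      evaluate_pathway(pw, apply_param_value(p, "accuracy.csf_sensitivity", v))$frac_tp
    }, numeric(1))
    expect_true(all(diff(tp_csf) >= -1e-12))
  }
})

test_that("perfect tests leave only never-tested SCD misclassified", {
  p <- default_parameters()
  for (nm in names(p$accuracy)) p$accuracy[[nm]] <- 1
  out <- evaluate_pathway("BBM_PHC", p)
  expect_equal(out$frac_fp, 0)
  expect_equal(out$frac_fn,
               p$population$share_scd * p$population$amyloid_prev_scd)
})

test_that("diagnosis cost is linear in its inputs and checks pathway identity", {
  p <- default_parameters()
  out <- evaluate_pathway("SOC", p)
  zero <- p$costs
  for (nm in names(zero)) zero[[nm]] <- 0
  expect_equal(diagnosis_cost("SOC", out, zero)$total, 0)
  expect_error(diagnosis_cost("BBM_PHC", out, p$costs),
               class = "bbm_validation_error")
  expect_error(evaluate_pathway("PETSCAN", p), class = "bbm_validation_error")
  # components always add to the total
  for (pw in c("SOC", "BBM_PHC", "BBM_MC")) {
    o <- evaluate_pathway(pw, p)
    expect_equal(sum(o$cost_components), o$diagnosis_cost_per_person,
                 tolerance = 1e-12)
  }
})

test_that("pathway comparison differences and population scaling behave", {
  p <- default_parameters()
  soc <- evaluate_pathway("SOC", p)
  self <- compare_pathways(soc, soc)
  expect_true(all(self$difference == 0))

  phc <- evaluate_pathway("BBM_PHC", p)
  diff <- compare_pathways(soc, phc)
  ref_row <- diff[diff$metric == "frac_referred", ]
  expect_equal(round(ref_row$difference, 3), 0.080)

  scaled <- population_scale(diff, 10000)
  expect_equal(scaled$difference[scaled$metric == "frac_referred"],
               ref_row$difference * 10000)
  cost_row <- scaled[scaled$metric == "diagnosis_cost", ]
  expect_equal(cost_row$difference,
               diff$difference[diff$metric == "diagnosis_cost"] * 10000)
  expect_true(all(population_scale(diff, 0)$difference == 0))
  expect_error(population_scale(diff, -5), class = "bbm_domain_error")
})
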