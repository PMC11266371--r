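# Brute-force decision-tree oracle: enumerates every leaf of each diagnostic
# pathway (true state x amyloid x referral x BBM result x CSF result) with an
# explicit probability product and per-leaf cost accounting, independently of
# the package's aggregated algebra.

oracle_pathway <- function(pathway, params) {
  pop <- params$population
  acc <- params$accuracy
  pol <- params$policy
  costs <- params$costs

  shares <- list(SCD = pop$share_scd, MCI = pop$share_mci,
                 MILD_DEM = pop$share_mild_dem)
  prev <- list(SCD = pop$amyloid_prev_scd, MCI = pop$amyloid_prev_mci,
               MILD_DEM = pop$amyloid_prev_dem)
  phc_cost <- list(SCD = costs$phc_cost_scd, MCI = costs$phc_cost_mci,
                   MILD_DEM = costs$phc_cost_dem)

  leaves <- list()
  add <- function(prob, state, amy, label, referred, bbm, csf) {
    cost <- phc_cost[[state]]
    if (bbm) cost <- cost + costs$bbm_test
    if (pathway == "BBM_MC") {
      if (referred) cost <- cost + costs$mc_visit
      if (csf) cost <- cost + (costs$csf_exam_incl_mc_visit - costs$mc_visit)
    } else {
      if (csf) cost <- cost + costs$csf_exam_incl_mc_visit
    }
    leaves[[length(leaves) + 1L]] <<- data.frame(
      prob = prob, state = state, amy = amy, label = label,
      referred = referred, bbm = bbm, csf = csf, cost = cost,
      stringsAsFactors = FALSE)
  }

  for (state in c("SCD", "MCI", "MILD_DEM")) {
    for (amy in c("positive", "negative")) {
      m <- shares[[state]] * if (amy == "positive") prev[[state]] else 1 - prev[[state]]
      p_cp <- if (amy == "positive") acc$csf_sensitivity else 1 - acc$csf_specificity
      p_bp <- if (amy == "positive") acc$bbm_sensitivity else 1 - acc$bbm_specificity
      if (state == "SCD") {
        add(m, state, amy, "NOT_AD", FALSE, FALSE, FALSE)
      } else if (pathway == "SOC") {
        r <- pol$soc_referral_rate
        add(m * r * p_cp, state, amy, "AD_DIAGNOSED", TRUE, FALSE, TRUE)
        add(m * r * (1 - p_cp), state, amy, "NOT_AD", TRUE, FALSE, TRUE)
        add(m * (1 - r), state, amy, "NOT_AD", FALSE, FALSE, FALSE)
      } else if (pathway == "BBM_PHC") {
        rr <- pol$bbm_positive_referral_rate
        add(m * p_bp * rr * p_cp, state, amy, "AD_DIAGNOSED", TRUE, TRUE, TRUE)
        add(m * p_bp * rr * (1 - p_cp), state, amy, "NOT_AD", TRUE, TRUE, TRUE)
        add(m * p_bp * (1 - rr), state, amy, "NOT_AD", FALSE, TRUE, FALSE)
        add(m * (1 - p_bp), state, amy, "NOT_AD", FALSE, TRUE, FALSE)
      } else if (pathway == "BBM_MC") {
        r <- pol$soc_referral_rate
        add(m * r * p_bp * p_cp, state, amy, "AD_DIAGNOSED", TRUE, TRUE, TRUE)
        add(m * r * p_bp * (1 - p_cp), state, amy, "NOT_AD", TRUE, TRUE, TRUE)
        add(m * r * (1 - p_bp), state, amy, "NOT_AD", TRUE, TRUE, FALSE)
        add(m * (1 - r), state, amy, "NOT_AD", FALSE, FALSE, FALSE)
      }
    }
  }
  leaves <- do.call(rbind, leaves)

  pos <- leaves$amy == "positive"
  ad <- leaves$label == "AD_DIAGNOSED"
  list(
    leaves = leaves,
    frac_referred = sum(leaves$prob[leaves$referred]),
    frac_csf = sum(leaves$prob[leaves$csf]),
    frac_tp = sum(leaves$prob[pos & ad]),
    frac_fp = sum(leaves$prob[!pos & ad]),
    frac_tn = sum(leaves$prob[!pos & !ad]),
    frac_fn = sum(leaves$prob[pos & !ad]),
    diagnosis_cost = sum(leaves$prob * leaves$cost)
  )
}

# group masses from oracle leaves, aggregated to (state, amyloid, label)
oracle_group_mass <- function(oracle, state, amy, label) {
  l <- oracle$leaves
  sum(l$prob[l$state == state & l$amy == amy & l$label == label])
}

# random but valid parameter sets for property tests
random_parameters <- function() {
  p <- default_parameters()
  s <- runif(3)
  s <- s / sum(s)
  p$population$share_scd <- s[1]
  p$population$share_mci <- s[2]
  p$population$share_mild_dem <- s[3]
  p$population$amyloid_prev_scd <- runif(1, 0.05, 0.6)
  p$population$amyloid_prev_mci <- runif(1, 0.2, 0.8)
  p$population$amyloid_prev_dem <- runif(1, 0.5, 0.95)
  p$accuracy$bbm_sensitivity <- runif(1, 0.5, 1)
  p$accuracy$bbm_specificity <- runif(1, 0.5, 1)
  p$accuracy$csf_sensitivity <- runif(1, 0.5, 1)
  p$accuracy$csf_specificity <- runif(1, 0.5, 1)
  p$policy$soc_referral_rate <- runif(1)
  validate_parameters(p)
}

# a parameter set whose cohort is a single untreated amyloid-negative MCI
# group under SOC (no referral), for closed-form Markov checks
single_mci_parameters <- function(p_progress = 0.05) {
  p <- default_parameters()
  p$population$share_scd <- 0
  p$population$share_mci <- 1
  p$population$share_mild_dem <- 0
  p$population$amyloid_prev_mci <- 0
  p$policy$soc_referral_rate <- 0
  p$natural_history$p_mci_to_mild_amyneg <- p_progress
  validate_parameters(p)
}

# fixture bundle with no background mortality and an identity dementia block
immortal_fixtures <- function() {
  f <- default_fixture_bundle()
  f$life_table <- generate_life_table(a = 0, b = 0.11, ages = 60:110)
  f$dementia_transitions <- generate_dementia_transition_fixture(
    seed = 1, progression_level = 0, institutionalisation_level = 0,
    regression_level = 0)
  f
}

# fixture bundle with certain death at every age
lethal_fixtures <- function() {
  f <- default_fixture_bundle()
  f$life_table <- structure(data.frame(age = 60:110, q = 1),
                            class = c("bbm_life_table", "data.frame"))
  f
}
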