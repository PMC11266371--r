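# Markov cohort engine. Nine health states (SCD, MCI, mild/moderate/severe
# dementia in the community or institutionalised, dead) plus tunnel copies
# of MCI and mild dementia that track the year on disease-modifying
# treatment, so that a memoryless chain can express "treatment for two years
# or until progression to moderate dementia".

STATES <- c("SCD", "MCI", "MCI_T1", "MCI_T2",
            "MILD", "MILD_T1", "MILD_T2",
            "MODERATE", "SEVERE",
            "MILD_LTC", "MODERATE_LTC", "SEVERE_LTC", "DEAD")
BASE_STATES <- c("SCD", "MCI", "MILD", "MODERATE", "SEVERE",
                 "MILD_LTC", "MODERATE_LTC", "SEVERE_LTC", "DEAD")
TUNNEL_STATES <- c("MCI_T1", "MCI_T2", "MILD_T1", "MILD_T2")

# map every extended state onto its underlying health state
base_state_of <- c(
  SCD = "SCD", MCI = "MCI", MCI_T1 = "MCI", MCI_T2 = "MCI",
  MILD = "MILD", MILD_T1 = "MILD", MILD_T2 = "MILD",
  MODERATE = "MODERATE", SEVERE = "SEVERE",
  MILD_LTC = "MILD_LTC", MODERATE_LTC = "MODERATE_LTC",
  SEVERE_LTC = "SEVERE_LTC", DEAD = "DEAD"
)

#' Combine background mortality with a disease-stage hazard ratio
#'
#' Annual probability of death for a disease stage:
#' `1 - exp(-q_age * hr)`, treating the age-specific annual death
#' probability as a rate that the stage hazard ratio multiplies.
#'
#' @param q_age age-specific annual death probability in \[0, 1\].
#' @param hr hazard ratio of death for the disease stage (>= 0).
#' @return annual death probability for the stage.
#' @export
#' @examples
#' combine_mortality(0.01, 1.82)
combine_mortality <- function(q_age, hr) {
  if (any(q_age < 0 | q_age > 1)) bbm_domain_error("'q_age' must lie in [0, 1]")
  if (any(hr < 0)) bbm_domain_error("'hr' must be non-negative")
  1 - exp(-q_age * hr)
}

#' Apply the disease-modifying treatment effect to a progression probability
#'
#' The treatment reduces the annual progression probability by a fixed
#' fraction; the removed mass stays in the current state.
#'
#' @param base_progression annual progression probability in \[0, 1\].
#' @param effect fractional reduction in \[0, 1\].
#' @return `base_progression * (1 - effect)`.
#' @export
apply_treatment_effect <- function(base_progression, effect) {
  if (any(base_progression < 0 | base_progression > 1)) {
    bbm_domain_error("'base_progression' must lie in [0, 1]")
  }
  if (any(effect < 0 | effect > 1)) bbm_domain_error("'effect' must lie in [0, 1]")
  base_progression * (1 - effect)
}

#' Build the annual transition matrix at one age
#'
#' Competing risks are resolved death-first: each state's annual death
#' probability is applied, and all non-death transition probabilities are
#' scaled by the surviving fraction so rows stay stochastic. Pre-dementia
#' progression is amyloid specific; the dementia block comes from the
#' fixture bundle and is identical for both amyloid groups; SCD and MCI use
#' the raw life-table death probability (hazard ratio 1) while dementia
#' states combine it with their stage hazard ratio. A non-zero `effect`
#' reduces progression out of the MCI and mild tunnel states
#' (MCI -> mild, mild -> moderate) while on treatment.
#'
#' @param age age in years (must be covered by the life table).
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param amyloid `"positive"` or `"negative"`.
#' @param effect treatment effect applied in the tunnel states (0 for
#'   untreated or non-responding groups).
#' @return 13 x 13 row-stochastic matrix over the extended state space.
#' @export
build_transition_matrix <- function(age, params, fixtures,
                                    amyloid = c("positive", "negative"),
                                    effect = 0) {
  amyloid <- match.arg(amyloid)
  validate_fixtures(fixtures)
  q <- life_table_q(fixtures$life_table, age)
  nh <- params$natural_history
  pos <- amyloid == "positive"
  p_scd <- if (pos) nh$p_scd_to_mci_amypos else nh$p_scd_to_mci_amyneg
  p_mci <- if (pos) nh$p_mci_to_mild_amypos else nh$p_mci_to_mild_amyneg

  M <- matrix(0, 13, 13, dimnames = list(STATES, STATES))
  M["DEAD", "DEAD"] <- 1

  M["SCD", "DEAD"] <- q
  M["SCD", "MCI"] <- (1 - q) * p_scd
  M["SCD", "SCD"] <- (1 - q) * (1 - p_scd)

  M["MCI", "DEAD"] <- q
  M["MCI", "MILD"] <- (1 - q) * p_mci
  M["MCI", "MCI"] <- (1 - q) * (1 - p_mci)

  p_mci_tx <- apply_treatment_effect(p_mci, effect)
  # year 1 on treatment: progression continues treatment in mild (year 2)
  M["MCI_T1", "DEAD"] <- q
  M["MCI_T1", "MILD_T2"] <- (1 - q) * p_mci_tx
  M["MCI_T1", "MCI_T2"] <- (1 - q) * (1 - p_mci_tx)
  # year 2 on treatment: any exit is to untreated states
  M["MCI_T2", "DEAD"] <- q
  M["MCI_T2", "MILD"] <- (1 - q) * p_mci_tx
  M["MCI_T2", "MCI"] <- (1 - q) * (1 - p_mci_tx)

  dt <- fixtures$dementia_transitions
  hrs <- fixtures$mortality_hrs
  for (s in DEM_STATES) {
    pd <- combine_mortality(q, hrs[[s]])
    M[s, DEM_STATES] <- (1 - pd) * dt[s, ]
    M[s, "DEAD"] <- pd
  }

  # treated mild dementia: reduce mild -> moderate progression (either care
  # setting); institutionalisation or progression ends the treatment tunnel
  mild_row <- dt["MILD", ]
  reduced <- mild_row
  reduced["MODERATE"] <- apply_treatment_effect(mild_row[["MODERATE"]], effect)
  reduced["MODERATE_LTC"] <- apply_treatment_effect(mild_row[["MODERATE_LTC"]], effect)
  reduced["MILD"] <- mild_row[["MILD"]] +
    (mild_row[["MODERATE"]] - reduced[["MODERATE"]]) +
    (mild_row[["MODERATE_LTC"]] - reduced[["MODERATE_LTC"]])
  pd_mild <- combine_mortality(q, hrs[["MILD"]])
  other <- setdiff(DEM_STATES, "MILD")
  M["MILD_T1", "DEAD"] <- pd_mild
  M["MILD_T1", other] <- (1 - pd_mild) * reduced[other]
  M["MILD_T1", "MILD_T2"] <- (1 - pd_mild) * reduced[["MILD"]]
  M["MILD_T2", "DEAD"] <- pd_mild
  M["MILD_T2", other] <- (1 - pd_mild) * reduced[other]
  M["MILD_T2", "MILD"] <- (1 - pd_mild) * reduced[["MILD"]]

  M
}

group_effect <- function(group_label, amyloid, treatment) {
  if (!identical(group_label, "AD_DIAGNOSED")) return(0)
  responder <- if (amyloid == "positive") {
    treatment$responder_fraction_amypos
  } else {
    treatment$responder_fraction_amyneg
  }
  treatment$effect * responder
}

group_start_state <- function(true_state, label) {
  treated <- identical(label, "AD_DIAGNOSED")
  switch(true_state,
    SCD = "SCD",
    MCI = if (treated) "MCI_T1" else "MCI",
    MILD_DEM = if (treated) "MILD_T1" else "MILD",
    bbm_validation_error(sprintf("unknown true state '%s'", true_state))
  )
}

#' Run the Markov cohort simulation for every diagnostic group
#'
#' Each of the ten diagnostic groups starts in its true health state at the
#' model start age (treated groups start in the first treatment tunnel) and
#' is propagated through age-specific annual transition matrices over the
#' model horizon. Treatment effect applies only to amyloid-positive treated
#' groups; amyloid-negative treated (false-positive) groups occupy the
#' tunnels — and accrue drug cost — without clinical benefit.
#'
#' @param outcome a `bbm_outcome` from [evaluate_pathway()].
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @return object of class `bbm_trajectory`: array `occupancy` of dimension
#'   groups x (horizon + 1) x 13 states holding cohort fractions, plus the
#'   group table and ages per cycle.
#' @export
run_cohort <- function(outcome, params, fixtures) {
  validate_parameters(params)
  validate_fixtures(fixtures)
  groups <- outcome$groups
  H <- as.integer(params$econ$horizon)
  ages <- params$econ$start_age + 0:(H - 1)
  rng <- range(fixtures$life_table$age)
  if (params$econ$start_age < rng[1] || params$econ$start_age + H - 1 > rng[2]) {
    bbm_domain_error("model horizon exceeds the life table's age range")
  }

  eff <- mapply(group_effect, groups$label, groups$amyloid,
                MoreArgs = list(treatment = params$treatment))
  keys <- paste(groups$amyloid, signif(eff, 12), sep = "|")
  mats <- list()
  for (k in unique(keys)) {
    i <- match(k, keys)
    mats[[k]] <- lapply(ages, build_transition_matrix, params = params,
                        fixtures = fixtures, amyloid = groups$amyloid[i],
                        effect = eff[i])
  }

  occ <- array(0, dim = c(nrow(groups), H + 1, length(STATES)),
               dimnames = list(NULL, NULL, STATES))
  for (g in seq_len(nrow(groups))) {
    v <- setNames(numeric(length(STATES)), STATES)
    v[group_start_state(groups$true_state[g], groups$label[g])] <- groups$mass[g]
    occ[g, 1, ] <- v
    for (t in seq_len(H)) {
      v <- drop(v %*% mats[[keys[g]]][[t]])
      occ[g, t + 1, ] <- v
    }
  }
  structure(
    list(occupancy = occ, groups = groups, ages = params$econ$start_age + 0:H,
         pathway = outcome$pathway),
    class = "bbm_trajectory"
  )
}

#' Aggregate a trajectory's tunnel states onto the nine base states
#'
#' @param trajectory a `bbm_trajectory`.
#' @return array groups x cycles x 9 base states.
#' @export
collapse_tunnels <- function(trajectory) {
  occ <- trajectory$occupancy
  out <- array(0, dim = c(dim(occ)[1], dim(occ)[2], length(BASE_STATES)),
               dimnames = list(NULL, NULL, BASE_STATES))
  for (s in STATES) {
    b <- base_state_of[[s]]
    out[, , b] <- out[, , b] + occ[, , s]
  }
  out
}

#' Individual-level microsimulation of the same model
#'
#' Verification oracle for [run_cohort()]: simulates `n_individuals` annual
#' state paths with the same transition matrices and returns the estimated
#' occupancy in the same layout (fractions of the total simulated
#' population, so the estimate converges to the cohort-matrix occupancy
#' with Monte-Carlo error of order `n^(-1/2)`). Deterministic given `seed`.
#'
#' @param outcome a `bbm_outcome` from [evaluate_pathway()].
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param n_individuals number of simulated individuals (>= 1), allocated to
#'   diagnostic groups by largest remainder of the group masses.
#' @param seed integer seed.
#' @return object of class `bbm_trajectory` with an additional
#'   `n_individuals` field.
#' @export
microsimulate <- function(outcome, params, fixtures, n_individuals, seed) {
  if (n_individuals < 1) bbm_domain_error("'n_individuals' must be >= 1")
  groups <- outcome$groups
  H <- as.integer(params$econ$horizon)
  ages <- params$econ$start_age + 0:(H - 1)

  # largest-remainder allocation of individuals to groups
  target <- groups$mass * n_individuals
  n_g <- floor(target)
  short <- n_individuals - sum(n_g)
  if (short > 0) {
    order_rem <- order(target - n_g, decreasing = TRUE)
    n_g[order_rem[seq_len(short)]] <- n_g[order_rem[seq_len(short)]] + 1
  }

  eff <- mapply(group_effect, groups$label, groups$amyloid,
                MoreArgs = list(treatment = params$treatment))
  keys <- paste(groups$amyloid, signif(eff, 12), sep = "|")
  mats <- list()
  for (k in unique(keys)) {
    i <- match(k, keys)
    mats[[k]] <- lapply(ages, build_transition_matrix, params = params,
                        fixtures = fixtures, amyloid = groups$amyloid[i],
                        effect = eff[i])
  }

  occ <- array(0, dim = c(nrow(groups), H + 1, length(STATES)),
               dimnames = list(NULL, NULL, STATES))
  with_private_seed(seed, {
    for (g in seq_len(nrow(groups))) {
      if (n_g[g] == 0) next
      state <- rep(match(group_start_state(groups$true_state[g], groups$label[g]),
                         STATES), n_g[g])
      occ[g, 1, ] <- tabulate(state, nbins = length(STATES))
      for (t in seq_len(H)) {
        M <- mats[[keys[g]]][[t]]
        new_state <- state
        for (s in unique(state)) {
          idx <- which(state == s)
          new_state[idx] <- sample.int(length(STATES), length(idx),
                                       replace = TRUE, prob = M[s, ])
        }
        state <- new_state
        occ[g, t + 1, ] <- tabulate(state, nbins = length(STATES))
      }
    }
  })
  structure(
    list(occupancy = occ / n_individuals, groups = groups,
         ages = params$econ$start_age + 0:H, pathway = outcome$pathway,
         n_individuals = n_individuals, seed = seed),
    class = "bbm_trajectory"
  )
}
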