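# Economic valuation: converts state occupancy into discounted costs,
# life years and QALYs, and incremental comparisons between strategies.

#' Discount factor at an annual rate
#'
#' @param rate annual discount rate (fraction per year, >= 0).
#' @param t cycle index (years from model start, >= 0); cycle 0 is
#'   undiscounted.
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  if (any(rate < 0)) bbm_domain_error("'rate' must be non-negative")
  if (any(t < 0)) bbm_domain_error("'t' must be non-negative")
  (1 + rate)^(-t)
}

state_cost_vector <- function(costs) {
  c(SCD = costs$state_scd,
    MCI = costs$state_mci, MCI_T1 = costs$state_mci, MCI_T2 = costs$state_mci,
    MILD = costs$state_mild, MILD_T1 = costs$state_mild, MILD_T2 = costs$state_mild,
    MODERATE = costs$state_moderate, SEVERE = costs$state_severe,
    MILD_LTC = costs$state_mild_ltc, MODERATE_LTC = costs$state_moderate_ltc,
    SEVERE_LTC = costs$state_severe_ltc, DEAD = 0)[STATES]
}

state_utility_vector <- function(utilities, amyloid) {
  u_scd <- if (amyloid == "positive") utilities$u_scd_amypos else utilities$u_scd_amyneg
  u_mci <- if (amyloid == "positive") utilities$u_mci_amypos else utilities$u_mci_amyneg
  c(SCD = u_scd, MCI = u_mci, MCI_T1 = u_mci, MCI_T2 = u_mci,
    MILD = utilities$u_mild, MILD_T1 = utilities$u_mild, MILD_T2 = utilities$u_mild,
    MODERATE = utilities$u_moderate, SEVERE = utilities$u_severe,
    MILD_LTC = utilities$u_mild, MODERATE_LTC = utilities$u_moderate,
    SEVERE_LTC = utilities$u_severe, DEAD = 0)[STATES]
}

#' Accrue discounted costs, life years and QALYs over a trajectory
#'
#' Per cycle, disease cost is occupancy times the annual state cost (SCD is
#' costed as MCI; institutionalised states carry their long-term-care
#' costs), treatment cost is the occupancy of active treatment tunnels times
#' the annual drug price, and utility is occupancy times the state utility
#' (pre-dementia utilities split by amyloid status, dementia utilities by
#' stage; institutionalised states reuse their stage's community utility).
#' By default state membership at the start of each cycle accrues that full
#' cycle's cost and utility; `params$econ$half_cycle = TRUE` switches to a
#' half-cycle (trapezoidal) correction. The decision tree's per-person
#' diagnosis cost is added undiscounted at cycle 0.
#'
#' @param trajectory a `bbm_trajectory` from [run_cohort()].
#' @param outcome the `bbm_outcome` the trajectory was built from.
#' @param params a `bbm_parameters` object.
#' @return object of class `bbm_econ` with `total_cost`, `diagnosis_cost`,
#'   `disease_cost`, `dmt_cost`, `life_years`, `qalys`, discounted
#'   `dmt_tunnel_years`, and undiscounted expected `time_in_state`.
#' @export
accrue <- function(trajectory, outcome, params) {
  if (!identical(trajectory$pathway, outcome$pathway)) {
    bbm_validation_error("trajectory and outcome come from different pathways")
  }
  occ <- trajectory$occupancy
  H <- dim(occ)[2] - 1L
  econ <- params$econ
  half_cycle <- isTRUE(econ$half_cycle)

  cost_vec <- state_cost_vector(params$costs)
  dmt_vec <- as.numeric(STATES %in% TUNNEL_STATES)
  alive_vec <- as.numeric(STATES != "DEAD")

  # occupancy summed over groups, but utilities depend on the group's
  # amyloid status, so keep the utility-weighted sum per group
  pooled <- apply(occ, c(2, 3), sum)
  uw <- matrix(0, H + 1, 1)
  for (g in seq_len(dim(occ)[1])) {
    u_vec <- state_utility_vector(params$utilities, trajectory$groups$amyloid[g])
    uw <- uw + occ[g, , ] %*% u_vec
  }

  if (half_cycle) {
    tt <- 0:H
    w <- c(0.5, rep(1, H - 1), 0.5)
  } else {
    tt <- 0:(H - 1)
    w <- rep(1, H)
  }
  wc <- w * discount_factor(econ$discount_rate_costs, tt)
  we <- w * discount_factor(econ$discount_rate_effects, tt)
  rows <- tt + 1L

  disease_cost <- sum(wc * (pooled[rows, , drop = FALSE] %*% cost_vec))
  dmt_tunnel_years <- sum(wc * (pooled[rows, , drop = FALSE] %*% dmt_vec))
  dmt_cost <- dmt_tunnel_years * params$treatment$annual_cost
  qalys <- sum(we * uw[rows, 1])
  life_years <- sum(we * (pooled[rows, , drop = FALSE] %*% alive_vec))

  time_in_state <- setNames(numeric(length(BASE_STATES)), BASE_STATES)
  undisc <- colSums(pooled[seq_len(H), , drop = FALSE])
  for (s in STATES) {
    b <- base_state_of[[s]]
    time_in_state[b] <- time_in_state[b] + undisc[[s]]
  }

  diagnosis_cost <- outcome$diagnosis_cost_per_person
  structure(
    list(
      total_cost = diagnosis_cost + disease_cost + dmt_cost,
      diagnosis_cost = diagnosis_cost,
      disease_cost = disease_cost,
      dmt_cost = dmt_cost,
      dmt_tunnel_years = dmt_tunnel_years,
      life_years = life_years,
      qalys = qalys,
      time_in_state = time_in_state,
      pathway = trajectory$pathway
    ),
    class = "bbm_econ"
  )
}

#' Incremental cost-effectiveness of an intervention versus a reference
#'
#' Computes incremental cost and QALYs (intervention minus reference), the
#' ICER where defined, the cost-effectiveness-plane quadrant, and a decision
#' at the willingness-to-pay threshold. In the northeast quadrant the
#' intervention is cost-effective when the ICER does not exceed the
#' threshold; in the southwest quadrant (cheaper but less effective) the
#' interpretation follows the convention that an ICER at or above the
#' threshold favours the reference strategy.
#'
#' @param reference a `bbm_econ` result for the comparator.
#' @param intervention a `bbm_econ` result for the strategy under study.
#' @param wtp willingness to pay per QALY (euros).
#' @return object of class `bbm_ce` with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when `delta_qaly` is 0), `quadrant` (NE/SE/SW/NW) and
#'   `decision_at_wtp`.
#' @export
compute_icer <- function(reference, intervention, wtp) {
  if (wtp <= 0) bbm_domain_error("'wtp' must be positive")
  dc <- intervention$total_cost - reference$total_cost
  dq <- intervention$qalys - reference$qalys
  icer <- if (dq == 0) NA_real_ else dc / dq
  quadrant <- if (dq > 0 && dc > 0) "NE"
  else if (dq > 0) "SE"
  else if (dq < 0 && dc < 0) "SW"
  else if (dq < 0) "NW"
  else if (dc > 0) "NW" else if (dc < 0) "SE" else "NE"
  decision <- if (is.na(icer)) {
    if (dc < 0) "dominant" else if (dc > 0) "dominated" else "cost_effective"
  } else {
    switch(quadrant,
      NE = if (icer <= wtp) "cost_effective" else "not_cost_effective",
      SE = "dominant",
      NW = "dominated",
      SW = if (icer >= wtp) "not_cost_effective" else "cost_effective"
    )
  }
  structure(
    list(delta_cost = dc, delta_qaly = dq, icer = icer,
         quadrant = quadrant, decision_at_wtp = decision, wtp = wtp),
    class = "bbm_ce"
  )
}

#' Run one diagnostic strategy end to end
#'
#' Decision tree, Markov cohort simulation and economic accrual for one
#' pathway.
#'
#' @param pathway one of `"SOC"`, `"BBM_PHC"`, `"BBM_MC"`.
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @return list (class `bbm_strategy`) with `outcome`, `trajectory`, `econ`.
#' @export
run_strategy <- function(pathway, params, fixtures) {
  outcome <- evaluate_pathway(pathway, params)
  trajectory <- run_cohort(outcome, params, fixtures)
  econ <- accrue(trajectory, outcome, params)
  structure(list(pathway = pathway, outcome = outcome,
                 trajectory = trajectory, econ = econ),
            class = "bbm_strategy")
}

#' Compare two diagnostic strategies
#'
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param intervention pathway evaluated against the reference.
#' @param reference comparator pathway (default standard of care).
#' @param wtp willingness to pay per QALY; defaults to the parameter set's.
#' @return list (class `bbm_comparison`) with both `bbm_strategy` runs, the
#'   intermediate-outcome difference table and the `bbm_ce` result.
#' @export
compare_strategies <- function(params, fixtures, intervention = "BBM_PHC",
                               reference = "SOC", wtp = NULL) {
  wtp <- wtp %||% params$econ$wtp
  ref <- run_strategy(reference, params, fixtures)
  int <- run_strategy(intervention, params, fixtures)
  structure(
    list(
      reference = ref, intervention = int,
      diff_table = compare_pathways(ref$outcome, int$outcome),
      ce = compute_icer(ref$econ, int$econ, wtp)
    ),
    class = "bbm_comparison"
  )
}

#' Value-based price threshold for the disease-modifying treatment
#'
#' Finds the annual treatment price at which the ICER of the intervention
#' pathway versus the reference equals the willingness-to-pay threshold.
#' Incremental QALYs do not depend on the price and incremental cost is
#' linear in it, so the ICER is strictly monotone in price; the root is
#' located with `uniroot` to a tolerance of well under one euro of ICER.
#'
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param wtp willingness to pay per QALY; defaults to the parameter set's.
#' @param intervention,reference the pathways compared.
#' @return the annual price (euros per treatment year). Errors with class
#'   `bbm_no_solution` when the intervention gains no QALYs or is already
#'   above the threshold at price zero.
#' @export
price_threshold <- function(params, fixtures, wtp = NULL,
                            intervention = "BBM_PHC", reference = "SOC") {
  wtp <- wtp %||% params$econ$wtp
  base <- compare_strategies(params, fixtures, intervention, reference, wtp)
  dq <- base$ce$delta_qaly
  if (dq <= 0) {
    bbm_stop("intervention gains no QALYs; no positive price satisfies the threshold",
             "bbm_no_solution")
  }
  p0 <- params$treatment$annual_cost
  d_tunnel <- base$intervention$econ$dmt_tunnel_years -
    base$reference$econ$dmt_tunnel_years
  dc0 <- base$ce$delta_cost - d_tunnel * p0 # incremental cost at price 0
  icer_at <- function(price) (dc0 + d_tunnel * price) / dq
  if (d_tunnel <= 0) {
    bbm_stop("intervention does not add treatment exposure; ICER is not increasing in price",
             "bbm_no_solution")
  }
  f <- function(price) icer_at(price) - wtp
  if (f(0) > 0) {
    if (f(0) < 1) return(0) # boundary: threshold already met at price zero
    bbm_stop("ICER exceeds the threshold even at price zero", "bbm_no_solution")
  }
  hi <- 1e4
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) < 0) bbm_stop("no price below 1e9 reaches the threshold", "bbm_no_solution")
  root <- uniroot(f, lower = 0, upper = hi, tol = 1e-6)$root
  root
}
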