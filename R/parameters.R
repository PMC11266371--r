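#' Default model parameters
#'
#' Builds the complete parameter registry of the base-case analysis: economic
#' settings, cohort composition, test accuracies, referral policy, natural
#' history, treatment, costs and utilities. Two published sets of amyloid
#' prevalence figures circulate for the same model (the input table prints
#' 0.555/0.84 for MCI/dementia while the accompanying text quotes
#' 54.8%/84.1%); both are exposed as parameter "dialects" because different
#' printed result cells are reproducible only under one or the other.
#'
#' @param dialect `"text"` (default; amyloid prevalence 0.548/0.841 for
#'   MCI/dementia) or `"table1"` (0.555/0.84).
#' @return A validated parameter set (class `bbm_parameters`): a named list
#'   with components `econ`, `population`, `accuracy`, `policy`,
#'   `natural_history`, `treatment`, `costs`, `utilities`, `distributions`
#'   and `dialect`.
#' @seealso [load_parameters()] to read a configuration file,
#'   [parameter_table()] for a flat export.
#' @export
#' @examples
#' p <- default_parameters()
#' p$accuracy$bbm_sensitivity
default_parameters <- function(dialect = c("text", "table1")) {
  dialect <- match.arg(dialect)
  prev_mci <- if (dialect == "table1") 0.555 else 0.548
  prev_dem <- if (dialect == "table1") 0.840 else 0.841
  params <- list(
    schema_version = 1L,
    dialect = dialect,
    econ = list(
      start_age = 65,
      horizon = 30L,
      cycle_length = 1,
      discount_rate_costs = 0.03,
      discount_rate_effects = 0.03,
      wtp = 50000,
      half_cycle = FALSE
    ),
    population = list(
      share_scd = 0.53,
      share_mci = 0.30,
      share_mild_dem = 0.17,
      amyloid_prev_scd = 0.31,
      amyloid_prev_mci = prev_mci,
      amyloid_prev_dem = prev_dem
    ),
    accuracy = list(
      bbm_sensitivity = 0.89,
      bbm_specificity = 0.69,
      csf_sensitivity = 0.91,
      csf_specificity = 0.89
    ),
    policy = list(
      soc_referral_rate = 0.52,
      bbm_positive_referral_rate = 1.0
    ),
    natural_history = list(
      p_scd_to_mci_amypos = 0.41,
      p_mci_to_mild_amypos = 0.22,
      p_scd_to_mci_amyneg = 0.10,
      p_mci_to_mild_amyneg = 0.05,
      progression_odds_ratio = 5.89
    ),
    treatment = list(
      effect = 0.27,
      max_duration = 2L,
      annual_cost = 5000,
      responder_fraction_amypos = 1.0,
      responder_fraction_amyneg = 0.0
    ),
    costs = list(
      phc_cost_scd = 959,
      phc_cost_mci = 1896,
      phc_cost_dem = 1896,
      csf_exam_incl_mc_visit = 1940,
      mc_visit = 524,
      bbm_test = 200,
      state_scd = 9180,
      state_mci = 9180,
      state_mild = 27014,
      state_moderate = 30824,
      state_severe = 35471,
      state_mild_ltc = 81383,
      state_moderate_ltc = 66849,
      state_severe_ltc = 66977
    ),
    utilities = list(
      u_scd_amyneg = 0.87,
      u_scd_amypos = 0.86,
      u_mci_amyneg = 0.71,
      u_mci_amypos = 0.81,
      u_mild = 0.74,
      u_moderate = 0.59,
      u_severe = 0.36
    )
  )
  params$distributions <- default_distributions(dialect)
  class(params) <- "bbm_parameters"
  validate_parameters(params)
}

#' Uncertainty distributions of the input parameters
#'
#' One row per input parameter with its sampling family for probabilistic
#' sensitivity analysis: beta for probabilities/utilities, gamma for costs,
#' `fixed` for parameters held constant. `low`/`high` are the published 95%
#' interval bounds (or +/-20% bounds where no interval was available).
#'
#' @param dialect parameter dialect, see [default_parameters()].
#' @return data.frame with columns `name` (dotted path into the parameter
#'   list), `family`, `mean`, `low`, `high`.
#' @export
default_distributions <- function(dialect = c("text", "table1")) {
  dialect <- match.arg(dialect)
  prev_mci <- if (dialect == "table1") 0.555 else 0.548
  prev_dem <- if (dialect == "table1") 0.840 else 0.841
  spec <- function(name, family, mean, low = mean, high = mean) {
    data.frame(name = name, family = family, mean = mean, low = low,
               high = high, stringsAsFactors = FALSE)
  }
  out <- rbind(
    spec("econ.start_age", "fixed", 65),
    spec("population.share_scd", "fixed", 0.53),
    spec("population.share_mci", "beta", 0.30, 0.25, 0.35),
    spec("population.share_mild_dem", "beta", 0.17, 0.14, 0.20),
    spec("population.amyloid_prev_scd", "fixed", 0.31),
    spec("population.amyloid_prev_mci", "beta", prev_mci, 0.501, 0.595),
    spec("population.amyloid_prev_dem", "beta", prev_dem, 0.775, 0.890),
    spec("policy.soc_referral_rate", "beta", 0.52, 0.416, 0.624),
    spec("policy.bbm_positive_referral_rate", "fixed", 1.0),
    spec("accuracy.bbm_sensitivity", "beta", 0.89, 0.80, 0.95),
    spec("accuracy.bbm_specificity", "beta", 0.69, 0.54, 0.81),
    spec("accuracy.csf_sensitivity", "beta", 0.91, 0.84, 0.96),
    spec("accuracy.csf_specificity", "beta", 0.89, 0.84, 0.94),
    spec("natural_history.p_scd_to_mci_amypos", "fixed", 0.41),
    spec("natural_history.p_mci_to_mild_amypos", "fixed", 0.22),
    spec("natural_history.p_scd_to_mci_amyneg", "fixed", 0.10),
    spec("natural_history.p_mci_to_mild_amyneg", "fixed", 0.05),
    spec("treatment.effect", "beta", 0.27, 0.22, 0.324),
    spec("utilities.u_scd_amyneg", "beta", 0.87, 0.86, 0.89),
    spec("utilities.u_scd_amypos", "beta", 0.86, 0.83, 0.89),
    spec("utilities.u_mci_amyneg", "beta", 0.71, 0.64, 0.78),
    spec("utilities.u_mci_amypos", "beta", 0.81, 0.77, 0.85),
    spec("utilities.u_mild", "beta", 0.74, 0.69, 0.79),
    spec("utilities.u_moderate", "beta", 0.59, 0.47, 0.71),
    spec("utilities.u_severe", "beta", 0.36, 0.18, 0.53),
    spec("costs.phc_cost_scd", "fixed", 959),
    spec("costs.phc_cost_mci", "fixed", 1896),
    spec("costs.phc_cost_dem", "fixed", 1896),
    spec("costs.csf_exam_incl_mc_visit", "gamma", 1940, 1552, 2328),
    spec("costs.mc_visit", "gamma", 524, 419, 629),
    spec("costs.bbm_test", "gamma", 200, 100, 300),
    spec("costs.state_mci", "gamma", 9180, 7344, 11016),
    spec("costs.state_mild", "gamma", 27014, 21348, 32681),
    spec("costs.state_moderate", "fixed", 30824),
    spec("costs.state_severe", "fixed", 35471),
    spec("costs.state_mild_ltc", "fixed", 81383),
    spec("costs.state_moderate_ltc", "fixed", 66849),
    spec("costs.state_severe_ltc", "fixed", 66977),
    spec("treatment.annual_cost", "gamma", 5000, 4000, 6000)
  )
  out
}

get_param <- function(params, name) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  out <- params
  for (key in path) {
    out <- out[[key]]
    if (is.null(out)) bbm_validation_error(sprintf("unknown parameter '%s'", name))
  }
  out
}

set_param <- function(params, name, value) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(path) != 2L) bbm_validation_error(sprintf("unknown parameter '%s'", name))
  if (is.null(params[[path[1]]][[path[2]]])) {
    bbm_validation_error(sprintf("unknown parameter '%s'", name))
  }
  params[[path[1]]][[path[2]]] <- unname(value)
  params
}

#' Set one parameter, propagating linked values
#'
#' Used by the sensitivity analyses: setting `costs.state_mci` also updates
#' the SCD state cost (the model costs SCD as MCI), and varying a cohort
#' share rebalances the SCD share so the three shares still sum to one.
#'
#' @param params a `bbm_parameters` object.
#' @param name dotted parameter path, e.g. `"accuracy.bbm_specificity"`.
#' @param value new value.
#' @return the modified, re-validated parameter set.
#' @export
apply_param_value <- function(params, name, value) {
  params <- set_param(params, name, value)
  if (name == "costs.state_mci") {
    params$costs$state_scd <- unname(value)
  }
  if (name %in% c("population.share_mci", "population.share_mild_dem")) {
    rest <- params$population$share_mci + params$population$share_mild_dem
    if (rest > 1) {
      bbm_validation_error("population shares of MCI and mild dementia exceed 1")
    }
    params$population$share_scd <- 1 - rest
  }
  validate_parameters(params)
}

check_fraction <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    bbm_validation_error(
      sprintf("parameter '%s' must be a fraction in [0, 1], got %s",
              name, format(value))
    )
  }
  invisible(value)
}

check_nonneg <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    bbm_validation_error(
      sprintf("parameter '%s' must be non-negative, got %s", name, format(value))
    )
  }
  invisible(value)
}

#' Validate a parameter set
#'
#' Checks ranges (probabilities and utilities in \[0, 1\], costs
#' non-negative), the sum-to-one constraint on the cohort shares (tolerance
#' 1e-9), economic settings, and the internal consistency of the
#' distribution table. Errors are classed `bbm_validation_error` and name
#' the offending field.
#'
#' @param params a `bbm_parameters` object (or plain list with the same shape).
#' @return the validated object, invisibly classed `bbm_parameters`.
#' @export
validate_parameters <- function(params) {
  econ <- params$econ
  if (is.null(econ)) bbm_validation_error("missing 'econ' block")
  if (!is.numeric(econ$horizon) || econ$horizon < 1) {
    bbm_validation_error("parameter 'econ.horizon' must be >= 1")
  }
  if (!identical(as.numeric(econ$cycle_length), 1)) {
    bbm_validation_error("parameter 'econ.cycle_length' must be 1 (annual cycles only)")
  }
  for (nm in c("discount_rate_costs", "discount_rate_effects")) {
    v <- econ[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1) {
      bbm_validation_error(sprintf("parameter 'econ.%s' must be in [0, 1)", nm))
    }
  }
  if (!is.numeric(econ$wtp) || econ$wtp <= 0) {
    bbm_validation_error("parameter 'econ.wtp' must be > 0")
  }

  pop <- params$population
  for (nm in names(pop)) check_fraction(pop[[nm]], paste0("population.", nm))
  share_sum <- pop$share_scd + pop$share_mci + pop$share_mild_dem
  if (abs(share_sum - 1) > 1e-9) {
    bbm_validation_error(
      sprintf("population shares must sum to 1 (got %.10f)", share_sum)
    )
  }

  for (nm in names(params$accuracy)) {
    check_fraction(params$accuracy[[nm]], paste0("accuracy.", nm))
  }
  for (nm in names(params$policy)) {
    check_fraction(params$policy[[nm]], paste0("policy.", nm))
  }
  nh <- params$natural_history
  for (nm in setdiff(names(nh), "progression_odds_ratio")) {
    check_fraction(nh[[nm]], paste0("natural_history.", nm))
  }
  if (nh$progression_odds_ratio <= 0) {
    bbm_validation_error("parameter 'natural_history.progression_odds_ratio' must be > 0")
  }

  trt <- params$treatment
  check_fraction(trt$effect, "treatment.effect")
  check_fraction(trt$responder_fraction_amypos, "treatment.responder_fraction_amypos")
  check_fraction(trt$responder_fraction_amyneg, "treatment.responder_fraction_amyneg")
  if (trt$max_duration < 1) bbm_validation_error("parameter 'treatment.max_duration' must be >= 1")
  check_nonneg(trt$annual_cost, "treatment.annual_cost")

  for (nm in names(params$costs)) check_nonneg(params$costs[[nm]], paste0("costs.", nm))
  if (params$costs$csf_exam_incl_mc_visit <= params$costs$mc_visit) {
    bbm_validation_error(
      "parameter 'costs.csf_exam_incl_mc_visit' must exceed 'costs.mc_visit'"
    )
  }
  for (nm in names(params$utilities)) {
    check_fraction(params$utilities[[nm]], paste0("utilities.", nm))
  }

  dist <- params$distributions
  if (!is.null(dist)) {
    bad <- dist$low > dist$mean | dist$mean > dist$high
    if (any(bad)) {
      bbm_validation_error(
        sprintf("distribution for '%s' must satisfy low <= mean <= high",
                dist$name[which(bad)[1]])
      )
    }
    beta_rows <- dist$family == "beta"
    if (any(beta_rows & (dist$low < 0 | dist$high > 1))) {
      bbm_validation_error("beta distributions require bounds within [0, 1]")
    }
    if (any(dist$family == "gamma" & dist$low < 0)) {
      bbm_validation_error("gamma distributions require non-negative bounds")
    }
  }
  class(params) <- "bbm_parameters"
  invisible(params)
}

#' Load parameters from a YAML configuration file
#'
#' The file mirrors the structure of [default_parameters()]; any key left out
#' falls back to the base-case default, so a minimal config may override a
#' single value. An optional top-level `dialect` key selects the amyloid
#' prevalence dialect before overrides are applied.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param dialect default dialect when the file does not set one.
#' @return a validated `bbm_parameters` object.
#' @export
load_parameters <- function(path = NULL, dialect = "text") {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      bbm_validation_error(sprintf("config file '%s' does not exist", path))
    }
    user <- yaml::read_yaml(path)
    if (!is.list(user)) bbm_validation_error("config file does not parse to a mapping")
  }
  dialect <- user$dialect %||% dialect
  params <- default_parameters(dialect)
  blocks <- c("econ", "population", "accuracy", "policy", "natural_history",
              "treatment", "costs", "utilities")
  for (block in blocks) {
    if (is.null(user[[block]])) next
    unknown <- setdiff(names(user[[block]]), names(params[[block]]))
    if (length(unknown) > 0) {
      bbm_validation_error(
        sprintf("unknown key '%s.%s' in config", block, unknown[1])
      )
    }
    params[[block]] <- modifyList(params[[block]], user[[block]])
  }
  extra <- setdiff(names(user), c(blocks, "dialect", "schema_version"))
  if (length(extra) > 0) {
    bbm_validation_error(sprintf("unknown top-level config key '%s'", extra[1]))
  }
  validate_parameters(params)
}

#' Write a parameter set to a YAML configuration file
#'
#' @param params a `bbm_parameters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  keep <- c("schema_version", "dialect", "econ", "population", "accuracy",
            "policy", "natural_history", "treatment", "costs", "utilities")
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}

#' Flat table of resolved parameters
#'
#' One row per parameter with its resolved base-case value and its
#' sensitivity-analysis distribution, suitable for CSV export.
#'
#' @param params a `bbm_parameters` object.
#' @return data.frame with columns `name`, `value`, `family`, `low`, `high`.
#' @export
parameter_table <- function(params) {
  dist <- params$distributions
  value <- vapply(dist$name, function(nm) as.numeric(get_param(params, nm)),
                  numeric(1))
  data.frame(name = dist$name, value = unname(value), family = dist$family,
             low = dist$low, high = dist$high, stringsAsFactors = FALSE)
}

#' Convert an odds ratio to a probability in the reference-odds group
#'
#' Given an odds ratio `OR = odds(p_reference) / odds(p)` (e.g. the odds of
#' annual progression in amyloid-positive relative to amyloid-negative
#' individuals) and the probability in the numerator group, returns the
#' probability `p` in the denominator group.
#'
#' @param odds_ratio positive odds ratio.
#' @param p_reference probability in the reference (numerator) group,
#'   strictly inside (0, 1).
#' @return the implied probability in the comparison group.
#' @export
#' @examples
#' odds_to_probability(5.89, 0.41) # amyloid-negative SCD -> MCI
#' odds_to_probability(5.89, 0.22) # amyloid-negative MCI -> mild dementia
odds_to_probability <- function(odds_ratio, p_reference) {
  if (!is.numeric(odds_ratio) || odds_ratio <= 0) {
    bbm_domain_error("'odds_ratio' must be > 0")
  }
  if (!is.numeric(p_reference) || p_reference <= 0 || p_reference >= 1) {
    bbm_domain_error("'p_reference' must lie strictly inside (0, 1)")
  }
  odds <- p_reference / (1 - p_reference) / odds_ratio
  odds / (1 + odds)
}

#' Inflate a cost to 2022 price levels with consumer price indices
#'
#' @param cost cost in the original year's currency units (>= 0).
#' @param cpi_original CPI of the original year (> 0).
#' @param cpi_2022 CPI of the target year (> 0).
#' @return `cost * cpi_2022 / cpi_original`.
#' @export
cpi_adjust <- function(cost, cpi_original, cpi_2022) {
  if (any(cost < 0)) bbm_domain_error("'cost' must be non-negative")
  if (cpi_original <= 0 || cpi_2022 <= 0) {
    bbm_domain_error("CPI indices must be positive")
  }
  cost * cpi_2022 / cpi_original
}
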