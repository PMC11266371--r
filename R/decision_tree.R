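# Decision tree for the diagnostic year. A unit cohort of 65-year-olds with
# subjective cognitive complaints is partitioned by true cognitive state
# (SCD / MCI / mild dementia) and amyloid status; each pathway routes them
# through referral, blood biomarker (BBM) and CSF testing, ending in a final
# label: biomarker-confirmed AD (treated) or not-AD.

PATHWAYS <- c("SOC", "BBM_PHC", "BBM_MC")
TRUE_STATES <- c("SCD", "MCI", "MILD_DEM")

#' Evaluate a diagnostic pathway on a unit cohort
#'
#' Routes the cohort through one of three diagnostic strategies:
#'
#' * `SOC` — standard of care: SCD exits at primary care untested; MCI and
#'   dementia are referred to the memory clinic with the standard referral
#'   rate (independent of amyloid status); referred individuals receive a
#'   CSF test whose result sets the final label.
#' * `BBM_PHC` — blood biomarker at primary care: MCI and dementia receive a
#'   BBM test; BBM-positives are referred (rate 1) and receive CSF;
#'   BBM-negatives exit as not-AD.
#' * `BBM_MC` — blood biomarker at the memory clinic: referral as in SOC;
#'   referred individuals receive BBM at the clinic and only BBM-positives
#'   continue to CSF.
#'
#' Individuals whose true state is SCD are never tested, so amyloid-positive
#' SCD always counts as false negative. CSF accuracy is conditioned on true
#' amyloid status only, never on the BBM result.
#'
#' @param pathway one of `"SOC"`, `"BBM_PHC"`, `"BBM_MC"`.
#' @param params a `bbm_parameters` object.
#' @return An object of class `bbm_outcome`: the ten diagnostic groups with
#'   their cohort masses (`groups`), confusion-matrix fractions (`frac_tp`,
#'   `frac_tn`, `frac_fp`, `frac_fn`), referral and CSF burden
#'   (`frac_referred`, `frac_csf`), and the per-person diagnosis cost with
#'   its component breakdown.
#' @export
#' @examples
#' out <- evaluate_pathway("SOC", default_parameters())
#' round(out$frac_referred, 3)
evaluate_pathway <- function(pathway, params) {
  if (!is.character(pathway) || length(pathway) != 1L || !pathway %in% PATHWAYS) {
    bbm_validation_error(sprintf(
      "unknown pathway '%s' (expected one of %s)",
      paste(pathway, collapse = ","), paste(PATHWAYS, collapse = ", ")
    ))
  }
  validate_parameters(params)
  pop <- params$population
  acc <- params$accuracy
  pol <- params$policy

  shares <- c(SCD = pop$share_scd, MCI = pop$share_mci, MILD_DEM = pop$share_mild_dem)
  prev <- c(SCD = pop$amyloid_prev_scd, MCI = pop$amyloid_prev_mci,
            MILD_DEM = pop$amyloid_prev_dem)

  groups <- data.frame(
    true_state = character(0), amyloid = character(0),
    label = character(0), mass = numeric(0), stringsAsFactors = FALSE
  )
  add_group <- function(state, amy, label, mass) {
    key <- groups$true_state == state & groups$amyloid == amy & groups$label == label
    if (any(key)) {
      groups$mass[key] <<- groups$mass[key] + mass
    } else {
      groups[nrow(groups) + 1L, ] <<- list(state, amy, label, mass)
    }
  }

  frac_referred <- 0
  frac_csf <- 0
  for (state in TRUE_STATES) {
    for (amy in c("positive", "negative")) {
      m <- shares[[state]] * if (amy == "positive") prev[[state]] else 1 - prev[[state]]
      p_csf_pos <- if (amy == "positive") acc$csf_sensitivity else 1 - acc$csf_specificity
      p_bbm_pos <- if (amy == "positive") acc$bbm_sensitivity else 1 - acc$bbm_specificity
      if (state == "SCD") {
        add_group(state, amy, "NOT_AD", m)
        next
      }
      if (pathway == "SOC") {
        p_ref <- pol$soc_referral_rate
        p_test <- p_ref
      } else if (pathway == "BBM_PHC") {
        p_ref <- p_bbm_pos * pol$bbm_positive_referral_rate
        p_test <- p_ref
      } else { # BBM_MC
        p_ref <- pol$soc_referral_rate
        p_test <- p_ref * p_bbm_pos
      }
      frac_referred <- frac_referred + m * p_ref
      frac_csf <- frac_csf + m * p_test
      add_group(state, amy, "AD_DIAGNOSED", m * p_test * p_csf_pos)
      add_group(state, amy, "NOT_AD", m * (1 - p_test * p_csf_pos))
    }
  }

  pos <- groups$amyloid == "positive"
  ad <- groups$label == "AD_DIAGNOSED"
  out <- structure(
    list(
      pathway = pathway,
      dialect = params$dialect,
      groups = groups,
      shares = as.list(shares),
      frac_referred = frac_referred,
      frac_csf = frac_csf,
      frac_tp = sum(groups$mass[pos & ad]),
      frac_fp = sum(groups$mass[!pos & ad]),
      frac_tn = sum(groups$mass[!pos & !ad]),
      frac_fn = sum(groups$mass[pos & !ad])
    ),
    class = "bbm_outcome"
  )
  cost <- diagnosis_cost(pathway, out, params$costs)
  out$diagnosis_cost_per_person <- cost$total
  out$cost_components <- cost$components
  out
}

#' Per-person diagnosis cost of a pathway
#'
#' Sums primary-care work-up costs by presenting state, BBM test costs for
#' everyone tested, memory-clinic visits, and CSF examinations. The CSF
#' examination fee includes the clinic consultation; in the `BBM_MC` pathway
#' the clinic visit is billed separately for referred individuals and the
#' CSF component only adds the examination excess for those triaged to it.
#'
#' @param pathway one of `"SOC"`, `"BBM_PHC"`, `"BBM_MC"`.
#' @param outcome a `bbm_outcome` from [evaluate_pathway()] for the same pathway.
#' @param costs the `costs` block of a parameter set.
#' @return list with `total` (euros per person) and `components`
#'   (named vector: `phc`, `bbm`, `mc_visit`, `csf`).
#' @export
diagnosis_cost <- function(pathway, outcome, costs) {
  if (!identical(pathway, outcome$pathway)) {
    bbm_validation_error(sprintf(
      "outcome was produced for pathway '%s', not '%s'", outcome$pathway, pathway
    ))
  }
  sh <- outcome$shares
  phc <- sh$SCD * costs$phc_cost_scd + sh$MCI * costs$phc_cost_mci +
    sh$MILD_DEM * costs$phc_cost_dem
  tested_phc <- sh$MCI + sh$MILD_DEM
  if (pathway == "SOC") {
    comp <- c(phc = phc, bbm = 0, mc_visit = 0,
              csf = outcome$frac_csf * costs$csf_exam_incl_mc_visit)
  } else if (pathway == "BBM_PHC") {
    comp <- c(phc = phc, bbm = tested_phc * costs$bbm_test, mc_visit = 0,
              csf = outcome$frac_csf * costs$csf_exam_incl_mc_visit)
  } else {
    comp <- c(phc = phc,
              bbm = outcome$frac_referred * costs$bbm_test,
              mc_visit = outcome$frac_referred * costs$mc_visit,
              csf = outcome$frac_csf * (costs$csf_exam_incl_mc_visit - costs$mc_visit))
  }
  list(total = sum(comp), components = comp)
}

#' Compare the intermediate outcomes of two pathways
#'
#' @param a,b `bbm_outcome` objects evaluated on the same parameters.
#' @return data.frame with one row per intermediate outcome (referral, CSF,
#'   confusion-matrix fractions, diagnosis cost and its components) and
#'   columns `metric`, `a`, `b`, `difference` (`b - a`).
#' @export
compare_pathways <- function(a, b) {
  if (!identical(a$dialect, b$dialect)) {
    bbm_validation_error("outcomes were evaluated under different parameter dialects")
  }
  metrics <- c(
    frac_referred = "frac_referred", frac_csf = "frac_csf",
    frac_tp = "frac_tp", frac_tn = "frac_tn",
    frac_fp = "frac_fp", frac_fn = "frac_fn",
    diagnosis_cost = "diagnosis_cost_per_person"
  )
  rows <- data.frame(
    metric = names(metrics),
    a = vapply(metrics, function(f) a[[f]], numeric(1)),
    b = vapply(metrics, function(f) b[[f]], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  comp <- data.frame(
    metric = paste0("cost_", names(a$cost_components)),
    a = as.numeric(a$cost_components),
    b = as.numeric(b$cost_components),
    stringsAsFactors = FALSE
  )
  out <- rbind(rows, comp)
  out$difference <- out$b - out$a
  attr(out, "pathways") <- c(a$pathway, b$pathway)
  out
}

#' Scale a pathway comparison to a population of size n
#'
#' Multiplies cohort fractions and per-person euro amounts by the number of
#' individuals seeking diagnostic evaluation, turning e.g. a referral-rate
#' difference of 0.08 into 800 additional referrals per 10,000 evaluated.
#'
#' @param diff_table output of [compare_pathways()].
#' @param n population size (> 0; 0 allowed and returns zeros).
#' @return the table with `a`, `b` and `difference` scaled by `n`.
#' @export
population_scale <- function(diff_table, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    bbm_domain_error("'n' must be a non-negative count")
  }
  out <- diff_table
  for (col in c("a", "b", "difference")) out[[col]] <- out[[col]] * n
  attr(out, "population") <- n
  out
}
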