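# One-way deterministic (tornado) and probabilistic sensitivity analyses.

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full pipeline (decision tree + Markov model, both arms) with
#' each uncertain parameter set to its lower and upper bound while all
#' others stay at base case, and records the resulting ICER swing.
#' Parameters without bounds (family `fixed`, or zero-width interval) are
#' skipped with a warning.
#'
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param param_names dotted parameter paths to vary; default all non-fixed
#'   entries of the distribution table.
#' @param intervention,reference the pathways compared (defaults
#'   `"BBM_PHC"` vs `"SOC"`).
#' @return data.frame (class `bbm_tornado`) with one row per parameter:
#'   `name`, `low_value`, `high_value`, `icer_at_low`, `icer_at_high`,
#'   `swing`, sorted by decreasing swing. The base-case ICER is stored in
#'   attribute `base_icer`.
#' @export
one_way_dsa <- function(params, fixtures, param_names = NULL,
                        intervention = "BBM_PHC", reference = "SOC") {
  dist <- params$distributions
  if (is.null(param_names)) {
    param_names <- dist$name[dist$family != "fixed"]
  }
  base <- compare_strategies(params, fixtures, intervention, reference)
  rows <- list()
  for (nm in param_names) {
    row <- dist[dist$name == nm, ]
    if (nrow(row) == 0 || row$family == "fixed" || row$low == row$high) {
      warning(sprintf("parameter '%s' has no bounds; skipped", nm))
      next
    }
    icer_of <- function(value) {
      p2 <- apply_param_value(params, nm, value)
      compare_strategies(p2, fixtures, intervention, reference)$ce$icer
    }
    rows[[nm]] <- data.frame(
      name = nm, low_value = row$low, high_value = row$high,
      icer_at_low = icer_of(row$low), icer_at_high = icer_of(row$high),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(name = character(0), low_value = numeric(0),
               high_value = numeric(0), icer_at_low = numeric(0),
               icer_at_high = numeric(0))
  }
  out$swing <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$ce$icer
  class(out) <- c("bbm_tornado", "data.frame")
  out
}

psa_stream_seed <- function(master_seed, index) {
  ((as.numeric(master_seed) %% 2^20) * 1009 + index * 7919) %% 2147483647
}

#' Draw the probabilistic-sensitivity-analysis parameter matrix
#'
#' One independent counter-based stream per parameter, derived from the
#' master seed, so adding or removing a parameter never perturbs the other
#' parameters' draws. Fixed parameters are excluded.
#'
#' @param params a `bbm_parameters` object.
#' @param n_iter number of iterations.
#' @param seed master seed.
#' @return numeric matrix `n_iter` x (number of uncertain parameters) with
#'   parameter names as column names.
#' @export
psa_draws <- function(params, n_iter, seed) {
  dist <- params$distributions
  varied <- dist[dist$family != "fixed", , drop = FALSE]
  draws <- matrix(NA_real_, n_iter, nrow(varied),
                  dimnames = list(NULL, varied$name))
  for (j in seq_len(nrow(varied))) {
    draws[, j] <- with_private_seed(
      psa_stream_seed(seed, j),
      sample_distribution(varied[j, ], n_iter)
    )
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration, draws every uncertain parameter from its distribution,
#' re-runs both arms and records incremental cost, incremental QALYs and the
#' ICER. Summaries: fractions of iterations whose ICER lies above/below the
#' willingness-to-pay threshold (counted in the northeast quadrant;
#' dominant iterations count as below; dominated and southwest iterations
#' are neither), and a cost-effectiveness acceptability curve over a
#' willingness-to-pay grid using net monetary benefit.
#'
#' @param params a `bbm_parameters` object.
#' @param fixtures a `bbm_fixtures` bundle.
#' @param n_iter number of iterations (>= 1).
#' @param seed master seed; results are reproducible given the seed.
#' @param intervention,reference the pathways compared.
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @return object of class `bbm_psa`: per-iteration `results` data.frame
#'   (`delta_cost`, `delta_qaly`, `icer`, `quadrant`), `fraction_above_wtp`,
#'   `fraction_below_wtp`, `ceac` data.frame, `seed`, `n_iter`.
#' @export
run_psa <- function(params, fixtures, n_iter = 1000, seed = 1,
                    intervention = "BBM_PHC", reference = "SOC",
                    wtp_grid = seq(0, 150000, by = 10000)) {
  if (n_iter < 1) bbm_domain_error("'n_iter' must be >= 1")
  draws <- psa_draws(params, n_iter, seed)
  wtp <- params$econ$wtp
  dc <- dq <- numeric(n_iter)
  quadrant <- character(n_iter)
  for (it in seq_len(n_iter)) {
    p_it <- params
    for (nm in colnames(draws)) {
      p_it <- apply_param_value(p_it, nm, draws[it, nm])
    }
    cmp <- compare_strategies(p_it, fixtures, intervention, reference, wtp)
    dc[it] <- cmp$ce$delta_cost
    dq[it] <- cmp$ce$delta_qaly
    quadrant[it] <- cmp$ce$quadrant
  }
  icer <- ifelse(dq == 0, NA_real_, dc / dq)
  ne <- dq > 0 & dc > 0
  dominant <- dq > 0 & dc <= 0
  above <- ne & icer > wtp
  below <- (ne & icer <= wtp) | dominant
  ceac <- data.frame(
    wtp = wtp_grid,
    probability_cost_effective = vapply(
      wtp_grid, function(lambda) mean(lambda * dq - dc > 0), numeric(1)
    )
  )
  structure(
    list(
      results = data.frame(iteration = seq_len(n_iter), delta_cost = dc,
                           delta_qaly = dq, icer = icer, quadrant = quadrant),
      fraction_above_wtp = mean(above),
      fraction_below_wtp = mean(below),
      ceac = ceac,
      wtp = wtp,
      seed = seed,
      n_iter = n_iter,
      draws = draws
    ),
    class = "bbm_psa"
  )
}
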