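# Synthetic stand-ins for registry-derived inputs: an old-age life table,
# the dementia-stage transition block, and stage-specific mortality hazard
# ratios. These are deliberately simple, clearly tagged synthetic, and are
# NOT estimates of any dementia registry; real tables can be supplied
# through the same CSV schema.

DEM_STATES <- c("MILD", "MODERATE", "SEVERE",
                "MILD_LTC", "MODERATE_LTC", "SEVERE_LTC")

#' Generate a Gompertz life table
#'
#' Annual death probability `q(age) = 1 - exp(-a * exp(b * age))`, capped at
#' 1; strictly increasing in age for positive parameters. The defaults give
#' a remaining life expectancy of roughly two decades at age 65, in the
#' range of a contemporary Nordic general population.
#'
#' @param a Gompertz level parameter (>= 0).
#' @param b Gompertz slope parameter (> 0).
#' @param ages integer vector of ages covered.
#' @return data.frame (class `bbm_life_table`) with columns `age` and `q`.
#' @export
generate_life_table <- function(a = 2e-5, b = 0.11, ages = 60:110) {
  if (a < 0 || b <= 0) bbm_domain_error("Gompertz parameters require a >= 0, b > 0")
  q <- pmin(1, 1 - exp(-a * exp(b * ages)))
  structure(data.frame(age = as.integer(ages), q = q),
            class = c("bbm_life_table", "data.frame"))
}

life_table_q <- function(life_table, age) {
  idx <- match(round(age), life_table$age)
  if (any(is.na(idx))) {
    bbm_domain_error(sprintf("age %s outside the life table range [%d, %d]",
                             paste(age[is.na(idx)], collapse = ","),
                             min(life_table$age), max(life_table$age)))
  }
  life_table$q[idx]
}

#' Generate a synthetic dementia-stage transition block
#'
#' Row-stochastic annual transitions over the six dementia states (mild,
#' moderate, severe, each in the community or institutionalised),
#' conditional on surviving the cycle. Structure: forward progression
#' mild -> moderate -> severe; community -> institution entries at the same
#' or next stage; small backward (regression) probabilities within a care
#' setting; no return from institution to community. A seeded multiplicative
#' jitter makes distinct seeds produce distinct but structurally identical
#' blocks.
#'
#' @param seed integer seed; the block is deterministic given the seed.
#' @param progression_level annual probability scale of stage progression.
#' @param institutionalisation_level annual probability scale of moving into
#'   institutional care.
#' @param regression_level annual probability scale of moving back one stage.
#' @return 6 x 6 matrix over `MILD`, `MODERATE`, `SEVERE`, `MILD_LTC`,
#'   `MODERATE_LTC`, `SEVERE_LTC`; every row sums to 1.
#' @export
generate_dementia_transition_fixture <- function(seed = 20240410,
                                                 progression_level = 0.25,
                                                 institutionalisation_level = 0.06,
                                                 regression_level = 0.02) {
  for (lv in c(progression_level, institutionalisation_level, regression_level)) {
    if (lv < 0 || lv > 1) bbm_domain_error("fixture levels must lie in [0, 1]")
  }
  p <- progression_level
  i <- institutionalisation_level
  r <- regression_level
  m <- matrix(0, 6, 6, dimnames = list(DEM_STATES, DEM_STATES))
  m["MILD", "MODERATE"] <- p
  m["MILD", "MILD_LTC"] <- i
  m["MILD", "MODERATE_LTC"] <- p * i
  m["MODERATE", "SEVERE"] <- p
  m["MODERATE", "MILD"] <- r
  m["MODERATE", "MODERATE_LTC"] <- 1.5 * i
  m["MODERATE", "SEVERE_LTC"] <- p * i
  m["SEVERE", "SEVERE_LTC"] <- 2 * i
  m["SEVERE", "MODERATE"] <- r
  m["MILD_LTC", "MODERATE_LTC"] <- p
  m["MODERATE_LTC", "SEVERE_LTC"] <- p
  m["MODERATE_LTC", "MILD_LTC"] <- r
  m["SEVERE_LTC", "MODERATE_LTC"] <- r
  jitter <- with_private_seed(seed, matrix(runif(36, 0.9, 1.1), 6, 6))
  m <- m * jitter
  rs <- rowSums(m)
  if (any(rs > 1)) {
    warning("off-diagonal transition mass exceeded 1; rescaling rows")
    m[rs > 1, ] <- m[rs > 1, , drop = FALSE] / rs[rs > 1]
    rs <- rowSums(m)
  }
  diag(m) <- diag(m) + (1 - rs)
  m
}

#' Generate severity-monotone mortality hazard ratios
#'
#' Hazard ratios of death versus the general population for the six
#' dementia states, anchored at the very-mild-dementia hazard ratio and
#' increased multiplicatively with stage severity; institutionalised states
#' carry an additional multiplier. Pre-dementia states (SCD, MCI) use
#' hazard ratio 1.
#'
#' @param base hazard ratio anchor for very mild dementia (default 1.82).
#' @param step multiplicative increment per severity stage (>= 1).
#' @param institution_multiplier extra hazard for institutionalised states
#'   (>= 1).
#' @return named numeric vector over the six dementia states, with the
#'   anchor stored in attribute `anchor`.
#' @export
generate_mortality_hr_fixture <- function(base = 1.82, step = 1.4,
                                          institution_multiplier = 1.15) {
  if (base < 1 || step < 1 || institution_multiplier < 1) {
    bbm_domain_error("hazard-ratio fixture requires base, step and multiplier >= 1")
  }
  community <- c(MILD = base * step,
                 MODERATE = base * step^2,
                 SEVERE = base * step^3)
  hrs <- c(community,
           setNames(community * institution_multiplier,
                    paste0(names(community), "_LTC")))
  hrs <- hrs[DEM_STATES]
  attr(hrs, "anchor") <- base
  hrs
}

#' The default synthetic fixture bundle ("F0")
#'
#' The versioned, seed-fixed bundle used throughout the tests and example
#' analyses: Gompertz life table, dementia transition block, and mortality
#' hazard ratios. Its provenance field is always `"synthetic"`; it stands in
#' for registry-derived tables and does not reproduce them.
#'
#' @return object of class `bbm_fixtures` with fields `life_table`,
#'   `dementia_transitions`, `mortality_hrs`, `seed`, `provenance`, `version`.
#' @export
#' @examples
#' f0 <- default_fixture_bundle()
#' f0$provenance
default_fixture_bundle <- function() {
  seed <- 20240410
  structure(
    list(
      life_table = generate_life_table(),
      dementia_transitions = generate_dementia_transition_fixture(seed = seed),
      mortality_hrs = generate_mortality_hr_fixture(),
      seed = seed,
      provenance = "synthetic",
      version = "F0"
    ),
    class = "bbm_fixtures"
  )
}

#' Validate a fixture bundle
#'
#' Checks the schema the Markov engine relies on: life-table probabilities
#' in \[0, 1\], a row-stochastic 6 x 6 dementia block with the expected state
#' names, and severity-monotone hazard ratios >= 1 within each care setting.
#'
#' @param fixtures a `bbm_fixtures` object.
#' @return the bundle, invisibly.
#' @export
validate_fixtures <- function(fixtures) {
  lt <- fixtures$life_table
  if (is.null(lt$age) || is.null(lt$q) || any(lt$q < 0 | lt$q > 1)) {
    bbm_validation_error("life table must provide columns age and q with q in [0, 1]")
  }
  dt <- fixtures$dementia_transitions
  if (!identical(dim(dt), c(6L, 6L)) ||
      !identical(rownames(dt), DEM_STATES) || !identical(colnames(dt), DEM_STATES)) {
    bbm_validation_error("dementia transition block must be 6 x 6 over the dementia states")
  }
  if (any(dt < 0) || any(abs(rowSums(dt) - 1) > 1e-9)) {
    bbm_validation_error("dementia transition rows must be non-negative and sum to 1")
  }
  hrs <- fixtures$mortality_hrs
  if (is.null(names(hrs)) || !all(DEM_STATES %in% names(hrs))) {
    bbm_validation_error("mortality hazard ratios must cover all six dementia states")
  }
  if (any(hrs < 1)) bbm_validation_error("mortality hazard ratios must be >= 1")
  for (setting in list(DEM_STATES[1:3], DEM_STATES[4:6])) {
    if (any(diff(hrs[setting]) < 0)) {
      bbm_validation_error("mortality hazard ratios must be non-decreasing in severity")
    }
  }
  if (any(hrs[DEM_STATES[4:6]] < hrs[DEM_STATES[1:3]])) {
    bbm_validation_error("institutionalised hazard ratios must be >= community counterparts")
  }
  invisible(fixtures)
}

#' Write a fixture bundle to CSV files
#'
#' Writes `life_table.csv` (age, q), `dementia_transitions.csv`
#' (from_state, to_state, probability) and `mortality_hrs.csv`
#' (state, setting, hr) plus a small `provenance.yaml` tag.
#'
#' @param fixtures a `bbm_fixtures` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(fixtures$life_table, file.path(dir, "life_table.csv"),
            row.names = FALSE)
  dt <- fixtures$dementia_transitions
  long <- data.frame(
    from_state = rep(rownames(dt), times = ncol(dt)),
    to_state = rep(colnames(dt), each = nrow(dt)),
    probability = as.vector(dt)
  )
  write.csv(long, file.path(dir, "dementia_transitions.csv"), row.names = FALSE)
  hrs <- fixtures$mortality_hrs
  hr_df <- data.frame(
    state = sub("_LTC$", "", names(hrs)),
    setting = ifelse(grepl("_LTC$", names(hrs)), "institution", "community"),
    hr = as.numeric(hrs)
  )
  write.csv(hr_df, file.path(dir, "mortality_hrs.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(provenance = fixtures$provenance, seed = fixtures$seed,
         version = fixtures$version, anchor_hr = attr(fixtures$mortality_hrs, "anchor")),
    file.path(dir, "provenance.yaml")
  )
  invisible(dir)
}

#' Read a fixture bundle from CSV files
#'
#' Inverse of [write_fixture_bundle()]; also accepts user-supplied tables in
#' the same schema (provenance is then recorded as `"user-supplied"` unless
#' a provenance.yaml says otherwise).
#'
#' @param dir directory containing the fixture CSV files.
#' @return a validated `bbm_fixtures` object.
#' @export
read_fixture_bundle <- function(dir) {
  lt <- read.csv(file.path(dir, "life_table.csv"))
  long <- read.csv(file.path(dir, "dementia_transitions.csv"))
  dt <- matrix(0, 6, 6, dimnames = list(DEM_STATES, DEM_STATES))
  dt[cbind(match(long$from_state, DEM_STATES),
           match(long$to_state, DEM_STATES))] <- long$probability
  hr_df <- read.csv(file.path(dir, "mortality_hrs.csv"))
  state <- ifelse(hr_df$setting == "institution",
                  paste0(hr_df$state, "_LTC"), hr_df$state)
  hrs <- setNames(hr_df$hr, state)[DEM_STATES]
  prov_path <- file.path(dir, "provenance.yaml")
  meta <- if (file.exists(prov_path)) yaml::read_yaml(prov_path) else list()
  if (!is.null(meta$anchor_hr)) attr(hrs, "anchor") <- meta$anchor_hr
  fixtures <- structure(
    list(
      life_table = structure(lt, class = c("bbm_life_table", "data.frame")),
      dementia_transitions = dt,
      mortality_hrs = hrs,
      seed = meta$seed %||% NA_integer_,
      provenance = meta$provenance %||% "user-supplied",
      version = meta$version %||% "user"
    ),
    class = "bbm_fixtures"
  )
  validate_fixtures(fixtures)
  fixtures
}
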