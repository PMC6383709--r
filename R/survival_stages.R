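#' Stage-wise juvenile survival models
#'
#' For each developmental transition (egg to hatchling, hatchling to
#' fledgling, fledgling to recruit, and the compound egg to recruit),
#' fits AIC-selected binomial mixed models of per-clutch survival with year
#' and female identity random intercepts. Candidate fixed effects are the
#' quadratic lay-date effect, clutch number, a three-class age effect
#' (young 1 / middle 2-6 / old >6) and standardized tarsus. When the
#' quadratic lay-date effect is retained, the Gaussian-curve optimum model
#' (binomial layer, `A_max = 1`) is fitted for that stage.
#'
#' @param records Prepared breeding records with `lay_z` (standardized lay
#'   date, attributes kept), `clutch_number`, `female_age`, and stage
#'   counts.
#' @param stages Subset of the four transitions to run.
#' @param optimum_args List of arguments passed on to [fit_optimum()]
#'   (chains, iterations, seed ...) for stages with a supported optimum.
#' @param fit_optima Fit the optimum model where supported?
#' @return Named list per stage: `stepwise`, `mean_survival`, `n_trials`,
#'   `optimum` (an `optimum_fit` or NULL), `skipped` flag.
#' @export
stage_survival_models <- function(records,
                                  stages = c("egg_hatchling",
                                             "hatchling_fledgling",
                                             "fledgling_recruit",
                                             "egg_recruit"),
                                  optimum_args = list(),
                                  fit_optima = TRUE) {
  stage_def <- list(
    egg_hatchling = c(trials = "n_eggs", succ = "n_hatchlings"),
    hatchling_fledgling = c(trials = "n_hatchlings", succ = "n_fledglings"),
    fledgling_recruit = c(trials = "n_fledglings", succ = "n_recruits"),
    egg_recruit = c(trials = "n_eggs", succ = "n_recruits")
  )
  stages <- match.arg(stages, several.ok = TRUE)
  records <- prepare_stage_covariates(records)

  out <- purrr::map(stages, function(st) {
    def <- stage_def[[st]]
    d <- records[records[[def["trials"]]] > 0, , drop = FALSE]
    succ <- d[[def["succ"]]]
    trials <- d[[def["trials"]]]
    if (nrow(d) == 0 || all(succ == 0) || all(succ == trials)) {
      return(list(stage = st, skipped = TRUE,
                  reason = "no variation in survival"))
    }
    resp <- sprintf("cbind(%s, %s - %s)", def["succ"], def["trials"],
                    def["succ"])
    sw <- aic_stepwise(
      d, resp,
      candidates = list(
        lay_date = c("lay_z", "I(lay_z^2)"),
        clutch_number = "clutch_number",
        age_class = "age_class",
        tarsus = "tarsus_z"
      ),
      random = c("season", "female_id"),
      family = "binomial"
    )
    opt <- NULL
    if (fit_optima && "lay_date" %in% sw$selected) {
      od <- tibble::tibble(x = as.numeric(d$lay_z), y = succ,
                           trials = trials, year = d$season)
      attr(od$x, "center") <- attr(records$lay_z, "center")
      attr(od$x, "scale") <- attr(records$lay_z, "scale")
      opt <- do.call(fit_optimum, c(
        list(data = od, family = "binomial", A_max = 1), optimum_args))
    }
    list(stage = st, skipped = FALSE, stepwise = sw,
         mean_survival = sum(succ) / sum(trials),
         n_trials = sum(trials), optimum = opt)
  })
  stats::setNames(out, stages)
}

prepare_stage_covariates <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"lay_z" %in% names(records)) {
    records$lay_z <- standardize(records$lay_day)
  }
  if (!"age_class" %in% names(records)) {
    records$age_class <- cut(records$female_age, c(0, 1, 6, Inf),
                             labels = c("young", "middle", "old"))
  }
  if (!"tarsus_z" %in% names(records) &&
      "female_tarsus" %in% names(records)) {
    tz <- records$female_tarsus
    records$tarsus_z <- if (sum(!is.na(tz)) > 2 && sd(tz, na.rm = TRUE) > 0)
      as.numeric(standardize(tz)) else 0
  }
  records
}

#' Reclutching and female overwinter survival models
#'
#' AIC-selected binomial mixed models on the female-by-season table: the
#' probability of laying more than one clutch, and survival to the next
#' season (right-censored final season excluded), each with candidate
#' effects of standardized start of breeding season, age (linear /
#' first-year vs older / three-class, mutually exclusive encodings), clutch
#' count (survival only) and standardized tarsus, with female identity and
#' year random intercepts.
#'
#' @param seasons Season table from [derive_clutch_structure()].
#' @return List with `reclutch` and `survival` `phen_stepwise` objects (the
#'   latter NULL when fewer than two seasons are available).
#' @export
female_outcome_models <- function(seasons) {
  seasons <- tibble::as_tibble(seasons)
  seasons$start_z <- as.numeric(standardize(seasons$start_day))
  seasons$first_year <- as.numeric(seasons$female_age == 1)
  seasons$age_class <- cut(seasons$female_age, c(0, 1, 6, Inf),
                           labels = c("young", "middle", "old"))
  seasons$tarsus_z <- if (sum(!is.na(seasons$female_tarsus)) > 2 &&
                          sd(seasons$female_tarsus, na.rm = TRUE) > 0)
    as.numeric(standardize(seasons$female_tarsus)) else 0

  age_cands <- list(age_linear = "female_age", age_firstyear = "first_year",
                    age_threeclass = "age_class")
  reclutch <- aic_stepwise(
    seasons, "reclutched",
    candidates = c(list(start = "start_z"), age_cands,
                   list(tarsus = "tarsus_z")),
    random = c("female_id", "season"), family = "binomial",
    exclusive = list(names(age_cands))
  )
  surv_d <- seasons[seasons$season < max(seasons$season), , drop = FALSE]
  survival <- NULL
  if (nrow(surv_d) > 0 && length(unique(surv_d$survived_to_next_season)) > 1) {
    survival <- aic_stepwise(
      surv_d, "survived_to_next_season",
      candidates = c(list(start = "start_z", n_clutches = "n_clutches"),
                     age_cands, list(tarsus = "tarsus_z")),
      random = c("female_id", "season"), family = "binomial",
      exclusive = list(names(age_cands))
    )
  }
  list(reclutch = reclutch, survival = survival)
}
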