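#' Heritability power study by pedigree simulation
#'
#' Simulates a new trait over the observed data structure (pedigree and the
#' record-to-female/mate/year mapping) with a chosen heritability, then
#' refits the animal model to each replicate. The permanent environment,
#' mate and year effects all share one variance `v`; the additive genetic
#' and residual variances are then solved so that the heritability (year
#' excluded from the denominator, no fixed effects simulated) equals
#' `target_h2` and the total variance (year included) equals
#' `total_variance`:
#' `v = v_share * total`, `V_A = target_h2 * (total - v)`,
#' `V_R = (total - v) - V_A - 2 v`.
#'
#' @param pedigree Pedigree tibble.
#' @param data_structure Records tibble supplying the repeated-measures
#'   structure: `female_id`, `social_male_id`, `season`, `clutch_number`.
#' @param target_h2 Simulated heritability (default 0.1).
#' @param total_variance Total simulated variance, days^2 scale.
#' @param v_share Fraction of the total given to each of the PE, mate and
#'   year components.
#' @param replicates Number of simulation replicates.
#' @param seed Base seed; replicate r uses a derived stream.
#' @param n_iter,thin,burnin Animal-model MCMC protocol per replicate
#'   (reduced by default; pass larger values to match a full-length run).
#' @return Tibble with one row per replicate: posterior mean, median, mode
#'   and 95% CI of h2, plus the generating values as attributes.
#' @export
run_power_study <- function(pedigree, data_structure, target_h2 = 0.1,
                            total_variance = 830, v_share = 0.07,
                            replicates = 100, seed = 1,
                            n_iter = 50000, thin = 10, burnin = 3000) {
  v <- v_share * total_variance
  D <- total_variance - v           # phenotypic variance excluding year
  V_A <- target_h2 * D
  V_R <- D - V_A - 2 * v            # PE and mate take v each
  if (V_R <= 0 || V_A < 0) {
    stop("infeasible variance allocation: V_R = ", round(V_R, 2),
         call. = FALSE)
  }
  ds <- tibble::as_tibble(data_structure)
  fem <- as.character(ds$female_id)
  male <- as.character(ds$social_male_id)
  male[is.na(male)] <- "<unknown>"
  yrs <- as.character(ds$season)

  res <- purrr::map_dfr(seq_len(replicates), function(r) {
    seed_r <- component_seed(seed, 100 + r)
    set.seed(seed_r)
    bv <- if (V_A > 0) {
      simulate_breeding_values(pedigree, V_A, seed = seed_r)
    } else {
      tibble::tibble(id = as.character(pedigree$id),
                     bv = 0)
    }
    bv_map <- stats::setNames(bv$bv, bv$id)
    pe <- stats::setNames(rnorm(length(unique(fem)), 0, sqrt(v)),
                          unique(fem))
    me <- stats::setNames(rnorm(length(unique(male)), 0, sqrt(v)),
                          unique(male))
    ye <- stats::setNames(rnorm(length(unique(yrs)), 0, sqrt(v)),
                          unique(yrs))
    y <- 60 + bv_map[fem] + pe[fem] + me[male] + ye[yrs] +
      rnorm(nrow(ds), 0, sqrt(V_R))
    sim <- ds
    sim$sim_trait <- as.numeric(y)
    fit <- fit_animal_model(sim, pedigree, response = "sim_trait",
                            n_iter = n_iter, thin = thin, burnin = burnin,
                            seed = seed_r, ess_warn = 0)
    h2 <- fit$draws$h2
    s <- posterior_point_and_interval(h2)
    tibble::tibble(replicate = r, seed = seed_r,
                   h2_mean = mean(h2), h2_median = s$median,
                   h2_mode = s$mode, h2_lower = s$lower, h2_upper = s$upper)
  })
  attr(res, "allocation") <- list(V_A = V_A, V_PE = v, V_Mate = v,
                                  V_Year = v, V_R = V_R,
                                  target_h2 = target_h2,
                                  total_variance = total_variance)
  res
}

#' Summarise a power study against a reference estimate
#'
#' @param replicate_table Output of [run_power_study()].
#' @param reference_mode,reference_median Reference h2 point estimates (for
#'   instance from the real-data fit): the fractions of replicates whose
#'   posterior mode/median exceed them measure how unusual a reference that
#'   low would be if the true heritability matched the simulated target.
#' @param target_h2 Simulated target (for CI coverage).
#' @return Tibble: fraction_mode_higher, fraction_median_higher,
#'   ci_coverage, n_replicates.
#' @export
summarize_power <- function(replicate_table, reference_mode,
                            reference_median, target_h2 = 0.1) {
  tb <- replicate_table
  if (nrow(tb) < 10) warning("fewer than 10 replicates", call. = FALSE)
  tibble::tibble(
    fraction_mode_higher = mean(tb$h2_mode > reference_mode),
    fraction_median_higher = mean(tb$h2_median > reference_median),
    ci_coverage = mean(tb$h2_lower <= target_h2 & target_h2 <= tb$h2_upper),
    n_replicates = nrow(tb)
  )
}
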