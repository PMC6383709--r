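#' Prepare a study for analysis
#'
#' Runs the data-preparation stage: validation, lay-date imputation from
#' hatch dates where needed, clutch numbering and the season table,
#' recruitment-based fitness from the pedigree, the pre-season temperature
#' cue, and standardized covariates (`lay_z`, per-season `start_z`,
#' `age_class`, `tarsus_z`).
#'
#' @param study A `phen_study` (or any list with `records`, `pedigree`,
#'   `temperatures`).
#' @param cue_window,cue_max_missing Passed to [compute_temperature_cue()].
#' @param recompute_fitness Recount recruits from the pedigree via
#'   [compute_fitness()] (the observational method) instead of keeping the
#'   `n_recruits` column as supplied.
#' @return List of class `phen_prepared`: `records` (with `lay_z`,
#'   `age_class`, ...), `seasons` (with `start_z`, `cue`), `cue` table,
#'   `pedigree`, `temperatures`.
#' @export
prepare_study <- function(study, cue_window = 50, cue_max_missing = 0.1,
                          recompute_fitness = TRUE) {
  records <- impute_lay_from_hatch(study$records)
  cs <- derive_clutch_structure(records)
  records <- cs$records
  seasons <- cs$seasons
  if (recompute_fitness) {
    records <- compute_fitness(records, study$pedigree)
    seasons <- seasons |>
      dplyr::select(-"annual_recruits") |>
      dplyr::left_join(
        records |>
          dplyr::group_by(.data$female_id, .data$season) |>
          dplyr::summarise(annual_recruits = sum(.data$n_recruits),
                           .groups = "drop"),
        by = c("female_id", "season"))
  }
  validate_breeding_records(records)
  cue <- compute_temperature_cue(study$temperatures, seasons,
                                 window = cue_window,
                                 max_missing = cue_max_missing)
  seasons <- dplyr::left_join(seasons, cue[, c("season", "cue")],
                              by = "season")
  records <- prepare_stage_covariates(records)
  seasons$start_z <- as.numeric(standardize(seasons$start_day))

  out <- list(records = records, seasons = seasons, cue = cue,
              pedigree = study$pedigree, temperatures = study$temperatures)
  class(out) <- "phen_prepared"
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the lay-date analysis on a prepared (or raw)
#' study: phenology model selection for start of breeding season (broken-line
#' age models, temperature-cue test, reclutch and female-survival models),
#' the animal model of lay-date heritability, the Gaussian fitness-optimum
#' model (with cue variant and lay-date mode), stage-wise survival optima,
#' selection statistics, and optionally the heritability power study.
#' Stages can be selected individually; later stages reuse earlier results.
#'
#' MCMC protocol arguments default to short exploratory runs; raise them for
#' reference-quality posteriors.
#'
#' @param study A `phen_study` (e.g. from [generate_breeding_data()] or
#'   [make_fixture()]), or an already-prepared `phen_prepared`.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param seed Base seed for all stochastic stages.
#' @param animal_iter,animal_thin,animal_burnin Animal-model protocol.
#' @param optimum_chains,optimum_iter,optimum_thin,optimum_burnin Optimum
#'   model protocol.
#' @param power_replicates Replicates for the power stage (0 skips it even
#'   when listed).
#' @param power_h2 Target heritability for the power stage.
#' @param out_dir Optional directory for TSV/YAML outputs.
#' @return List of class `phen_report` with one element per executed stage.
#' @export
run_pipeline <- function(study,
                         stages = c("prepare", "phenology", "animal",
                                    "optimum", "selection"),
                         seed = 1,
                         animal_iter = 30000, animal_thin = 10,
                         animal_burnin = 2000,
                         optimum_chains = 4, optimum_iter = 12000,
                         optimum_thin = 10, optimum_burnin = 3000,
                         power_replicates = 0, power_h2 = 0.1,
                         out_dir = NULL) {
  report <- list(seed = seed, stages = stages)

  prepared <- if (inherits(study, "phen_prepared")) study else
    prepare_study(study)
  if ("prepare" %in% stages) report$prepare <- prepared
  records <- prepared$records
  seasons <- prepared$seasons

  if ("phenology" %in% stages) {
    sdat <- seasons
    age_m <- build_age_design(sdat$female_age, "break2_6")
    sdat <- dplyr::bind_cols(sdat, tibble::as_tibble(age_m[, -1]))
    fy <- build_age_design(sdat$female_age, "firstyear_plus_break")
    sdat$first_year <- fy[, "first_year"]
    sdat$age_mid <- fy[, "age_mid"]
    sdat$age_sq <- sdat$female_age^2
    sdat$tarsus_c <- sdat$female_tarsus -
      mean(sdat$female_tarsus, na.rm = TRUE)
    age_cands <- list(
      age_linear = "female_age",
      age_quadratic = c("female_age", "age_sq"),
      age_break2_6 = c("female_age", "age_over2", "age_over6"),
      age_firstyear_break = c("first_year", "age_mid", "age_over6")
    )
    start_sel <- aic_stepwise(
      sdat, "start_day",
      candidates = c(age_cands, list(tarsus = "tarsus_c")),
      random = c("female_id", "season"), family = "gaussian",
      exclusive = list(names(age_cands))
    )
    # temperature-plasticity test: add the cue to the selected model
    sdat$cue_c <- sdat$cue - mean(sdat$cue, na.rm = TRUE)
    base_terms <- unlist(start_sel$fit$formula |> all.vars() |>
                           setdiff(c("start_day", "female_id", "season")))
    with_cue <- fit_mixed_model(sdat, "start_day", c(base_terms, "cue_c"),
                                c("female_id", "season"), "gaussian")
    without_cue <- fit_mixed_model(sdat, "start_day", base_terms,
                                   c("female_id", "season"), "gaussian")
    cue_row <- with_cue$estimates[with_cue$estimates$term == "cue_c", ]
    outcomes <- female_outcome_models(seasons)
    report$phenology <- list(
      start_selection = start_sel,
      cue_test = list(
        aic_with = with_cue$aic, aic_without = without_cue$aic,
        supported = without_cue$aic - with_cue$aic > 2,
        slope = cue_row$estimate, slope_se = cue_row$se,
        p_value = cue_row$p_value
      ),
      reclutch = outcomes$reclutch,
      female_survival = outcomes$survival
    )
  }

  if ("animal" %in% stages) {
    am <- fit_animal_model(records, prepared$pedigree,
                           n_iter = animal_iter, thin = animal_thin,
                           burnin = animal_burnin, seed = seed,
                           ess_warn = 0)
    report$animal <- list(
      fit = am,
      h2 = heritability_repeatability(am),
      mother_daughter = mother_daughter_h2(records, prepared$pedigree)
    )
  }

  if ("optimum" %in% stages) {
    od <- tibble::tibble(
      x = as.numeric(records$lay_z), y = records$n_recruits,
      year = records$season
    )
    attr(od$x, "center") <- attr(records$lay_z, "center")
    attr(od$x, "scale") <- attr(records$lay_z, "scale")
    pre <- quadratic_pretest(records, "n_recruits", random = "season",
                             family = "poisson")
    opt <- fit_optimum(od, family = "poisson", A_max = 5,
                       chains = optimum_chains, n_iter = optimum_iter,
                       thin = optimum_thin, burnin = optimum_burnin,
                       seed = seed, min_total_ess = 0)
    cue_std <- prepared$cue
    cue_std$theta <- as.numeric(standardize(cue_std$cue))
    opt_cue <- fit_optimum_with_cue(
      od, cue = cue_std[, c("season", "theta")] |>
        dplyr::rename(year = "season"),
      family = "poisson", A_max = 5,
      chains = optimum_chains, n_iter = optimum_iter,
      thin = optimum_thin, burnin = optimum_burnin, seed = seed,
      min_total_ess = 0)
    stage_opts <- stage_survival_models(
      records,
      optimum_args = list(chains = optimum_chains, n_iter = optimum_iter,
                          thin = optimum_thin, burnin = optimum_burnin,
                          seed = seed, min_total_ess = 0))
    report$optimum <- list(
      pretest = pre,
      fit = opt,
      summary = optimum_summary(opt),
      mode = trait_mode(records$lay_day),
      ppc = posterior_predictive_check(opt, n_rep = 500, seed = seed),
      cue_fit = opt_cue,
      cue_slope = opt_cue$cue_slope,
      stage_survival = stage_opts
    )
  }

  if ("selection" %in% stages) {
    report$selection <- selection_stats(records, trait = "lay_day",
                                        fitness = "n_recruits",
                                        seed = seed)
  }

  if ("power" %in% stages && power_replicates > 0) {
    pw <- run_power_study(prepared$pedigree, records,
                          target_h2 = power_h2,
                          replicates = power_replicates, seed = seed,
                          n_iter = animal_iter, thin = animal_thin,
                          burnin = animal_burnin)
    ref <- if (!is.null(report$animal)) {
      s <- report$animal$h2$summary
      list(mode = s$mode[s$parameter == "h2"],
           median = s$median[s$parameter == "h2"])
    } else list(mode = power_h2, median = power_h2)
    report$power <- list(
      replicates = pw,
      summary = summarize_power(pw, ref$mode, ref$median,
                                target_h2 = power_h2)
    )
  }

  class(report) <- "phen_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @exportS3Method base::print
print.phen_report <- function(x, ...) {
  cat("Lay-date analysis report (stages:",
      paste(intersect(c("prepare", "phenology", "animal", "optimum",
                        "selection", "power"), names(x)),
            collapse = ", "), ")\n")
  if (!is.null(x$optimum)) {
    s <- x$optimum$summary
    cat(sprintf("Fitness optimum: %s (95%% CI %s to %s); lay-date mode %s\n",
                format_season_day(s$median_day),
                format_season_day(s$lower_day),
                format_season_day(s$upper_day),
                x$optimum$mode$date_label))
  }
  if (!is.null(x$animal)) {
    h <- x$animal$h2$summary
    cat(sprintf("h2 mode %.3f (median %.3f, 95%% CI %.3f-%.3f)\n",
                h$mode[1], h$median[1], h$lower[1], h$upper[1]))
  }
  if (!is.null(x$selection)) {
    cat(sprintf("Selection differential S = %.2f days (SE %.2f)\n",
                x$selection$estimate[1], x$selection$se[1]))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$selection)) {
    readr::write_tsv(report$selection,
                     file.path(out_dir, "selection_stats.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$animal)) {
    readr::write_tsv(tidy(report$animal$fit),
                     file.path(out_dir, "animal_model.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$optimum)) {
    readr::write_tsv(report$optimum$summary,
                     file.path(out_dir, "optimum.tsv"), progress = FALSE)
    readr::write_tsv(per_year_optima(report$optimum$fit),
                     file.path(out_dir, "per_year_optima.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$phenology)) {
    write_aic_trace(report$phenology$start_selection,
                    file.path(out_dir, "start_model_aic_trace.tsv"))
  }
  yaml::write_yaml(list(seed = report$seed, stages = report$stages),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
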