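#' Configuration for the synthetic study generator
#'
#' Defaults emulate a 16-season study of a reintroduced, closely monitored
#' island passerine: two founder releases, overlapping generations with
#' widespread extra-pair paternity, roughly 330 breeding females and 1,400
#' clutch records. Lay-date effects sit at realistic field magnitudes
#' (first-year females 12.5 days later; a +1.33 days/year slope after age 6;
#' -1.70 days/mm of tarsus; -18.28 days/degC of pre-season temperature cue)
#' and variance components are on the ~830 days^2 total scale (V_A 27,
#' V_PE 46.1, V_Mate 14.6, V_R 161, year effects ~58 including the cue).
#' Stage survivals: hatching ~0.73 throughout; hatchling-to-fledgling
#' follows a Gaussian curve of lay date peaking at 0.82 near mid-October and
#' flooring at 0.12; fledgling recruitment ~0.3 before the harvest cap.
#'
#' @param n_seasons Number of breeding seasons.
#' @param first_season Calendar year of the first season.
#' @param n_founder_females,n_founder_males First-release founders.
#' @param second_release_females,second_release_males Second-release cohort
#'   (season 2).
#' @param adult_survival Annual adult survival probability.
#' @param carrying_cap Cap on same-sex adults; surplus new recruits are
#'   removed (mimicking translocation harvests).
#' @param lay_intercept Baseline start-of-season lay day (day 0 = 1 Sept).
#' @param first_year_offset Extra days for 1-year-old females.
#' @param mid_age_slope Slope (days/year) over ages 2-6.
#' @param old_age_slope Slope (days/year) above age 6.
#' @param tarsus_slope Days per mm of tarsus (centred at `tarsus_mean`).
#' @param tarsus_mean,tarsus_sd Female tarsus distribution (mm).
#' @param cue_slope Days per degC of the pre-season temperature cue.
#' @param year_sd SD of the cue-independent year effect (days).
#' @param V_A,V_PE,V_Mate,V_R Variance components (days^2).
#' @param clutch_gap Expected days between successive clutch starts.
#' @param max_clutches Maximum clutches per female-season.
#' @param reclutch_intercept,reclutch_start_slope,reclutch_firstyear
#'   Logit-scale reclutching model (slope per internal start-date SD).
#' @param eggs_min,eggs_max Clutch size range.
#' @param p_hatch Egg-to-hatchling survival.
#' @param fledge_peak,fledge_floor,fledge_opt_day,fledge_width
#'   Hatchling-to-fledgling Gaussian survival curve of lay day.
#' @param p_recruit Fledgling recruitment probability.
#' @param epp_rate Probability a chick's genetic sire is an extra-pair male.
#' @param female_fraction Chick sex ratio (fraction female).
#' @param temp_mean,temp_amplitude,temp_noise_sd,temp_year_sd Daily maximum
#'   temperature model: annual sinusoid (warmest mid-January), daily noise,
#'   and a per-season offset (the component the cue responds to).
#' @param cue_window,cue_anchor_day Cue definition: mean tmax over
#'   `cue_window` days before season day `cue_anchor_day`. The default
#'   anchor matches the grand-mean start of breeding the default
#'   configuration realises (~day 51), so the cue the analysis measures is
#'   the cue the birds respond to.
#' @param seed Base seed; per-component streams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_seasons = 16, first_season = 1998,
                       n_founder_females = 42, n_founder_males = 42,
                       second_release_females = 13,
                       second_release_males = 13,
                       adult_survival = 0.75, carrying_cap = 58,
                       lay_intercept = 50, first_year_offset = 12.5,
                       mid_age_slope = 0, old_age_slope = 1.33,
                       tarsus_slope = -1.70, tarsus_mean = 29,
                       tarsus_sd = 0.8,
                       cue_slope = -18.28, year_sd = 5.3,
                       V_A = 27, V_PE = 46.1, V_Mate = 14.6, V_R = 161,
                       clutch_gap = 40,
                       max_clutches = 3,
                       reclutch_intercept = -0.1,
                       reclutch_start_slope = -1.5,
                       reclutch_firstyear = -1.1,
                       eggs_min = 3, eggs_max = 5,
                       p_hatch = 0.73,
                       fledge_peak = 0.82, fledge_floor = 0.12,
                       fledge_opt_day = 44, fledge_width = 20,
                       p_recruit = 0.33, epp_rate = 0.6,
                       female_fraction = 0.5,
                       temp_mean = 17, temp_amplitude = 5.5,
                       temp_noise_sd = 1.5, temp_year_sd = 0.3,
                       cue_window = 50, cue_anchor_day = 51,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_seasons >= 3, cfg$V_A >= 0, cfg$V_PE >= 0,
            cfg$V_Mate >= 0, cfg$V_R >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic fan-out of per-component seeds from the base seed
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

# Gaussian survival curve of lay day for the hatchling-to-fledgling stage
fledge_survival_curve <- function(day, cfg) {
  cfg$fledge_floor + (cfg$fledge_peak - cfg$fledge_floor) *
    exp(-((day - cfg$fledge_opt_day) / cfg$fledge_width)^2)
}

simulate_temperatures <- function(cfg) {
  set.seed(component_seed(cfg$seed, 1))
  first <- as.Date(sprintf("%d-03-01", cfg$first_season))
  last <- as.Date(sprintf("%d-02-28", cfg$first_season + cfg$n_seasons))
  dates <- seq(first, last, by = "day")
  # season a date's pre-breeding window belongs to (Mar-Feb blocks)
  seas <- season_of_date(dates)
  seas[format(dates, "%m") %in% c("03", "04", "05", "06", "07", "08")] <-
    as.integer(format(dates, "%Y"))[format(dates, "%m") %in%
                                      c("03", "04", "05", "06", "07", "08")]
  season_levels <- cfg$first_season + seq_len(cfg$n_seasons) - 1L
  offsets <- stats::setNames(rnorm(cfg$n_seasons, 0, cfg$temp_year_sd),
                             season_levels)
  off <- offsets[as.character(seas)]
  off[is.na(off)] <- 0
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$temp_mean +
    cfg$temp_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  tmax <- seasonal + off + rnorm(length(dates), 0, cfg$temp_noise_sd)
  list(
    temperatures = tibble::tibble(date = dates, tmax = round(tmax, 1)),
    year_offsets = offsets
  )
}

#' Generate a complete synthetic study
#'
#' Runs the demographic and phenotypic simulation engine: founder releases,
#' per-season breeding with lay dates built from age, size, temperature-cue,
#' year, additive genetic (transmitted down the realized pedigree),
#' permanent environment, mate and residual effects; clutch sizes, stage
#' survivals (with the Gaussian hatchling-to-fledgling curve inducing
#' stabilizing selection on lay date), recruitment feeding back into later
#' breeder pools, extra-pair paternity, adult mortality and harvest caps.
#'
#' @param config A [sim_config()].
#' @return List of class `phen_study`: `records`, `pedigree`,
#'   `temperatures`, `truth` (ground-truth manifest: config, per-season cue
#'   and year effects, expected h2, per-individual breeding values).
#' @export
generate_breeding_data <- function(config = sim_config()) {
  cfg <- config
  tmp <- simulate_temperatures(cfg)
  season_levels <- cfg$first_season + seq_len(cfg$n_seasons) - 1L

  # realized cue per season, exactly as the analysis pipeline measures it
  cue_tbl <- compute_temperature_cue(
    tmp$temperatures,
    seasons = tibble::tibble(season = season_levels, start_day = NA),
    window = cfg$cue_window, grand_mean_day = cfg$cue_anchor_day
  )
  cue <- stats::setNames(cue_tbl$cue, cue_tbl$season)
  cue_c <- cue - mean(cue)

  set.seed(component_seed(cfg$seed, 2))
  year_eff <- stats::setNames(
    cfg$cue_slope * cue_c + rnorm(cfg$n_seasons, 0, cfg$year_sd),
    season_levels)

  # individual registry
  ind <- new.env(parent = emptyenv())
  ind$tbl <- tibble::tibble(
    id = character(), sex = character(), dam = NA_character_,
    sire = NA_character_, birth_season = NA_integer_,
    birth_clutch = NA_integer_, bv = numeric(0), pe = numeric(0),
    mate_eff = numeric(0), tarsus = numeric(0), age0_season = integer(0),
    alive = logical(0), recruit = logical(0)
  )
  counter <- 0L
  new_ids <- function(n, prefix) {
    counter <<- counter + n
    sprintf("%s%04d", prefix, counter - n + seq_len(n))
  }
  add_founders <- function(n, sex, season) {
    if (n == 0) return(invisible())
    ids <- new_ids(n, if (sex == "F") "F" else "M")
    ind$tbl <- dplyr::bind_rows(ind$tbl, tibble::tibble(
      id = ids, sex = sex, dam = NA_character_, sire = NA_character_,
      birth_season = NA_integer_, birth_clutch = NA_integer_,
      bv = rnorm(n, 0, sqrt(cfg$V_A)),
      pe = rnorm(n, 0, sqrt(cfg$V_PE)),
      mate_eff = rnorm(n, 0, sqrt(cfg$V_Mate)),
      tarsus = rnorm(n, cfg$tarsus_mean, cfg$tarsus_sd),
      age0_season = season - sample(1:3, n, replace = TRUE),
      alive = TRUE, recruit = TRUE
    ))
  }
  add_founders(cfg$n_founder_females, "F", season_levels[1])
  add_founders(cfg$n_founder_males, "M", season_levels[1])

  records <- vector("list", cfg$n_seasons * 120)
  rec_i <- 0L

  for (s_idx in seq_len(cfg$n_seasons)) {
    s <- season_levels[s_idx]
    if (s_idx == 2) {
      add_founders(cfg$second_release_females, "F", s)
      add_founders(cfg$second_release_males, "M", s)
    }
    tb <- ind$tbl
    fem_idx <- which(tb$alive & tb$sex == "F" &
                       (s - tb$age0_season) >= 1)
    male_idx <- which(tb$alive & tb$sex == "M" &
                        (s - tb$age0_season) >= 1)
    if (length(fem_idx) == 0 || length(male_idx) == 0) next

    chicks <- list()
    for (fi in fem_idx) {
      age <- s - tb$age0_season[fi]
      mate <- male_idx[sample.int(length(male_idx), 1)]
      age_part <- cfg$first_year_offset * (age == 1) +
        cfg$mid_age_slope * pmax(0, pmin(age, 6) - 2) +
        cfg$old_age_slope * pmax(0, age - 6)
      mu_base <- cfg$lay_intercept + age_part +
        cfg$tarsus_slope * (tb$tarsus[fi] - cfg$tarsus_mean) +
        year_eff[[as.character(s)]] + tb$bv[fi] + tb$pe[fi] +
        tb$mate_eff[mate]
      # independent residual per clutch around the expected schedule
      start <- max(5, round(mu_base + rnorm(1, 0, sqrt(cfg$V_R))))
      z_start <- (start - cfg$lay_intercept) / 12
      lay <- start
      for (k in seq_len(cfg$max_clutches)) {
        eggs <- sample(cfg$eggs_min:cfg$eggs_max, 1)
        hatch <- rbinom(1, eggs, cfg$p_hatch)
        fledge <- rbinom(1, hatch, fledge_survival_curve(lay, cfg))
        rec_i <- rec_i + 1L
        records[[rec_i]] <- tibble::tibble(
          female_id = tb$id[fi], social_male_id = tb$id[mate],
          season = s, clutch_number = k, lay_day = lay,
          hatch_day = if (hatch > 0) lay + 17L else NA_integer_,
          fledge_day = if (fledge > 0) lay + 38L else NA_integer_,
          n_eggs = eggs, n_hatchlings = hatch, n_fledglings = fledge,
          n_recruits = 0L,  # filled below from chick fates
          female_age = age, female_tarsus = tb$tarsus[fi]
        )
        if (fledge > 0) {
          sex <- ifelse(runif(fledge) < cfg$female_fraction, "F", "M")
          epp <- runif(fledge) < cfg$epp_rate
          sires <- rep(tb$id[mate], fledge)
          if (any(epp) && length(male_idx) > 1) {
            others <- setdiff(male_idx, mate)
            sires[epp] <- tb$id[others[sample.int(length(others),
                                                  sum(epp),
                                                  replace = TRUE)]]
          }
          recruit <- runif(fledge) < cfg$p_recruit
          ids <- new_ids(fledge, "C")
          # Mendelian transmission of breeding values
          sire_bv <- tb$bv[match(sires, tb$id)]
          bv <- (tb$bv[fi] + sire_bv) / 2 +
            rnorm(fledge, 0, sqrt(cfg$V_A / 2))
          chicks[[length(chicks) + 1]] <- tibble::tibble(
            id = ids, sex = sex, dam = tb$id[fi], sire = sires,
            birth_season = s, birth_clutch = k, bv = bv,
            pe = rnorm(fledge, 0, sqrt(cfg$V_PE)),
            mate_eff = rnorm(fledge, 0, sqrt(cfg$V_Mate)),
            tarsus = rnorm(fledge, cfg$tarsus_mean, cfg$tarsus_sd),
            age0_season = s, alive = recruit, recruit = recruit
          )
        }
        if (k == cfg$max_clutches) break
        p_re <- stats::plogis(cfg$reclutch_intercept +
                                cfg$reclutch_start_slope * z_start +
                                cfg$reclutch_firstyear * (age == 1))
        if (runif(1) > p_re) break
        lay <- max(lay + 7,
                   round(mu_base + cfg$clutch_gap * k +
                           rnorm(1, 0, sqrt(cfg$V_R))))
      }
    }
    if (length(chicks) > 0) {
      ind$tbl <- dplyr::bind_rows(ind$tbl, dplyr::bind_rows(chicks))
    }
    # adult mortality, then harvest down to the cap
    tb <- ind$tbl
    adults <- which(tb$alive)
    dies <- adults[runif(length(adults)) > cfg$adult_survival &
                     (s - tb$age0_season[adults]) >= 1]
    tb$alive[dies] <- FALSE
    for (sx in c("F", "M")) {
      pool <- which(tb$alive & tb$sex == sx)
      excess <- length(pool) - cfg$carrying_cap
      if (excess > 0) {
        newbies <- pool[tb$age0_season[pool] == s]
        cut <- newbies[sample.int(length(newbies),
                                  min(excess, length(newbies)))]
        tb$alive[cut] <- FALSE
        tb$recruit[cut] <- FALSE
      }
    }
    ind$tbl <- tb
  }

  records <- dplyr::bind_rows(records[seq_len(rec_i)])
  tb <- ind$tbl

  # recruit truth: a chick recruits if flagged and born before the last season
  recruited <- tb$recruit & !is.na(tb$birth_season) &
    tb$birth_season < max(season_levels)
  rec_counts <- tb[recruited, c("dam", "birth_season", "birth_clutch")] |>
    dplyr::count(.data$dam, .data$birth_season, .data$birth_clutch,
                 name = "n_rec")
  records <- records |>
    dplyr::left_join(rec_counts,
                     by = c(female_id = "dam", season = "birth_season",
                            clutch_number = "birth_clutch")) |>
    dplyr::mutate(n_recruits = dplyr::coalesce(.data$n_rec, 0L)) |>
    dplyr::select(-"n_rec")

  pedigree <- tb |>
    dplyr::select("id", "dam", "sire", "birth_season", "birth_clutch",
                  "sex") |>
    tibble::as_tibble()

  # expected heritability given the realized fixed-effect variance
  ages <- records$female_age
  fixed_pred <- cfg$first_year_offset * (ages == 1) +
    cfg$mid_age_slope * pmax(0, pmin(ages, 6) - 2) +
    cfg$old_age_slope * pmax(0, ages - 6) +
    cfg$tarsus_slope * (records$female_tarsus - cfg$tarsus_mean) +
    cfg$clutch_gap * (records$clutch_number - 1)
  V_F <- mean((fixed_pred - mean(fixed_pred))^2)
  h2_expected <- cfg$V_A / (V_F + cfg$V_Mate + cfg$V_PE + cfg$V_A + cfg$V_R)

  out <- list(
    records = records,
    pedigree = pedigree,
    temperatures = tmp$temperatures,
    truth = list(
      config = cfg,
      cue = cue_tbl,
      year_effects = year_eff,
      temp_year_offsets = tmp$year_offsets,
      V_F_realized = V_F,
      h2_expected = h2_expected,
      breeding_values = tb[, c("id", "bv")]
    )
  )
  class(out) <- "phen_study"
  out
}

#' @exportS3Method base::print
print.phen_study <- function(x, ...) {
  cat("Synthetic breeding study:", nrow(x$records), "clutch records,",
      length(unique(x$records$female_id)), "females,",
      length(unique(x$records$season)), "seasons,",
      nrow(x$pedigree), "pedigree individuals\n")
  invisible(x)
}

#' Generate only the pedigree of a synthetic study
#'
#' Runs the same engine as [generate_breeding_data()] (so the pedigree is
#' identical for the same configuration) and returns the pedigree table.
#'
#' @param config A [sim_config()].
#' @return Pedigree tibble.
#' @export
generate_pedigree <- function(config = sim_config()) {
  generate_breeding_data(config)$pedigree
}

#' Simulate data directly from the fitness-optimum model
#'
#' Draws standardized lay dates, year effects and responses straight from
#' the Gaussian-curve model (no demography): used for parameter-recovery
#' studies of [fit_optimum()].
#'
#' @param n Number of records.
#' @param n_years Number of years.
#' @param A,mu,sigma,sigma2_U Generating curve parameters.
#' @param B,theta Optional cue slope and per-year cue values.
#' @param family `"poisson"` or `"binomial"`.
#' @param trials Binomial trials per record.
#' @param x_mean Mean of the standardized lay dates (a nonzero value places
#'   the bulk of laying away from the optimum).
#' @param seed Seed.
#' @return Tibble (`x`, `year`, `y`, `trials`) with the generating values in
#'   `attr(, "truth")`.
#' @export
simulate_optimum_data <- function(n = 1400, n_years = 16, A = 1.5,
                                  mu = -0.9, sigma = 0.6, sigma2_U = 0.05,
                                  B = 0, theta = NULL,
                                  family = c("poisson", "binomial"),
                                  trials = 4, x_mean = 0, seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  if (is.null(theta)) theta <- rep(0, n_years)
  # truncated-normal year effects on [-2, 2]
  u <- numeric(n_years)
  for (j in seq_len(n_years)) {
    repeat {
      u[j] <- rnorm(1, 0, sqrt(sigma2_U))
      if (abs(u[j]) <= 2) break
    }
  }
  lambda <- mu + B * theta + u
  year <- sample.int(n_years, n, replace = TRUE)
  x <- rnorm(n, x_mean, 1)
  z <- fitness_curve(x, A, lambda[year], sigma)
  y <- if (family == "poisson") rpois(n, z) else
    rbinom(n, trials, pmin(z, 1 - 1e-12))
  out <- tibble::tibble(x = x, year = year, y = y,
                        trials = if (family == "binomial") trials else
                          NA_real_)
  attr(out, "truth") <- list(A = A, mu = mu, sigma = sigma,
                             sigma2_U = sigma2_U, B = B, u = u,
                             lambda = lambda)
  out
}

#' Build a ready-made synthetic fixture
#'
#' `"tiny"` is a few-season micro-study that runs the full pipeline in
#' seconds (useful for smoke tests); `"default"` is the study-scale dataset.
#' With `dir` set, the records, pedigree and temperature tables are written
#' as the same CSV dialects the readers consume, plus a YAML truth manifest.
#'
#' @param size `"tiny"` or `"default"`.
#' @param seed Base seed.
#' @param dir Optional output directory.
#' @return A `phen_study` (invisibly when writing to `dir`).
#' @export
make_fixture <- function(size = c("tiny", "default"), seed = 1, dir = NULL) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    sim_config(n_seasons = 4, n_founder_females = 6, n_founder_males = 6,
               second_release_females = 0, second_release_males = 0,
               carrying_cap = 9, seed = seed)
  } else {
    sim_config(seed = seed)
  }
  study <- generate_breeding_data(cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(study$records, file.path(dir, "records.csv"),
                     progress = FALSE)
    readr::write_csv(study$pedigree, file.path(dir, "pedigree.csv"),
                     progress = FALSE)
    readr::write_csv(study$temperatures, file.path(dir, "temperatures.csv"),
                     progress = FALSE)
    manifest <- study$truth
    manifest$breeding_values <- NULL
    manifest$config <- unclass(manifest$config)
    manifest$cue <- as.list(stats::setNames(manifest$cue$cue,
                                            manifest$cue$season))
    manifest$year_effects <- as.list(manifest$year_effects)
    manifest$temp_year_offsets <- as.list(manifest$temp_year_offsets)
    yaml::write_yaml(manifest, file.path(dir, "truth.yaml"))
    return(invisible(study))
  }
  study
}
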