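#' Gaussian fitness curve
#'
#' The latent expected fitness at standardized lay date `x` given curve
#' height `A`, optimum `lambda` and width `sigma`:
#' `Z = A * exp(-((x - lambda) / sigma)^2)`. Large `sigma` flattens the
#' curve, which is how a no-optimum model is expressible within the same
#' family.
#'
#' @param x Standardized lay date (numeric vector).
#' @param A Curve height (> 0).
#' @param lambda Optimum on the standardized scale.
#' @param sigma Curve width (> 0).
#' @return Numeric vector of latent fitness values.
#' @export
fitness_curve <- function(x, A, lambda, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  A * exp(-((x - lambda) / sigma)^2)
}

#' Format a season day as a calendar label
#'
#' Day 0 is 1 September; labels use a non-leap reference calendar.
#'
#' @param day Numeric season day.
#' @return Character label like `"Oct 5"`.
#' @export
format_season_day <- function(day) {
  format(as.Date("2001-09-01") + round(day), "%b %e") |>
    gsub(pattern = "  ", replacement = " ")
}

#' Pretest for the presence of a fitness optimum
#'
#' Fits a generalized linear mixed model of the fitness-related response with
#' linear plus quadratic standardized lay-date terms against the linear-only
#' model, both with a year random intercept (plus any confounders supplied).
#' An AIC improvement larger than `delta` supports an internal optimum and is
#' the gate for fitting the full Gaussian-curve model.
#'
#' @param data Tibble with the response, `lay_z` (standardized lay date) and
#'   grouping columns.
#' @param response Response expression string (counts, or
#'   `cbind(succ, fail)` for binomial).
#' @param covariates Extra fixed-effect terms.
#' @param random Random-intercept factors (default year/season).
#' @param family `"poisson"` or `"binomial"`.
#' @param delta AIC threshold (default 2).
#' @return List: `supported` (logical), `delta_aic`
#'   (AIC linear - AIC quadratic), `aic_linear`, `aic_quadratic`,
#'   `inconclusive` (TRUE when either fit failed to converge).
#' @export
quadratic_pretest <- function(data, response, covariates = character(),
                              random = "season",
                              family = c("poisson", "binomial"),
                              delta = 2) {
  family <- match.arg(family)
  f_lin <- fit_mixed_model(data, response, c("lay_z", covariates),
                           random, family)
  f_quad <- fit_mixed_model(data, response,
                            c("lay_z", "I(lay_z^2)", covariates),
                            random, family)
  d <- f_lin$aic - f_quad$aic
  list(
    supported = isTRUE(d > delta),
    delta_aic = d,
    aic_linear = f_lin$aic,
    aic_quadratic = f_quad$aic,
    inconclusive = !(f_lin$converged && f_quad$converged)
  )
}

#' Fit the hierarchical Gaussian fitness-optimum model
#'
#' Estimates, by adaptive Metropolis-within-Gibbs MCMC, the model in which a
#' latent Gaussian curve of standardized lay date `Z = A exp(-((x -
#' lambda_j)/sigma)^2)` has year-specific optima `lambda_j = mu + B theta_j +
#' u_j`, with `u_j` a truncated-normal `N_[-2,2](0, sigma2_U)` year effect,
#' and the observed response Poisson (fitness counts) or binomial (stage
#' survival) around `Z`. Priors: `mu ~ U(-2,2)`, `sigma ~ U(0,100)` (so a
#' flat, no-optimum curve is attainable), `A ~ U(0, A_max)`,
#' `1/sigma2_U ~ Gamma(0.001, 0.001)` and, when a temperature cue is
#' supplied, `B ~ N(0, 1e6)`.
#'
#' Multiple chains run from dispersed starts; convergence is summarised by
#' the Gelman-Rubin potential scale reduction factor and the fit is flagged
#' when any parameter exceeds `psrf_threshold`. Note that because `u_j` is
#' truncated but `mu` is merely bounded, a drawn `lambda_j` can fall outside
#' `[-2, 2]`; the fraction of such draws is reported.
#'
#' @param data Tibble with columns `x` (standardized lay date; attributes
#'   `center`/`scale` from [standardize()] enable day-scale reporting), `y`
#'   (response), `year` (season identifier), and `trials` for the binomial
#'   family.
#' @param family `"poisson"` or `"binomial"`.
#' @param A_max Upper prior bound for `A`: 5 for fitness counts, 1 for
#'   survival probabilities.
#' @param cue Optional per-year cue values: tibble with `year`/`season` and
#'   `theta` columns or a named numeric vector; must cover every year.
#'   `theta` should be standardized.
#' @param chains,n_iter,thin,burnin MCMC protocol (defaults: 8 chains of
#'   50,000 iterations, thin 10, burn-in 3,000).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param sample_u Sample year effects? `FALSE` collapses to a single shared
#'   optimum (used for toy/oracle problems and single-year data).
#' @param fix_A,fix_sigma Fix these parameters at a known value instead of
#'   sampling (toy/oracle problems); `NA` = sample.
#' @param min_total_ess Warn when total post-thin draws fall below this.
#' @param psrf_threshold Convergence flag threshold (1.1).
#' @return Object of class `optimum_fit`.
#' @export
fit_optimum <- function(data, family = c("poisson", "binomial"), A_max = 5,
                        cue = NULL, chains = 8, n_iter = 50000, thin = 10,
                        burnin = 3000, seed = 1, sample_u = TRUE,
                        fix_A = NA_real_, fix_sigma = NA_real_,
                        min_total_ess = 10000, psrf_threshold = 1.1) {
  family <- match.arg(family)
  stopifnot(all(c("x", "y", "year") %in% names(data)))
  x_center <- attr(data$x, "center")
  x_scale <- attr(data$x, "scale")
  x <- as.numeric(data$x)
  year_levels <- sort(unique(data$year))
  J <- length(year_levels)
  year_idx <- match(data$year, year_levels) - 1L
  trials <- if (family == "binomial") {
    if (!"trials" %in% names(data)) {
      stop("binomial family needs a 'trials' column", call. = FALSE)
    }
    as.numeric(data$trials)
  } else rep(1, nrow(data))
  if (family == "binomial" && any(data$y > trials)) {
    stop("successes exceed trials", call. = FALSE)
  }

  use_cue <- !is.null(cue)
  theta <- rep(0, J)
  if (use_cue) {
    if (is.data.frame(cue)) {
      ycol <- intersect(c("year", "season"), names(cue))[1]
      theta_map <- stats::setNames(cue$theta, cue[[ycol]])
    } else {
      theta_map <- cue
    }
    theta <- as.numeric(theta_map[as.character(year_levels)])
    if (anyNA(theta)) {
      stop("cue missing for season(s): ",
           paste(year_levels[is.na(theta)], collapse = ", "), call. = FALSE)
    }
  }

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    res <- optimum_mcmc_cpp(
      x = x, year = year_idx, y = as.numeric(data$y), trials = trials,
      family = if (family == "poisson") 0L else 1L, J = J, Amax = A_max,
      theta = theta, use_cue = use_cue, sample_u = sample_u,
      fix_A = fix_A, fix_sigma = fix_sigma,
      n_iter = as.integer(n_iter), burnin = as.integer(burnin),
      thin = as.integer(thin)
    )
    chain_draws[[ch]] <- res$draws
  }
  draws <- do.call(rbind, chain_draws)
  if (nrow(draws) < min_total_ess) {
    warning("total post-thin draws (", nrow(draws), ") below ",
            min_total_ess, call. = FALSE)
  }

  monitored <- setdiff(colnames(draws), "loglik")
  if (is.finite(fix_A)) monitored <- setdiff(monitored, "A")
  if (is.finite(fix_sigma)) monitored <- setdiff(monitored, "sigma")
  if (!sample_u) monitored <- setdiff(
    monitored, c("sigma2_U", grep("^u_", colnames(draws), value = TRUE)))
  diag_tbl <- if (chains >= 2) {
    psrf_table(lapply(chain_draws, function(m) m[, monitored, drop = FALSE]),
               threshold = psrf_threshold)
  } else {
    tibble::tibble(parameter = monitored, psrf = NA_real_, converged = NA)
  }
  converged <- if (chains >= 2) all(diag_tbl$converged) else NA

  u_cols <- grep("^u_", colnames(draws), value = TRUE)
  lambda <- draws[, "mu"] +
    (if (use_cue) outer(draws[, "B"], theta) else 0) +
    draws[, u_cols, drop = FALSE]
  colnames(lambda) <- paste0("lambda_", year_levels)
  frac_lambda_out <- mean(abs(lambda) > 2)

  out <- list(
    draws = draws, chains = chain_draws, lambda = lambda,
    psrf = diag_tbl, converged = converged,
    frac_lambda_outside = frac_lambda_out,
    family = family, A_max = A_max, use_cue = use_cue, theta = theta,
    year_levels = year_levels, sample_u = sample_u,
    x_center = x_center, x_scale = x_scale,
    data = data,
    settings = list(chains = chains, n_iter = n_iter, thin = thin,
                    burnin = burnin, seed = seed)
  )
  class(out) <- "optimum_fit"
  out
}

#' Fit the optimum model with a temperature cue on the optimum
#'
#' Convenience wrapper around [fit_optimum()] with a cue: adds the slope `B`
#' between the per-year cue `theta_j` and the optimum `lambda_j`, and reports
#' its pMCMC (twice the fraction of draws whose sign differs from the
#' posterior median's).
#'
#' @inheritParams fit_optimum
#' @param cue Per-year cue values (required here); standardized.
#' @return An `optimum_fit` whose `cue_slope` element holds the posterior
#'   summary and pMCMC of `B`.
#' @export
fit_optimum_with_cue <- function(data, cue, family = "poisson", A_max = 5,
                                 ...) {
  if (is.null(cue)) stop("cue is required", call. = FALSE)
  fit <- fit_optimum(data, family = family, A_max = A_max, cue = cue, ...)
  b <- fit$draws[, "B"]
  fit$cue_slope <- dplyr::bind_cols(
    posterior_point_and_interval(b),
    tibble::tibble(pmcmc = pmcmc(b))
  )
  fit
}

#' Posterior summary of the overall optimum
#'
#' Summarises the across-year optimum `mu` on the standardized scale and,
#' when the standardization parameters are known, on the day scale with a
#' calendar label (day 0 = 1 September).
#'
#' @param fit An `optimum_fit`.
#' @return Tibble with one row: mode/median/CI on both scales.
#' @export
optimum_summary <- function(fit) {
  s <- posterior_point_and_interval(fit$draws[, "mu"])
  out <- dplyr::mutate(s, parameter = "mu", .before = 1)
  if (!is.null(fit$x_center) && !is.null(fit$x_scale)) {
    out$mode_day <- unstandardize(s$mode, fit$x_center, fit$x_scale)
    out$median_day <- unstandardize(s$median, fit$x_center, fit$x_scale)
    out$lower_day <- unstandardize(s$lower, fit$x_center, fit$x_scale)
    out$upper_day <- unstandardize(s$upper, fit$x_center, fit$x_scale)
    out$date_label <- format_season_day(out$median_day)
  }
  out
}

#' Per-year optimum table
#'
#' @param fit An `optimum_fit`.
#' @return Tibble: year, posterior median and 95% CI of `lambda_j`, on the
#'   standardized and (when available) day scale.
#' @export
per_year_optima <- function(fit) {
  purrr::map_dfr(seq_along(fit$year_levels), function(j) {
    s <- posterior_point_and_interval(fit$lambda[, j])
    tibble::tibble(year = fit$year_levels[j], median = s$median,
                   lower = s$lower, upper = s$upper)
  }) |>
    (\(tb) {
      if (!is.null(fit$x_center)) {
        tb$median_day <- unstandardize(tb$median, fit$x_center, fit$x_scale)
      }
      tb
    })()
}

#' @exportS3Method base::print
print.optimum_fit <- function(x, ...) {
  cat("Gaussian fitness-optimum model (", x$family, " layer, A_max = ",
      x$A_max, ")\n", sep = "")
  cat(x$settings$chains, "chain(s) x", x$settings$n_iter, "iterations,",
      nrow(x$draws), "retained draws\n")
  if (isTRUE(!x$converged)) cat("WARNING: PSRF above threshold\n")
  print(optimum_summary(x))
  invisible(x)
}

#' Gelman-Rubin diagnostics table of an optimum fit
#'
#' @param fit An `optimum_fit` (needs >= 2 chains).
#' @return Tibble: parameter, psrf, converged.
#' @export
mcmc_diagnostics <- function(fit) {
  fit$psrf
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from posterior draws of the fitted optimum
#' model and compares them to the observed response. The headline statistic
#' is the zero fraction (fitness counts are prone to zero inflation); the
#' observed value is located within the replicate distribution.
#'
#' @param fit An `optimum_fit`.
#' @param n_rep Number of replicate datasets.
#' @param seed Seed for replicate simulation.
#' @return List of class `phen_ppc`: `observed_zero_frac`,
#'   `rep_zero_frac` (vector of length `n_rep`), `quantile` (position of the
#'   observed value), `observed` and `replicates` summaries for plotting.
#' @export
posterior_predictive_check <- function(fit, n_rep = 1000, seed = 1) {
  set.seed(seed)
  idx <- sample(nrow(fit$draws), n_rep, replace = n_rep > nrow(fit$draws))
  x <- as.numeric(fit$data$x)
  jmap <- match(fit$data$year, fit$year_levels)
  trials <- if (fit$family == "binomial") fit$data$trials else NULL
  rep_zero <- numeric(n_rep)
  rep_mean <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    k <- idx[r]
    lam <- fit$lambda[k, jmap]
    z <- fitness_curve(x, fit$draws[k, "A"], lam, fit$draws[k, "sigma"])
    y_rep <- if (fit$family == "poisson") rpois(length(x), z) else
      rbinom(length(x), trials, pmin(z, 1 - 1e-12))
    rep_zero[r] <- mean(y_rep == 0)
    rep_mean[r] <- mean(y_rep)
  }
  obs_zero <- mean(fit$data$y == 0)
  out <- list(
    observed_zero_frac = obs_zero,
    rep_zero_frac = rep_zero,
    rep_mean = rep_mean,
    observed_mean = mean(fit$data$y),
    quantile = mean(rep_zero < obs_zero),
    n_rep = n_rep
  )
  class(out) <- "phen_ppc"
  out
}

#' @exportS3Method base::print
print.phen_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_rep, " replicates)\n", sep = "")
  cat(sprintf("zero fraction: observed %.3f, replicates %.3f [%.3f, %.3f]\n",
              x$observed_zero_frac, median(x$rep_zero_frac),
              quantile(x$rep_zero_frac, 0.025),
              quantile(x$rep_zero_frac, 0.975)))
  invisible(x)
}

#' Modal lay date
#'
#' The mode of the lay-date distribution (argmax of its kernel density
#' estimate) is the natural central summary to compare with the fitness
#' optimum because lay dates are right-skewed, which shifts the mean but not
#' the mode.
#'
#' @param lay_days Numeric vector of lay days (>= 50 values recommended).
#' @param bw Kernel bandwidth (see [stats::density()]).
#' @return Tibble with `mode_day` and `date_label`.
#' @export
trait_mode <- function(lay_days, bw = "nrd0") {
  lay_days <- lay_days[!is.na(lay_days)]
  if (length(lay_days) < 50) {
    warning("fewer than 50 values: mode estimate may be unstable",
            call. = FALSE)
  }
  m <- kde_mode(lay_days, bw = bw)
  tibble::tibble(mode_day = m, date_label = format_season_day(m))
}
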