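#' Tidy an animal-model fit
#'
#' One row per variance component, fixed effect and derived ratio, with the
#' posterior mode, median and 95% HPD interval.
#'
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.animal_model_fit <- function(x, ...) {
  pars <- c("V_F", "V_Year", "V_Mate", "V_PE", "V_A", "V_R", "V_P",
            "h2", "r2", setdiff(colnames(x$X), "(Intercept)"),
            "(Intercept)")
  pars <- intersect(pars, names(x$draws))
  purrr::map_dfr(pars, function(p) {
    dplyr::mutate(posterior_point_and_interval(x$draws[[p]]),
                  term = p, .before = 1)
  })
}

#' @rdname tidy.animal_model_fit
#' @export
glance.animal_model_fit <- function(x, ...) {
  h <- heritability_repeatability(x)$summary
  tibble::tibble(
    h2_mode = h$mode[h$parameter == "h2"],
    h2_median = h$median[h$parameter == "h2"],
    r2_mode = h$mode[h$parameter == "r2"],
    n_obs = x$n_obs,
    n_individuals = x$n_individuals,
    n_draws = nrow(x$draws),
    min_ess = min(x$ess$ess)
  )
}

#' Posterior densities of the animal-model variance components
#'
#' @param object An `animal_model_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.animal_model_fit <- function(object, ...) {
  d <- object$draws[, c("V_A", "V_PE", "V_Mate", "V_Year", "V_R")] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "component",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = expression(Variance ~ (days^2)), y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' Tidy an optimum-model fit
#'
#' @param x An `optimum_fit`.
#' @param ... Unused.
#' @return Tibble of posterior summaries for the curve parameters.
#' @export
tidy.optimum_fit <- function(x, ...) {
  pars <- intersect(c("mu", "sigma", "A", "sigma2_U", "B"),
                    colnames(x$draws))
  purrr::map_dfr(pars, function(p) {
    dplyr::mutate(posterior_point_and_interval(x$draws[, p]),
                  term = p, .before = 1)
  })
}

#' @rdname tidy.optimum_fit
#' @export
glance.optimum_fit <- function(x, ...) {
  s <- optimum_summary(x)
  out <- tibble::tibble(
    optimum_median = s$median, optimum_lower = s$lower,
    optimum_upper = s$upper,
    n_draws = nrow(x$draws),
    max_psrf = if (all(is.na(x$psrf$psrf))) NA_real_ else
      max(x$psrf$psrf, na.rm = TRUE),
    converged = x$converged,
    frac_lambda_outside = x$frac_lambda_outside
  )
  if ("median_day" %in% names(s)) {
    out$optimum_day <- s$median_day
    out$optimum_date <- s$date_label
  }
  out
}

#' Fitted fitness curve over the data
#'
#' Plots the observed response against standardized lay date, the
#' posterior-mean Gaussian curve, and the optimum with its 95% interval.
#'
#' @param object An `optimum_fit`.
#' @param n_grid Grid resolution for the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optimum_fit <- function(object, n_grid = 200, ...) {
  xg <- seq(min(object$data$x), max(object$data$x), length.out = n_grid)
  A <- object$draws[, "A"]; s <- object$draws[, "sigma"]
  mu <- object$draws[, "mu"]
  idx <- seq(1, nrow(object$draws),
             by = max(1, floor(nrow(object$draws) / 500)))
  curve <- vapply(xg, function(xx) {
    mean(fitness_curve(xx, A[idx], mu[idx], s[idx]))
  }, numeric(1))
  sm <- optimum_summary(object)
  obs <- tibble::tibble(x = as.numeric(object$data$x),
                        y = object$data$y /
                          (if (object$family == "binomial")
                            object$data$trials else 1))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_count(alpha = 0.3) +
    ggplot2::geom_line(data = tibble::tibble(x = xg, y = curve),
                       colour = "red", linewidth = 1) +
    ggplot2::geom_vline(xintercept = sm$median, colour = "red",
                        linetype = "dashed") +
    ggplot2::annotate("rect", xmin = sm$lower, xmax = sm$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red") +
    ggplot2::labs(x = "Standardized lay date",
                  y = if (object$family == "binomial") "Survival" else
                    "Fitness") +
    ggplot2::theme_minimal()
}

#' @export
tidy.phen_mixed_fit <- function(x, ...) x$estimates

#' @export
glance.phen_mixed_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, logLik_ml = x$logLik_ml,
                 logLik_reml = x$logLik_reml, k = x$k, n_obs = x$n_obs,
                 converged = x$converged)
}

#' @export
tidy.phen_stepwise <- function(x, ...) x$trace

#' Posterior predictive zero-fraction plot
#'
#' @param object A `phen_ppc` from [posterior_predictive_check()].
#' @param ... Unused.
#' @return A ggplot: replicate zero fractions with the observed value.
#' @export
autoplot.phen_ppc <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(zf = object$rep_zero_frac),
                  ggplot2::aes(x = .data$zf)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_zero_frac,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "Zero fraction in replicate data", y = "Replicates") +
    ggplot2::theme_minimal()
}
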