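#' Age design matrices for phenology models
#'
#' Builds the candidate encodings of female age used when modelling the start
#' of the breeding season: a linear trend, a quadratic trend, broken-line
#' (hinge) models with breaks at age 2 or at ages 2 and 6, a separate slope
#' per age transition, and a first-year indicator combined with a mid/old
#' broken line (capturing a first-year offset, a flat segment over ages 2-6
#' and a late-life slope).
#'
#' Hinge terms are `max(0, age - knot)`; the first-year indicator is 1 iff
#' `age == 1`.
#'
#' @param ages Integer vector of ages (>= 1).
#' @param variant One of `"linear"`, `"quadratic"`, `"break2"`,
#'   `"break2_6"`, `"per_transition"`, `"firstyear_plus_break"`.
#' @return Numeric design matrix (no intercept column) with named columns.
#' @export
build_age_design <- function(ages,
                             variant = c("linear", "quadratic", "break2",
                                         "break2_6", "per_transition",
                                         "firstyear_plus_break")) {
  variant <- match.arg(variant)
  if (any(ages < 1, na.rm = TRUE)) stop("ages must be >= 1", call. = FALSE)
  hinge <- function(k) pmax(0, ages - k)
  out <- switch(
    variant,
    linear = cbind(age = ages),
    quadratic = cbind(age = ages, age_sq = ages^2),
    break2 = cbind(age = ages, age_over2 = hinge(2)),
    break2_6 = cbind(age = ages, age_over2 = hinge(2), age_over6 = hinge(6)),
    per_transition = {
      if (all(is.na(ages))) stop("all ages missing", call. = FALSE)
      ks <- seq_len(max(ages, na.rm = TRUE) - 1L)
      if (length(ks) == 0) {
        stop("per_transition needs at least two distinct ages", call. = FALSE)
      }
      m <- vapply(ks, function(k) pmax(0, pmin(ages, k + 1) - k),
                  numeric(length(ages)))
      colnames(m) <- paste0("trans_", ks, "_", ks + 1L)
      m
    },
    firstyear_plus_break = cbind(
      first_year = as.numeric(ages == 1),
      age_mid = pmax(0, pmin(ages, 6) - 2),
      age_over6 = hinge(6)
    )
  )
  out
}

#' Akaike information criterion
#'
#' @param lnL Maximized log-likelihood (at ML, not REML).
#' @param k Number of estimated parameters.
#' @return `2 * k - 2 * lnL`.
#' @export
aic <- function(lnL, k) {
  stopifnot(k >= 0)
  2 * k - 2 * lnL
}

#' Fit a mixed model with the package's reporting conventions
#'
#' Thin wrapper around lme4 with the reporting conventions used throughout
#' the analysis: the AIC is computed under maximum likelihood while the
#' reported estimates come from REML (Gaussian responses; for binomial and
#' Poisson GLMMs the single Laplace fit serves both purposes). Gaussian
#' fixed-effect p-values use Satterthwaite degrees of freedom (lmerTest).
#' Rows with missing response or covariates are dropped listwise with a
#' message.
#'
#' @param data A tibble.
#' @param response Response expression as a string, e.g. `"start_day"` or
#'   `"cbind(n_fledglings, n_hatchlings - n_fledglings)"`.
#' @param fixed_terms Character vector of fixed-effect terms (may be empty
#'   for an intercept-only model).
#' @param random Character vector of random-intercept grouping factors, e.g.
#'   `c("female_id", "season")`. May be empty, in which case a plain
#'   (generalized) linear model is fitted.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @return Object of class `phen_mixed_fit`: a list with `estimates` (tibble:
#'   term, estimate, se, statistic, p_value), `varcomp` (tibble: group,
#'   variance), `aic` (ML), `logLik_ml`, `logLik_reml`, `n_obs`, `k`,
#'   `converged`, and the underlying fitted model objects.
#' @export
fit_mixed_model <- function(data, response, fixed_terms = character(),
                            random = character(),
                            family = c("gaussian", "binomial", "poisson")) {
  family <- match.arg(family)
  rhs_fixed <- if (length(fixed_terms) > 0) {
    paste(fixed_terms, collapse = " + ")
  } else "1"
  rhs_rand <- if (length(random) > 0) {
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  } else ""
  rhs <- paste(c(rhs_fixed, rhs_rand)[nzchar(c(rhs_fixed, rhs_rand))],
               collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))

  used_vars <- intersect(all.vars(fml), names(data))
  keep <- stats::complete.cases(data[, used_vars, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped (missing response or covariates)")
  }
  d <- data[keep, , drop = FALSE]

  converged <- TRUE
  note <- character()
  wrn <- function(w) {
    converged <<- FALSE
    note <<- c(note, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (length(random) == 0) {
    fit <- if (family == "gaussian") stats::lm(fml, data = d) else
      stats::glm(fml, data = d, family = family)
    sm <- summary(fit)$coefficients
    est <- tibble::tibble(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      statistic = sm[, 3], p_value = sm[, 4]
    )
    ll <- as.numeric(logLik(fit))
    k <- attr(logLik(fit), "df")
    out <- list(estimates = est, varcomp = tibble::tibble(),
                aic = aic(ll, k), logLik_ml = ll, logLik_reml = NA_real_,
                n_obs = stats::nobs(fit), k = k, converged = TRUE,
                family = family, formula = fml, fit_ml = fit, fit_reml = fit,
                notes = character())
    class(out) <- "phen_mixed_fit"
    return(out)
  }

  if (family == "gaussian") {
    fit_ml <- withCallingHandlers(
      lmerTest::lmer(fml, data = d, REML = FALSE), warning = wrn)
    fit_reml <- withCallingHandlers(
      lmerTest::lmer(fml, data = d, REML = TRUE), warning = wrn)
    sm <- summary(fit_reml)$coefficients
    est <- tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], statistic = sm[, "t value"],
      p_value = sm[, "Pr(>|t|)"], df = sm[, "df"]
    )
    logLik_reml <- as.numeric(logLik(fit_reml))
  } else {
    fit_ml <- withCallingHandlers(
      lme4::glmer(fml, data = d, family = family), warning = wrn)
    fit_reml <- fit_ml
    sm <- summary(fit_ml)$coefficients
    est <- tibble::tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], statistic = sm[, "z value"],
      p_value = sm[, "Pr(>|z|)"]
    )
    logLik_reml <- NA_real_
  }
  vc <- lme4::VarCorr(fit_reml)
  varcomp <- tibble::tibble(
    group = c(names(vc),
              if (family == "gaussian") "Residual" else character()),
    variance = c(vapply(vc, function(m) m[1, 1], numeric(1)),
                 if (family == "gaussian") attr(vc, "sc")^2 else numeric())
  )
  ll <- as.numeric(logLik(fit_ml))
  k <- attr(logLik(fit_ml), "df")
  out <- list(
    estimates = est, varcomp = varcomp, aic = aic(ll, k),
    logLik_ml = ll, logLik_reml = logLik_reml,
    n_obs = stats::nobs(fit_ml), k = k, converged = converged,
    family = family, formula = fml, fit_ml = fit_ml, fit_reml = fit_reml,
    notes = note
  )
  class(out) <- "phen_mixed_fit"
  out
}

#' @exportS3Method base::print
print.phen_mixed_fit <- function(x, ...) {
  cat("Mixed model (", x$family, "): ", deparse(x$formula), "\n", sep = "")
  cat("n =", x$n_obs, " AIC(ML) =", round(x$aic, 1),
      if (!x$converged) " [convergence warning]" else "", "\n")
  print(x$estimates, ...)
  invisible(x)
}

#' Stepwise AIC variable selection
#'
#' Implements the study's selection procedure: (1) each candidate variable is
#' evaluated alone against the null model and discarded unless it improves
#' the AIC by more than `delta`; (2) the survivors form a full model; (3)
#' variables are dropped one at a time, keeping the drop whenever it yields
#' the lowest AIC, iterating until no drop helps; (4) the best *inferential*
#' model is the most parsimonious model whose AIC lies within `delta` of the
#' best predictive model. Mutually exclusive encodings of one covariate (the
#' age variants) are supplied as an `exclusive` group so at most one enters
#' the full model.
#'
#' @param data A tibble.
#' @param response Response expression (see [fit_mixed_model()]).
#' @param candidates Named list: each element is a character vector of
#'   fixed-effect terms constituting one candidate variable.
#' @param base_terms Fixed-effect terms always included (on top of the
#'   intercept).
#' @param random Random-intercept grouping factors.
#' @param family Model family.
#' @param delta AIC improvement required to call a variable significant, and
#'   the parsimony window; 2 by default.
#' @param exclusive Optional list of character vectors of candidate names
#'   that are mutually exclusive alternatives; the best-AIC member of each
#'   group is carried forward.
#' @return List of class `phen_stepwise`: `selected` (candidate names in the
#'   inferential model), `fit` (the selected [fit_mixed_model()] object),
#'   `trace` (tibble of every model evaluated: label, k, logLik, AIC, dAIC,
#'   decision), `best_predictive` (names in the lowest-AIC model).
#' @export
aic_stepwise <- function(data, response, candidates,
                         base_terms = character(), random = character(),
                         family = "gaussian", delta = 2,
                         exclusive = NULL) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  trace <- tibble::tibble(step = character(), model = character(),
                          k = integer(), logLik = numeric(), aic = numeric(),
                          decision = character())
  fit_cache <- new.env(parent = emptyenv())
  fit_set <- function(vars) {
    key <- paste0("m:", paste(sort(vars), collapse = "+"))
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    terms <- c(base_terms, unlist(candidates[vars], use.names = FALSE))
    f <- fit_mixed_model(data, response, terms, random, family)
    fit_cache[[key]] <- f
    f
  }
  log_row <- function(step, vars, f, decision) {
    trace <<- dplyr::bind_rows(trace, tibble::tibble(
      step = step,
      model = if (length(vars) == 0) "<null>" else
        paste(sort(vars), collapse = " + "),
      k = f$k, logLik = f$logLik_ml, aic = f$aic, decision = decision))
  }

  null_fit <- fit_set(character())
  log_row("null", character(), null_fit, "reference")

  # (1) each variable alone vs null
  solo_aic <- vapply(names(candidates), function(v) fit_set(v)$aic,
                     numeric(1))
  survivors <- character()
  for (v in names(candidates)) {
    f <- fit_set(v)
    sig <- null_fit$aic - f$aic > delta
    log_row("solo", v, f, if (sig) "kept" else "discarded")
    if (sig) survivors <- c(survivors, v)
  }
  # mutually exclusive encodings: keep the best-AIC survivor of each group
  if (!is.null(exclusive)) {
    for (grp in exclusive) {
      present <- intersect(grp, survivors)
      if (length(present) > 1) {
        best <- present[which.min(solo_aic[present])]
        survivors <- setdiff(survivors, setdiff(present, best))
      }
    }
  }
  if (length(survivors) == 0) {
    out <- list(selected = character(), fit = null_fit, trace = trace,
                best_predictive = character())
    class(out) <- "phen_stepwise"
    return(out)
  }

  # (2)-(3) full model of survivors, then iterated drop-one
  current <- survivors
  repeat {
    f_cur <- fit_set(current)
    log_row("drop-one", current, f_cur, "current")
    if (length(current) == 0) break
    drop_aic <- vapply(current, function(v) fit_set(setdiff(current, v))$aic,
                       numeric(1))
    best_drop <- names(drop_aic)[which.min(drop_aic)]
    if (min(drop_aic) < f_cur$aic) {
      log_row("drop-one", setdiff(current, best_drop),
              fit_set(setdiff(current, best_drop)),
              paste("dropped", best_drop))
      current <- setdiff(current, best_drop)
    } else break
  }
  best_predictive <- current

  # (4) parsimony: most parsimonious nested submodel within delta of the best
  best_aic <- fit_set(best_predictive)$aic
  subsets <- unlist(lapply(0:length(best_predictive), function(m)
    utils::combn(best_predictive, m, simplify = FALSE)), recursive = FALSE)
  cand_tbl <- purrr::map_dfr(subsets, function(vars) {
    f <- fit_set(vars)
    tibble::tibble(model = list(vars), k = f$k, aic = f$aic)
  }) |>
    dplyr::filter(.data$aic - best_aic < delta) |>
    dplyr::arrange(.data$k, .data$aic)
  selected <- cand_tbl$model[[1]]
  if (length(selected) < length(best_predictive)) {
    log_row("parsimony", selected, fit_set(selected),
            sprintf("chosen (dAIC %.2f from best)",
                    fit_set(selected)$aic - best_aic))
  }

  trace <- trace |>
    dplyr::mutate(dAIC = .data$aic - min(.data$aic))
  out <- list(selected = selected, fit = fit_set(selected), trace = trace,
              best_predictive = best_predictive)
  class(out) <- "phen_stepwise"
  out
}

#' @exportS3Method base::print
print.phen_stepwise <- function(x, ...) {
  cat("AIC stepwise selection\n")
  cat("Best predictive model:",
      if (length(x$best_predictive) == 0) "<null>" else
        paste(x$best_predictive, collapse = " + "), "\n")
  cat("Selected (inferential):",
      if (length(x$selected) == 0) "<null>" else
        paste(x$selected, collapse = " + "), "\n")
  invisible(x)
}

#' Write an AIC trace as TSV
#'
#' @param x A `phen_stepwise` object.
#' @param path Output path.
#' @export
write_aic_trace <- function(x, path) {
  readr::write_tsv(x$trace, path, progress = FALSE)
  invisible(path)
}
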