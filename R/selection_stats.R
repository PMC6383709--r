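#' Relative fitness
#'
#' Divides absolute fitness by its mean so the result averages 1.
#'
#' @param W Non-negative fitness vector with positive mean.
#' @return Relative fitness vector.
#' @export
relative_fitness <- function(W) {
  W <- as.numeric(W)
  mw <- mean(W, na.rm = TRUE)
  if (!is.finite(mw) || mw <= 0) {
    stop("mean fitness must be positive", call. = FALSE)
  }
  W / mw
}

#' Robertson selection differential
#'
#' The selection differential on a trait is the covariance between the trait
#' and relative fitness (equivalently, the change in trait mean produced by
#' fitness-weighting the distribution within a generation). The sample
#' (n - 1) covariance is the default; standard errors come from a
#' non-parametric bootstrap over records.
#'
#' @param trait Trait vector (days here).
#' @param W Absolute fitness vector, paired with `trait`.
#' @param n_boot Bootstrap replicates for the SE (0 skips it).
#' @param seed Bootstrap seed.
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Tibble: `S` (trait units), `S_std` (trait SD units), their
#'   bootstrap SEs, `n_obs`.
#' @export
selection_differential <- function(trait, W, n_boot = 2000, seed = 1,
                                   denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(trait) & !is.na(W)
  trait <- trait[ok]; W <- W[ok]
  if (length(trait) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(trait) == 0) {
    warning("zero trait variance: S = 0", call. = FALSE)
    return(tibble::tibble(S = 0, S_se = 0, S_std = 0, S_std_se = 0,
                          n_obs = length(trait)))
  }
  S_of <- function(tr, w) {
    s <- cov(tr, relative_fitness(w))
    if (denominator == "n") s <- s * (length(tr) - 1) / length(tr)
    s
  }
  S <- S_of(trait, W)
  sd_tr <- sd(trait)
  se <- se_std <- NA_real_
  if (n_boot > 0) {
    boots <- bootstrap_se(function(d) S_of(d$trait, d$W),
                          tibble::tibble(trait = trait, W = W),
                          B = n_boot, seed = seed)
    se <- boots$se
    boots_std <- bootstrap_se(function(d) S_of(d$trait, d$W) / sd(d$trait),
                              tibble::tibble(trait = trait, W = W),
                              B = n_boot, seed = seed)
    se_std <- boots_std$se
  }
  tibble::tibble(S = S, S_se = se, S_std = S / sd_tr, S_std_se = se_std,
                 n_obs = length(trait))
}

#' Lande-Arnold selection gradients
#'
#' Regresses relative fitness on the standardized trait and its square. The
#' linear coefficient is the directional gradient beta; the quadratic
#' gradient gamma is, by the usual convention, twice the quadratic
#' regression coefficient (the raw coefficient is available via
#' `quadratic_convention = "raw"`). Standard errors are the regression SEs
#' (gamma's doubled with its coefficient).
#'
#' @param trait Trait vector; standardized internally to mean 0, sd 1.
#' @param W Absolute fitness vector.
#' @param quadratic_convention `"doubled"` (gamma = 2c) or `"raw"`.
#' @return Tibble: `beta`, `beta_se`, `gamma`, `gamma_se`, convention,
#'   `n_obs`.
#' @export
selection_gradients <- function(trait, W,
                                quadratic_convention = c("doubled", "raw")) {
  quadratic_convention <- match.arg(quadratic_convention)
  ok <- !is.na(trait) & !is.na(W)
  trait <- trait[ok]; W <- W[ok]
  if (sd(trait) == 0) stop("constant trait: gradients undefined",
                           call. = FALSE)
  z <- as.numeric(scale(trait))
  w <- relative_fitness(W)
  fit <- lm(w ~ z + I(z^2))
  sm <- summary(fit)$coefficients
  mult <- if (quadratic_convention == "doubled") 2 else 1
  tibble::tibble(
    beta = sm["z", "Estimate"], beta_se = sm["z", "Std. Error"],
    gamma = mult * sm["I(z^2)", "Estimate"],
    gamma_se = mult * sm["I(z^2)", "Std. Error"],
    quadratic_convention = quadratic_convention,
    n_obs = length(z)
  )
}

#' Non-parametric bootstrap standard error
#'
#' Resamples records with replacement, recomputes the statistic, and reports
#' the standard deviation over replicates. Degenerate resamples (where the
#' statistic is NA or errors, e.g. zero variance) are skipped and counted.
#'
#' @param statistic Function of a resampled data frame returning a scalar.
#' @param data Data frame resampled at the row level.
#' @param B Number of replicates (>= 200 recommended).
#' @param seed Seed; identical seeds give identical SEs.
#' @return List: `se`, `estimates` (vector), `n_skipped`.
#' @export
bootstrap_se <- function(statistic, data, B = 2000, seed = 1) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  set.seed(seed)
  n <- nrow(data)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  skipped <- sum(is.na(vals))
  list(se = sd(vals, na.rm = TRUE), estimates = vals, n_skipped = skipped)
}

#' Full selection-statistics table for lay date
#'
#' Computes the Robertson differential (raw and standardized) and the
#' Lande-Arnold gradients for a trait/fitness pairing, at the record level.
#'
#' @param data Tibble with the trait and fitness columns.
#' @param trait Trait column name.
#' @param fitness Fitness column name.
#' @inheritParams selection_differential
#' @inheritParams selection_gradients
#' @return Tibble in long form: statistic, estimate, se, n_obs.
#' @export
selection_stats <- function(data, trait = "lay_day", fitness = "n_recruits",
                            n_boot = 2000, seed = 1,
                            quadratic_convention = "doubled") {
  tr <- data[[trait]]
  W <- data[[fitness]]
  sdif <- selection_differential(tr, W, n_boot = n_boot, seed = seed)
  grad <- selection_gradients(tr, W,
                              quadratic_convention = quadratic_convention)
  tibble::tibble(
    statistic = c("S", "S_std", "beta", "gamma"),
    estimate = c(sdif$S, sdif$S_std, grad$beta, grad$gamma),
    se = c(sdif$S_se, sdif$S_std_se, grad$beta_se, grad$gamma_se),
    n_obs = sdif$n_obs
  )
}
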