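#' Fit a Bayesian Gaussian animal model for lay date
#'
#' Decomposes lay-date variance into additive genetic (pedigree-structured),
#' permanent environment (female identity), social mate, year and residual
#' components, with clutch number as a fixed effect (which absorbs most of
#' the right skew of lay dates). Estimation is by Gibbs sampling: all
#' location effects (fixed effects and random-effect solutions) are drawn
#' jointly from their Gaussian full conditional through a sparse Cholesky
#' factorisation of the mixed-model equations, the residual variance from
#' its conjugate scaled-inverse-chi-squared conditional (prior `V = 1`,
#' `nu = 0.02`), and each random-effect variance by a Metropolis step on the
#' log scale under a parameter-expanded prior: the scaled F(1,1) distribution
#' with scale `alpha_V = 1000` (equivalently, a half-Cauchy prior with scale
#' `sqrt(1000)` on the standard deviation), the marginal implied by the
#' expansion `V = 1`, `nu = 1`, `alpha.mu = 0`, `alpha.V = 1000`.
#'
#' The pedigree enters through the sparse inverse additive relationship
#' matrix and is pruned to phenotyped females and their ancestors before
#' fitting. Records with a missing response or clutch number are dropped
#' listwise (reported); females absent from the pedigree are an error.
#'
#' @param records Breeding-record tibble with `female_id`,
#'   `social_male_id`, `season`, `clutch_number` and the response column.
#' @param pedigree Pedigree tibble (`id`, `dam`, `sire`).
#' @param response Response column name (default `"lay_day"`).
#' @param n_iter,thin,burnin MCMC protocol; defaults follow the package's
#'   reference protocol of 500,000 iterations, thinning 10, burn-in 3,000.
#'   Shorter runs are fine for exploration and simulation studies.
#' @param seed Integer seed.
#' @param alpha_V Scale of the parameter-expanded variance prior.
#' @param resid_prior List with `V` and `nu` for the residual variance.
#' @param ess_warn Warn when any variance component's effective sample size
#'   falls below this (set lower for reduced runs).
#' @param prune Prune the pedigree to phenotyped females plus ancestors?
#' @return Object of class `animal_model_fit` with a `draws` tibble (one row
#'   per retained draw: `V_A`, `V_PE`, `V_Mate`, `V_Year`, `V_R`, `V_F`,
#'   fixed-effect coefficients, `V_P`, `h2`, `r2`), an `ess` table, and
#'   metadata.
#' @export
fit_animal_model <- function(records, pedigree, response = "lay_day",
                             n_iter = 500000, thin = 10, burnin = 3000,
                             seed = 1, alpha_V = 1000,
                             resid_prior = list(V = 1, nu = 0.02),
                             ess_warn = 8000, prune = TRUE) {
  set.seed(seed)
  records <- tibble::as_tibble(records)
  req <- c("female_id", "season", "clutch_number", response)
  stopifnot(all(req %in% names(records)))
  keep <- stats::complete.cases(records[, req])
  if (any(!keep)) {
    message(sum(!keep), " record(s) dropped (missing ", response,
            " or clutch number)")
    records <- records[keep, , drop = FALSE]
  }
  females <- unique(as.character(records$female_id))
  ped_ids <- as.character(pedigree$id)
  orphans <- setdiff(females, ped_ids)
  if (length(orphans) > 0) {
    stop("females with records but absent from the pedigree: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ..." else "", call. = FALSE)
  }
  ped <- if (prune) prune_pedigree(pedigree, females) else
    sort_pedigree(pedigree)
  Ainv <- additive_relationship_inverse(ped)
  ids <- rownames(Ainv)

  n <- nrow(records)
  y <- as.numeric(records[[response]])
  X <- cbind(`(Intercept)` = 1, clutch_number = records$clutch_number)
  p <- ncol(X)
  fem <- factor(as.character(records$female_id), levels = unique(females))
  male <- as.character(records$social_male_id)
  male[is.na(male)] <- "<unknown>"
  male <- factor(male)
  yearf <- factor(records$season)

  Za <- Matrix::sparseMatrix(i = seq_len(n),
                             j = match(as.character(fem), ids),
                             x = 1, dims = c(n, length(ids)))
  Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fem), x = 1,
                              dims = c(n, nlevels(fem)))
  Zm <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(male), x = 1,
                             dims = c(n, nlevels(male)))
  Zy <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(yearf), x = 1,
                             dims = c(n, nlevels(yearf)))
  W <- cbind(methods::as(X, "CsparseMatrix"), Za, Zpe, Zm, Zy)
  q <- c(a = ncol(Za), pe = ncol(Zpe), m = ncol(Zm), y = ncol(Zy))
  offs <- p + c(0, cumsum(q))[1:4]
  ranges <- Map(function(o, k) o + seq_len(k), offs, q)
  names(ranges) <- names(q)

  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  Ipe <- Matrix::Diagonal(q["pe"])
  Im <- Matrix::Diagonal(q["m"])
  Iy <- Matrix::Diagonal(q["y"])
  Zp <- Matrix::Diagonal(p, x = 0)

  # log prior density of a variance under the scaled-F(1,1) construction
  lprior_v <- function(v) {
    -log(pi) - 0.5 * log(v / alpha_V) - log1p(v / alpha_V) - log(alpha_V)
  }

  vy <- var(y)
  yty <- sum(y^2)
  # state: log variances (a, pe, m, y, e)
  lv <- log(c(a = vy / 10, pe = vy / 10, m = vy / 10, y = vy / 10,
              e = vy / 2))
  nu0 <- resid_prior$nu
  V0 <- resid_prior$V

  # marginal log posterior of the variances with all location effects
  # (flat-prior fixed effects included) integrated out analytically
  Ch_cur <- NULL
  # Assemble C = W'W/ve + blockdiag(0, Ainv/va, I/vpe, I/vm, I/vy) at the
  # slot level: the sparsity pattern is fixed, so precompute, once, where
  # each component's entries land in the pattern's x-slot.
  ntot_all <- p + sum(q)
  key_of <- function(i0, j0) i0 + j0 * ntot_all  # 0-based upper-tri keys
  dsc_keys <- function(M, off = 0L) {
    j0 <- rep(seq_len(ncol(M)) - 1L, diff(M@p))
    key_of(M@i + off, j0 + off)
  }
  Cpat <- Matrix::forceSymmetric(
    abs(WtW) +
      Matrix::bdiag(Matrix::Diagonal(p),
                    abs(Ainv) + Matrix::Diagonal(q[["a"]]), Ipe, Im, Iy))
  Cpat <- methods::as(Cpat, "CsparseMatrix")
  pat_keys <- dsc_keys(Cpat)
  map_wtw <- match(dsc_keys(WtW), pat_keys)
  map_ainv <- match(dsc_keys(Ainv, off = p), pat_keys)
  diag_keys <- function(off, k) match(key_of(off + seq_len(k) - 1L,
                                             off + seq_len(k) - 1L),
                                      pat_keys)
  map_pe <- diag_keys(p + q[["a"]], q[["pe"]])
  map_m <- diag_keys(p + q[["a"]] + q[["pe"]], q[["m"]])
  map_y <- diag_keys(p + q[["a"]] + q[["pe"]] + q[["m"]], q[["y"]])
  wtw_x <- WtW@x
  ainv_x <- Ainv@x
  build_C <- function(v) {
    x <- numeric(length(pat_keys))
    x[map_wtw] <- wtw_x / v[["e"]]
    x[map_ainv] <- x[map_ainv] + ainv_x / v[["a"]]
    x[map_pe] <- x[map_pe] + 1 / v[["pe"]]
    x[map_m] <- x[map_m] + 1 / v[["m"]]
    x[map_y] <- x[map_y] + 1 / v[["y"]]
    C <- Cpat
    C@x <- x
    C
  }
  marg_lpost <- function(lvv) {
    v <- exp(lvv)
    C <- build_C(v)
    Ch <- if (is.null(Ch_cur)) {
      Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      Matrix::update(Ch_cur, C)
    }
    rhs <- Wty / v[["e"]]
    theta_hat <- as.numeric(Matrix::solve(Ch, rhs))
    logdetC <- as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                              sqrt = FALSE)$modulus)
    lml <- -0.5 * (n * lvv[["e"]] + sum(q * lvv[1:4]) + logdetC +
                     yty / v[["e"]] - sum(rhs * theta_hat))
    lp <- sum(vapply(1:4, function(k) lprior_v(v[[k]]), numeric(1))) +
      (-(nu0 / 2 + 1) * lvv[["e"]] - nu0 * V0 / (2 * v[["e"]]))
    list(lp = lml + lp + sum(lvv), Ch = Ch)  # + sum(lvv): log-scale Jacobian
  }
  cur <- marg_lpost(lv)
  Ch_cur <- cur$Ch

  # joint random-walk on the log variances, scale adapted during burn-in
  prop_sd <- c(a = 0.5, pe = 0.5, m = 0.5, y = 0.5, e = 3 / sqrt(n))
  adapt_mult <- 1
  acc_window <- 0L

  n_keep <- ceiling((n_iter - burnin) / thin)
  draw_names <- c("V_A", "V_PE", "V_Mate", "V_Year", "V_R",
                  colnames(X), "V_F")
  out <- matrix(NA_real_, n_keep, length(draw_names),
                dimnames = list(NULL, draw_names))
  row <- 0L
  ntot <- p + sum(q)

  for (it in seq_len(n_iter)) {
    lv_prop <- lv + rnorm(5, 0, prop_sd * adapt_mult)
    prop <- marg_lpost(lv_prop)
    if (log(runif(1)) < prop$lp - cur$lp) {
      lv <- lv_prop
      cur <- prop
      Ch_cur <- prop$Ch
      acc_window <- acc_window + 1L
    }
    if (it <= burnin && it %% 50 == 0) {
      adapt_mult <- adapt_mult * exp(0.7 * (acc_window / 50 - 0.25))
      adapt_mult <- min(max(adapt_mult, 0.05), 20)
      acc_window <- 0L
    }

    if (it > burnin && (it - burnin) %% thin == 1 - (thin == 1)) {
      # draw location effects given the variances (only when storing)
      v <- exp(lv)
      mean_theta <- as.numeric(Matrix::solve(Ch_cur, Wty / v[["e"]]))
      z <- rnorm(ntot)
      dev <- Matrix::solve(Ch_cur, z, system = "Lt")
      dev <- as.numeric(Matrix::solve(Ch_cur, dev, system = "Pt"))
      theta <- mean_theta + dev
      row <- row + 1L
      if (row <= n_keep) {
        beta <- theta[seq_len(p)]
        xb <- as.numeric(X %*% beta)
        vf <- mean((xb - mean(xb))^2)
        out[row, ] <- c(v[["a"]], v[["pe"]], v[["m"]], v[["y"]], v[["e"]],
                        beta, vf)
      }
    }
  }
  out <- out[seq_len(row), , drop = FALSE]
  draws <- tibble::as_tibble(out)
  draws$V_P <- draws$V_F + draws$V_Mate + draws$V_PE + draws$V_A + draws$V_R
  draws$h2 <- draws$V_A / draws$V_P
  draws$r2 <- (draws$V_A + draws$V_PE) / draws$V_P

  ess <- tibble::tibble(
    parameter = c("V_A", "V_PE", "V_Mate", "V_Year", "V_R", "h2"),
    ess = vapply(c("V_A", "V_PE", "V_Mate", "V_Year", "V_R", "h2"),
                 function(pn) as.numeric(
                   coda::effectiveSize(coda::as.mcmc(draws[[pn]]))),
                 numeric(1))
  )
  if (any(ess$ess < ess_warn)) {
    warning("effective sample size below ", ess_warn, " for: ",
            paste(ess$parameter[ess$ess < ess_warn], collapse = ", "),
            call. = FALSE)
  }

  fit <- list(
    draws = draws, ess = ess, X = X, n_obs = n,
    n_individuals = length(ids), response = response,
    settings = list(n_iter = n_iter, thin = thin, burnin = burnin,
                    seed = seed, alpha_V = alpha_V,
                    resid_prior = resid_prior)
  )
  class(fit) <- "animal_model_fit"
  fit
}

#' @exportS3Method base::print
print.animal_model_fit <- function(x, ...) {
  cat("Animal model for", x$response, "-", x$n_obs, "records,",
      x$n_individuals, "pedigree individuals,", nrow(x$draws), "draws\n")
  print(tidy(x))
  invisible(x)
}

#' Variance explained by fixed effects
#'
#' Per posterior draw, the population variance (denominator n) over
#' observations of the fixed-effect linear predictor `X beta`, the
#' convention under which a balanced binary covariate with effect `d`
#' contributes exactly `d^2 / 4`.
#'
#' @param X Design matrix, or an `animal_model_fit` (whose stored draws are
#'   returned).
#' @param beta Coefficient vector or matrix (draws x coefficients).
#' @return Numeric vector of `V_F` values (one per draw).
#' @export
fixed_effect_variance <- function(X, beta = NULL) {
  if (inherits(X, "animal_model_fit")) return(X$draws$V_F)
  beta <- rbind(beta)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  as.numeric(apply(beta, 1, function(b) {
    xb <- as.numeric(X %*% b)
    mean((xb - mean(xb))^2)
  }))
}

#' Heritability and repeatability of an animal-model fit
#'
#' Per draw, `h2 = V_A / (V_F + V_Mate + V_PE + V_A + V_R)` and
#' `r2 = (V_A + V_PE) /` the same denominator: the phenotypic variance
#' excludes the between-year component but includes the fixed-effect
#' variance. Summaries report the posterior mode (kernel-density argmax),
#' median and 95% interval of the per-draw ratios; note that a ratio of
#' component modes generally differs from the mode of the per-draw ratio.
#'
#' @param fit An `animal_model_fit`.
#' @param interval `"hpd"` or `"quantile"`.
#' @return List with `draws` (tibble `h2`, `r2`) and `summary` (tibble with
#'   one row per ratio).
#' @export
heritability_repeatability <- function(fit, interval = "hpd") {
  draws <- fit$draws[, c("h2", "r2")]
  summary <- dplyr::bind_rows(
    dplyr::mutate(posterior_point_and_interval(draws$h2, interval = interval),
                  parameter = "h2", .before = 1),
    dplyr::mutate(posterior_point_and_interval(draws$r2, interval = interval),
                  parameter = "r2", .before = 1)
  )
  list(draws = draws, summary = summary)
}

#' Mother-daughter regression heritability
#'
#' Regresses daughters' mean lay dates on their mothers' mean lay dates
#' (means over each female's breeding records). Under the default
#' convention the single-parent regression slope is doubled to give h2; the
#' raw slope is also reported since published values sometimes leave it
#' undoubled.
#'
#' @param records Breeding records with `female_id` and the phenotype column.
#' @param pedigree Pedigree tibble linking daughters (`id`) to dams.
#' @param response Phenotype column (default `"lay_day"`).
#' @param convention `"double"` (h2 = 2 x slope) or `"raw"`.
#' @return Tibble: slope, se, t, df, p_value, h2, convention, n_pairs.
#' @export
mother_daughter_h2 <- function(records, pedigree, response = "lay_day",
                               convention = c("double", "raw")) {
  convention <- match.arg(convention)
  pheno <- records |>
    dplyr::group_by(id = as.character(.data$female_id)) |>
    dplyr::summarise(pheno = mean(.data[[response]], na.rm = TRUE),
                     .groups = "drop")
  pairs <- pedigree |>
    dplyr::mutate(id = as.character(.data$id), dam = as.character(.data$dam)) |>
    dplyr::filter(!is.na(.data$dam)) |>
    dplyr::inner_join(pheno, by = "id") |>
    dplyr::inner_join(pheno, by = c(dam = "id"),
                      suffix = c("_daughter", "_mother"))
  if (nrow(pairs) < 30) {
    warning("only ", nrow(pairs),
            " mother-daughter pairs: low power", call. = FALSE)
  }
  if (nrow(pairs) < 3) {
    stop("too few mother-daughter pairs for a regression", call. = FALSE)
  }
  fit <- lm(pheno_daughter ~ pheno_mother, data = pairs)
  sm <- summary(fit)$coefficients
  slope <- sm["pheno_mother", "Estimate"]
  se <- sm["pheno_mother", "Std. Error"]
  mult <- if (convention == "double") 2 else 1
  tibble::tibble(
    slope = slope, se = se,
    t = sm["pheno_mother", "t value"],
    df = fit$df.residual,
    p_value = sm["pheno_mother", "Pr(>|t|)"],
    h2 = mult * slope, h2_se = mult * se,
    convention = convention, n_pairs = nrow(pairs),
    low_power = nrow(pairs) < 30
  )
}
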