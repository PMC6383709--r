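#' Kernel-density mode of a sample
#'
#' The mode is the argmax of a Gaussian kernel density estimate with
#' Silverman's rule-of-thumb bandwidth by default. Constant samples return
#' the constant.
#'
#' @param x Numeric vector.
#' @param bw Bandwidth specification passed to [stats::density()].
#' @return The modal value.
#' @export
kde_mode <- function(x, bw = "nrd0") {
  x <- x[!is.na(x)]
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Posterior point estimates and interval
#'
#' Summarises a vector of posterior draws the way animal-model results are
#' conventionally reported: posterior mode (kernel-density argmax), posterior
#' median, and a 95% interval -- highest posterior density by default, or
#' equal-tailed.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval probability mass (default 0.95).
#' @param interval `"hpd"` or `"quantile"`.
#' @param bw Bandwidth for the mode's kernel density estimate.
#' @return Tibble with `mode`, `median`, `lower`, `upper`.
#' @export
posterior_point_and_interval <- function(draws, prob = 0.95,
                                         interval = c("hpd", "quantile"),
                                         bw = "nrd0") {
  interval <- match.arg(interval)
  draws <- draws[!is.na(draws)]
  if (length(unique(draws)) == 1) {
    return(tibble::tibble(mode = draws[1], median = draws[1],
                          lower = draws[1], upper = draws[1]))
  }
  if (interval == "hpd") {
    ci <- as.numeric(coda::HPDinterval(coda::as.mcmc(draws), prob = prob))
  } else {
    ci <- as.numeric(quantile(draws, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  }
  tibble::tibble(
    mode = kde_mode(draws, bw = bw),
    median = median(draws),
    lower = ci[1],
    upper = ci[2]
  )
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic multi-chain PSRF for a single parameter:
#' `R = sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of chain means (times n).
#' Identical chains give `B = 0` and hence `R = sqrt((n - 1) / n)`. With
#' `split = TRUE` each chain is first split in half, which additionally
#' detects within-chain drift.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors.
#' @param split Split each chain into halves first? Default `FALSE` (the
#'   classic between-chain comparison).
#' @return The PSRF (scalar). `NA` with a warning for a single chain.
#' @export
psrf <- function(chains, split = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (split) {
    n2 <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(n2), , drop = FALSE],
                    chains[nrow(chains) - n2 + seq_len(n2), , drop = FALSE])
  }
  m <- ncol(chains)
  if (m < 2) {
    warning("PSRF needs at least 2 chains", call. = FALSE)
    return(NA_real_)
  }
  n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  if (W == 0) return(1)  # fully degenerate (constant) chains
  B_over_n <- var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Per-parameter PSRF table for a multi-chain fit
#'
#' @param chains_list List of draw matrices (one per chain, iterations x
#'   parameters, identical column names).
#' @param threshold Convergence threshold; parameters above it are flagged.
#' @param split Passed to [psrf()].
#' @return Tibble with `parameter`, `psrf`, `converged`.
#' @export
psrf_table <- function(chains_list, threshold = 1.1, split = FALSE) {
  stopifnot(length(chains_list) >= 1)
  pars <- colnames(chains_list[[1]])
  if (length(chains_list) < 2) {
    warning("single chain: PSRF unavailable", call. = FALSE)
    return(tibble::tibble(parameter = pars, psrf = NA_real_,
                          converged = NA))
  }
  vals <- vapply(pars, function(p) {
    psrf(lapply(chains_list, function(ch) ch[, p]), split = split)
  }, numeric(1))
  tibble::tibble(parameter = pars, psrf = vals,
                 converged = vals <= threshold)
}

# long-run variance by a Bartlett (Newey-West) window with a fixed-rate
# bandwidth; deliberately short-memory so that trends inflate the bridge
# statistic rather than the variance estimate
bartlett_lrv <- function(x) {
  n <- length(x)
  q <- min(n - 1, max(5, ceiling(1.5 * n^(1 / 3))))
  xc <- x - mean(x)
  g0 <- mean(xc^2)
  s <- g0
  for (k in seq_len(q)) {
    gk <- mean(xc[seq_len(n - k)] * xc[k + seq_len(n - k)])
    s <- s + 2 * (1 - k / (q + 1)) * gk
  }
  max(s, g0 * 1e-8)
}

# stationarity test of one chain segment: Cramer-von-Mises functional of the
# standardized partial-sum bridge (95% critical value 0.4614)
cvm_bridge_stat <- function(x) {
  n <- length(x)
  s0 <- bartlett_lrv(x)
  cs <- cumsum(x)
  k <- seq_len(n)
  bridge <- (cs - k * mean(x)) / sqrt(n * s0)
  mean(bridge^2)
}

#' Stationarity and half-width convergence diagnostics
#'
#' Per-parameter Heidelberger-Welch-style tests plus effective sample sizes.
#' The stationarity test computes the Cramer-von-Mises statistic of the
#' standardized partial-sum bridge, discarding the first 10%, 20%, ... up to
#' 50% of the chain until the remainder passes; the long-run variance uses a
#' fixed-bandwidth Bartlett window, so trending chains inflate the bridge
#' statistic and fail rather than inflating the variance estimate. The
#' half-width test requires the 95% interval half-width of the retained
#' mean to be below `eps` times its magnitude. Constant (degenerate) chains
#' are flagged rather than tested.
#'
#' @param draws Matrix of draws (iterations x parameters) or a numeric
#'   vector.
#' @param eps Relative half-width tolerance (default 0.1).
#' @param crit Critical value of the Cramer-von-Mises statistic (0.4614 is
#'   the 5% point).
#' @return Tibble with `parameter`, `stationarity_pass`, `start_frac`
#'   (fraction of the chain discarded before stationarity), `halfwidth_pass`,
#'   `ess`, `degenerate`.
#' @export
mcmc_convergence <- function(draws, eps = 0.1, crit = 0.4614) {
  draws <- as.matrix(draws)
  pars <- colnames(draws)
  if (is.null(pars)) pars <- paste0("par", seq_len(ncol(draws)))
  purrr::map_dfr(seq_along(pars), function(i) {
    x <- draws[, i]
    if (length(unique(x)) == 1) {
      return(tibble::tibble(parameter = pars[i], stationarity_pass = NA,
                            start_frac = NA_real_, halfwidth_pass = NA,
                            ess = 0, degenerate = TRUE))
    }
    pass <- FALSE
    start_frac <- NA_real_
    kept <- x
    for (frac in seq(0, 0.5, by = 0.1)) {
      kept <- x[(floor(frac * length(x)) + 1):length(x)]
      if (cvm_bridge_stat(kept) < crit) {
        pass <- TRUE
        start_frac <- frac
        break
      }
    }
    hw <- 1.96 * sqrt(bartlett_lrv(kept) / length(kept))
    hw_pass <- if (abs(mean(kept)) < .Machine$double.eps^0.25) NA else
      hw / abs(mean(kept)) < eps
    tibble::tibble(
      parameter = pars[i],
      stationarity_pass = pass,
      start_frac = start_frac,
      halfwidth_pass = hw_pass,
      ess = as.numeric(coda::effectiveSize(coda::as.mcmc(x))),
      degenerate = FALSE
    )
  })
}

#' pMCMC sign test
#'
#' Twice the fraction of posterior draws whose sign differs from the sign of
#' the posterior median: a Bayesian two-sided test of departure from zero.
#'
#' @param draws Numeric vector of posterior draws.
#' @return p-value in `[0, 1]` (capped at 1).
#' @export
pmcmc <- function(draws) {
  draws <- draws[!is.na(draws)]
  md <- median(draws)
  if (md == 0) return(1)
  min(1, 2 * mean(sign(draws) != sign(md)))
}
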