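test_that("fixed-effect variance follows the population-variance convention", {
  X0 <- cbind(1)
  expect_equal(fixed_effect_variance(X0, 3.2), 0)
  # balanced binary covariate with effect d contributes d^2 / 4
  Xb <- cbind(1, rep(c(0, 1), 50))
  expect_equal(fixed_effect_variance(Xb, c(2, 1.6)), 1.6^2 / 4)
  # arbitrary design against a brute-force oracle
  set.seed(1)
  X <- cbind(1, rnorm(40), runif(40))
  b <- c(0.5, -1.2, 2)
  xb <- as.numeric(X %*% b)
  expect_equal(fixed_effect_variance(X, b),
               mean((xb - mean(xb))^2))
})

test_that("heritability and repeatability ratios are consistent", {
  fake <- list(draws = tibble::tibble(
    V_A = c(10, 5), V_PE = c(20, 10), V_Mate = c(5, 5), V_Year = c(50, 1),
    V_R = c(35, 20), V_F = c(30, 10)
  ))
  fake$draws$V_P <- with(fake$draws, V_F + V_Mate + V_PE + V_A + V_R)
  fake$draws$h2 <- fake$draws$V_A / fake$draws$V_P
  fake$draws$r2 <- (fake$draws$V_A + fake$draws$V_PE) / fake$draws$V_P
  class(fake) <- "animal_model_fit"
  expect_equal(fake$draws$h2[1], 0.10)
  hr <- heritability_repeatability(fake)
  expect_true(all(hr$draws$r2 >= hr$draws$h2))
  # the year variance never enters the denominator
  expect_false(any(abs(fake$draws$V_P - 100) > 1e-9 &
                     abs(fake$draws$V_P - 50) > 1e-9))
})

test_that("the animal model recovers variance components on simulated data", {
  study <- small_study()
  fit <- suppressMessages(fit_animal_model(
    study$records, study$pedigree, n_iter = 4000, thin = 4, burnin = 800,
    seed = 7, ess_warn = 0))
  td <- tidy(fit)
  # residual variance: truth 161, well identified from repeated measures
  vr <- td[td$term == "V_R", ]
  expect_gt(vr$upper, 120)
  expect_lt(vr$lower, 230)
  # clutch-number effect: the generator spaces clutches ~40 days apart
  cn <- td[td$term == "clutch_number", ]
  expect_gt(cn$lower, 30)
  expect_lt(cn$upper, 50)
  # all variance draws positive, V_P identity holds per draw
  expect_true(all(fit$draws$V_A > 0))
  expect_equal(fit$draws$V_P,
               with(fit$draws, V_F + V_Mate + V_PE + V_A + V_R))
})

test_that("records reference missing pedigree members loudly", {
  study <- tiny_study()
  ped_broken <- dplyr::filter(study$pedigree,
                              id != study$records$female_id[1])
  expect_error(
    suppressMessages(fit_animal_model(study$records, ped_broken,
                                      n_iter = 100, burnin = 10,
                                      ess_warn = 0)),
    "absent from the pedigree")
})

test_that("mother-daughter regression behaves at its anchor points", {
  study <- small_study()
  rec <- study$records

  # null case: phenotypes independent of the mother
  set.seed(8)
  rec_null <- rec
  rec_null$lay_day <- rnorm(nrow(rec_null), 60, 15)
  md0 <- suppressWarnings(mother_daughter_h2(rec_null, study$pedigree))
  expect_lt(abs(md0$slope), 3 * md0$se)

  # perfect equality: daughter mean equals mother mean
  pheno <- tibble::tibble(id = unique(as.character(rec$female_id)))
  ped <- study$pedigree
  base <- stats::setNames(rnorm(nrow(pheno), 60, 10), pheno$id)
  dam_of <- stats::setNames(as.character(ped$dam), as.character(ped$id))
  val <- function(id) {
    seen <- character()
    while (!is.na(dam_of[id]) && !(id %in% seen)) {
      seen <- c(seen, id); id <- dam_of[[id]]
    }
    if (id %in% names(base)) base[[id]] else 60
  }
  rec_eq <- rec
  rec_eq$lay_day <- vapply(as.character(rec$female_id), val, numeric(1))
  md1 <- suppressWarnings(mother_daughter_h2(rec_eq, study$pedigree))
  expect_equal(md1$slope, 1, tolerance = 1e-6)
  expect_equal(md1$h2, 2)

  # simulated h2 = 0.5: doubled slope near 0.5
  set.seed(9)
  bv <- simulate_breeding_values(study$pedigree, sigma2_A = 50, seed = 10)
  bv_map <- stats::setNames(bv$bv, bv$id)
  rec_h <- rec
  rec_h$lay_day <- 60 + bv_map[as.character(rec_h$female_id)] +
    rnorm(nrow(rec_h), 0, sqrt(50))
  md5 <- suppressWarnings(mother_daughter_h2(rec_h, study$pedigree))
  expect_lt(abs(md5$h2 - 0.5), 2 * md5$h2_se)
})

test_that("posterior summaries handle constants, skew and scale", {
  s <- posterior_point_and_interval(rep(2.5, 2000))
  expect_equal(unlist(s), c(mode = 2.5, median = 2.5, lower = 2.5,
                            upper = 2.5))
  set.seed(10)
  z <- rnorm(2e5)
  sz <- posterior_point_and_interval(z)
  expect_lt(abs(sz$mode), 0.05)
  expect_lt(abs(sz$median), 0.01)
  skew <- rlnorm(2e5, 0, 0.6)
  ss <- posterior_point_and_interval(skew)
  expect_lt(ss$mode, ss$median)
})
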