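trio <- tibble::tibble(id = c("d", "s", "o"), dam = c(NA, NA, "d"),
                       sire = c(NA, NA, "s"))
sibs <- tibble::tibble(id = c("d", "s", "o1", "o2"),
                       dam = c(NA, NA, "d", "d"),
                       sire = c(NA, NA, "s", "s"))
sib_mating <- dplyr::bind_rows(
  sibs, tibble::tibble(id = "x", dam = "o1", sire = "o2"))

test_that("tabular relationships match the closed forms", {
  A <- additive_relationship(trio)
  expect_equal(A["d", "o"], 0.5)
  expect_equal(A["d", "s"], 0)
  A2 <- additive_relationship(sibs)
  expect_equal(A2["o1", "o2"], 0.5)
  A3 <- additive_relationship(sib_mating)
  expect_equal(A3["x", "x"], 1.25)
})

test_that("pedigree cycles are rejected by name", {
  cyc <- tibble::tibble(id = c("a", "b"), dam = c("b", "a"),
                        sire = c(NA, NA))
  expect_error(sort_pedigree(cyc), "cycle")
})

test_that("relationship matrices are symmetric PSD and invert correctly", {
  for (seed in 1:4) {
    ped <- random_pedigree(5, 12, seed)
    A <- additive_relationship(ped)
    expect_equal(A, t(A))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    Ainv <- as.matrix(additive_relationship_inverse(ped))
    expect_equal(Ainv %*% A[rownames(Ainv), colnames(Ainv)],
                 diag(nrow(Ainv)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("tabular A agrees with the gene-dropping oracle", {
  ped <- dplyr::bind_rows(
    sib_mating,
    tibble::tibble(id = c("y", "z"), dam = c("x", "y"),
                   sire = c("o1", NA)))
  A <- additive_relationship(ped)
  A_drop <- gene_drop_relationship(ped, n_rep = 20000, seed = 42)
  # Monte-Carlo SE of a mean of indicators at 20k reps is < 0.004
  expect_lt(max(abs(A - A_drop[rownames(A), colnames(A)])), 0.02)
})

test_that("inbreeding is missing whenever ancestry is incomplete", {
  fcoef <- inbreeding_coefficients(sib_mating)
  # founders and their offspring (founder grandparents unknown) are missing
  expect_true(all(is.na(fcoef$F[fcoef$id %in% c("d", "s", "o1", "o2")])))
  expect_equal(fcoef$F[fcoef$id == "x"], 0.25)
  # complete ancestry with unrelated grandparents: F = 0
  ped4 <- tibble::tibble(
    id = c("g1", "g2", "g3", "g4", "p1", "p2", "k"),
    dam = c(NA, NA, NA, NA, "g1", "g3", "p1"),
    sire = c(NA, NA, NA, NA, "g2", "g4", "p2"))
  f4 <- inbreeding_coefficients(ped4)
  expect_equal(f4$F[f4$id == "k"], 0)
})

test_that("generation depth counts the longest known-ancestor chain", {
  chain <- tibble::tibble(id = c("a", "b", "c"), dam = c(NA, "a", "b"),
                          sire = c(NA, NA, NA))
  pd <- pedigree_depth(chain)
  expect_equal(pd$depths$depth, c(0L, 1L, 2L))
  expect_equal(pd$summary$max_depth, 2L)
  expect_equal(pd$summary$mean_depth_founder1,
               pd$summary$mean_depth_founder0 + 1)
})

test_that("breeding-value simulation has the pedigree covariance structure", {
  expect_equal(simulate_breeding_values(sib_mating, 0)$bv, rep(0, 5))

  # founder variance: Monte Carlo over many founders
  founders <- tibble::tibble(id = as.character(1:20000),
                             dam = NA_character_, sire = NA_character_)
  bv <- simulate_breeding_values(founders, sigma2_A = 4, seed = 1)$bv
  se <- 4 * sqrt(2 / length(bv))  # SE of a variance estimate
  expect_lt(abs(var(bv) - 4), 3 * se)

  # trio: Var(offspring - midparent) = sigma2_A / 2
  devs <- vapply(1:4000, function(r) {
    b <- simulate_breeding_values(trio, 2, seed = r)$bv
    b[3] - (b[1] + b[2]) / 2
  }, numeric(1))
  expect_lt(abs(var(devs) - 1), 0.12)

  # covariance across replicates matches sigma2_A * A on a 6-member pedigree
  ped6 <- dplyr::bind_rows(sibs, tibble::tibble(
    id = c("x", "y"), dam = c("o1", "o2"), sire = c("s", "x")))
  A <- additive_relationship(ped6)
  reps <- vapply(1:4000, function(r) {
    simulate_breeding_values(ped6, 3, seed = 10000 + r)$bv
  }, numeric(6))
  emp <- cov(t(reps))
  expect_lt(max(abs(emp - 3 * A)), 0.45)
})

test_that("pruning keeps relationships among retained individuals", {
  ped <- random_pedigree(4, 15, seed = 9)
  keep <- utils::tail(ped$id, 3)
  pruned <- prune_pedigree(ped, keep)
  expect_true(all(keep %in% pruned$id))
  A_full <- additive_relationship(ped)
  A_sub <- additive_relationship(pruned)
  expect_equal(A_sub[keep, keep], A_full[keep, keep])
})
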