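test_that("generation is deterministic and component-seed stable", {
  cfg <- sim_config(n_seasons = 4, n_founder_females = 8,
                    n_founder_males = 8, second_release_females = 0,
                    second_release_males = 0, carrying_cap = 12, seed = 55)
  a <- generate_breeding_data(cfg)
  b <- generate_breeding_data(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$temperatures, b$temperatures)
  expect_identical(generate_pedigree(cfg), a$pedigree)
})

test_that("generated records satisfy every breeding-record invariant", {
  study <- default_study()
  expect_silent(validate_breeding_records(study$records))
  r <- study$records
  expect_true(all(r$n_eggs >= r$n_hatchlings))
  expect_true(all(r$n_hatchlings >= r$n_fledglings))
  expect_true(all(r$n_fledglings >= r$n_recruits))
  expect_true(all(r$female_age >= 1))
  expect_true(all(is.na(r$hatch_day) | r$lay_day <= r$hatch_day))
})

test_that("the default study matches the emulated study dimensions", {
  study <- default_study()
  r <- study$records
  expect_gt(nrow(r), 1000)
  expect_lt(nrow(r), 2000)
  expect_gt(length(unique(r$female_id)), 180)
  expect_equal(length(unique(r$season)), 16)
  # total lay-date variance on the intended days^2 scale
  expect_gt(var(r$lay_day), 0.6 * 830)
  expect_lt(var(r$lay_day), 1.4 * 830)
  # pedigree structure: acyclic, deep, founders unknown
  expect_silent(sort_pedigree(study$pedigree))
  expect_gte(pedigree_depth(study$pedigree)$summary$max_depth, 5)
  founders <- dplyr::filter(study$pedigree, is.na(dam))
  expect_true(all(is.na(founders$sire)))
})

test_that("truth manifest heritability is the stated component ratio", {
  study <- tiny_study()
  cfg <- study$truth$config
  h2 <- cfg$V_A / (study$truth$V_F_realized + cfg$V_Mate + cfg$V_PE +
                     cfg$V_A + cfg$V_R)
  expect_equal(study$truth$h2_expected, h2)
})

test_that("clutch re-derivation reproduces the generator's ordering", {
  study <- default_study()
  rederived <- suppressMessages(
    derive_clutch_structure(study$records))$records
  key <- function(d) d[order(d$female_id, d$season, d$lay_day), ]
  expect_equal(key(rederived)$clutch_number,
               key(study$records)$clutch_number)
})

test_that("extra-pair paternity rate and dam-offspring kinship are right", {
  study <- default_study()
  chicks <- dplyr::filter(study$pedigree, !is.na(dam))
  social <- study$records |>
    dplyr::distinct(female_id, season, clutch_number, social_male_id)
  linked <- dplyr::inner_join(
    chicks, social,
    by = c(dam = "female_id", birth_season = "season",
           birth_clutch = "clutch_number"))
  epp <- mean(linked$sire != linked$social_male_id)
  expect_gt(epp, 0.5)
  expect_lt(epp, 0.7)

  # tabular check of dam-offspring relationship on a subsample
  sub_ids <- unique(c(utils::head(chicks$id, 30),
                      utils::head(chicks$dam, 30)))
  ped_sub <- prune_pedigree(study$pedigree, sub_ids)
  A <- additive_relationship(ped_sub)
  pairs <- chicks[chicks$id %in% rownames(A) &
                    chicks$dam %in% rownames(A), ][1:20, ]
  rel <- mapply(function(i, d) A[i, d], pairs$id, pairs$dam)
  expect_gt(mean(rel), 0.45)
  expect_lt(mean(rel), 0.65)
})

test_that("direct optimum-model simulation carries its truth", {
  d <- simulate_optimum_data(n = 300, n_years = 5, seed = 9)
  truth <- attr(d, "truth")
  expect_equal(truth$A, 1.5)
  expect_true(all(abs(truth$u) <= 2))
  expect_equal(sort(unique(d$year)), 1:5)
  d2 <- simulate_optimum_data(n = 300, n_years = 5, seed = 9)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("fixture writing lists seeds and re-reads cleanly", {
  dir <- withr::local_tempdir()
  suppressMessages(make_fixture("tiny", seed = 31, dir = dir))
  manifest <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(manifest$config$seed, 31)
  expect_true(file.exists(file.path(dir, "records.csv")))
  rec <- read_breeding_records(file.path(dir, "records.csv"))
  expect_silent(validate_breeding_records(rec))
})
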