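test_that("season-day conversion anchors on 1 September and round-trips", {
  expect_equal(to_season_day(as.Date("2000-09-01"), 2000), 0L)
  expect_equal(to_season_day(as.Date("2000-11-01"), 2000), 61L)
  # calendar-sum oracle: Sep 30 + Oct 31 + Nov 30 + Dec 31 days
  expect_equal(to_season_day(as.Date("2001-01-01"), 2000),
               30L + 31L + 30L + 31L)
  expect_error(to_season_day(as.Date("2000-08-31"), 2000), "season window")

  days <- seq(as.Date("2005-09-01"), as.Date("2006-08-31"), by = "day")
  expect_equal(season_day_to_date(to_season_day(days, 2005), 2005), days)
  expect_equal(season_of_date(as.Date(c("2005-09-01", "2005-12-31",
                                        "2006-01-01", "2006-08-31"))),
               c(2005L, 2005L, 2005L, 2005L))
})

test_that("lay days are imputed 17 days before hatch, unusable rows dropped", {
  rec <- tibble::tibble(lay_day = c(NA, NA, 10, NA),
                        hatch_day = c(51, 17, 27, NA))
  expect_warning(out <- impute_lay_from_hatch(rec), "dropped")
  expect_equal(out$lay_day, c(34, 0, 10))
  expect_equal(out$lay_imputed, c(TRUE, TRUE, FALSE))
})

test_that("clutch numbering follows lay order with deterministic tie-break", {
  rec <- tibble::tibble(
    female_id = c("F", "F", "F", "G"),
    season = 2005,
    lay_day = c(70, 34, 110, 50),
    hatch_day = NA_integer_,
    n_eggs = 4, n_hatchlings = 3, n_fledglings = 2, n_recruits = 0,
    female_age = 2
  )
  cs <- derive_clutch_structure(rec)
  got <- cs$records[order(match(cs$records$lay_day, c(70, 34, 110, 50))), ]
  expect_equal(got$clutch_number, c(2L, 1L, 3L, 1L))
  f_row <- cs$seasons[cs$seasons$female_id == "F", ]
  expect_equal(f_row$start_day, 34)
  expect_equal(f_row$n_clutches, 3L)
  expect_true(f_row$reclutched)
  expect_false(cs$seasons$reclutched[cs$seasons$female_id == "G"])

  # tie on lay day: hatch day breaks it, and the tie is reported
  tied <- tibble::tibble(
    female_id = "F", season = 2001, lay_day = c(30, 30),
    hatch_day = c(50, 47), n_eggs = 4, n_hatchlings = 3,
    n_fledglings = 2, n_recruits = 0, female_age = 2
  )
  expect_message(cs2 <- derive_clutch_structure(tied), "tied")
  expect_equal(cs2$records$clutch_number[cs2$records$hatch_day == 47], 1L)
})

test_that("recruit counting credits clutches through the pedigree", {
  rec <- tibble::tibble(
    female_id = c("F1", "F1", "F2"), season = c(2000, 2001, 2000),
    clutch_number = 1L, lay_day = 30,
    n_eggs = 4L, n_hatchlings = 3L, n_fledglings = c(3L, 0L, 2L),
    n_recruits = NA_integer_, female_age = 2
  )
  ped <- tibble::tibble(
    id = c("F1", "F2", "K1", "K2", "K3", "K4"),
    dam = c(NA, NA, "F1", "F1", "F2", NA),
    sire = c(NA, NA, "M1", "M1", "M2", "M3"),
    birth_season = c(NA, NA, 2000, 2000, 2000, 2000),
    birth_clutch = c(NA, NA, 1, 1, 1, 1)
  )
  # K1 breeds later (dam of a 2001 pedigree entry), K2/K3 never do
  ped <- dplyr::bind_rows(ped, tibble::tibble(
    id = "Z", dam = "K1", sire = "M9", birth_season = 2001,
    birth_clutch = 1))
  out <- compute_fitness(rec, ped)
  expect_equal(out$n_recruits[out$female_id == "F1" & out$season == 2000], 1L)
  expect_equal(out$n_recruits[out$female_id == "F1" & out$season == 2001], 0L)
  expect_equal(out$n_recruits[out$female_id == "F2"], 0L)
  # K4 has unknown dam: credited to no record
  expect_equal(sum(out$n_recruits), 1L)
  expect_true(all(out$recruitment_truncated[out$season == 2001]))
})

test_that("all fledglings breeding makes recruits equal fledglings", {
  study <- tiny_study()
  # construct breeders claiming every pedigree chick bred one season later
  chicks <- dplyr::filter(study$pedigree, !is.na(dam))
  breeders <- tibble::tibble(id = chicks$id,
                             first_breeding_season = chicks$birth_season + 1)
  out <- compute_fitness(study$records, study$pedigree, breeders = breeders)
  expect_equal(out$n_recruits, out$n_fledglings)
})

test_that("temperature cue averages the window before the grand mean start", {
  dates <- seq(as.Date("2000-03-01"), as.Date("2001-02-28"), by = "day")
  seasons <- tibble::tibble(season = 2000, start_day = 30)

  const <- tibble::tibble(date = dates, tmax = 20)
  cue <- compute_temperature_cue(const, seasons)
  expect_equal(cue$cue, 20)

  # linearly rising tmax across the window: mean of 10..59 = 34.5
  anchor <- season_day_to_date(30, 2000)
  window_days <- anchor - 50:1
  lin <- tibble::tibble(date = dates, tmax = 0)
  lin$tmax[match(window_days, lin$date)] <- 10:59
  cue_lin <- compute_temperature_cue(lin, seasons)
  expect_equal(cue_lin$cue, 34.5)

  # invariance to temperatures outside the window
  lin2 <- lin
  outside <- !(lin2$date %in% window_days)
  lin2$tmax[outside] <- lin2$tmax[outside] + 100
  expect_equal(compute_temperature_cue(lin2, seasons)$cue, 34.5)

  # fully missing window: NA cue with a warning
  gap <- dplyr::filter(lin, !(date %in% window_days))
  expect_warning(cue_na <- compute_temperature_cue(gap, seasons), "missing")
  expect_true(is.na(cue_na$cue))
})

test_that("standardization is unit-variance with a working back-transform", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(var(as.numeric(z)), 1)
  v <- rnorm(50, 100, 7)
  expect_equal(unstandardize(standardize(v)), v)
  z2 <- standardize(as.numeric(standardize(v)))
  expect_equal(as.numeric(z2), as.numeric(standardize(v)), tolerance = 1e-12)
  expect_error(standardize(rep(3, 5)), "variance")
})

test_that("record validation enforces stage monotonicity", {
  bad <- tibble::tibble(female_id = "F", season = 2000, lay_day = 10,
                        n_eggs = 3L, n_hatchlings = 4L, n_fledglings = 1L,
                        n_recruits = 0L, female_age = 2)
  expect_error(validate_breeding_records(bad), "hatchling")
  good <- bad
  good$n_hatchlings <- 2L
  expect_silent(validate_breeding_records(good))
})

test_that("CSV round trip through the readers preserves a study", {
  dir <- withr::local_tempdir()
  study <- suppressMessages(make_fixture("tiny", seed = 77, dir = dir))
  rec <- read_breeding_records(file.path(dir, "records.csv"))
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  tmp <- read_temperatures(file.path(dir, "temperatures.csv"))
  expect_equal(nrow(rec), nrow(study$records))
  expect_equal(ped$id, as.character(study$pedigree$id))
  expect_equal(nrow(tmp), nrow(study$temperatures))
  manifest <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(manifest$config$seed, 77)
})
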