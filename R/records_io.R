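#' Convert a calendar date to a season day
#'
#' Breeding seasons in this package run austral-style from 1 September of the
#' season's starting year to 31 August of the following calendar year. Lay
#' dates are expressed as the number of days since 1 September, so 1 September
#' itself is day 0.
#'
#' @param date A `Date` vector (or something coercible via [as.Date()]).
#' @param season_start_year Integer vector of season starting years, recycled
#'   against `date`.
#' @return Integer vector of day offsets since 1 September.
#' @examples
#' to_season_day(as.Date("2000-11-01"), 2000)
#' @export
to_season_day <- function(date, season_start_year) {
  date <- as.Date(date)
  origin <- as.Date(sprintf("%d-09-01", season_start_year))
  upper <- as.Date(sprintf("%d-08-31", season_start_year + 1))
  bad <- !is.na(date) & (date < origin | date > upper)
  if (any(bad)) {
    stop(
      "date(s) outside the season window [1 Sept, 31 Aug]: ",
      paste(format(date[bad]), "vs season", season_start_year[bad][1],
            collapse = ", "),
      call. = FALSE
    )
  }
  as.integer(date - origin)
}

#' Convert a season day back to a calendar date
#'
#' Inverse of [to_season_day()]: day 0 maps to 1 September of the season's
#' starting year.
#'
#' @param day Integer vector of days since 1 September.
#' @param season_start_year Integer vector of season starting years.
#' @return A `Date` vector.
#' @export
season_day_to_date <- function(day, season_start_year) {
  as.Date(sprintf("%d-09-01", season_start_year)) + as.integer(round(day))
}

#' Assign a calendar date to its breeding season
#'
#' Records dated September to December belong to the season starting that
#' calendar year; January to August records belong to the season starting the
#' previous year.
#'
#' @param date A `Date` vector.
#' @return Integer vector of season starting years.
#' @export
season_of_date <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  ifelse(mo >= 9L, yr, yr - 1L)
}

#' Impute missing lay days from hatch days
#'
#' Where a clutch's lay day was not recorded but its hatch day was, the lay
#' day is reconstructed as a fixed number of days before hatching (17 by
#' default, the egg-laying plus incubation interval recovered by regressing
#' lay on hatch dates). Records missing both dates are dropped with a warning.
#'
#' @param records A breeding-record tibble with `lay_day` and `hatch_day`
#'   columns (season-day units).
#' @param offset Days between lay and hatch, subtracted from `hatch_day`.
#' @return `records` with `lay_day` filled where possible and a logical
#'   `lay_imputed` column; unusable rows removed.
#' @export
impute_lay_from_hatch <- function(records, offset = 17L) {
  records <- tibble::as_tibble(records)
  if (!"lay_imputed" %in% names(records)) records$lay_imputed <- FALSE
  to_fill <- is.na(records$lay_day) & !is.na(records$hatch_day)
  records$lay_day[to_fill] <- records$hatch_day[to_fill] - as.integer(offset)
  records$lay_imputed[to_fill] <- TRUE
  unusable <- is.na(records$lay_day)
  if (any(unusable)) {
    warning(sum(unusable), " record(s) dropped: lay and hatch day both missing",
            call. = FALSE)
    records <- records[!unusable, , drop = FALSE]
  }
  records
}

#' Validate breeding records
#'
#' Checks the structural invariants of a clutch table: stage counts are
#' non-negative and monotone (eggs >= hatchlings >= fledglings >= recruits),
#' stage dates are ordered where present, ages are at least 1 and clutch
#' numbers (when present) are unique within female and season.
#'
#' @param records A breeding-record tibble.
#' @return `records` invisibly; errors describe every violated rule.
#' @export
validate_breeding_records <- function(records) {
  req <- c("female_id", "season", "lay_day", "n_eggs", "n_hatchlings",
           "n_fledglings", "n_recruits", "female_age")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character()
  counts <- records[, c("n_eggs", "n_hatchlings", "n_fledglings", "n_recruits")]
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative stage counts")
  }
  mono <- with(records, n_eggs >= n_hatchlings & n_hatchlings >= n_fledglings &
                 n_fledglings >= n_recruits)
  if (any(!mono, na.rm = TRUE)) {
    problems <- c(problems, sprintf(
      "%d record(s) violate egg >= hatchling >= fledgling >= recruit",
      sum(!mono, na.rm = TRUE)))
  }
  if (all(c("hatch_day", "fledge_day") %in% names(records))) {
    ord <- with(records,
                (is.na(hatch_day) | lay_day <= hatch_day) &
                  (is.na(hatch_day) | is.na(fledge_day) | hatch_day <= fledge_day))
    if (any(!ord, na.rm = TRUE)) {
      problems <- c(problems, sprintf("%d record(s) with unordered stage dates",
                                      sum(!ord, na.rm = TRUE)))
    }
  }
  if (any(records$female_age < 1, na.rm = TRUE)) {
    problems <- c(problems, "female_age below 1")
  }
  if ("clutch_number" %in% names(records)) {
    dup <- records |>
      dplyr::filter(!is.na(.data$clutch_number)) |>
      dplyr::count(.data$female_id, .data$season, .data$clutch_number) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      problems <- c(problems, sprintf(
        "%d duplicated clutch number(s) within female x season", nrow(dup)))
    }
  }
  if (length(problems) > 0) {
    stop("invalid breeding records: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(records)
}

#' Number clutches and build the female-by-season table
#'
#' Within each female and season, breeding attempts are numbered 1, 2, ... in
#' order of lay day, regardless of their success. The season table summarises
#' each female-season: start of breeding season (lay day of the first clutch),
#' number of clutches, annual totals of fledglings and recruits, whether the
#' female reclutched (more than one clutch) and whether she was observed
#' breeding again in a later season.
#'
#' Ties in lay day within a female-season are broken by hatch day and then by
#' stable input order; ties are reported via a message.
#'
#' @param records A breeding-record tibble with `female_id`, `season`,
#'   `lay_day` (all required).
#' @return A list with `records` (input plus/with refreshed `clutch_number`)
#'   and `seasons` (the female-by-season tibble).
#' @export
derive_clutch_structure <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("female_id", "season", "lay_day") %in% names(records)))
  if (any(is.na(records$lay_day))) {
    stop("all records must have a lay_day; run impute_lay_from_hatch() first",
         call. = FALSE)
  }
  records$.row <- seq_len(nrow(records))
  hatch <- if ("hatch_day" %in% names(records)) records$hatch_day else
    rep(NA_integer_, nrow(records))
  records$.hatch_key <- dplyr::coalesce(hatch, .Machine$integer.max)

  ties <- records |>
    dplyr::count(.data$female_id, .data$season, .data$lay_day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(ties) > 0) {
    message(nrow(ties), " tied lay day(s) within female x season; ",
            "broken by hatch day then input order")
  }

  records <- records |>
    dplyr::arrange(.data$female_id, .data$season, .data$lay_day,
                   .data$.hatch_key, .data$.row) |>
    dplyr::group_by(.data$female_id, .data$season) |>
    dplyr::mutate(clutch_number = dplyr::row_number()) |>
    dplyr::ungroup()

  seasons <- records |>
    dplyr::group_by(.data$female_id, .data$season) |>
    dplyr::summarise(
      start_day = .data$lay_day[1],
      n_clutches = dplyr::n(),
      annual_eggs = sum(.data$n_eggs),
      annual_fledglings = sum(.data$n_fledglings),
      annual_recruits = sum(.data$n_recruits),
      female_age = .data$female_age[1],
      female_tarsus = if ("female_tarsus" %in% names(records))
        .data$female_tarsus[1] else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(reclutched = .data$n_clutches > 1)

  last_season <- seasons |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(.last = max(.data$season), .groups = "drop")
  seasons <- seasons |>
    dplyr::left_join(last_season, by = "female_id") |>
    dplyr::mutate(survived_to_next_season = .data$season < .data$.last) |>
    dplyr::select(-".last")

  records$.row <- NULL
  records$.hatch_key <- NULL
  list(records = records, seasons = seasons)
}

#' Count recruited offspring per clutch
#'
#' Fitness here is the number of a clutch's offspring that later recruit into
#' the breeding population. An offspring is credited to the clutch recorded as
#' its birth clutch in the pedigree (`birth_season`, `birth_clutch` columns,
#' linked through the dam), and counts as a recruit if it is itself observed
#' breeding -- as a dam, social male or genetic sire -- in any later season.
#'
#' @param records Breeding-record tibble with `clutch_number` assigned.
#' @param pedigree Pedigree tibble (`id`, `dam`, `sire`) with `birth_season`
#'   and `birth_clutch` columns for individuals of known origin.
#' @param breeders Optional tibble (`id`, `first_breeding_season`) overriding
#'   the breeder set derived from `records` and `pedigree`.
#' @return `records` with `n_recruits` recomputed and a logical
#'   `recruitment_truncated` flag for clutches of the final season, whose
#'   offspring cannot yet have been observed recruiting.
#' @export
compute_fitness <- function(records, pedigree, breeders = NULL) {
  records <- tibble::as_tibble(records)
  pedigree <- tibble::as_tibble(pedigree)
  if (is.null(breeders)) breeders <- breeder_set(records, pedigree)

  born <- pedigree |>
    dplyr::filter(!is.na(.data$dam), !is.na(.data$birth_season),
                  !is.na(.data$birth_clutch)) |>
    dplyr::left_join(breeders, by = "id") |>
    dplyr::mutate(recruited = !is.na(.data$first_breeding_season) &
                    .data$first_breeding_season > .data$birth_season) |>
    dplyr::group_by(.data$dam, .data$birth_season, .data$birth_clutch) |>
    dplyr::summarise(n_recruits = sum(.data$recruited), .groups = "drop")

  records |>
    dplyr::select(-dplyr::any_of("n_recruits")) |>
    dplyr::left_join(
      born,
      by = c(female_id = "dam", season = "birth_season",
             clutch_number = "birth_clutch")
    ) |>
    dplyr::mutate(
      n_recruits = dplyr::coalesce(.data$n_recruits, 0L),
      recruitment_truncated = .data$season >= max(.data$season)
    )
}

#' Derive the breeder set from records and pedigree
#'
#' An individual counts as a breeder from the first season in which it appears
#' as the dam or social male of a breeding record, or as the dam or genetic
#' sire of an individual born that season in the pedigree.
#'
#' @inheritParams compute_fitness
#' @return Tibble with `id` and `first_breeding_season`.
#' @export
breeder_set <- function(records, pedigree) {
  from_records <- dplyr::bind_rows(
    tibble::tibble(id = as.character(records$female_id),
                   season = records$season),
    if ("social_male_id" %in% names(records))
      tibble::tibble(id = as.character(records$social_male_id),
                     season = records$season)
  )
  from_pedigree <- dplyr::bind_rows(
    tibble::tibble(id = as.character(pedigree$dam),
                   season = pedigree$birth_season),
    tibble::tibble(id = as.character(pedigree$sire),
                   season = pedigree$birth_season)
  )
  dplyr::bind_rows(from_records, from_pedigree) |>
    dplyr::filter(!is.na(.data$id), !is.na(.data$season)) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(first_breeding_season = min(.data$season),
                     .groups = "drop")
}

#' Pre-season temperature cue
#'
#' The yearly environmental cue is the mean daily maximum temperature over a
#' fixed window (50 days by default) strictly before the grand mean start of
#' the breeding season. The grand mean is computed once, across all seasons,
#' from the female-season start days, then anchored to each season's calendar.
#'
#' @param temps Tibble with `date` (Date) and `tmax` (deg C) columns.
#' @param seasons Season table from [derive_clutch_structure()] (needs
#'   `season` and `start_day`), or a numeric grand-mean start day via
#'   `grand_mean_day`.
#' @param window Window length in days before the grand-mean start date.
#' @param max_missing Largest tolerated fraction of missing days in the
#'   window; seasons beyond it get a missing cue and a warning.
#' @param grand_mean_day Optional: supply the grand-mean start day directly.
#' @return Tibble with `season`, `cue` (deg C), `n_days_used` and
#'   `grand_mean_day` attribute.
#' @export
compute_temperature_cue <- function(temps, seasons, window = 50L,
                                    max_missing = 0.1,
                                    grand_mean_day = NULL) {
  temps <- tibble::as_tibble(temps)
  stopifnot(all(c("date", "tmax") %in% names(temps)))
  temps$date <- as.Date(temps$date)
  if (anyDuplicated(temps$date) > 0) {
    stop("duplicate dates in temperature series", call. = FALSE)
  }
  if (is.null(grand_mean_day)) {
    grand_mean_day <- mean(seasons$start_day, na.rm = TRUE)
  }
  anchor_day <- as.integer(round(grand_mean_day))
  season_levels <- sort(unique(seasons$season))
  lookup <- stats::setNames(temps$tmax, format(temps$date))

  cue <- purrr::map_dfr(season_levels, function(s) {
    anchor <- season_day_to_date(anchor_day, s)
    days <- anchor - seq_len(window)  # strictly before the anchor date
    vals <- lookup[format(days)]
    n_missing <- sum(is.na(vals))
    if (n_missing > max_missing * window) {
      warning("season ", s, ": ", n_missing, "/", window,
              " cue-window days missing; cue set to NA", call. = FALSE)
      tibble::tibble(season = s, cue = NA_real_,
                     n_days_used = window - n_missing)
    } else {
      tibble::tibble(season = s, cue = mean(vals, na.rm = TRUE),
                     n_days_used = window - n_missing)
    }
  })
  attr(cue, "grand_mean_day") <- grand_mean_day
  cue
}

#' Standardize a trait, keeping the back-transform
#'
#' Mean-centres and scales to unit variance (sample, n - 1 denominator). The
#' centre and scale are kept as attributes so results on the standardized
#' scale can be mapped back to days.
#'
#' @param x Numeric vector with at least two non-missing, non-constant values.
#' @return Numeric vector of class `std_trait` with `center` and `scale`
#'   attributes.
#' @seealso [unstandardize()]
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  ctr <- mean(x[ok])
  scl <- stats::sd(x[ok])
  if (scl == 0) stop("zero variance: cannot standardize", call. = FALSE)
  out <- (x - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  class(out) <- "std_trait"
  out
}

#' Back-transform a standardized trait
#'
#' @param z Numeric vector on the standardized scale.
#' @param center,scale Transform parameters; taken from `z`'s attributes when
#'   it came from [standardize()].
#' @return Numeric vector on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale)) {
    stop("center/scale not supplied and not found in attributes",
         call. = FALSE)
  }
  as.numeric(z) * scale + center
}

#' Read a breeding-record CSV
#'
#' Expects one row per clutch. Column names can be remapped through
#' `col_map`, a named character vector of the form
#' `c(female_id = "their_name", ...)`. Empty fields are missing values.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector mapping package column
#'   names to file column names.
#' @return Validated breeding-record tibble.
#' @export
read_breeding_records <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  validate_breeding_records(raw)
  raw
}

#' Read a pedigree CSV
#'
#' Expects columns `id`, `dam`, `sire` (empty = unknown); extra columns such
#' as `birth_season` and `birth_clutch` are kept.
#'
#' @inheritParams read_breeding_records
#' @return Pedigree tibble with character `id`/`dam`/`sire`.
#' @export
read_pedigree <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  stopifnot(all(c("id", "dam", "sire") %in% names(raw)))
  raw |>
    dplyr::mutate(dplyr::across(c("id", "dam", "sire"), as.character))
}

#' Read a daily maximum temperature CSV
#'
#' Expects `date` (ISO-8601) and `tmax` (deg C) columns, strictly increasing
#' dates without duplicates.
#'
#' @inheritParams read_breeding_records
#' @return Temperature tibble.
#' @export
read_temperatures <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  stopifnot(all(c("date", "tmax") %in% names(raw)))
  raw$date <- as.Date(raw$date)
  if (is.unsorted(raw$date, strictly = TRUE)) {
    stop("temperature dates must be strictly increasing", call. = FALSE)
  }
  raw
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (target in names(col_map)) {
    src <- col_map[[target]]
    if (!src %in% names(df)) {
      stop("mapped column not found in file: ", src, call. = FALSE)
    }
    names(df)[names(df) == src] <- target
  }
  df
}
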