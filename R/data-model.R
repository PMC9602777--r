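# Core domain model: participants, perceptual ratings, temperature records,
# and the validated container tying them together.

#' Factor levels used throughout the QST data model
#'
#' Categorical fields are stored as upper-snake strings and parsed
#' case-insensitively from files.
#'
#' @return Named list of character vectors: `group`, `sex`, `session`,
#'   `site`, `quality`, `mode`, `ms_type`.
#' @export
#' @examples
#' qst_levels()$session
qst_levels <- function() {
  list(
    group   = c("MS", "CTR"),
    sex     = c("M", "F"),
    session = c("NEUTRAL", "HEAT", "COLD"),
    site    = c("FINGER_PAD", "FOREARM", "FOREHEAD"),
    quality = c("COLD_WET", "NEUTRAL_WET", "WARM_WET"),
    mode    = c("STATIC", "DYNAMIC"),
    ms_type = c("RR", "PP", "SP")
  )
}

#' Probe temperature of a wet stimulus
#'
#' The wet probe is temperature-controlled at 25, 30 or 35 degC depending on
#' the stimulus quality; contact area (1.32 cm^2) and water content (0.8 mL)
#' are fixed properties of the stimulus.
#'
#' @param quality Character vector of stimulus qualities
#'   (`"COLD_WET"`, `"NEUTRAL_WET"`, `"WARM_WET"`).
#' @return Numeric vector of probe temperatures in degC.
#' @export
#' @examples
#' probe_temperature("COLD_WET")
probe_temperature <- function(quality) {
  quality <- parse_enum(quality, qst_levels()$quality, "quality")
  unname(c(COLD_WET = 25, NEUTRAL_WET = 30, WARM_WET = 35)[quality])
}

#' Physical constants of the wet stimulus probe
#'
#' @return Named list: `contact_area_cm2` (1.32), `water_content_ml` (0.8).
#' @export
stimulus_constants <- function() {
  list(contact_area_cm2 = 1.32, water_content_ml = 0.8)
}

# --- schemas -----------------------------------------------------------------

participant_cols <- c(
  "id", "group", "sex", "age_yr", "height_m", "mass_kg",
  "ethnicity", "edss", "ms_type", "medications"
)
rating_cols <- c(
  "participant_id", "session", "site", "quality", "mode",
  "wetness_mm", "thermal_mm"
)
temperature_cols <- c(
  "participant_id", "session", "time_s", "cheek_c", "chest_c",
  "forearm_c", "hand_c", "thigh_c", "back_c", "rectal_c"
)

parse_enum <- function(x, levels, field) {
  out <- toupper(trimws(as.character(x)))
  out[out == ""] <- NA_character_
  bad <- !is.na(out) & !(out %in% levels)
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "Invalid %s value(s): %s (allowed: %s)",
        field, paste(unique(out[bad]), collapse = ", "),
        paste(levels, collapse = ", ")
      ),
      class = "hygro_invalid_enum"
    )
  }
  out
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("%s table is missing column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "hygro_missing_column"
    )
  }
  invisible(df)
}

# --- constructors ------------------------------------------------------------

#' Assemble a validated QST dataset
#'
#' Bundles participant metadata, per-trial perceptual ratings and
#' skin/rectal temperature records, enforcing the invariants of the data
#' model: VAS values on \[0, 100\] mm, unique rating keys, temperatures in
#' (10, 45) degC, EDSS only for the MS group, and strict referential
#' integrity (every rating and temperature row must reference a known
#' participant).
#'
#' @param participants Tibble with columns `id`, `group`, `sex`, `age_yr`,
#'   `height_m`, `mass_kg`, `ethnicity`, `edss`, `ms_type`, `medications`.
#' @param ratings Tibble with columns `participant_id`, `session`, `site`,
#'   `quality`, `mode`, `wetness_mm`, `thermal_mm`.
#' @param temperatures Tibble with columns `participant_id`, `session`,
#'   `time_s` and the six local channels `cheek_c`, `chest_c`, `forearm_c`,
#'   `hand_c`, `thigh_c`, `back_c`, plus `rectal_c`.
#' @return An object of class `hygro_dataset`: a named list of the three
#'   validated tibbles.
#' @export
#' @examples
#' d <- hygro_dataset(
#'   participants = tibble::tibble(
#'     id = "P1", group = "CTR", sex = "F", age_yr = 30, height_m = 1.7,
#'     mass_kg = 60, ethnicity = "WE", edss = NA_real_,
#'     ms_type = NA_character_, medications = NA_character_
#'   ),
#'   ratings = tibble::tibble(
#'     participant_id = "P1", session = "NEUTRAL", site = "FOREHEAD",
#'     quality = "COLD_WET", mode = "DYNAMIC", wetness_mm = 54, thermal_mm = 30
#'   )
#' )
#' d
hygro_dataset <- function(participants, ratings = NULL, temperatures = NULL) {
  if (is.null(ratings)) ratings <- empty_ratings()
  if (is.null(temperatures)) temperatures <- empty_temperatures()
  d <- structure(
    list(
      participants = tibble::as_tibble(participants),
      ratings = tibble::as_tibble(ratings),
      temperatures = tibble::as_tibble(temperatures)
    ),
    class = "hygro_dataset"
  )
  validate_dataset(d)
}

empty_participants <- function() {
  tibble::tibble(
    id = character(), group = character(), sex = character(),
    age_yr = numeric(), height_m = numeric(), mass_kg = numeric(),
    ethnicity = character(), edss = numeric(), ms_type = character(),
    medications = character()
  )
}

empty_ratings <- function() {
  tibble::tibble(
    participant_id = character(), session = character(), site = character(),
    quality = character(), mode = character(),
    wetness_mm = numeric(), thermal_mm = numeric()
  )
}

empty_temperatures <- function() {
  tibble::tibble(
    participant_id = character(), session = character(), time_s = numeric(),
    cheek_c = numeric(), chest_c = numeric(), forearm_c = numeric(),
    hand_c = numeric(), thigh_c = numeric(), back_c = numeric(),
    rectal_c = numeric()
  )
}

#' Validate a QST dataset
#'
#' Runs all data-model invariants; raises a classed error on the first
#' violation. Called by [hygro_dataset()] and [read_dataset()].
#'
#' @param d A `hygro_dataset`.
#' @return `d`, invisibly unchanged, if valid.
#' @export
validate_dataset <- function(d) {
  lv <- qst_levels()
  p <- check_columns(d$participants, participant_cols, "participants")
  r <- check_columns(d$ratings, rating_cols, "ratings")
  tt <- check_columns(d$temperatures, temperature_cols, "temperatures")

  p$id <- as.character(p$id)
  p$ethnicity <- as.character(p$ethnicity)
  p$medications <- as.character(p$medications)
  p$edss <- as.numeric(p$edss)
  p$group <- parse_enum(p$group, lv$group, "group")
  p$sex <- parse_enum(p$sex, lv$sex, "sex")
  p$ms_type <- parse_enum(p$ms_type, lv$ms_type, "ms_type")
  if (anyDuplicated(p$id)) {
    rlang::abort("Duplicate participant id", class = "hygro_duplicate_key")
  }
  if (any(!is.na(p$age_yr) & p$age_yr <= 0) ||
      any(!is.na(p$mass_kg) & p$mass_kg <= 0)) {
    rlang::abort("age_yr and mass_kg must be positive",
                 class = "hygro_out_of_range")
  }
  if (any(!is.na(p$height_m) & (p$height_m <= 1.0 | p$height_m >= 2.5))) {
    rlang::abort("height_m must lie in (1.0, 2.5)", class = "hygro_out_of_range")
  }
  if (any(!is.na(p$edss) & p$group != "MS")) {
    rlang::abort("EDSS may only be present for MS participants",
                 class = "hygro_invalid_field")
  }
  if (any(!is.na(p$edss) & (p$edss < 0 | p$edss > 10 | (p$edss * 2) %% 1 != 0))) {
    rlang::abort("EDSS must lie in [0, 10] in 0.5 steps",
                 class = "hygro_out_of_range")
  }

  r$participant_id <- as.character(r$participant_id)
  r$session <- parse_enum(r$session, lv$session, "session")
  r$site <- parse_enum(r$site, lv$site, "site")
  r$quality <- parse_enum(r$quality, lv$quality, "quality")
  r$mode <- parse_enum(r$mode, lv$mode, "mode")
  vas <- c(r$wetness_mm, r$thermal_mm)
  if (any(is.na(vas)) || any(vas < 0 | vas > 100)) {
    rlang::abort("VAS ratings must lie in [0, 100] mm and be non-missing",
                 class = "hygro_vas_out_of_range")
  }
  key <- paste(r$participant_id, r$session, r$site, r$quality, r$mode, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort(
      "Duplicate rating key (participant, session, site, quality, mode)",
      class = "hygro_duplicate_key"
    )
  }

  tt$participant_id <- as.character(tt$participant_id)
  tt$session <- parse_enum(tt$session, lv$session, "session")
  tchan <- c("cheek_c", "chest_c", "forearm_c", "hand_c", "thigh_c",
             "back_c", "rectal_c")
  tv <- unlist(tt[tchan], use.names = FALSE)
  if (length(tv) > 0 && (any(is.na(tv)) || any(tv <= 10 | tv >= 45))) {
    rlang::abort("Temperatures must lie in (10, 45) degC",
                 class = "hygro_out_of_range")
  }
  if (any(tt$time_s < 0)) {
    rlang::abort("time_s must be >= 0", class = "hygro_out_of_range")
  }
  tt <- dplyr::arrange(tt, .data$participant_id, .data$session, .data$time_s)

  unknown <- setdiff(c(r$participant_id, tt$participant_id), p$id)
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("Rows reference unknown participant(s): %s",
              paste(unique(unknown), collapse = ", ")),
      class = "hygro_unknown_participant"
    )
  }

  d$participants <- p
  d$ratings <- r
  d$temperatures <- tt
  d
}

#' @export
print.hygro_dataset <- function(x, ...) {
  ng <- table(factor(x$participants$group, levels = qst_levels()$group))
  cat("<hygro_dataset>\n")
  cat(sprintf("  participants: %d (MS %d, CTR %d)\n",
              nrow(x$participants), ng[["MS"]], ng[["CTR"]]))
  cat(sprintf("  ratings:      %d rows\n", nrow(x$ratings)))
  cat(sprintf("  temperatures: %d rows\n", nrow(x$temperatures)))
  invisible(x)
}

# --- readers/writers ---------------------------------------------------------

read_table_file <- function(path, what, col_types = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("%s file not found: %s", what, path),
                 class = "hygro_missing_file")
  }
  if (is.null(col_types)) col_types <- readr::cols(.default = readr::col_guess())
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE, na = c("", "NA"))
}

participant_col_types <- function() {
  readr::cols(
    id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), age_yr = readr::col_double(),
    height_m = readr::col_double(), mass_kg = readr::col_double(),
    ethnicity = readr::col_character(), edss = readr::col_double(),
    ms_type = readr::col_character(), medications = readr::col_character()
  )
}

#' Read a QST dataset from delimited text files
#'
#' Reads the three comma-delimited, UTF-8 tables (participants, ratings,
#' temperatures), parses enumerations case-insensitively, and validates the
#' full data model including referential integrity. Each violation raises a
#' distinct classed error (`hygro_missing_column`, `hygro_vas_out_of_range`,
#' `hygro_unknown_participant`, `hygro_duplicate_key`).
#'
#' @param participants,ratings,temperatures Paths to the three CSV files.
#'   `ratings` and `temperatures` may be `NULL` for metadata-only datasets.
#' @return A validated [hygro_dataset()].
#' @export
read_dataset <- function(participants, ratings = NULL, temperatures = NULL) {
  p <- read_table_file(participants, "participants")
  check_columns(p, participant_cols, "participants")
  # re-read with the fixed schema once the header is known to be complete
  p <- read_table_file(participants, "participants", participant_col_types())
  r <- if (is.null(ratings)) {
    empty_ratings()
  } else {
    read_table_file(
      ratings, "ratings",
      readr::cols(participant_id = readr::col_character(),
                  session = readr::col_character(),
                  site = readr::col_character(),
                  quality = readr::col_character(),
                  mode = readr::col_character(),
                  wetness_mm = readr::col_double(),
                  thermal_mm = readr::col_double())
    )
  }
  tt <- if (is.null(temperatures)) {
    empty_temperatures()
  } else {
    read_table_file(
      temperatures, "temperatures",
      readr::cols(participant_id = readr::col_character(),
                  session = readr::col_character(),
                  .default = readr::col_double())
    )
  }
  hygro_dataset(p, r, tt)
}

#' Write a QST dataset to delimited text files
#'
#' Inverse of [read_dataset()]: writes `participants.csv`, `ratings.csv` and
#' `temperatures.csv` into `dir` such that reading them back reproduces the
#' dataset field-for-field (missing optional fields are serialized as empty
#' strings, never as 0).
#'
#' @param d A `hygro_dataset`.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "hygro_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    rlang::abort(sprintf("Cannot create directory: %s", dir),
                 class = "hygro_unwritable")
  }
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    ratings = file.path(dir, "ratings.csv"),
    temperatures = file.path(dir, "temperatures.csv")
  )
  readr::write_csv(d$participants, paths[["participants"]], na = "")
  readr::write_csv(d$ratings, paths[["ratings"]], na = "")
  readr::write_csv(d$temperatures, paths[["temperatures"]], na = "")
  invisible(paths)
}

#' Per-group summary of cohort characteristics
#'
#' Sample mean and SD (n-1 denominator) of age, height, body mass and — for
#' the MS group — EDSS, in the style of a participant-characteristics table.
#' With a single participant in a group the SD is reported as missing.
#'
#' @param participants Participants tibble (or a `hygro_dataset`).
#' @param groups Which groups to summarize (default both).
#' @return Tibble with one row per group: `n`, and `mean`/`sd` columns for
#'   `age_yr`, `height_m`, `mass_kg`, `edss`.
#' @export
#' @examples
#' summarize_cohort(ms_participants_table())
summarize_cohort <- function(participants, groups = c("MS", "CTR")) {
  if (inherits(participants, "hygro_dataset")) {
    participants <- participants$participants
  }
  check_columns(participants, participant_cols, "participants")
  groups <- parse_enum(groups, qst_levels()$group, "group")
  p <- dplyr::filter(participants, .data$group %in% groups)
  missing_grp <- setdiff(groups, unique(p$group))
  if (length(missing_grp) > 0) {
    rlang::abort(sprintf("No participants in group(s): %s",
                         paste(missing_grp, collapse = ", ")),
                 class = "hygro_empty_group")
  }
  sd1 <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else stats::sd(x, na.rm = TRUE)
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  p |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mn(.data$age_yr), age_sd = sd1(.data$age_yr),
      height_mean = mn(.data$height_m), height_sd = sd1(.data$height_m),
      mass_mean = mn(.data$mass_kg), mass_sd = sd1(.data$mass_kg),
      edss_mean = mn(.data$edss), edss_sd = sd1(.data$edss),
      .groups = "drop"
    )
}
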