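# Injury-registry schema: variable encodings, validation, CSV input/output.

time_bin_levels <- c("0:00-4:00", "4:00-8:00", "8:00-12:00",
                     "12:00-16:00", "16:00-20:00", "20:00-24:00")
season_levels <- c("spring", "summer", "fall", "winter")
road_width_levels <- c("lt3", "w3to5_5", "w5_5to13", "gt13")
age_group_levels <- c("working_age", "older")
gender_levels <- c("male", "female")
severity_levels <- c("minor", "severe")

#' Study variables used by the signal detection analysis
#'
#' The ten predictors considered at every node of the partitioning:
#' demographics (age, gender), timing (4-hour time bin, season), exposure
#' (road-network distance from residence to injury site), road environment
#' (national-road flag, road-width class, densely-inhabited-district flag)
#' and residence-area socioeconomic context (aging rate, proportion of
#' low-income households).
#'
#' @return Character vector of column names.
#' @export
sda_variables <- function() {
  c("age", "gender", "time_bin", "season", "network_distance_m",
    "national_road", "road_width_class", "did", "aging_rate", "low_ses_prop")
}

#' Classify age into the two analysis strata
#'
#' Adults 18-64 form the working-age stratum; 65 and over the older stratum
#' (65 is the Japanese retirement age and the WHO old-age threshold).
#' Pedestrians under 18 are outside the study population.
#'
#' @param age Integer vector of ages in years, all `>= 18`.
#' @return Factor with levels `working_age`, `older`.
#' @export
#' @examples
#' derive_age_group(c(18, 64, 65, 80))
derive_age_group <- function(age) {
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age))) {
    stop_domain("`age` must be a finite numeric vector with no missing values.")
  }
  if (any(age < 18)) {
    stop_domain("`age` below 18: pedestrians aged 17 years and under are excluded from the study population.")
  }
  factor(ifelse(age >= 65, "older", "working_age"), levels = age_group_levels)
}

#' Encode measured road width into the four ordinal classes
#'
#' Road width per lane is classified as under 3 m (below the Japanese minimum
#' for ordinary motor vehicles), 3-5.5 m, 5.5-13 m, and over 13 m (typical of
#' national roads). Boundary values go to the upper class (half-open
#' intervals `[lo, hi)`).
#'
#' @param width_m Positive numeric vector, road width per lane in meters.
#' @return Ordered factor with levels `lt3 < w3to5_5 < w5_5to13 < gt13`.
#' @export
#' @examples
#' encode_road_width(c(2.9, 3, 5.5, 20))
encode_road_width <- function(width_m) {
  if (!is.numeric(width_m) || anyNA(width_m) || any(!is.finite(width_m))) {
    stop_domain("`width_m` must be finite and non-missing.")
  }
  if (any(width_m <= 0)) stop_domain("`width_m` must be positive.")
  cut(width_m, breaks = c(0, 3, 5.5, 13, Inf), labels = road_width_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Map calendar month to season
#'
#' Meteorological quarters: Mar-May spring, Jun-Aug summer, Sep-Nov fall,
#' Dec-Feb winter.
#'
#' @param month Integer vector in 1..12.
#' @return Factor with levels `spring`, `summer`, `fall`, `winter`.
#' @export
derive_season <- function(month) {
  if (!is.numeric(month) || anyNA(month) || any(month %% 1 != 0) ||
      any(month < 1 | month > 12)) {
    stop_domain("`month` must be an integer in 1..12.")
  }
  idx <- c(4, 4, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4)[month]
  factor(season_levels[idx], levels = season_levels)
}

#' Bin clock hour into the six 4-hour injury-time bins
#'
#' @param hour Numeric vector in `[0, 24)`.
#' @return Factor with levels `0:00-4:00` ... `20:00-24:00`.
#' @export
derive_time_bin <- function(hour) {
  if (!is.numeric(hour) || anyNA(hour) || any(hour < 0 | hour >= 24)) {
    stop_domain("`hour` must be in [0, 24).")
  }
  factor(time_bin_levels[floor(hour / 4) + 1L], levels = time_bin_levels)
}

registry_required_cols <- function() {
  c("record_id", "age", "gender", "injury_datetime",
    "residence_x", "residence_y", "injury_x", "injury_y",
    "national_road", "did", "aging_rate", "low_ses_prop", "severity")
}

as_lgl <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  xx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[xx %in% c("true", "t", "1", "yes")] <- TRUE
  out[xx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read an injury registry from CSV
#'
#' Expects one row per transported pedestrian with columns `record_id`,
#' `age`, `gender` (male/female), `injury_datetime` (ISO 8601),
#' `residence_x`, `residence_y`, `injury_x`, `injury_y` (planar meters),
#' `national_road`, `did` (logical), `aging_rate`, `low_ses_prop` (percent),
#' `severity` (minor/severe), and either `road_width_m` (meters, encoded via
#' [encode_road_width()]) or `road_width_class`. Every row is validated with
#' [validate_registry()].
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row).
#' @param exclude_minors If `TRUE`, rows with `age < 18` are dropped (their
#'   count is kept in attribute `n_excluded_minors`) instead of raising a
#'   validation error. The pipeline uses this to account for exclusions.
#' @return A validated registry tibble, row order preserved.
#' @export
read_registry <- function(path, exclude_minors = FALSE) {
  if (!file.exists(path)) stop_schema(paste0("registry file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    gender = readr::col_character(),
    severity = readr::col_character(),
    injury_datetime = readr::col_datetime(format = "")
  ), progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_schema(paste0("unparseable cell(s) in ", path, ": row ",
                       paste(unique(probs$row), collapse = ", ")))
  }
  missing <- setdiff(registry_required_cols(), names(raw))
  if (length(missing) > 0) {
    stop_schema(paste0("registry is missing required column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (!any(c("road_width_m", "road_width_class") %in% names(raw))) {
    stop_schema("registry is missing required column(s): road_width_m or road_width_class")
  }
  out <- raw |>
    mutate(
      gender = factor(.data$gender, levels = gender_levels),
      severity = factor(.data$severity, levels = severity_levels),
      national_road = as_lgl(.data$national_road),
      did = as_lgl(.data$did)
    )
  if ("road_width_class" %in% names(out)) {
    out <- mutate(out, road_width_class = factor(
      as.character(.data$road_width_class), levels = road_width_levels,
      ordered = TRUE))
  } else {
    out <- mutate(out, road_width_class = encode_road_width(.data$road_width_m))
  }
  n_minor_age <- 0L
  if (exclude_minors) {
    keep <- is.na(out$age) | out$age >= 18
    n_minor_age <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  out <- validate_registry(out)
  attr(out, "n_excluded_minors") <- n_minor_age
  out
}

#' Validate an injury registry
#'
#' Enforces the registry invariants: unique record ids; integer ages of 18
#' or more (the study excludes minors); known gender, severity and road-width
#' levels; percentages within `[0, 100]`; finite coordinates; logical road
#' and district flags. Errors name the offending column and row numbers.
#'
#' @param data A registry data frame.
#' @return The (invisibly returned) validated tibble with canonical column
#'   types.
#' @export
validate_registry <- function(data) {
  data <- as_tibble(data)
  bad <- function(cond) which(!cond)
  fail <- function(col, rows, why) {
    stop_validation(paste0("invalid `", col, "` (", why, ") in row(s): ",
                           paste(head(rows, 10), collapse = ", ")))
  }
  dup <- data$record_id[duplicated(data$record_id)]
  if (length(dup) > 0) {
    stop_validation(paste0("duplicated record_id: ", paste(unique(dup), collapse = ", ")))
  }
  r <- bad(!is.na(data$age) & data$age >= 18 & data$age %% 1 == 0)
  if (length(r)) fail("age", r, "must be an integer >= 18; minors are excluded from the study")
  if (!is.factor(data$gender)) data$gender <- factor(as.character(data$gender), levels = gender_levels)
  r <- bad(!is.na(data$gender))
  if (length(r)) fail("gender", r, "must be male or female")
  if (!is.factor(data$severity)) data$severity <- factor(as.character(data$severity), levels = severity_levels)
  r <- bad(!is.na(data$severity))
  if (length(r)) fail("severity", r, "must be minor or severe")
  if (!is.factor(data$road_width_class)) {
    data$road_width_class <- factor(as.character(data$road_width_class),
                                    levels = road_width_levels, ordered = TRUE)
  }
  r <- bad(!is.na(data$road_width_class))
  if (length(r)) fail("road_width_class", r,
                      paste0("must be one of ", paste(road_width_levels, collapse = "/")))
  for (col in c("aging_rate", "low_ses_prop")) {
    v <- data[[col]]
    r <- bad(!is.na(v) & v >= 0 & v <= 100)
    if (length(r)) fail(col, r, "must be a percentage in [0, 100]")
  }
  for (col in c("residence_x", "residence_y", "injury_x", "injury_y")) {
    v <- data[[col]]
    r <- bad(is.finite(v))
    if (length(r)) fail(col, r, "must be finite planar coordinates (meters)")
  }
  for (col in c("national_road", "did")) {
    data[[col]] <- as_lgl(data[[col]])
    r <- bad(!is.na(data[[col]]))
    if (length(r)) fail(col, r, "must be logical")
  }
  if ("time_bin" %in% names(data) && !is.factor(data$time_bin)) {
    data$time_bin <- factor(as.character(data$time_bin), levels = time_bin_levels)
  }
  if ("season" %in% names(data) && !is.factor(data$season)) {
    data$season <- factor(as.character(data$season), levels = season_levels)
  }
  if ("age_group" %in% names(data) && !is.factor(data$age_group)) {
    data$age_group <- factor(as.character(data$age_group), levels = age_group_levels)
  }
  invisible(data)
}

#' Add derived analysis variables to a registry
#'
#' Adds `age_group` (working-age vs older), `time_bin` (six 4-hour bins from
#' the injury timestamp) and `season`.
#'
#' @param data A validated registry tibble.
#' @return The tibble with the three derived columns.
#' @export
augment_registry <- function(data) {
  lt <- as.POSIXlt(data$injury_datetime, tz = "UTC")
  data |>
    mutate(
      age_group = derive_age_group(.data$age),
      time_bin = derive_time_bin(lt$hour + lt$min / 60),
      season = derive_season(lt$mon + 1L)
    )
}

#' Write an injury registry to CSV
#'
#' Inverse of [read_registry()]: factors are written as their labels and the
#' timestamp in ISO 8601 UTC, so that write-read-write round-trips are
#' byte-identical.
#'
#' @param data Registry tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(data, path) {
  out <- data |>
    mutate(
      across(where(is.factor), as.character),
      injury_datetime = format(.data$injury_datetime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
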