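#' Long-format panel datasets
#'
#' Both tasks in an ascending-series threshold study produce long tables with
#' one row per panelist and ladder level:
#'
#' * discrimination (triangle) data: columns `panelist`, optional
#'   `condition`, `concentration` (ng/L) and logical `correct`;
#' * paired-preference (2AFC) data: columns `panelist`, `concentration`
#'   and `choice` (`"spike"` or `"blank"`).
#'
#' `as_discrimination_data()` / `as_preference_data()` validate a data frame
#' against these contracts (every panelist must have exactly one row per
#' ladder level, concentrations positive) and return a tibble sorted by
#' panelist and ascending concentration, so shuffled inputs are accepted.
#'
#' @param data A data frame in long format.
#' @param series Optional [concentration_series()]; inferred from the sorted
#'   unique concentrations when omitted.
#' @return A validated tibble with a `series` attribute.
#' @name panel-data
NULL

validate_panel <- function(data, value_col, series) {
  if (!is.data.frame(data)) stop_schema("`data` must be a data frame")
  needed <- c("panelist", "concentration", value_col)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(data$concentration)) || any(data$concentration <= 0)) {
    stop_domain("concentrations must be finite and > 0 ng/L")
  }
  series <- if (is.null(series)) series_from_data(data) else as_concentration_series(series)
  lv <- as.numeric(series)

  out <- data |>
    as_tibble() |>
    mutate(panelist = as.character(.data$panelist)) |>
    arrange(.data$panelist, .data$concentration)

  bad <- out |>
    summarise(
      ok = length(.data$concentration) == length(lv) &&
        all(sort(.data$concentration) == lv),
      .by = "panelist"
    ) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop_integrity(paste0(
      "panelist(s) with missing or duplicate ladder levels: ",
      paste(bad$panelist, collapse = ", ")
    ))
  }
  attr(out, "series") <- series
  out
}

#' @rdname panel-data
#' @export
as_discrimination_data <- function(data, series = NULL) {
  data <- as_tibble(data)
  if ("correct" %in% names(data) && !is.logical(data$correct)) {
    data$correct <- parse_outcome(data$correct)
  }
  out <- validate_panel(data, "correct", series)
  class(out) <- c("discrimination_data", class(out))
  out
}

#' @rdname panel-data
#' @export
as_preference_data <- function(data, series = NULL) {
  data <- as_tibble(data)
  if ("choice" %in% names(data)) data$choice <- parse_choice(data$choice)
  out <- validate_panel(data, "choice", series)
  class(out) <- c("preference_data", class(out))
  out
}

#' Retrieve the ladder attached to a dataset
#'
#' @param data A validated panel dataset (or any long table with a
#'   `concentration` column, from which the ladder is inferred).
#' @return A [concentration_series()].
#' @export
dataset_series <- function(data) {
  attr(data, "series") %||% series_from_data(data)
}

# outcome tokens accepted case-insensitively: 1/0, correct/incorrect, TRUE/FALSE
parse_outcome <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(tok))
  out[tok %in% c("1", "correct", "true", "t", "yes")] <- TRUE
  out[tok %in% c("0", "incorrect", "false", "f", "no")] <- FALSE
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop_domain(paste0("unrecognised outcome token(s): ",
                       paste(bad, collapse = ", ")))
  }
  as.logical(out)
}

parse_choice <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  if (!all(tok %in% c("spike", "blank"))) {
    bad <- unique(tok[!tok %in% c("spike", "blank")])
    stop_domain(paste0("choice must be 'spike' or 'blank'; offending token(s): ",
                       paste(bad, collapse = ", ")))
  }
  tok
}

default_schema <- function(schema) {
  base <- list(panelist = "panelist", condition = "condition",
               concentration = "concentration", outcome = "outcome",
               choice = "choice")
  utils::modifyList(base, as.list(schema %||% list()))
}

read_panel_csv <- function(path, schema, value_from, value_to, parser) {
  if (!file.exists(path)) stop_schema(paste0("file not found: ", path))
  schema <- default_schema(schema)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c(schema$panelist, schema$concentration, schema[[value_from]])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing required column(s) in ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    panelist = as.character(raw[[schema$panelist]]),
    concentration = as.numeric(raw[[schema$concentration]])
  )
  if (anyNA(out$concentration)) {
    stop_domain("non-numeric concentration value in input file")
  }
  if (schema$condition %in% names(raw)) out$condition <- raw[[schema$condition]]
  out[[value_to]] <- parser(raw[[schema[[value_from]]]])
  select(out, dplyr::any_of(c("panelist", "condition", "concentration", value_to)))
}

#' Read / write discrimination (triangle) responses
#'
#' CSV interchange for triangle-test outcomes: comma-separated, UTF-8,
#' header row required, one row per panelist and concentration. Outcomes
#' are parsed case-insensitively from `1/0`, `correct/incorrect` or
#' `TRUE/FALSE`. Column names are configurable through `schema`, a named
#' list with any of `panelist`, `condition`, `concentration`, `outcome`.
#'
#' @param path File path.
#' @param schema Named list of column-name overrides.
#' @param series Optional [concentration_series()] the file must conform to.
#' @return `read_discrimination_csv()` returns a validated
#'   discrimination tibble; `write_discrimination_csv()` invisibly returns
#'   `path`.
#' @export
read_discrimination_csv <- function(path, schema = NULL, series = NULL) {
  out <- read_panel_csv(path, schema, "outcome", "correct", parse_outcome)
  as_discrimination_data(out, series = series)
}

#' @rdname read_discrimination_csv
#' @param data A discrimination dataset.
#' @export
write_discrimination_csv <- function(data, path) {
  out <- as_tibble(data)
  out$correct <- as.integer(out$correct)
  names(out)[names(out) == "correct"] <- "outcome"
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write paired-preference (2AFC) responses
#'
#' As [read_discrimination_csv()], but the outcome column holds the chosen
#' sample and is restricted to the two-valued alphabet `spike` / `blank`
#' (parsed case-insensitively). The schema key for the choice column is
#' `choice`.
#'
#' @inheritParams read_discrimination_csv
#' @return `read_preference_csv()` returns a validated preference tibble;
#'   `write_preference_csv()` invisibly returns `path`.
#' @export
read_preference_csv <- function(path, schema = NULL, series = NULL) {
  out <- read_panel_csv(path, schema, "choice", "choice", parse_choice)
  as_preference_data(out, series = series)
}

#' @rdname read_preference_csv
#' @param data A preference dataset.
#' @export
write_preference_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}
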