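#' Consistency gating for paired-preference panels
#'
#' In a 2AFC preference ladder the guessing rate is 1/2, so a single
#' choice carries little information. Responder status is therefore gated
#' on *consistency* over the top `k_top` (default 3) concentrations —
#' levels high enough that anyone able to detect the compound should do
#' so. A panelist choosing the spiked sample at all top levels is a
#' `consistent-preferer`, one choosing the blank at all of them a
#' `consistent-rejecter`; anything mixed is a `non-responder`. Choosing
#' the same sample three times by pure chance has probability 12.5% per
#' direction (see [chance_consistency_probability()]).
#'
#' @param data A preference dataset (see [as_preference_data()]), or a
#'   single character choice vector in ascending ladder order.
#' @param k_top Number of top concentrations examined (>= 1).
#' @return A tibble with one row per panelist: `panelist`, `status`,
#'   `top_choices` (comma-separated, ascending).
#' @export
classify_consistency <- function(data, k_top = 3) {
  if (k_top < 1) stop_domain("`k_top` must be >= 1")
  if (!is.data.frame(data)) {
    choices <- parse_choice(data)
    if (k_top > length(choices)) stop_domain("`k_top` exceeds number of levels")
    return(tibble(panelist = NA_character_,
                  status = consistency_status(choices, k_top),
                  top_choices = paste(utils::tail(choices, k_top), collapse = ",")))
  }
  data <- as_preference_data(data, series = attr(data, "series"))
  n_levels <- length(as.numeric(dataset_series(data)))
  if (k_top > n_levels) stop_domain("`k_top` exceeds number of levels")
  data |>
    arrange(.data$panelist, .data$concentration) |>
    summarise(
      status = consistency_status(.data$choice, k_top),
      top_choices = paste(utils::tail(.data$choice, k_top), collapse = ","),
      .by = "panelist"
    )
}

consistency_status <- function(choices, k_top) {
  top <- utils::tail(choices, k_top)
  if (all(top == "spike")) "consistent-preferer"
  else if (all(top == "blank")) "consistent-rejecter"
  else "non-responder"
}

#' Chance probability of a consistent choice run
#'
#' Probability that a panelist choosing at random in `k_top` successive
#' 2AFC trials picks the same sample every time: `(1/2)^k_top` for a
#' fixed direction (12.5% for three trials), and twice that when either
#' direction counts as consistent (the two one-sided events are
#' disjoint).
#'
#' @param k_top Number of successive 2AFC trials (>= 1).
#' @param directions `"one-sided"` (a named direction) or `"either"`.
#' @return A probability.
#' @examples
#' chance_consistency_probability(3) # 0.125
#' chance_consistency_probability(3, "either") # 0.25
#' @export
chance_consistency_probability <- function(k_top = 3,
                                           directions = c("one-sided", "either")) {
  if (k_top < 1) stop_domain("`k_top` must be >= 1")
  directions <- match.arg(directions)
  p <- (1 / 2)^k_top
  if (directions == "either") 2 * p else p
}

#' Consumer rejection threshold by spike-coded preference regression
#'
#' Codes each choice as 1 (spike preferred) / 0 (blank preferred), fits
#' an OLS line against log10 concentration over the selected consistency
#' segment, and reads thresholds where the line crosses fixed criteria:
#' crossing 0.25 from above (negative slope) marks the concentration
#' where the group rejects the spiked sample — the *rejection threshold*
#' — while crossing 0.75 from below (positive slope) marks a group
#' *preference threshold*. A monotone line can only cross one of the two
#' within the tested range. Crossings further than one ladder step
#' outside the range are reported as undefined rather than extrapolated
#' to absurd concentrations.
#'
#' @param data A preference dataset (see [as_preference_data()]).
#' @param segment Which panelists to fit: all consistent responders,
#'   consistent rejecters only, or consistent preferers only.
#' @param rejection_criterion,preference_criterion Proportion-choosing-
#'   spike criteria (defaults 0.25 and 0.75).
#' @param k_top Passed to [classify_consistency()].
#' @return An object of class `rejection_fit`: `slope`, `intercept`,
#'   `rejection_threshold`, `rejection_status`, `preference_threshold`,
#'   `preference_status`, `n_included`, `segment`, `series`, per-level
#'   spike proportions.
#' @export
fit_rejection <- function(data,
                          segment = c("all-consistent", "rejecters-only",
                                      "preferers-only"),
                          rejection_criterion = 0.25,
                          preference_criterion = 0.75,
                          k_top = 3) {
  segment <- match.arg(segment)
  data <- as_preference_data(data, series = attr(data, "series"))
  series <- dataset_series(data)
  cls <- classify_consistency(data, k_top = k_top)
  keep <- switch(segment,
    "all-consistent" = cls$panelist[cls$status != "non-responder"],
    "rejecters-only" = cls$panelist[cls$status == "consistent-rejecter"],
    "preferers-only" = cls$panelist[cls$status == "consistent-preferer"]
  )
  if (length(keep) < 2) {
    stop_insufficient(paste0("segment '", segment, "' selects fewer than 2 ",
                             "consistent panelists"))
  }
  sub <- filter(data, .data$panelist %in% keep)
  ols <- binary_ols(sub$concentration, as.numeric(sub$choice == "spike"))
  rej <- guarded_crossing(ols$intercept, ols$slope, rejection_criterion,
                          series, "down")
  pref <- guarded_crossing(ols$intercept, ols$slope, preference_criterion,
                           series, "up")
  props <- sub |>
    summarise(p_spike = mean(.data$choice == "spike"), n = dplyr::n(),
              .by = "concentration") |>
    arrange(.data$concentration)
  fitted_rng <- ols$intercept + ols$slope * log10(range(as.numeric(series)))
  if (any(fitted_rng < -1e-8 | fitted_rng > 1 + 1e-8)) {
    warn("fitted preference proportion leaves [0, 1] within the tested range",
         class = "threshpanel_out_of_range_fit")
  }
  structure(
    list(
      slope = ols$slope, intercept = ols$intercept,
      rejection_criterion = rejection_criterion,
      preference_criterion = preference_criterion,
      rejection_threshold = rej$threshold, rejection_status = rej$status,
      preference_threshold = pref$threshold, preference_status = pref$status,
      n_included = length(keep), segment = segment,
      series = series, level_proportions = props, model = ols$model
    ),
    class = "rejection_fit"
  )
}

#' @export
print.rejection_fit <- function(x, ...) {
  cat("<rejection_fit> segment '", x$segment, "', ", x$n_included,
      " panelists\n", sep = "")
  cat(sprintf("  line: p(spike) = %.4f %+.4f * log10(c)\n",
              x$intercept, x$slope))
  fmt <- function(v, s, lab, crit) {
    if (is.na(v)) cat("  ", lab, " (", crit, "): undefined (", s, ")\n", sep = "")
    else cat(sprintf("  %s (%.2f): %.3g ng/L (%s)\n", lab, crit, v, s))
  }
  fmt(x$rejection_threshold, x$rejection_status, "rejection threshold",
      x$rejection_criterion)
  fmt(x$preference_threshold, x$preference_status, "preference threshold",
      x$preference_criterion)
  invisible(x)
}

#' @rdname fit_rejection
#' @param x A `rejection_fit`.
#' @param ... Unused.
#' @export
glance.rejection_fit <- function(x, ...) {
  tibble(
    segment = x$segment,
    n_included = x$n_included,
    slope = x$slope,
    intercept = x$intercept,
    rejection_threshold = x$rejection_threshold,
    rejection_status = x$rejection_status,
    preference_threshold = x$preference_threshold,
    preference_status = x$preference_status
  )
}

#' @rdname fit_rejection
#' @export
tidy.rejection_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' Segment-aware rejection-threshold report
#'
#' Tallies the consistency classification of a preference panel and fits
#' the rejection regression for the all-consistent and rejecters-only
#' segments. The preferers-only segment is summarised descriptively
#' (per-level spike proportions); a threshold fit is only attempted when
#' that segment reaches `min_preferers` panelists, since a handful of
#' preferers cannot support a meaningful crossing estimate.
#'
#' @param data A preference dataset.
#' @param k_top Consistency window, see [classify_consistency()].
#' @param min_preferers Minimum preferers-only segment size for a fit.
#' @return An object of class `segment_report`: `counts` (one-row
#'   tibble), `classification` (per-panelist tibble), `fit_all`,
#'   `fit_rejecters` (`rejection_fit` or `NULL` when the segment is
#'   degenerate), `preferer_proportions`, `fit_preferers`.
#' @export
segment_report <- function(data, k_top = 3, min_preferers = 10) {
  data <- as_preference_data(data, series = attr(data, "series"))
  cls <- classify_consistency(data, k_top = k_top)
  counts <- tibble(
    n_total = nrow(cls),
    n_preferers = sum(cls$status == "consistent-preferer"),
    n_rejecters = sum(cls$status == "consistent-rejecter"),
    n_non_responders = sum(cls$status == "non-responder")
  )
  try_fit <- function(segment) {
    tryCatch(fit_rejection(data, segment = segment, k_top = k_top),
             threshpanel_insufficient_data_error = function(e) NULL)
  }
  preferers <- cls$panelist[cls$status == "consistent-preferer"]
  pref_props <- data |>
    filter(.data$panelist %in% preferers) |>
    summarise(p_spike = mean(.data$choice == "spike"), n = dplyr::n(),
              .by = "concentration") |>
    arrange(.data$concentration)
  structure(
    list(
      counts = counts,
      classification = cls,
      fit_all = try_fit("all-consistent"),
      fit_rejecters = try_fit("rejecters-only"),
      preferer_proportions = pref_props,
      fit_preferers = if (counts$n_preferers >= min_preferers)
        try_fit("preferers-only") else NULL
    ),
    class = "segment_report"
  )
}

#' @export
print.segment_report <- function(x, ...) {
  cat("<segment_report>\n")
  print(x$counts)
  if (!is.null(x$fit_all)) { cat("\nall-consistent fit:\n"); print(x$fit_all) }
  if (!is.null(x$fit_rejecters)) { cat("\nrejecters-only fit:\n"); print(x$fit_rejecters) }
  if (is.null(x$fit_preferers) && nrow(x$preferer_proportions) > 0) {
    cat("\npreferers-only: descriptive proportions only (segment too small for a fit)\n")
    print(x$preferer_proportions)
  }
  invisible(x)
}
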