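#' Chance-adjusted performance criterion
#'
#' The graphical group-threshold method reads the threshold off a fitted
#' performance line at the proportion correct halfway between perfect
#' performance (1) and chance performance: `(1 + chance) / 2`. For the
#' triangle test (chance 1/3) this is 2/3, usually quoted as 67%.
#'
#' @param chance Guessing probability of the forced-choice task, in (0, 1).
#' @return The criterion proportion.
#' @examples
#' criterion_for(1 / 3) # 2/3
#' criterion_for(1 / 2) # 0.75
#' @export
criterion_for <- function(chance) {
  if (!is.numeric(chance) || any(chance <= 0) || any(chance >= 1)) {
    stop_domain("`chance` must lie strictly between 0 and 1")
  }
  (1 + chance) / 2
}

# ---- shared 0/1-on-log10-concentration OLS machinery -----------------------
# Used by both the graphical detection threshold and the rejection threshold:
# individual binary codes are regressed on log10 concentration and the line
# is inverted at a criterion proportion. For complete balanced panels this
# is identical to fitting per-level proportions weighted by per-level n.

binary_ols <- function(concentration, y) {
  x <- log10(concentration)
  fit <- lm(y ~ x)
  list(
    model = fit,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    n_points = length(y)
  )
}

# log10-scale guard band: the tested range extended by one local ladder step
# on each side; crossings beyond it are declared undefined rather than
# reported as absurd extrapolations
guard_band <- function(series) {
  lv <- as.numeric(series)
  c(log10(extend_series(series, "below")), log10(extend_series(series, "above")))
}

# invert the fitted line at `criterion`, requiring the stated slope sign
# ("up" = performance rises with concentration). Returns threshold (ng/L or
# NA) plus a status flag.
guarded_crossing <- function(intercept, slope, criterion, series, sign = c("up", "down")) {
  sign <- match.arg(sign)
  ok_slope <- if (sign == "up") slope > 0 else slope < 0
  if (!is.finite(slope) || !ok_slope) {
    status <- if (isTRUE(abs(slope) < .Machine$double.eps^0.5) &&
                  ((sign == "up" && intercept >= criterion) ||
                   (sign == "down" && intercept <= criterion))) {
      "undefined-below-range" # flat line already past the criterion
    } else {
      "undefined-nonpositive-slope"
    }
    return(list(threshold = NA_real_, status = status))
  }
  x0 <- (criterion - intercept) / slope
  lv <- log10(range(as.numeric(series)))
  gb <- guard_band(series)
  if (x0 < gb[1] || x0 > gb[2]) {
    list(threshold = NA_real_, status = "undefined-beyond-range")
  } else if (x0 < lv[1] || x0 > lv[2]) {
    list(threshold = 10^x0, status = "extrapolated")
  } else {
    list(threshold = 10^x0, status = "defined")
  }
}

# inverse-prediction (calibration) bounds: the two concentrations where the
# (1 - alpha) pointwise confidence band for the regression mean crosses the
# criterion. Solved in closed form; algebraically identical to Fieller's
# interval for (criterion - intercept)/slope.
inverse_prediction_ci <- function(fit, criterion, conf_level) {
  mod <- fit$model
  x <- mod$model$x
  n <- length(x)
  if (n <= 2) return(c(NA_real_, NA_real_))
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  sigma2 <- sum(mod$residuals^2) / (n - 2)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  b <- fit$slope
  ybar <- fit$intercept + b * xbar
  cc <- tcrit^2 * sigma2 / sxx
  aa <- b^2 - cc
  if (aa <= 0) return(c(NA_real_, NA_real_)) # slope not distinguishable from 0
  bb <- -2 * b * (criterion - ybar)
  c0 <- (criterion - ybar)^2 - tcrit^2 * sigma2 / n
  disc <- bb^2 - 4 * aa * c0
  if (disc < 0) return(c(NA_real_, NA_real_))
  u <- sort((-bb + c(-1, 1) * sqrt(disc)) / (2 * aa))
  10^(xbar + u)
}

#' Group threshold by the graphical (0/1 regression) method
#'
#' Codes each triangle outcome 0 (incorrect) / 1 (correct), fits an
#' ordinary least-squares line to the individual codes against log10
#' concentration, and inverts the line at a chance-adjusted criterion
#' (default 2/3, see [criterion_for()]); the antilog of the crossing is
#' the group threshold. Confidence bounds come from inverse prediction:
#' the two concentrations where the pointwise confidence band for the
#' regression mean crosses the criterion (equivalently, Fieller's
#' interval for the crossing).
#'
#' A non-positive slope — the signature of an anosmic group, whose
#' performance hovers at chance across the ladder — yields a fit with the
#' threshold and bounds marked undefined (with a warning), not an error.
#' Crossings beyond one ladder step outside the tested range are likewise
#' undefined; crossings outside the tested range but within that guard are
#' reported with an `extrapolated` status.
#'
#' @param data A discrimination dataset (see [as_discrimination_data()]).
#' @param include Optional character vector of panelist ids to restrict
#'   the fit to (e.g. the responders identified by [estimate_bets()]).
#' @param criterion Proportion-correct criterion, strictly between
#'   `chance` and 1.
#' @param chance Guessing rate of the task (1/3 for the triangle test).
#' @param conf_level Confidence level for the inverse-prediction bounds.
#' @return An object of class `graphical_fit` with fields `slope`,
#'   `intercept`, `criterion`, `threshold` (ng/L or `NA`),
#'   `threshold_status`, `ci_lower`, `ci_upper`, `n_points`,
#'   `n_panelists`, `confidence_level`, `series`, and the per-level
#'   proportions used for plotting.
#' @export
fit_graphical <- function(data, include = NULL, criterion = 2 / 3,
                          chance = 1 / 3, conf_level = 0.95) {
  data <- as_discrimination_data(data, series = attr(data, "series"))
  if (!is.null(include)) {
    data <- filter(data, .data$panelist %in% include)
    attr(data, "series") <- NULL
  }
  if (nrow(data) == 0) stop_insufficient("no panelists selected for the fit")
  series <- series_from_data(data)
  if (length(unique(data$concentration)) < 2) {
    stop_insufficient("need at least 2 distinct concentration levels")
  }
  if (criterion <= chance || criterion >= 1) {
    stop_domain("`criterion` must lie strictly between `chance` and 1")
  }
  ols <- binary_ols(data$concentration, as.numeric(data$correct))
  cross <- guarded_crossing(ols$intercept, ols$slope, criterion, series, "up")
  ci <- c(NA_real_, NA_real_)
  if (cross$status %in% c("defined", "extrapolated")) {
    ci <- inverse_prediction_ci(ols, criterion, conf_level)
  } else {
    warn(paste0("graphical threshold undefined (", cross$status,
                "); group may be at chance across the ladder"),
         class = "threshpanel_undefined_threshold")
  }
  props <- data |>
    summarise(p_correct = mean(.data$correct), n = dplyr::n(),
              .by = "concentration") |>
    arrange(.data$concentration)
  structure(
    list(
      slope = ols$slope, intercept = ols$intercept,
      criterion = criterion, chance = chance,
      threshold = cross$threshold, threshold_status = cross$status,
      ci_lower = ci[1], ci_upper = ci[2],
      n_points = ols$n_points,
      n_panelists = length(unique(data$panelist)),
      confidence_level = conf_level,
      series = series, level_proportions = props, model = ols$model
    ),
    class = "graphical_fit"
  )
}

#' Invert a fitted performance line at a criterion
#'
#' Pure algebraic inversion of a `graphical_fit` line:
#' `10^((criterion - intercept) / slope)`, with no range guard. Errors on
#' a non-positive slope, for which no crossing from below exists.
#'
#' @param fit A `graphical_fit`.
#' @param criterion Proportion-correct criterion.
#' @return A concentration in ng/L.
#' @export
invert_at <- function(fit, criterion = fit$criterion) {
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop_domain("threshold undefined: fitted slope is not positive")
  }
  10^((criterion - fit$intercept) / fit$slope)
}

#' @export
print.graphical_fit <- function(x, ...) {
  cat("<graphical_fit> ", x$n_points, " binary points from ", x$n_panelists,
      " panelists\n", sep = "")
  cat(sprintf("  line: p = %.4f %+.4f * log10(c);  criterion %.3f\n",
              x$intercept, x$slope, x$criterion))
  if (is.na(x$threshold)) {
    cat("  threshold: undefined (", x$threshold_status, ")\n", sep = "")
  } else {
    cat(sprintf("  threshold: %.3g ng/L (%s), %g%% bounds %.3g - %.3g ng/L\n",
                x$threshold, x$threshold_status, 100 * x$confidence_level,
                x$ci_lower, x$ci_upper))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_graphical
#' @param x A `graphical_fit`.
#' @param ... Unused.
#' @export
tidy.graphical_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_graphical
#' @export
glance.graphical_fit <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    threshold_status = x$threshold_status,
    ci_lower = x$ci_lower,
    ci_upper = x$ci_upper,
    criterion = x$criterion,
    slope = x$slope,
    intercept = x$intercept,
    n_points = x$n_points,
    n_panelists = x$n_panelists,
    confidence_level = x$confidence_level
  )
}
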