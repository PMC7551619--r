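#' Ascending concentration ladder
#'
#' A concentration series is the fixed ascending ladder of spike
#' concentrations presented to every panelist in a forced-choice
#' ascending-series study. Ladders need not be uniformly log-spaced: the
#' detection ladder used in threshold work is often a pure decade series
#' (e.g. 0.2, 2, 20, 200, 2000 ng/L) while rejection ladders mix step
#' ratios (e.g. 3.75, 7.5, 37.5, 75, 375, 750 ng/L).
#'
#' @param levels Numeric vector of concentrations in ng/L; strictly
#'   increasing after sorting is *not* applied — supply them ascending.
#' @return An object of class `concentration_series`: the numeric level
#'   vector with `step_ratio_low` and `step_ratio_high` attributes (the
#'   ratios between the two lowest and the two highest levels).
#' @examples
#' triangle_ladder <- concentration_series(c(0.2, 2, 20, 200, 2000))
#' extend_series(triangle_ladder, "above") # 20000
#' @export
concentration_series <- function(levels) {
  if (!is.numeric(levels) || length(levels) < 2) {
    stop_domain("a concentration series needs at least 2 numeric levels")
  }
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop_domain("concentration levels must be finite and > 0")
  }
  if (any(diff(levels) <= 0)) {
    stop_domain("concentration levels must be strictly increasing")
  }
  structure(
    as.numeric(levels),
    step_ratio_low = levels[2] / levels[1],
    step_ratio_high = levels[length(levels)] / levels[length(levels) - 1],
    class = "concentration_series"
  )
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series> ", paste(unclass(x), collapse = ", "),
      " ng/L (step ratios ", attr(x, "step_ratio_low"), " low / ",
      attr(x, "step_ratio_high"), " high)\n", sep = "")
  invisible(x)
}

#' Hypothetical next ladder level
#'
#' The ASTM-style decision rules refer to concentrations one step beyond
#' the tested ladder: the next hypothetical level below the lowest
#' concentration (for panelists correct at every level) and the next
#' theoretical level above the highest (for non-responder imputation).
#' The extension uses the *local* step ratio between the two adjacent
#' extreme levels, so non-uniform ladders extend consistently with their
#' own end spacing.
#'
#' @param series A [concentration_series()].
#' @param direction `"below"` or `"above"`.
#' @return A single concentration in ng/L.
#' @examples
#' s <- concentration_series(c(0.2, 2, 20, 200, 2000))
#' extend_series(s, "below") # 0.02
#' extend_series(s, "above") # 20000
#' @export
extend_series <- function(series, direction = c("below", "above")) {
  series <- as_concentration_series(series)
  direction <- match.arg(direction)
  lv <- unclass(series)
  if (direction == "below") {
    lv[1] / attr(series, "step_ratio_low")
  } else {
    lv[length(lv)] * attr(series, "step_ratio_high")
  }
}

as_concentration_series <- function(x) {
  if (inherits(x, "concentration_series")) x else concentration_series(x)
}

# ladder inferred from a long-format dataset: the sorted unique concentrations
series_from_data <- function(data) {
  concentration_series(sort(unique(data$concentration)))
}
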