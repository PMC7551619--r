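#' Per-panelist best estimate threshold (modified ASTM E679 rule)
#'
#' Applies the three-branch decision rule to one panelist's ordered
#' triangle outcomes on an ascending ladder:
#'
#' 1. **standard** — if the top-level answer is correct, find the lowest
#'    level `L` such that every answer at `L` and above is correct; the BET
#'    is the geometric mean of `L`'s concentration and the level below
#'    (the hypothetical level below the ladder when `L` is the lowest
#'    tested level, in which case the rule label is `lowest-extrapolated`).
#' 2. **adaptation** — otherwise, if the outcomes contain a run of at
#'    least three consecutive correct answers ending strictly below a
#'    later incorrect answer, the panelist is treated as sensitive but
#'    adapted at the higher levels (three correct in a row by chance has
#'    probability (1/3)^3 = 3.7%): the BET is the geometric mean of the
#'    run's starting concentration and the level below it. When several
#'    runs qualify, the run with the lowest starting concentration is used.
#' 3. **non-responder-imputed** — otherwise the panelist did not detect
#'    the compound at any usable level; the BET is imputed as the
#'    geometric mean of the top concentration and the next theoretical
#'    level above the ladder. Imputed BETs are flagged `responder = FALSE`
#'    and are used only for display, never in group statistics.
#'
#' @param outcomes Logical vector of triangle outcomes, ascending ladder
#'   order (`TRUE` = correct).
#' @param series The [concentration_series()] the outcomes align to.
#' @return A one-row tibble: `bet` (ng/L), `rule`, `responder`.
#' @examples
#' s <- concentration_series(c(0.2, 2, 20, 200, 2000))
#' classify_and_estimate(c(FALSE, FALSE, FALSE, TRUE, TRUE), s)
#' @export
classify_and_estimate <- function(outcomes, series) {
  series <- as_concentration_series(series)
  lv <- as.numeric(series)
  n <- length(lv)
  if (!is.logical(outcomes) || length(outcomes) != n || anyNA(outcomes)) {
    stop_integrity(paste0("outcomes must be a complete logical vector of length ",
                          n, " (one entry per ladder level)"))
  }
  below <- c(extend_series(series, "below"), lv[-n])

  if (outcomes[n]) {
    L <- n
    while (L > 1 && outcomes[L - 1]) L <- L - 1
    return(tibble(
      bet = geomean(c(lv[L], below[L])),
      rule = if (L == 1) "lowest-extrapolated" else "standard",
      responder = TRUE
    ))
  }

  runs <- rle(outcomes)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # top answer is wrong here, so any correct run of >=3 ends strictly below
  # a later incorrect answer
  qual <- which(runs$values & runs$lengths >= 3)
  if (length(qual) > 0) {
    s <- starts[qual[1]] # lowest starting concentration among qualifying runs
    return(tibble(
      bet = geomean(c(lv[s], below[s])),
      rule = "adaptation",
      responder = TRUE
    ))
  }

  tibble(
    bet = geomean(c(lv[n], extend_series(series, "above"))),
    rule = "non-responder-imputed",
    responder = FALSE
  )
}

#' Best estimate thresholds for a whole panel
#'
#' Maps [classify_and_estimate()] over every panelist in a validated
#' discrimination dataset.
#'
#' @param data A discrimination dataset (see [as_discrimination_data()]).
#' @return A tibble with one row per panelist: `panelist`, `condition`
#'   (if present in the data), `bet`, `rule`, `responder`.
#' @export
estimate_bets <- function(data) {
  data <- as_discrimination_data(data, series = attr(data, "series"))
  series <- dataset_series(data)
  keys <- intersect(c("panelist", "condition"), names(data))
  data |>
    arrange(.data$panelist, .data$concentration) |>
    summarise(classify_and_estimate(.data$correct, series),
              .by = dplyr::all_of(keys))
}

#' Group threshold summary over a set of BETs
#'
#' The group threshold is the geometric mean of the responder BETs
#' (antilog of the arithmetic mean of their base-10 logs). Panelists with
#' an imputed non-responder BET count toward the anosmic tally and are
#' excluded from every numeric summary; with zero responders the
#' geometric mean and log-SD are reported as `NA` rather than an error.
#'
#' @param bets A tibble of BET rows as returned by [estimate_bets()].
#' @return One-row tibble: `n_total`, `n_responders`, `n_anosmic`,
#'   `responder_fraction`, `geometric_mean_bet` (ng/L), `sd_log_bet`
#'   (SD of log10 BET).
#' @export
summarize_bets <- function(bets) {
  if (nrow(bets) == 0) stop_insufficient("no BETs to summarise")
  resp <- bets$bet[bets$responder]
  tibble(
    n_total = nrow(bets),
    n_responders = length(resp),
    n_anosmic = nrow(bets) - length(resp),
    responder_fraction = length(resp) / nrow(bets),
    geometric_mean_bet = if (length(resp) > 0) geomean(resp) else NA_real_,
    sd_log_bet = if (length(resp) > 1) sd(log10(resp)) else NA_real_
  )
}

#' Compare two conditions on logged BETs
#'
#' Unpaired pooled-variance (Student) t-test on the base-10 logs of the
#' responder BETs of two groups, e.g. orthonasal vs retronasal delivery.
#' Imputed non-responder BETs are excluded before testing.
#'
#' @param bets_a,bets_b BET tibbles from [estimate_bets()].
#' @return One-row tibble: `t_statistic`, `df` (`n_a + n_b - 2`),
#'   `p_value` (two-sided), `n_a`, `n_b`, and the two group geometric
#'   means `geomean_a`, `geomean_b` (ng/L).
#' @export
compare_log_bets <- function(bets_a, bets_b) {
  la <- log10(bets_a$bet[bets_a$responder])
  lb <- log10(bets_b$bet[bets_b$responder])
  if (length(la) < 2 || length(lb) < 2) {
    stop_insufficient("need at least 2 responders in each group")
  }
  ht <- t.test(la, lb, var.equal = TRUE)
  tibble(
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_a = length(la),
    n_b = length(lb),
    geomean_a = 10^mean(la),
    geomean_b = 10^mean(lb)
  )
}

#' Chance probability of a correct run
#'
#' Probability that a guessing panelist produces `k` consecutive correct
#' forced-choice answers purely by chance — the argument behind treating
#' a run of three correct triangle answers (chance (1/3)^3 = 3.7%)
#' as evidence of sensitivity in the adaptation branch.
#'
#' @param chance Per-trial guessing probability (1/3 triangle, 1/2 2AFC).
#' @param k Run length.
#' @return A probability.
#' @export
chance_run_probability <- function(chance, k) {
  if (chance <= 0 || chance >= 1) stop_domain("`chance` must be in (0, 1)")
  if (k < 1) stop_domain("`k` must be >= 1")
  chance^k
}
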