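#' Simulation configuration for a synthetic sensory panel
#'
#' Describes the population and task model used to generate synthetic
#' panels with the structure threshold analyses assume: a point mass of
#' panelists with a specific anosmia for the compound, log-normally
#' distributed individual thresholds among the rest, a logistic detection
#' function on log10 concentration, one-step adaptation carryover, and a
#' preference split among detectors.
#'
#' Defaults mirror a single-visit wine-spiking threshold study: a panel
#' of 56, a five-level decade ladder 0.2--2000 ng/L, roughly 40% of the
#' sample anosmic, a median responder threshold of 50 ng/L with
#' individual thresholds spread over about one decade either side
#' (`threshold_log_sd = 1`), and a minority (~25%) of detectors who
#' prefer the spiked sample.
#'
#' @param n_panelists Panel size.
#' @param series [concentration_series()] ladder presented to everyone.
#' @param anosmic_fraction Probability a panelist cannot detect the
#'   compound at any concentration.
#' @param threshold_median Median individual detection threshold (ng/L)
#'   among non-anosmic panelists.
#' @param threshold_log_sd SD of log10 individual thresholds.
#' @param psychometric_slope Logistic slope on the log10 scale
#'   (inverse width of the individual detection function).
#' @param adaptation_carryover Multiplier in \[0, 1\] applied to the
#'   detection probability at a level when the panelist detected the
#'   compound at the immediately preceding level; 1 disables adaptation.
#' @param preferer_fraction Probability a non-anosmic panelist prefers
#'   the spiked sample once they detect it.
#' @param chance_level Guessing rate of the discrimination task (1/3 for
#'   the triangle test).
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical datasets.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_panelists = 56,
                             series = concentration_series(c(0.2, 2, 20, 200, 2000)),
                             anosmic_fraction = 0.4,
                             threshold_median = 50,
                             threshold_log_sd = 1,
                             psychometric_slope = 3,
                             adaptation_carryover = 0.85,
                             preferer_fraction = 0.25,
                             chance_level = 1 / 3,
                             seed = 1L) {
  probs <- c(anosmic_fraction = anosmic_fraction,
             preferer_fraction = preferer_fraction,
             chance_level = chance_level,
             adaptation_carryover = adaptation_carryover)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop_domain(paste0("probability parameter(s) outside [0, 1]: ",
                       paste(names(probs)[bad], collapse = ", ")))
  }
  if (n_panelists < 1) stop_domain("`n_panelists` must be >= 1")
  if (threshold_median <= 0) stop_domain("`threshold_median` must be > 0")
  if (psychometric_slope <= 0) stop_domain("`psychometric_slope` must be > 0")
  structure(
    list(
      n_panelists = as.integer(n_panelists),
      series = as_concentration_series(series),
      anosmic_fraction = anosmic_fraction,
      threshold_median = threshold_median,
      threshold_log_sd = threshold_log_sd,
      psychometric_slope = psychometric_slope,
      adaptation_carryover = adaptation_carryover,
      preferer_fraction = preferer_fraction,
      chance_level = chance_level,
      seed = as.integer(seed)
    ),
    class = "panel_sim_config"
  )
}

#' Draw subject-level latent profiles
#'
#' Samples the latent state of each panelist: anosmic or not, the log10
#' individual detection threshold (normal around
#' `log10(threshold_median)` with SD `threshold_log_sd`), and the
#' preference direction (+1 spike-liker / -1 spike-rejecter). Anosmic
#' subjects carry neither a threshold nor a preference direction.
#'
#' @param config A [panel_sim_config()].
#' @return A tibble with one row per panelist: `panelist`, `anosmic`,
#'   `log10_threshold`, `preference_direction`.
#' @export
draw_subjects <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  n <- config$n_panelists
  withr::with_seed(config$seed, {
    anosmic <- runif(n) < config$anosmic_fraction
    thr <- rnorm(n, mean = log10(config$threshold_median),
                 sd = config$threshold_log_sd)
    dir <- ifelse(runif(n) < config$preferer_fraction, 1L, -1L)
  })
  tibble(
    panelist = sprintf("S%04d", seq_len(n)),
    anosmic = anosmic,
    log10_threshold = ifelse(anosmic, NA_real_, thr),
    preference_direction = ifelse(anosmic, NA_integer_, dir)
  )
}

# n_subjects x n_levels matrix of true detection probabilities (0 for anosmic)
det_prob_matrix <- function(subjects, levels, config) {
  x <- log10(levels)
  p <- plogis(config$psychometric_slope *
                outer(-subjects$log10_threshold, x, `+`))
  p[is.na(p)] <- 0 # anosmic: no detection at any concentration
  p
}

#' True detection probability of a subject at a concentration
#'
#' The generating psychometric model: anosmic subjects never detect;
#' sighted subjects detect with probability
#' `plogis(psychometric_slope * (log10(c) - log10_threshold))`, i.e. 0.5
#' exactly at their threshold, increasing in concentration.
#'
#' @param subjects Tibble from [draw_subjects()] (any subset of rows).
#' @param concentration Vector of concentrations (ng/L), all > 0.
#' @param config The [panel_sim_config()].
#' @return A tibble: `panelist`, `concentration`, `p_detect`.
#' @export
detection_probability <- function(subjects, concentration, config) {
  if (any(concentration <= 0)) stop_domain("concentrations must be > 0")
  p <- det_prob_matrix(subjects, concentration, config)
  tidyr::expand_grid(panelist = subjects$panelist,
                     concentration = as.numeric(concentration)) |>
    mutate(p_detect = as.vector(t(p)))
}

#' Simulate an ascending triangle-test session
#'
#' Walks each subject up the ladder. At each level the subject truly
#' detects the spike with their detection probability — attenuated by
#' `adaptation_carryover` if they detected at the immediately preceding
#' level — and a true detection always yields a correct triangle answer;
#' otherwise they guess and are correct with probability `chance_level`.
#' This is a pure high-threshold model: guessing carries no partial
#' information, matching the chance-correction arithmetic of the
#' downstream analyses.
#'
#' @param subjects Tibble from [draw_subjects()].
#' @param config The [panel_sim_config()].
#' @param condition Condition label stored in the dataset.
#' @return A validated discrimination dataset.
#' @export
simulate_triangle <- function(subjects, config, condition = "simulated") {
  stopifnot(inherits(config, "panel_sim_config"))
  lv <- as.numeric(config$series)
  n <- nrow(subjects)
  m <- length(lv)
  p <- det_prob_matrix(subjects, lv, config)
  correct <- matrix(NA, n, m)
  withr::with_seed(config$seed + 1L, {
    prev_detected <- rep(FALSE, n)
    for (j in seq_len(m)) {
      pj <- p[, j]
      pj[prev_detected] <- pj[prev_detected] * config$adaptation_carryover
      detected <- runif(n) < pj
      correct[, j] <- detected | (runif(n) < config$chance_level)
      prev_detected <- detected
    }
  })
  out <- tidyr::expand_grid(panelist = subjects$panelist, concentration = lv) |>
    mutate(condition = condition, correct = as.vector(t(correct))) |>
    select("panelist", "condition", "concentration", "correct")
  as_discrimination_data(out, series = config$series)
}

#' Simulate an ascending paired-preference (2AFC) session
#'
#' At each level the probability of choosing the spiked sample is
#' `1/2 + preference_direction * (1/2) * p_detect`: anosmic and
#' non-detecting subjects choose at chance (1/2); detecting subjects are
#' pulled toward the spike (+1) or the blank (-1) in proportion to how
#' reliably they detect it. Preference strength is tied directly to
#' detectability — polarisation emerges as soon as the compound is
#' perceptible.
#'
#' @inheritParams simulate_triangle
#' @return A validated preference dataset.
#' @export
simulate_preference <- function(subjects, config) {
  stopifnot(inherits(config, "panel_sim_config"))
  lv <- as.numeric(config$series)
  n <- nrow(subjects)
  m <- length(lv)
  p <- det_prob_matrix(subjects, lv, config)
  dir <- ifelse(is.na(subjects$preference_direction), 0L,
                subjects$preference_direction)
  p_spike <- 0.5 + dir * 0.5 * p
  withr::with_seed(config$seed + 2L, {
    spike <- matrix(runif(n * m), n, m) < p_spike
  })
  out <- tidyr::expand_grid(panelist = subjects$panelist, concentration = lv) |>
    mutate(choice = ifelse(as.vector(t(spike)), "spike", "blank")) |>
    select("panelist", "concentration", "choice")
  as_preference_data(out, series = config$series)
}

#' Concentration where the generating group psychometric function
#' crosses a criterion
#'
#' For the subjects supplied, the group proportion-correct curve under
#' the generating model is
#' `chance + (1 - chance) * mean(p_detect)`; this returns the
#' concentration where it crosses `criterion` (solved numerically), or
#' `NA` if the curve never reaches it — e.g. when anosmic subjects cap
#' the asymptote below the criterion. Used as the ground truth in
#' parameter-recovery checks of the graphical estimator.
#'
#' @param subjects Tibble of subject profiles (filter to the subset whose
#'   group curve you mean, e.g. responders only).
#' @param config The [panel_sim_config()].
#' @param chance Guessing rate; defaults to the config's `chance_level`.
#' @param criterion Target proportion correct; defaults to
#'   [criterion_for()] of `chance`.
#' @return A concentration in ng/L, or `NA_real_`.
#' @export
theoretical_group_threshold <- function(subjects, config,
                                        chance = config$chance_level,
                                        criterion = criterion_for(chance)) {
  f <- function(x) {
    pd <- plogis(config$psychometric_slope * (x - subjects$log10_threshold))
    pd[is.na(pd)] <- 0
    chance + (1 - chance) * mean(pd) - criterion
  }
  thr <- subjects$log10_threshold[!is.na(subjects$log10_threshold)]
  if (length(thr) == 0) return(NA_real_)
  lo <- min(thr) - 50 / config$psychometric_slope
  hi <- max(thr) + 50 / config$psychometric_slope
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  10^uniroot(f, c(lo, hi), tol = 1e-10)$root
}
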