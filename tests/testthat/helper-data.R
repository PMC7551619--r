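# In-code fixture builders shared across test files.

triangle_ladder <- function() concentration_series(c(0.2, 2, 20, 200, 2000))
rejection_ladder <- function() concentration_series(c(3.75, 7.5, 37.5, 75, 375, 750))

# Discrimination dataset from a named list of outcome patterns, e.g.
# make_tri(list(P1 = c(F,F,F,T,T)), triangle_ladder())
make_tri <- function(patterns, series, condition = "orthonasal") {
  lv <- as.numeric(series)
  rows <- purrr::imap(patterns, function(o, id) {
    tibble::tibble(panelist = id, condition = condition,
                   concentration = lv, correct = as.logical(o))
  })
  as_discrimination_data(dplyr::bind_rows(rows), series = series)
}

# Preference dataset from a named list of choice vectors ("s"/"b" shorthand).
make_pref <- function(patterns, series) {
  lv <- as.numeric(series)
  rows <- purrr::imap(patterns, function(ch, id) {
    ch <- ifelse(ch %in% c("s", "spike"), "spike", "blank")
    tibble::tibble(panelist = id, concentration = lv, choice = ch)
  })
  as_preference_data(dplyr::bind_rows(rows), series = series)
}

# BET tibble with a given number of responders / imputed non-responders.
make_bets <- function(responder_bets, n_imputed, imputed_value = sqrt(2000 * 20000)) {
  tibble::tibble(
    panelist = sprintf("P%03d", seq_len(length(responder_bets) + n_imputed)),
    bet = c(responder_bets, rep(imputed_value, n_imputed)),
    rule = c(rep("standard", length(responder_bets)),
             rep("non-responder-imputed", n_imputed)),
    responder = rep(c(TRUE, FALSE), c(length(responder_bets), n_imputed))
  )
}

# Preference panel with exact per-level spike counts, panelists nested so
# that panelist i chooses spike at level j iff i <= count[j].
pref_from_counts <- function(counts, n_panelists, series) {
  lv <- as.numeric(series)
  stopifnot(length(counts) == length(lv), all(counts <= n_panelists))
  rows <- purrr::map(seq_len(n_panelists), function(i) {
    tibble::tibble(panelist = sprintf("P%03d", i), concentration = lv,
                   choice = ifelse(i <= counts, "spike", "blank"))
  })
  as_preference_data(dplyr::bind_rows(rows), series = series)
}
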