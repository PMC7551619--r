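test_that("consistency status follows the top-three choices exactly", {
  s <- rejection_ladder()
  data <- make_pref(list(
    pref = c("b", "s", "b", "s", "s", "s"),   # top-3 all spike
    rej  = c("s", "s", "s", "b", "b", "b"),   # top-3 all blank
    non  = c("b", "b", "b", "s", "b", "s")    # mixed top-3
  ), s)
  cls <- classify_consistency(data)
  expect_equal(cls$status[cls$panelist == "pref"], "consistent-preferer")
  expect_equal(cls$status[cls$panelist == "rej"], "consistent-rejecter")
  expect_equal(cls$status[cls$panelist == "non"], "non-responder")
  expect_equal(cls$top_choices[cls$panelist == "non"], "spike,blank,spike")
  expect_error(classify_consistency(data, k_top = 0),
               class = "threshpanel_domain_error")
  expect_error(classify_consistency(data, k_top = 7),
               class = "threshpanel_domain_error")
})

test_that("chance consistency probability is (1/2)^k per direction", {
  expect_equal(chance_consistency_probability(3, "one-sided"), 0.125)
  expect_equal(chance_consistency_probability(3, "either"), 0.25)
  expect_equal(chance_consistency_probability(1, "one-sided"), 0.5)
  expect_error(chance_consistency_probability(0), class = "threshpanel_domain_error")
})

test_that("rejection fit matches the closed-form OLS oracle", {
  s <- rejection_ladder()
  # per-level spike proportions exactly (0.5, 0.5, 0.45, 0.3, 0.15, 0.1),
  # 20 panelists; gate on the single top level so every panelist is
  # consistent and the fitted segment keeps these exact proportions
  data <- pref_from_counts(c(10, 10, 9, 6, 3, 2), 20, s)
  fit <- fit_rejection(data, segment = "all-consistent", k_top = 1)
  expect_equal(fit$n_included, 20)
  props <- rep(c(0.5, 0.5, 0.45, 0.3, 0.15, 0.1), times = 20)
  want <- oracle_ols(rep(log10(as.numeric(s)), times = 20),
                     as.numeric(as_tibble(data) |>
                                  dplyr::arrange(panelist, concentration) |>
                                  dplyr::pull(choice) == "spike"))
  expect_lt(fit$slope, 0)
  expect_equal(fit$slope, want$slope)
  expect_equal(fit$rejection_threshold,
               10^((0.25 - want$intercept) / want$slope))
  expect_equal(fit$rejection_status, "defined")
  expect_true(is.na(fit$preference_threshold))
})

test_that("degenerate segments leave both thresholds undefined", {
  s <- rejection_ladder()
  always_spike <- make_pref(setNames(
    purrr::map(1:4, ~ rep("s", 6)), paste0("P", 1:4)), s)
  fit <- fit_rejection(always_spike)
  expect_true(is.na(fit$rejection_threshold))
  expect_true(is.na(fit$preference_threshold)) # constant 1 never crosses 0.75

  # exact indifference: half choose spike at every level (gate on top level)
  indiff <- pref_from_counts(rep(5, 6), 10, s)
  fit2 <- fit_rejection(indiff, k_top = 1)
  expect_equal(fit2$slope, 0)
  expect_true(is.na(fit2$rejection_threshold))
  expect_true(is.na(fit2$preference_threshold))

  only_non <- make_pref(list(A = c("s", "b", "s", "b", "s", "b"),
                             B = c("b", "s", "b", "s", "b", "s")), s)
  expect_error(fit_rejection(only_non),
               class = "threshpanel_insufficient_data_error")
})

test_that("relabelling spike and blank mirrors the fit and swaps thresholds", {
  s <- rejection_ladder()
  set.seed(37)
  pats <- purrr::map(1:30, function(i) {
    dir <- sample(c("s", "b"), 1)
    low <- sample(c("s", "b"), 3, replace = TRUE)
    c(low, rep(dir, 3))
  })
  names(pats) <- paste0("P", 1:30)
  data <- make_pref(pats, s)
  flipped <- as_tibble(data) |>
    dplyr::mutate(choice = ifelse(choice == "spike", "blank", "spike")) |>
    as_preference_data(series = s)
  f1 <- fit_rejection(data)
  f2 <- fit_rejection(flipped)
  expect_equal(f2$slope, -f1$slope)
  expect_equal(f2$intercept, 1 - f1$intercept)
  expect_equal(f2$rejection_threshold, f1$preference_threshold)
  expect_equal(f2$preference_threshold, f1$rejection_threshold)
  expect_equal(f2$rejection_status, f1$preference_status)
})

test_that("segment report recovers constructed counts and fit ordering", {
  s <- rejection_ladder()
  set.seed(43)
  mk <- function(n, top, prefix) {
    pats <- purrr::map(seq_len(n), ~ c(sample(c("s", "b"), 3, replace = TRUE), top))
    names(pats) <- paste0(prefix, seq_len(n))
    pats
  }
  mixed_top <- purrr::map(1:52, ~ {
    t3 <- sample(c("s", "b"), 3, replace = TRUE)
    while (length(unique(t3)) == 1) t3 <- sample(c("s", "b"), 3, replace = TRUE)
    c(sample(c("s", "b"), 3, replace = TRUE), t3)
  })
  names(mixed_top) <- paste0("N", 1:52)
  data <- make_pref(c(mk(8, rep("s", 3), "L"), mk(26, rep("b", 3), "R"),
                      mixed_top), s)
  rep <- suppressWarnings(segment_report(data)) # rejecter line exits [0,1] at the top
  expect_equal(rep$counts$n_total, 86)
  expect_equal(rep$counts$n_preferers, 8)
  expect_equal(rep$counts$n_rejecters, 26)
  expect_equal(rep$counts$n_non_responders, 52)

  # rejecters dominate the consistent pool, so the pooled line slopes down
  expect_lt(rep$fit_all$slope, 0)
  # preferers pull the pooled crossing upward
  expect_lt(rep$fit_rejecters$rejection_threshold,
            rep$fit_all$rejection_threshold)
  # 8 preferers are below the descriptive-only cutoff: no fit, proportions only
  expect_null(rep$fit_preferers)
  expect_equal(nrow(rep$preferer_proportions), 6)
  expect_equal(rep$preferer_proportions$p_spike[4:6], rep(1, 3))
})
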