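test_that("config validation rejects out-of-range parameters", {
  expect_error(panel_sim_config(anosmic_fraction = 1.2),
               class = "threshpanel_domain_error")
  expect_error(panel_sim_config(threshold_median = -5),
               class = "threshpanel_domain_error")
  expect_error(panel_sim_config(psychometric_slope = 0),
               class = "threshpanel_domain_error")
})

test_that("identical config and seed reproduce identical datasets", {
  cfg <- panel_sim_config(n_panelists = 40, seed = 99)
  s1 <- draw_subjects(cfg)
  s2 <- draw_subjects(cfg)
  expect_identical(s1, s2)
  expect_identical(as.data.frame(simulate_triangle(s1, cfg)),
                   as.data.frame(simulate_triangle(s2, cfg)))
  expect_identical(as.data.frame(simulate_preference(s1, cfg)),
                   as.data.frame(simulate_preference(s2, cfg)))
  cfg2 <- panel_sim_config(n_panelists = 40, seed = 100)
  expect_false(identical(as.data.frame(simulate_triangle(draw_subjects(cfg2), cfg2)),
                         as.data.frame(simulate_triangle(s1, cfg))))
})

test_that("subject draws respect the population mixture", {
  cfg <- panel_sim_config(n_panelists = 10000, anosmic_fraction = 0.4, seed = 5)
  sub <- draw_subjects(cfg)
  tol3 <- 3 * sqrt(10000 * 0.4 * 0.6)
  expect_lt(abs(sum(sub$anosmic) - 4000), tol3)
  expect_true(all(is.na(sub$log10_threshold[sub$anosmic])))
  expect_true(all(is.na(sub$preference_direction[sub$anosmic])))
  expect_true(all(!is.na(sub$log10_threshold[!sub$anosmic])))

  all_anosmic <- draw_subjects(panel_sim_config(n_panelists = 50,
                                                anosmic_fraction = 1, seed = 6))
  expect_true(all(all_anosmic$anosmic))

  fixed <- draw_subjects(panel_sim_config(n_panelists = 50,
                                          anosmic_fraction = 0,
                                          threshold_median = 100,
                                          threshold_log_sd = 0, seed = 6))
  expect_equal(fixed$log10_threshold, rep(2, 50))
})

test_that("detection probability is 0 for anosmics, 0.5 at threshold, increasing", {
  cfg <- panel_sim_config(n_panelists = 4, anosmic_fraction = 0, seed = 8)
  sub <- draw_subjects(cfg)
  sub$anosmic[1] <- TRUE
  sub$log10_threshold[1] <- NA
  p <- detection_probability(sub, c(0.2, 2, 20, 200, 2000), cfg)
  expect_true(all(p$p_detect[p$panelist == sub$panelist[1]] == 0))
  at_thr <- detection_probability(sub[2, ], 10^sub$log10_threshold[2], cfg)
  expect_equal(at_thr$p_detect, 0.5)
  ten_x <- detection_probability(sub[2, ], 10^(sub$log10_threshold[2] + 1), cfg)
  expect_gt(ten_x$p_detect, 0.5)
  expect_error(detection_probability(sub, c(-1, 2), cfg),
               class = "threshpanel_domain_error")
})

test_that("anosmic panels answer the triangle at chance and prefer at one half", {
  cfg <- panel_sim_config(n_panelists = 10000, anosmic_fraction = 1, seed = 9)
  sub <- draw_subjects(cfg)
  tri <- simulate_triangle(sub, cfg)
  p_hat <- mean(tri$correct)
  expect_lt(abs(p_hat - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / nrow(tri)))
  pref <- simulate_preference(sub, cfg)
  expect_lt(abs(mean(pref$choice == "spike") - 0.5),
            3 * sqrt(0.25 / nrow(pref)))
})

test_that("a very sensitive subject with no adaptation answers all-correct", {
  cfg <- panel_sim_config(n_panelists = 3, anosmic_fraction = 0,
                          threshold_median = 1e-4, threshold_log_sd = 0,
                          psychometric_slope = 10, adaptation_carryover = 1,
                          seed = 10)
  tri <- simulate_triangle(draw_subjects(cfg), cfg)
  expect_true(all(tri$correct))
})

test_that("polarised detectors saturate their preference in the right direction", {
  cfg <- panel_sim_config(n_panelists = 400, anosmic_fraction = 0,
                          threshold_median = 1, threshold_log_sd = 0,
                          psychometric_slope = 10, preferer_fraction = 0.5,
                          series = concentration_series(c(1, 10, 100, 1000)),
                          seed = 11)
  sub <- draw_subjects(cfg)
  pref <- simulate_preference(sub, cfg)
  top <- dplyr::filter(as_tibble(pref), concentration == 1000) |>
    dplyr::left_join(sub, by = "panelist")
  expect_true(all(top$choice[top$preference_direction == 1] == "spike"))
  expect_true(all(top$choice[top$preference_direction == -1] == "blank"))
})

test_that("full adaptation carryover loss raises adaptation-branch classifications", {
  mk <- function(carry) {
    cfg <- panel_sim_config(n_panelists = 2000, anosmic_fraction = 0,
                            threshold_median = 20, threshold_log_sd = 0.3,
                            psychometric_slope = 6,
                            adaptation_carryover = carry, seed = 12)
    bets <- estimate_bets(simulate_triangle(draw_subjects(cfg), cfg))
    mean(bets$rule == "adaptation")
  }
  expect_gt(mk(0), mk(1))
})

test_that("Monte Carlo responder classification matches the enumeration oracle", {
  # under pure guessing, classification as a responder happens with the
  # exact probability obtained by enumerating all outcome patterns
  cfg <- panel_sim_config(n_panelists = 10000, anosmic_fraction = 1, seed = 13)
  bets <- estimate_bets(simulate_triangle(draw_subjects(cfg), cfg))
  want <- oracle_guesser_responder_rate(5, 1 / 3)
  expect_lt(abs(mean(bets$responder) - want),
            3 * sqrt(want * (1 - want) / 10000))
})

test_that("theoretical group threshold solves the chance-corrected crossing", {
  cfg <- panel_sim_config(n_panelists = 30, anosmic_fraction = 0,
                          threshold_median = 100, threshold_log_sd = 0, seed = 14)
  sub <- draw_subjects(cfg)
  # degenerate spread: the population curve crosses the criterion exactly at
  # the median threshold
  expect_equal(theoretical_group_threshold(sub, cfg), 100, tolerance = 1e-6)
  # with anosmics capping the asymptote below the criterion there is no crossing
  cfg2 <- panel_sim_config(n_panelists = 100, anosmic_fraction = 0.8, seed = 15)
  sub2 <- draw_subjects(cfg2)
  expect_true(is.na(theoretical_group_threshold(sub2, cfg2)))
})
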