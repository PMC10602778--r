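test_that("configuration invariants are enforced", {
  expect_error(cohort_config(funnel_targets = c(100, 120, 72, 66)),
               "non-increasing")
  expect_error(cohort_config(n_enrolled = 100,
                             funnel_targets = c(371, 100, 72, 66)),
               "n_enrolled")
  expect_error(cohort_config(p_male = 1.2), "fractions")
  expect_error(small_config(missingness_rates = c(swn = 1.5)), "missingness")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- small_config(n = 40, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  fa <- inject_missingness(apply_attrition_funnel(a, cfg), cfg)
  fb <- inject_missingness(apply_attrition_funnel(b, cfg), cfg)
  expect_identical(fa, fb)
})

test_that("attrition funnel hits every stage target exactly", {
  for (seed in c(1, 2)) {
    cfg <- small_config(n = 80, seed = seed,
                        funnel_targets = c(70, 50, 33, 30))
    co <- apply_attrition_funnel(generate_cohort(cfg), cfg)
    expect_equal(sum(co$completed_phase1), 70)
    expect_equal(sum(co$continued_phase2), 50)
    expect_equal(sum(co$completed_phase2), 33)
    expect_equal(sum(co$completed_phase2 & co$panss_complete), 30)
    # flag consistency: phase-2 completion implies the earlier stages
    expect_true(all(!co$completed_phase2 | co$continued_phase2))
    expect_true(all(!co$continued_phase2 | co$completed_phase1))
  }
})

test_that("degenerate funnel (all targets = n) leaves everyone in", {
  cfg <- small_config(n = 30, seed = 5, funnel_targets = c(30, 30, 30, 30))
  co <- apply_attrition_funnel(generate_cohort(cfg), cfg)
  expect_true(all(co$completed_phase2 & co$panss_complete))
  expect_false(anyNA(co[, paste0(c("panss_p1", "psp_1"), "_v6")]))
})

test_that("funnel target larger than the cohort errors", {
  cfg <- small_config(n = 50, seed = 1, funnel_targets = c(45, 40, 30, 25))
  co <- generate_cohort(cfg)
  expect_error(apply_attrition_funnel(co[1:20, ], cfg), "exceeds")
})

test_that("dropouts lose the visits they never attended", {
  cfg <- small_config(n = 80, seed = 3, funnel_targets = c(60, 40, 25, 22))
  co <- apply_attrition_funnel(generate_cohort(cfg), cfg)
  p1_only <- co$completed_phase1 & !co$continued_phase2
  expect_true(all(is.na(co[p1_only, "panss_p1_v6"])))
  expect_false(anyNA(co[p1_only, "panss_p1_v4"]))
  never <- !co$completed_phase1
  expect_true(all(is.na(co[never, "panss_p1_v3"])))
  expect_false(anyNA(co[never, "panss_p1_v1"]))
})

test_that("zero-coefficient symmetric propensity gives ~50% remission", {
  cfg <- cohort_config(n_enrolled = 10000,
                       funnel_targets = c(371, 100, 72, 66),
                       beta = rep(0, 48), beta0 = 0, gamma = 0, seed = 21)
  co <- generate_cohort(cfg)
  # 3 binomial SDs at n = 10,000
  expect_lt(abs(mean(co$remission_sr) - 0.5), 3 * 0.5 / 100)
})

test_that("a planted depression effect depresses remission by the oracle gap", {
  # frozen oracle: E plogis(-0.2 -/+ 2 + eps), eps ~ N(0, 0.5), by quadrature
  p_yes_oracle <- 0.108661
  p_no_oracle <- 0.847584
  beta <- rep(0, 48); beta[1] <- -2
  cfg <- cohort_config(n_enrolled = 5000,
                       funnel_targets = c(371, 100, 72, 66),
                       beta = beta, gamma = 0, seed = 13)
  co <- generate_cohort(cfg)
  dep <- co[[mini_item_names()[1]]] == 1
  p_yes <- mean(co$remission_sr[dep])
  p_no <- mean(co$remission_sr[!dep])
  expect_lt(p_yes, p_no)
  # ~250 carriers at 5% prevalence: allow 3 SDs of the smaller subgroup
  expect_lt(abs(p_yes - p_yes_oracle), 3 * sqrt(0.11 * 0.89 / 200))
  expect_lt(abs(p_no - p_no_oracle), 3 * sqrt(0.15 * 0.85 / 4000))
})

test_that("planted-effect direction holds across seeds and signs", {
  for (s in 1:5) {
    beta <- rep(0, 48)
    sign <- if (s %% 2 == 0) 1 else -1
    beta[7] <- 1.5 * sign
    cfg <- cohort_config(n_enrolled = 2000,
                         funnel_targets = c(371, 100, 72, 66),
                         beta = beta, gamma = 0, seed = 60 + s)
    co <- generate_cohort(cfg)
    x <- co[[mini_item_names()[7]]] == 1
    gap <- mean(co$remission_sr[x]) - mean(co$remission_sr[!x])
    expect_true(sign * gap > 0)
  }
})

test_that("generated marginals match configuration at n = 10,000", {
  cfg <- cohort_config(n_enrolled = 10000,
                       funnel_targets = c(371, 100, 72, 66), seed = 7)
  co <- generate_cohort(cfg)
  n <- nrow(co)
  sd3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex) - 0.79), sd3(0.79))
  expect_lt(abs(mean(co$hospitalization_status) - 0.55), sd3(0.55))
  expect_lt(abs(mean(co$occupation_status) - 0.32), sd3(0.32))
  mini <- as.matrix(co[, mini_item_names()])
  expect_lt(abs(mean(rowSums(mini) > 0) - 0.30), sd3(0.30) + 0.005)
  expect_lt(abs(mean(mini[, 11]) - 0.20), sd3(0.20))
  expect_lt(abs(mean(co$age) - 25.3), 0.2)
  expect_lt(abs(mean(co$episode_duration) - 2.5), 0.1)
})

test_that("PANSS values stay within instrument bounds at every visit", {
  fx <- full_cohort()
  panss_cols <- grep("^panss_.*_v[1-6]$", names(fx$cohort), value = TRUE)
  vals <- unlist(fx$cohort[, panss_cols])
  expect_true(all(vals >= 1 & vals <= 7))
  cgi <- unlist(fx$cohort[, grep("^cgi_severity_v", names(fx$cohort))])
  expect_true(all(cgi >= 1 & cgi <= 7))
  psp <- unlist(fx$cohort[, grep("^psp_._v", names(fx$cohort))])
  expect_true(all(psp >= 0 & psp <= 100))
})

test_that("final-visit severity matches the assigned remission status", {
  fx <- full_cohort()
  co <- fx$cohort
  crit <- paste0(andreasen_items(), "_v6")
  all_mild <- apply(co[, crit] <= 3, 1, all)
  expect_identical(all_mild, co$remission_sr == 1)
})

test_that("zero decay rate freezes trajectories at baseline", {
  cfg <- small_config(n = 1000, seed = 17, decay_rate = 0,
                      funnel_targets = c(1000, 1000, 1000, 1000))
  co <- generate_cohort(cfg)
  drift <- as.matrix(co[, paste0(sprintf("panss_p%d", 1:7), "_v6")]) -
    as.matrix(co[, paste0(sprintf("panss_p%d", 1:7), "_v1")])
  expect_lt(abs(mean(drift)), 0.05)   # noise only, mean ~ 0
})

test_that("single-patient trajectory simulation is usable standalone", {
  row <- data.frame(remission_sr = 1L)
  tr <- simulate_trajectories(row, small_config(), seed = 2)
  expect_length(tr, 37 * 6)
  crit <- unlist(tr[paste0(andreasen_items(), "_v6")])
  expect_true(all(crit <= 3))
  expect_identical(tr, simulate_trajectories(row, small_config(), seed = 2))
})

test_that("missingness injection follows the configured rates", {
  fx <- full_cohort()
  cfg0 <- small_config(n = 60, seed = 42,
                       funnel_targets = c(60, 60, 60, 60),
                       missingness_rates = c(swn = 0))
  expect_identical(inject_missingness(fx$cohort, cfg0), fx$cohort)

  cfg1 <- small_config(n = 60, seed = 42,
                       funnel_targets = c(60, 60, 60, 60),
                       missingness_rates = c(swn = 1))
  co1 <- inject_missingness(fx$cohort, cfg1)
  swn_cols <- sprintf("swn_%02d", 1:20)
  expect_true(all(is.na(co1[, swn_cols])))
  expect_false(anyNA(co1$age))

  cfg2 <- cohort_config(n_enrolled = 1000,
                        funnel_targets = c(371, 100, 72, 66), seed = 8,
                        missingness_rates = c(swn = 0.1))
  co2 <- inject_missingness(generate_cohort(cfg2), cfg2)
  frac <- mean(is.na(as.matrix(co2[, swn_cols])))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
  expect_false(anyNA(co2$remission_sr))
})

test_that("cohort round-trips through CSV + JSON schema", {
  fx <- full_cohort()
  cfg <- small_config(n = 30, seed = 2, funnel_targets = c(25, 20, 15, 14),
                      missingness_rates = c(swn = 0.2))
  co <- inject_missingness(apply_attrition_funnel(generate_cohort(cfg), cfg),
                           cfg)
  path <- file.path(tempdir(), "cohort.csv")
  paths <- write_cohort(co, path)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(path)
  expect_equal(nrow(back), 30)
  expect_identical(back$completed_phase2, co$completed_phase2)
  expect_equal(back$panss_p1_v1, co$panss_p1_v1)
  sch <- jsonlite::read_json(paths[["schema"]])
  expect_length(sch$features, nrow(feature_schema()))
})
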