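test_that("eligibility filter keeps exactly the analyzable patients", {
  co <- full_cohort()$cohort[1:10, ]
  co$completed_phase2 <- c(TRUE, TRUE, FALSE, TRUE, FALSE,
                           TRUE, FALSE, FALSE, TRUE, TRUE)
  co$panss_complete <- c(TRUE, FALSE, TRUE, TRUE, FALSE,
                         FALSE, TRUE, FALSE, TRUE, FALSE)
  out <- filter_eligible(co)
  # brute-force row scan oracle
  keep <- which(co$completed_phase2 & co$panss_complete)
  expect_identical(out$patient_id, co$patient_id[keep])
  expect_equal(nrow(out), 3)

  co$completed_phase2 <- FALSE
  expect_equal(nrow(filter_eligible(co)), 0)
})

test_that("imputer fits medians, modes and robust bounds on training data", {
  co <- full_cohort()$cohort
  sch <- feature_schema()
  tr <- co
  tr$age <- c(1, 2, 100, rep(NA, nrow(tr) - 3))
  st <- fit_imputer_scaler(tr, sch)
  expect_equal(st$continuous$age$median, 2)

  tr2 <- co
  tr2$sex <- c(1, 1, 0, NA, rep(1, nrow(tr2) - 4))
  st2 <- fit_imputer_scaler(tr2, sch)
  expect_equal(st2$discrete$sex$mode, "1")

  tr3 <- co
  tr3$age <- NA
  expect_error(fit_imputer_scaler(tr3, sch), "age")
})

test_that("robust bounds recover the percentile pair of a known sample", {
  co <- full_cohort()$cohort
  n <- 10000
  big <- co[rep(1, n), ]
  set.seed(4)
  big$age <- stats::rnorm(n)
  st <- fit_imputer_scaler(big, feature_schema(), probs = c(0.05, 0.95))
  # oracle: theoretical N(0,1) percentiles, tolerance from order-stat noise
  expect_lt(abs(st$continuous$age$lower - stats::qnorm(0.05)), 0.06)
  expect_lt(abs(st$continuous$age$upper - stats::qnorm(0.95)), 0.06)
})

test_that("transform encodes endpoints, one-hots and -1/+1 binaries", {
  fx <- tiny_setup()
  st <- fx$state
  co <- fx$cohort
  lo <- st$continuous$age$lower
  hi <- st$continuous$age$upper
  co$age[1] <- lo
  co$age[2] <- hi
  co$age[3] <- lo - 50          # clipped
  ts <- transform_features(co, fx$schema, st)
  expect_equal(unname(ts$static[1, "age"]), 0)
  expect_equal(unname(ts$static[2, "age"]), 1)
  expect_equal(unname(ts$static[3, "age"]), 0)
  expect_true(all(ts$static[, "age"] >= 0 & ts$static[, "age"] <= 1))

  dsm_cols <- paste0("dsm_classification.",
                     c("schizophrenia", "schizophreniform", "schizoaffective"))
  block <- ts$static[, dsm_cols]
  expect_true(all(rowSums(block) == 1))
  i <- which(co$dsm_classification == "schizophreniform")[1]
  expect_equal(unname(block[i, ]), c(0, 1, 0))

  expect_true(all(ts$static[, ts$mini_index] %in% c(-1, 1)))
  expect_length(ts$mini_index, 48)
})

test_that("transform of a complete table logs zero imputations", {
  fx <- tiny_setup()
  ts <- transform_features(fx$cohort, fx$schema, fx$state)
  expect_equal(ts$log$imputed, 0)
  expect_false(anyNA(ts$static))
  expect_false(anyNA(ts$dynamic))
})

test_that("unseen categories map to an all-zero block and are logged", {
  fx <- tiny_setup()
  co <- fx$cohort
  co$dwelling[1] <- "houseboat"
  ts <- transform_features(co, fx$schema, fx$state)
  dw <- ts$static[1, grep("^dwelling\\.", colnames(ts$static))]
  expect_equal(sum(dw), 0)
  expect_match(ts$log$unseen, "dwelling=houseboat", all = FALSE)
})

test_that("transform is idempotent and the fitted state never reads test rows", {
  fx <- tiny_setup()
  a <- transform_features(fx$cohort, fx$schema, fx$state)
  b <- transform_features(fx$cohort, fx$schema, fx$state)
  expect_identical(a$static, b$static)
  expect_identical(a$dynamic, b$dynamic)

  train <- fx$cohort[1:30, ]
  test <- fx$cohort[31:60, ]
  st1 <- fit_imputer_scaler(train, fx$schema)
  test$age <- test$age + 1000     # mutate test rows
  st2 <- fit_imputer_scaler(train, fx$schema)
  expect_identical(st1, st2)
})

test_that("missing cells are imputed and the result is complete", {
  fx <- tiny_setup()
  cfg <- small_config(n = 60, seed = 42, funnel_targets = c(60, 60, 60, 60),
                      missingness_rates = c(swn = 0.3, demographic = 0.2))
  co <- inject_missingness(fx$cohort, cfg)
  ts <- transform_features(co, fx$schema, fx$state)
  expect_gt(ts$log$imputed, 0)
  expect_false(anyNA(ts$static))
  expect_false(anyNA(ts$dynamic))
})

test_that("dynamic tensors route visits and masks correctly", {
  fx <- tiny_setup()
  cfg <- small_config(n = 60, seed = 42, funnel_targets = c(50, 40, 30, 28))
  co <- apply_attrition_funnel(fx$cohort, cfg)
  st <- fit_imputer_scaler(filter_eligible(co), fx$schema)
  ts <- transform_features(co, fx$schema, st)
  p1_only <- which(co$completed_phase1 & !co$continued_phase2)[1]
  expect_identical(unname(ts$visit_mask[p1_only, ]),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(ts$dynamic[p1_only, 5:6, ] == 0))
  full <- which(co$completed_phase2 & co$panss_complete)[1]
  expect_true(all(ts$visit_mask[full, ]))
})

test_that("remission labelling implements the 8-item severity conjunction", {
  boundary <- as.data.frame(as.list(stats::setNames(rep(3, 8),
                                                    andreasen_items())))
  expect_true(label_remission(boundary))
  one_bad <- boundary
  one_bad$panss_p2 <- 4
  expect_false(label_remission(one_bad))

  set.seed(11)
  mat <- as.data.frame(matrix(sample(1:7, 1000 * 8, TRUE), 1000,
                              dimnames = list(NULL, andreasen_items())))
  got <- label_remission(mat)
  # brute-force 8-way conjunction oracle
  oracle <- rep(TRUE, 1000)
  for (item in andreasen_items()) oracle <- oracle & (mat[[item]] <= 3)
  expect_identical(got, oracle)

  expect_error(label_remission(boundary[, -1]), "panss_p1")
  boundary$panss_p1 <- NA
  expect_error(label_remission(boundary), "missing")
})
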