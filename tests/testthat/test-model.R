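test_that("analytic gradients match central differences", {
  set.seed(42)
  dims <- list(modality_cols = list(panss = 1:2, psp = 3L, cgi = 4L),
               d_dyn = 4L, d_static = 3L, heads = c("sr", "fr"))
  arch <- list(hidden = 3L, fusion = 4L, interaction = 3L,
               w_ce = 1, w_mse = 0.7)
  params <- remitcf:::init_network_params(dims, arch)
  B <- 3; Tn <- 4
  batch <- list(
    S = matrix(stats::rnorm(B * 3), B, 3),
    dyn = lapply(1:Tn, function(t) matrix(stats::runif(B * 4), B, 4)),
    mask = matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), B, Tn),
    labels = list(sr = c(1L, 0L, 1L), fr = c(0L, 0L, 1L)))
  res <- remitcf:::net_loss_grad(params, batch, dims, arch)
  eps <- 1e-5
  for (nm in names(params)) {
    idx <- seq_along(params[[nm]])
    if (length(idx) > 6) idx <- sample(idx, 6)
    for (i in idx) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- remitcf:::net_loss_grad(pp, batch, dims, arch,
                                    forward_only = TRUE)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- remitcf:::net_loss_grad(pp, batch, dims, arch,
                                    forward_only = TRUE)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("parameter count matches the closed-form layer arithmetic", {
  fx <- tiny_setup()
  arch <- tiny_arch(hidden = 2, fusion = 3, interaction = 2)
  m <- build_model(arch, fx$ts)
  H <- 2; Fw <- 3; Iw <- 2
  Ds <- ncol(fx$ts$static); Dd <- dim(fx$ts$dynamic)[3]
  d_mod <- vapply(fx$ts$modality_cols, length, integer(1))
  # hand-computed: per-modality LSTM, fusion, 3 heads, regression head
  expected <- sum(d_mod * 4 * H + H * 4 * H + 4 * H) +
    (3 * H + Ds) * Fw + Fw +
    3 * (Fw * Iw + Iw + Iw * 2 + 2) +
    Fw * Iw + Iw + Iw * Dd + Dd
  expect_equal(remitcf:::n_parameters(m), expected)
})

test_that("class-probability heads are normalised and zero-init is constant", {
  fx <- tiny_setup()
  batch <- remitcf:::make_batch(fx$ts, 1:20)
  fw <- remitcf:::net_forward(fx$model$params, batch, fx$model$dims,
                              fx$model$arch)
  for (t in 1:6)
    expect_equal(rowSums(fw$probs[[paste0("sr", t)]]), rep(1, 20),
                 tolerance = 1e-6)

  z <- build_model(fx$arch, fx$ts, zero_init = TRUE)
  p <- predict_remission_prob(z, fx$ts, 1, calibrated = FALSE)
  expect_true(all(p == p[1]))   # constant function
})

test_that("pretraining runs the configured schedule exactly", {
  fx <- tiny_setup()
  bank <- tensor_rows(fx$ts, rep(1:50, 2))   # 100 rows
  arch <- tiny_arch(pretrain_epochs = 2, pretrain_batch = 25)
  m <- build_model(arch, fx$ts)
  m2 <- pretrain(m, bank, arch)
  expect_equal(m2$step, 8L)   # 2 epochs x ceiling(100/25) batches

  arch0 <- tiny_arch(pretrain_epochs = 0)
  m3 <- pretrain(build_model(arch0, fx$ts), bank, arch0)
  expect_identical(m3$params, build_model(arch0, fx$ts)$params)
})

test_that("pretraining descends the loss on its own bank", {
  fx <- tiny_setup()
  bank <- tensor_rows(fx$ts, 1:40)
  batch <- remitcf:::make_batch(bank)
  wins <- 0
  for (s in 1:5) {
    arch <- tiny_arch(seed = 100 + s, pretrain_epochs = 3,
                      pretrain_batch = 8, lr = 3e-3)
    m <- build_model(arch, fx$ts)
    before <- remitcf:::net_loss_grad(m$params, batch, m$dims, m$arch,
                                      forward_only = TRUE)$loss
    m <- pretrain(m, bank, arch)
    after <- remitcf:::net_loss_grad(m$params, batch, m$dims, m$arch,
                                     forward_only = TRUE)$loss
    wins <- wins + (after <= before)
  }
  expect_gte(wins, 4)
})

test_that("augmentation preserves originals, labels and bounds", {
  fx <- tiny_setup()
  ts10 <- tensor_rows(fx$ts, 1:10)
  arch1 <- tiny_arch(augment_multiplier = 1)
  expect_identical(augment(ts10, arch1), ts10)

  arch5 <- tiny_arch(augment_multiplier = 5, jitter_sd = 3)
  aug <- augment(ts10, arch5, seed = 2)
  expect_equal(nrow(aug$static), 50)
  expect_identical(aug$static[1:10, ], ts10$static)
  expect_identical(aug$dynamic[1:10, , ], ts10$dynamic[, , ])
  expect_identical(aug$labels$remission_sr, rep(ts10$labels$remission_sr, 5))
  # scaled representation bounded => raw PANSS stays in [1, 7]
  expect_true(all(aug$dynamic >= 0 & aug$dynamic <= 1))
  # masked visits never acquire signal
  expect_true(all(aug$dynamic[, , 1][!aug$visit_mask] == 0))
})

test_that("the learning-rate schedule decays exponentially", {
  arch <- arch_config()
  lr_at <- function(step) arch$lr * arch$decay_rate^(step / arch$decay_steps)
  expect_equal(lr_at(10000), 2.7e-4)
  expect_equal(lr_at(0), 3e-4)
})

test_that("zero regression weight removes the regression gradient", {
  fx <- tiny_setup()
  batch <- remitcf:::make_batch(fx$ts, 1:8)
  arch <- fx$arch
  arch$w_mse <- 0
  res <- remitcf:::net_loss_grad(fx$model$params, batch, fx$model$dims, arch)
  expect_true(all(res$grads$Wo_reg == 0))
  expect_true(all(res$grads$Wi_reg == 0))
  arch$w_mse <- 1
  res2 <- remitcf:::net_loss_grad(fx$model$params, batch, fx$model$dims, arch)
  expect_false(all(res2$grads$Wo_reg == 0))
})

test_that("training is deterministic and separates a linear toy", {
  fx <- tiny_setup()
  # plant a linearly separable signal in two static columns
  ts <- tensor_rows(fx$ts, 1:40)
  set.seed(1)
  y <- rep(c(0L, 1L), 20)
  ts$labels$remission_sr <- y
  ts$labels$remission_fr <- y
  ts$labels$remission_cr <- y
  ts$static[, 1] <- ifelse(y == 1, 0.9, 0.1)
  ts$static[, 2] <- ifelse(y == 1, 0.05, 0.95)
  wins <- 0
  for (s in 1:3) {
    arch <- tiny_arch(seed = 200 + s, epochs = 50, batch = 8, lr = 1e-2)
    m <- train_model(build_model(arch, ts), ts)
    p <- predict_remission_prob(m, ts, 1, calibrated = FALSE)
    bac <- compute_metrics(y, p)$bac
    wins <- wins + (bac == 1)
    if (s == 1) {
      m_again <- train_model(build_model(arch, ts), ts)
      expect_identical(m$params, m_again$params)
    }
  }
  expect_gte(wins, 2)
})

test_that("calibration is monotone, rank-preserving and guards degeneracy", {
  set.seed(8)
  n <- 2000
  raw <- stats::runif(n)
  y <- stats::rbinom(n, 1, raw)     # perfectly calibrated scores
  fx <- tiny_setup()
  m <- fx$model
  # bypass prediction: calibrate directly against the raw scores
  lraw <- stats::qlogis(raw)
  fit <- suppressWarnings(stats::glm(y ~ lraw, family = stats::binomial()))
  m$calibration <- list(type = "platt", a = unname(stats::coef(fit)[1]),
                        b = unname(stats::coef(fit)[2]))
  mapped <- remitcf:::apply_calibration(m, raw)
  expect_lt(max(abs(mapped - raw)), 0.05)
  expect_true(all(diff(mapped[order(raw)]) >= 0))

  # AUC unchanged by any monotone map
  auc_raw <- compute_metrics(y, raw)$auc
  auc_cal <- compute_metrics(y, mapped)$auc
  expect_equal(auc_raw, auc_cal)

  val1 <- tensor_rows(fx$ts, 1:10)
  val1$labels$remission_sr <- rep(1L, 10)
  expect_warning(m2 <- calibrate(fx$model, val1), "single-class")
  expect_equal(m2$calibration$type, "identity")
})

test_that("prediction respects its contracts", {
  fx <- tiny_setup()
  m <- fx$model
  p <- predict_remission_prob(m, fx$ts, 1)
  expect_true(all(p >= 0 & p <= 1))
  dup <- tensor_rows(fx$ts, c(1, 1))
  pd <- predict_remission_prob(m, dup, 3)
  expect_identical(pd[1], pd[2])
  expect_error(predict_remission_prob(m, fx$ts, 7), "upto_visit")
  expect_error(predict_remission_prob(m, fx$ts, 0), "upto_visit")
})

test_that("non-finite loss aborts with diagnostics", {
  fx <- tiny_setup()
  m <- fx$model
  m$params$Wf[] <- NaN
  expect_error(remitcf:::train_loop(m, tensor_rows(fx$ts, 1:8), 1, 4,
                                    "train", 1),
               "non-finite")
})

test_that("the model learns strong planted signal and nothing from pure noise", {
  sch <- feature_schema()
  anneal <- function(seed) arch_config(hidden = 8, fusion = 16, interaction = 8,
                                       epochs = 60, batch = 32, lr = 0.02,
                                       decay_rate = 0.5, decay_steps = 300,
                                       pretrain_epochs = 0,
                                       augment_multiplier = 1, seed = seed)
  beta <- rep(0, 48)
  beta[c(1, 2, 8, 13, 20)] <- -2
  beta[c(11, 40, 41)] <- 2
  heldout_auc <- function(seed, strong) {
    cfg <- cohort_config(n_enrolled = 600, funnel_targets = rep(600, 4),
                         beta = if (strong) beta else rep(0, 48),
                         gamma = if (strong) -2 else 0,
                         beta0 = if (strong) -4 else -0.2, seed = seed)
    co <- generate_cohort(cfg)
    st <- fit_imputer_scaler(co[1:480, ], sch)
    tr <- transform_features(co[1:480, ], sch, st)
    te <- transform_features(co[481:600, ], sch, st)
    m <- train_model(build_model(anneal(7), tr), tr)
    p <- predict_remission_prob(m, te, 1, calibrated = FALSE)
    compute_metrics(te$labels$remission_sr, p)$auc
  }
  strong <- vapply(31:33, heldout_auc, numeric(1), strong = TRUE)
  expect_gt(mean(strong), 0.75)
  null <- vapply(31:33, heldout_auc, numeric(1), strong = FALSE)
  expect_lt(abs(mean(null) - 0.5), 0.07)
})
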