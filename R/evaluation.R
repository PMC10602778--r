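#' Classification metrics at a probability threshold
#'
#' AUC by the rank (Mann-Whitney) definition with half credit for ties,
#' sensitivity and specificity at the threshold, and balanced accuracy
#' (their mean).
#'
#' @param labels Binary outcome vector (0/1 or logical).
#' @param probabilities Predicted probabilities in [0, 1].
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `auc`, `bac`, `sensitivity`, `specificity`. AUC is
#'   `NA` (with a warning) when only one outcome class is present.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)),
            all(probabilities >= 0 & probabilities <= 1))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single outcome class: AUC undefined")
    auc <- NA_real_
  } else {
    r <- rank(probabilities)
    auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- as.integer(probabilities >= threshold)
  sens <- if (n1 > 0) sum(pred == 1 & y == 1) / n1 else NA_real_
  spec <- if (n0 > 0) sum(pred == 0 & y == 0) / n0 else NA_real_
  list(auc = auc, bac = mean(c(sens, spec)),
       sensitivity = sens, specificity = spec)
}

# Outcome-stratified fold assignment: within each class, patients are
# shuffled and dealt round-robin, so fold test sizes differ by at most one
# per class.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Remove the MINI block from an encoded feature set
#'
#' Drops the 48 encoded MINI columns from the static matrix (the
#' "without-comorbidity" model variant). Everything else is untouched.
#' Calling it on an already-ablated set is an error.
#'
#' @param ts A `feature_tensors` object.
#' @return The ablated `feature_tensors` (empty `mini_index`).
#' @export
ablate_mini <- function(ts) {
  if (length(ts$mini_index) == 0)
    stop("feature set has already been ablated: no MINI columns present",
         call. = FALSE)
  ts$static <- ts$static[, -ts$mini_index, drop = FALSE]
  ts$mini_index <- integer(0)
  ts
}

# One full train/calibrate/predict cycle on a train/test split of the raw
# eligible cohort. Scaler, calibration and training never see test rows.
#' @keywords internal
fit_fold <- function(cohort, train_rows, test_rows, schema, arch,
                     variant = "with_mini", pretrain_bank = NULL,
                     upto_visit = arch$upto_visit) {
  train_tab <- cohort[train_rows, , drop = FALSE]
  test_tab <- cohort[test_rows, , drop = FALSE]
  state <- fit_imputer_scaler(train_tab, schema)
  ts_train <- transform_features(train_tab, schema, state)
  ts_test <- transform_features(test_tab, schema, state)
  if (variant == "without_mini") {
    ts_train <- ablate_mini(ts_train)
    ts_test <- ablate_mini(ts_test)
  }

  # inner calibration split, stratified on the outcome
  y <- ts_train$labels$remission_sr
  set.seed(arch$seed + 31L)
  val_rows <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, floor(length(idx) / 5))
    val_rows <- c(val_rows, idx[sample.int(length(idx), n_val)])
  }
  core_rows <- setdiff(seq_along(y), val_rows)
  ts_core <- tensor_rows(ts_train, core_rows)
  ts_val <- tensor_rows(ts_train, val_rows)

  model <- build_model(arch, ts_core)
  if (!is.null(pretrain_bank) && arch$pretrain_epochs > 0) {
    ts_bank <- transform_features(pretrain_bank, schema, state)
    if (variant == "without_mini") ts_bank <- ablate_mini(ts_bank)
    model <- pretrain(model, ts_bank)
  }
  aug <- augment(ts_core, arch, seed = arch$seed + 47L)
  model <- train_model(model, aug)
  model <- suppressWarnings(calibrate(model, ts_val))
  model$train_ids <- unique(ts_train$patient_id)

  probs <- predict_remission_prob(model, ts_test, upto_visit)
  met <- withCallingHandlers(
    compute_metrics(ts_test$labels$remission_sr, probs),
    warning = function(w) invokeRestart("muffleWarning"))
  list(model = model, probs = probs, metrics = met, ts_test = ts_test,
       state = state)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition, draws a fresh seeded outcome-stratified partition
#' into k folds and runs the full preprocessing + pretraining +
#' augmentation + training + calibration + prediction cycle per fold.
#' Folds with a single outcome class record `NA` AUC.
#'
#' @param cohort The eligible cohort table (raw, unencoded).
#' @param schema Feature schema.
#' @param arch An [arch_config()].
#' @param k Number of folds (default 10).
#' @param repetitions Number of repetitions (default 20).
#' @param seed Integer seed governing all partitions and model seeds.
#' @param variant `"with_mini"` or `"without_mini"`.
#' @param pretrain_bank Optional synthesized cohort table for pretraining.
#' @param upto_visit Visit index fed at prediction time.
#' @param collect_importance Also compute per-patient importance maps with
#'   each fold's out-of-fold model (with-MINI variant only).
#' @return List with `metrics` (one row per repetition x fold) and `maps`
#'   (long data.frame or `NULL`).
#' @export
repeated_stratified_kfold <- function(cohort, schema = feature_schema(),
                                      arch = arch_config(),
                                      k = 10L, repetitions = 20L,
                                      seed = 1L,
                                      variant = c("with_mini", "without_mini"),
                                      pretrain_bank = NULL,
                                      upto_visit = arch$upto_visit,
                                      collect_importance = FALSE) {
  variant <- match.arg(variant)
  y <- cohort$remission_sr
  stopifnot(nrow(cohort) >= k, length(unique(y)) == 2)
  metrics <- list()
  maps <- list()
  for (rep_i in seq_len(repetitions)) {
    fold_of <- stratified_folds(y, k, seed = seed + 1000L * rep_i)
    fold_models <- vector("list", k)
    fold_tests <- vector("list", k)
    fold_states <- vector("list", k)
    for (f in seq_len(k)) {
      test_rows <- which(fold_of == f)
      train_rows <- which(fold_of != f)
      arch_f <- arch
      arch_f$seed <- as.integer(seed + 1000L * rep_i + f)
      res <- fit_fold(cohort, train_rows, test_rows, schema, arch_f,
                      variant, pretrain_bank, upto_visit)
      met <- res$metrics
      metrics[[length(metrics) + 1L]] <- data.frame(
        repetition = rep_i, fold = f, variant = variant,
        n_test = length(test_rows), site_held_out = NA_integer_,
        auc = met$auc, bac = met$bac,
        sensitivity = met$sensitivity, specificity = met$specificity)
      fold_models[[f]] <- res$model
      fold_tests[[f]] <- test_rows
      fold_states[[f]] <- res$state
    }
    if (collect_importance && variant == "with_mini") {
      # maps come from each patient's out-of-fold model; each fold's test
      # rows are encoded with that fold's training scaler (no leakage)
      rep_maps <- lapply(seq_len(k), function(f) {
        ts <- transform_features(cohort, schema, fold_states[[f]])
        collect_maps(fold_models[f], fold_tests[f], ts,
                     upto_visit, repetition = rep_i)
      })
      maps[[rep_i]] <- do.call(rbind, rep_maps)
    }
  }
  list(metrics = do.call(rbind, metrics),
       maps = if (length(maps)) do.call(rbind, maps) else NULL)
}

#' Leave-one-site-out cross-validation
#'
#' One fold per recruiting site: train on all other sites, predict the
#' held-out site. Tests cross-site generalization of the multicenter model.
#'
#' @inheritParams repeated_stratified_kfold
#' @return List with `metrics` (one row per site).
#' @export
leave_one_site_out <- function(cohort, schema = feature_schema(),
                               arch = arch_config(), seed = 1L,
                               variant = c("with_mini", "without_mini"),
                               pretrain_bank = NULL,
                               upto_visit = arch$upto_visit) {
  variant <- match.arg(variant)
  sites <- sort(unique(cohort$site_id))
  if (length(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  metrics <- list()
  for (s in sites) {
    test_rows <- which(cohort$site_id == s)
    train_rows <- which(cohort$site_id != s)
    arch_f <- arch
    arch_f$seed <- as.integer(seed + s)
    res <- fit_fold(cohort, train_rows, test_rows, schema, arch_f,
                    variant, pretrain_bank, upto_visit)
    met <- res$metrics
    metrics[[length(metrics) + 1L]] <- data.frame(
      repetition = 1L, fold = match(s, sites), variant = variant,
      n_test = length(test_rows), site_held_out = s,
      auc = met$auc, bac = met$bac,
      sensitivity = met$sensitivity, specificity = met$specificity)
  }
  list(metrics = do.call(rbind, metrics))
}

#' Compare the with- and without-comorbidity model variants
#'
#' Per metric, a two-sided Mann-Whitney U test over the fold-level values
#' of the two variants (fold rows with an undefined value in either
#' variant are excluded pairwise), plus mean and SD per variant and
#' significance stars at 0.05 / 0.01.
#'
#' @param metrics_with,metrics_without Metric data.frames from CV runs of
#'   the two variants (identical partitions, paired seeds).
#' @return A data.frame with one row per metric.
#' @export
compare_variants <- function(metrics_with, metrics_without) {
  out <- list()
  for (metric in c("auc", "bac", "sensitivity", "specificity")) {
    x <- metrics_with[[metric]]
    y <- metrics_without[[metric]]
    keep <- !is.na(x) & !is.na(y)
    n_dropped <- sum(!keep)
    x <- x[keep]; y <- y[keep]
    p <- if (length(x) && (stats::var(c(x, y)) > 0))
      suppressWarnings(stats::wilcox.test(x, y)$p.value) else 1
    out[[metric]] <- data.frame(
      metric = metric,
      mean_with = mean(x), sd_with = stats::sd(x),
      mean_without = mean(y), sd_without = stats::sd(y),
      p_value = p,
      stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns",
      n_folds = length(x), n_dropped = n_dropped,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
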