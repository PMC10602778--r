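#' Eligibility filter
#'
#' Retains, in order, the patients who completed the second treatment phase
#' and have complete PANSS records — the analysis sample of the study
#' design the package emulates.
#'
#' @param cohort A cohort table with funnel flags.
#' @return The filtered cohort (possibly empty).
#' @export
filter_eligible <- function(cohort) {
  stopifnot(all(c("completed_phase2", "panss_complete") %in% names(cohort)))
  cohort[cohort$completed_phase2 & cohort$panss_complete, , drop = FALSE]
}

#' Fit the imputer and robust scaler on training rows
#'
#' For each continuous feature: the training median (imputation value) and
#' robust min-max bounds taken at the configured percentile pair. For each
#' categorical or binary feature: the training mode. Dynamic features are
#' pooled across visits so one state serves all visit columns. Fitting never
#' reads anything outside `train_table`, which is the no-leakage contract
#' cross-validation relies on.
#'
#' @param train_table Training rows of a cohort table.
#' @param schema Feature schema from [feature_schema()].
#' @param probs Length-2 percentile pair for the robust bounds.
#' @return An object of class `scaler_state`.
#' @export
fit_imputer_scaler <- function(train_table, schema = feature_schema(),
                               probs = c(0.01, 0.99)) {
  stopifnot(nrow(train_table) > 0, length(probs) == 2, probs[1] < probs[2])
  state <- list(probs = probs, continuous = list(), discrete = list())
  for (i in seq_len(nrow(schema))) {
    name <- schema$name[i]
    cols <- if (schema$dynamic[i]) paste0(name, "_v", seq_len(n_visits())) else name
    cols <- intersect(cols, names(train_table))
    vals <- unlist(train_table[, cols], use.names = FALSE)
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0)
      stop(sprintf("feature '%s' is entirely missing in the training data", name),
           call. = FALSE)
    if (schema$value_type[i] == "continuous") {
      q <- stats::quantile(as.numeric(vals), probs, names = FALSE, type = 7)
      state$continuous[[name]] <- list(median = stats::median(as.numeric(vals)),
                                       lower = q[1], upper = q[2])
    } else {
      tab <- table(vals)
      mode <- names(tab)[which.max(tab)]
      cats <- if (schema$value_type[i] == "categorical")
        schema$categories[[i]] else NULL
      state$discrete[[name]] <- list(mode = mode, categories = cats,
                                     type = schema$value_type[i])
    }
  }
  class(state) <- "scaler_state"
  state
}

#' Encode a cohort into model-ready tensors
#'
#' Applies the fitted imputation/scaling state: continuous features are
#' median-imputed then mapped through a clipped robust min-max into [0, 1];
#' categorical features are mode-imputed and one-hot encoded over the
#' training category set (unseen categories map to an all-zero block and are
#' logged); binary features are mode-imputed and encoded -1/+1. Dynamic
#' features are routed into a patients x visits x features array with a
#' visit-availability mask.
#'
#' @param table Cohort rows to encode.
#' @param schema Feature schema.
#' @param state A fitted `scaler_state`.
#' @return An object of class `feature_tensors`: list with `static`
#'   (matrix), `dynamic` (3-d array), `visit_mask` (logical matrix),
#'   `mini_index` (positions of the 48 MINI entries in `static`), `labels`
#'   (named list of outcome vectors, when present in `table`),
#'   `patient_id`, `site_id`, `scaler_state` and an imputation/unseen log.
#' @export
transform_features <- function(table, schema = feature_schema(), state) {
  stopifnot(inherits(state, "scaler_state"))
  n <- nrow(table)
  log <- list(imputed = 0L, unseen = character(0))

  scale_cont <- function(vals, st) {
    miss <- is.na(vals)
    log$imputed <<- log$imputed + sum(miss)
    vals[miss] <- st$median
    if (st$upper > st$lower) {
      pmin(pmax((vals - st$lower) / (st$upper - st$lower), 0), 1)
    } else rep(0.5, length(vals))
  }

  static_blocks <- list()
  mini_index <- integer(0)
  static_schema <- schema[!schema$dynamic, , drop = FALSE]
  width <- 0L
  for (i in seq_len(nrow(static_schema))) {
    name <- static_schema$name[i]
    type <- static_schema$value_type[i]
    vals <- table[[name]]
    if (type == "continuous") {
      col <- matrix(scale_cont(as.numeric(vals), state$continuous[[name]]),
                    ncol = 1, dimnames = list(NULL, name))
    } else if (type == "binary") {
      st <- state$discrete[[name]]
      miss <- is.na(vals)
      log$imputed <- log$imputed + sum(miss)
      vals[miss] <- st$mode
      col <- matrix(ifelse(as.character(vals) %in% c("1", "yes", "TRUE"),
                           1, -1),
                    ncol = 1, dimnames = list(NULL, name))
      if (static_schema$modality[i] == "mini")
        mini_index <- c(mini_index, width + 1L)
    } else {
      st <- state$discrete[[name]]
      miss <- is.na(vals)
      log$imputed <- log$imputed + sum(miss)
      vals[miss] <- st$mode
      vals <- as.character(vals)
      unseen <- setdiff(unique(vals), st$categories)
      if (length(unseen))
        log$unseen <- c(log$unseen, paste0(name, "=", unseen))
      col <- matrix(0, n, length(st$categories),
                    dimnames = list(NULL, paste0(name, ".", st$categories)))
      hit <- match(vals, st$categories)
      ok <- !is.na(hit)
      col[cbind(which(ok), hit[ok])] <- 1
    }
    width <- width + ncol(col)
    static_blocks[[name]] <- col
  }
  static <- do.call(cbind, static_blocks)

  dyn_schema <- schema[schema$dynamic, , drop = FALSE]
  nd <- nrow(dyn_schema)
  nv <- n_visits()
  dynamic <- array(0, dim = c(n, nv, nd),
                   dimnames = list(NULL, paste0("v", seq_len(nv)),
                                   dyn_schema$name))
  observed <- matrix(FALSE, n, nv)
  for (v in seq_len(nv)) {
    raw <- as.matrix(table[, paste0(dyn_schema$name, "_v", v), drop = FALSE])
    observed[, v] <- rowSums(!is.na(raw)) > 0
  }
  for (j in seq_len(nd)) {
    name <- dyn_schema$name[j]
    st <- state$continuous[[name]]
    for (v in seq_len(nv)) {
      vals <- as.numeric(table[[paste0(name, "_v", v)]])
      scaled <- scale_cont(vals, st)
      scaled[!observed[, v]] <- 0    # masked visits carry no signal
      dynamic[, v, j] <- scaled
    }
  }

  labels <- list()
  for (lab in c("remission_sr", "remission_fr", "remission_cr"))
    if (lab %in% names(table)) labels[[lab]] <- as.integer(table[[lab]])

  out <- list(static = static,
              dynamic = dynamic,
              visit_mask = observed,
              mini_index = mini_index,
              labels = labels,
              patient_id = table$patient_id,
              site_id = table$site_id,
              scaler_state = state,
              modality_cols = list(
                panss = which(dyn_schema$modality == "panss"),
                psp = which(dyn_schema$modality == "psp"),
                cgi = which(dyn_schema$modality == "cgi")),
              log = log)
  class(out) <- "feature_tensors"
  out
}

#' Subset rows of a feature tensor set
#' @param ts A `feature_tensors` object.
#' @param rows Integer or logical row index.
#' @return The subsetted `feature_tensors`.
#' @export
tensor_rows <- function(ts, rows) {
  out <- ts
  out$static <- ts$static[rows, , drop = FALSE]
  out$dynamic <- ts$dynamic[rows, , , drop = FALSE]
  out$visit_mask <- ts$visit_mask[rows, , drop = FALSE]
  out$labels <- lapply(ts$labels, function(x) x[rows])
  out$patient_id <- ts$patient_id[rows]
  out$site_id <- ts$site_id[rows]
  out
}

#' @export
print.feature_tensors <- function(x, ...) {
  cat(sprintf("<feature_tensors> %d patients, %d static columns, %d visits x %d dynamic features\n",
              nrow(x$static), ncol(x$static), dim(x$dynamic)[2], dim(x$dynamic)[3]))
  cat(sprintf("  MINI entries: %d, imputations: %d, unseen categories: %d\n",
              length(x$mini_index), x$log$imputed, length(x$log$unseen)))
  invisible(x)
}

#' Symptomatic-remission severity rule
#'
#' A patient is in symptomatic remission when all eight criterion PANSS
#' items (P1, P2, P3, N1, N4, N6, G5, G9) score 3 (mild) or below. The
#' duration component of the published criterion is dropped because the
#' 10-week trial horizon cannot support a 6-month requirement; remission is
#' evaluated at the final (week 8) visit.
#'
#' @param panss_final_visit A data.frame, matrix or named vector carrying
#'   the 30 PANSS items of the final visit (names `panss_p1`, ...,
#'   optionally with a visit suffix).
#' @return Logical vector, `TRUE` for remission.
#' @export
label_remission <- function(panss_final_visit) {
  if (is.vector(panss_final_visit) && !is.list(panss_final_visit))
    panss_final_visit <- as.data.frame(as.list(panss_final_visit))
  nm <- names(panss_final_visit)
  crit <- andreasen_items()
  pick <- function(item) {
    j <- which(nm == item | startsWith(nm, paste0(item, "_v")))
    if (length(j) == 0)
      stop(sprintf("criterion item '%s' is missing", item), call. = FALSE)
    as.numeric(panss_final_visit[[j[length(j)]]])
  }
  vals <- vapply(crit, pick, numeric(nrow(as.data.frame(panss_final_visit))))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  if (anyNA(vals))
    stop("criterion items contain missing values", call. = FALSE)
  apply(vals <= 3, 1, all)
}
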