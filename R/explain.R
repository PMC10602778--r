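#' Generate the 48 single-flip counterfactual records
#'
#' For one encoded patient record, produces the 48 counterfactual static
#' rows in which exactly one MINI comorbidity item is flipped (yes <-> no;
#' on the encoded representation a flip is the negation of the -1/+1
#' entry). All other features are untouched, so every counterfactual sits
#' at Hamming distance 1 from the record on the MINI block.
#'
#' @param ts A `feature_tensors` object.
#' @param row Row index of the patient within `ts`.
#' @return A 48 x ncol(static) matrix; row `j` flips item `j`.
#' @export
generate_counterfactuals <- function(ts, row) {
  stopifnot(inherits(ts, "feature_tensors"))
  mi <- ts$mini_index
  if (length(mi) != 48)
    stop("record must carry all 48 encoded MINI items", call. = FALSE)
  s <- ts$static[row, ]
  if (anyNA(s[mi]))
    stop("MINI items must be imputed before counterfactual generation",
         call. = FALSE)
  out <- matrix(rep(s, each = 48), nrow = 48,
                dimnames = list(NULL, colnames(ts$static)))
  out[cbind(seq_len(48), mi)] <- -out[cbind(seq_len(48), mi)]
  out
}

#' Signed counterfactual effect size
#'
#' The effect of a comorbidity item on an individual prediction:
#' `prob(remission | item = yes) - prob(remission | item = no)`.
#'
#' @param prob_yes,prob_no Predicted remission probabilities in [0, 1].
#' @return `prob_yes - prob_no`, in [-1, 1].
#' @export
effect_size <- function(prob_yes, prob_no) {
  if (any(prob_yes < 0 | prob_yes > 1 | prob_no < 0 | prob_no > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  prob_yes - prob_no
}

#' Per-patient feature-importance map
#'
#' Predicts the remission probability for the actual record and its 48
#' single-flip counterfactuals (49 model evaluations) and assembles the
#' 48 signed effect sizes: when the patient's actual item value is "yes"
#' the effect is `p_actual - p_counterfactual`, otherwise
#' `p_counterfactual - p_actual`, i.e. always
#' `prob(remission | yes) - prob(remission | no)`.
#'
#' @param model A trained `remit_model` (trained on a fold not containing
#'   this record; enforced by [collect_maps()]).
#' @param ts A `feature_tensors` object.
#' @param row Row index of the patient.
#' @param upto_visit Visit index fed at prediction time.
#' @return An object of class `importance_map`: list with `patient_id`,
#'   `effects` (length-48 numeric), `actual_prob`.
#' @export
importance_map <- function(model, ts, row,
                           upto_visit = model$arch$upto_visit) {
  cf <- generate_counterfactuals(ts, row)
  mi <- ts$mini_index
  probe <- ts
  probe$static <- rbind(ts$static[row, , drop = FALSE], cf)
  reps <- rep(row, 49)
  probe$dynamic <- ts$dynamic[reps, , , drop = FALSE]
  probe$visit_mask <- ts$visit_mask[reps, , drop = FALSE]
  probe$labels <- lapply(ts$labels, function(x) x[reps])
  probe$patient_id <- ts$patient_id[reps]
  probe$site_id <- ts$site_id[reps]
  p <- predict_remission_prob(model, probe, upto_visit)
  p_act <- p[1]
  p_cf <- p[-1]
  actual_yes <- ts$static[row, mi] > 0
  effects <- ifelse(actual_yes, p_act - p_cf, p_cf - p_act)
  structure(list(patient_id = ts$patient_id[row],
                 effects = as.numeric(effects),
                 actual_prob = p_act),
            class = "importance_map")
}

#' Collect importance maps across folds and repetitions
#'
#' Computes one map per patient per cross-validation repetition, each by
#' the model of the fold that held the patient out. A leakage guard errors
#' if a patient id appears in the training ids of its own fold model.
#'
#' @param fold_models List of trained `remit_model`s, one per fold.
#' @param fold_test_rows List of integer row indices (into `ts`) of each
#'   fold's test set.
#' @param ts The full encoded `feature_tensors`.
#' @param upto_visit Visit index fed at prediction time.
#' @param repetition Repetition id recorded on each map.
#' @return A long data.frame: `patient_id`, `repetition`, `fold`, `item`,
#'   `item_label`, `delta`, `actual_prob`.
#' @export
collect_maps <- function(fold_models, fold_test_rows, ts,
                         upto_visit = fold_models[[1]]$arch$upto_visit,
                         repetition = 1L) {
  stopifnot(length(fold_models) == length(fold_test_rows))
  labels <- mini_items()$label
  out <- vector("list", length(fold_models))
  for (f in seq_along(fold_models)) {
    model <- fold_models[[f]]
    rows <- fold_test_rows[[f]]
    leaked <- intersect(ts$patient_id[rows], model$train_ids)
    if (length(leaked))
      stop(sprintf("leakage: patient(s) %s present in both train and test of fold %d",
                   paste(leaked, collapse = ", "), f), call. = FALSE)
    maps <- lapply(rows, function(r) importance_map(model, ts, r, upto_visit))
    out[[f]] <- data.frame(
      patient_id = rep(ts$patient_id[rows], each = 48),
      repetition = repetition, fold = f,
      item = rep(seq_len(48), length(rows)),
      item_label = rep(labels, length(rows)),
      delta = unlist(lapply(maps, `[[`, "effects")),
      actual_prob = rep(vapply(maps, `[[`, numeric(1), "actual_prob"),
                        each = 48),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Wide per-patient map matrix from long-format maps
#'
#' Averages each patient's maps across repetitions (the per-patient map
#' used for clustering) and returns a patients x 48 matrix.
#'
#' @param maps_long Long data.frame from [collect_maps()].
#' @return Numeric matrix, rownames = patient ids, 48 columns.
#' @export
maps_matrix <- function(maps_long) {
  agg <- stats::aggregate(delta ~ patient_id + item, data = maps_long,
                          FUN = mean)
  ids <- sort(unique(agg$patient_id))
  m <- matrix(NA_real_, length(ids), 48,
              dimnames = list(ids, mini_items()$name))
  m[cbind(match(agg$patient_id, ids), agg$item)] <- agg$delta
  m
}
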