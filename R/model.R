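#' Architecture and training configuration of the prognosis model
#'
#' Holds every tunable of the recurrent multi-modal remission classifier.
#' The optimisation constants default to the published training recipe:
#' Adam with initial learning rate 3e-4 and exponential decay (rate 0.9
#' every 10,000 steps), pretraining for 2 epochs at mini-batch 25 on a
#' synthesized patient bank, then 50 epochs at mini-batch 2 on augmented
#' data. Architectural widths are not published for this pipeline and
#' default to recurrent hidden size 16 per modality, fusion width 64 and
#' interaction width 32 per outcome head.
#'
#' @param hidden Recurrent hidden units per dynamic modality.
#' @param fusion Width of the fusion layer joining hidden states and statics.
#' @param interaction Width of the per-outcome interaction layers.
#' @param lr Initial Adam learning rate.
#' @param decay_rate,decay_steps Exponential learning-rate schedule:
#'   `lr * decay_rate^(step / decay_steps)`.
#' @param w_mse,w_ce Weights of the regression (next-visit scores) and
#'   classification (outcome heads) terms of the multi-objective loss.
#' @param pretrain_epochs,pretrain_batch Pretraining schedule.
#' @param epochs,batch Main training schedule.
#' @param augment_multiplier Output/input size ratio of [augment()].
#' @param jitter_sd Augmentation jitter SD in raw PANSS points (converted to
#'   the scaled representation internally).
#' @param visit_dropout Probability that an augmented copy loses one
#'   non-baseline visit.
#' @param calibration `"platt"` or `"identity"`.
#' @param upto_visit Default visit index (1 = baseline) fed at prediction
#'   time.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(hidden = 16L, fusion = 64L, interaction = 32L,
                        lr = 3e-4, decay_rate = 0.9, decay_steps = 10000,
                        w_mse = 1, w_ce = 1,
                        pretrain_epochs = 2L, pretrain_batch = 25L,
                        epochs = 50L, batch = 2L,
                        augment_multiplier = 5L, jitter_sd = 0.5,
                        visit_dropout = 0.1,
                        calibration = c("platt", "identity"),
                        upto_visit = 1L, seed = 1L) {
  stopifnot(hidden >= 1, fusion >= 1, interaction >= 1, lr > 0,
            w_mse >= 0, w_ce >= 0, augment_multiplier >= 1)
  cfg <- list(hidden = as.integer(hidden), fusion = as.integer(fusion),
              interaction = as.integer(interaction), lr = lr,
              decay_rate = decay_rate, decay_steps = decay_steps,
              w_mse = w_mse, w_ce = w_ce,
              pretrain_epochs = as.integer(pretrain_epochs),
              pretrain_batch = as.integer(pretrain_batch),
              epochs = as.integer(epochs), batch = as.integer(batch),
              augment_multiplier = as.integer(augment_multiplier),
              jitter_sd = jitter_sd, visit_dropout = visit_dropout,
              calibration = match.arg(calibration),
              upto_visit = as.integer(upto_visit), seed = as.integer(seed))
  class(cfg) <- "arch_config"
  cfg
}

#' Build an untrained prognosis model
#'
#' Instantiates the recurrent multi-modal architecture for a given encoded
#' feature set: one LSTM branch per dynamic modality (PANSS, PSP, CGI), a
#' fusion layer concatenating the three hidden states with the static
#' features, per-outcome time-distributed interaction layers, softmax
#' outcome heads (SR/FR/CR) and a dense head regressing the next visit's
#' dynamic features.
#'
#' @param arch An [arch_config()].
#' @param ts A `feature_tensors` object (defines the input dimensions).
#' @param zero_init Initialise all weights at zero (diagnostic).
#' @return An object of class `remit_model`.
#' @export
build_model <- function(arch, ts, zero_init = FALSE) {
  stopifnot(inherits(arch, "arch_config"), inherits(ts, "feature_tensors"))
  if (any(vapply(ts$modality_cols, length, integer(1)) == 0))
    stop("schema must define the PANSS, PSP and CGI dynamic modalities",
         call. = FALSE)
  dims <- list(modality_cols = ts$modality_cols,
               d_dyn = dim(ts$dynamic)[3],
               d_static = ncol(ts$static),
               heads = c("sr", "fr", "cr"))
  set.seed(arch$seed)
  params <- init_network_params(dims, arch, zero = zero_init)
  model <- list(params = params, dims = dims, arch = arch,
                adam = adam_init(params), step = 0L,
                calibration = NULL, train_ids = character(0),
                log = data.frame(phase = character(0), epoch = integer(0),
                                 loss = numeric(0)))
  class(model) <- "remit_model"
  model
}

#' @keywords internal
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

#' @export
print.remit_model <- function(x, ...) {
  cat(sprintf("<remit_model> %d parameters, %d optimizer steps, calibration: %s\n",
              n_parameters(x), x$step,
              if (is.null(x$calibration)) "none" else x$calibration$type))
  invisible(x)
}

# Shared mini-batch SGD loop. Continues the model's global step counter so
# the learning-rate schedule spans pretraining and training.
#' @keywords internal
train_loop <- function(model, ts, epochs, batch_size, phase, seed) {
  if (epochs <= 0) return(model)
  arch <- model$arch
  n <- nrow(ts$static)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + batch_size - 1, n)]
      batch <- make_batch(ts, rows)
      res <- net_loss_grad(model$params, batch, model$dims, arch)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite loss at %s epoch %d (step %d)",
                     phase, ep, model$step), call. = FALSE)
      lr <- arch$lr * arch$decay_rate^(model$step / arch$decay_steps)
      up <- adam_step(model$params, res$grads, model$adam, lr)
      model$params <- up$params
      model$adam <- up$state
      model$step <- model$step + 1L
      ep_loss <- ep_loss + res$loss * length(rows)
    }
    model$log <- rbind(model$log,
                       data.frame(phase = phase, epoch = ep,
                                  loss = ep_loss / n))
  }
  model
}

#' Pretrain on a synthesized patient bank
#'
#' Runs `arch$pretrain_epochs` passes at mini-batch `arch$pretrain_batch`
#' over an encoded bank of synthesized patients (generated with a seed
#' disjoint from any evaluation seed), warm-starting the network before the
#' main training phase.
#'
#' @param model A `remit_model`.
#' @param synthetic_bank A `feature_tensors` of synthesized patients.
#' @param arch Optional [arch_config()] override.
#' @return The updated model.
#' @export
pretrain <- function(model, synthetic_bank, arch = model$arch) {
  model$arch <- arch
  train_loop(model, synthetic_bank, arch$pretrain_epochs,
             arch$pretrain_batch, "pretrain", arch$seed + 11L)
}

#' Augment a training set
#'
#' Expands the encoded training set to `augment_multiplier` times its size:
#' the originals are retained bit-identically and each additional copy
#' receives Gaussian jitter on the observed dynamic entries (SD
#' `jitter_sd` instrument points, applied on the scaled representation and
#' clipped back into [0, 1], so raw PANSS values stay within their 1-7
#' bounds) plus random dropout of one non-baseline visit with probability
#' `visit_dropout`. Labels and static features are preserved.
#'
#' @param ts A `feature_tensors` training set.
#' @param arch An [arch_config()].
#' @param seed Integer seed.
#' @return The augmented `feature_tensors`.
#' @export
augment <- function(ts, arch, seed = arch$seed) {
  mult <- arch$augment_multiplier
  if (mult == 1L) return(ts)
  set.seed(seed)
  n <- nrow(ts$static)
  nv <- dim(ts$dynamic)[2]
  pieces <- vector("list", mult)
  pieces[[1]] <- ts
  scale_span <- 6                      # PANSS instrument range 1..7
  for (r in 2:mult) {
    cp <- ts
    jit <- array(stats::rnorm(length(cp$dynamic), 0,
                              arch$jitter_sd / scale_span),
                 dim = dim(cp$dynamic))
    cp$dynamic <- pmin(pmax(cp$dynamic + jit, 0), 1)
    for (i in seq_len(n)) {           # respect the visit mask
      off <- !cp$visit_mask[i, ]
      if (any(off)) cp$dynamic[i, off, ] <- 0
      if (stats::runif(1) < arch$visit_dropout) {
        on <- which(cp$visit_mask[i, ])
        on <- setdiff(on, 1L)
        if (length(on)) {
          drop_v <- on[sample.int(length(on), 1)]
          cp$visit_mask[i, drop_v] <- FALSE
          cp$dynamic[i, drop_v, ] <- 0
        }
      }
    }
    pieces[[r]] <- cp
  }
  out <- ts
  out$static <- do.call(rbind, lapply(pieces, `[[`, "static"))
  dyn <- array(0, dim = c(n * mult, nv, dim(ts$dynamic)[3]),
               dimnames = dimnames(ts$dynamic))
  for (r in seq_len(mult))
    dyn[((r - 1) * n + 1):(r * n), , ] <- pieces[[r]]$dynamic
  out$dynamic <- dyn
  out$visit_mask <- do.call(rbind, lapply(pieces, `[[`, "visit_mask"))
  out$labels <- lapply(ts$labels, function(x) rep(x, mult))
  out$patient_id <- rep(ts$patient_id, mult)
  out$site_id <- rep(ts$site_id, mult)
  out
}

#' Train the prognosis model
#'
#' Optimises the multi-objective loss `w_mse * MSE(next-visit scores) +
#' w_ce * CE(outcome heads)` with Adam and the exponential learning-rate
#' schedule, for `arch$epochs` epochs at mini-batch `arch$batch`.
#' Deterministic given the architecture seed.
#'
#' @param model A `remit_model` (possibly pretrained).
#' @param train_set An encoded (optionally augmented) `feature_tensors`.
#' @param arch Optional [arch_config()] override.
#' @return The trained (uncalibrated) model.
#' @export
train_model <- function(model, train_set, arch = model$arch) {
  model$arch <- arch
  model$train_ids <- unique(train_set$patient_id)
  train_loop(model, train_set, arch$epochs, arch$batch, "train",
             arch$seed + 23L)
}

#' Calibrate the symptomatic-remission probabilities
#'
#' Fits a monotone Platt map `p = plogis(a + b * logit(raw))` (b
#' constrained non-negative; the identity map is the member a = 0, b = 1)
#' from raw SR scores to calibrated probabilities on a
#' validation split disjoint from the training rows. Ranking — hence AUC —
#' is unchanged. Degenerate splits (a single outcome class, or a fitted
#' non-positive slope) fall back to the identity map with a warning.
#'
#' @param model A trained `remit_model`.
#' @param validation_split A `feature_tensors` of held-out rows.
#' @return The model with `$calibration` installed.
#' @export
calibrate <- function(model, validation_split) {
  raw <- predict_remission_prob(model, validation_split,
                                calibrated = FALSE)
  y <- validation_split$labels$remission_sr
  if (model$arch$calibration == "identity" || length(unique(y)) < 2) {
    if (length(unique(y)) < 2)
      warning("single-class validation split: identity calibration installed")
    model$calibration <- list(type = "identity")
    return(model)
  }
  lraw <- stats::qlogis(pmin(pmax(raw, 1e-6), 1 - 1e-6))
  fit <- suppressWarnings(stats::glm(y ~ lraw, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co[2] <= 0) {
    warning("non-monotone Platt fit: identity calibration installed")
    model$calibration <- list(type = "identity")
  } else {
    model$calibration <- list(type = "platt",
                              a = unname(co[1]), b = unname(co[2]))
  }
  model
}

#' @keywords internal
apply_calibration <- function(model, raw) {
  cal <- model$calibration
  if (is.null(cal) || cal$type == "identity") return(raw)
  lraw <- stats::qlogis(pmin(pmax(raw, 1e-6), 1 - 1e-6))
  stats::plogis(cal$a + cal$b * lraw)
}

#' Predict the probability of symptomatic remission
#'
#' Runs the network over visits 1..`upto_visit` and returns the (optionally
#' calibrated) SR-head probability at the last consumed visit.
#'
#' @param model A trained `remit_model`.
#' @param ts A `feature_tensors` object (any number of rows).
#' @param upto_visit Visit index fed at prediction time (1 = baseline);
#'   defaults to the architecture's `upto_visit`.
#' @param calibrated Apply the fitted calibration map.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_remission_prob <- function(model, ts,
                                   upto_visit = model$arch$upto_visit,
                                   calibrated = TRUE) {
  stopifnot(inherits(model, "remit_model"))
  nv <- dim(ts$dynamic)[2]
  if (upto_visit < 1 || upto_visit > nv)
    stop(sprintf("upto_visit must lie in 1..%d", nv), call. = FALSE)
  batch <- make_batch(ts)
  fw <- net_forward(model$params, batch, model$dims, model$arch,
                    upto = upto_visit)
  raw <- fw$probs[[paste0("sr", upto_visit)]][, 2]
  if (calibrated) apply_calibration(model, raw) else raw
}
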