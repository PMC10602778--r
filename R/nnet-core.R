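# Recurrent multi-modal network core: modality-specific LSTMs over the
# visit sequence, a fusion layer joining their hidden states with the
# static features, per-outcome time-distributed interaction layers, softmax
# classification heads (symptomatic / functional / clinical remission) and
# a dense regression head predicting the next visit's scaled dynamic
# features. Written in vectorised base R with analytic backpropagation;
# gradients are verified against central differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' @keywords internal
init_network_params <- function(dims, arch, zero = FALSE) {
  H <- arch$hidden; Fw <- arch$fusion; Iw <- arch$interaction
  mk <- function(a, b) if (zero) matrix(0, a, b) else glorot(a, b)
  p <- list()
  for (m in names(dims$modality_cols)) {
    d <- length(dims$modality_cols[[m]])
    p[[paste0("Wx_", m)]] <- mk(d, 4 * H)
    p[[paste0("Wh_", m)]] <- mk(H, 4 * H)
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1          # forget-gate bias
    p[[paste0("b_", m)]] <- if (zero) rep(0, 4 * H) else b
  }
  nmod <- length(dims$modality_cols)
  p$Wf <- mk(nmod * H + dims$d_static, Fw)
  p$bf <- rep(0, Fw)
  for (k in dims$heads) {
    p[[paste0("Wi_", k)]] <- mk(Fw, Iw)
    p[[paste0("bi_", k)]] <- rep(0, Iw)
    p[[paste0("Wo_", k)]] <- mk(Iw, 2)
    p[[paste0("bo_", k)]] <- rep(0, 2)
  }
  p$Wi_reg <- mk(Fw, Iw)
  p$bi_reg <- rep(0, Iw)
  p$Wo_reg <- mk(Iw, dims$d_dyn)
  p$bo_reg <- rep(0, dims$d_dyn)
  p
}

# Forward pass. batch: list(S [B x Ds], dyn [list of T matrices B x Dd],
# mask [B x T]). Returns per-timestep head probabilities, regression
# outputs and the cache needed for the backward pass.
#' @keywords internal
net_forward <- function(params, batch, dims, arch, upto = NULL) {
  H <- arch$hidden
  B <- nrow(batch$S)
  Tn <- if (is.null(upto)) length(batch$dyn) else upto
  mods <- names(dims$modality_cols)
  cache <- list(h = list(), gates = list(), c = list(), x = list())
  hprev <- cprev <- lapply(mods, function(m) matrix(0, B, H))
  names(hprev) <- names(cprev) <- mods
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    for (m in mods) {
      x <- batch$dyn[[t]][, dims$modality_cols[[m]], drop = FALSE]
      a <- x %*% params[[paste0("Wx_", m)]] +
        hprev[[m]] %*% params[[paste0("Wh_", m)]]
      a <- sweep(a, 2, params[[paste0("b_", m)]], "+")
      i <- sigmoid(a[, 1:H, drop = FALSE])
      f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
      o <- sigmoid(a[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
      cnew <- f * cprev[[m]] + i * g
      tc <- tanh(cnew)
      h <- o * tc
      cache$x[[paste0(m, t)]] <- x
      cache$gates[[paste0(m, t)]] <- list(i = i, f = f, o = o, g = g,
                                          cprev = cprev[[m]], tc = tc)
      cache$h[[paste0(m, t)]] <- hprev[[m]]
      hprev[[m]] <- h
      cprev[[m]] <- cnew
    }
    hs[[t]] <- do.call(cbind, lapply(mods, function(m) hprev[[m]]))
  }

  probs <- list(); acts <- list(); fus <- list(); reg <- list(); regact <- list()
  for (t in seq_len(Tn)) {
    Ct <- cbind(hs[[t]], batch$S)
    Upre <- sweep(Ct %*% params$Wf, 2, params$bf, "+")
    U <- pmax(Upre, 0)
    fus[[t]] <- list(C = Ct, Upre = Upre, U = U)
    for (k in dims$heads) {
      Apre <- sweep(U %*% params[[paste0("Wi_", k)]], 2,
                    params[[paste0("bi_", k)]], "+")
      A <- pmax(Apre, 0)
      logits <- sweep(A %*% params[[paste0("Wo_", k)]], 2,
                      params[[paste0("bo_", k)]], "+")
      mx <- apply(logits, 1, max)
      ex <- exp(logits - mx)
      P <- ex / rowSums(ex)
      probs[[paste0(k, t)]] <- P
      acts[[paste0(k, t)]] <- list(Apre = Apre, A = A)
    }
    Rpre <- sweep(U %*% params$Wi_reg, 2, params$bi_reg, "+")
    Ra <- pmax(Rpre, 0)
    reg[[t]] <- sweep(Ra %*% params$Wo_reg, 2, params$bo_reg, "+")
    regact[[t]] <- list(Rpre = Rpre, Ra = Ra)
  }
  list(probs = probs, reg = reg, cache = cache, fus = fus, acts = acts,
       regact = regact, Tn = Tn, B = B)
}

# Multi-objective loss: weighted categorical cross-entropy of the outcome
# heads at every observed visit plus weighted MSE of the next-visit
# regression at every step whose successor visit is observed.
#' @keywords internal
net_loss_grad <- function(params, batch, dims, arch, forward_only = FALSE) {
  fw <- net_forward(params, batch, dims, arch)
  Tn <- fw$Tn; B <- fw$B
  mask <- batch$mask[, seq_len(Tn), drop = FALSE]
  heads <- dims$heads
  active_heads <- heads[vapply(heads, function(k)
    !is.null(batch$labels[[k]]), logical(1))]

  n_cls <- sum(mask)
  ce <- 0
  dlogits <- list()
  for (k in active_heads) {
    y <- batch$labels[[k]]
    for (t in seq_len(Tn)) {
      P <- fw$probs[[paste0(k, t)]]
      pick <- cbind(seq_len(B), y + 1L)
      ll <- -log(pmax(P[pick], 1e-12)) * mask[, t]
      ce <- ce + sum(ll)
      if (!forward_only) {
        Y <- matrix(0, B, 2); Y[pick] <- 1
        dlogits[[paste0(k, t)]] <- (P - Y) * mask[, t] /
          (n_cls * length(active_heads))
      }
    }
  }
  ce <- if (n_cls > 0 && length(active_heads)) ce / (n_cls * length(active_heads)) else 0

  mse <- 0
  dreg <- vector("list", Tn)
  nv_pairs <- 0
  d_dyn <- dims$d_dyn
  for (t in seq_len(Tn - 1)) {
    valid <- mask[, t] & mask[, t + 1]
    nv_pairs <- nv_pairs + sum(valid)
  }
  for (t in seq_len(Tn)) dreg[[t]] <- matrix(0, B, d_dyn)
  if (nv_pairs > 0) {
    for (t in seq_len(Tn - 1)) {
      valid <- (mask[, t] & mask[, t + 1]) * 1
      err <- (fw$reg[[t]] - batch$dyn[[t + 1]]) * valid
      mse <- mse + sum(err^2)
      if (!forward_only)
        dreg[[t]] <- 2 * err / (nv_pairs * d_dyn)
    }
    mse <- mse / (nv_pairs * d_dyn)
  }

  loss <- arch$w_ce * ce + arch$w_mse * mse
  if (forward_only)
    return(list(loss = loss, ce = ce, mse = mse, probs = fw$probs))
  if (!is.finite(loss))   # caller aborts; gradients would be garbage anyway
    return(list(loss = loss, ce = ce, mse = mse, grads = NULL))

  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  H <- arch$hidden
  mods <- names(dims$modality_cols)
  nmod <- length(mods)
  dh_top <- vector("list", Tn)   # gradient w.r.t. concatenated hidden states

  for (t in seq_len(Tn)) {
    U <- fw$fus[[t]]$U
    dU <- matrix(0, B, ncol(U))
    for (k in active_heads) {
      dl <- dlogits[[paste0(k, t)]] * arch$w_ce
      A <- fw$acts[[paste0(k, t)]]$A
      Apre <- fw$acts[[paste0(k, t)]]$Apre
      grads[[paste0("Wo_", k)]] <- grads[[paste0("Wo_", k)]] + crossprod(A, dl)
      grads[[paste0("bo_", k)]] <- grads[[paste0("bo_", k)]] + colSums(dl)
      dA <- dl %*% t(params[[paste0("Wo_", k)]])
      dApre <- dA * (Apre > 0)
      grads[[paste0("Wi_", k)]] <- grads[[paste0("Wi_", k)]] + crossprod(U, dApre)
      grads[[paste0("bi_", k)]] <- grads[[paste0("bi_", k)]] + colSums(dApre)
      dU <- dU + dApre %*% t(params[[paste0("Wi_", k)]])
    }
    dR <- dreg[[t]] * arch$w_mse
    if (any(dR != 0)) {
      Ra <- fw$regact[[t]]$Ra
      Rpre <- fw$regact[[t]]$Rpre
      grads$Wo_reg <- grads$Wo_reg + crossprod(Ra, dR)
      grads$bo_reg <- grads$bo_reg + colSums(dR)
      dRa <- dR %*% t(params$Wo_reg)
      dRpre <- dRa * (Rpre > 0)
      grads$Wi_reg <- grads$Wi_reg + crossprod(U, dRpre)
      grads$bi_reg <- grads$bi_reg + colSums(dRpre)
      dU <- dU + dRpre %*% t(params$Wi_reg)
    }
    dUpre <- dU * (fw$fus[[t]]$Upre > 0)
    grads$Wf <- grads$Wf + crossprod(fw$fus[[t]]$C, dUpre)
    grads$bf <- grads$bf + colSums(dUpre)
    dC <- dUpre %*% t(params$Wf)
    dh_top[[t]] <- dC[, seq_len(nmod * H), drop = FALSE]
    # gradient w.r.t. statics is not needed
  }

  # backprop through time per modality
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    cols <- ((mi - 1) * H + 1):(mi * H)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    Wh <- params[[paste0("Wh_", m)]]
    Wx <- params[[paste0("Wx_", m)]]
    for (t in rev(seq_len(Tn))) {
      g <- fw$cache$gates[[paste0(m, t)]]
      dh <- dh_top[[t]][, cols, drop = FALSE] + dh_next
      dc <- dc_next + dh * g$o * (1 - g$tc^2)
      do_ <- dh * g$tc
      di <- dc * g$g
      dgg <- dc * g$i
      df <- dc * g$cprev
      dc_next <- dc * g$f
      da <- cbind(di * g$i * (1 - g$i),
                  df * g$f * (1 - g$f),
                  do_ * g$o * (1 - g$o),
                  dgg * (1 - g$g^2))
      grads[[paste0("Wx_", m)]] <- grads[[paste0("Wx_", m)]] +
        crossprod(fw$cache$x[[paste0(m, t)]], da)
      grads[[paste0("Wh_", m)]] <- grads[[paste0("Wh_", m)]] +
        crossprod(fw$cache$h[[paste0(m, t)]], da)
      grads[[paste0("b_", m)]] <- grads[[paste0("b_", m)]] + colSums(da)
      dh_next <- da %*% t(Wh)
    }
  }

  list(loss = loss, ce = ce, mse = mse, grads = grads)
}

#' @keywords internal
adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)

#' @keywords internal
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Slice a feature_tensors object into the batch structure net_forward eats.
#' @keywords internal
make_batch <- function(ts, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(ts$static))
  if (is.logical(rows)) rows <- which(rows)
  Tn <- dim(ts$dynamic)[2]
  dyn <- lapply(seq_len(Tn), function(t) {
    m <- ts$dynamic[rows, t, , drop = FALSE]
    matrix(m, nrow = length(rows),
           dimnames = list(NULL, dimnames(ts$dynamic)[[3]]))
  })
  labels <- list(sr = ts$labels$remission_sr[rows],
                 fr = ts$labels$remission_fr[rows],
                 cr = ts$labels$remission_cr[rows])
  labels <- labels[!vapply(labels, is.null, logical(1))]
  list(S = ts$static[rows, , drop = FALSE],
       dyn = dyn,
       mask = ts$visit_mask[rows, , drop = FALSE],
       labels = labels)
}
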