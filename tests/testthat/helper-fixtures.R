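# Shared fixtures: tiny cohorts and architectures sized for fast unit tests.

small_config <- function(n = 60, seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_enrolled = n,
    funnel_targets = c(phase1 = round(0.9 * n), phase2_continued = round(0.8 * n),
                       phase2_completed = round(0.7 * n),
                       panss_complete = round(0.65 * n)),
    seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# generated once per test run; complete cohort (no attrition/missingness)
full_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(n = 60, seed = 42,
                          funnel_targets = c(60, 60, 60, 60))
      cache <<- list(cfg = cfg, cohort = generate_cohort(cfg))
    }
    cache
  }
})

# a tiny encoded tensor set plus a matching untrained model
tiny_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- full_cohort()
      sch <- feature_schema()
      state <- fit_imputer_scaler(fx$cohort, sch)
      ts <- transform_features(fx$cohort, sch, state)
      arch <- tiny_arch()
      model <- build_model(arch, ts)
      cache <<- list(cohort = fx$cohort, schema = sch, state = state,
                     ts = ts, arch = arch, model = model)
    }
    cache
  }
})

tiny_arch <- function(seed = 3, ...) {
  args <- list(...)
  defaults <- list(hidden = 4L, fusion = 8L, interaction = 4L,
                   epochs = 2L, batch = 16L, lr = 3e-3,
                   pretrain_epochs = 0L, augment_multiplier = 1L,
                   seed = seed)
  do.call(arch_config, utils::modifyList(defaults, args))
}

# training profile used by the pipeline-level experiments: small widths,
# mini-batch 16, annealed learning rate
smoke_arch <- function(seed = 7, ...) {
  args <- list(...)
  defaults <- list(hidden = 8L, fusion = 16L, interaction = 8L,
                   epochs = 16L, batch = 16L, lr = 6e-3,
                   pretrain_epochs = 0L, augment_multiplier = 1L,
                   seed = seed)
  do.call(arch_config, utils::modifyList(defaults, args))
}

# Brute-force Ward linkage: at every step merge the pair of clusters whose
# merge minimally increases the total within-cluster sum of squares.
# Returns the merge sequence as sets of point indices plus the ESS increase
# of each merge. Independent of stats::hclust.
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best_inc - 1e-12) {
          best_inc <- inc
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- list(members = merged, increase = best_inc)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Exhaustive Mann-Whitney U: count wins over all pairs (ties half credit).
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y)
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}
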