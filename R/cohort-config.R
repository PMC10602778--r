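#' Configuration of the synthetic first-episode-psychosis cohort generator
#'
#' Builds the full parameter set of the synthetic cohort generator. Defaults
#' reproduce the published structure of the multicenter antipsychotic
#' switching trial the package emulates: an attrition funnel of
#' 446 enrolled patients, 371 phase-1 completers, 72 phase-2 completers and
#' 66 patients with complete PANSS records; 79% males; mean age 25.3 years;
#' 55% admitted at baseline; DSM classes schizophrenia / schizophreniform /
#' schizoaffective at roughly 67/32/2 percent; mean duration of the current
#' psychotic episode 2.5 months; 32% with (volunteer) work or school; 30%
#' with at least one positive MINI comorbidity item, of which the
#' current-suicidality item alone has 20% prevalence.
#'
#' Comorbidity items are drawn from a Gaussian-copula correlated-binary model
#' with one global comorbidity-burden factor shared by all 48 items plus one
#' extra factor per diagnostic block (mood, suicidality, anxiety, substance,
#' other). Per-item marginal prevalences are exact by construction (probit
#' thresholds); the global factor loading is solved numerically at
#' configuration time so that the probability of at least one positive item
#' equals `p_any_comorbidity`.
#'
#' The remission outcome follows a logistic propensity
#' \deqn{p = \sigma(\beta_0 + \sum_i \beta_i x_i + \gamma s + \epsilon)}
#' with \eqn{x_i \in \{-1, +1\}} the encoded comorbidity items, \eqn{s} the
#' standardized baseline symptom severity and \eqn{\epsilon} Gaussian noise.
#' The `beta` coefficients are generator constructs used to plant known
#' comorbidity effects for parameter-recovery experiments; the defaults
#' plant moderate negative depression effects and moderate positive
#' suicidality / substance-abuse effects, mirroring the qualitative pattern
#' the explanation pipeline is designed to detect.
#'
#' @param n_enrolled Number of enrolled patients.
#' @param funnel_targets Named integer vector with non-increasing elements
#'   `phase1`, `phase2_continued`, `phase2_completed`, `panss_complete`.
#'   The phase-2 continuation count is not part of the published funnel and
#'   defaults to 100.
#' @param p_male,age_mean,age_sd,p_admitted Demographics. The published age
#'   dispersion (0.8) is implausibly small for an SD of a first-episode
#'   sample and is treated as a standard error; `age_sd` defaults to 5.
#' @param dsm_probs Probabilities of the three DSM classes (normalised).
#' @param episode_duration_mean,episode_duration_sd Months; truncated at 0.25.
#' @param p_work_school Fraction with work or school at baseline.
#' @param mini_prevalence Length-48 vector of marginal item prevalences.
#' @param p_any_comorbidity Target probability of at least one positive item.
#' @param block_loading Extra within-block copula loading (0 disables blocks).
#' @param beta0 Baseline log-odds of remission.
#' @param beta Length-48 vector of per-item log-odds coefficients on the
#'   remission propensity (in the -1/+1 item coding).
#' @param gamma Coefficient of standardized baseline severity.
#' @param propensity_noise_sd SD of the Gaussian noise on the linear predictor.
#' @param decay_rate Weekly exponential improvement rate of the symptom
#'   trajectories; 0 selects a static diagnostic mode in which trajectories
#'   stay at baseline (plus observation noise) and remission labels are not
#'   enforced on the final visit.
#' @param trajectory_noise_sd Observation noise (instrument points) at
#'   interior visits.
#' @param missingness_rates Named per-modality probabilities of a static cell
#'   being set missing by [inject_missingness()].
#' @param n_sites Number of recruiting sites (multinomial assignment).
#' @param seed Integer seed; the configuration plus seed fully determines the
#'   generated cohort.
#' @return An object of class `cohort_config` (a list), with the solved
#'   global copula loading stored in `$copula$global_loading`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$funnel_targets
#' @export
cohort_config <- function(n_enrolled = 446L,
                          funnel_targets = c(phase1 = 371L,
                                             phase2_continued = 100L,
                                             phase2_completed = 72L,
                                             panss_complete = 66L),
                          p_male = 0.79,
                          age_mean = 25.3,
                          age_sd = 5,
                          p_admitted = 0.55,
                          dsm_probs = c(schizophrenia = 0.67,
                                        schizophreniform = 0.32,
                                        schizoaffective = 0.01),
                          episode_duration_mean = 2.5,
                          episode_duration_sd = 0.5,
                          p_work_school = 0.32,
                          mini_prevalence = NULL,
                          p_any_comorbidity = 0.30,
                          block_loading = 0.25,
                          beta0 = -0.2,
                          beta = NULL,
                          gamma = -0.5,
                          propensity_noise_sd = 0.5,
                          decay_rate = 0.35,
                          trajectory_noise_sd = 0.5,
                          missingness_rates = c(demographic = 0.05,
                                                diagnostic = 0.03,
                                                lifestyle = 0.05,
                                                somatic = 0.05,
                                                treatment = 0.02,
                                                cdss = 0.05,
                                                swn = 0.05,
                                                mini = 0),
                          n_sites = 8L,
                          seed = 1234L) {
  items <- mini_items()
  if (is.null(mini_prevalence)) {
    mini_prevalence <- rep(0.05, 48)
    mini_prevalence[items$block == "substance"] <- 0.02
    mini_prevalence[11] <- 0.20  # suicidality: current
  }
  stopifnot(length(mini_prevalence) == 48, all(mini_prevalence > 0),
            all(mini_prevalence < 1))
  if (is.null(beta)) {
    beta <- rep(0, 48)
    beta[1] <- -0.5   # major depressive episode: current
    beta[2] <- -0.4   # major depressive episode: recurrent
    beta[8] <- -0.3   # melancholic recurrent
    beta[11] <- 0.5   # suicidality: current
    beta[40] <- 0.5   # substance abuse: past 12 months
  }
  stopifnot(length(beta) == 48)

  funnel_targets <- as.integer(funnel_targets)
  names(funnel_targets) <- c("phase1", "phase2_continued",
                             "phase2_completed", "panss_complete")
  if (any(diff(funnel_targets) > 0L))
    stop("funnel_targets must be non-increasing", call. = FALSE)
  if (n_enrolled < funnel_targets[1L])
    stop("n_enrolled must be >= the phase-1 funnel target", call. = FALSE)

  fracs <- c(p_male, p_admitted, p_work_school, p_any_comorbidity)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (any(missingness_rates < 0 | missingness_rates > 1))
    stop("missingness_rates must lie in [0, 1]", call. = FALSE)

  dsm_probs <- dsm_probs / sum(dsm_probs)

  copula <- calibrate_mini_copula(mini_prevalence, items$block,
                                  p_any = p_any_comorbidity,
                                  block_loading = block_loading)

  cfg <- list(
    n_enrolled = as.integer(n_enrolled),
    funnel_targets = funnel_targets,
    p_male = p_male, age_mean = age_mean, age_sd = age_sd,
    p_admitted = p_admitted, dsm_probs = dsm_probs,
    episode_duration_mean = episode_duration_mean,
    episode_duration_sd = episode_duration_sd,
    p_work_school = p_work_school,
    mini_prevalence = mini_prevalence,
    p_any_comorbidity = p_any_comorbidity,
    copula = copula,
    beta0 = beta0, beta = beta, gamma = gamma,
    propensity_noise_sd = propensity_noise_sd,
    decay_rate = decay_rate,
    trajectory_noise_sd = trajectory_noise_sd,
    missingness_rates = missingness_rates,
    n_sites = as.integer(n_sites),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Solve the global copula loading `a` such that, in the latent factor model
#   X_i = a*g + b*u_{block(i)} + sqrt(1 - a^2 - b^2)*e_i,   X_i ~ N(0,1),
# with item i positive iff X_i > qnorm(1 - p_i), the probability that at
# least one of the 48 items is positive equals p_any. Marginals are exact
# for any loading; only the "any item" rate depends on (a, b).
.copula_cache <- new.env(parent = emptyenv())

#' @keywords internal
calibrate_mini_copula <- function(prevalence, block, p_any, block_loading) {
  key <- paste(c(signif(prevalence, 10), block, signif(p_any, 10),
                 signif(block_loading, 10)), collapse = "|")
  hit <- .copula_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- calibrate_mini_copula_impl(prevalence, block, p_any, block_loading)
  .copula_cache[[key]] <- res
  res
}

#' @keywords internal
calibrate_mini_copula_impl <- function(prevalence, block, p_any, block_loading) {
  z <- stats::qnorm(1 - prevalence)
  blocks <- split(seq_along(prevalence), block)
  b <- block_loading
  if (b < 0 || b >= 1) stop("block_loading must be in [0, 1)", call. = FALSE)

  # quadrature grid for the standard normal factors
  gr <- seq(-6, 6, length.out = 121)
  w <- stats::dnorm(gr) * (gr[2] - gr[1])
  w <- w / sum(w)

  p_none <- function(a) {
    cc <- sqrt(1 - a^2 - b^2)
    # log P(no item in block | g) for each g node, summed over blocks
    log_none_g <- numeric(length(gr))
    for (idx in blocks) {
      # matrix over (g node, u node): log prod_i Phi((z_i - a g - b u)/cc)
      lp <- matrix(0, length(gr), length(gr))
      for (i in idx) {
        lp <- lp + stats::pnorm(outer(z[i] - a * gr, b * gr, "-") / cc,
                                log.p = TRUE)
      }
      # integrate the block factor u
      log_none_g <- log_none_g + log(pmax(exp(lp) %*% w, 1e-300))
    }
    sum(w * exp(log_none_g))
  }

  target_none <- 1 - p_any
  a_max <- sqrt(1 - b^2) - 1e-6
  f <- function(a) p_none(a) - target_none
  if (f(0) > 0) {
    a <- 0  # already fewer comorbid patients than targeted at independence
  } else if (f(a_max) < 0) {
    a <- a_max
  } else {
    a <- stats::uniroot(f, c(0, a_max), tol = 1e-5)$root
  }
  list(global_loading = a, block_loading = b,
       thresholds = z, block = block,
       achieved_p_any = 1 - p_none(a))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_enrolled:", x$n_enrolled, "\n")
  cat("  funnel:", paste(names(x$funnel_targets), x$funnel_targets,
                         sep = "=", collapse = ", "), "\n")
  cat(sprintf("  demographics: male %.0f%%, age %.1f (%.1f), admitted %.0f%%\n",
              100 * x$p_male, x$age_mean, x$age_sd, 100 * x$p_admitted))
  cat(sprintf("  comorbidity: P(any item) target %.2f, achieved %.3f (copula loading %.3f)\n",
              x$p_any_comorbidity, x$copula$achieved_p_any,
              x$copula$global_loading))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
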