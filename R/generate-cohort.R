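#' Generate a synthetic first-episode-psychosis cohort
#'
#' Draws `config$n_enrolled` patients: multicenter site assignment, mixed
#' continuous/categorical/binary baseline features across eight static
#' modalities, 48 correlated binary MINI comorbidity items, a latent
#' remission propensity \eqn{p = \sigma(\beta_0 + \sum_i \beta_i x_i +
#' \gamma s + \epsilon)} (items coded \eqn{x_i = \pm 1}, \eqn{s} the
#' standardized baseline severity), the symptomatic-remission outcome
#' `remission_sr ~ Bernoulli(p)`, and PANSS/PSP/CGI visit trajectories
#' consistent with that outcome (see [simulate_trajectories()]).
#' All patients start with every funnel flag `TRUE`; attrition is applied
#' separately by [apply_attrition_funnel()].
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per patient: identifiers, static
#'   features, MINI items (0/1), visit-suffixed dynamic columns, funnel
#'   flags and the outcomes `remission_sr`, `remission_fr`, `remission_cr`.
#' @examples
#' co <- generate_cohort(cohort_config(n_enrolled = 50, seed = 1))
#' nrow(co)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_enrolled
  set.seed(config$seed)
  items <- mini_items()

  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    site_id = sample.int(config$n_sites, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## --- demographics -------------------------------------------------------
  df$age <- round(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 15), 1)
  df$sex <- stats::rbinom(n, 1, config$p_male)          # 1 = male
  df$race <- sample(c("white", "black", "asian", "other"), n, TRUE,
                    prob = c(0.7, 0.12, 0.1, 0.08))
  df$immigration_status <- stats::rbinom(n, 1, 0.2)
  df$marital_status <- stats::rbinom(n, 1, 0.12)
  df$divorce_status <- stats::rbinom(n, 1, 0.03)
  df$occupation_status <- stats::rbinom(n, 1, config$p_work_school)
  occ_cats <- c("none", "manual", "office", "professional")
  df$occupation_type <- ifelse(df$occupation_status == 1,
                               sample(occ_cats[-1], n, TRUE), "none")
  df$previous_occupation_status <- stats::rbinom(n, 1, 0.55)
  df$previous_occupation_type <- ifelse(df$previous_occupation_status == 1,
                                        sample(occ_cats[-1], n, TRUE), "none")
  df$father_occupation <- sample(occ_cats, n, TRUE, prob = c(0.1, 0.4, 0.3, 0.2))
  df$mother_occupation <- sample(occ_cats, n, TRUE, prob = c(0.25, 0.3, 0.3, 0.15))
  df$years_education <- round(pmax(stats::rnorm(n, 12, 2.5), 6), 1)
  edu_cats <- c("primary", "secondary", "vocational", "university")
  df$highest_education <- sample(edu_cats, n, TRUE, prob = c(0.1, 0.45, 0.3, 0.15))
  df$father_highest_degree <- sample(edu_cats, n, TRUE, prob = c(0.15, 0.4, 0.25, 0.2))
  df$mother_highest_degree <- sample(edu_cats, n, TRUE, prob = c(0.2, 0.4, 0.25, 0.15))
  df$living_status <- stats::rbinom(n, 1, 0.6)          # 1 = lives with others
  df$dwelling <- sample(c("house", "apartment", "institution"), n, TRUE,
                        prob = c(0.45, 0.45, 0.1))
  df$income_source <- sample(c("employment", "benefits", "family"), n, TRUE,
                             prob = c(0.3, 0.35, 0.35))
  df$living_environment <- sample(c("urban", "suburban", "rural"), n, TRUE,
                                  prob = c(0.55, 0.3, 0.15))

  ## --- diagnostics --------------------------------------------------------
  df$dsm_classification <- sample(names(config$dsm_probs), n, TRUE,
                                  prob = config$dsm_probs)
  df$episode_duration <- round(pmax(stats::rnorm(n, config$episode_duration_mean,
                                                 config$episode_duration_sd),
                                    0.25), 2)
  df$hospitalization_status <- stats::rbinom(n, 1, config$p_admitted)
  df$current_psychiatric_treatment <- ifelse(
    df$hospitalization_status == 1, "inpatient",
    sample(c("none", "outpatient"), n, TRUE, prob = c(0.3, 0.7)))
  df$psychosocial_interventions <- stats::rbinom(n, 1, 0.25)
  df$estimated_prognosis <- sample(c("good", "intermediate", "poor"), n, TRUE,
                                   prob = c(0.35, 0.45, 0.2))

  ## --- lifestyle ----------------------------------------------------------
  df$recreational_drugs_history <- stats::rbinom(n, 1, 0.45)
  df$recreational_drugs_since_last_visit <- stats::rbinom(n, 1, 0.15)
  df$caffeine_drinks_per_day <- round(pmax(stats::rnorm(n, 2.5, 1.8), 0), 1)
  df$last_caffeine_drink <- sample(c("today", "yesterday", "earlier"), n, TRUE,
                                   prob = c(0.55, 0.25, 0.2))
  df$drink_alcohol <- stats::rbinom(n, 1, 0.5)
  df$alcoholic_drinks_last_year <- sample(c("none", "monthly", "weekly", "daily"),
                                          n, TRUE, prob = c(0.4, 0.3, 0.25, 0.05))
  df$smoking_status <- stats::rbinom(n, 1, 0.55)

  ## --- somatic ------------------------------------------------------------
  height <- stats::rnorm(n, 176 - 10 * (1 - df$sex), 8)
  weight <- stats::rnorm(n, 74 - 8 * (1 - df$sex), 12)
  df$height <- round(height, 1)
  df$weight <- round(pmax(weight, 40), 1)
  df$waist <- round(pmax(stats::rnorm(n, 84, 11), 55), 1)
  df$hip <- round(pmax(stats::rnorm(n, 96, 9), 65), 1)
  df$bmi <- round(df$weight / (df$height / 100)^2, 1)
  df$systolic_bp <- round(stats::rnorm(n, 122, 12))
  df$diastolic_bp <- round(stats::rnorm(n, 78, 9))
  df$pulse <- round(stats::rnorm(n, 76, 10))
  df$ecg_abnormality <- stats::rbinom(n, 1, 0.06)
  df$last_mealtime <- sample(c("morning", "midday", "evening"), n, TRUE)
  df$last_meal_type <- sample(c("light", "full", "snack"), n, TRUE,
                              prob = c(0.35, 0.45, 0.2))

  ## --- treatment / clinical scales ---------------------------------------
  df$avg_medication_dosage <- round(pmax(stats::rnorm(n, 400, 120), 50))
  for (j in 1:9)
    df[[sprintf("cdss_%02d", j)]] <- pmin(pmax(round(stats::rnorm(n, 0.8, 0.8)), 0), 3)
  for (j in 1:20)
    df[[sprintf("swn_%02d", j)]] <- pmin(pmax(round(stats::rnorm(n, 3.8, 1.1)), 1), 6)

  ## --- MINI comorbidity items (correlated binaries) -----------------------
  mini <- draw_mini_items(n, config)
  df <- cbind(df, as.data.frame(mini))

  ## --- latent severity, remission propensity ------------------------------
  severity <- stats::rnorm(n)
  x <- 2 * mini - 1                                     # -1/+1 coding
  eta <- config$beta0 + drop(x %*% config$beta) +
    config$gamma * severity +
    stats::rnorm(n, 0, config$propensity_noise_sd)
  p_remit <- stats::plogis(eta)
  df$remission_sr <- stats::rbinom(n, 1, p_remit)

  ## --- dynamic trajectories ----------------------------------------------
  traj <- simulate_trajectories_bulk(df$remission_sr, severity, config)
  df <- cbind(df, traj$columns)
  df$remission_fr <- traj$remission_fr
  df$remission_cr <- traj$remission_cr

  df$completed_phase1 <- TRUE
  df$continued_phase2 <- TRUE
  df$completed_phase2 <- TRUE
  df$panss_complete <- TRUE

  attr(df, "severity") <- severity
  df
}

#' @keywords internal
draw_mini_items <- function(n, config) {
  cop <- config$copula
  a <- cop$global_loading
  b <- cop$block_loading
  cc <- sqrt(1 - a^2 - b^2)
  blocks <- unique(cop$block)
  g <- stats::rnorm(n)
  u <- matrix(stats::rnorm(n * length(blocks)), n,
              dimnames = list(NULL, blocks))
  e <- matrix(stats::rnorm(n * 48), n, 48)
  out <- matrix(0L, n, 48, dimnames = list(NULL, mini_item_names()))
  for (i in seq_len(48)) {
    xi <- a * g + b * u[, cop$block[i]] + cc * e[, i]
    out[, i] <- as.integer(xi > cop$thresholds[i])
  }
  out
}

#' Simulate symptom-scale trajectories for one patient
#'
#' Draws the PANSS (30 items, 1-7), PSP (5 domains, 0-100) and CGI
#' (severity and improvement, 1-7) series over the six scheduled visits
#' (baseline, weeks 2, 3, 5, 6, 8). Items decay exponentially from a
#' severity-linked baseline toward an endpoint drawn conditional on the
#' patient's remission status: remitters end with all eight
#' symptomatic-remission criterion items at 3 or below, non-remitters
#' violate at least one. With `decay_rate = 0` the generator switches to a
#' static diagnostic mode: every visit equals the baseline plus observation
#' noise and no endpoint rule is enforced.
#'
#' @param patient_row A single cohort row carrying `remission_sr`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this patient's draws.
#' @param severity Standardized baseline severity; drawn if `NULL`.
#' @return A named list of visit-suffixed dynamic values.
#' @export
simulate_trajectories <- function(patient_row, config, seed,
                                  severity = NULL) {
  stopifnot(!is.null(patient_row$remission_sr))
  set.seed(seed)
  if (is.null(severity)) severity <- stats::rnorm(1)
  res <- simulate_trajectories_bulk(patient_row$remission_sr, severity, config)
  as.list(res$columns[1, ])
}

# Vectorised trajectory engine shared by generate_cohort() and
# simulate_trajectories(). Final-visit values of remitters/non-remitters
# are exact w.r.t. the severity rule when decay_rate > 0.
#' @keywords internal
simulate_trajectories_bulk <- function(remission, severity, config) {
  n <- length(remission)
  k <- config$decay_rate
  noise_sd <- config$trajectory_noise_sd
  weeks <- visit_weeks()
  nv <- n_visits()
  schema <- feature_schema()
  panss_names <- schema$name[schema$modality == "panss"]
  crit <- match(andreasen_items(), panss_names)

  # baseline PANSS: per-item base mean by subscale, shifted by severity
  base_mu <- c(rep(4.0, 7), rep(3.6, 7), rep(3.2, 16))
  B <- matrix(base_mu, n, 30, byrow = TRUE) + 0.8 * severity +
    matrix(stats::rnorm(n * 30, 0, 0.9), n, 30)
  B <- pmin(pmax(round(B), 1), 7)

  # endpoint: improvement fraction depends on remission
  imp <- ifelse(remission == 1,
                stats::runif(n, 0.55, 0.9),
                stats::runif(n, 0.1, 0.45))
  F_ <- 1 + (1 - imp) * (B - 1) + matrix(stats::rnorm(n * 30, 0, 0.5), n, 30)
  F_ <- pmin(pmax(round(F_), 1), 7)

  if (k > 0) {
    # enforce the severity rule exactly at the final visit
    rem <- remission == 1
    if (any(rem)) F_[rem, crit] <- pmin(F_[rem, crit, drop = FALSE], 3L)
    nonrem <- which(remission == 0)
    if (length(nonrem)) {
      ok <- apply(F_[nonrem, crit, drop = FALSE], 1, max) >= 4
      fix <- nonrem[!ok]
      if (length(fix)) {
        j <- sample(crit, length(fix), replace = TRUE)
        F_[cbind(fix, j)] <- sample(4:6, length(fix), replace = TRUE)
      }
    }
  }

  # interpolation weights: 1 at baseline, 0 at the final visit
  if (k > 0) {
    wts <- (exp(-k * weeks) - exp(-k * max(weeks))) /
      (1 - exp(-k * max(weeks)))
  } else {
    wts <- rep(1, nv)
  }

  panss <- vector("list", nv)
  for (v in seq_len(nv)) {
    V <- F_ + (B - F_) * wts[v]
    if (v > 1 && v < nv) V <- V + matrix(stats::rnorm(n * 30, 0, noise_sd), n, 30)
    if (k == 0 && v > 1) V <- B + matrix(stats::rnorm(n * 30, 0, noise_sd), n, 30)
    panss[[v]] <- pmin(pmax(round(V), 1), 7)
  }
  if (k > 0) {
    panss[[1]] <- B
    panss[[nv]] <- F_
  }

  # PSP: upward trend for remitters
  P0 <- pmin(pmax(round(matrix(stats::rnorm(n * 5, 45, 10), n, 5)), 10), 90)
  P1 <- ifelse(remission == 1,
               stats::rnorm(n, 70, 8), stats::rnorm(n, 50, 10))
  P1 <- pmin(pmax(round(P1 + matrix(stats::rnorm(n * 5, 0, 4), n, 5)), 0), 100)
  psp <- vector("list", nv)
  for (v in seq_len(nv)) {
    V <- P1 + (P0 - P1) * wts[v]
    if (v > 1 && v < nv) V <- V + matrix(stats::rnorm(n * 5, 0, 3), n, 5)
    if (k == 0 && v > 1) V <- P0 + matrix(stats::rnorm(n * 5, 0, 3), n, 5)
    psp[[v]] <- pmin(pmax(round(V), 0), 100)
  }
  if (k > 0) {
    psp[[1]] <- P0
    psp[[nv]] <- P1
  }

  # CGI: severity tracks the mean PANSS item score; improvement tracks the
  # relative drop of the PANSS total from baseline (4 = no change)
  cgi_sev <- vector("list", nv)
  cgi_imp <- vector("list", nv)
  total0 <- rowSums(panss[[1]])
  for (v in seq_len(nv)) {
    m <- rowMeans(panss[[v]])
    cgi_sev[[v]] <- pmin(pmax(round(m + stats::rnorm(n, 0, 0.3)), 1), 7)
    rel_drop <- (total0 - rowSums(panss[[v]])) / pmax(total0 - 30, 1)
    cgi_imp[[v]] <- pmin(pmax(round(4 - 4 * rel_drop), 1), 7)
  }

  cols <- list()
  dyn_names <- schema$name[schema$dynamic]
  for (v in seq_len(nv)) {
    mat <- cbind(panss[[v]], psp[[v]], cgi_sev[[v]], cgi_imp[[v]])
    colnames(mat) <- paste0(dyn_names, "_v", v)
    cols[[v]] <- mat
  }
  columns <- as.data.frame(do.call(cbind, cols))

  list(columns = columns,
       remission_fr = as.integer(rowMeans(psp[[nv]]) >= 60),
       remission_cr = as.integer(cgi_sev[[nv]] <= 3))
}

#' Apply the study attrition funnel
#'
#' Sets the four funnel flags by seeded assignment so that stage counts
#' exactly match `config$funnel_targets`: phase-1 completion, phase-2
#' continuation, phase-2 completion and PANSS completeness (the latter is
#' set `FALSE` for exactly `phase2_completed - panss_complete` phase-2
#' completers, whose PANSS records also receive missing cells). Visits a
#' patient never attended are blanked: patients who did not complete
#' phase 1 keep the baseline and week-2 visits, phase-1-only patients keep
#' visits through week 5, phase-2 dropouts through week 6.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param config The [cohort_config()] used to generate it.
#' @return The cohort with funnel flags and visit availability applied.
#' @export
apply_attrition_funnel <- function(cohort, config) {
  tg <- config$funnel_targets
  n <- nrow(cohort)
  if (tg[["phase1"]] > n)
    stop("funnel target exceeds available patients", call. = FALSE)
  set.seed(config$seed + 1L)

  resample <- function(x, size) x[sample.int(length(x), size)]
  idx_p1 <- sample.int(n, tg[["phase1"]])
  idx_cont <- resample(idx_p1, tg[["phase2_continued"]])
  idx_p2 <- resample(idx_cont, tg[["phase2_completed"]])
  idx_incomplete <- resample(idx_p2, tg[["phase2_completed"]] - tg[["panss_complete"]])

  cohort$completed_phase1 <- seq_len(n) %in% idx_p1
  cohort$continued_phase2 <- seq_len(n) %in% idx_cont
  cohort$completed_phase2 <- seq_len(n) %in% idx_p2
  cohort$panss_complete <- !(seq_len(n) %in% idx_incomplete)

  schema <- feature_schema()
  dyn <- schema$name[schema$dynamic]
  blank_visits <- function(rows, visits) {
    for (v in visits)
      cohort[rows, paste0(dyn, "_v", v)] <<- NA
  }
  blank_visits(which(!cohort$completed_phase1), 3:6)
  blank_visits(which(cohort$completed_phase1 & !cohort$continued_phase2), 5:6)
  blank_visits(which(cohort$continued_phase2 & !cohort$completed_phase2), 6)

  # phase-2 completers without complete PANSS: punch holes in their records
  for (i in idx_incomplete) {
    nmiss <- sample(1:3, 1)
    cols <- paste0(sample(schema$name[schema$modality == "panss"], nmiss),
                   "_v", sample(2:6, nmiss, replace = TRUE))
    cohort[i, cols] <- NA
  }
  cohort
}

#' Inject static missingness
#'
#' Independently sets eligible static cells missing at the per-modality
#' rates in `config$missingness_rates`. Outcomes, funnel flags, identifiers
#' and the PANSS records of PANSS-complete patients are never touched.
#'
#' @param cohort A cohort table.
#' @param config A [cohort_config()].
#' @return The cohort with missing cells injected (seeded, reproducible).
#' @export
inject_missingness <- function(cohort, config) {
  rates <- config$missingness_rates
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  set.seed(config$seed + 2L)
  schema <- feature_schema()
  for (mod in names(rates)) {
    r <- rates[[mod]]
    if (r <= 0) next
    cols <- schema$name[schema$modality == mod & !schema$dynamic]
    for (col in cols) {
      hit <- stats::runif(nrow(cohort)) < r
      if (any(hit)) cohort[hit, col] <- NA
    }
  }
  cohort
}
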