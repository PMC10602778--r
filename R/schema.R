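#' Default feature schema of the synthetic cohort
#'
#' Declares every patient-level feature the generator produces and the
#' preprocessing layer consumes: 122 static baseline features across eight
#' modalities (demographic, diagnostic, lifestyle, somatic, treatment,
#' CDSS, SWN, MINI) and 37 dynamic features across three repeatedly
#' administered instruments (30 PANSS items, 5 PSP domains, 2 CGI scales)
#' observed at up to six visits (baseline and weeks 2, 3, 5, 6, 8).
#' Dynamic features appear once in the schema with `dynamic = TRUE`; in the
#' cohort table they expand to visit-suffixed columns (`_v1` ... `_v6`).
#'
#' @param target_total Optional expected total feature count; if supplied,
#'   an error is raised when the schema size differs. The published feature
#'   count is internally inconsistent (the per-modality counts do not sum to
#'   the quoted total), so no default check is enforced.
#' @return A data.frame with columns `name`, `modality`, `value_type`
#'   (`"continuous"`, `"categorical"` or `"binary"`), `dynamic` (logical)
#'   and `categories` (list column; `NULL` for non-categorical features).
#' @examples
#' sch <- feature_schema()
#' table(sch$modality)
#' @export
feature_schema <- function(target_total = NULL) {
  f <- function(name, modality, type, categories = NULL)
    data.frame(name = name, modality = modality, value_type = type,
               dynamic = FALSE, stringsAsFactors = FALSE,
               categories = I(rep(list(categories), length(name))))

  occ_cats <- c("none", "manual", "office", "professional")
  edu_cats <- c("primary", "secondary", "vocational", "university")

  demographic <- rbind(
    f("age", "demographic", "continuous"),
    f("sex", "demographic", "binary"),
    f("race", "demographic", "categorical", c("white", "black", "asian", "other")),
    f("immigration_status", "demographic", "binary"),
    f("marital_status", "demographic", "binary"),
    f("divorce_status", "demographic", "binary"),
    f("occupation_status", "demographic", "binary"),
    f("occupation_type", "demographic", "categorical", occ_cats),
    f("previous_occupation_status", "demographic", "binary"),
    f("previous_occupation_type", "demographic", "categorical", occ_cats),
    f("father_occupation", "demographic", "categorical", occ_cats),
    f("mother_occupation", "demographic", "categorical", occ_cats),
    f("years_education", "demographic", "continuous"),
    f("highest_education", "demographic", "categorical", edu_cats),
    f("father_highest_degree", "demographic", "categorical", edu_cats),
    f("mother_highest_degree", "demographic", "categorical", edu_cats),
    f("living_status", "demographic", "binary"),
    f("dwelling", "demographic", "categorical", c("house", "apartment", "institution")),
    f("income_source", "demographic", "categorical", c("employment", "benefits", "family")),
    f("living_environment", "demographic", "categorical", c("urban", "suburban", "rural"))
  )
  diagnostic <- rbind(
    f("dsm_classification", "diagnostic", "categorical",
      c("schizophrenia", "schizophreniform", "schizoaffective")),
    f("episode_duration", "diagnostic", "continuous"),
    f("current_psychiatric_treatment", "diagnostic", "categorical",
      c("none", "outpatient", "inpatient")),
    f("psychosocial_interventions", "diagnostic", "binary"),
    f("estimated_prognosis", "diagnostic", "categorical",
      c("good", "intermediate", "poor")),
    f("hospitalization_status", "diagnostic", "binary")
  )
  lifestyle <- rbind(
    f("recreational_drugs_history", "lifestyle", "binary"),
    f("recreational_drugs_since_last_visit", "lifestyle", "binary"),
    f("caffeine_drinks_per_day", "lifestyle", "continuous"),
    f("last_caffeine_drink", "lifestyle", "categorical",
      c("today", "yesterday", "earlier")),
    f("drink_alcohol", "lifestyle", "binary"),
    f("alcoholic_drinks_last_year", "lifestyle", "categorical",
      c("none", "monthly", "weekly", "daily")),
    f("smoking_status", "lifestyle", "binary")
  )
  somatic <- rbind(
    f(c("height", "weight", "waist", "hip", "bmi", "systolic_bp",
        "diastolic_bp", "pulse"), "somatic", "continuous"),
    f("ecg_abnormality", "somatic", "binary"),
    f("last_mealtime", "somatic", "categorical",
      c("morning", "midday", "evening")),
    f("last_meal_type", "somatic", "categorical",
      c("light", "full", "snack"))
  )
  treatment <- f("avg_medication_dosage", "treatment", "continuous")
  cdss <- f(sprintf("cdss_%02d", 1:9), "cdss", "continuous")
  swn <- f(sprintf("swn_%02d", 1:20), "swn", "continuous")
  mini <- f(mini_item_names(), "mini", "binary")

  panss_names <- c(sprintf("panss_p%d", 1:7), sprintf("panss_n%d", 1:7),
                   sprintf("panss_g%d", 1:16))
  dyn <- rbind(
    f(panss_names, "panss", "continuous"),
    f(sprintf("psp_%d", 1:5), "psp", "continuous"),
    f(c("cgi_severity", "cgi_improvement"), "cgi", "continuous")
  )
  dyn$dynamic <- TRUE

  sch <- rbind(demographic, diagnostic, lifestyle, somatic, treatment,
               cdss, swn, mini, dyn)
  rownames(sch) <- NULL
  n_mini <- sum(sch$modality == "mini" & sch$value_type == "binary")
  stopifnot(n_mini == 48L)
  if (!is.null(target_total) && nrow(sch) != target_total)
    stop(sprintf("schema holds %d features, expected %d", nrow(sch),
                 target_total), call. = FALSE)
  sch
}

#' @keywords internal
visit_weeks <- function() c(0, 2, 3, 5, 6, 8)

#' @keywords internal
n_visits <- function() 6L

#' @keywords internal
dynamic_column_names <- function(schema = feature_schema()) {
  dyn <- schema$name[schema$dynamic]
  unlist(lapply(seq_len(n_visits()),
                function(v) paste0(dyn, "_v", v)))
}

#' Write a cohort and its schema to disk
#'
#' The cohort is serialized as a tidy CSV (one row per patient, dynamic
#' features as visit-suffixed columns); the schema as a JSON file declaring
#' each column's modality, value type, dynamic flag and visit index.
#'
#' @param cohort A cohort table from [generate_cohort()].
#' @param path Path of the CSV file to write; the schema is written next to
#'   it with the extension `.schema.json`.
#' @param schema Feature schema (defaults to [feature_schema()]).
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path, schema = feature_schema()) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  entries <- schema
  entries$categories <- lapply(entries$categories, function(x) x)
  schema_path <- sub("\\.csv$", "", path)
  schema_path <- paste0(schema_path, ".schema.json")
  jsonlite::write_json(
    list(visits = visit_weeks(),
         features = entries),
    schema_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(cohort = path, schema = schema_path))
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path Path of the cohort CSV.
#' @return The cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("completed_phase1", "continued_phase2", "completed_phase2",
                "panss_complete")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
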