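#' Validate a pipeline run configuration
#'
#' Fills defaults and checks a run configuration read from a YAML file (or
#' given as a list). The configuration drives [run_pipeline()]: cohort
#' generator parameters, architecture parameters, cross-validation scheme,
#' explanation, inference and clustering settings, output directory and the
#' global seed.
#'
#' @param x Path to a YAML file, or a (possibly partial) configuration list.
#' @return A validated configuration list of class `run_config`.
#' @export
validate_run_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  defaults <- list(
    cohort = list(),
    arch = list(),
    cv = list(scheme = "kfold", k = 10L, repetitions = 20L),
    explain = list(upto_visit = 1L),
    inference = list(B = 200L, alpha = 0.05),
    clustering = list(k = 2L),
    out_dir = "remitcf-run",
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, x)
  check <- function(ok, key) if (!ok)
    stop(sprintf("invalid configuration value for '%s'", key), call. = FALSE)
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  check(cfg$cv$k >= 2, "cv.k")
  check(cfg$cv$repetitions >= 1, "cv.repetitions")
  check(cfg$cv$scheme %in% c("kfold", "site"), "cv.scheme")
  check(cfg$explain$upto_visit >= 1 && cfg$explain$upto_visit <= n_visits(),
        "explain.upto_visit")
  check(cfg$inference$B >= 1, "inference.B")
  check(cfg$inference$alpha > 0 && cfg$inference$alpha < 1, "inference.alpha")
  check(cfg$clustering$k >= 2, "clustering.k")
  class(cfg) <- c("run_config", "list")
  cfg
}

# Global-seed fan-out: stage i receives (seed mod 2e7) * 100 + i, keeping
# derived seeds well below 2^31 while making stages independently rerunnable.
#' @keywords internal
stage_seed <- function(seed, stage) as.integer((seed %% 20000000) * 100 + stage)

#' Run the full analysis pipeline
#'
#' Executes the four-step pipeline end to end: (1) simulate the cohort and
#' apply attrition and missingness, (2) filter the analysis sample and
#' cross-validate the remission classifier (training, calibration,
#' prediction), (3) generate single-flip counterfactual importance maps
#' for every out-of-fold patient, and (4) summarise group-level
#' comorbidity effects and cluster the per-patient maps. All stage outputs
#' are written as CSV under `config$out_dir` together with a JSON run
#' manifest; rerunning with the same configuration reproduces identical
#' outputs.
#'
#' @param config A [validate_run_config()] result, configuration list or
#'   YAML path.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(if (inherits(config, "run_config")) unclass(config) else config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifest <- list(config = unclass(cfg),
                   seeds = list(), counts = list(), files = character(0))

  ## stage 1: simulate ------------------------------------------------------
  cohort <- stage("simulate", {
    s <- stage_seed(cfg$seed, 1L)
    manifest$seeds$simulate <- s
    ccfg <- do.call(cohort_config, utils::modifyList(cfg$cohort,
                                                     list(seed = s)))
    co <- generate_cohort(ccfg)
    co <- apply_attrition_funnel(co, ccfg)
    co <- inject_missingness(co, ccfg)
    write_cohort(co, outfile("cohort.csv"))
    co
  })
  manifest$counts$cohort <- nrow(cohort)
  manifest$files <- c(manifest$files, "cohort.csv", "cohort.schema.json")

  ## stage 2: preprocess ----------------------------------------------------
  eligible <- stage("preprocess", {
    el <- filter_eligible(cohort)
    utils::write.csv(el, outfile("eligible.csv"), row.names = FALSE, na = "")
    el
  })
  manifest$counts$eligible <- nrow(eligible)
  manifest$files <- c(manifest$files, "eligible.csv")

  ## stage 3: cross-validated training + explanation ------------------------
  cv <- stage("train_explain", {
    arch <- do.call(arch_config,
                    utils::modifyList(cfg$arch,
                                      list(seed = stage_seed(cfg$seed, 2L),
                                           upto_visit = cfg$explain$upto_visit)))
    manifest$seeds$cv <- stage_seed(cfg$seed, 3L)
    if (cfg$cv$scheme == "kfold") {
      repeated_stratified_kfold(eligible, feature_schema(), arch,
                                k = cfg$cv$k,
                                repetitions = cfg$cv$repetitions,
                                seed = manifest$seeds$cv,
                                collect_importance = TRUE)
    } else {
      leave_one_site_out(eligible, feature_schema(), arch,
                         seed = manifest$seeds$cv)
    }
  })
  utils::write.csv(cv$metrics, outfile("cv_metrics.csv"), row.names = FALSE)
  manifest$counts$metric_rows <- nrow(cv$metrics)
  manifest$files <- c(manifest$files, "cv_metrics.csv")
  if (is.null(cv$maps))
    stop("pipeline stage 'train_explain' produced no importance maps",
         call. = FALSE)
  utils::write.csv(cv$maps, outfile("importance_maps.csv"), row.names = FALSE)
  manifest$counts$map_rows <- nrow(cv$maps)
  manifest$files <- c(manifest$files, "importance_maps.csv")

  ## stage 4: group inference -----------------------------------------------
  effects <- stage("group_inference", {
    manifest$seeds$inference <- stage_seed(cfg$seed, 4L)
    summarize_group_effects(cv$maps, B = cfg$inference$B,
                            seed = manifest$seeds$inference,
                            alpha = cfg$inference$alpha)
  })
  utils::write.csv(effects, outfile("group_effects.csv"), row.names = FALSE)
  manifest$files <- c(manifest$files, "group_effects.csv")

  ## stage 5: clustering ----------------------------------------------------
  clus <- stage("clustering", {
    m <- maps_matrix(cv$maps)
    ward_cluster(m, k = cfg$clustering$k)
  })
  lab_df <- data.frame(patient_id = names(clus$labels),
                       cluster = unname(clus$labels))
  utils::write.csv(lab_df, outfile("cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(clus$mean_maps), outfile("cluster_mean_maps.csv"),
                   row.names = TRUE)
  linkage <- cbind(clus$hclust$merge, clus$hclust$height)
  colnames(linkage) <- c("child1", "child2", "height")
  utils::write.csv(as.data.frame(linkage), outfile("linkage.csv"),
                   row.names = FALSE)
  manifest$counts$clustered_patients <- length(clus$labels)
  manifest$counts$cluster_sizes <- clus$cluster_sizes
  manifest$files <- c(manifest$files,
                      "cluster_labels.csv", "cluster_mean_maps.csv",
                      "linkage.csv")

  manifest$files <- c(manifest$files, "manifest.json")
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
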