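#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: which conditions to
#' generate, observer counts, feature variant and regression settings.
#' The resolved configuration is serialized (JSON) next to the outputs of
#' every run, so any artifact can be regenerated from (config, code).
#'
#' @param master_seed integer; every stage derives its own seeds from it.
#' @param tasks,objects,illums design subset (see [design_conditions()]).
#' @param image_size stimulus side in pixels.
#' @param n_lab_observers,n_lab_reps laboratory design (default 20 x 10).
#' @param n_crowd_observers crowd design (one judgment each).
#' @param crowd_attenuation crowd sensitivity attenuation factor.
#' @param lapse observer lapse probability.
#' @param feature_variant regression feature set (see [reduce_features()]).
#' @param n_resamples resampled splits in the regression stage.
#' @param lasso_k fixed lasso support size.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L,
                            tasks = names(task_grids()),
                            objects = 1:2, illums = 1:3,
                            image_size = 128,
                            n_lab_observers = 20, n_lab_reps = 10,
                            n_crowd_observers = 200,
                            crowd_attenuation = 0.7, lapse = 0.02,
                            feature_variant = "ps_color",
                            n_resamples = 200, lasso_k = 18,
                            out_dir = "matodd_out") {
  cfg <- list(master_seed = as.integer(master_seed), tasks = tasks,
              objects = objects, illums = illums, image_size = image_size,
              n_lab_observers = n_lab_observers, n_lab_reps = n_lab_reps,
              n_crowd_observers = n_crowd_observers,
              crowd_attenuation = crowd_attenuation, lapse = lapse,
              feature_variant = feature_variant,
              n_resamples = n_resamples, lasso_k = lasso_k,
              out_dir = out_dir)
  # validate early: GP exists only under illumination condition 1
  if ("GP" %in% tasks && !(1 %in% illums))
    stop("GP is only defined under illumination condition 1")
  structure(cfg, class = "pipeline_config")
}

# condition identifier shared by the feature and sensitivity stages
condition_id <- function(task, illum, object, difficulty)
  sprintf("%s_i%d_o%d_d%g", task, illum, object, difficulty)

#' Feature matrices for every task condition
#'
#' Renders each condition's stimulus set (anchor images across the
#' condition's poses or illumination proxies, plus the target images at
#' the condition's difficulty; for GP, consistent target plus
#' inconsistent non-targets) and computes one feature vector per image.
#' Images shared between conditions (the anchors) are rendered once.
#'
#' @param conditions data frame from [design_conditions()].
#' @param variant feature variant (see [reduce_features()]).
#' @param size render size in pixels.
#' @return Named list (by condition id) of feature matrices.
#' @export
condition_feature_sets <- function(conditions, variant = "ps_color",
                                   size = 128) {
  cache <- new.env(parent = emptyenv())
  wp_cache <- lapply(1:3, condition_white_point)
  img_feat <- function(task, illum, object, value, proxy, pose, incons) {
    key <- sprintf("%s_%d_%d_%g_%d_%d_%d", task, illum, object, value,
                   proxy, pose, incons)
    if (is.null(cache[[key]])) {
      img <- render_object(scene_spec(object, proxy, pose),
                           material_spec(task, value,
                                         inconsistent = incons == 1),
                           size = size)
      cache[[key]] <- image_features(img, wp_cache[[illum]], variant)
    }
    cache[[key]]
  }
  out <- list()
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    proxies <- illum_condition_proxies(cd$illumination_condition)
    poses <- if (cd$illumination_condition == 1) seq(0, 144, by = 36) else 0
    combos <- expand.grid(proxy = proxies, pose = poses)
    rows <- list()
    for (j in seq_len(nrow(combos))) {
      pr <- combos$proxy[j]; po <- combos$pose[j]
      if (cd$task == "GP") {
        rows[[sprintf("tgt_x%d_r%d", pr, po)]] <-
          img_feat(cd$task, cd$illumination_condition, cd$object,
                   cd$difficulty, pr, po, 0L)
        rows[[sprintf("ntg_x%d_r%d", pr, po)]] <-
          img_feat(cd$task, cd$illumination_condition, cd$object,
                   cd$difficulty, pr, po, 1L)
      } else {
        anchor <- task_anchor(cd$task)
        rows[[sprintf("ntg_x%d_r%d", pr, po)]] <-
          img_feat(cd$task, cd$illumination_condition, cd$object,
                   anchor, pr, po, 0L)
        rows[[sprintf("tgt_x%d_r%d", pr, po)]] <-
          img_feat(cd$task, cd$illumination_condition, cd$object,
                   cd$difficulty, pr, po, 0L)
      }
    }
    out[[condition_id(cd$task, cd$illumination_condition, cd$object,
                      cd$difficulty)]] <- do.call(rbind, rows)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages: generate stimuli (per-condition image sets) -> simulate
#' observers (lab and crowd response tables) -> estimate d-prime ->
#' extract features and per-feature condition distances -> regression of
#' d-prime on feature distances. All tables are written as CSV under the
#' configured output directory together with the resolved configuration
#' and a manifest of file hashes.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the stage outputs (`conditions`,
#'   `responses`, `sensitivity`, `features`, `regression`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  conds <- design_conditions(config$tasks, config$objects, config$illums)

  # --- observers -------------------------------------------------------
  lab <- simulate_response_table(conds, config$n_lab_observers,
                                 config$n_lab_reps, "lab",
                                 lapse = config$lapse,
                                 seed = derive_seed(config$master_seed, "lab"))
  crowd <- simulate_response_table(conds, config$n_crowd_observers, 1,
                                   "crowd",
                                   attenuation = config$crowd_attenuation,
                                   lapse = config$lapse,
                                   seed = derive_seed(config$master_seed,
                                                      "crowd"))
  responses <- rbind(lab, crowd)
  write_response_table(responses,
                       file.path(config$out_dir, "responses.csv"))

  # --- sensitivity -----------------------------------------------------
  sens_lab <- aggregate_sensitivity(lab, "per_observer")
  sens_crowd <- aggregate_sensitivity(crowd, "pooled")
  sens_lab$environment <- "lab"; sens_crowd$environment <- "crowd"
  sens_crowd$sem <- NA_real_; sens_crowd$n_observers <- NA_integer_
  sensitivity <- rbind(sens_lab, sens_crowd)
  utils::write.csv(sensitivity,
                   file.path(config$out_dir, "sensitivity.csv"),
                   row.names = FALSE)

  # --- stimuli + features ---------------------------------------------
  features <- condition_feature_sets(conds, config$feature_variant,
                                     config$image_size)

  # --- regression ------------------------------------------------------
  sens_key <- condition_id(sens_lab$task, sens_lab$illumination_condition,
                           sens_lab$object, sens_lab$difficulty)
  dp_by_cond <- stats::setNames(sens_lab$d_prime, sens_key)
  ds <- assemble_dataset(features, dp_by_cond[names(features)],
                         task = vapply(strsplit(names(features), "_"),
                                       `[`, "", 1))
  reg <- resample_evaluate(ds, config$feature_variant,
                           n_resamples = config$n_resamples,
                           k = min(config$lasso_k, ncol(ds$X) - 1),
                           seed = derive_seed(config$master_seed, "reg"))
  utils::write.csv(
    data.frame(resample = seq_along(reg$mse_distribution),
               mse = reg$mse_distribution, r2 = reg$r2_distribution),
    file.path(config$out_dir, "regression_distributions.csv"),
    row.names = FALSE)
  utils::write.csv(reg$per_task_mse,
                   file.path(config$out_dir, "regression_per_task.csv"),
                   row.names = FALSE)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- build_manifest(setdiff(files,
                                     file.path(config$out_dir,
                                               "manifest.json")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(list(conditions = conds, responses = responses,
                 sensitivity = sensitivity, features = features,
                 dataset = ds, regression = reg, manifest = manifest))
}
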