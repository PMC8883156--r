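#' Assemble one oddity display for a task condition
#'
#' Under illumination condition 1 the display holds four images of the
#' same object in different poses (drawn without replacement from the five
#' 36-degree-step poses) under one illumination proxy; under conditions 2
#' and 3 it holds three images in the same pose under the three similar
#' (condition 2) or dissimilar (condition 3) proxies. Non-target images
#' use the anchor parameter, the target uses the condition's difficulty
#' parameter, and the target position is uniform random under the seed.
#' For GP the target is the consistent glossy render and the non-targets
#' are highlight-inconsistent renders at the same DOI.
#'
#' @param condition a [task_condition()].
#' @param seed integer seed (target position, pose draw, GP mappings).
#' @param size image side in pixels.
#' @return List of class `oddity_display`: `images` (list of 8-bit
#'   arrays), `target_index`, `condition`, `m`.
#' @export
make_oddity_display <- function(condition, seed = 1L, size = 128) {
  stopifnot(inherits(condition, "task_condition"))
  m <- condition$m
  tk <- condition$task
  with_seed(seed, {
    target_index <- sample.int(m, 1)
    if (condition$illumination_condition == 1) {
      poses <- sample(seq(0, 144, by = 36), m)
      proxies <- rep(1L, m)
    } else {
      poses <- rep(0, m)
      proxies <- sample(illum_condition_proxies(
        condition$illumination_condition))
    }
  })
  geom <- geometry_preset(condition$object)
  images <- vector("list", m)
  for (i in seq_len(m)) {
    sc <- scene_spec(geom, proxies[i], poses[i])
    mat <- if (tk == "GP") {
      material_spec("GP", condition$difficulty,
                    inconsistent = (i != target_index))
    } else if (i == target_index) {
      material_spec(tk, condition$difficulty)
    } else {
      material_spec(tk, task_anchor(tk))
    }
    images[[i]] <- render_object(sc, mat, size = size)
  }
  structure(list(images = images, target_index = target_index,
                 condition = condition, m = m),
            class = "oddity_display")
}

#' Simulate one observer response to an oddity display
#'
#' The synthetic observer follows the same differencing decision rule as
#' [simulate_oddity_pc()]: its sensitivity on the trial is
#' `link(task_param_distance(task, difficulty))`, internal responses are
#' unit-variance normal draws with the target shifted by that d-prime,
#' and the alternative most distant from the mean of the others is
#' chosen. With probability `lapse` the response is instead uniform over
#' the alternatives.
#'
#' @param display an [make_oddity_display()] result, or any list with
#'   fields `condition`, `target_index`, `m` (images are not consulted:
#'   the ground-truth link operates on the parameter distance).
#' @param link monotone nondecreasing function mapping parameter distance
#'   to d-prime, with `link(0) = 0`.
#' @param lapse lapse probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param observer_id,environment identifiers copied into the record.
#' @return One-row data frame: `observer_id`, `environment`, `task`,
#'   `illumination_condition`, `object`, `difficulty`, `m`,
#'   `chosen_index`, `correct`.
#' @export
simulate_observer <- function(display, link, lapse = 0, seed = 1L,
                              observer_id = 1L, environment = "lab") {
  stopifnot(lapse >= 0, lapse < 0.5)
  cond <- display$condition
  dp <- link(task_param_distance(cond$task, cond$difficulty))
  stopifnot(dp >= 0)
  m <- display$m
  chosen <- with_seed(seed, {
    if (stats::runif(1) < lapse) {
      sample.int(m, 1)
    } else {
      x <- stats::rnorm(m)
      x[display$target_index] <- x[display$target_index] + dp
      oddity_choose(matrix(x, 1, m))
    }
  })
  data.frame(observer_id = observer_id, environment = environment,
             task = cond$task,
             illumination_condition = cond$illumination_condition,
             object = cond$object, difficulty = cond$difficulty,
             m = m, chosen_index = as.integer(chosen),
             correct = chosen == display$target_index,
             stringsAsFactors = FALSE)
}

#' Ground-truth sensitivity links for the synthetic observers
#'
#' One link per material dimension, mapping the target-anchor parameter
#' distance to d-prime. Slopes are fixed study conditions chosen so each
#' difficulty grid spans roughly d-prime 0 to 3 (GP: constant sensitivity
#' to the inconsistency, since its DOI parameter leaves the
#' target/non-target difference unchanged).
#'
#' @param task material dimension code.
#' @param attenuation multiplicative factor on the link output (the crowd
#'   environment uses 0.7).
#' @return A function `f(distance) -> d-prime`.
#' @export
default_link <- function(task, attenuation = 1) {
  slope <- switch(match.arg(task, names(task_grids())),
                  GC = 40, GD = 40, OT = 0.35, MP = 3.2, MG = 3.2, GP = NA)
  if (is.na(slope)) {
    function(delta) attenuation * 1.0 * (delta > 0)
  } else {
    function(delta) attenuation * slope * delta
  }
}

#' Simulate a full response table over a set of conditions
#'
#' Fast path over [simulate_observer()]: for every condition row and
#' observer repetition it draws the target position and applies the same
#' decision rule (the rendered images are not needed because the
#' ground-truth link operates on the parameter distance).
#'
#' @param conditions data frame as from [design_conditions()].
#' @param n_observers number of observers.
#' @param n_reps judgments per observer per condition (laboratory: 10;
#'   crowdsourcing: 1).
#' @param environment `"lab"` or `"crowd"`; the crowd link is attenuated.
#' @param attenuation crowd sensitivity attenuation factor.
#' @param lapse lapse probability.
#' @param observer_sdlog per-task SD (log scale) of the log-normal
#'   per-observer ability factor multiplying the link's d-prime
#'   (mean-preserving). The highlight-consistency task (GP) is given a
#'   much wider spread than the parametric tasks, reflecting the large
#'   individual differences characteristic of that judgment; set all
#'   entries to 0 for homogeneous observers.
#' @param seed master seed; per-trial seeds are derived from it.
#' @return Data frame of trial records (see [simulate_observer()]).
#' @export
simulate_response_table <- function(conditions, n_observers, n_reps = 1,
                                    environment = c("lab", "crowd"),
                                    attenuation = if (environment == "crowd")
                                      0.7 else 1,
                                    lapse = 0.02,
                                    observer_sdlog = c(GC = 0.3, GD = 0.3,
                                                       OT = 0.3, MP = 0.3,
                                                       MG = 0.3, GP = 1.0),
                                    seed = 1L) {
  environment <- match.arg(environment)
  links <- lapply(setNames(nm = names(task_grids())), default_link,
                  attenuation = attenuation)
  # per-(observer, task) ability factors, consistent across conditions
  ability <- with_seed(derive_seed(seed, environment, "ability"), {
    sdl <- observer_sdlog[names(task_grids())]
    sdl[is.na(sdl)] <- 0
    f <- vapply(sdl, function(s)
      exp(stats::rnorm(n_observers, -s^2 / 2, s)), numeric(n_observers))
    matrix(f, nrow = n_observers,
           dimnames = list(NULL, names(task_grids())))
  })
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    m <- cd$m
    dp <- links[[cd$task]](task_param_distance(cd$task, cd$difficulty)) *
      rep(ability[, cd$task], each = n_reps)
    n <- n_observers * n_reps
    rec <- with_seed(derive_seed(seed, environment, cd$task,
                                 cd$illumination_condition, cd$object,
                                 cd$difficulty), {
      target <- sample.int(m, n, replace = TRUE)
      x <- matrix(stats::rnorm(n * m), n, m)
      x[cbind(seq_len(n), target)] <- x[cbind(seq_len(n), target)] + dp
      chosen <- oddity_choose(x)
      lapses <- stats::runif(n) < lapse
      chosen[lapses] <- sample.int(m, sum(lapses), replace = TRUE)
      data.frame(observer_id = rep(seq_len(n_observers), each = n_reps),
                 environment = environment, task = cd$task,
                 illumination_condition = cd$illumination_condition,
                 object = cd$object, difficulty = cd$difficulty, m = m,
                 chosen_index = chosen, correct = chosen == target,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Render and write a stimulus corpus to disk
#'
#' Writes 8-bit PNG images in the layout
#' `task_<name>/illum_<k>/object_<j>/param_<value>/pose_<deg>.png`
#' together with a JSON manifest of scene/material parameters and file
#' hashes.
#'
#' @param dir output directory (created if needed).
#' @param conditions data frame as from [design_conditions()]; images are
#'   written per unique (task, illumination proxy, object, parameter,
#'   pose) combination implied by the rows.
#' @param size image side in pixels.
#' @param poses poses (degrees) rendered under illumination condition 1.
#' @return Invisibly, the manifest as a data frame (`path`, `md5`).
#' @export
write_stimulus_corpus <- function(dir, conditions, size = 128,
                                  poses = seq(0, 144, by = 36)) {
  paths <- character(0)
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    proxies <- illum_condition_proxies(cd$illumination_condition)
    pose_set <- if (cd$illumination_condition == 1) poses else 0
    for (pr in proxies) for (po in pose_set) {
      rel <- file.path(sprintf("task_%s", cd$task),
                       sprintf("illum_%d", cd$illumination_condition),
                       sprintf("object_%d", cd$object),
                       sprintf("param_%g", cd$difficulty),
                       sprintf("proxy%d_pose_%03d.png", pr, po))
      f <- file.path(dir, rel)
      if (file.exists(f)) next
      dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
      img <- render_object(scene_spec(cd$object, pr, po),
                           material_spec(cd$task, cd$difficulty),
                           size = size)
      write_png(img, f)
      paths <- c(paths, f)
    }
  }
  manifest <- data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}
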