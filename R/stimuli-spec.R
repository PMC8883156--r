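#' Material dimensions, parameter grids and task conditions
#'
#' Six material dimensions are manipulated, each along a printed parameter
#' grid. The non-target (anchor) stimuli sit at a fixed grid value and the
#' target takes one of the grid values, so the target-anchor separation
#' controls difficulty:
#'
#' * `GC` gloss contrast: specular energy `rho_s` 0.00-0.12 in steps of
#'   0.02 (anchor 0.06), diffuse reflectance fixed at 0.416, DOI 0.94.
#' * `GD` gloss distinctness-of-image: `d` 0.88-1.00 in steps of 0.02
#'   (anchor 0.94), `rho_s` fixed at 0.06.
#' * `OT` opaque-translucent: medium density scale in
#'   {0.0039, 0.0156, 0.0625, 0.25, 1.00} (anchor 1.00, opaque).
#' * `MP` gold-plastic: blend weight 0.00-0.80 in steps of 0.20 (anchor 0,
#'   pure gold).
#' * `MG` silver-glass: blend weight 0.00-0.80 in steps of 0.20 (anchor 0,
#'   pure silver).
#' * `GP` glossy-painted: `d` 0.88-1.00 in steps of 0.04 at contrast gloss
#'   c = 0.067; the target is a consistent glossy render, the non-targets
#'   are highlight-inconsistent ("painted") renders at the same `d`.
#'
#' @return `task_grids()` returns a named list of numeric grids;
#'   `task_anchor()` the anchor value for one dimension.
#' @export
task_grids <- function() {
  list(GC = seq(0, 0.12, by = 0.02),
       GD = seq(0.88, 1.00, by = 0.02),
       OT = c(0.0039, 0.0156, 0.0625, 0.25, 1.00),
       MP = seq(0, 0.80, by = 0.20),
       MG = seq(0, 0.80, by = 0.20),
       GP = seq(0.88, 1.00, by = 0.04))
}

#' @rdname task_grids
#' @param dimension one of `"GC"`, `"GD"`, `"OT"`, `"MP"`, `"MG"`, `"GP"`.
#' @export
task_anchor <- function(dimension) {
  switch(match.arg(dimension, names(task_grids())),
         GC = 0.06, GD = 0.94, OT = 1.00, MP = 0, MG = 0,
         GP = NA_real_)  # GP anchors differ by consistency, not parameter
}

#' Construct a material specification
#'
#' @param dimension material dimension code (see [task_grids()]).
#' @param value task parameter; must lie on the dimension's grid.
#' @param inconsistent logical; for `GP` only, whether the highlights are
#'   spatially inconsistent with the diffuse shading ("painted").
#' @return List of class `material_spec`.
#' @export
material_spec <- function(dimension, value, inconsistent = FALSE) {
  dimension <- match.arg(dimension, names(task_grids()))
  grid <- task_grids()[[dimension]]
  i <- which(abs(grid - value) < 1e-9)
  if (!length(i))
    stop(sprintf("value %g is off the %s grid; valid values: %s",
                 value, dimension, paste(grid, collapse = ", ")))
  if (inconsistent && dimension != "GP")
    stop("inconsistent highlights exist only for the GP dimension")
  structure(list(dimension = dimension, value = grid[i],
                 inconsistent = isTRUE(inconsistent)),
            class = "material_spec")
}

#' Task condition: the unit at which sensitivity and feature distance meet
#'
#' @param task material dimension code.
#' @param illumination_condition 1 (four alternatives, one light probe
#'   proxy, varied poses), 2 (three alternatives, similar proxies) or
#'   3 (three alternatives, dissimilar proxies).
#' @param object object geometry index 1-5 (see [geometry_preset()]).
#' @param difficulty target parameter value on the task grid.
#' @return List of class `task_condition` with an `m` field (4 for
#'   illumination condition 1, else 3).
#' @export
task_condition <- function(task, illumination_condition, object, difficulty) {
  task <- match.arg(task, names(task_grids()))
  stopifnot(illumination_condition %in% 1:3, object %in% 1:5)
  if (task == "GP" && illumination_condition != 1)
    stop("the GP task exists only under illumination condition 1")
  material_spec(task, difficulty)  # grid validation
  structure(list(task = task,
                 illumination_condition = as.integer(illumination_condition),
                 object = as.integer(object),
                 difficulty = difficulty,
                 m = if (illumination_condition == 1) 4L else 3L),
            class = "task_condition")
}

#' Full stimulus design (the corpus layout)
#'
#' Expands the study design: all six tasks under illumination condition 1
#' and tasks GC/GD/OT/MP/MG under conditions 2 and 3, each crossed with
#' the five objects and the task's difficulty grid.
#'
#' @param tasks subset of tasks to include.
#' @param objects subset of objects (1-5).
#' @param illums subset of illumination conditions (1-3).
#' @return Data frame with columns `task`, `illumination_condition`,
#'   `object`, `difficulty`, `m`.
#' @export
design_conditions <- function(tasks = names(task_grids()), objects = 1:5,
                              illums = 1:3) {
  rows <- list()
  for (ic in illums) {
    for (tk in tasks) {
      if (tk == "GP" && ic != 1) next
      for (ob in objects) for (v in task_grids()[[tk]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          task = tk, illumination_condition = ic, object = ob,
          difficulty = v, m = if (ic == 1) 4L else 3L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Parameter distance between target and non-target stimuli
#'
#' The separation that drives discriminability: absolute grid distance to
#' the anchor for GC/GD/MP/MG, log2 density distance for OT (the density
#' scale spans orders of magnitude), and a constant 1 for GP (presence of
#' the highlight inconsistency; its `d` parameter does not change the
#' target/non-target difference).
#'
#' @param task material dimension code.
#' @param value target parameter value.
#' @return Nonnegative scalar distance.
#' @export
task_param_distance <- function(task, value) {
  task <- match.arg(task, names(task_grids()))
  switch(task,
         GC = abs(value - 0.06),
         GD = abs(value - 0.94),
         OT = abs(log2(value) - log2(1)),
         MP = abs(value),
         MG = abs(value),
         GP = 1)
}
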