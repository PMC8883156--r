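test_that("material grids match the study parameter lists", {
  g <- task_grids()
  expect_equal(g$GC, seq(0, 0.12, by = 0.02))
  expect_equal(g$GD, seq(0.88, 1.00, by = 0.02))
  expect_equal(g$OT, c(0.0039, 0.0156, 0.0625, 0.25, 1.00))
  expect_equal(g$MP, seq(0, 0.8, by = 0.2))
  expect_equal(g$GP, seq(0.88, 1.00, by = 0.04))
  expect_equal(task_anchor("GC"), 0.06)
  expect_equal(task_anchor("OT"), 1.00)
})

test_that("off-grid parameters are rejected with the valid grid listed", {
  expect_error(material_spec("GC", 0.05), "0.02")
  expect_error(material_spec("OT", 0.5), "0.0039")
  expect_error(material_spec("GC", 0.06, inconsistent = TRUE), "GP")
})

test_that("the corpus design reproduces the stimulus-condition table", {
  conds <- design_conditions()
  units <- unique(conds[c("task", "illumination_condition", "object")])
  counts <- table(units$illumination_condition)
  expect_equal(as.integer(counts), c(30L, 25L, 25L))  # 6x5, 5x5, 5x5
  expect_false(any(conds$task == "GP" & conds$illumination_condition != 1))
  expect_true(all(conds$m[conds$illumination_condition == 1] == 4))
  expect_true(all(conds$m[conds$illumination_condition != 1] == 3))
})

test_that("rendering is deterministic and respects the blend identity", {
  sc <- scene_spec(2, 1, 72)
  a <- render_object(sc, material_spec("GC", 0.08), 128)
  b <- render_object(sc, material_spec("GC", 0.08), 128)
  expect_identical(a, b)
  # MP weight 0 equals the pure-gold endpoint pixelwise
  g0 <- render_object(sc, material_spec("MP", 0), 128)
  expect_identical(g0, render_object(sc, material_spec("MP", 0), 128))
  expect_error(render_object(sc, material_spec("GC", 0.08), 64), "128")
})

test_that("each dimension's manipulated property is monotone on its grid", {
  sc <- scene_spec(1, 1, 0)
  spec_energy <- vapply(task_grids()$GC, function(v)
    mean(render_object(sc, material_spec("GC", v), 128,
                       layers = TRUE)$spec), numeric(1))
  expect_true(all(diff(spec_energy) > 0))
  sharpness <- vapply(task_grids()$GD, function(v) {
    s <- render_object(sc, material_spec("GD", v), 128, layers = TRUE)$spec
    mean(diff(s)^2)
  }, numeric(1))
  expect_true(all(diff(sharpness) > 0))
  show_through <- vapply(task_grids()$OT, function(v)
    mean(render_object(sc, material_spec("OT", v), 128)), numeric(1))
  expect_true(all(diff(show_through) < 0))
  for (tk in c("MP", "MG")) {
    ref <- render_object(sc, material_spec(tk, 0), 128)
    dst <- vapply(task_grids()[[tk]], function(v)
      mean(abs(render_object(sc, material_spec(tk, v), 128) - ref)),
      numeric(1))
    expect_true(all(diff(dst) > 0))
  }
})

test_that("geometry presets are reproducible and pose rotates the surface", {
  hf1 <- height_field(geometry_preset(4), 128, pose_deg = 0)
  hf2 <- height_field(geometry_preset(4), 128, pose_deg = 0)
  expect_identical(hf1$h, hf2$h)
  hf3 <- height_field(geometry_preset(4), 128, pose_deg = 72)
  expect_gt(mean(abs(hf1$h - hf3$h)), 1e-4)
})

test_that("inconsistent highlights preserve the reference color histogram", {
  for (ob in c(1, 4)) {
    lay <- make_inconsistent_highlights(scene_spec(ob, 1, 0), d = 0.92,
                                        seed = 7, size = 128, layers = TRUE)
    for (ch in 1:3)
      expect_identical(sort(as.vector(lay$image[, , ch])),
                       sort(as.vector(lay$consistent_image[, , ch])))
  }
})

test_that("identity highlight mapping reproduces the consistent render", {
  lay <- make_inconsistent_highlights(scene_spec(2, 1, 0), d = 0.92,
                                      seed = 7, size = 128,
                                      identity_mapping = TRUE, layers = TRUE)
  expect_lt(mean(abs(as.numeric(lay$image) -
                       as.numeric(lay$consistent_image))), 1.0)
})

# gradient-field coherence between the (lightly smoothed) highlight layer
# and the diffuse shading layer: normalized inner product of the two
# gradient fields over the object
grad_coherence <- function(spec, diff_l, mask, sigma = 3) {
  gx <- function(m) m[c(2:nrow(m), nrow(m)), ] - m
  gy <- function(m) m[, c(2:ncol(m), ncol(m))] - m
  env <- matodd:::gauss_blur(spec, sigma)
  dls <- matodd:::gauss_blur(diff_l, sigma)
  sx <- gx(env)[mask]; sy <- gy(env)[mask]
  dx <- gx(dls)[mask]; dy <- gy(dls)[mask]
  sum(sx * dx + sy * dy) / sqrt(sum(sx^2 + sy^2) * sum(dx^2 + dy^2))
}

test_that("highlight-shading coherence drops when highlights are displaced", {
  grad_cons <- grad_inc <- numeric(5)
  for (ob in 1:5) {
    sc <- scene_spec(ob, 1, 0)
    cons <- render_object(sc, material_spec("GP", 0.92), 128, layers = TRUE)
    inc <- make_inconsistent_highlights(sc, 0.92, seed = 11, size = 128,
                                        layers = TRUE)
    dl <- cons$diff[[1]]
    # highlights sit on the bright shading regions only when consistent
    expect_gt(cor(cons$spec[cons$mask], dl[cons$mask]),
              cor(inc$spec[inc$mask], dl[inc$mask]))
    grad_cons[ob] <- grad_coherence(cons$spec, dl, cons$mask)
    grad_inc[ob] <- grad_coherence(inc$spec, dl, inc$mask)
  }
  # gradient-orientation alignment, aggregated over the five geometries
  # (for the roughest bump fields the per-object alignment is at floor)
  expect_gt(mean(grad_cons), mean(grad_inc) + 0.05)
})

test_that("oddity displays follow the illumination-condition design", {
  d1 <- make_oddity_display(task_condition("GC", 1, 1, 0.12), seed = 2,
                            size = 128)
  expect_length(d1$images, 4)
  expect_true(d1$target_index %in% 1:4)
  # four distinct poses of the same object: all four images differ
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(mean(abs(d1$images[[i]] - d1$images[[j]])), 0.1)
  d3 <- make_oddity_display(task_condition("OT", 3, 2, 0.0625), seed = 2,
                            size = 128)
  expect_length(d3$images, 3)
  expect_error(task_condition("GP", 2, 1, 0.92), "illumination condition 1")
})

test_that("simulated observers respect the sensitivity link", {
  stub <- function(target, m) list(
    condition = task_condition("GC", if (m == 4) 1 else 2, 1, 0.12),
    target_index = target, m = m)
  # link == 0: chance accuracy
  n <- 4000
  acc0 <- mean(vapply(seq_len(n), function(i)
    simulate_observer(stub(1 + i %% 4, 4), function(d) 0, seed = i)$correct,
    logical(1)))
  expect_lt(abs(acc0 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # saturating link: near-perfect accuracy
  acc1 <- mean(vapply(seq_len(500), function(i)
    simulate_observer(stub(1 + i %% 4, 4), function(d) 10,
                      lapse = 0, seed = i)$correct, logical(1)))
  expect_gt(acc1, 0.98)
})

test_that("display-level observers agree with the psychometric simulator", {
  n <- 3e4
  stub <- function(target) list(
    condition = task_condition("GC", 2, 1, 0.12), target_index = target,
    m = 3)
  set.seed(8)
  targets <- sample.int(3, n, replace = TRUE)
  acc <- mean(vapply(seq_len(n), function(i)
    simulate_observer(stub(targets[i]), function(d) 2, lapse = 0,
                      seed = 5000 + i)$correct, logical(1)))
  ref <- simulate_oddity_pc(2, oddity_design(3, n_sim = 1e6, seed = 17L))
  expect_lt(abs(acc - ref), 3 * sqrt(ref * (1 - ref) / n))
})

test_that("simulated response tables recover their generating accuracy", {
  conds <- design_conditions("GC", objects = 1, illums = 1)
  conds <- conds[conds$difficulty == 0.12, ]
  zero_sd <- setNames(rep(0, 6), names(task_grids()))
  tab <- simulate_response_table(conds, n_observers = 400, n_reps = 1,
                                 environment = "lab", lapse = 0.02,
                                 observer_sdlog = zero_sd, seed = 3L)
  expect_equal(nrow(tab), 400)
  dp <- default_link("GC")(task_param_distance("GC", 0.12))
  pc_exp <- simulate_oddity_pc(dp, oddity_design(4, n_sim = 1e6, seed = 2L))
  pc_exp <- pc_exp * 0.98 + 0.02 * 0.25
  expect_lt(abs(mean(tab$correct) - pc_exp),
            3 * sqrt(pc_exp * (1 - pc_exp) / 400))
})

test_that("individual differences are widest for highlight-consistency judgments", {
  conds <- design_conditions(c("GC", "GD", "GP"), objects = 1:5, illums = 1)
  tab <- simulate_response_table(conds, n_observers = 120, n_reps = 1,
                                 environment = "crowd", seed = 9L)
  acc <- observer_accuracy(tab)
  sds <- unique(acc[c("task", "sd_accuracy")])
  expect_gt(sds$sd_accuracy[sds$task == "GP"],
            sds$sd_accuracy[sds$task == "GC"])
  expect_gt(sds$sd_accuracy[sds$task == "GP"],
            sds$sd_accuracy[sds$task == "GD"])
})

test_that("a written stimulus corpus is reproducible bit for bit", {
  conds <- design_conditions("GD", objects = 3, illums = 2)
  conds <- conds[conds$difficulty %in% c(0.88, 0.94), ]
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_stimulus_corpus(d1, conds, size = 128)
  m2 <- write_stimulus_corpus(d2, conds, size = 128)
  expect_equal(nrow(m1), 6)  # 2 parameters x 3 proxies
  expect_equal(m1$md5, m2$md5)
  expect_true(all(file.exists(m1$path)))
  img <- read_png(m1$path[1])
  expect_equal(dim(img), c(128, 128, 3))
})
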