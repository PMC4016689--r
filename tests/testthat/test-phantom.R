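test_that("phantom preconditions are enforced", {
  expect_error(phantom_params(n_cells = 0), "positive integer")
  expect_error(phantom_params(nucleolus_eccentricity = 1), "\\[0, 1\\)")
  expect_error(phantom_params(box = c(100, 100, 0)), "positive")
  expect_error(generate_phantom(list()), "phantom_params")
})

test_that("monodisperse spheres have the exact analytic mean volume", {
  p <- generate_phantom(small_params(somal_cv = 0), seed = 1)
  r <- p$cells$sa[1]
  expect_equal(p$true_mean_somal_volume, 4 / 3 * pi * r^3)
  expect_true(all(p$cells$sa == r))
})

test_that("log-normal somal volumes match the configured mean", {
  target <- 3600
  p <- generate_phantom(
    phantom_params(n_cells = 800, box = c(260, 260, 200),
                   mean_somal_volume = target, somal_cv = 0.3),
    seed = 7
  )
  v <- p$cells$volume
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - target), 3 * se)
})

test_that("recorded ground truth matches the constructed cell list exactly", {
  p <- generate_phantom(small_params(somal_cv = 0.25), seed = 11)
  expect_identical(p$true_cell_count, nrow(p$cells))
  expect_identical(p$true_layer_volume, prod(p$box) / 1e9)
  expect_identical(p$true_mean_somal_volume,
                   mean(4 / 3 * pi * p$cells$sa * p$cells$sb * p$cells$sc))
})

test_that("generation is deterministic given the seed", {
  a <- generate_phantom(small_params(), seed = 42)
  b <- generate_phantom(small_params(), seed = 42)
  expect_identical(a, b)
  c <- generate_phantom(small_params(), seed = 43)
  expect_false(identical(a$cells, c$cells))
})

test_that("cells lie inside the box and nucleoli strictly inside cells", {
  p <- generate_phantom(small_params(nucleolus_eccentricity = 0.6), seed = 3)
  ce <- p$cells
  expect_true(all(ce$cx - ce$sa >= 0 & ce$cx + ce$sa <= p$box[1]))
  expect_true(all(ce$cz - ce$sc >= 0 & ce$cz + ce$sc <= p$box[3]))
  q <- ((ce$nx - ce$cx) / ce$sa)^2 + ((ce$ny - ce$cy) / ce$sb)^2 +
    ((ce$nz - ce$cz) / ce$sc)^2
  expect_true(all(q < 1))
})

test_that("infeasible packing raises an explicit error", {
  pp <- phantom_params(n_cells = 200, box = c(40, 40, 40),
                       mean_somal_volume = 3600, somal_cv = 0,
                       min_sep_frac = 2, max_attempts_per_cell = 20)
  expect_error(generate_phantom(pp, seed = 1), "packing failure")
})

test_that("empirical somal-volume CV tracks the configured CV", {
  cv_target <- 0.3
  vols <- unlist(lapply(1:100, function(i) {
    generate_phantom(
      phantom_params(n_cells = 60, box = c(110, 110, 90),
                     somal_cv = cv_target),
      seed = 500 + i
    )$cells$volume
  }))
  cv_emp <- sd(vols) / mean(vols)
  expect_lt(abs(cv_emp - cv_target) / cv_target, 0.10)
})

test_that("ellipsoid cells preserve the target volume distribution", {
  p <- generate_phantom(
    phantom_params(n_cells = 400, box = c(240, 240, 200),
                   shape = "ellipsoid", axis_ratio = c(1.4, 1, 0.7),
                   somal_cv = 0.25),
    seed = 9
  )
  v <- p$cells$volume
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 3600) / se, 3)
  # anisotropy present
  expect_gt(mean(p$cells$sa / p$cells$sc), 1.5)
})

test_that("zero between-animal CV gives identical group parameters", {
  sc <- study_scenario(n_per_group = 2, control_params = small_params(),
                       between_animal_cv = 0)
  st <- generate_study(sc, seed = 5)
  ctrl <- Filter(function(a) a$group == "control", st)
  expect_equal(ctrl[[1]]$phantom$box, ctrl[[2]]$phantom$box)
  expect_equal(ctrl[[1]]$phantom$params$mean_somal_volume,
               ctrl[[2]]$phantom$params$mean_somal_volume)
})

test_that("a configured group effect appears in the emitted phantoms", {
  ctrl <- small_params()
  trt <- small_params(mean_somal_volume = 0.85 * 3600)
  trt$box <- ctrl$box * 0.92^(1 / 3)
  sc <- study_scenario(n_per_group = 8, control_params = ctrl,
                       treated_params = trt, between_animal_cv = 0.05)
  st <- generate_study(sc, seed = 21)
  som <- vapply(st, function(a) a$phantom$true_mean_somal_volume, 0)
  vol <- vapply(st, function(a) a$phantom$true_layer_volume, 0)
  grp <- vapply(st, function(a) a$group, "")
  expect_lt(mean(som[grp == "treated"]), mean(som[grp == "control"]))
  expect_lt(mean(vol[grp == "treated"]), mean(vol[grp == "control"]))
  expect_equal(sum(grp == "treated"), 8)
})

test_that("phantom JSON round-trip preserves ground truth and cells", {
  p <- generate_phantom(small_params(), seed = 2)
  f <- tempfile(fileext = ".json")
  write_phantom_json(p, f)
  q <- read_phantom_json(f)
  expect_equal(q$true_layer_volume, p$true_layer_volume)
  expect_equal(q$true_cell_count, p$true_cell_count)
  expect_equal(q$cells$cx, p$cells$cx)
  unlink(f)
})

test_that("scaling cells emulates isotropic volume shrinkage exactly", {
  p <- generate_phantom(small_params(nucleolus_eccentricity = 0.4), seed = 6)
  q <- scale_phantom_cells(p, 0.85)
  expect_equal(q$cells$volume, p$cells$volume * 0.85)
  expect_equal(q$true_mean_somal_volume, p$true_mean_somal_volume * 0.85)
  # nucleoli stay strictly inside the shrunken cells
  qq <- ((q$cells$nx - q$cells$cx) / q$cells$sa)^2 +
    ((q$cells$ny - q$cells$cy) / q$cells$sb)^2 +
    ((q$cells$nz - q$cells$cz) / q$cells$sc)^2
  expect_true(all(qq < 1))
})
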