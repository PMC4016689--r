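test_that("a centred-nucleolus sphere gives the exact sphere volume", {
  ph <- manual_phantom(data.frame(cx = 20, cy = 20, cz = 20, r = 7),
                       box = c(40, 40, 40))
  vs <- cut_vertical_sections(ph, section_plan(thickness = 2), n_blocks = 1,
                              seed = 1)
  rays <- sample_rays(ph, vs, cell_ids = 1, n_rays = 6, seed = 2)
  expect_equal(nrow(rays), 6)
  expect_true(all(abs(rays$length - 7) < 1e-12))
  est <- nucleator_mean_volume(rays)
  expect_equal(est$mean_volume, 4 / 3 * pi * 7^3)
  expect_equal(est$n_cells, 1L)
})

test_that("ray preconditions are enforced", {
  ph <- manual_phantom(data.frame(cx = 20, cy = 20, cz = 20, r = 7),
                       box = c(40, 40, 40))
  vs <- cut_vertical_sections(ph, section_plan(thickness = 2), n_blocks = 1,
                              seed = 1)
  expect_error(sample_rays(ph, vs, 1, n_rays = 3), "even")
  expect_error(sample_rays(ph, vs, 99), "unknown cell")
  # nucleolus outside the cell boundary is geometrically impossible input
  bad <- ph
  bad$cells$nx <- 40
  expect_error(sample_rays(bad, vs, 1, n_rays = 2, seed = 1), "outside")
})

test_that("ray angles to the vertical axis are sine-weighted", {
  ph <- manual_phantom(data.frame(cx = 20, cy = 20, cz = 20, r = 7),
                       box = c(40, 40, 40))
  vs <- cut_vertical_sections(ph, section_plan(thickness = 2), n_blocks = 1,
                              seed = 1)
  rays <- sample_rays(ph, vs, rep(1, 5000), n_rays = 2, seed = 3)
  alpha_fwd <- rays$alpha[seq_len(5000)]
  ks <- suppressWarnings(
    ks.test(alpha_fwd, function(q) (1 - cos(q)) / 2)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("the vertical nucleator pipeline is unbiased for sphere layers", {
  p <- generate_phantom(small_params(n_cells = 250, somal_cv = 0.25),
                        seed = 41)
  plan <- section_plan(thickness = 2)
  est <- vapply(1:60, function(i) {
    vs <- cut_vertical_sections(p, plan, n_blocks = 4, seed = 100 + i)
    ids <- select_cells_disector(vs, 9, seed = 300 + i)
    nucleator_mean_volume(sample_rays(p, vs, ids, 2, seed = 500 + i))$mean_volume
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - p$true_mean_somal_volume), 3 * se)
})

test_that("the nucleator stays unbiased for ellipsoids with eccentric nucleoli", {
  pp <- phantom_params(n_cells = 500, box = c(220, 220, 180),
                       shape = "ellipsoid", axis_ratio = c(1.4, 1, 0.7),
                       nucleolus_eccentricity = 0.5)
  p <- generate_phantom(pp, seed = 9)
  plan <- section_plan(thickness = 2)
  est <- vapply(1:60, function(i) {
    vs <- cut_vertical_sections(p, plan, n_blocks = 4, seed = 200 + i)
    ids <- select_cells_disector(vs, 9, seed = 400 + i)
    nucleator_mean_volume(sample_rays(p, vs, ids, 2, seed = 600 + i))$mean_volume
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - p$true_mean_somal_volume), 3 * se)
})

test_that("uniform in-plane rays are biased on anisotropic cells", {
  # documented negative control: dropping the sine weighting breaks the
  # vertical design on flattened ellipsoids
  pp <- phantom_params(n_cells = 500, box = c(220, 220, 180),
                       shape = "ellipsoid", axis_ratio = c(1.4, 1, 0.7))
  p <- generate_phantom(pp, seed = 9)
  plan <- section_plan(thickness = 2)
  est <- vapply(1:40, function(i) {
    vs <- cut_vertical_sections(p, plan, n_blocks = 4, seed = 200 + i)
    ids <- select_cells_disector(vs, 9, seed = 400 + i)
    nucleator_mean_volume(
      sample_rays(p, vs, ids, 2, seed = 600 + i, sine_weighted = FALSE)
    )$mean_volume
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_gt(abs(mean(est) - p$true_mean_somal_volume), 3 * se)
})

test_that("shrinkage arithmetic follows 1 - after/before", {
  expect_equal(shrinkage_fraction(1.0, 0.85), 0.15)
  expect_equal(shrinkage_fraction(2, 2), 0)
  expect_warning(s <- shrinkage_fraction(1, 1.1), "swelling")
  expect_lt(s, 0)
  expect_equal(weight_to_volume(0.5), 0.52)
})

test_that("shrinkage correction rescales per-cell volumes", {
  rays <- data.frame(sample_id = c(1, 1, 2, 2), cell_id = c(1, 1, 2, 2),
                     alpha = rep(pi / 2, 4), length = c(5, 5, 6, 6))
  est <- nucleator_mean_volume(rays)
  same <- correct_for_shrinkage(est, 0)
  expect_equal(same$mean_volume, est$mean_volume)
  dbl <- correct_for_shrinkage(est, 0.5)
  expect_equal(dbl$mean_volume, 2 * est$mean_volume)
  expect_equal(dbl$per_cell$volume, 2 * est$per_cell$volume)
  expect_error(correct_for_shrinkage(est, 1), "< 1")
})

test_that("shrink-measure-correct round-trips to the unshrunk pipeline", {
  p <- generate_phantom(small_params(n_cells = 200), seed = 51)
  plan <- section_plan(thickness = 2)
  run_arm <- function(ph, corr) {
    vs <- cut_vertical_sections(ph, plan, n_blocks = 4, seed = 7)
    ids <- select_cells_disector(vs, 9, seed = 8)
    est <- nucleator_mean_volume(sample_rays(ph, vs, ids, 2, seed = 9))
    if (corr > 0) est <- correct_for_shrinkage(est, corr) else est
  }
  plain <- run_arm(p, 0)
  shrunk <- run_arm(scale_phantom_cells(p, 1 - 0.15), 0.15)
  # same seeds: geometric scaling makes the round-trip nearly exact
  expect_lt(abs(shrunk$mean_volume - plain$mean_volume) /
              plain$mean_volume, 0.02)
})

test_that("per-sample histograms cover all measured cells", {
  p <- generate_phantom(small_params(), seed = 61)
  vs <- cut_vertical_sections(p, section_plan(thickness = 2), 4, seed = 1)
  ids <- select_cells_disector(vs, 9, seed = 2)
  est <- nucleator_mean_volume(sample_rays(p, vs, ids, 2, seed = 3))
  expect_equal(sum(est$histogram$counts), est$n_cells)
  expect_equal(est$n_cells, length(ids))
  expect_equal(est$mean_volume, mean(est$per_cell$volume))
})
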