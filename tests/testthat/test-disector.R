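test_that("counting-frame selection obeys the forbidden-line rule", {
  fr <- counting_frame(10, 10, 20, 20)
  inside <- data.frame(cell_id = 1, x = 20, y = 20, a = 3, b = 3)
  expect_identical(frame_select(inside, fr), 1)
  # crossing the left forbidden edge
  left <- data.frame(cell_id = 2, x = 10.5, y = 20, a = 2, b = 2)
  expect_length(frame_select(left, fr), 0)
  # crossing the upward extension of the left edge
  ext <- data.frame(cell_id = 3, x = 10.5, y = 32, a = 2, b = 2)
  expect_length(frame_select(ext, fr), 0)
  # crossing the top (inclusion) edge is fine
  top <- data.frame(cell_id = 4, x = 20, y = 29.5, a = 2, b = 2)
  expect_identical(frame_select(top, fr), 4)
  # entirely outside
  out <- data.frame(cell_id = 5, x = 50, y = 50, a = 2, b = 2)
  expect_length(frame_select(out, fr), 0)
})

test_that("tiling frames count every profile exactly once", {
  set.seed(55)
  n <- 400
  prof <- data.frame(
    cell_id = seq_len(n),
    x = runif(n, 25, 95), y = runif(n, 25, 95),
    a = runif(n, 0.5, 6), b = runif(n, 0.5, 6)
  )
  counts <- integer(n)
  for (ix in 0:5) for (iy in 0:5) {
    fr <- counting_frame(ix * 20, iy * 20, 20, 20)
    sel <- frame_select(prof, fr)
    counts[sel] <- counts[sel] + 1L
  }
  expect_true(all(counts == 1L))
})

test_that("Q-minus counts tops of the reference section", {
  fr <- counting_frame(0, 0, 40, 40)
  ref <- data.frame(cell_id = c(1, 2), x = c(20, 30), y = c(20, 25),
                    a = 3, b = 3)
  expect_equal(count_Q_minus(ref, ref, fr), 0)
  none <- ref[0, ]
  expect_equal(count_Q_minus(ref, none, fr), 2)
  look <- ref[ref$cell_id == 1, ]
  expect_equal(count_Q_minus(ref, look, fr), 1)
  expect_error(count_Q_minus(ref, look, fr, ref_section = 3,
                             lookup_section = 5), "consecutive")
})

test_that("phantom Q-minus equals the brute-force caliper-top oracle", {
  p <- generate_phantom(small_params(somal_cv = 0.3), seed = 17)
  st <- cut_serial_sections(p, section_plan(thickness = 2))
  pairs <- disector_pair_design(st, 7, seed = 3)
  dis <- run_disector(st, pairs, c(40, 40), directions = "both")
  # oracle: recompute tops per direction from raw cell extents
  ce <- p$cells
  t <- 2
  top_hi <- ceiling((ce$cz + ce$sc) / t) - 1  # last slab openly intersected
  top_lo <- floor((ce$cz - ce$sc) / t)
  oracle_Q <- function(ref, dir) {
    ids <- if (dir == "down") ce$cell_id[top_hi == ref] else
      ce$cell_id[top_lo == ref]
    # all profiles lie inside the footprint, so a frame tiling counts each
    sum(ids %in% ce$cell_id)
  }
  k <- 0
  for (pr in seq_len(nrow(pairs))) {
    for (d in c("down", "up")) {
      ref <- if (d == "down") pairs[pr, "ref"] else pairs[pr, "lookup"]
      if (ref < 0 || ref >= st$n_sections) next
      k <- k + 1
      expect_equal(dis$Q[k], oracle_Q(ref, d))
    }
  }
  expect_equal(k, nrow(dis))
})

test_that("numerical density divides counts by sampled volume", {
  d <- disector_counts("p1", 1, frame_area = 1e4, h = 2)
  nv <- numerical_density(d)
  expect_equal(nv$Nv, 5e4)
  expect_equal(nv$Nv_per_1e3, 50)
  z <- numerical_density(disector_counts(c("a", "b"), c(0, 0), 1e4, 2))
  expect_equal(z$Nv, 0)
  expect_error(disector_counts("p", -1, 1e4, 2), "non-negative")
})

test_that("disector density and number are unbiased on a phantom", {
  p <- generate_phantom(small_params(n_cells = 200, somal_cv = 0.25),
                        seed = 23)
  st <- cut_serial_sections(p, section_plan(thickness = 2))
  truth_nv <- p$true_cell_count / p$true_layer_volume
  est <- vapply(1:200, function(i) {
    pairs <- disector_pair_design(st, 6, seed = 9000 + i)
    numerical_density(run_disector(st, pairs, c(40, 40)))$Nv
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth_nv), 3 * se)
  # N = Nv x V with the true volume recovers the true count
  N <- total_number(mean(est), p$true_layer_volume)
  expect_lt(abs(N$N - p$true_cell_count), 3 * se * p$true_layer_volume)
})

test_that("swapping disector directions does not change the expectation", {
  both <- vapply(1:120, function(i) {
    p <- generate_phantom(small_params(n_cells = 120), seed = 7000 + i)
    st <- cut_serial_sections(p, section_plan(thickness = 2))
    pairs <- disector_pair_design(st, 6, seed = 400 + i)
    dis <- run_disector(st, pairs, c(40, 40), directions = "both")
    vapply(c("down", "up"), function(dir) {
      numerical_density(dis[grepl(dir, dis$pair_id), , drop = FALSE])$Nv
    }, numeric(1))
  }, numeric(2))
  # per-pair counts differ between directions...
  expect_false(isTRUE(all.equal(both[1, ], both[2, ])))
  # ...but the two directions estimate the same quantity
  d <- both[1, ] - both[2, ]
  se_d <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se_d)
})

test_that("total number reproduces printed stereological table arithmetic", {
  expect_equal(total_number(84e3, 1.90)$N_millions_rounded, 0.160)
  expect_equal(total_number(170e3, 1.48)$N_millions_rounded, 0.252)
  expect_equal(total_number(0, 1.5)$N, 0)
  expect_error(total_number(-1, 1), "invalid")
})
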