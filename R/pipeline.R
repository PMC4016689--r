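#' Configuration for a full simulated stereology study
#'
#' Bundles the two-group scenario with the sampling design of both
#' estimation arms: serial ("coronal") sectioning with Cavalieri point
#' counting and physical-disector counting, and vertical sectioning with
#' nucleator somal-volume estimation under tissue shrinkage.
#'
#' The defaults describe the scaled-down study the package simulates:
#' 500-cell phantoms (~85 x 10^3 cells/mm^3), 2 um sections, a sampling
#' period giving 13-14 consecutive section pairs, counting frames tiling
#' the layer footprint so the summed disector count lands in the 100-200
#' design window, a ~30 um test-point grid, about 100 cells measured per
#' animal with one bidirectional nucleator ray pair, and 15% volume
#' shrinkage applied to (and corrected in) the vertical arm only.
#'
#' @param scenario A [study_scenario()].
#' @param thickness Section thickness, um.
#' @param period Serial-section sampling period (sections between pairs).
#' @param grid_spacing Test-point spacing in the section plane, um.
#' @param frame_size Length-2 counting-frame dimensions, um; must tile the
#'   layer footprint.
#' @param directions Disector directions (`"both"` or `"down"`).
#' @param n_blocks Bars per animal for vertical sections.
#' @param vertical_period Pair-sampling period on the vertical sections
#'   (controls how many cells are measured).
#' @param n_rays Nucleator rays per sampled cell (even).
#' @param applied_shrinkage Volume shrinkage fraction simulated on the
#'   vertical-arm tissue before measurement.
#' @param corrected_shrinkage Shrinkage fraction used for the correction
#'   (equal to `applied_shrinkage` in the calibrated design).
#' @param alpha Significance level of the group comparisons.
#' @return Object of class `study_config`.
#' @export
study_config <- function(scenario = study_scenario(),
                         thickness = 2,
                         period = 6,
                         grid_spacing = 30,
                         frame_size = c(48, 48),
                         directions = "both",
                         n_blocks = 4,
                         vertical_period = 9,
                         n_rays = 2,
                         applied_shrinkage = 0.15,
                         corrected_shrinkage = 0.15,
                         alpha = 0.05) {
  structure(
    list(scenario = scenario, thickness = thickness, period = period,
         grid_spacing = grid_spacing, frame_size = frame_size,
         directions = directions, n_blocks = n_blocks,
         vertical_period = vertical_period, n_rays = n_rays,
         applied_shrinkage = applied_shrinkage,
         corrected_shrinkage = corrected_shrinkage, alpha = alpha),
    class = "study_config"
  )
}

#' Run both estimation arms on one phantom
#'
#' The serial arm cuts the phantom, samples consecutive section pairs
#' systematically, estimates the layer volume by Cavalieri point counting on
#' the reference section of each pair, and counts cells with the physical
#' disector. The vertical arm applies the configured tissue shrinkage, cuts
#' vertical sections, samples cells by disector selection, measures
#' sine-weighted nucleator rays, and corrects the somal volumes for
#' shrinkage.
#'
#' @param phantom A `phantom`.
#' @param config A [study_config()].
#' @param seed Integer RNG seed.
#' @return List of class `animal_result`: `V` (`volume_estimate`), `Nv`
#'   (`density_estimate`), `N` (`number_estimate`), `somal`
#'   (`somal_volume_estimate`, shrinkage-corrected), `Q_sequence` (per-pair
#'   disector counts, summed over directions), `ce_count` (Gundersen-Jensen
#'   CE of the count sequence), `n_pairs`.
#' @export
run_animal <- function(phantom, config, seed = NULL) {
  seeds <- derive_seeds(seed, 5L)
  plan <- section_plan(thickness = config$thickness, period = config$period)
  stack <- cut_serial_sections(phantom, plan)
  pairs <- disector_pair_design(stack, config$period, seed = seeds[1])

  # Cavalieri on the reference section of each sampled pair that lies in
  # the tissue (guard sections carry no layer profile).
  refs <- pairs[, "ref"]
  refs <- refs[refs >= 0 & refs < stack$n_sections]
  a_p_mm2 <- (config$grid_spacing / 1000)^2
  t_eff <- config$period * config$thickness
  P <- integer(length(refs))
  grid_seeds <- derive_seeds(seeds[2], length(refs))
  for (k in seq_along(refs)) {
    zmid <- (refs[k] + 0.5) * config$thickness
    if (footprint_area(phantom, zmid) > 0) {
      g <- point_grid(config$grid_spacing, seed = grid_seeds[k])
      P[k] <- count_points(stack$footprint, g)
    }
  }
  rec <- point_count_records(refs, P, a_p_mm2, t_eff)
  V <- cavalieri_volume(rec)

  # Physical disector over the same pairs. The frame grid is fitted to this
  # animal's footprint: the nearest exact tiling to the configured frame
  # size (animal-level layer volumes differ, so the footprint does too).
  nx <- max(1, round(phantom$box[1] / config$frame_size[1]))
  ny <- max(1, round(phantom$box[2] / config$frame_size[2]))
  frame_size <- c(phantom$box[1] / nx, phantom$box[2] / ny)
  dis <- run_disector(stack, pairs, frame_size,
                      directions = config$directions)
  Nv <- numerical_density(dis)
  N <- total_number(Nv, V)
  Qseq <- tapply(dis$Q, sub("_(down|up)$", "", dis$pair_id), sum)
  Qseq <- as.integer(Qseq[order(names(Qseq))])
  ce_count <- if (length(Qseq) >= 3) ce_cavalieri(Qseq) else NA_real_

  # Vertical arm: shrink, cut, sample, measure, correct.
  ph_v <- if (config$applied_shrinkage > 0) {
    scale_phantom_cells(phantom, 1 - config$applied_shrinkage)
  } else {
    phantom
  }
  vs <- cut_vertical_sections(ph_v, plan, n_blocks = config$n_blocks,
                              seed = seeds[3])
  ids <- select_cells_disector(vs, config$vertical_period, seed = seeds[4])
  somal <- NULL
  if (length(ids) > 0) {
    rays <- sample_rays(ph_v, vs, ids, n_rays = config$n_rays,
                        seed = seeds[5])
    somal <- nucleator_mean_volume(rays)
    if (config$corrected_shrinkage > 0) {
      somal <- correct_for_shrinkage(somal, config$corrected_shrinkage)
    }
  }
  structure(
    list(V = V, Nv = Nv, N = N, somal = somal, Q_sequence = Qseq,
         ce_count = ce_count, n_pairs = nrow(pairs)),
    class = "animal_result"
  )
}

#' Run a full two-group simulated stereology study
#'
#' Generates the per-animal phantoms of the scenario, runs both estimation
#' arms on every animal, aggregates group summaries (mean and CV) for the
#' four reported parameters — layer volume, numerical density, total cell
#' number and mean somal volume — and compares the groups with Student's
#' t-tests. Fully deterministic given `seed` (child seeds are derived
#' hierarchically).
#'
#' @param config A [study_config()].
#' @param seed Master integer seed.
#' @return Object of class `study_report`: `animals` (per-animal results
#'   data frame), `summaries` (per group x parameter), `comparisons` (list
#'   of `comparison_result`), `per_cell_volumes` (per animal, for
#'   distribution plots), `config`, `seed`.
#' @export
run_study <- function(config = study_config(), seed = NULL) {
  if (!inherits(config, "study_config")) {
    stop("'config' must come from study_config()", call. = FALSE)
  }
  n_animals <- 2L * config$scenario$n_per_group
  seeds <- derive_seeds(seed, n_animals + 1L)
  study <- generate_study(config$scenario, seed = seeds[1])
  animal_seeds <- seeds[-1]
  rows <- vector("list", n_animals)
  per_cell <- list(control = list(), treated = list())
  for (i in seq_len(n_animals)) {
    an <- study[[i]]
    res <- run_animal(an$phantom, config, seed = animal_seeds[i])
    rows[[i]] <- data.frame(
      animal_id = an$animal_id,
      group = an$group,
      V_mm3 = res$V$V,
      CE_V = res$V$CE,
      Nv_1e3_mm3 = res$Nv$Nv_per_1e3,
      total_Q = res$Nv$total_Q,
      CE_count = res$ce_count,
      N_1e6 = res$N$N_millions,
      somal_um3 = if (is.null(res$somal)) NA_real_ else
        res$somal$mean_volume,
      cells_measured = if (is.null(res$somal)) 0L else res$somal$n_cells,
      n_pairs = res$n_pairs,
      true_V_mm3 = an$phantom$true_layer_volume,
      true_Nv_1e3_mm3 = an$phantom$true_cell_count /
        an$phantom$true_layer_volume / 1e3,
      true_somal_um3 = an$phantom$true_mean_somal_volume
    )
    if (!is.null(res$somal)) {
      per_cell[[an$group]][[an$animal_id]] <- res$somal$per_cell$volume
    }
  }
  animals <- do.call(rbind, rows)
  params <- c(V_mm3 = "layer volume (mm^3)",
              Nv_1e3_mm3 = "numerical density (x10^3/mm^3)",
              N_1e6 = "total number (x10^6)",
              somal_um3 = "mean somal volume (um^3)")
  summaries <- list()
  comparisons <- list()
  for (col in names(params)) {
    a <- animals[animals$group == "control", col]
    b <- animals[animals$group == "treated", col]
    summaries[[col]] <- list(control = summarize_group(a),
                             treated = summarize_group(b))
    comparisons[[col]] <- t_test_groups(b, a, variant = "pooled",
                                        parameter = params[[col]],
                                        alpha = config$alpha)
  }
  structure(
    list(animals = animals, summaries = summaries,
         comparisons = comparisons, per_cell_volumes = per_cell,
         config = config, seed = seed),
    class = "study_report"
  )
}

#' Check a study report against its design targets
#'
#' Flags animals whose summed disector count falls outside the 100-200
#' design window or whose count coefficient of error reaches 0.10.
#'
#' @param report A [run_study()] report.
#' @param q_range Acceptable window for the summed disector count.
#' @param ce_max Exclusive upper bound for the CE.
#' @return Data frame with one row per animal: `animal_id`, `total_Q`,
#'   `CE_count`, `q_ok`, `ce_ok`, `status` (`"pass"`/`"warn"`).
#' @export
design_check <- function(report, q_range = c(100, 200), ce_max = 0.10) {
  a <- report$animals
  q_ok <- a$total_Q >= q_range[1] & a$total_Q <= q_range[2]
  ce_ok <- is.finite(a$CE_count) & a$CE_count < ce_max
  data.frame(animal_id = a$animal_id, total_Q = a$total_Q,
             CE_count = a$CE_count, q_ok = q_ok, ce_ok = ce_ok,
             status = ifelse(q_ok & ce_ok, "pass", "warn"))
}

#' Format a study report as a stereological summary table
#'
#' One row per parameter with per-group "mean (CV)" entries and the t-test
#' p-value, using the printing conventions of stereological reports: layer
#' volumes to 2 decimals, densities to whole 10^3/mm^3, total numbers to 3
#' decimals of 10^6, somal volumes to whole um^3, CVs to 2 decimals.
#'
#' @param report A [run_study()] report.
#' @return Data frame with columns `parameter`, `treated`, `control`, `p`.
#' @export
format_report_table <- function(report) {
  fmt <- list(
    V_mm3 = function(x) sprintf("%.2f", x),
    Nv_1e3_mm3 = function(x) sprintf("%.0f", x),
    N_1e6 = function(x) sprintf("%.3f", x),
    somal_um3 = function(x) sprintf("%.0f", x)
  )
  labels <- c(V_mm3 = "Volume of cell layer (mm^3)",
              Nv_1e3_mm3 = "Numerical density (x10^3/mm^3)",
              N_1e6 = "Number of cells (x10^6)",
              somal_um3 = "Individual somal volume (um^3)")
  rows <- lapply(names(fmt), function(col) {
    s <- report$summaries[[col]]
    cmp <- report$comparisons[[col]]
    data.frame(
      parameter = labels[[col]],
      treated = sprintf("%s (%.2f)", fmt[[col]](s$treated$mean),
                        s$treated$cv),
      control = sprintf("%s (%.2f)", fmt[[col]](s$control$mean),
                        s$control$cv),
      p = sprintf("%.3f", cmp$p)
    )
  })
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("simulated stereology study: %d animals/group, seed %s\n",
              x$config$scenario$n_per_group, format(x$seed)))
  print(format_report_table(x), row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes the per-animal table and design diagnostics as CSV, the summary
#' table as CSV and Markdown, and the comparisons as JSON.
#'
#' @param report A [run_study()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  utils::write.csv(design_check(report), file.path(dir, "design_check.csv"),
                   row.names = FALSE)
  tab <- format_report_table(report)
  utils::write.csv(tab, file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  md <- c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
          paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
          apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |")))
  writeLines(md, file.path(dir, "summary_table.md"))
  cmp <- lapply(report$comparisons, function(x) {
    x[c("parameter", "mean_a", "mean_b", "t", "df", "p", "significant")]
  })
  jsonlite::write_json(cmp, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
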