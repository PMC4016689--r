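#' Parameter set for a synthetic cell-layer phantom
#'
#' Describes a bounded 3D cell layer — an axis-aligned box of pyramidal-layer
#' tissue — populated by convex cells (spheres or axis-aligned triaxial
#' ellipsoids) whose somal volumes follow a log-normal distribution. Each cell
#' carries an interior nucleolus point. The defaults emulate a scaled-down
#' hippocampal pyramidal layer: numerical density near 85 x 10^3 cells/mm^3
#' and mean somal volume near 3600 um^3.
#'
#' @param n_cells Number of cells to place (positive integer).
#' @param box Numeric length-3, box edge lengths in um (x, y, z).
#' @param mean_somal_volume Target mean somal volume, um^3.
#' @param somal_cv Coefficient of variation of the somal-volume distribution
#'   (0 gives monodisperse cells).
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param axis_ratio Length-3 relative semi-axis ratios for ellipsoids
#'   (rescaled internally to preserve the target volume distribution).
#' @param nucleolus_eccentricity Fraction in `[0, 1)`: each nucleolus is
#'   placed uniformly in the cell scaled by this fraction; 0 puts it at the
#'   cell center.
#' @param min_sep_frac Minimum allowed center separation between two cells,
#'   as a fraction of the sum of their equivalent radii. 0 disables the
#'   packing rule; the default 0.6 lets neighbours overlap moderately while
#'   keeping nucleoli out of other cells.
#' @param max_attempts_per_cell Placement attempts per cell before the
#'   generator gives up with a packing-failure error.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_cells = 500,
                           box = c(192, 192, 160),
                           mean_somal_volume = 3600,
                           somal_cv = 0.25,
                           shape = c("sphere", "ellipsoid"),
                           axis_ratio = c(1.3, 1, 0.8),
                           nucleolus_eccentricity = 0,
                           min_sep_frac = 0.6,
                           max_attempts_per_cell = 500) {
  shape <- match.arg(shape)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells)) {
    stop("'n_cells' must be a positive integer", call. = FALSE)
  }
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("'box' must be three positive edge lengths (um)", call. = FALSE)
  }
  stopifnot_scalar_pos(mean_somal_volume, "mean_somal_volume")
  if (somal_cv < 0) stop("'somal_cv' must be >= 0", call. = FALSE)
  if (nucleolus_eccentricity < 0 || nucleolus_eccentricity >= 1) {
    stop("'nucleolus_eccentricity' must lie in [0, 1)", call. = FALSE)
  }
  if (min_sep_frac < 0) stop("'min_sep_frac' must be >= 0", call. = FALSE)
  if (shape == "ellipsoid" &&
      (length(axis_ratio) != 3L || any(axis_ratio <= 0))) {
    stop("'axis_ratio' must be three positive ratios", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells),
      box = as.numeric(box),
      mean_somal_volume = mean_somal_volume,
      somal_cv = somal_cv,
      shape = shape,
      axis_ratio = as.numeric(axis_ratio),
      nucleolus_eccentricity = nucleolus_eccentricity,
      min_sep_frac = min_sep_frac,
      max_attempts_per_cell = as.integer(max_attempts_per_cell)
    ),
    class = "phantom_params"
  )
}

# Log-normal equivalent radii with a prescribed mean volume and volume CV.
# If V ~ logN(mu, sigma^2) then r = (3V / 4pi)^(1/3) is log-normal too,
# with mu_r = (mu - log(4pi/3)) / 3 and sigma_r = sigma / 3.
draw_equiv_radii <- function(n, mean_volume, cv) {
  if (cv == 0) {
    return(rep((3 * mean_volume / (4 * pi))^(1 / 3), n))
  }
  sigma2 <- log(1 + cv^2)
  mu <- log(mean_volume) - sigma2 / 2
  v <- stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
  (3 * v / (4 * pi))^(1 / 3)
}

#' Generate a synthetic tissue phantom with known ground truth
#'
#' Places `n_cells` convex cells uniformly inside the layer box (each cell
#' kept entirely within the box, subject to the configured minimum-separation
#' rule) and records exact ground truth: layer volume, cell count, and mean
#' somal volume. Deterministic given `seed`.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer RNG seed (or `NULL` to use the current stream).
#' @return Object of class `phantom` with elements `cells` (data frame:
#'   `cell_id`, center `cx, cy, cz`, semi-axes `sa, sb, sc`, nucleolus
#'   `nx, ny, nz`, equivalent radius `r_eq`, somal volume `volume`),
#'   `box` (um), `true_layer_volume` (mm^3), `true_cell_count`,
#'   `true_mean_somal_volume` (um^3), `params`, and `seed`.
#' @export
generate_phantom <- function(params, seed = NULL) {
  if (!inherits(params, "phantom_params")) {
    stop("'params' must come from phantom_params()", call. = FALSE)
  }
  with_seed(seed, {
    n <- params$n_cells
    box <- params$box
    r_eq <- draw_equiv_radii(n, params$mean_somal_volume, params$somal_cv)
    if (params$shape == "sphere") {
      semi <- cbind(sa = r_eq, sb = r_eq, sc = r_eq)
    } else {
      ratio <- params$axis_ratio / prod(params$axis_ratio)^(1 / 3)
      semi <- cbind(sa = r_eq * ratio[1], sb = r_eq * ratio[2],
                    sc = r_eq * ratio[3])
    }
    # Per-axis margin keeps each cell entirely inside the layer box.
    for (ax in 1:3) {
      if (any(2 * semi[, ax] > box[ax])) {
        stop("cells too large for the region box", call. = FALSE)
      }
    }
    centers <- place_centers(semi, r_eq, box, params$min_sep_frac,
                             params$max_attempts_per_cell)
    nuc <- draw_nucleoli(centers, semi, params$nucleolus_eccentricity)
    vol <- 4 / 3 * pi * semi[, 1] * semi[, 2] * semi[, 3]
    cells <- data.frame(
      cell_id = seq_len(n),
      cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
      sa = semi[, 1], sb = semi[, 2], sc = semi[, 3],
      nx = nuc[, 1], ny = nuc[, 2], nz = nuc[, 3],
      r_eq = r_eq, volume = vol
    )
    structure(
      list(
        cells = cells,
        box = box,
        shape = params$shape,
        true_layer_volume = prod(box) / UM3_PER_MM3,
        true_cell_count = n,
        true_mean_somal_volume = mean(vol),
        params = params,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      ),
      class = "phantom"
    )
  })
}

# Sequential uniform placement with an optional hard minimum-separation rule.
place_centers <- function(semi, r_eq, box, min_sep_frac, max_attempts) {
  n <- nrow(semi)
  lo <- semi
  hi <- cbind(box[1] - semi[, 1], box[2] - semi[, 2], box[3] - semi[, 3])
  if (min_sep_frac == 0) {
    u <- matrix(stats::runif(3 * n), ncol = 3)
    return(lo + u * (hi - lo))
  }
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- lo[i, ] + stats::runif(3) * (hi[i, ] - lo[i, ])
      if (i == 1L) { placed <- TRUE; break }
      prev <- seq_len(i - 1L)
      d2 <- (centers[prev, 1] - cand[1])^2 +
            (centers[prev, 2] - cand[2])^2 +
            (centers[prev, 3] - cand[3])^2
      min_d <- min_sep_frac * (r_eq[prev] + r_eq[i])
      if (all(d2 >= min_d^2)) { placed <- TRUE; break }
    }
    if (!placed) {
      stop(sprintf(
        "packing failure: could not place cell %d of %d after %d attempts",
        i, n, max_attempts), call. = FALSE)
    }
    centers[i, ] <- cand
  }
  centers
}

# Nucleolus uniform in the cell scaled by the eccentricity fraction: draw a
# point uniformly in the unit ball and map through the scaled semi-axes.
draw_nucleoli <- function(centers, semi, ecc) {
  n <- nrow(centers)
  if (ecc == 0) {
    return(centers)
  }
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- stats::runif(n)^(1 / 3)
  centers + u * rad * ecc * semi
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %d %s cells in %.0f x %.0f x %.0f um box\n",
    x$true_cell_count, x$shape, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  true layer volume     : %.4g mm^3\n", x$true_layer_volume))
  cat(sprintf("  true numerical density: %.4g x10^3/mm^3\n",
              x$true_cell_count / x$true_layer_volume / 1e3))
  cat(sprintf("  true mean somal volume: %.4g um^3\n",
              x$true_mean_somal_volume))
  invisible(x)
}

#' Scale all cells of a phantom by a volume factor
#'
#' Used to emulate isotropic tissue shrinkage: every cell (and its nucleolus
#' offset) is scaled about the cell center by `volume_factor^(1/3)`, so somal
#' volumes scale by `volume_factor`. Ground-truth somal fields are updated;
#' the layer box is left unchanged.
#'
#' @param phantom A `phantom`.
#' @param volume_factor Positive volume scale (e.g. `1 - 0.15` for 15%
#'   volume shrinkage).
#' @return The scaled `phantom`.
#' @export
scale_phantom_cells <- function(phantom, volume_factor) {
  stopifnot_scalar_pos(volume_factor, "volume_factor")
  f <- volume_factor^(1 / 3)
  ce <- phantom$cells
  ce$nx <- ce$cx + (ce$nx - ce$cx) * f
  ce$ny <- ce$cy + (ce$ny - ce$cy) * f
  ce$nz <- ce$cz + (ce$nz - ce$cz) * f
  ce$sa <- ce$sa * f; ce$sb <- ce$sb * f; ce$sc <- ce$sc * f
  ce$r_eq <- ce$r_eq * f
  ce$volume <- ce$volume * volume_factor
  phantom$cells <- ce
  phantom$true_mean_somal_volume <- mean(ce$volume)
  phantom
}

#' Define a two-group simulated study scenario
#'
#' Two groups of animals (control and a "stressed" condition), each animal an
#' independent phantom whose parameters are drawn around its group means with
#' a between-animal coefficient of variation. The default treated condition
#' mirrors the headline structure of a prenatal-stress experiment: smaller
#' mean somal volume and smaller layer volume with unchanged cell number.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param control_params [phantom_params()] for the control group.
#' @param treated_params [phantom_params()] for the treated group.
#' @param between_animal_cv Between-animal CV applied (independently) to mean
#'   somal volume and layer volume; cell count is kept at the group value.
#' @return Object of class `study_scenario`.
#' @export
study_scenario <- function(n_per_group = 8,
                           control_params = phantom_params(),
                           treated_params = NULL,
                           between_animal_cv = 0.07) {
  if (n_per_group < 2) stop("'n_per_group' must be >= 2", call. = FALSE)
  if (between_animal_cv < 0) {
    stop("'between_animal_cv' must be >= 0", call. = FALSE)
  }
  if (is.null(treated_params)) {
    # Default effect: 15% smaller somata, ~8% smaller layer, same count.
    treated_params <- control_params
    treated_params$mean_somal_volume <- 0.85 * control_params$mean_somal_volume
    treated_params$box <- control_params$box * (0.92)^(1 / 3)
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      control_params = control_params,
      treated_params = treated_params,
      between_animal_cv = between_animal_cv
    ),
    class = "study_scenario"
  )
}

#' Generate the per-animal phantoms of a two-group study
#'
#' Draws one phantom per animal. Animal-level mean somal volume and layer
#' volume are jittered around the group values with log-normal multipliers of
#' unit mean and CV `between_animal_cv`; group assignment is balanced.
#' Deterministic given `seed`.
#'
#' @param scenario A [study_scenario()].
#' @param seed Integer RNG seed.
#' @return A list of class `study_phantoms`: one element per animal with
#'   `animal_id`, `group` (`"control"`/`"treated"`), and `phantom`.
#' @export
generate_study <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "study_scenario")) {
    stop("'scenario' must come from study_scenario()", call. = FALSE)
  }
  n <- scenario$n_per_group
  seeds <- derive_seeds(seed, 2L * n + 1L)
  animals <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    grp <- if (i <= n) "control" else "treated"
    base <- if (grp == "control") scenario$control_params else
      scenario$treated_params
    p <- jitter_params(base, scenario$between_animal_cv, seeds[i])
    animals[[i]] <- list(
      animal_id = sprintf("%s_%02d", grp, ((i - 1L) %% n) + 1L),
      group = grp,
      phantom = generate_phantom(p, seed = seeds[i])
    )
  }
  structure(animals, class = "study_phantoms",
            scenario = scenario, seed = seed)
}

# Animal-level biological variability: log-normal multipliers (mean 1) on the
# group mean somal volume and on the layer volume (box scaled isotropically).
jitter_params <- function(params, cv, seed) {
  if (cv == 0) return(params)
  with_seed(seed + 1L, {
    s2 <- log(1 + cv^2)
    m_som <- stats::rlnorm(1, -s2 / 2, sqrt(s2))
    m_vol <- stats::rlnorm(1, -s2 / 2, sqrt(s2))
    params$mean_somal_volume <- params$mean_somal_volume * m_som
    params$box <- params$box * m_vol^(1 / 3)
    params
  })
}

#' Export a phantom's cell table
#'
#' @param phantom A `phantom`.
#' @return Data frame with one row per cell (id, center, semi-axes,
#'   nucleolus, somal volume).
#' @export
phantom_cell_table <- function(phantom) {
  phantom$cells
}

#' Serialize / restore a phantom as JSON
#'
#' Ground truth and the full cell table are written so a phantom can be
#' archived and reloaded exactly.
#'
#' @param phantom A `phantom`.
#' @param path File path to write to / read from.
#' @return `write_phantom_json` returns `path` invisibly;
#'   `read_phantom_json` returns the restored `phantom`.
#' @export
write_phantom_json <- function(phantom, path) {
  obj <- list(
    box = phantom$box,
    shape = phantom$shape,
    true_layer_volume = phantom$true_layer_volume,
    true_cell_count = phantom$true_cell_count,
    true_mean_somal_volume = phantom$true_mean_somal_volume,
    seed = phantom$seed,
    cells = phantom$cells
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      cells = as.data.frame(obj$cells),
      box = as.numeric(obj$box),
      shape = obj$shape,
      true_layer_volume = obj$true_layer_volume,
      true_cell_count = obj$true_cell_count,
      true_mean_somal_volume = obj$true_mean_somal_volume,
      params = NULL,
      seed = obj$seed
    ),
    class = "phantom"
  )
}
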