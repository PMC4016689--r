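#' Area per test point of a projected point grid
#'
#' A square grid with points `screen_spacing` apart on the projection screen
#' corresponds, at linear magnification `magnification`, to an area per point
#' of `(screen_spacing / magnification)^2` in the section plane.
#'
#' @param screen_spacing Point spacing on the screen, mm.
#' @param magnification Linear magnification (dimensionless).
#' @return Area per point in mm^2.
#' @export
point_area <- function(screen_spacing, magnification) {
  stopifnot_scalar_pos(screen_spacing, "screen_spacing")
  stopifnot_scalar_pos(magnification, "magnification")
  (screen_spacing / magnification)^2
}

#' Systematic uniform test-point grid
#'
#' @param spacing Grid spacing in the section plane, um.
#' @param offset Length-2 offset in `[0, spacing)^2`; drawn uniformly at
#'   random when `NULL`.
#' @param rotation Grid rotation angle in radians (default 0, axis-aligned).
#' @param seed Integer RNG seed for the random offset.
#' @return Object of class `point_grid`.
#' @export
point_grid <- function(spacing, offset = NULL, rotation = 0, seed = NULL) {
  stopifnot_scalar_pos(spacing, "spacing")
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, 0, spacing))
  }
  if (length(offset) != 2L || any(offset < 0) || any(offset >= spacing)) {
    stop("'offset' components must lie in [0, spacing)", call. = FALSE)
  }
  structure(list(spacing = spacing, offset = as.numeric(offset),
                 rotation = rotation),
            class = "point_grid")
}

#' Count test points hitting a 2D region
#'
#' Counts grid points falling in the region. Points strictly inside always
#' count; points on the boundary are resolved by a half-open rule (a point on
#' an inclusion edge counts, on the opposite edge it does not), so tiling a
#' plane with congruent regions counts every grid point exactly once.
#'
#' @param region Either an `n x 2` matrix of polygon vertices (closed
#'   implicitly, any orientation) or a list `list(type = "disc", center =
#'   c(x, y), radius = r)`; um coordinates.
#' @param grid A [point_grid()].
#' @return Integer hit count P.
#' @export
count_points <- function(region, grid) {
  if (!inherits(grid, "point_grid")) {
    stop("'grid' must come from point_grid()", call. = FALSE)
  }
  if (is.list(region) && identical(region$type, "disc")) {
    verts <- cbind(region$center[1] + c(-1, 1, 1, -1) * region$radius,
                   region$center[2] + c(-1, -1, 1, 1) * region$radius)
  } else {
    region <- as.matrix(region)
    if (!is.numeric(region) || ncol(region) != 2L || nrow(region) < 3L) {
      stop("'region' must be a polygon matrix or a disc", call. = FALSE)
    }
    if (any(!is.finite(region))) {
      stop("'region' must be bounded", call. = FALSE)
    }
    verts <- region
  }
  s <- grid$spacing
  th <- grid$rotation
  # Work in the grid's frame: rotate the region by -theta, lay down the
  # axis-aligned lattice there, and test membership back in that frame.
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  vr <- verts %*% rot
  bx <- range(vr[, 1]); by <- range(vr[, 2])
  kx <- seq(floor((bx[1] - grid$offset[1]) / s) - 1,
            ceiling((bx[2] - grid$offset[1]) / s) + 1)
  ky <- seq(floor((by[1] - grid$offset[2]) / s) - 1,
            ceiling((by[2] - grid$offset[2]) / s) + 1)
  gx <- rep(grid$offset[1] + kx * s, times = length(ky))
  gy <- rep(grid$offset[2] + ky * s, each = length(kx))
  if (is.list(region) && identical(region$type, "disc")) {
    # Map lattice points back to world coordinates for the disc test.
    wx <- gx * cos(th) - gy * sin(th)
    wy <- gx * sin(th) + gy * cos(th)
    hits <- (wx - region$center[1])^2 + (wy - region$center[2])^2 <
      region$radius^2
  } else {
    hits <- points_in_polygon(gx, gy, vr)
  }
  sum(hits)
}

#' Assemble per-section point-count records
#'
#' @param section_index Integer section indices.
#' @param P Integer hit counts per section.
#' @param a_p Area per point, mm^2 (shared by all records).
#' @param t_eff Distance between sampled sections, um (shared).
#' @return Data frame of class `point_count_records`.
#' @export
point_count_records <- function(section_index, P, a_p, t_eff) {
  if (any(P < 0)) stop("'P' must be non-negative", call. = FALSE)
  stopifnot_scalar_pos(a_p, "a_p")
  stopifnot_scalar_pos(t_eff, "t_eff")
  structure(
    data.frame(section_index = as.integer(section_index), P = as.integer(P),
               a_p = a_p, t_eff = t_eff),
    class = c("point_count_records", "data.frame")
  )
}

#' Cavalieri volume estimate from point counts
#'
#' `V = t_eff * sum(P) * a_p`, with `t_eff` the distance between sampled
#' sections (um) and `a_p` the area per point (mm^2); the result is in mm^3.
#' The coefficient of error is the Gundersen-Jensen systematic-sampling
#' estimate from [ce_cavalieri()].
#'
#' @param records A [point_count_records()] data frame (all records must
#'   share `a_p` and `t_eff`).
#' @param shape_factor Profile shape factor b/sqrt(a) passed to the CE noise
#'   term.
#' @return Object of class `volume_estimate`: `V` (mm^3), `CE`,
#'   `n_sections`, `total_points`.
#' @export
cavalieri_volume <- function(records, shape_factor = 2 * sqrt(pi)) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("at least one point-count record is required", call. = FALSE)
  }
  if (length(unique(records$a_p)) != 1L ||
      length(unique(records$t_eff)) != 1L) {
    stop("all records must share 'a_p' and 't_eff'", call. = FALSE)
  }
  a_p <- records$a_p[1]
  t_eff_mm <- records$t_eff[1] / 1000
  total_P <- sum(records$P)
  V <- t_eff_mm * total_P * a_p
  CE <- if (nrow(records) >= 3L) {
    ce_cavalieri(records$P, shape_factor = shape_factor)
  } else {
    NA_real_
  }
  structure(list(V = V, CE = CE, n_sections = nrow(records),
                 total_points = total_P),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("Cavalieri volume estimate: %.4g mm^3 (CE %.3f, %d sections, %d points)\n",
              x$V, x$CE, x$n_sections, x$total_points))
  invisible(x)
}

#' Gundersen-Jensen coefficient of error for a systematic count sequence
#'
#' For an ordered sequence of counts from systematically sampled sections,
#' the total variance combines the systematic-sampling (smoothness class
#' m = 1) term with a point-counting "nugget" noise term:
#' \deqn{noise = 0.0724 (b/\sqrt{a}) \sqrt{n \sum P}}
#' \deqn{totalvar = (3 (A - noise) - 4 B + C) / 240 + noise}
#' with \eqn{A = \sum P_i^2}, \eqn{B = \sum P_i P_{i+1}},
#' \eqn{C = \sum P_i P_{i+2}}, and `CE = sqrt(totalvar) / sum(P)`. The
#' systematic term is clamped at zero if the finite sequence drives it
#' negative.
#'
#' @param P Ordered integer counts (length >= 3).
#' @param shape_factor Mean profile shape factor b/sqrt(a); the default
#'   `2 * sqrt(pi)` is the value for circular profiles.
#' @param include_noise Set `FALSE` to drop the nugget term (useful for
#'   testing the systematic term alone).
#' @return The CE estimate (0 when `sum(P)` is 0).
#' @export
ce_cavalieri <- function(P, shape_factor = 2 * sqrt(pi),
                         include_noise = TRUE) {
  if (length(P) < 3L) stop("at least 3 counts are required", call. = FALSE)
  if (any(P < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- length(P)
  total <- sum(P)
  if (total == 0) return(0)
  A <- sum(P^2)
  B <- sum(P[-n] * P[-1])
  C <- sum(P[seq_len(n - 2)] * P[-(1:2)])
  noise <- if (include_noise) 0.0724 * shape_factor * sqrt(n * total) else 0
  sys_var <- max(0, (3 * (A - noise) - 4 * B + C) / 240)
  sqrt(sys_var + noise) / total
}
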