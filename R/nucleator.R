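#' Sample sine-weighted nucleator rays for cells on vertical sections
#'
#' For each selected cell, ray directions are drawn in its vertical section
#' plane (the plane with the block's azimuth passing through the nucleolus).
#' The angle alpha between a ray and the vertical axis is sampled with
#' probability density proportional to `sin(alpha)` — the weighting that
#' restores 3D isotropy under the vertical-sections design — and each
#' direction is paired with its antipode (a "bidirectional" ruler), so
#' `n_rays` must be even. Lengths run from the nucleolus to the cell
#' boundary.
#'
#' @param phantom The `phantom` the cells belong to.
#' @param vs A [cut_vertical_sections()] object.
#' @param cell_ids Cells to measure. Repeated ids are treated as distinct
#'   sampling events (as when a cell is hit by more than one disector), so
#'   the selection stays exactly number-weighted.
#' @param n_rays Rays per cell (even, >= 2).
#' @param seed Integer RNG seed.
#' @param sine_weighted Set `FALSE` to draw alpha uniformly instead — a
#'   deliberately biased negative control for anisotropic cells.
#' @return Data frame of class `ray_samples`: `sample_id`, `cell_id`,
#'   `alpha` (angle to the vertical axis), `length` (um).
#' @export
sample_rays <- function(phantom, vs, cell_ids, n_rays = 2, seed = NULL,
                        sine_weighted = TRUE) {
  if (n_rays < 2 || n_rays %% 2 != 0) {
    stop("'n_rays' must be an even number >= 2", call. = FALSE)
  }
  ce <- phantom$cells
  idx <- match(cell_ids, ce$cell_id)
  if (anyNA(idx)) stop("unknown cell id", call. = FALSE)
  qn <- ((ce$nx - ce$cx) / ce$sa)^2 + ((ce$ny - ce$cy) / ce$sb)^2 +
    ((ce$nz - ce$cz) / ce$sc)^2
  if (any(qn[idx] >= 1)) {
    stop("nucleolus lies outside the cell boundary", call. = FALSE)
  }
  vc <- vs$cells[match(cell_ids, vs$cells$cell_id), , drop = FALSE]
  n_half <- n_rays / 2L
  m <- length(cell_ids)
  with_seed(seed, {
    u <- stats::runif(m * n_half)
    alpha <- if (sine_weighted) acos(1 - 2 * u) else u * pi
    cell_rep <- rep(idx, each = n_half)
    phi <- rep(vc$azimuth, each = n_half)
    # In-plane basis: vertical axis z and the horizontal in-plane unit
    # vector (cos phi, sin phi, 0).
    dx <- sin(alpha) * cos(phi)
    dy <- sin(alpha) * sin(phi)
    dz <- cos(alpha)
    px <- ce$nx[cell_rep]; py <- ce$ny[cell_rep]; pz <- ce$nz[cell_rep]
    args <- list(px = px, py = py, pz = pz,
                 cx = ce$cx[cell_rep], cy = ce$cy[cell_rep],
                 cz = ce$cz[cell_rep], sa = ce$sa[cell_rep],
                 sb = ce$sb[cell_rep], sc = ce$sc[cell_rep])
    l_fwd <- ray_length_ellipsoid(px, py, pz, dx, dy, dz,
                                  args$cx, args$cy, args$cz,
                                  args$sa, args$sb, args$sc)
    l_bwd <- ray_length_ellipsoid(px, py, pz, -dx, -dy, -dz,
                                  args$cx, args$cy, args$cz,
                                  args$sa, args$sb, args$sc)
    structure(
      data.frame(
        sample_id = rep(rep(seq_along(cell_ids), each = n_half), times = 2),
        cell_id = rep(rep(cell_ids, each = n_half), times = 2),
        alpha = c(alpha, pi - alpha),
        length = c(l_fwd, l_bwd)
      ),
      class = c("ray_samples", "data.frame")
    )
  })
}

#' Nucleator estimate of mean somal volume
#'
#' Per-cell volume `v = (4*pi/3) * mean(l^3)` over that cell's rays; the
#' population estimate is the mean over sampled cells. A fixed-width
#' histogram of the per-cell volumes is included for size-distribution
#' plots.
#'
#' @param rays A [sample_rays()] data frame (or any data frame with
#'   `cell_id` and `length`; rays are grouped by `sample_id` when present so
#'   repeated disector hits of one cell stay distinct sampling events).
#' @param bin_width Histogram bin width in um^3; `NULL` picks a width giving
#'   at least 10 bins over the observed range.
#' @return Object of class `somal_volume_estimate`: `mean_volume` (um^3),
#'   `n_cells`, `per_cell` (data frame `cell_id`, `volume`), `cv`,
#'   `histogram` (`breaks`, `counts`), `shrinkage_corrected`.
#' @export
nucleator_mean_volume <- function(rays, bin_width = NULL) {
  if (!is.data.frame(rays) || nrow(rays) == 0L) {
    stop("no ray measurements supplied", call. = FALSE)
  }
  if (any(rays$length < 0)) stop("ray lengths must be >= 0", call. = FALSE)
  key <- if ("sample_id" %in% names(rays)) rays$sample_id else rays$cell_id
  l3 <- tapply(rays$length^3, key, mean)
  cell_of <- tapply(rays$cell_id, key, function(x) x[1])
  per_cell <- data.frame(
    cell_id = as.vector(cell_of),
    volume = as.numeric(4 / 3 * pi * l3)
  )
  build_somal_estimate(per_cell, bin_width, corrected = FALSE)
}

build_somal_estimate <- function(per_cell, bin_width, corrected) {
  v <- per_cell$volume
  rng <- range(v)
  if (is.null(bin_width)) {
    span <- max(rng[2] - rng[1], max(rng[2], 1) * 1e-6)
    bin_width <- span / 10
  }
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                rng[2] + bin_width, by = bin_width)
  counts <- as.integer(table(cut(v, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(
    list(mean_volume = mean(v), n_cells = length(v), per_cell = per_cell,
         cv = if (length(v) > 1) stats::sd(v) / mean(v) else NA_real_,
         histogram = list(breaks = breaks, counts = counts),
         shrinkage_corrected = corrected),
    class = "somal_volume_estimate"
  )
}

#' @export
print.somal_volume_estimate <- function(x, ...) {
  cat(sprintf(
    "nucleator somal volume: mean %.0f um^3 over %d cells (CV %.2f)%s\n",
    x$mean_volume, x$n_cells, x$cv,
    if (x$shrinkage_corrected) ", shrinkage-corrected" else ""))
  invisible(x)
}

#' Volume shrinkage fraction of a processed tissue bar
#'
#' `shrinkage = 1 - volume_after / volume_before`. A negative value
#' (swelling) is physically possible and produces a warning, not an error.
#'
#' @param volume_before Fresh volume, cm^3 (see [weight_to_volume()]).
#' @param volume_after Volume after processing, cm^3.
#' @return Shrinkage fraction.
#' @export
shrinkage_fraction <- function(volume_before, volume_after) {
  stopifnot_scalar_pos(volume_before, "volume_before")
  stopifnot_scalar_pos(volume_after, "volume_after")
  s <- 1 - volume_after / volume_before
  if (s < 0) warning("volume_after exceeds volume_before: negative shrinkage (swelling)")
  s
}

#' Convert fresh tissue weight to volume
#'
#' @param weight_g Tissue weight in grams.
#' @param ratio Volume/weight ratio, cm^3/g (default 1.04 for brain tissue).
#' @return Volume in cm^3.
#' @export
weight_to_volume <- function(weight_g, ratio = 1.04) {
  stopifnot_scalar_pos(weight_g, "weight_g")
  stopifnot_scalar_pos(ratio, "ratio")
  weight_g * ratio
}

#' Correct somal volumes for tissue shrinkage
#'
#' Each per-cell volume is divided by `(1 - shrinkage)` before
#' re-aggregation, undoing an isotropic volume shrinkage measured on the
#' processed tissue.
#'
#' @param estimate A [nucleator_mean_volume()] estimate.
#' @param shrinkage Volume shrinkage fraction in `[0, 1)`.
#' @param bin_width Histogram bin width for the corrected estimate (`NULL`
#'   to re-derive).
#' @return A corrected `somal_volume_estimate`.
#' @export
correct_for_shrinkage <- function(estimate, shrinkage, bin_width = NULL) {
  if (!inherits(estimate, "somal_volume_estimate")) {
    stop("'estimate' must be a somal_volume_estimate", call. = FALSE)
  }
  if (shrinkage >= 1) stop("'shrinkage' must be < 1", call. = FALSE)
  if (shrinkage < 0) warning("negative shrinkage: volumes will shrink")
  per_cell <- estimate$per_cell
  per_cell$volume <- per_cell$volume / (1 - shrinkage)
  build_somal_estimate(per_cell, bin_width, corrected = TRUE)
}

#' Sample cells for the nucleator by disector selection on vertical sections
#'
#' Number-weighted cell sampling: consecutive section pairs along each
#' block's cutting axis are sampled systematically with a random start, and
#' the cells whose profile run ends at a sampled reference section (in
#' either direction) are selected — the physical-disector rule applied on
#' the vertical sections.
#'
#' @param vs A [cut_vertical_sections()] object.
#' @param period Sampling period along the cutting axis.
#' @param seed Integer RNG seed.
#' @return Integer vector of selected `cell_id`s. A cell hit by two distinct
#'   disector events appears twice: each event is an independent sampling
#'   item, which keeps the inclusion weighting exactly uniform per event.
#' @export
select_cells_disector <- function(vs, period, seed = NULL) {
  seeds <- derive_seeds(seed, nrow(vs$blocks))
  sel <- integer(0)
  for (b in seq_len(nrow(vs$blocks))) {
    nb <- vs$blocks$n_sections[b]
    if (nb < 2) next
    pairs <- sample_section_pairs(nb, min(period, nb), seed = seeds[b])
    cells_b <- vs$cells[vs$cells$block == b, , drop = FALSE]
    top_down <- cells_b$cell_id[cells_b$slab_hi %in% pairs[, "ref"]]
    top_up <- cells_b$cell_id[cells_b$slab_lo %in% pairs[, "lookup"]]
    sel <- c(sel, top_down, top_up)
  }
  sort(sel)
}
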