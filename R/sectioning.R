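#' Serial sectioning plan
#'
#' @param thickness Section thickness t in um (> 0). The default 2 um matches
#'   semi-thin plastic sections.
#' @param axis Sectioning axis for serial (coronal-like) sections; only `"z"`
#'   is meaningful for the box phantom.
#' @param period Sections between successive sampled items in systematic
#'   uniform random sampling (>= 1).
#' @param paired Whether consecutive section pairs (for the physical
#'   disector) are sampled rather than single sections.
#' @return Object of class `section_plan`.
#' @export
section_plan <- function(thickness = 2, axis = "z", period = 200,
                         paired = TRUE) {
  stopifnot_scalar_pos(thickness, "thickness")
  if (!identical(axis, "z")) stop("only axis = 'z' is supported",
                                  call. = FALSE)
  if (period < 1 || period != round(period)) {
    stop("'period' must be a positive integer", call. = FALSE)
  }
  structure(list(thickness = thickness, axis = axis,
                 period = as.integer(period), paired = paired),
            class = "section_plan")
}

# Slab presence along one axis. Slab i covers [i*t, (i+1)*t); a cell with
# extent (wmin, wmax) is present in slab i iff the open intervals overlap,
# so a cell exactly tangent to a slab face is not credited with a zero-area
# appearance and every boundary is counted once.
slab_range <- function(wmin, wmax, t, n_slabs) {
  lo <- pmax(0L, floor(wmin / t))
  hi <- pmin(n_slabs - 1L, ceiling(wmax / t) - 1L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Cut a phantom into serial sections
#'
#' The virtual microtome: tiles the region along z with slabs of thickness
#' `t` and records, for every cell and every slab it appears in, the exact
#' mid-plane profile (a circle or axis-aligned ellipse) plus the largest
#' profile the cell attains anywhere inside the slab (the "slab view" used by
#' the disector, which treats a section as a slab of height t).
#'
#' @param phantom A `phantom`.
#' @param plan A [section_plan()].
#' @return Object of class `section_stack`: a list with `profiles` (data
#'   frame: `section`, `cell_id`, profile center `x, y`, mid-plane semi-axes
#'   `a_mid, b_mid` (NA when the cell misses the mid-plane), slab-view
#'   semi-axes `a_slab, b_slab`, `nucleolus_hit`), `n_sections`, `thickness`,
#'   `footprint` (closed polygon of the layer's 2D footprint), and the cell
#'   table's slab extents (`cell_slabs`: `cell_id`, `slab_lo`, `slab_hi`).
#' @export
cut_serial_sections <- function(phantom, plan) {
  if (!inherits(plan, "section_plan")) {
    stop("'plan' must come from section_plan()", call. = FALSE)
  }
  t <- plan$thickness
  Lz <- phantom$box[3]
  if (!is.finite(Lz) || Lz <= 0) {
    stop("phantom region has zero extent along the sectioning axis",
         call. = FALSE)
  }
  n_sections <- as.integer(ceiling(Lz / t))
  ce <- phantom$cells
  zmin <- ce$cz - ce$sc
  zmax <- ce$cz + ce$sc
  rng <- slab_range(zmin, zmax, t, n_sections)
  counts <- rng$hi - rng$lo + 1L
  idx <- rep.int(seq_len(nrow(ce)), counts)
  section <- unlist(mapply(seq.int, rng$lo, rng$hi, SIMPLIFY = FALSE),
                    use.names = FALSE)
  cz <- ce$cz[idx]; sc <- ce$sc[idx]
  # Mid-plane profile: scaled cross-section at z = (i + 1/2) t.
  zmid <- (section + 0.5) * t
  dz <- (zmid - cz) / sc
  smid <- ifelse(abs(dz) < 1, sqrt(pmax(0, 1 - dz^2)), NA_real_)
  # Slab view: cross-section at the z inside the slab closest to the equator.
  z_lo <- section * t
  z_hi <- (section + 1) * t
  z_best <- pmin(pmax(cz, z_lo), z_hi)
  dzb <- (z_best - cz) / sc
  sslab <- sqrt(pmax(0, 1 - dzb^2))
  nz <- ce$nz[idx]
  profiles <- data.frame(
    section = section,
    cell_id = ce$cell_id[idx],
    x = ce$cx[idx], y = ce$cy[idx],
    a_mid = ce$sa[idx] * smid, b_mid = ce$sb[idx] * smid,
    a_slab = ce$sa[idx] * sslab, b_slab = ce$sb[idx] * sslab,
    nucleolus_hit = nz >= z_lo & nz < z_hi
  )
  footprint <- rbind(c(0, 0), c(phantom$box[1], 0),
                     c(phantom$box[1], phantom$box[2]), c(0, phantom$box[2]))
  structure(
    list(
      profiles = profiles,
      cell_slabs = data.frame(cell_id = ce$cell_id,
                              slab_lo = rng$lo, slab_hi = rng$hi),
      n_sections = n_sections,
      thickness = t,
      footprint = footprint,
      box = phantom$box
    ),
    class = "section_stack"
  )
}

#' Footprint area of the layer region on a given section plane
#'
#' For the box phantom the footprint is the full rectangle for planes inside
#' the region and empty outside.
#'
#' @param phantom A `phantom`.
#' @param z Plane position, um.
#' @return Area in um^2.
#' @export
footprint_area <- function(phantom, z) {
  ifelse(z > 0 & z < phantom$box[3], phantom$box[1] * phantom$box[2], 0)
}

#' Systematic uniform random sampling of consecutive section pairs
#'
#' The first pair starts at a uniform random index in `[0, period)`;
#' subsequent pairs follow every `period` sections. A pair `(i, i + 1)` is
#' kept only if both members exist.
#'
#' @param total_sections Total number of serial sections (>= 2).
#' @param period Sampling period (1 <= period <= total_sections).
#' @param seed Integer RNG seed.
#' @param start Optional fixed start index in `[0, period)` overriding the
#'   random draw.
#' @return Integer matrix with columns `ref` and `lookup` (0-based section
#'   indices), plus attribute `start`.
#' @export
sample_section_pairs <- function(total_sections, period, seed = NULL,
                                 start = NULL) {
  if (total_sections < 2) stop("'total_sections' must be >= 2", call. = FALSE)
  if (period < 1 || period > total_sections) {
    stop("'period' must lie in [1, total_sections]", call. = FALSE)
  }
  if (is.null(start)) {
    start <- with_seed(seed, sample.int(period, 1L) - 1L)
  }
  if (start < 0 || start >= period) {
    stop("'start' must lie in [0, period)", call. = FALSE)
  }
  first <- seq.int(from = start, to = total_sections - 2L, by = period)
  pairs <- cbind(ref = as.integer(first), lookup = as.integer(first + 1L))
  attr(pairs, "start") <- as.integer(start)
  pairs
}

#' Cut vertical uniform random sections
#'
#' The phantom's vertical axis is z. The layer is split into `n_blocks` bars
#' along x; each bar is rotated about the vertical axis by an independent
#' uniform azimuth in `[0, pi)` and cut serially along the rotated normal
#' `(-sin phi, cos phi, 0)`, so every section plane contains the vertical
#' direction. For each cell the caliper extent along its block's normal and
#' the slab holding its nucleolus are recorded; these drive the
#' disector-based cell sampling and the nucleator ray measurements.
#'
#' @param phantom A `phantom`.
#' @param plan A [section_plan()] (its `thickness` is used).
#' @param n_blocks Number of bars (>= 1).
#' @param seed Integer RNG seed.
#' @return Object of class `vertical_sections`: `cells` data frame
#'   (`cell_id`, `block`, `azimuth`, caliper slab extents `slab_lo`,
#'   `slab_hi`, `nucleolus_slab`, w-coordinates), `blocks` data frame
#'   (`block`, `azimuth`, `w0`, `n_sections`), and `thickness`.
#' @export
cut_vertical_sections <- function(phantom, plan, n_blocks = 4, seed = NULL) {
  if (!inherits(plan, "section_plan")) {
    stop("'plan' must come from section_plan()", call. = FALSE)
  }
  t <- plan$thickness
  ce <- phantom$cells
  box <- phantom$box
  block <- pmin(n_blocks, 1L + floor(ce$cx / (box[1] / n_blocks)))
  azimuth <- with_seed(seed, stats::runif(n_blocks, 0, pi))
  phi <- azimuth[block]
  nx <- -sin(phi); ny <- cos(phi)
  w <- ce$cx * nx + ce$cy * ny
  # Support of the (axis-aligned) ellipsoid along the section normal.
  hw <- sqrt((ce$sa * nx)^2 + (ce$sb * ny)^2)
  wn <- ce$nx * nx + ce$ny * ny
  # Block-wise slab origin: projection of the box onto the normal.
  corners_w <- function(p) {
    cw <- c(0, box[1] * (-sin(p)), box[2] * cos(p),
            box[1] * (-sin(p)) + box[2] * cos(p))
    range(cw)
  }
  blocks <- data.frame(block = seq_len(n_blocks), azimuth = azimuth,
                       w0 = NA_real_, n_sections = NA_integer_)
  for (b in seq_len(n_blocks)) {
    rg <- corners_w(azimuth[b])
    blocks$w0[b] <- rg[1]
    blocks$n_sections[b] <- as.integer(ceiling((rg[2] - rg[1]) / t))
  }
  w0 <- blocks$w0[block]
  nsec <- blocks$n_sections[block]
  rng <- slab_range(w - hw - w0, w + hw - w0, t, nsec)
  cells <- data.frame(
    cell_id = ce$cell_id,
    block = block,
    azimuth = phi,
    w = w, half_width = hw,
    slab_lo = rng$lo, slab_hi = rng$hi,
    nucleolus_slab = as.integer(floor((wn - w0) / t))
  )
  structure(list(cells = cells, blocks = blocks, thickness = t,
                 vertical_axis = "z"),
            class = "vertical_sections")
}
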