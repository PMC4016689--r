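#' Unbiased 2D counting frame
#'
#' Rectangle `[x0, x0+width] x [y0, y0+height]` with inclusion edges top and
#' right and forbidden edges left and bottom. The forbidden line carries the
#' classical infinite extensions: it descends from infinity along the left
#' edge line, runs along the bottom edge, and drops to infinity below the
#' bottom-right corner, so tiling the plane with frames assigns every convex
#' profile to exactly one frame.
#'
#' @param x0,y0 Lower-left corner, um.
#' @param width,height Frame dimensions, um (> 0).
#' @return Object of class `counting_frame`.
#' @export
counting_frame <- function(x0, y0, width, height) {
  stopifnot_scalar_pos(width, "width")
  stopifnot_scalar_pos(height, "height")
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "counting_frame")
}

#' Select profiles by the unbiased counting-frame rule
#'
#' A profile is selected iff it intersects the frame and touches neither
#' forbidden edge nor their infinite extensions (tangency counts as
#' touching). Profiles are circles or axis-aligned ellipses.
#'
#' @param profiles Data frame with columns `cell_id`, `x`, `y` and semi-axes
#'   `a`, `b` (use equal values for circles). Zero/NA semi-axes rows are
#'   never selected.
#' @param frame A [counting_frame()].
#' @return The `cell_id`s of the selected profiles.
#' @export
frame_select <- function(profiles, frame) {
  if (!inherits(frame, "counting_frame")) {
    stop("'frame' must come from counting_frame()", call. = FALSE)
  }
  if (nrow(profiles) == 0L) return(integer(0))
  a <- profiles$a; b <- profiles$b
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  x <- profiles$x; y <- profiles$y
  sel <- ok
  x1 <- frame$x0 + frame$width
  sel[ok] <- ellipse_intersects_rect(
    x[ok], y[ok], a[ok], b[ok],
    frame$x0, frame$y0, x1, frame$y0 + frame$height) &
    !ellipse_touches_vray_up(x[ok], y[ok], a[ok], b[ok],
                             frame$x0, frame$y0) &
    !ellipse_touches_hseg(x[ok], y[ok], a[ok], b[ok],
                          frame$x0, x1, frame$y0) &
    !ellipse_touches_vray_down(x[ok], y[ok], a[ok], b[ok], x1, frame$y0)
  profiles$cell_id[sel]
}

#' Disector Q-minus count for one section pair and frame
#'
#' Counts "tops": frame-selected profiles present in the reference section
#' whose cell has no profile in the adjacent look-up section.
#'
#' @param reference Data frame of reference-section profiles (columns as in
#'   [frame_select()], plus optionally `section`).
#' @param lookup Data frame of look-up-section profiles (only `cell_id` is
#'   used; may have zero rows).
#' @param frame A [counting_frame()].
#' @param ref_section,lookup_section Optional 0-based section indices; when
#'   both are given they must be consecutive.
#' @return Integer Q-minus.
#' @export
count_Q_minus <- function(reference, lookup, frame,
                          ref_section = NULL, lookup_section = NULL) {
  if (!is.null(ref_section) && !is.null(lookup_section) &&
      abs(ref_section - lookup_section) != 1L) {
    stop("reference and look-up sections must be consecutive", call. = FALSE)
  }
  sel <- frame_select(reference, frame)
  sum(!(sel %in% lookup$cell_id))
}

#' Assemble disector count records
#'
#' @param pair_id Identifier per section pair (and direction).
#' @param Q Q-minus counts (>= 0).
#' @param frame_area Total frame area examined per record, um^2.
#' @param h Disector height, um (section thickness for the physical
#'   disector on consecutive sections).
#' @return Data frame of class `disector_counts`.
#' @export
disector_counts <- function(pair_id, Q, frame_area, h) {
  if (any(Q < 0)) stop("'Q' must be non-negative", call. = FALSE)
  if (any(frame_area <= 0)) stop("'frame_area' must be positive",
                                 call. = FALSE)
  if (any(h <= 0)) stop("'h' must be positive", call. = FALSE)
  structure(
    data.frame(pair_id = pair_id, Q = as.integer(Q),
               frame_area = frame_area, h = h),
    class = c("disector_counts", "data.frame")
  )
}

#' Numerical density from disector counts
#'
#' `Nv = sum(Q) / sum(frame_area * h)`, converted from um^-3 to cells/mm^3.
#'
#' @param counts A [disector_counts()] data frame.
#' @return Object of class `density_estimate`: `Nv` (cells/mm^3),
#'   `Nv_per_1e3` (x10^3/mm^3), `total_Q`, `sampled_volume` (mm^3),
#'   `n_disectors`.
#' @export
numerical_density <- function(counts) {
  if (!is.data.frame(counts) || nrow(counts) < 1L) {
    stop("at least one disector count is required", call. = FALSE)
  }
  v_um3 <- sum(counts$frame_area * counts$h)
  if (v_um3 <= 0) stop("sampled volume is zero", call. = FALSE)
  total_Q <- sum(counts$Q)
  Nv <- total_Q / v_um3 * UM3_PER_MM3
  structure(list(Nv = Nv, Nv_per_1e3 = Nv / 1e3, total_Q = total_Q,
                 sampled_volume = v_um3 / UM3_PER_MM3,
                 n_disectors = nrow(counts)),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "numerical density: %.4g x10^3/mm^3 (total Q- %d in %.4g mm^3)\n",
    x$Nv_per_1e3, x$total_Q, x$sampled_volume))
  invisible(x)
}

#' Total cell number from density and reference volume
#'
#' `N = Nv x Vref`. For report parity with stereological tables the value is
#' also given in units of 10^6 rounded to 3 decimals.
#'
#' @param density A [numerical_density()] estimate (cells/mm^3).
#' @param volume A [cavalieri_volume()] estimate (mm^3), or a plain number
#'   in mm^3.
#' @return Object of class `number_estimate`: `N` (cells), `N_millions`,
#'   `N_millions_rounded`.
#' @export
total_number <- function(density, volume) {
  Nv <- if (inherits(density, "density_estimate")) density$Nv else
    as.numeric(density)
  V <- if (inherits(volume, "volume_estimate")) volume$V else
    as.numeric(volume)
  if (!is.finite(Nv) || Nv < 0) stop("invalid numerical density",
                                     call. = FALSE)
  if (!is.finite(V) || V < 0) stop("invalid reference volume", call. = FALSE)
  N <- Nv * V
  structure(list(N = N, N_millions = N / 1e6,
                 N_millions_rounded = round(N / 1e6, 3)),
            class = "number_estimate")
}

#' @export
print.number_estimate <- function(x, ...) {
  cat(sprintf("total number: %.4g cells (%.3f x10^6)\n",
              x$N, x$N_millions))
  invisible(x)
}

# Profiles of one section in the 'slab view' used by the disector, formatted
# for frame_select().
section_profiles <- function(stack, section) {
  pr <- stack$profiles[stack$profiles$section == section, , drop = FALSE]
  data.frame(cell_id = pr$cell_id, x = pr$x, y = pr$y,
             a = pr$a_slab, b = pr$b_slab, section = pr$section)
}

#' Sample disector pairs over a section stack with end guards
#'
#' Systematic uniform random pair sampling over the stack extended by one
#' empty guard section at each end (the microtome cuts past the layer, so
#' the first and last tissue sections still have an adjacent look-up).
#' Without the guards, cells whose top profile falls in an end section could
#' never be counted and the density estimate would be biased low.
#'
#' @param stack A [cut_serial_sections()] stack.
#' @param period Sampling period.
#' @param seed Integer RNG seed.
#' @return Pair matrix as in [sample_section_pairs()]; indices may include
#'   `-1` and `n_sections` (the guard sections, empty of profiles).
#' @export
disector_pair_design <- function(stack, period, seed = NULL) {
  p <- sample_section_pairs(stack$n_sections + 2L, period, seed = seed)
  s <- attr(p, "start")
  p <- p - 1L
  attr(p, "start") <- s
  p
}

#' Run a physical-disector design over a section stack
#'
#' Applies a grid of counting frames tiling the layer footprint to every
#' sampled consecutive section pair. By default each pair is used in both
#' directions (each section serving once as reference).
#'
#' @param stack A [cut_serial_sections()] stack.
#' @param pairs Pair matrix from [disector_pair_design()] (or
#'   [sample_section_pairs()]). Directions whose reference section lies
#'   outside the tissue (a guard section) examine zero layer area and are
#'   dropped.
#' @param frame_size Length-2 frame dimensions, um. Must tile the footprint
#'   exactly (the footprint edges must be integer multiples).
#' @param directions `"both"` or `"down"` (reference = lower index only).
#' @return A [disector_counts()] data frame with one row per
#'   (pair, direction), carrying the summed Q-minus over the frame grid and
#'   the summed frame area.
#' @export
run_disector <- function(stack, pairs, frame_size, directions = c("both", "down")) {
  directions <- match.arg(directions)
  fw <- frame_size[1]; fh <- frame_size[2]
  Lx <- stack$box[1]; Ly <- stack$box[2]
  nx <- round(Lx / fw); ny <- round(Ly / fh)
  if (abs(nx * fw - Lx) > 1e-9 * Lx || abs(ny * fh - Ly) > 1e-9 * Ly) {
    stop("frame size must tile the footprint exactly", call. = FALSE)
  }
  h <- stack$thickness
  slabs <- stack$cell_slabs
  p_sec <- stack$profiles$section
  p_id <- stack$profiles$cell_id
  p_x <- stack$profiles$x
  p_y <- stack$profiles$y
  p_a <- stack$profiles$a_slab
  p_b <- stack$profiles$b_slab
  dirs <- if (directions == "both") c("down", "up") else "down"
  ids <- character(0); Qs <- integer(0)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, "ref"]; j <- pairs[p, "lookup"]
    for (d in dirs) {
      ref_sec <- if (d == "down") i else j
      if (ref_sec < 0 || ref_sec >= stack$n_sections) next
      # Tops resolved by cell identity: cells whose profile run ends at the
      # reference slab in this direction.
      top_ids <- if (d == "down") slabs$cell_id[slabs$slab_hi == ref_sec]
                 else slabs$cell_id[slabs$slab_lo == ref_sec]
      rows <- which(p_sec == ref_sec & p_id %in% top_ids)
      Q <- 0L
      if (length(rows)) {
        x <- p_x[rows]; y <- p_y[rows]; a <- p_a[rows]; b <- p_b[rows]
        for (ix in seq_len(nx) - 1L) {
          x0 <- ix * fw
          for (iy in seq_len(ny) - 1L) {
            y0 <- iy * fh
            sel <- ellipse_intersects_rect(x, y, a, b,
                                           x0, y0, x0 + fw, y0 + fh) &
              !ellipse_touches_vray_up(x, y, a, b, x0, y0) &
              !ellipse_touches_hseg(x, y, a, b, x0, x0 + fw, y0) &
              !ellipse_touches_vray_down(x, y, a, b, x0 + fw, y0)
            Q <- Q + sum(sel)
          }
        }
      }
      ids <- c(ids, sprintf("p%03d_%s", p, d))
      Qs <- c(Qs, Q)
    }
  }
  disector_counts(ids, Qs, rep(nx * ny * fw * fh, length(Qs)),
                  rep(h, length(Qs)))
}
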