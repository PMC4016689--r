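# Low-level geometry used by the virtual microtome, the counting-frame rule
# and the nucleator ray measurements. Cells are spheres or axis-aligned
# triaxial ellipsoids, so every section profile is a circle or an
# axis-aligned ellipse and all tests below have closed forms.

# Distance travelled from an interior point p along unit direction d until the
# boundary of the ellipsoid (center, semi-axes) is reached. All arguments are
# equal-length vectors (one element per ray); semi-axes sa/sb/sc along x/y/z.
ray_length_ellipsoid <- function(px, py, pz, dx, dy, dz,
                                 cx, cy, cz, sa, sb, sc) {
  ex <- (px - cx) / sa^2
  ey <- (py - cy) / sb^2
  ez <- (pz - cz) / sc^2
  a2 <- dx^2 / sa^2 + dy^2 / sb^2 + dz^2 / sc^2
  b1 <- dx * ex + dy * ey + dz * ez
  c0 <- (px - cx) * ex + (py - cy) * ey + (pz - cz) * ez - 1
  disc <- b1^2 - a2 * c0
  if (any(disc < 0)) {
    stop("ray origin lies outside the cell boundary", call. = FALSE)
  }
  (-b1 + sqrt(disc)) / a2
}

# Half-open point-in-polygon test (crossing number with strict inequalities):
# points on "left/bottom"-type edges are inside, on "right/top"-type edges
# outside, so a tiling of congruent polygons counts each lattice point once.
# px, py vectors; poly an n x 2 vertex matrix (closed implicitly).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# The three tests below work in scaled coordinates: dividing x by the
# ellipse's x semi-axis and y by its y semi-axis maps the profile to a unit
# circle while keeping frames and edge rays axis-aligned, so a single
# circle-distance computation covers circles and ellipses alike.

# Does an axis-aligned ellipse profile intersect the closed rectangle
# [x0,x1] x [y0,y1]? Vectorised over profiles.
ellipse_intersects_rect <- function(cx, cy, a, b, x0, y0, x1, y1) {
  ux <- cx / a; uy <- cy / b
  qx <- pmin(pmax(ux, x0 / a), x1 / a)
  qy <- pmin(pmax(uy, y0 / b), y1 / b)
  (ux - qx)^2 + (uy - qy)^2 <= 1
}

# Does the profile touch the upward forbidden ray {x = x0, y >= y0}
# (left frame edge plus its extension above the top-left corner)?
# Touching includes tangency.
ellipse_touches_vray_up <- function(cx, cy, a, b, x0, y0) {
  ux <- cx / a; uy <- cy / b
  rx <- x0 / a; ry <- y0 / b
  dx <- ux - rx
  dy <- pmin(uy - ry, 0)   # 0 when the center is level with or above the foot
  dx^2 + dy^2 <= 1
}

# Downward forbidden ray {x = x1, y <= y0}: the extension hanging below the
# bottom-right corner of the frame.
ellipse_touches_vray_down <- function(cx, cy, a, b, x1, y0) {
  ux <- cx / a; uy <- cy / b
  rx <- x1 / a; ry <- y0 / b
  dx <- ux - rx
  dy <- pmax(uy - ry, 0)
  dx^2 + dy^2 <= 1
}

# Bottom forbidden edge segment {y = y0, x0 <= x <= x1}.
ellipse_touches_hseg <- function(cx, cy, a, b, x0, x1, y0) {
  ux <- cx / a; uy <- cy / b
  ry <- y0 / b
  qx <- pmin(pmax(ux, x0 / a), x1 / a)
  (ux - qx)^2 + (uy - ry)^2 <= 1
}
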