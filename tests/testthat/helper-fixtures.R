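# Builders for controlled test geometry.

# Phantom with explicitly placed spherical/ellipsoidal cells, bypassing the
# random generator, for tests that need exact positions.
manual_phantom <- function(cells, box) {
  n <- nrow(cells)
  if (is.null(cells$sa)) {
    cells$sa <- cells$r; cells$sb <- cells$r; cells$sc <- cells$r
  }
  if (is.null(cells$nx)) {
    cells$nx <- cells$cx; cells$ny <- cells$cy; cells$nz <- cells$cz
  }
  cells$cell_id <- seq_len(n)
  cells$r_eq <- (cells$sa * cells$sb * cells$sc)^(1 / 3)
  cells$volume <- 4 / 3 * pi * cells$sa * cells$sb * cells$sc
  structure(
    list(cells = cells, box = box, shape = "sphere",
         true_layer_volume = prod(box) / 1e9,
         true_cell_count = n,
         true_mean_somal_volume = mean(cells$volume),
         params = NULL, seed = NA_integer_),
    class = "phantom"
  )
}

# Small default phantom parameter set used across tests (fast to generate).
small_params <- function(n_cells = 150, box = c(120, 120, 100), ...) {
  phantom_params(n_cells = n_cells, box = box, ...)
}
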