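#' Construct a cell table
#'
#' Cells are rows of a plain data frame: unique `id`, `species` (name of a
#' [syn_species()]), `tag` (lineage color, e.g. `"near"`/`"far"`), continuous
#' position `x`, `y` in um (`y = 0` at the substratum), `mass` in g and the
#' derived `radius` in um (disc of out-of-plane depth equal to the grid
#' resolution, fixed biomass density).
#'
#' @param species Character vector of species names.
#' @param x,y Positions, um.
#' @param mass Masses, g.
#' @param tag Lineage tags (default `"none"`).
#' @param params Parameter list from [syn_params()].
#' @param id Integer ids (default sequential).
#' @return A `data.frame` of class `syn_cells`.
#' @export
new_cells <- function(species, x, y, mass, tag = "none",
                      params = syn_params(), id = seq_along(x)) {
  stopifnot(all(mass > 0))
  df <- data.frame(id = as.integer(id), species = as.character(species),
                   tag = rep_len(as.character(tag), length(x)),
                   x = as.numeric(x), y = as.numeric(y),
                   mass = as.numeric(mass),
                   radius = radius_from_mass(mass, params),
                   stringsAsFactors = FALSE)
  class(df) <- c("syn_cells", "data.frame")
  df
}

#' Grow cell biomass over one timestep
#'
#' Applies exponential growth `mass <- mass * exp(mu * dt)` per cell with the
#' cell's local specific growth rate, and reports which cells now exceed the
#' division threshold. Positions are untouched.
#'
#' @param cells A [new_cells()] table.
#' @param mu Per-cell specific growth rates (1/h), evaluated at each cell's
#'   voxel concentrations.
#' @param dt Timestep, h (> 0).
#' @param params Parameter list.
#' @return `cells` with updated `mass`/`radius` and an integer attribute
#'   `to_divide` of row indices queued for division.
#' @export
advance_biomass <- function(cells, mu, dt, params = syn_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(mu))) {
    bad <- cells$id[!is.finite(mu)][1L]
    stop("non-finite growth rate for cell id ", bad)
  }
  net <- mu - params$maintenance
  cells$mass <- cells$mass * exp(net * dt)
  cells$radius <- radius_from_mass(cells$mass, params)
  attr(cells, "to_divide") <- which(cells$mass >= division_mass(params))
  cells
}

#' Divide one cell into two daughters
#'
#' The parent mass is split by a uniform fraction in `[0.45, 0.55]`;
#' daughters inherit species and lineage tag, receive fresh ids, and are
#' placed centre-symmetrically at a uniform random angle, separated by the
#' sum of their radii.
#'
#' @param cell A single-row cell table at or above the division threshold.
#' @param params Parameter list.
#' @param next_id First id to assign to the daughters.
#' @return A two-row `syn_cells` table.
#' @export
divide_cell <- function(cell, params = syn_params(), next_id = cell$id + 1L) {
  if (cell$mass < division_mass(params))
    stop("cell id ", cell$id, " is below the division threshold")
  out <- divide_cells(cell, params, next_id)
  out
}

## Vectorised division of many parents; draws are made parent-by-parent in
## row order so trajectories are reproducible under a fixed seed.
divide_cells <- function(parents, params, next_id) {
  n <- nrow(parents)
  frac <- stats::runif(n, params$split_range[1L], params$split_range[2L])
  ang <- stats::runif(n, 0, 2 * pi)
  m1 <- parents$mass * frac
  m2 <- parents$mass - m1
  r1 <- radius_from_mass(m1, params)
  r2 <- radius_from_mass(m2, params)
  sep <- r1 + r2
  dx <- cos(ang) * sep / 2
  dy <- sin(ang) * sep / 2
  d1 <- new_cells(parents$species, parents$x - dx,
                  pmax(parents$y - dy, r1), m1, tag = parents$tag,
                  params = params, id = next_id + seq_len(n) - 1L)
  d2 <- new_cells(parents$species, parents$x + dx,
                  pmax(parents$y + dy, r2), m2, tag = parents$tag,
                  params = params, id = next_id + n + seq_len(n) - 1L)
  rbind(d1, d2)
}

#' Resolve cell overlaps by shoving
#'
#' Iteratively moves every overlapping pair apart along its centre line
#' (half the overlap each) until the worst overlap fraction drops below
#' `tol` or `max_sweeps` is exhausted (best effort, with a warning). Fully
#' superposed cells separate along +x (deterministic tie-break). Cells are
#' kept above the substratum and wrapped or clamped laterally.
#'
#' @param cells A cell table.
#' @param domain List with `width` (um) and logical `cyclic`.
#' @param tol Maximum allowed overlap as a fraction of `r_i + r_j`.
#' @param max_sweeps Sweep cap.
#' @return `cells` with updated positions and attribute `sweeps`.
#' @export
relax_overlaps <- function(cells, domain, tol = 0.05, max_sweeps = 50) {
  if (nrow(cells) < 2L) return(cells)
  res <- shove_cpp(cells$x, cells$y, cells$radius, domain$width,
                   isTRUE(domain$cyclic), tol, as.integer(max_sweeps))
  cells$x <- res$x
  cells$y <- res$y
  if (res$max_overlap >= tol)
    warning(sprintf("relax_overlaps: sweep budget exhausted (overlap %.3f)",
                    res$max_overlap))
  attr(cells, "sweeps") <- res$sweeps
  cells
}

## Map cells to voxel indices (row = y band, col = x band) on the grid.
cell_voxels <- function(cells, p) {
  nx <- as.integer(round(p$domain_width / p$grid_h))
  ny <- as.integer(round(p$domain_height / p$grid_h))
  col <- pmin(pmax(floor(cells$x / p$grid_h) + 1L, 1L), nx)
  row <- pmin(pmax(floor(cells$y / p$grid_h) + 1L, 1L), ny)
  list(row = as.integer(row), col = as.integer(col), nx = nx, ny = ny)
}

## Per-species biomass density (g/L) matrices on the grid.
biomass_by_species <- function(cells, p, species_names) {
  vox <- cell_voxels(cells, p)
  vol_L <- p$grid_h^3 * 1e-15
  out <- list()
  for (nm in species_names) {
    m <- matrix(0, vox$ny, vox$nx)
    sel <- cells$species == nm
    if (any(sel)) {
      ind <- (vox$col[sel] - 1L) * vox$ny + vox$row[sel]
      agg <- rowsum(cells$mass[sel], ind)
      m[as.integer(rownames(agg))] <- agg[, 1L] / vol_L
    }
    out[[nm]] <- m
  }
  out
}
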