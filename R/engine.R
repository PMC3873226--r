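#' Run an individual-based biofilm simulation
#'
#' Operator-split loop: every biological timestep the solute fields are
#' relaxed to quasi-steady state around the standing biomass
#' ([steady_state_solve()]), per-cell growth rates are evaluated at each
#' cell's voxel, biomass is advanced exponentially, threshold-crossing cells
#' divide, and overlaps are shoved apart. Snapshots (cells, fields,
#' per-species counts) are recorded at `t = 0`, every `save_interval` hours,
#' and at the end.
#'
#' @param scenario A `syn_scenario` from [build_scenario()].
#' @param seed Integer RNG seed; the trajectory is deterministic given
#'   `(scenario, seed)`.
#' @param progress Print per-snapshot progress lines.
#' @return A `syn_trajectory`: list with `scenario`, `seed`, `times`,
#'   `counts` (time x species matrix), `snapshots` (cells, optional fields),
#'   and `flags` (e.g. `early_stop` when the biofilm front reaches the
#'   domain ceiling).
#' @examples
#' \donttest{
#' scn <- build_scenario("control", domain_width = 80, domain_height = 80,
#'                       duration = 4, n_inoc = 10)
#' tr <- run_simulation(scn, seed = 1)
#' tail(tr$counts, 1)
#' }
#' @export
run_simulation <- function(scenario, seed = 1L, progress = FALSE) {
  p <- scenario$params
  if (p$dt <= 0) stop("dt must be positive")
  mu_cap <- max(vapply(scenario$species, function(s)
    (1 - s$omega) * s$mu_max_R + s$omega * s$mu_max_E, 0))
  if (mu_cap * p$dt > 0.1 + 1e-9)
    stop("dt too large: max mu * dt must be <= 0.1")
  set.seed(as.integer(seed))
  sp_names <- names(scenario$species)
  nx <- as.integer(round(p$domain_width / p$grid_h))
  ny <- as.integer(round(p$domain_height / p$grid_h))

  cells <- seed_inoculum(scenario)
  fields <- lapply(names(scenario$fields), function(nm) {
    fs <- scenario$fields[[nm]]
    solute_field(nm, nx, ny, grid_h = p$grid_h, D = fs$D, bulk = fs$bulk,
                 lateral = fs$lateral, mult = fs$mult)
  })
  names(fields) <- names(scenario$fields)

  n_steps <- as.integer(round(p$duration / p$dt))
  save_every <- max(1L, as.integer(round(p$save_interval / p$dt)))
  m_div <- division_mass(p)
  domain <- list(width = p$domain_width, cyclic = scenario$cyclic)

  snapshots <- list()
  times <- numeric(0)
  counts <- NULL
  take_snapshot <- function(t, cells, fields) {
    cnt <- vapply(sp_names, function(nm) sum(cells$species == nm), 0L)
    snapshots[[length(snapshots) + 1L]] <<- list(
      time = t, cells = cells,
      fields = if (isTRUE(p$save_fields)) lapply(fields, `[[`, "conc"))
    times <<- c(times, t)
    counts <<- rbind(counts, cnt)
    if (progress)
      message(sprintf("t = %6.2f h  N = %s", t,
                      paste(sp_names, cnt, sep = ":", collapse = "  ")))
  }
  take_snapshot(0, cells, fields)

  flags <- list(early_stop = FALSE, stop_time = NA_real_)
  t <- 0
  for (step in seq_len(n_steps)) {
    front <- max(cells$y + cells$radius)
    bc <- boundary_spec(p$boundary_layer, front_height = front)
    bio <- biomass_by_species(cells, p, sp_names)
    src <- linearized_sources(bio, scenario$species)
    fields <- tryCatch(
      steady_state_solve(fields, src, bc, tol = p$solver_tol,
                         max_iter = p$solver_max_iter, damp = p$solver_damp),
      error = function(e)
        stop("at t = ", t + p$dt, " h: ", conditionMessage(e), call. = FALSE))

    ## per-cell rates at the containing voxel
    vox <- cell_voxels(cells, p)
    mu <- numeric(nrow(cells))
    for (nm in sp_names) {
      sel <- cells$species == nm
      if (!any(sel)) next
      sp <- scenario$species[[nm]]
      ind <- cbind(vox$row[sel], vox$col[sel])
      R <- if (!is.na(sp$nutrient)) fields[[sp$nutrient]]$conc[ind] else 0
      E_in <- if (!is.na(sp$e_in)) fields[[sp$e_in]]$conc[ind] else 0
      E_inh <- if (is.finite(sp$K_tox) && !is.na(sp$e_out))
        fields[[sp$e_out]]$conc[ind] else 0
      mu[sel] <- species_rates(sp, R = R, E_in = E_in, E_inh = E_inh)$mu
    }

    cells <- advance_biomass(cells, mu, p$dt, p)
    div <- attr(cells, "to_divide")
    if (length(div)) {
      daughters <- divide_cells(cells[div, , drop = FALSE], p,
                                next_id = max(cells$id) + 1L)
      cells <- rbind(cells[-div, , drop = FALSE], daughters)
      class(cells) <- c("syn_cells", "data.frame")
    }
    if (p$maintenance > 0) {
      keep <- cells$mass >= p$m_min_frac * m_div
      cells <- cells[keep, , drop = FALSE]
    }
    cells <- suppressWarnings(
      relax_overlaps(cells, domain, p$shove_tol, p$shove_max_sweeps))
    t <- step * p$dt

    if (step %% save_every == 0L || step == n_steps)
      take_snapshot(t, cells, fields)
    if (max(cells$y + cells$radius) > p$early_stop_frac * p$domain_height) {
      flags$early_stop <- TRUE
      flags$stop_time <- t
      if (step %% save_every != 0L && step != n_steps)
        take_snapshot(t, cells, fields)
      break
    }
  }

  rownames(counts) <- NULL
  structure(list(scenario = scenario, seed = as.integer(seed), times = times,
                 counts = counts, snapshots = snapshots, flags = flags),
            class = "syn_trajectory")
}

#' @exportS3Method base::print
print.syn_trajectory <- function(x, ...) {
  cat("<syn_trajectory> scenario:", x$scenario$name,
      " seed:", x$seed, "\n")
  cat("  times:", paste(range(x$times), collapse = " .. "), "h in",
      length(x$times), "snapshots\n")
  fin <- x$counts[nrow(x$counts), ]
  cat("  final counts:",
      paste(colnames(x$counts), fin, sep = ":", collapse = "  "), "\n")
  if (x$flags$early_stop)
    cat("  early stop at", x$flags$stop_time, "h (front reached ceiling)\n")
  invisible(x)
}

final_counts <- function(traj) traj$counts[nrow(traj$counts), ]

#' Write a trajectory to disk
#'
#' One delimited cell table per snapshot (`cells_t<time>.tsv` with columns
#' time_h, id, species, lineage_tag, x_um, y_um, radius_um, mass_g), one
#' delimited field dump per solute per snapshot, a counts table, and a JSON
#' manifest recording scenario name, seed, saved times and file list.
#'
#' @param traj A `syn_trajectory`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(traj$snapshots)) {
    sn <- traj$snapshots[[i]]
    lab <- sprintf("t%07.2f", sn$time)
    cf <- file.path(dir, paste0("cells_", lab, ".tsv"))
    ## %.17g keeps doubles bit-exact across the write/read round trip
    cdf <- data.frame(time_h = sprintf("%.17g", sn$time), id = sn$cells$id,
                      species = sn$cells$species,
                      lineage_tag = sn$cells$tag,
                      x_um = sprintf("%.17g", sn$cells$x),
                      y_um = sprintf("%.17g", sn$cells$y),
                      radius_um = sprintf("%.17g", sn$cells$radius),
                      mass_g = sprintf("%.17g", sn$cells$mass))
    utils::write.table(cdf, cf, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, basename(cf))
    for (nm in names(sn$fields)) {
      ff <- file.path(dir, paste0("field_", nm, "_", lab, ".tsv"))
      utils::write.table(sn$fields[[nm]], ff, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, basename(ff))
    }
  }
  cnt <- data.frame(time_h = traj$times, traj$counts, check.names = FALSE)
  utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c(files, "counts.tsv")
  manifest <- list(scenario = traj$scenario$name,
                   culture = traj$scenario$culture,
                   seed = traj$seed, times = traj$times,
                   species = names(traj$scenario$species),
                   producer = traj$scenario$producer,
                   grid = list(width = traj$scenario$params$domain_width,
                               height = traj$scenario$params$domain_height,
                               h = traj$scenario$params$grid_h),
                   cyclic = traj$scenario$cyclic,
                   early_stop = traj$flags$early_stop,
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stopifnot(all(file.exists(file.path(dir, files))))
  invisible(manifest)
}

#' Read back a written trajectory's cell tables
#'
#' @param dir Directory written by [write_trajectory()].
#' @return List with `manifest`, `counts` data frame, and `cells`, a list of
#'   per-snapshot cell tables in time order.
#' @export
read_trajectory <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  counts <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE)
  cell_files <- sort(grep("^cells_", manifest$files, value = TRUE))
  cells <- lapply(cell_files, function(f)
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
  list(manifest = manifest, counts = counts, cells = cells)
}
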