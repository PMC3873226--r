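#' Default physical and numerical parameters
#'
#' Returns the full list of model defaults used to resolve a [build_scenario()]
#' call. Every value can be overridden per scenario. Units are micrometres,
#' hours, and g/L throughout.
#'
#' The kinetic asymmetry between producer and cross-feeder (`K_R_A < K_R_B`,
#' `Y_R_A > Y_R_B`) encodes that the producer has higher affinity for, and is
#' more efficient on, the shared nutrient. The by-product stoichiometry
#' follows mass balance: substrate carbon not fixed as producer biomass leaves
#' the cell as by-product, `gamma_E = (1 - Y_R_A) / Y_R_A`.
#'
#' @param ... name = value overrides of any default.
#' @return Named list of parameters.
#' @examples
#' p <- syn_params(domain_width = 130)
#' p$domain_width
#' @export
syn_params <- function(...) {
  p <- list(
    ## domain / grid
    domain_width    = 260,    # um
    domain_height   = 200,    # um
    grid_h          = 4,      # um, voxel edge (also out-of-plane depth)
    boundary_layer  = 40,     # um of still liquid above the biofilm front

    ## solutes
    D_R             = 4e4,    # um^2/h
    D_E             = 4e4,    # um^2/h
    R_bulk          = 0.25,   # g/L, held constant in the bulk
    E_bulk          = 0,      # g/L

    ## kinetics (see vignette for the calibration of the yields)
    mu_max_R_A      = 1.0,    # 1/h
    mu_max_R_B      = 1.0,
    mu_max_E_B      = 1.0,
    K_R_A           = 0.05,   # g/L
    K_R_B           = 0.25,
    K_E             = 0.05,
    Y_R_A           = 0.2,    # g biomass / g nutrient
    Y_R_B           = 0.14,
    Y_E             = 0.5,
    gamma_E         = NULL,   # g by-product / g new producer biomass; NULL -> (1-Y_R_A)/Y_R_A
    toxicity_levels = c(Inf, 5, 1, 0.2, 0.04),       # K_tox ladder, g/L
    omega_levels    = c(B_ncf = 0, B_facW = 0.25, B_facI = 0.5,
                        B_facS = 0.75, B_obl = 1),

    ## agents
    rho_cell        = 200,    # g/L biomass density inside a cell
    r_div           = 2,      # um, division radius
    split_range     = c(0.45, 0.55),
    shove_tol       = 0.05,   # max allowed overlap as a fraction of r_i + r_j
    shove_max_sweeps = 50,
    maintenance     = 0,      # 1/h specific maintenance (off by default)
    m_min_frac      = 0.25,   # removal threshold, fraction of m_div (only if maintenance > 0)

    ## engine
    dt              = 0.05,   # h
    duration        = 96,     # h
    save_interval   = 12,     # h
    early_stop_frac = 0.8,    # stop when front exceeds this fraction of height
    save_fields     = TRUE,

    ## solver
    solver_tol      = 1e-6,
    solver_max_iter = 200,
    solver_damp     = 0.7,

    ## inoculum
    n_inoc          = 60,     # cells per species
    colony_width    = 30,     # um
    colony_sep      = 70      # um, edge to edge
  )
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1L]])) ov <- ov[[1L]]
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (is.null(p$gamma_E)) p$gamma_E <- (1 - p$Y_R_A) / p$Y_R_A
  p
}

## mass of a cell of radius r: a disc of depth grid_h at density rho_cell.
## rho_cell is in g/L = 1e-15 g/um^3.
mass_from_radius <- function(r, p) {
  p$rho_cell * 1e-15 * pi * r^2 * p$grid_h
}

radius_from_mass <- function(m, p) {
  sqrt(m / (p$rho_cell * 1e-15 * pi * p$grid_h))
}

division_mass <- function(p) mass_from_radius(p$r_div, p)

## Stationary-size-distribution draw for seeded cells. For exponential mass
## growth with division into halves at m_div, the stable number density is
## proportional to 1/m^2 on [m_div/2, m_div); inverting its CDF gives
## m = m_div / (2 - U). Seeding from it keeps populations on the well-mixed
## exponential N(t) = N0 exp(mu t) without census oscillations.
draw_seed_mass <- function(n, p) {
  division_mass(p) / (2 - stats::runif(n))
}
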