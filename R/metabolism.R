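#' Species definition
#'
#' A `syn_species` bundles one species' kinetic and stoichiometric parameters
#' together with its wiring to named solute fields. Growth follows additive
#' substitutable-resource kinetics
#' \deqn{\mu = (1-\omega)\,\mu_{max,R}\frac{R}{K_R+R}\frac{1}{1+E/K_{tox}}
#'       \;+\; \omega\,\mu_{max,E}\frac{E}{K_E+E}}
#' where the non-competitive inhibition factor applies only when `K_tox` is
#' finite (producers poisoned by their own by-product) and the obligacy weight
#' `omega` splits growth capacity between the shared nutrient and the
#' partner's by-product.
#'
#' @param name Identifier (e.g. `"A"`, `"B_obl"`).
#' @param mu_max_R,mu_max_E Maximal specific growth rates (1/h) on the
#'   nutrient and the by-product. `mu_max_R = 0` for the obligate
#'   cross-feeder, `mu_max_E = 0` for the non-cross-feeder.
#' @param K_R,K_E Half-saturation constants (g/L).
#' @param Y_R,Y_E Biomass yields (g biomass per g solute).
#' @param K_tox Inhibition constant of the by-product on growth (g/L);
#'   `Inf` disables inhibition.
#' @param gamma_E By-product produced per unit new biomass (g/g); `> 0` only
#'   for producers.
#' @param omega Obligacy weight in `[0, 1]`; 0 = pure nutrient user,
#'   1 = obligate by-product user.
#' @param nutrient,e_in,e_out Names of the solute fields this species
#'   consumes as nutrient, consumes as by-product, and produces (or `NA`).
#' @return An object of class `syn_species`.
#' @examples
#' a <- syn_species("A", mu_max_R = 1, K_R = 0.05, Y_R = 0.2,
#'                  K_tox = 0.04, gamma_E = 4, e_out = "E")
#' producer_growth_rate(0.05, 0, a)  # half-saturation: mu_max/2
#' @export
syn_species <- function(name, mu_max_R = 0, mu_max_E = 0, K_R = 1, K_E = 1,
                        Y_R = 1, Y_E = 1, K_tox = Inf, gamma_E = 0,
                        omega = 0, nutrient = "R", e_in = NA_character_,
                        e_out = NA_character_) {
  sp <- list(name = name, mu_max_R = mu_max_R, mu_max_E = mu_max_E,
             K_R = K_R, K_E = K_E, Y_R = Y_R, Y_E = Y_E, K_tox = K_tox,
             gamma_E = gamma_E, omega = omega, nutrient = nutrient,
             e_in = e_in, e_out = e_out)
  class(sp) <- "syn_species"
  validate_species(sp)
  sp
}

validate_species <- function(sp) {
  stopifnot(is.character(sp$name), length(sp$name) == 1L)
  num <- c("mu_max_R", "mu_max_E", "K_R", "K_E", "Y_R", "Y_E", "gamma_E",
           "omega")
  for (f in num) {
    v <- sp[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("species '", sp$name, "': field '", f, "' must be a single value >= 0")
  }
  if (sp$K_R <= 0 || sp$K_E <= 0 || sp$Y_R <= 0 || sp$Y_E <= 0)
    stop("species '", sp$name, "': kinetic constants must be strictly positive")
  if (sp$omega > 1) stop("species '", sp$name, "': omega must lie in [0, 1]")
  if (!is.numeric(sp$K_tox) || sp$K_tox <= 0)
    stop("species '", sp$name, "': K_tox must be > 0 (Inf disables inhibition)")
  if (sp$gamma_E > 0 && is.na(sp$e_out))
    stop("species '", sp$name, "': producers must name an output field (e_out)")
  invisible(sp)
}

is_producer <- function(sp) sp$gamma_E > 0

#' @exportS3Method base::print
print.syn_species <- function(x, ...) {
  cat("<syn_species> ", x$name,
      if (is_producer(x)) " (producer)" else " (non-producer)", "\n", sep = "")
  cat(sprintf("  mu_max_R=%g mu_max_E=%g K_R=%g K_E=%g omega=%g\n",
              x$mu_max_R, x$mu_max_E, x$K_R, x$K_E, x$omega))
  cat(sprintf("  Y_R=%g Y_E=%g gamma_E=%g K_tox=%g\n",
              x$Y_R, x$Y_E, x$gamma_E, x$K_tox))
  cat(sprintf("  fields: nutrient=%s e_in=%s e_out=%s\n",
              x$nutrient, x$e_in, x$e_out))
  invisible(x)
}

## Vectorised growth kernel shared by all species types. R, E_in, E_inh may
## be scalars, vectors or matrices (local concentrations).
species_rates <- function(sp, R = 0, E_in = 0, E_inh = 0) {
  monod_R <- if (sp$mu_max_R > 0) R / (sp$K_R + R) else R * 0
  inhib <- if (is.finite(sp$K_tox)) 1 / (1 + E_inh / sp$K_tox) else 1
  mu_R <- (1 - sp$omega) * sp$mu_max_R * monod_R * inhib
  monod_E <- if (sp$mu_max_E > 0) E_in / (sp$K_E + E_in) else E_in * 0
  mu_E <- sp$omega * sp$mu_max_E * monod_E
  mu <- mu_R + mu_E
  structure(list(mu = mu,
                 q_R = mu_R / sp$Y_R,
                 q_E_uptake = mu_E / sp$Y_E,
                 q_E_production = sp$gamma_E * mu),
            class = "syn_rates")
}

check_conc <- function(...) {
  for (v in list(...)) {
    if (anyNA(v) || any(v < 0))
      stop("concentrations must be non-negative and not NA")
  }
  invisible(TRUE)
}

#' Producer specific growth rate
#'
#' Monod growth on the shared nutrient, reduced by simple (non-competitive)
#' inhibition from the accumulated by-product:
#' `mu = mu_max_R * R/(K_R + R) * 1/(1 + E/K_tox)`.
#'
#' @param R_conc,E_conc Local nutrient and by-product concentrations (g/L);
#'   vectorised.
#' @param spec A producer [syn_species()] (`gamma_E > 0`).
#' @return Specific growth rate(s) in `[0, mu_max_R]` (1/h).
#' @export
producer_growth_rate <- function(R_conc, E_conc, spec) {
  check_conc(R_conc, E_conc)
  if (!is_producer(spec))
    stop("species '", spec$name, "' is not a producer (gamma_E = 0)")
  species_rates(spec, R = R_conc, E_inh = E_conc)$mu
}

#' Cross-feeder reaction rates
#'
#' Additive substitutable-resource kinetics on the shared nutrient and the
#' producer by-product, weighted by the obligacy `omega` of the variant:
#' `mu = (1-omega) mu_max_R R/(K_R+R) + omega mu_max_E E/(K_E+E)`.
#'
#' @inheritParams producer_growth_rate
#' @param spec A cross-feeder [syn_species()] (`gamma_E = 0`).
#' @return A `syn_rates` list: `mu`, `q_R` (nutrient uptake, g/g/h),
#'   `q_E_uptake`, `q_E_production` (zero for cross-feeders).
#' @export
crossfeeder_growth_rate <- function(R_conc, E_conc, spec) {
  check_conc(R_conc, E_conc)
  if (is_producer(spec))
    stop("species '", spec$name, "' is a producer; use producer_growth_rate()")
  species_rates(spec, R = R_conc, E_in = E_conc)
}

#' Net solute source terms from standing biomass
#'
#' Maps per-voxel, per-species biomass densities and current solute
#' concentrations to the net volumetric rate of each solute field:
#' consumption of the nutrient, uptake of the by-product, and production of
#' the by-product. Voxels with zero biomass have exactly zero rate.
#'
#' @param biomass Named list (one entry per species) of matrices of biomass
#'   density (g/L) on the shared grid.
#' @param fields Named list of [solute_field()] objects (their `conc`
#'   matrices are the concentrations used).
#' @param specs Named list of [syn_species()], names matching `biomass`.
#' @return Named list of matrices, net rate in g/L/h per solute field.
#' @export
solute_source_terms <- function(biomass, fields, specs) {
  dims <- dim(fields[[1L]]$conc)
  for (f in fields) {
    if (!identical(dim(f$conc), dims))
      stop("all solute fields must share one grid shape")
  }
  rate <- lapply(fields, function(f) matrix(0, dims[1L], dims[2L]))
  for (nm in names(biomass)) {
    sp <- specs[[nm]]
    if (is.null(sp)) stop("no species spec named '", nm, "'")
    X <- biomass[[nm]]
    if (!identical(dim(X), dims)) stop("biomass grid shape mismatch for '", nm, "'")
    if (any(X < 0)) stop("biomass densities must be non-negative")
    R <- if (!is.na(sp$nutrient)) fields[[sp$nutrient]]$conc else 0
    E_in <- if (!is.na(sp$e_in)) fields[[sp$e_in]]$conc else 0
    E_inh <- if (is.finite(sp$K_tox) && !is.na(sp$e_out)) fields[[sp$e_out]]$conc else 0
    rr <- species_rates(sp, R = R, E_in = E_in, E_inh = E_inh)
    if (!is.na(sp$nutrient))
      rate[[sp$nutrient]] <- rate[[sp$nutrient]] - rr$q_R * X
    if (!is.na(sp$e_in))
      rate[[sp$e_in]] <- rate[[sp$e_in]] - rr$q_E_uptake * X
    if (!is.na(sp$e_out))
      rate[[sp$e_out]] <- rate[[sp$e_out]] + rr$q_E_production * X
  }
  rate
}

## Picard-linearised sources: per field, rate(S) = p - k * S with k, p >= 0
## evaluated at the current concentrations. The linearisation is exact at the
## evaluation point (k * S equals the Monod uptake there), so residuals
## computed from fresh (k, p) are true nonlinear residuals.
linearized_sources <- function(biomass, specs) {
  ## biomass is sparse on the grid: precompute occupied voxels per species
  occ <- lapply(biomass, function(X) {
    idx <- which(X > 0)
    list(idx = idx, X = X[idx])
  })
  dims <- dim(biomass[[1L]])
  function(fields) {
    k <- lapply(fields, function(f) matrix(0, dims[1L], dims[2L]))
    p <- lapply(fields, function(f) matrix(0, dims[1L], dims[2L]))
    for (nm in names(biomass)) {
      sp <- specs[[nm]]
      idx <- occ[[nm]]$idx
      if (!length(idx)) next
      X <- occ[[nm]]$X
      R <- if (!is.na(sp$nutrient)) fields[[sp$nutrient]]$conc[idx] else 0
      E_in <- if (!is.na(sp$e_in)) fields[[sp$e_in]]$conc[idx] else 0
      E_inh <- if (is.finite(sp$K_tox) && !is.na(sp$e_out))
        fields[[sp$e_out]]$conc[idx] else 0
      inhib <- if (is.finite(sp$K_tox)) 1 / (1 + E_inh / sp$K_tox) else 1
      ## Monod uptake linearised by its tangent (Newton): rate at the current
      ## point is exact, so the convergence test still sees true residuals
      if (!is.na(sp$nutrient) && sp$mu_max_R > 0 && sp$omega < 1) {
        a <- (1 - sp$omega) * sp$mu_max_R * inhib * X / sp$Y_R
        den <- (sp$K_R + R)^2
        k[[sp$nutrient]][idx] <- k[[sp$nutrient]][idx] + a * sp$K_R / den
        p[[sp$nutrient]][idx] <- p[[sp$nutrient]][idx] - a * R^2 / den
      }
      if (!is.na(sp$e_in) && sp$mu_max_E > 0 && sp$omega > 0) {
        a <- sp$omega * sp$mu_max_E * X / sp$Y_E
        den <- (sp$K_E + E_in)^2
        k[[sp$e_in]][idx] <- k[[sp$e_in]][idx] + a * sp$K_E / den
        p[[sp$e_in]][idx] <- p[[sp$e_in]][idx] - a * E_in^2 / den
      }
      if (!is.na(sp$e_out) && sp$gamma_E > 0) {
        mu <- species_rates(sp, R = R, E_in = E_in, E_inh = E_inh)$mu
        p[[sp$e_out]][idx] <- p[[sp$e_out]][idx] + sp$gamma_E * mu * X
        if (is.finite(sp$K_tox)) {
          ## the production of E falls with E (self-inhibition); folding the
          ## (negative) slope into the uptake diagonal keeps the linearised
          ## system an M-matrix and makes the Picard loop Newton-like in E
          dk <- sp$gamma_E * mu * X / (sp$K_tox + E_inh)
          k[[sp$e_out]][idx] <- k[[sp$e_out]][idx] + dk
          p[[sp$e_out]][idx] <- p[[sp$e_out]][idx] + dk * E_inh
        }
      }
    }
    list(k = k, p = p)
  }
}

#' Build the standard species pair
#'
#' Constructs the producer `A` and a cross-feeder variant from the default
#' parameter set: `B_obl` (obligate), `B_facS`/`B_facI`/`B_facW`
#' (facultative, strongly / intermediately / weakly dependent on the
#' by-product) or `B_ncf` (non-cross-feeder competing only for the nutrient).
#'
#' @param variant Cross-feeder variant name.
#' @param K_tox Producer inhibition constant (g/L); `Inf` = non-toxic.
#' @param params Parameter list from [syn_params()].
#' @return Named list of two `syn_species` (`A` and the variant).
#' @examples
#' sp <- default_species("B_obl", K_tox = 0.04)
#' sp$B_obl$omega
#' @export
default_species <- function(variant = "B_obl", K_tox = Inf,
                            params = syn_params()) {
  p <- params
  if (!variant %in% names(p$omega_levels))
    stop("unknown cross-feeder variant '", variant, "'; one of: ",
         paste(names(p$omega_levels), collapse = ", "))
  omega <- unname(p$omega_levels[variant])
  A <- syn_species("A", mu_max_R = p$mu_max_R_A, K_R = p$K_R_A,
                   Y_R = p$Y_R_A, K_tox = K_tox, gamma_E = p$gamma_E,
                   omega = 0, nutrient = "R", e_out = "E")
  B <- syn_species(variant,
                   mu_max_R = if (variant == "B_obl") 0 else p$mu_max_R_B,
                   mu_max_E = if (variant == "B_ncf") 0 else p$mu_max_E_B,
                   K_R = p$K_R_B, K_E = p$K_E, Y_R = p$Y_R_B, Y_E = p$Y_E,
                   omega = omega, nutrient = "R",
                   e_in = if (variant == "B_ncf") NA_character_ else "E")
  stats::setNames(list(A, B), c("A", variant))
}
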