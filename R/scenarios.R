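#' Seed a random lawn inoculum on the substratum
#'
#' Places the requested number of cells of each species at uniformly random
#' lateral positions with `y = radius` (sitting on the substratum), species
#' labels randomly interleaved. The default experimental design is additive:
#' 60 cells per species in coculture, 60 cells total in monoculture, so each
#' species' own inoculation density is constant across culture types.
#'
#' @param counts Named integer vector, cells per species.
#' @param params Parameter list from [syn_params()].
#' @return A `syn_cells` table.
#' @export
seed_random_lawn <- function(counts, params = syn_params()) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1L) stop("empty inoculum")
  species <- sample(rep(names(counts), counts))
  mass <- draw_seed_mass(n, params)
  r <- radius_from_mass(mass, params)
  if (sum(pi * r^2) > 0.2 * params$domain_width * params$domain_height)
    stop("inoculum too crowded for the domain")
  x <- stats::runif(n, 0, params$domain_width)
  new_cells(species, x, r, mass, params = params)
}

#' Seed one or two microcolony inocula
#'
#' Builds the microcolony seeding geometry: substratum bands of width
#' `colony_width` (30 um), edge-to-edge `separation` (70 um) apart, relaxed
#' once so each band mounds into a microcolony. With two species,
#' `initial_segregation` in `[0, 1]` sets the per-colony composition: colony
#' 1 receives the fraction `(1 + s) / 2` of species 1 and `(1 - s) / 2` of
#' species 2 (counts rounded so totals are conserved exactly); `s = 1` gives
#' clonal colonies, `s = 0` a 1:1 mix in each. An increment of 0.1 in `s`
#' therefore shifts 5% of each species' cells between colonies.
#'
#' @param counts Named integer vector per species (one species = a single
#'   colony, the monoculture control geometry).
#' @param initial_segregation Value in `[0, 1]`.
#' @param halves_tagging If `TRUE`, tag each colony's half facing the other
#'   colony `"near"` and the outer half `"far"` (lineage tracking).
#' @param single_colony Force all cells into one central colony.
#' @param cyclic Lateral wrap used for the single relaxation pass.
#' @param params Parameter list.
#' @return A `syn_cells` table.
#' @export
seed_two_microcolonies <- function(counts, initial_segregation = 0,
                                   halves_tagging = FALSE,
                                   single_colony = length(counts) == 1L,
                                   cyclic = TRUE, params = syn_params()) {
  s <- initial_segregation
  if (s < 0 || s > 1) stop("initial_segregation must lie in [0, 1]")
  counts <- counts[counts > 0]
  w <- params$colony_width
  W <- params$domain_width
  if (!single_colony && w * 2 + params$colony_sep > W)
    stop("colonies do not fit in the domain width")
  if (single_colony) {
    centers <- W / 2
    split <- list(counts)
  } else {
    centers <- W / 2 + c(-1, 1) * (params$colony_sep + w) / 2
    n1 <- sapply(seq_along(counts), function(i) {
      fr <- if (i == 1L) (1 + s) / 2 else (1 - s) / 2
      as.integer(round(counts[i] * fr))
    })
    split <- list(stats::setNames(n1, names(counts)),
                  counts - n1)
  }
  pieces <- list()
  for (ci in seq_along(centers)) {
    cnt <- split[[ci]]
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) next
    n <- sum(cnt)
    species <- rep(names(cnt), cnt)
    mass <- draw_seed_mass(n, params)
    r <- radius_from_mass(mass, params)
    x <- stats::runif(n, centers[ci] - w / 2, centers[ci] + w / 2)
    tag <- "none"
    if (halves_tagging && !single_colony) {
      facing <- if (ci == 1L) x >= centers[ci] else x < centers[ci]
      tag <- ifelse(facing, "near", "far")
    }
    pieces[[length(pieces) + 1L]] <-
      new_cells(species, x, r, mass, tag = tag, params = params)
  }
  cells <- do.call(rbind, pieces)
  ## shuffle row order so the index-ordered shove pass cannot stratify the
  ## mound by species (ids/indices must be independent of the label)
  cells <- cells[sample(nrow(cells)), , drop = FALSE]
  cells$id <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  class(cells) <- c("syn_cells", "data.frame")
  ## one-off inoculation relax gets a larger sweep budget: mounding a dense
  ## band into a microcolony takes longer than the per-step touch-ups
  relax_overlaps(cells, list(width = W, cyclic = cyclic),
                 tol = params$shove_tol,
                 max_sweeps = 8L * params$shove_max_sweeps)
}

scenario_registry <- function() {
  c("grid_cell", "space_only", "control", "segregation_sweep",
    "diffusion_sweep", "near_far", "bidirectional")
}

#' List the built-in scenario names
#' @return Character vector of registry names accepted by [build_scenario()].
#' @export
list_scenarios <- function() scenario_registry()

resolve_toxicity <- function(toxicity, K_tox, p) {
  if (!is.null(K_tox)) return(K_tox)
  if (!(toxicity %in% seq_along(p$toxicity_levels)))
    stop("toxicity must be a level index 1..", length(p$toxicity_levels),
         " (1 = non-toxic, ", length(p$toxicity_levels), " = highly toxic)")
  p$toxicity_levels[[toxicity]]
}

new_scenario <- function(name, p, species, fields, inoculum, cyclic = TRUE,
                         competition = "shared_nutrient", producer = "A",
                         toxicity = NA, obligacy = NA_character_,
                         culture = "co") {
  structure(list(name = name, params = p, species = species, fields = fields,
                 inoculum = inoculum, cyclic = cyclic,
                 competition = competition, producer = producer,
                 toxicity = toxicity, obligacy = obligacy, culture = culture),
            class = "syn_scenario")
}

#' @exportS3Method base::print
print.syn_scenario <- function(x, ...) {
  cat("<syn_scenario> ", x$name, " [", x$culture, "]\n", sep = "")
  cat("  species:", paste(names(x$species), collapse = " + "),
      " competition:", x$competition, "\n")
  cat("  K_tox:", x$toxicity, " inoculum:", x$inoculum$mode,
      " duration:", x$params$duration, "h\n")
  invisible(x)
}

field_spec <- function(D, bulk, lateral = "cyclic", mult = 1)
  list(D = D, bulk = bulk, lateral = lateral, mult = mult)

mono_counts <- function(counts, culture, species) {
  if (culture == "co") return(counts)
  which <- sub("^mono_", "", culture)
  nm <- if (which %in% names(counts)) which
        else if (which == "A") names(counts)[1L]
        else if (which == "B") names(counts)[2L]
        else stop("unknown culture '", culture, "'")
  counts[nm]
}

#' Build a fully resolved scenario
#'
#' Catalogue of the simulated experiments. Names and their options:
#'
#' * `grid_cell`: shared-nutrient coculture on a random lawn for one cell of
#'   the toxicity-by-obligacy grid (`toxicity` = level index 1..5,
#'   `obligacy` = cross-feeder variant).
#' * `space_only`: as `grid_cell` but each species gets a private nutrient
#'   field (`R_A`, `R_B`) with identical bulk values, removing nutrient
#'   competition while keeping competition for space.
#' * `control`: two parameter-identical, non-interacting species differing
#'   only in their lineage color.
#' * `segregation_sweep`: two microcolonies (30 um wide, 70 um apart) with
#'   per-colony composition set by `initial_segregation`, and overall
#'   producer share by `producer_proportion`.
#' * `diffusion_sweep`: four strong-interdependence microcolony scenarios
#'   with by-product diffusion multipliers {10, 1.4, 1, 0.14} (returned as a
#'   list).
#' * `near_far`: two clonal microcolonies with near/far half tagging,
#'   non-cyclic lateral boundaries permeable to the by-product; 120 h.
#' * `bidirectional`: mutual cross-feeding (A consumes R and E_B, produces
#'   E_A; B consumes only E_A and produces E_B).
#'
#' @param name Registry name (see [list_scenarios()]).
#' @param toxicity Toxicity level index (1..5; 5 = highly toxic).
#' @param K_tox Direct inhibition constant override (g/L).
#' @param obligacy Cross-feeder variant name.
#' @param culture `"co"`, `"mono_A"` or `"mono_B"`.
#' @param initial_segregation,producer_proportion,halves_tagging Microcolony
#'   seeding controls.
#' @param diffusion_mult Multiplier on the by-product diffusivity.
#' @param ... Overrides forwarded to [syn_params()].
#' @return A `syn_scenario` (a list of them for `diffusion_sweep`).
#' @examples
#' scn <- build_scenario("grid_cell", toxicity = 5, obligacy = "B_obl")
#' scn$species$B_obl$omega
#' @export
build_scenario <- function(name, toxicity = 1, K_tox = NULL,
                           obligacy = "B_obl", culture = "co",
                           initial_segregation = 0, producer_proportion = 0.5,
                           halves_tagging = FALSE, diffusion_mult = 1, ...) {
  if (!name %in% scenario_registry())
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenario_registry(), collapse = ", "))
  p <- syn_params(...)
  ktox <- resolve_toxicity(toxicity, K_tox, p)

  if (name == "diffusion_sweep") {
    mults <- c(10, 1.4, 1, 0.14)
    return(lapply(mults, function(m)
      build_scenario("segregation_sweep",
                     toxicity = if (is.null(K_tox)) toxicity else 1,
                     K_tox = K_tox %||% p$toxicity_levels[[length(p$toxicity_levels)]],
                     obligacy = obligacy, culture = culture,
                     initial_segregation = initial_segregation,
                     producer_proportion = producer_proportion,
                     diffusion_mult = m, ...)))
  }

  if (name == "control") {
    base <- default_species("B_ncf", K_tox = Inf, params = p)$A
    mk <- function(nm) {
      sp <- base; sp$name <- nm; sp$gamma_E <- 0; sp$K_tox <- Inf
      sp$e_out <- NA_character_; sp
    }
    species <- list(C_red = mk("C_red"), C_blue = mk("C_blue"))
    fields <- list(R = field_spec(p$D_R, p$R_bulk))
    counts <- stats::setNames(rep(as.integer(p$n_inoc), 2L), names(species))
    counts <- mono_counts(counts, culture, species)
    inoc <- list(mode = "random_lawn", counts = counts)
    return(new_scenario("control", p, species, fields, inoc,
                        producer = "C_red", toxicity = Inf,
                        culture = culture))
  }

  species <- default_species(obligacy, K_tox = ktox, params = p)

  if (name == "bidirectional") {
    A <- species$A
    A$omega <- 0.5; A$mu_max_E <- p$mu_max_E_B; A$K_E <- p$K_E
    A$Y_E <- p$Y_E; A$K_tox <- Inf
    A$e_in <- "E_B"; A$e_out <- "E_A"
    B <- species[[2L]]
    B$name <- "B_bid"; B$omega <- 1; B$mu_max_R <- 0
    B$gamma_E <- p$gamma_E; B$e_in <- "E_A"; B$e_out <- "E_B"
    species <- list(A = A, B_bid = B)
    fields <- list(R = field_spec(p$D_R, p$R_bulk),
                   E_A = field_spec(p$D_E, 0, mult = diffusion_mult),
                   E_B = field_spec(p$D_E, 0, mult = diffusion_mult))
    counts <- stats::setNames(rep(as.integer(p$n_inoc), 2L), names(species))
    counts <- mono_counts(counts, culture, species)
    inoc <- list(mode = "random_lawn", counts = counts)
    return(new_scenario("bidirectional", p, species, fields, inoc,
                        toxicity = Inf, obligacy = "B_bid", culture = culture))
  }

  fields <- list(R = field_spec(p$D_R, p$R_bulk),
                 E = field_spec(p$D_E, p$E_bulk, mult = diffusion_mult))
  competition <- "shared_nutrient"
  if (name == "space_only") {
    species$A$nutrient <- "R_A"
    species[[2L]]$nutrient <- "R_B"
    fields <- list(R_A = field_spec(p$D_R, p$R_bulk),
                   R_B = field_spec(p$D_R, p$R_bulk),
                   E = field_spec(p$D_E, p$E_bulk, mult = diffusion_mult))
    competition <- "space_only"
  }

  n_tot <- as.integer(round(2 * p$n_inoc))
  nA <- as.integer(round(n_tot * producer_proportion))
  counts <- stats::setNames(c(nA, n_tot - nA), names(species))
  counts <- mono_counts(counts, culture, species)

  cyclic <- TRUE
  if (name %in% c("grid_cell", "space_only")) {
    inoc <- list(mode = "random_lawn", counts = counts)
  } else if (name == "segregation_sweep") {
    inoc <- list(mode = if (culture == "co") "two_microcolonies"
                        else "single_microcolony",
                 counts = counts, initial_segregation = initial_segregation,
                 halves_tagging = halves_tagging)
  } else if (name == "near_far") {
    if (!"duration" %in% names(list(...))) p$duration <- 120
    fields$R$lateral <- "zero-flux"
    fields$E$lateral <- "permeable"
    cyclic <- FALSE
    inoc <- list(mode = if (culture == "co") "two_microcolonies"
                        else "single_microcolony",
                 counts = counts, initial_segregation = 1,
                 halves_tagging = TRUE)
  }
  sc <- new_scenario(name, p, species, fields, inoc, cyclic = cyclic,
                     competition = competition, toxicity = ktox,
                     obligacy = names(species)[2L], culture = culture)
  sc$params <- p
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed the inoculum described by a scenario
#'
#' @param scenario A `syn_scenario`; uses the current RNG state.
#' @return A `syn_cells` table.
#' @export
seed_inoculum <- function(scenario) {
  inoc <- scenario$inoculum
  p <- scenario$params
  switch(inoc$mode,
    random_lawn = seed_random_lawn(inoc$counts, params = p),
    two_microcolonies = seed_two_microcolonies(
      inoc$counts, initial_segregation = inoc$initial_segregation %||% 0,
      halves_tagging = isTRUE(inoc$halves_tagging), single_colony = FALSE,
      cyclic = scenario$cyclic, params = p),
    single_microcolony = seed_two_microcolonies(
      inoc$counts, single_colony = TRUE, cyclic = scenario$cyclic,
      params = p),
    stop("unknown inoculum mode '", inoc$mode, "'")
  )
}
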