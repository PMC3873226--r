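p0 <- syn_params()

test_that("biomass advances exponentially and flags division", {
  m0 <- division_mass <- syntromix:::division_mass(p0)
  cells <- new_cells(c("A", "A"), x = c(10, 20), y = c(2, 2),
                     mass = c(0.55, 0.9) * m0, params = p0)
  out <- advance_biomass(cells, mu = c(0, 0), dt = 1, params = p0)
  expect_equal(out$mass, cells$mass)
  expect_length(attr(out, "to_divide"), 0)

  out <- advance_biomass(cells, mu = rep(log(2), 2), dt = 1, params = p0)
  expect_equal(out$mass, cells$mass * 2)
  expect_identical(attr(out, "to_divide"), c(1L, 2L))
  expect_error(advance_biomass(cells, c(NaN, 0), 1, p0), "cell id 1")
  expect_error(advance_biomass(cells, c(0, 0), 0, p0), "dt must be positive")
})

test_that("division conserves mass and inherits tags", {
  m0 <- syntromix:::division_mass(p0)
  cell <- new_cells("A", 10, 10, mass = 1.1 * m0, tag = "near", params = p0)
  set.seed(1)
  d <- divide_cell(cell, p0, next_id = 100L)
  expect_identical(nrow(d), 2L)
  expect_identical(sum(d$mass), cell$mass)   # exact conservation
  expect_identical(d$tag, c("near", "near"))
  expect_identical(d$species, c("A", "A"))
  expect_identical(d$id, c(100L, 101L))
  ## daughters touch: separated by the sum of their radii
  expect_equal(sqrt(diff(d$x)^2 + diff(d$y)^2), sum(d$radius),
               tolerance = 1e-9)
  expect_error(divide_cell(new_cells("A", 1, 2, 0.5 * m0, params = p0), p0),
               "below the division threshold")
})

test_that("split fractions are uniform on [0.45, 0.55]", {
  m0 <- syntromix:::division_mass(p0)
  parents <- new_cells(rep("A", 1e4), runif(1e4, 0, 100), 2,
                       mass = rep(1.05 * m0, 1e4), params = p0)
  set.seed(99)
  d <- syntromix:::divide_cells(parents, p0, next_id = 1e5L)
  frac <- d$mass[1:1e4] / parents$mass
  expect_true(all(frac >= 0.45 & frac <= 0.55))
  expect_lt(abs(mean(frac) - 0.5), 0.003)
})

test_that("a desynchronised population tracks the well-mixed exponential", {
  ## deterministic stationary-size seeding; growth + division only
  n0 <- 100; mu <- 0.5; dt <- 0.01; t_end <- 10
  m_div <- syntromix:::division_mass(p0)
  ## stationary-size quantiles: number density ~ 1/m^2 on [m_div/2, m_div)
  mass <- m_div / (2 - (seq_len(n0) - 0.5) / n0)
  cells <- new_cells(rep("A", n0), x = seq_len(n0), y = 2, mass = mass,
                     params = p0)
  set.seed(5)
  for (i in seq_len(t_end / dt)) {
    cells <- advance_biomass(cells, rep(mu, nrow(cells)), dt, p0)
    div <- attr(cells, "to_divide")
    if (length(div)) {
      daughters <- syntromix:::divide_cells(cells[div, , drop = FALSE], p0,
                                            next_id = max(cells$id) + 1L)
      cells <- rbind(cells[-div, , drop = FALSE], daughters)
    }
  }
  expect_lt(abs(nrow(cells) / (n0 * exp(mu * t_end)) - 1), 0.01)
  expect_lt(abs(sum(cells$mass) / (sum(mass) * exp(mu * t_end)) - 1), 1e-9)
})

test_that("shoving separates overlaps and leaves distant cells alone", {
  m0 <- syntromix:::division_mass(p0)
  dom <- list(width = 100, cyclic = FALSE)
  far <- new_cells(c("A", "A"), x = c(20, 40), y = c(5, 5),
                   mass = rep(0.8 * m0, 2), params = p0)
  out <- relax_overlaps(far, dom)
  expect_identical(out$x, far$x)
  expect_identical(out$y, far$y)

  ## fully superposed pair separates along +x (deterministic tie-break)
  sup <- new_cells(c("A", "B"), x = c(50, 50), y = c(10, 10),
                   mass = rep(0.8 * m0, 2), params = p0)
  out <- relax_overlaps(sup, dom)
  expect_equal(out$y, sup$y)
  expect_equal(diff(out$x), sum(sup$radius), tolerance = 1e-9)
  expect_lt(out$x[1], out$x[2])

  ## overlap never increases with more sweeps (seeded dense cluster)
  set.seed(11)
  dense <- new_cells(rep("A", 60), x = runif(60, 45, 55), y = runif(60, 1, 8),
                     mass = draw_seed_mass(60, p0), params = p0)
  dense$y <- pmax(dense$y, dense$radius)
  ovs <- sapply(c(1, 4, 16, 64, 256), function(k) {
    out <- suppressWarnings(relax_overlaps(dense, dom, tol = 1e-4,
                                           max_sweeps = k))
    max_overlap_fraction(out)
  })
  ## relaxation resolves the cluster: the worst overlap falls from the
  ## packed start toward the tolerance as the sweep budget grows
  expect_lt(ovs[length(ovs)], 0.05)
  expect_true(all(diff(ovs[-(1:2)]) <= 1e-9))
  ## substratum and walls respected
  out <- suppressWarnings(relax_overlaps(dense, dom, max_sweeps = 200))
  expect_true(all(out$y >= out$radius - 1e-9))
})

test_that("shoving and division conserve total biomass", {
  set.seed(21)
  m0 <- syntromix:::division_mass(p0)
  cells <- new_cells(rep(c("A", "B"), 30), x = runif(60, 0, 30),
                     y = runif(60, 1, 5), mass = runif(60, 0.9, 1.4) * m0,
                     params = p0)
  cells$y <- pmax(cells$y, cells$radius)
  total <- sum(cells$mass)
  shoved <- suppressWarnings(
    relax_overlaps(cells, list(width = 30, cyclic = TRUE)))
  expect_identical(sum(shoved$mass), total)
  div <- which(cells$mass >= m0)
  daughters <- syntromix:::divide_cells(cells[div, ], p0, next_id = 1000L)
  expect_equal(sum(daughters$mass), sum(cells$mass[div]))
})

test_that("cyclic shoving wraps lateral positions into the domain", {
  m0 <- syntromix:::division_mass(p0)
  cells <- new_cells(c("A", "A"), x = c(0.1, 29.9), y = c(2, 2),
                     mass = rep(0.9 * m0, 2), params = p0)
  out <- relax_overlaps(cells, list(width = 30, cyclic = TRUE))
  expect_true(all(out$x >= 0 & out$x < 30))
  ## the pair overlapped across the seam and must now be separated
  dx <- abs(diff(out$x)); dx <- min(dx, 30 - dx)
  expect_gte(sqrt(dx^2 + diff(out$y)^2) + 1e-9, sum(out$radius) * 0.95)
})
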