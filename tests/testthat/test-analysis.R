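p0 <- syn_params()
mk_cells <- function(species, x, y) {
  new_cells(species, x, y, mass = rep(syntromix:::division_mass(p0) * 0.6,
                                      length(x)), params = p0)
}

test_that("local segregation is the same-species neighbor fraction", {
  focal <- mk_cells("A", 0, 0)
  nb5 <- mk_cells(rep("A", 5), 1:5, 0)
  expect_identical(local_segregation(focal, nb5), 1)
  nb4 <- mk_cells(c("A", "A", "B", "B"), 1:4, 0)
  expect_identical(local_segregation(focal, nb4), 0.5)
  expect_true(is.na(local_segregation(focal, nb4[0, ])))
})

test_that("segregation index hits the stated endpoints", {
  ## two clonal colonies 70 um apart -> s = 1 exactly for both species
  set.seed(12)
  cells <- seed_two_microcolonies(c(A = 60, B_obl = 60),
                                  initial_segregation = 1, params = p0)
  seg <- segregation_index(cells, radius = 10, width = 260, cyclic = TRUE)
  expect_identical(unname(seg$s), c(1, 1))
  expect_identical(unname(seg$seg), c(1, 1))
  expect_identical(unname(seg$p), c(0.5, 0.5))

  ## hand-computed over-mixed pair: A at (0,0), B at (5,0)
  pair <- mk_cells(c("A", "B"), c(0, 5), c(0, 0))
  seg <- segregation_index(pair, radius = 10)
  expect_identical(unname(seg$s), c(-1, -1))
  expect_identical(unname(seg$seg), c(0, 0))
  expect_identical(unname(seg$n_evaluated), c(1L, 1L))

  ## isolated cells (no neighbors) are excluded from the species mean
  iso <- mk_cells(c("A", "A", "B"), c(0, 3, 500), c(0, 0, 0))
  seg <- segregation_index(iso, radius = 10)
  expect_identical(unname(seg$n_evaluated), c(2L, 0L))
  expect_true(is.na(seg$s["B"]))
  expect_identical(unname(seg$seg["A"]), 1)
})

test_that("random labels give s ~ 0 under the permutation null", {
  set.seed(33)
  cells <- random_snapshot(200, clustered = TRUE)
  svals <- replicate(200, {
    cells$species <- sample(cells$species)
    mean(segregation_index(cells, radius = 10)$s, na.rm = TRUE)
  })
  se <- sd(svals) / sqrt(length(svals))
  expect_lt(abs(mean(svals)), 3 * se + 0.01)
})

test_that("segregation matches the brute-force oracle on random snapshots", {
  set.seed(44)
  for (i in 1:12) {
    n <- sample(20:300, 1)
    cyc <- i %% 2 == 0
    cells <- random_snapshot(n, clustered = i %% 3 == 0)
    fast <- segregation_index(cells, radius = 10, width = 100, cyclic = cyc)
    slow <- brute_force_segregation(cells, radius = 10, width = 100,
                                    cyclic = cyc)
    expect_equal(fast$s, slow$s, tolerance = 1e-12)
    expect_equal(fast$seg, slow$seg, tolerance = 1e-12)
  }
})

test_that("s is invariant under rigid motions of the snapshot", {
  set.seed(55)
  cells <- random_snapshot(150, clustered = TRUE)
  base <- segregation_index(cells, radius = 10)
  th <- 0.7
  rot <- cells
  rot$x <- cells$x * cos(th) - cells$y * sin(th) + 500
  rot$y <- cells$x * sin(th) + cells$y * cos(th) + 500
  moved <- segregation_index(rot, radius = 10)
  expect_equal(moved$s, base$s, tolerance = 1e-9)
})

test_that("growth rate is plain count arithmetic", {
  expect_identical(growth_rate(60, 540, 0, 96), 5)
  expect_identical(growth_rate(60, 60, 0, 96), 0)
  expect_identical(growth_rate(30, 318, 12, 108), 3)
  expect_error(growth_rate(10, 20, 5, 5), "invalid interval")
})

test_that("relative growth uses the obligate convention", {
  expect_identical(relative_growth(2, 2), 0)
  expect_equal(relative_growth(4, 2), log(2))
  expect_identical(relative_growth(1, obligate = TRUE), 0)
  expect_identical(relative_growth(0, 2), -Inf)
  expect_error(relative_growth(2, 0), "degenerate")
})

test_that("interaction classification follows the sign pattern", {
  expect_identical(classify_interaction(0.3, 0.5)$label, "mutualism")
  expect_identical(classify_interaction(-0.3, 0.5)$label, "exploitation_B_of_A")
  expect_identical(classify_interaction(0.3, -0.5)$label, "exploitation_A_of_B")
  expect_identical(classify_interaction(-0.3, -0.2)$label, "competition")
  expect_identical(classify_interaction(0.01, -0.01)$label, "neutral")
  expect_identical(classify_interaction(-Inf, 0.4)$label, "exploitation_B_of_A")

  ## mirror symmetry: swapping species swaps the exploitation direction
  mirror <- c(mutualism = "mutualism", competition = "competition",
              neutral = "neutral",
              exploitation_A_of_B = "exploitation_B_of_A",
              exploitation_B_of_A = "exploitation_A_of_B")
  set.seed(66)
  for (i in 1:50) {
    a <- runif(1, -1, 1); b <- runif(1, -1, 1)
    expect_identical(classify_interaction(b, a)$label,
                     unname(mirror[classify_interaction(a, b)$label]))
  }
})

test_that("productivity gain is the coculture minus monoculture sum", {
  expect_identical(productivity_gain(3, 4, 2, 5), 0)
  expect_identical(productivity_gain(5, 5, 2, 2), 6)
  expect_error(productivity_gain(NA, 1, 1, 1))
  ## mutualism implies a community productivity gain
  set.seed(77)
  for (i in 1:20) {
    gmA <- runif(1, 1, 5); gmB <- runif(1, 1, 5)
    eA <- runif(1, 0.05, 1); eB <- runif(1, 0.05, 1)
    gcA <- gmA * exp(eA); gcB <- gmB * exp(eB)
    lab <- classify_interaction(eA, eB)$label
    if (lab == "mutualism")
      expect_gt(productivity_gain(gcA, gcB, gmA, gmB), 0)
  }
})

test_that("producer fraction tracks counts over time", {
  fake <- structure(list(
    scenario = list(producer = "A"),
    times = c(0, 48, 96),
    counts = cbind(A = c(60L, 90L, 102L), B_obl = c(60L, 150L, 198L))),
    class = "syn_trajectory")
  pf <- producer_fraction(fake)
  expect_equal(pf$producer_fraction, c(0.5, 0.375, 0.34))
  mono <- fake; mono$counts <- cbind(A = c(60L, 80L, 90L),
                                     B_obl = c(0L, 0L, 0L))
  expect_true(all(producer_fraction(mono)$producer_fraction == 1))
})

test_that("near/far advantage vanishes when tags carry no information", {
  set.seed(88)
  mk_traj <- function(first, last, species) {
    structure(list(scenario = list(species = stats::setNames(
      as.list(species), species)),
      times = c(0, 48),
      snapshots = list(list(cells = first), list(cells = last))),
      class = "syn_trajectory")
  }
  sp <- rep(c("A", "B"), each = 40)
  first <- mk_cells(sp, runif(80, 0, 100), 2)
  first$tag <- rep(c("near", "far"), 40)
  ## growth multiplies every lineage equally: duplicate every cell once
  last <- rbind(first, first)
  tr <- mk_traj(first, last, c("A", "B"))
  adv <- near_far_advantage(tr)
  expect_equal(unname(adv), c(0, 0))
  ## permuted tags across many draws average to zero
  diffs <- replicate(100, {
    f2 <- first; f2$tag <- sample(f2$tag)
    l2 <- rbind(f2, f2[sample(80, 50, replace = TRUE), ])
    mean(near_far_advantage(mk_traj(f2, l2, c("A", "B"))))
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(100) + 0.01)
  bad <- first; bad$tag <- "none"
  expect_error(near_far_advantage(mk_traj(bad, bad, c("A", "B"))),
               "tags")
})

test_that("replicate density correlation behaves at the extremes", {
  expect_equal(replicate_density_correlation(c(10, 20, 30), c(20, 40, 60)), 1)
  expect_equal(replicate_density_correlation(c(10, 20, 30), c(60, 40, 20)), -1)
  expect_warning(v <- replicate_density_correlation(c(5, 5, 5), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(v))
  expect_error(replicate_density_correlation(c(1, 2), c(3, 4)), "3 replicates")
})
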