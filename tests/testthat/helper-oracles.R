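## Independent brute-force segregation oracle: all-pairs distances in plain
## R, no spatial hashing, same definition (neighbors strictly within
## `radius`, self excluded; cells without neighbors dropped from the mean;
## s = (seg - p) / (1 - p)).
brute_force_segregation <- function(cells, radius = 10, width = NULL,
                                    cyclic = FALSE) {
  n <- nrow(cells)
  dx <- outer(cells$x, cells$x, "-")
  if (cyclic) {
    dx <- dx - width * round(dx / width)
  }
  dy <- outer(cells$y, cells$y, "-")
  near <- (dx^2 + dy^2) <= radius^2
  diag(near) <- FALSE
  same <- outer(cells$species, cells$species, "==")
  sp_levels <- sort(unique(cells$species))
  p <- vapply(sp_levels, function(lv) mean(cells$species == lv), 0)
  seg <- s <- stats::setNames(rep(NA_real_, length(sp_levels)), sp_levels)
  for (lv in sp_levels) {
    loc <- numeric(0)
    for (i in which(cells$species == lv)) {
      nd <- sum(near[i, ])
      if (nd > 0) loc <- c(loc, sum(near[i, ] & same[i, ]) / nd)
    }
    if (length(loc)) {
      seg[lv] <- mean(loc)
      s[lv] <- (seg[lv] - p[lv]) / (1 - p[lv])
    }
  }
  list(s = s, seg = seg, p = p)
}

## maximum pairwise overlap fraction, plain R
max_overlap_fraction <- function(cells, width = NULL, cyclic = FALSE) {
  dx <- outer(cells$x, cells$x, "-")
  if (cyclic) dx <- dx - width * round(dx / width)
  dy <- outer(cells$y, cells$y, "-")
  d <- sqrt(dx^2 + dy^2)
  sumr <- outer(cells$radius, cells$radius, "+")
  ov <- (sumr - d) / sumr
  diag(ov) <- -Inf
  max(ov)
}

## random cell snapshot for property tests
random_snapshot <- function(n, width = 100, height = 60, clustered = FALSE,
                            params = syn_params()) {
  if (clustered) {
    k <- sample(2:5, 1)
    cx <- runif(k, 0, width); cy <- runif(k, 0, height)
    pick <- sample(k, n, replace = TRUE)
    x <- (cx[pick] + rnorm(n, 0, 8)) %% width
    y <- pmin(pmax(cy[pick] + rnorm(n, 0, 8), 0.5), height)
  } else {
    x <- runif(n, 0, width)
    y <- runif(n, 0, height)
  }
  new_cells(sample(c("A", "B"), n, replace = TRUE), x, y,
            mass = draw_seed_mass(n, params), params = params)
}

## shared reduced-scale overrides for simulation-heavy tests
fast_overrides <- function(...) {
  c(list(dt = 0.1, save_fields = FALSE), list(...))
}

draw_seed_mass <- syntromix:::draw_seed_mass
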