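#' Local segregation of one cell
#'
#' Fraction of a focal cell's neighbors (all cells within the neighborhood
#' radius, focal excluded) that belong to the focal cell's species.
#' Undefined when the cell has no neighbors; such cells are excluded from
#' the species mean by [segregation_index()].
#'
#' @param cell Single-row cell table (needs `species`).
#' @param neighbors Cell table of all cells within the radius.
#' @return Value in `[0, 1]`, or `NA` when there are no neighbors.
#' @export
local_segregation <- function(cell, neighbors) {
  if (nrow(neighbors) == 0L) return(NA_real_)
  mean(neighbors$species == cell$species)
}

#' Neighborhood segregation index
#'
#' For each species X, `seg_X` is the mean over X cells (with at least one
#' neighbor within `radius`) of the local same-species neighbor proportion.
#' Normalising against the global species proportion `p_X` gives
#' \deqn{s_X = (seg_X - \bar p_X) / (1 - \bar p_X),}
#' the relatedness-style index: 1 for fully segregated clonal patches, 0 in
#' expectation under random labeling, negative when over-mixed beyond
#' random.
#'
#' @param cells Cell table (`species`, `x`, `y`).
#' @param radius Neighborhood radius, um (10 by default; 5 for the
#'   finer-grained variant).
#' @param width Domain width for cyclic wrap-around distances (needed when
#'   `cyclic = TRUE`).
#' @param cyclic Use minimum-image lateral distances.
#' @return A `syn_segregation` list: named vectors `s`, `seg`, `p`,
#'   `n_evaluated`, plus `radius`.
#' @export
segregation_index <- function(cells, radius = 10, width = NULL,
                              cyclic = FALSE) {
  if (nrow(cells) == 0L) stop("empty snapshot")
  if (cyclic && is.null(width)) stop("cyclic distances need the domain width")
  sp <- factor(cells$species)
  if (is.null(width)) width <- max(cells$x) + radius + 1
  cnt <- neighbor_counts_cpp(cells$x, cells$y, as.integer(sp), radius,
                             width, isTRUE(cyclic))
  p_glob <- as.numeric(table(sp)) / nrow(cells)
  names(p_glob) <- levels(sp)
  seg <- s <- stats::setNames(rep(NA_real_, nlevels(sp)), levels(sp))
  n_eval <- stats::setNames(integer(nlevels(sp)), levels(sp))
  for (lv in levels(sp)) {
    sel <- sp == lv & cnt[, 2L] > 0L
    n_eval[lv] <- sum(sel)
    if (n_eval[lv] > 0L) {
      seg[lv] <- mean(cnt[sel, 1L] / cnt[sel, 2L])
      s[lv] <- if (p_glob[lv] < 1) (seg[lv] - p_glob[lv]) / (1 - p_glob[lv])
               else NA_real_
    }
  }
  structure(list(s = s, seg = seg, p = p_glob, n_evaluated = n_eval,
                 radius = radius), class = "syn_segregation")
}

#' @exportS3Method base::print
print.syn_segregation <- function(x, ...) {
  cat("<syn_segregation> radius", x$radius, "um\n")
  print(round(rbind(s = x$s, seg = x$seg, p = x$p,
                    n = as.numeric(x$n_evaluated)), 4))
  invisible(x)
}

#' Population growth rate from cell counts
#'
#' `(N_f - N_i) / (t_f - t_i)`, the count-based growth rate in cells per
#' hour over the simulation interval.
#'
#' @param N_i,N_f Initial and final cell counts.
#' @param t_i,t_f Interval endpoints, h (`t_f > t_i`).
#' @return Growth rate, cells/h.
#' @export
growth_rate <- function(N_i, N_f, t_i = 0, t_f = 96) {
  if (any(t_f <= t_i)) stop("invalid interval: t_f must exceed t_i")
  (N_f - N_i) / (t_f - t_i)
}

#' Log relative growth in coculture versus monoculture
#'
#' `log(X_co / X_mono)`; for an obligate cross-feeder (which cannot grow in
#' monoculture) the convention is `log(X_co)`. Positive values indicate a
#' net gain from association, negative a net loss. A coculture rate of zero
#' returns `-Inf` as an explicit sentinel.
#'
#' @param X_co,X_mono Growth rates (cells/h) in coculture and monoculture.
#' @param obligate Use the obligate convention (ignore `X_mono`).
#' @return Log effect (may be `-Inf`).
#' @export
relative_growth <- function(X_co, X_mono = NULL, obligate = FALSE) {
  if (X_co < 0) stop("negative coculture growth rate")
  if (obligate) return(log(X_co))
  if (is.null(X_mono) || X_mono <= 0)
    stop("degenerate monoculture baseline (X_mono must be > 0 unless obligate)")
  log(X_co / X_mono)
}

#' Classify the ecological interaction from per-species effects
#'
#' Signs of the two log relative-growth effects decide the label: both
#' positive = mutualism, both negative = competition, opposite =
#' exploitation naming the beneficiary. `eps` guards the knife edge where
#' both effects are indistinguishable from zero ("neutral"); when only one
#' effect lies inside the band the raw signs decide, which keeps the
#' classification symmetric under exchanging the species.
#'
#' @param effect_A,effect_B Log relative growth of producer and
#'   cross-feeder (finite or `-Inf`).
#' @param eps Half-width of the neutral band on the log scale.
#' @return A `syn_interaction` list: `label` in `{mutualism,
#'   exploitation_A_of_B, exploitation_B_of_A, competition, neutral}`,
#'   plus the two effects.
#' @export
classify_interaction <- function(effect_A, effect_B, eps = 0.02) {
  if (is.na(effect_A) || is.na(effect_B)) stop("effects must not be NA")
  label <- if (abs(effect_A) <= eps && abs(effect_B) <= eps) {
    "neutral"
  } else if (effect_A >= 0 && effect_B >= 0) {
    "mutualism"
  } else if (effect_A < 0 && effect_B < 0) {
    "competition"
  } else if (effect_A >= 0) {
    "exploitation_A_of_B"
  } else {
    "exploitation_B_of_A"
  }
  structure(list(label = label, effect_A = effect_A, effect_B = effect_B,
                 eps = eps), class = "syn_interaction")
}

#' @exportS3Method base::print
print.syn_interaction <- function(x, ...) {
  cat(sprintf("<syn_interaction> %s (effect_A = %.3f, effect_B = %.3f)\n",
              x$label, x$effect_A, x$effect_B))
  invisible(x)
}

## ordering used for "shift toward less negative outcomes" comparisons
interaction_rank <- function(label) {
  c(competition = 0, exploitation_A_of_B = 1, exploitation_B_of_A = 1,
    neutral = 1.5, mutualism = 2)[[label]]
}

#' Community productivity gain of coculture over summed monocultures
#'
#' `(A_co + B_co) - (A_mono + B_mono)` in cells/h; positive = community
#' gain, negative = loss.
#'
#' @param A_co,B_co,A_mono,B_mono Growth rates, cells/h.
#' @return Productivity difference, cells/h.
#' @export
productivity_gain <- function(A_co, B_co, A_mono, B_mono) {
  stopifnot(is.finite(A_co), is.finite(B_co), is.finite(A_mono),
            is.finite(B_mono))
  (A_co + B_co) - (A_mono + B_mono)
}

#' Producer frequency over time
#'
#' Time series of `N_A / (N_A + N_B)` along a trajectory, where species A is
#' the scenario's producer.
#'
#' @param traj A `syn_trajectory`.
#' @return Data frame with `time_h` and `producer_fraction`.
#' @export
producer_fraction <- function(traj) {
  prod <- traj$scenario$producer
  if (!prod %in% colnames(traj$counts))
    stop("trajectory has no producer species '", prod, "'")
  tot <- rowSums(traj$counts)
  if (any(tot == 0)) stop("both species extinct; fraction undefined")
  data.frame(time_h = traj$times,
             producer_fraction = traj$counts[, prod] / tot)
}

#' Growth-rate advantage of proximity to the partner species
#'
#' For a two-microcolony run with near/far half tagging, computes per
#' species the count growth rate of the colony half seeded nearer the
#' heterospecific colony minus that of the far half. Positive values mean
#' cells profit from partner proximity.
#'
#' @param traj A `syn_trajectory` whose inoculum used `halves_tagging`.
#' @return Named numeric vector (one entry per species), cells/h.
#' @export
near_far_advantage <- function(traj) {
  first <- traj$snapshots[[1L]]$cells
  last <- traj$snapshots[[length(traj$snapshots)]]$cells
  if (!all(c("near", "far") %in% first$tag))
    stop("trajectory lacks near/far lineage tags")
  t_i <- traj$times[1L]
  t_f <- traj$times[length(traj$times)]
  sp_names <- names(traj$scenario$species)
  out <- stats::setNames(numeric(length(sp_names)), sp_names)
  for (nm in sp_names) {
    gr <- vapply(c("near", "far"), function(tg) {
      growth_rate(sum(first$species == nm & first$tag == tg),
                  sum(last$species == nm & last$tag == tg), t_i, t_f)
    }, 0)
    out[nm] <- gr["near"] - gr["far"]
  }
  out
}

#' Correlation of final species densities across replicates
#'
#' Pearson correlation between final producer and cross-feeder cell counts
#' over replicate seeds. Positive correlations are the demographic
#' signature of mutual interdependence (a windfall for one lineage feeds
#' its partner); negative correlations indicate competitive coupling.
#'
#' @param N_A,N_B Final counts per replicate (length >= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
replicate_density_correlation <- function(N_A, N_B) {
  if (length(N_A) != length(N_B) || length(N_A) < 3L)
    stop("need matched counts from at least 3 replicates")
  if (stats::sd(N_A) == 0 || stats::sd(N_B) == 0) {
    warning("zero variance across replicates; correlation undefined")
    return(NA_real_)
  }
  stats::cor(N_A, N_B)
}
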