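#' Gridded solute field
#'
#' A solute lives on a uniform 2D grid of `ny` rows (y, row 1 at the
#' substratum) by `nx` columns (x), with voxel edge `grid_h` um. The field
#' carries its diffusivity, its constant bulk concentration (imposed above
#' the boundary layer), its lateral boundary mode, and a dimensionless
#' diffusion multiplier (the effective diffusivity is `D * mult`).
#'
#' @param name Field name (`"R"`, `"E"`, or variants such as `"R_A"`).
#' @param nx,ny Grid size in voxels.
#' @param grid_h Voxel edge, um.
#' @param D Diffusivity, um^2/h.
#' @param bulk Bulk concentration, g/L (0 for by-products).
#' @param lateral One of `"cyclic"`, `"zero-flux"`, `"permeable"`.
#' @param mult Multiplier applied to `D`.
#' @param conc Optional initial concentration matrix (`ny x nx`); defaults
#'   to the bulk value everywhere.
#' @return An object of class `syn_field`.
#' @export
solute_field <- function(name, nx, ny, grid_h = 4, D = 4e4, bulk = 0,
                         lateral = "cyclic", mult = 1, conc = NULL) {
  lateral <- match.arg(lateral, c("cyclic", "zero-flux", "permeable"))
  if (bulk < 0) stop("bulk concentration must be non-negative")
  if (D <= 0 || mult <= 0) stop("diffusivity must be positive")
  if (is.null(conc)) conc <- matrix(bulk, ny, nx)
  stopifnot(nrow(conc) == ny, ncol(conc) == nx)
  structure(list(name = name, conc = conc, nx = nx, ny = ny,
                 grid_h = grid_h, D = D, bulk = bulk, lateral = lateral,
                 mult = mult),
            class = "syn_field")
}

#' Boundary specification
#'
#' Top: the bulk concentration is imposed on every voxel above the biofilm
#' front plus a still boundary layer. Bottom: zero flux (inert substratum).
#' Lateral: per-field mode, stored on each [solute_field()].
#'
#' @param boundary_layer Thickness of the boundary layer above the biofilm
#'   front, um. Must be at least one voxel.
#' @param front_height Height of the biofilm front, um (0 for a bare
#'   substratum); may be updated per call to [steady_state_solve()].
#' @return An object of class `syn_boundary`.
#' @export
boundary_spec <- function(boundary_layer = 40, front_height = 0) {
  structure(list(boundary_layer = boundary_layer,
                 front_height = front_height),
            class = "syn_boundary")
}

## number of "active" rows solved for: everything up to front + boundary
## layer; rows above are pinned at bulk.
active_rows <- function(field, bc) {
  if (bc$boundary_layer < field$grid_h)
    stop("boundary-layer thickness must be at least the grid resolution")
  nr <- ceiling((bc$front_height + bc$boundary_layer) / field$grid_h)
  max(1L, min(field$ny, as.integer(nr)))
}

#' Fill ghost and pinned boundary values of a field
#'
#' Returns the concentration matrix padded with one ghost ring, with rows
#' above the active region pinned at the bulk value and ghosts set by the
#' boundary modes. Dirichlet ghosts are face-centred (`2*bulk - conc`), so
#' the interpolated face value equals the bulk exactly; zero-flux ghosts
#' mirror the interior; cyclic ghosts wrap.
#'
#' @param field A [solute_field()].
#' @param bc A [boundary_spec()].
#' @return A `(ny+2) x (nx+2)` matrix; entry `[i+1, j+1]` corresponds to
#'   voxel `[i, j]`.
#' @export
apply_boundary <- function(field, bc, front_height = NULL) {
  if (!is.null(front_height)) bc$front_height <- front_height
  if (bc$front_height > field$ny * field$grid_h)
    stop("biofilm front lies outside the domain")
  nr <- active_rows(field, bc)
  conc <- field$conc
  if (nr < field$ny) conc[(nr + 1L):field$ny, ] <- field$bulk
  ny <- field$ny; nx <- field$nx
  g <- matrix(NA_real_, ny + 2L, nx + 2L)
  g[2:(ny + 1L), 2:(nx + 1L)] <- conc
  ## bottom: zero flux (mirror); top: bulk Dirichlet at the face
  g[1L, 2:(nx + 1L)] <- conc[1L, ]
  g[ny + 2L, 2:(nx + 1L)] <- 2 * field$bulk - conc[ny, ]
  ## lateral
  switch(field$lateral,
    "cyclic" = {
      g[2:(ny + 1L), 1L] <- conc[, nx]
      g[2:(ny + 1L), nx + 2L] <- conc[, 1L]
    },
    "zero-flux" = {
      g[2:(ny + 1L), 1L] <- conc[, 1L]
      g[2:(ny + 1L), nx + 2L] <- conc[, nx]
    },
    "permeable" = {
      g[2:(ny + 1L), 1L] <- 2 * field$bulk - conc[, 1L]
      g[2:(ny + 1L), nx + 2L] <- 2 * field$bulk - conc[, nx]
    },
    stop("unknown lateral boundary mode '", field$lateral, "'")
  )
  ## corners unused by the 5-point stencil
  g
}

## ---- sparse Laplacian assembly (cached) -------------------------------

.lap_cache <- new.env(parent = emptyenv())

## Positive-definite form: M0 s = b_unit * bulk + p  with M0 = -(D/h^2) L.
## b_unit marks Dirichlet faces (value 2c per face, times bulk).
build_laplacian <- function(nr, nx, lateral, c_coef, top_dirichlet = TRUE) {
  key <- paste(nr, nx, lateral, signif(c_coef, 12), top_dirichlet, sep = "|")
  hit <- .lap_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nr * nx
  idx <- function(row, col) (col - 1L) * nr + row
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  b_unit <- numeric(n)
  rows <- rep.int(seq_len(nr), nx)
  cols <- rep(seq_len(nx), each = nr)
  ids <- seq_len(n)
  ## vertical links (build vectorised: link each voxel to the one above)
  up_ok <- rows < nr
  i_up <- ids[up_ok]; j_up <- idx(rows[up_ok] + 1L, cols[up_ok])
  ii <- c(ii, i_up, j_up); jj <- c(jj, j_up, i_up)
  xx <- c(xx, rep.int(-c_coef, 2L * length(i_up)))
  tab <- tabulate(c(i_up, j_up), nbins = n)
  diag_acc <- diag_acc + c_coef * tab
  ## top Dirichlet face
  if (top_dirichlet) {
    top <- ids[rows == nr]
    diag_acc[top] <- diag_acc[top] + 2 * c_coef
    b_unit[top] <- b_unit[top] + 2 * c_coef
  }
  ## horizontal links
  if (nx > 1L) {
    right_ok <- cols < nx
    i_r <- ids[right_ok]; j_r <- idx(rows[right_ok], cols[right_ok] + 1L)
    ii <- c(ii, i_r, j_r); jj <- c(jj, j_r, i_r)
    xx <- c(xx, rep.int(-c_coef, 2L * length(i_r)))
    diag_acc <- diag_acc + c_coef * tabulate(c(i_r, j_r), nbins = n)
    if (lateral == "cyclic" && nx > 2L) {
      i_w <- idx(seq_len(nr), 1L); j_w <- idx(seq_len(nr), nx)
      ii <- c(ii, i_w, j_w); jj <- c(jj, j_w, i_w)
      xx <- c(xx, rep.int(-c_coef, 2L * nr))
      diag_acc <- diag_acc + c_coef * tabulate(c(i_w, j_w), nbins = n)
    } else if (lateral == "permeable") {
      edge <- c(idx(seq_len(nr), 1L), idx(seq_len(nr), nx))
      diag_acc[edge] <- diag_acc[edge] + 2 * c_coef
      b_unit[edge] <- b_unit[edge] + 2 * c_coef
    }
    ## zero-flux: mirrored ghost contributes nothing
  }
  M0 <- Matrix::sparseMatrix(i = c(ii, ids), j = c(jj, ids),
                             x = c(xx, diag_acc), dims = c(n, n))
  M0 <- methods::as(Matrix::forceSymmetric(M0), "CsparseMatrix")
  ## positions of the diagonal in the CSC value slot (per column, for fast
  ## in-place k updates) and a cached symbolic Cholesky analysis
  pslot <- M0@p; islot <- M0@i
  dpos <- integer(n)
  for (j in seq_len(n)) {
    rng <- (pslot[j] + 1L):pslot[j + 1L]
    dpos[j] <- rng[islot[rng] == j - 1L]
  }
  chol_sym <- Matrix::Cholesky(M0, LDL = FALSE)
  out <- list(M0 = M0, b_unit = b_unit, dpos = dpos, chol_sym = chol_sym)
  .lap_cache[[key]] <- out
  out
}

## ---- quasi-steady-state reaction-diffusion solve ----------------------

#' Solve the quasi-steady reaction--diffusion system
#'
#' Solves `D lap(S) + r(S) = 0` for every field, under the boundary
#' conditions of [boundary_spec()] and each field's lateral mode. Reaction
#' rates are relinearised around the current iterate (Picard iteration with
#' damping); each linear step is an exact sparse solve. Because solute
#' transport is much faster than growth, the fields are assumed to
#' equilibrate within every biological timestep.
#'
#' @param fields Named list of [solute_field()] objects.
#' @param sources Either a function `f(fields)` returning a named list of
#'   net-rate matrices (g/L/h), or a linearised source function returning
#'   `list(k = ..., p = ...)` with per-field first-order uptake coefficients
#'   `k` (1/h) and productions `p` (g/L/h). Pass `NULL` for pure diffusion.
#' @param bc A [boundary_spec()].
#' @param tol Relative residual tolerance.
#' @param max_iter Maximum Picard iterations; non-convergence is an error
#'   carrying the last residual.
#' @param damp Damping factor applied once the Picard residual stops
#'   shrinking monotonically (full steps are taken while it does).
#' @return The updated field list, with a `diagnostics` attribute holding
#'   iterations, per-field relative residuals, and the boundary-flux /
#'   net-consumption balance (both in g/h).
#' @export
steady_state_solve <- function(fields, sources = NULL, bc = boundary_spec(),
                               tol = 1e-6, max_iter = 200, damp = 0.7) {
  for (f in fields) if (f$bulk < 0) stop("negative bulk concentration")
  nx <- fields[[1L]]$nx
  h <- fields[[1L]]$grid_h
  nr <- active_rows(fields[[1L]], bc)
  n <- nr * nx
  fnames <- names(fields)
  src_fun <- normalize_sources(sources, fields)

  ## pin rows above the active region at bulk
  for (nm in fnames) {
    f <- fields[[nm]]
    if (nr < f$ny) fields[[nm]]$conc[(nr + 1L):f$ny, ] <- f$bulk
  }
  lap <- lapply(fields, function(f)
    build_laplacian(nr, nx, f$lateral, f$D * f$mult / h^2))

  rel_res <- stats::setNames(rep(Inf, length(fields)), fnames)
  iter <- 0L
  clip_max <- 0
  prev_worst <- Inf
  cur_damp <- 1   # full Picard steps while the residual is shrinking;
                  # fall back to `damp` if it ever grows (stiff coupling)
  repeat {
    iter <- iter + 1L
    ## Gauss-Seidel over fields: each solve sees the others' fresh values
    for (nm in fnames) {
      if (rel_res[nm] < tol) next   # field already converged
      src <- src_fun(fields)
      f <- fields[[nm]]
      kv <- as.vector(src$k[[nm]][seq_len(nr), , drop = FALSE])
      pv <- as.vector(src$p[[nm]][seq_len(nr), , drop = FALSE])
      M <- lap[[nm]]$M0
      M@x[lap[[nm]]$dpos] <- M@x[lap[[nm]]$dpos] + kv
      rhs <- lap[[nm]]$b_unit * f$bulk + pv
      s_old <- as.vector(f$conc[seq_len(nr), , drop = FALSE])
      ch <- Matrix::update(lap[[nm]]$chol_sym, M)
      s_new <- as.vector(Matrix::solve(ch, rhs, system = "A"))
      s_new <- cur_damp * s_new + (1 - cur_damp) * s_old
      neg <- s_new < 0
      if (any(neg)) {
        clip_max <- max(clip_max, -min(s_new))
        s_new[neg] <- 0
      }
      fields[[nm]]$conc[seq_len(nr), ] <- s_new
    }
    ## true nonlinear residual at the updated concentrations
    src <- src_fun(fields)
    for (nm in fnames) {
      f <- fields[[nm]]
      kv <- as.vector(src$k[[nm]][seq_len(nr), , drop = FALSE])
      pv <- as.vector(src$p[[nm]][seq_len(nr), , drop = FALSE])
      s <- as.vector(f$conc[seq_len(nr), , drop = FALSE])
      resid <- lap[[nm]]$b_unit * f$bulk + pv -
        as.vector(lap[[nm]]$M0 %*% s) - kv * s
      scale <- sqrt(sum((abs(pv) + kv * s)^2))
      rel_res[nm] <- sqrt(sum(resid^2)) / max(scale, 1e-15)
      if (scale < 1e-15) rel_res[nm] <- sqrt(mean(resid^2)) /
        (f$D * f$mult / h^2 * max(f$bulk, 1))
    }
    if (all(rel_res < tol)) break
    worst <- max(rel_res)
    if (worst > 1.5 * prev_worst) cur_damp <- damp
    prev_worst <- worst
    if (iter >= max_iter)
      stop(sprintf(
        "steady_state_solve: no convergence after %d iterations (residual %.3g)",
        iter, max(rel_res)))
  }

  ## diagnostics: boundary influx vs net consumption (g/h)
  vox_L <- h^3 * 1e-15
  bal <- lapply(fnames, function(nm) {
    f <- fields[[nm]]
    s <- as.vector(f$conc[seq_len(nr), , drop = FALSE])
    src_k <- as.vector(src$k[[nm]][seq_len(nr), , drop = FALSE])
    src_p <- as.vector(src$p[[nm]][seq_len(nr), , drop = FALSE])
    influx <- sum(lap[[nm]]$b_unit * f$bulk - (lap[[nm]]$M0 %*% s)) * vox_L
    consumption <- sum(src_k * s - src_p) * vox_L
    c(influx = influx, consumption = consumption)
  })
  names(bal) <- fnames
  attr(fields, "diagnostics") <- list(iterations = iter, rel_res = rel_res,
                                      flux_balance = bal, n_active_rows = nr,
                                      max_clipped = clip_max)
  fields
}

## Accept either a plain net-rate function or a (k, p) linearised source.
normalize_sources <- function(sources, fields) {
  zero <- lapply(fields, function(f) matrix(0, f$ny, f$nx))
  if (is.null(sources)) {
    return(function(fields) list(k = zero, p = zero))
  }
  probe <- sources(fields)
  if (is.list(probe) && all(c("k", "p") %in% names(probe))) return(sources)
  function(fields) {
    r <- sources(fields)
    p <- zero
    for (nm in names(r)) p[[nm]] <- r[[nm]]
    list(k = zero, p = p)
  }
}
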