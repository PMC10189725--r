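#' Grid and time-stepping specification for the diffusion simulator
#'
#' Controls the finite-volume discretisation used by [simulate_uptake()] and
#' [simulate_1d()]. The radial grid is densest (`h_min`) at the disk edge
#' R = 1, where the flux is singular, and expands geometrically (factor
#' `r_expansion`) toward the axis and the outer truncation radius `r_max`.
#' The depth grid is uniform with `n_z` layers when that already resolves the
#' earliest reported time, and otherwise expands geometrically from the
#' contact face. Time is marched on a log-spaced schedule with
#' `steps_per_decade` steps, beginning `pad_decades` decades before the first
#' reported time so that start-up error has decayed by the first output.
#'
#' @param t_start,t_end First and last reported dimensionless times.
#' @param steps_per_decade Implicit steps per decade of dimensionless time.
#' @param n_z Minimum number of node layers across the cuticle (>= 8).
#' @param r_expansion Geometric expansion factor for radial spacing (<= 1.25).
#' @param h_min Smallest radial spacing, at the disk edge; default
#'   `min(z_ratio / 4, 1e-3)`, resolved when the grid is built.
#' @param r_max Outer radial truncation; default `1 + 6 * sqrt(t_end)`, far
#'   enough that the diffusion front cannot reach it.
#' @param dz0 First depth spacing at the contact face; default
#'   `min(z_ratio / (n_z - 1), 0.4 * sqrt(t_start))`.
#' @param z_expansion Geometric expansion factor for depth spacing when the
#'   depth grid is non-uniform; defaults to `r_expansion`.
#' @param pad_decades Decades of burn-in time simulated before `t_start`.
#' @param dt_cap Optional absolute cap on the time step. Log-spaced steps
#'   track power-law transients well but not a nearly-pure exponential decay
#'   (the plane-sheet tail), where the step must stay small against the
#'   decay time; [simulate_1d()] sets this automatically.
#' @param stepping `"bdf2"` (default; variable-step second-order backward
#'   differentiation, started with backward Euler) or `"be"` (backward
#'   Euler throughout). Both are backward-implicit and unconditionally
#'   stable.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(t_start = 1e-4, t_end = 10)
#' @export
grid_spec <- function(t_start = 1e-6, t_end = 10, steps_per_decade = 60,
                      n_z = 12, r_expansion = 1.15, h_min = NULL,
                      r_max = NULL, dz0 = NULL, z_expansion = NULL,
                      pad_decades = 2, stepping = c("bdf2", "be"),
                      dt_cap = NULL) {
  stepping <- match.arg(stepping)
  if (!is.finite(t_start) || t_start <= 0 || !is.finite(t_end) || t_end <= t_start)
    abort("need 0 < t_start < t_end.")
  if (n_z < 8) abort("`n_z` must be at least 8.")
  if (!(r_expansion > 1 && r_expansion <= 1.25))
    abort("`r_expansion` must lie in (1, 1.25].")
  if (!is.null(r_max) && r_max < 1 + 6 * sqrt(t_end))
    abort("`r_max` must be at least 1 + 6*sqrt(t_end) so the front never reaches it.")
  if (steps_per_decade < 10) abort("`steps_per_decade` must be at least 10.")
  structure(
    list(t_start = t_start, t_end = t_end, steps_per_decade = steps_per_decade,
         n_z = n_z, r_expansion = r_expansion, h_min = h_min, r_max = r_max,
         dz0 = dz0, z_expansion = z_expansion %||% r_expansion,
         pad_decades = pad_decades, stepping = stepping, dt_cap = dt_cap),
    class = "grid_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# geometric 1-D node ladder from `from` toward `to`, first spacing h0,
# growth factor f, spacing capped at h_cap; end snapped onto `to`
geom_ladder <- function(from, to, h0, f, h_cap = Inf) {
  out <- from
  h <- h0
  dir <- sign(to - from)
  repeat {
    nxt <- out[length(out)] + dir * h
    if (dir * (to - nxt) < h) nxt <- to
    out <- c(out, nxt)
    if (nxt == to) break
    h <- min(h * f, h_cap)
  }
  out
}

#' Build the axisymmetric finite-volume grid
#'
#' Constructs the (R, Z) tensor-product node set and the sparse
#' finite-volume Laplacian for the dimensionless cuticle slab. Radial nodes
#' sit exactly at R = 0 and R = 1; spacing is `h_min` at the disk edge and
#' expands geometrically away from it. Cell faces are at node midpoints, so
#' the discrete operator conserves mass exactly; the axisymmetric volume
#' element 2*pi*R is absorbed into the cell volumes.
#'
#' @param z_ratio Dimensionless cuticle thickness, or a [disk_geometry()].
#' @param spec A [grid_spec()].
#' @return An object of class `fv_grid`: node coordinates, cell volumes, the
#'   finite-volume Laplacian (`L_full`), its copy with saturated-disk rows
#'   blanked (`L_bc`), and the Dirichlet (saturated disk) node index.
#' @examples
#' g <- build_grid(0.01, grid_spec(t_start = 1e-5, t_end = 1e-2))
#' range(g$r); length(g$z)
#' @export
build_grid <- function(z_ratio, spec = grid_spec()) {
  z_ratio <- as_z_ratio(z_ratio)
  stopifnot(inherits(spec, "grid_spec"))
  h_min <- spec$h_min %||% min(z_ratio / 4, 1e-3)
  if (h_min > min(z_ratio / 4, 1e-3) + 1e-15)
    abort("`h_min` must be <= min(z_ratio/4, 1e-3) to resolve the disk-edge singularity.")
  r_max <- spec$r_max %||% (1 + 6 * sqrt(spec$t_end))
  h_cap <- max(0.25, (r_max - 1) / 50)

  # radial nodes: dense at R = 1, expanding toward 0 and r_max
  left <- geom_ladder(1, 0, h_min, spec$r_expansion, h_cap)
  right <- geom_ladder(1, r_max, h_min, spec$r_expansion, h_cap)
  r <- c(rev(left[-1]), right)

  # depth nodes: uniform when n_z layers already resolve sqrt(t_start)
  t0 <- spec$t_start * 10^(-spec$pad_decades)
  dz0 <- spec$dz0 %||% min(z_ratio / (spec$n_z - 1), 0.4 * sqrt(spec$t_start))
  if (z_ratio / (spec$n_z - 1) <= dz0 * (1 + 1e-12)) {
    z <- seq(0, z_ratio, length.out = spec$n_z)
  } else {
    z <- geom_ladder(0, z_ratio, dz0, spec$z_expansion, z_ratio / 4)
    if (length(z) < spec$n_z) z <- seq(0, z_ratio, length.out = spec$n_z)
  }

  nr <- length(r); nz <- length(z)
  if (nr * nz > 5e5) abort("grid would exceed 5e5 nodes; coarsen the grid specification.")

  # faces at midpoints; boundary faces on the domain boundary
  rf <- c(0, (r[-nr] + r[-1]) / 2, r_max)          # nr + 1 face radii
  zf <- c(0, (z[-nz] + z[-1]) / 2, z_ratio)        # nz + 1 face depths
  area_r <- (rf[-1]^2 - rf[-(nr + 1)]^2) / 2       # int R dR over the cell
  dzc <- diff(zf)

  w <- as.vector(outer(area_r, dzc))               # cell volumes / (2 pi)
  idx <- function(i, j) i + (j - 1L) * nr

  # triplets for the FV graph Laplacian (positive diagonal)
  ii <- jj <- xx <- vector("list", 4L)
  # radial faces between (i, i+1) for every layer j
  i1 <- rep(seq_len(nr - 1), nz); j1 <- rep(seq_len(nz), each = nr - 1)
  g_r <- rep(rf[2:nr], nz) * rep(dzc, each = nr - 1) / rep(diff(r), nz)
  kA <- idx(i1, j1); kB <- idx(i1 + 1L, j1)
  # depth faces between (j, j+1) for every radius i
  i2 <- rep(seq_len(nr), nz - 1); j2 <- rep(seq_len(nz - 1), each = nr)
  g_z <- rep(area_r, nz - 1) / rep(diff(z), each = nr)
  kC <- idx(i2, j2); kD <- idx(i2, j2 + 1L)

  ia <- c(kA, kB, kA, kB, kC, kD, kC, kD)
  ja <- c(kA, kB, kB, kA, kC, kD, kD, kC)
  xa <- c(g_r, g_r, -g_r, -g_r, g_z, g_z, -g_z, -g_z)
  L_full <- Matrix::sparseMatrix(i = ia, j = ja, x = xa, dims = c(nr * nz, nr * nz))

  disk_r <- which(r <= 1 + 1e-12)
  dir_idx <- idx(disk_r, 1L)
  L_bc <- L_full
  L_bc[dir_idx, ] <- 0

  structure(
    list(r = r, z = z, rf = rf, zf = zf, area_r = area_r, dzc = dzc,
         w = w, L_full = L_full, L_bc = L_bc, dir_idx = dir_idx,
         nr = nr, nz = nz, z_ratio = z_ratio, r_max = r_max,
         h_min = h_min, t0_internal = t0, spec = spec),
    class = "fv_grid"
  )
}

#' One backward-Euler diffusion step
#'
#' Advances the dimensionless concentration field by one backward-Euler step
#' of length `dT`: solves `(W/dT + L) C_new = (W/dT) C_old` with the
#' saturated-disk nodes held at C = 1, where `L` is the axisymmetric
#' finite-volume Laplacian of the grid. The linear system is solved by
#' sparse LU factorisation; the solution residual is verified against a
#' 1e-10 relative tolerance.
#'
#' @param field Concentration values: an `nr x nz` matrix (or vector of
#'   length `nr * nz`) on the grid's nodes, in `[0, 1]`.
#' @param dT Positive dimensionless time increment.
#' @param grid An [build_grid()] result.
#' @return The new field, in the same shape as the input.
#' @examples
#' g <- build_grid(0.5, grid_spec(t_start = 1e-4, t_end = 1, n_z = 8))
#' C1 <- step_implicit(matrix(0, g$nr, g$nz), 1e-4, g)
#' range(C1)
#' @export
step_implicit <- function(field, dT, grid) {
  stopifnot(inherits(grid, "fv_grid"))
  if (!is.finite(dT) || dT <= 0) abort("`dT` must be positive.")
  was_matrix <- is.matrix(field)
  C <- as.numeric(field)
  if (length(C) != grid$nr * grid$nz) abort("`field` has the wrong size for this grid.")
  dvec <- grid$w / dT
  rhs <- dvec * C
  dvec[grid$dir_idx] <- 1
  rhs[grid$dir_idx] <- 1
  A <- Matrix::Diagonal(x = dvec) + grid$L_bc
  Cn <- as.numeric(Matrix::solve(A, rhs))
  res <- sqrt(sum((A %*% Cn - rhs)^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (res > 1e-10)
    abort(sprintf("implicit solve did not meet the residual contract (relative residual %.2e).", res))
  if (was_matrix) matrix(Cn, grid$nr, grid$nz) else Cn
}

# march the implicit scheme over a log time schedule.
# The marched variable is the saturation deficit D = 1 - C (Dirichlet 0 on
# the disk, initial value 1): once the slab nears saturation C sits within
# ~1e-12 of 1 and boundary fluxes formed from C differences lose all
# significant digits, while the deficit retains full relative precision.
# W: cell volumes; L_bc/L_full: operator with/without Dirichlet rows blanked;
# dir: Dirichlet index; returns M(T) and instantaneous boundary flux (both
# without the angular factor; caller applies 2*pi or pi).
march_implicit <- function(W, L_bc, L_full, dir, Ts, stepping = "bdf2") {
  n <- length(W)
  D_prev2 <- NULL
  D_prev <- rep(1, n)
  Tprev <- 0
  M <- flux <- numeric(length(Ts))
  for (k in seq_along(Ts)) {
    dT <- Ts[k] - Tprev
    use_bdf2 <- stepping == "bdf2" && k > 2
    if (use_bdf2) {
      rho <- dT / (Tprev - Ts[k - 2])
      coef <- (1 + 2 * rho) / (1 + rho)
      dvec <- coef * W / dT
      rhs <- (W / dT) * ((1 + rho) * D_prev - rho^2 / (1 + rho) * D_prev2)
    } else {
      dvec <- W / dT
      rhs <- dvec * D_prev
    }
    dvec[dir] <- 1
    rhs[dir] <- 0
    A <- Matrix::Diagonal(x = dvec) + L_bc
    Dn <- as.numeric(Matrix::solve(A, rhs))
    M[k] <- sum(W * (1 - Dn))
    lc <- as.numeric(L_full %*% Dn)
    flux[k] <- -sum(lc[dir])         # influx through the saturated boundary
    D_prev2 <- D_prev
    D_prev <- Dn
    Tprev <- Ts[k]
  }
  list(M = M, flux = flux, C = 1 - D_prev)
}

log_schedule <- function(t0, t1, steps_per_decade, dt_cap = NULL) {
  n <- max(2L, ceiling(steps_per_decade * log10(t1 / t0)) + 1L)
  Ts <- exp(seq(log(t0), log(t1), length.out = n))
  if (!is.null(dt_cap)) {
    # subdivide any interval whose step exceeds the cap
    Ts <- c(Ts[1], unlist(lapply(seq_len(n - 1L), function(k) {
      d <- Ts[k + 1] - Ts[k]
      if (d <= dt_cap) return(Ts[k + 1])
      seq(Ts[k], Ts[k + 1], length.out = ceiling(d / dt_cap) + 1L)[-1]
    })))
  }
  Ts
}

finish_curve <- function(Ts, M, flux, angular, keep, z_ratio, spec, mode) {
  M <- angular * M
  rate <- angular * flux
  # mass balance: M(T) against cumulative boundary influx (trapezoid),
  # offset by the mass already present at the first internal step
  cumflux <- M[1] + c(0, cumsum(diff(Ts) * (rate[-1] + rate[-length(rate)]) / 2))
  bal <- abs(cumflux[keep] - M[keep]) / pmax(M[keep], .Machine$double.xmin)
  if (max(bal) > 0.01)
    abort(sprintf("mass balance violated: max |cum flux - M|/M = %.3g (> 1%%).", max(bal)))
  # secondary rate: central difference of M on the log time grid
  lt <- log(Ts)
  rate_m <- rate
  ik <- 2:(length(Ts) - 1)
  rate_m[ik] <- (M[ik + 1] - M[ik - 1]) / (Ts[ik + 1] - Ts[ik - 1])
  out <- tibble(T = Ts[keep], M = M[keep], rate = rate[keep], rate_m = rate_m[keep])
  structure(out,
            class = c("dimless_curve", class(out)),
            z_ratio = z_ratio, mode = mode, spec = spec,
            mass_balance = max(bal))
}

#' Simulate the dimensionless uptake curve
#'
#' Solves the dimensionless axisymmetric diffusion problem in a cuticle slab
#' of thickness `z_ratio`: a saturated unit disk (C = 1) on the contact face,
#' zero flux on the rest of that face, on the back face (wax-reservoir
#' condition), at the outer radius and at the axis, starting from C = 0.
#' Returns the cumulative dimensionless mass `M(T)` and the uptake rate
#' `dM/dT`.
#'
#' The rate reported in `rate` is the instantaneous finite-volume flux
#' through the saturated boundary (smoother than differentiating `M`); a
#' central-difference rate `rate_m` is retained as a cross-check, and the
#' run aborts if cumulative influx and `M` disagree by more than 1 % at any
#' reported time.
#'
#' @inheritParams build_grid
#' @return A `dimless_curve` tibble with columns `T`, `M`, `rate`, `rate_m`,
#'   and attributes `z_ratio`, `mode`, `mass_balance`.
#' @examples
#' \donttest{
#' crv <- simulate_uptake(0.1, grid_spec(t_start = 1e-4, t_end = 1e-2))
#' head(crv)
#' }
#' @export
simulate_uptake <- function(z_ratio, spec = grid_spec()) {
  grid <- build_grid(z_ratio, spec)
  Ts <- log_schedule(grid$t0_internal, spec$t_end, spec$steps_per_decade, spec$dt_cap)
  res <- march_implicit(grid$w, grid$L_bc, grid$L_full, grid$dir_idx, Ts, spec$stepping)
  keep <- Ts >= spec$t_start * (1 - 1e-9)
  finish_curve(Ts, res$M, res$flux, 2 * pi, keep, grid$z_ratio, spec, mode = "2d")
}

#' Simulate the one-dimensional (plane-sheet) uptake curve
#'
#' Same problem as [simulate_uptake()] but with the saturated boundary
#' covering the entire contact face and no radial transport: the
#' finite-volume analogue of the Crank plane-sheet problem, used as the
#' numerical oracle for [crank_rate()]. Mass and rate are per disk contact
#' (multiplied by `A_d = pi`), so the curve is directly comparable with the
#' 2-D simulator and the analytic series.
#'
#' @inheritParams build_grid
#' @return A `dimless_curve` tibble; `M` tends to `pi * z_ratio` (the
#'   saturated slab below the disk) at long times.
#' @examples
#' \donttest{
#' z <- 0.05
#' crv <- simulate_1d(z, grid_spec(t_start = z^2 / 100, t_end = 10 * z^2))
#' }
#' @export
simulate_1d <- function(z_ratio, spec = grid_spec()) {
  z_ratio <- as_z_ratio(z_ratio)
  t0 <- spec$t_start * 10^(-spec$pad_decades)
  dz0 <- spec$dz0 %||% min(z_ratio / 149, 0.4 * sqrt(spec$t_start))
  if (z_ratio / 149 <= dz0 * (1 + 1e-12)) {
    z <- seq(0, z_ratio, length.out = 150)
  } else {
    z <- geom_ladder(0, z_ratio, dz0, min(spec$z_expansion, 1.08), z_ratio / 50)
  }
  nz <- length(z)
  zf <- c(0, (z[-nz] + z[-1]) / 2, z_ratio)
  w <- diff(zf)
  g_z <- 1 / diff(z)
  kC <- seq_len(nz - 1); kD <- kC + 1L
  L_full <- Matrix::sparseMatrix(
    i = c(kC, kD, kC, kD), j = c(kC, kD, kD, kC),
    x = c(g_z, g_z, -g_z, -g_z), dims = c(nz, nz))
  L_bc <- L_full; L_bc[1, ] <- 0
  # the plane-sheet tail decays like exp(-pi^2 T / (4 z^2)); keep the step
  # small against that decay time so the implicit march tracks it
  dt_cap <- spec$dt_cap %||% (0.005 * z_ratio^2)
  Ts <- log_schedule(t0, spec$t_end, spec$steps_per_decade, dt_cap)
  res <- march_implicit(w, L_bc, L_full, 1L, Ts, spec$stepping)
  keep <- Ts >= spec$t_start * (1 - 1e-9)
  finish_curve(Ts, res$M, res$flux, pi, keep, z_ratio, spec, mode = "1d")
}
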