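# Independent numerical oracles and cached expensive simulations.
# The oracles are deliberately written without reusing the package's
# internals: brute-force series sums and a plain finite-difference radial
# solver, so that agreement with the package is a two-route check.

# brute-force Crank plane-sheet surface flux density (short-time image series)
oracle_crank_fd <- function(T, z, n_terms = 400) {
  n <- seq_len(n_terms)
  (1 + 2 * sum((-1)^n * exp(-n^2 * z^2 / T))) / sqrt(pi * T)
}

# backward-Euler finite-difference solution of the exterior-of-cylinder
# problem (unit radius, saturated surface), on an expanding radial grid;
# returns flux density per unit cylinder area at the requested times
oracle_radial_cylinder <- function(t_out, h_min = 2e-4, fac = 1.03,
                                   t_start = 1e-9, steps_per_decade = 120) {
  r <- 1
  repeat {
    h <- if (length(r) == 1) h_min else min((r[length(r)] - r[length(r) - 1]) * fac, 0.1)
    r <- c(r, r[length(r)] + h)
    if (r[length(r)] > 1 + 8 * sqrt(max(t_out))) break
  }
  n <- length(r) - 1
  gi <- 2:(n + 1)
  hl <- r[gi] - r[gi - 1]
  hr <- c(r[gi][-1], NA) - r[gi]; hr[n] <- hl[n]
  rl <- (r[gi] + r[gi - 1]) / 2
  rr <- r[gi] + hr / 2; rr[-n] <- (r[gi][-n] + r[gi + 1][-n]) / 2
  vol <- r[gi] * (rr - rl)
  wl <- rl / hl; wr <- rr / hr; wr[n] <- 0
  Ts <- exp(seq(log(t_start), log(max(t_out)),
                length.out = ceiling(steps_per_decade * log10(max(t_out) / t_start)) + 1))
  L <- Matrix::bandSparse(n, k = -1:1,
                          diagonals = list(-wl[-1], wl + wr, -wr[-n]))
  C <- numeric(n); Tprev <- 0
  flux <- numeric(length(Ts))
  for (k in seq_along(Ts)) {
    dt <- Ts[k] - Tprev; Tprev <- Ts[k]
    A <- Matrix::Diagonal(x = vol / dt) + L
    d <- vol / dt * C
    d[1] <- d[1] + wl[1]
    C <- as.numeric(Matrix::solve(A, d))
    flux[k] <- wl[1] * (1 - C[1]) # -dC/dr at the unit-radius surface
  }
  vapply(t_out, function(tq) flux[which.min(abs(log(Ts) - log(tq)))], numeric(1))
}

# cache for expensive simulations shared across test files (one R session)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

sim_z10 <- function() cached("z10", simulate_uptake(
  10, grid_spec(t_start = 1e-4, t_end = 1e2, steps_per_decade = 60, n_z = 12)))

sim_thin <- function() cached("thin", simulate_uptake(
  0.01, grid_spec(t_start = 1e-7, t_end = 1, steps_per_decade = 60)))

sim_1d_thin <- function() cached("oned", simulate_1d(
  0.01, grid_spec(t_start = 1e-6, t_end = 1e-3, steps_per_decade = 60)))

master_maize <- function() cached("maize", simulate_uptake(
  disk_geometry(450e-6, 50e-9)$z_ratio,
  grid_spec(t_start = 1e-11, t_end = 1e-5, steps_per_decade = 40)))
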