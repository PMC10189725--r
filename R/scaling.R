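#' Convert a dimensionless curve to laboratory units
#'
#' Maps a dimensionless uptake curve onto dimensional time and mass via the
#' reference scales: `t = T * t_ref` and
#' `mass = n_droplets * m_ref * M(T)`, the array total over independent
#' droplets.
#'
#' @param curve A `dimless_curve` (from [simulate_uptake()],
#'   [simulate_1d()]) or any tibble with columns `T` and `M` (optionally
#'   `rate`).
#' @param t_ref_s Reference time in seconds (`r_dep^2 / D_cut`).
#' @param m_ref_ug Reference mass in micrograms (`c_sat_cut * r_dep^3`).
#' @param n_droplets Number of independent droplets summed.
#' @return A tibble with `time_s`, `time_min`, `mass_ug` and, when the curve
#'   carries a rate, `rate_ug_per_min`.
#' @examples
#' crv <- tibble::tibble(T = c(1e-9, 1e-8), M = c(1e-6, 3e-6))
#' dimensionalize(crv, t_ref_s = 1.6e11, m_ref_ug = 170, n_droplets = 20)
#' @export
dimensionalize <- function(curve, t_ref_s, m_ref_ug, n_droplets = 1) {
  check_scales(t_ref_s, m_ref_ug, n_droplets)
  stopifnot(all(c("T", "M") %in% names(curve)))
  out <- tibble(
    time_s = curve$T * t_ref_s,
    time_min = curve$T * t_ref_s / 60,
    mass_ug = n_droplets * m_ref_ug * curve$M
  )
  if ("rate" %in% names(curve))
    out$rate_ug_per_min <- n_droplets * m_ref_ug * curve$rate / t_ref_s * 60
  out
}

#' Convert dimensional uptake data to dimensionless form
#'
#' Inverse of [dimensionalize()]: `T = t / t_ref`,
#' `M = mass / (n_droplets * m_ref)`.
#'
#' @param tbl A tibble with `time_s` and `mass_ug` columns.
#' @inheritParams dimensionalize
#' @return A tibble with columns `T` and `M`.
#' @export
nondimensionalize <- function(tbl, t_ref_s, m_ref_ug, n_droplets = 1) {
  check_scales(t_ref_s, m_ref_ug, n_droplets)
  stopifnot(all(c("time_s", "mass_ug") %in% names(tbl)))
  tibble(T = tbl$time_s / t_ref_s,
         M = tbl$mass_ug / (n_droplets * m_ref_ug))
}

check_scales <- function(t_ref_s, m_ref_ug, n_droplets) {
  if (!is.finite(t_ref_s) || t_ref_s <= 0) abort("`t_ref_s` must be positive.")
  if (!is.finite(m_ref_ug) || m_ref_ug <= 0) abort("`m_ref_ug` must be positive.")
  if (!is.finite(n_droplets) || n_droplets < 1) abort("`n_droplets` must be >= 1.")
  invisible(NULL)
}

# interpolator for M(T) of a master curve: monotone cubic in log-log space;
# extrapolates below the grid with the Cottrellian slope 1/2 and refuses above
master_interpolator <- function(master) {
  stopifnot(all(c("T", "M") %in% names(master)))
  ok <- master$M > 0 & master$T > 0
  lt <- log(master$T[ok]); lm <- log(master$M[ok])
  f <- splinefun(lt, lm, method = "monoH.FC")
  t_lo <- min(lt); t_hi <- max(lt)
  m_lo <- f(t_lo)
  function(T) {
    out <- numeric(length(T))
    pos <- T > 0
    l <- log(T[pos])
    if (any(l > t_hi + 1e-9))
      abort("data times fall beyond the master curve; simulate a wider T range.")
    v <- ifelse(l < t_lo, m_lo + 0.5 * (l - t_lo), f(pmin(l, t_hi)))
    out[pos] <- exp(v)
    out
  }
}

#' Fit the dimensionless master curve to uptake-assay data
#'
#' Infers the cuticular diffusion coefficient `D_cut` and saturation
#' concentration `c_sat_cut` from a destructive-sampling droplet-array
#' uptake assay, by least squares on the leaf-extract (TL) masses:
#' `mass_TL(t) = n_droplets * m_ref * M(t / t_ref)`, where `M(T)` is the
#' dimensionless master curve for the geometry's `z_ratio`. For fixed
#' `r_dep` the two scales act orthogonally - `t_ref` stretches time,
#' `m_ref` stretches mass - so the master curve is computed once and reused
#' across optimiser iterations.
#'
#' Optimisation is over `(log t_ref, log m_ref)` (positivity for free) with
#' the Levenberg-Marquardt algorithm, started from a coarse grid search in
#' `log t_ref` (the conditionally optimal `m_ref` is closed-form). Standard
#' errors come from the linearised covariance `s^2 (J'J)^-1` and are mapped
#' to `D_cut = r_dep^2 / t_ref` and `c_sat_cut = m_ref / r_dep^3` by the
#' delta method; 95 % intervals are formed on the log scale.
#'
#' @param data A tibble with columns `time_min` and `mass_TL_ug` (the schema
#'   written by [gen_assay()]; extra columns such as `mass_LW_ug`, `batch`,
#'   `replicate` are ignored). At least 3 distinct positive times.
#' @param master A `dimless_curve` whose `T` range covers
#'   `t / t_ref` for all data times at the fitted `t_ref` (short times may
#'   be Cottrell-extrapolated below the grid).
#' @param geom A [disk_geometry()]; supplies `r_dep` and `n_droplets`.
#' @param weights Optional per-point weights (reciprocal variances) applied
#'   to the residuals; unweighted by default. The string `"multiplicative"`
#'   requests one model-based reweighting pass (an unweighted fit followed
#'   by a refit with weights `1 / fitted^2`), the generalised-least-squares
#'   choice when measurement noise is multiplicative with constant
#'   coefficient of variation - as in [gen_assay()]'s noise model - and the
#'   setting under which the reported confidence intervals are calibrated
#'   for such data.
#' @return An object of class `uptake_fit`; see [tidy.uptake_fit()] and
#'   [glance.uptake_fit()].
#' @export
fit_uptake <- function(data, master, geom, weights = NULL) {
  stopifnot(inherits(geom, "disk_geometry"))
  if (!all(c("time_min", "mass_TL_ug") %in% names(data)))
    abort("`data` must have columns `time_min` and `mass_TL_ug`.")
  t_s <- data$time_min * 60
  y <- data$mass_TL_ug
  if (any(!is.finite(t_s)) || any(t_s < 0) || any(!is.finite(y)) || any(y < 0))
    abort("times and masses must be finite and non-negative.")
  if (length(unique(t_s[t_s > 0])) < 3)
    abort("need at least 3 distinct positive time points.")
  tp <- t_s[t_s > 0]
  if (max(tp) / min(tp) < 10)
    warn("data span less than one decade of time; the fit may be poorly constrained.")
  if (identical(weights, "multiplicative")) {
    pre <- fit_uptake(data, master, geom, weights = NULL)
    mu <- pre$data$fitted_ug
    weights <- 1 / pmax(mu, 1e-9 * max(mu))^2
  }
  wts <- if (is.null(weights)) rep(1, length(y)) else {
    stopifnot(length(weights) == length(y), all(weights > 0)); weights
  }
  n <- geom$n_droplets
  Mfun <- master_interpolator(master)

  # admissible log t_ref range keeps every T = t/t_ref on (or below) the grid
  lt_lo <- log(max(tp) / max(master$T))
  lt_hi <- log(min(tp) / (min(master$T) * 1e-3)) # allow Cottrell extrapolation
  if (lt_hi <= lt_lo)
    abort("master curve does not span the data times; simulate a wider T range.")

  model <- function(lt_ref, lm_ref) n * exp(lm_ref) * Mfun(t_s / exp(lt_ref))

  # coarse grid in log t_ref; conditional m_ref is linear least squares
  grid_lt <- seq(lt_lo, lt_hi, length.out = 80)
  best <- purrr::map_dfr(grid_lt, function(lt) {
    s <- n * Mfun(t_s / exp(lt))
    mref <- max(sum(wts * s * y) / max(sum(wts * s^2), .Machine$double.xmin), 1e-300)
    tibble(lt = lt, lm = log(mref),
           rss = sum(wts * (y - mref * s)^2))
  })
  st <- best[which.min(best$rss), ]

  resid_fn <- function(p) sqrt(wts) * (y - model(p[1], p[2]))
  fit <- minpack.lm::nls.lm(
    par = c(st$lt, st$lm), fn = resid_fn,
    lower = c(lt_lo, st$lm - 25), upper = c(lt_hi, st$lm + 25),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9))
    abort(sprintf("least-squares fit did not converge (info = %d).", fit$info))
  p <- fit$par
  if (min(p[1] - lt_lo, lt_hi - p[1]) < 1e-6)
    warn("fitted t_ref sits at the admissible bound; widen the master curve's T range.")

  # linearised covariance from a finite-difference Jacobian at the optimum
  r0 <- resid_fn(p)
  J <- vapply(1:2, function(j) {
    h <- 1e-6 * max(1, abs(p[j]))
    pj <- p; pj[j] <- pj[j] + h
    (resid_fn(pj) - r0) / h
  }, numeric(length(y)))
  dof <- length(y) - 2L
  s2 <- sum(r0^2) / dof
  cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA_real_, 2, 2))
  se_log <- sqrt(pmax(diag(cv), 0))

  t_ref <- exp(p[1]); m_ref_ug <- exp(p[2])
  d_cut <- geom$r_dep^2 / t_ref
  c_sat <- m_ref_ug * 1e-6 / geom$r_dep^3
  z95 <- qnorm(0.975)
  est <- tibble(
    term = c("t_ref_s", "m_ref_ug", "d_cut_m2_s", "c_sat_cut_ppm"),
    estimate = c(t_ref, m_ref_ug, d_cut, c_sat),
    std.error = c(t_ref * se_log[1], m_ref_ug * se_log[2],
                  d_cut * se_log[1], c_sat * se_log[2]),
    conf.low = estimate * exp(-z95 * c(se_log[1], se_log[2], se_log[1], se_log[2])),
    conf.high = estimate * exp(z95 * c(se_log[1], se_log[2], se_log[1], se_log[2]))
  )
  fitted <- model(p[1], p[2])
  rss <- sum(wts * (y - fitted)^2)
  tss <- sum(wts * (y - sum(wts * y) / sum(wts))^2)
  structure(
    list(estimates = est, r_squared = 1 - rss / tss,
         sigma = sqrt(s2), nobs = length(y), df_residual = dof,
         converged = !(fit$info %in% c(0, 9)), info = fit$info,
         par_log = p, vcov_log = cv,
         data = tibble(time_min = data$time_min, mass_TL_ug = y,
                       fitted_ug = fitted, residual_ug = y - fitted),
         geom = geom, master_range = range(master$T)),
    class = "uptake_fit"
  )
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("<uptake_fit> droplet-array uptake fit\n")
  cat(sprintf("  n = %d observations, R^2 = %.4f\n", x$nobs, x$r_squared))
  d <- x$estimates
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-14s %.4g  (se %.2g)\n", d$term[i], d$estimate[i], d$std.error[i]))
  invisible(x)
}

#' Tidy an uptake fit
#'
#' @param x An `uptake_fit` from [fit_uptake()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`t_ref_s`, `m_ref_ug`,
#'   `d_cut_m2_s`, `c_sat_cut_ppm`): `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (95 %, log-scale normal).
#' @method tidy uptake_fit
#' @export
tidy.uptake_fit <- function(x, ...) x$estimates

#' Glance at an uptake fit
#'
#' @inheritParams tidy.uptake_fit
#' @return A one-row tibble: `r.squared`, `sigma`, `nobs`, `df.residual`,
#'   `converged`.
#' @method glance uptake_fit
#' @export
glance.uptake_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$nobs,
         df.residual = x$df_residual, converged = x$converged)
}

#' Cuticle-water partition coefficient
#'
#' `K_cw = c_sat_cut / c_sat_aq`, the ratio of the saturation concentration
#' in the cuticle to the aqueous solubility; multiplying an aqueous
#' solubility by `K_cw` is the standard route to a cuticular solubility.
#'
#' @param c_sat_cut Cuticular saturation concentration (ppm, g m^-3).
#' @param c_sat_aq Aqueous saturation concentration, same units.
#' @return A tibble with `k_cw` and `log10_k_cw`.
#' @examples
#' csat_to_kcw(1.87e6, 1.87) # log10 K_cw = 6
#' @export
csat_to_kcw <- function(c_sat_cut, c_sat_aq) {
  if (any(!is.finite(c_sat_cut)) || any(c_sat_cut <= 0) ||
      any(!is.finite(c_sat_aq)) || any(c_sat_aq <= 0))
    abort("saturation concentrations must be positive.")
  tibble(k_cw = c_sat_cut / c_sat_aq,
         log10_k_cw = log10(c_sat_cut / c_sat_aq))
}

#' Direct-versus-indirect pathway criterion
#'
#' Dimensionless group comparing transport capacity through the direct
#' particle-cuticle contact against the indirect dissolution-plus-aqueous
#' diffusion route, taken here as the product ratio
#' `G = (D_cut * c_sat_cut) / (D_aq * c_sat_aq)`. `G < 1` predicts that the
#' indirect pathway dominates and particle-cuticle contact does not limit
#' uptake.
#'
#' Note: this product-ratio form matches the symbols involved in the
#' criterion but the original expression is defined in prior literature;
#' verify against that source before quantitative use. The classification
#' at `G < 1` is unaffected by monotone rescalings of the group.
#'
#' @param d_cut,d_aq Diffusion coefficients in cuticle and water (m^2 s^-1).
#' @param c_sat_cut,c_sat_aq Saturation concentrations in cuticle and water
#'   (same units as each other).
#' @return A tibble with `g`, `log10_g` and `regime`
#'   (`"indirect-dominant"`, `"direct-dominant"` or `"balanced"`).
#' @examples
#' pathway_criterion(1.24e-18, 1.87e6, 1e-10, 1)
#' @export
pathway_criterion <- function(d_cut, c_sat_cut, d_aq = 1e-10, c_sat_aq = NULL) {
  if (is.null(c_sat_aq))
    abort("insufficient data: the aqueous solubility `c_sat_aq` is required for G.")
  vals <- c(d_cut = d_cut, c_sat_cut = c_sat_cut, d_aq = d_aq, c_sat_aq = c_sat_aq)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all transport parameters must be positive.")
  g <- (d_cut * c_sat_cut) / (d_aq * c_sat_aq)
  tibble(g = g, log10_g = log10(g),
         regime = dplyr::case_when(
           g < 1 ~ "indirect-dominant",
           g > 1 ~ "direct-dominant",
           TRUE ~ "balanced"))
}
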