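#' Generate a synthetic droplet-array uptake assay
#'
#' Simulates the destructive-sampling uptake assay the fitting module
#' expects: an array of `n_droplets` independent droplets per leaf, one leaf
#' sacrificed per record, with the recovered mass split between a surface
#' wash (LW) and a leaf extract (TL). The forward model is the package's
#' own: `mass_TL(t) = n_droplets * m_ref * M(t / t_ref)` on the supplied
#' dimensionless master curve, with multiplicative lognormal measurement
#' noise of coefficient of variation `cv` (mean 1) applied independently to
#' each compartment. The noiseless compartments close exactly on the applied
#' dose: `mass_LW = dose - mass_TL(noiseless)`.
#'
#' The default design mirrors a short-time-weighted 24-h study: 2 batches of
#' 3 replicates at each of 12 time points, dense within the first hour and
#' sparse out to 1440 min.
#'
#' @param master A `dimless_curve` covering `t / t_ref` for all sample
#'   times (an error asks for a wider simulation otherwise).
#' @param geom A [disk_geometry()].
#' @param d_cut,c_sat_cut True transport parameters (m^2 s^-1; ppm) used to
#'   form `t_ref` and `m_ref`.
#' @param times_min Sample times in minutes (zero allowed).
#' @param n_batches,reps_per_batch Replication structure; each
#'   batch x replicate x time combination is an independent leaf.
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 for noiseless data).
#' @param dose_ug Applied dose per leaf in micrograms; defaults to
#'   [applied_dose()] of 0.2 uL droplets at 375 ppm.
#' @param seed Integer seed; the output is reproduced bit-for-bit for the
#'   same seed.
#' @return A tibble with columns `time_min`, `mass_LW_ug`, `mass_TL_ug`,
#'   `batch`, `replicate`, and attributes `truth` (the generating
#'   parameters) and `dose_ug`.
#' @examples
#' \donttest{
#' geom <- disk_geometry(450e-6, 50e-9)
#' master <- simulate_uptake(geom$z_ratio,
#'   grid_spec(t_start = 1e-11, t_end = 1e-5))
#' assay <- gen_assay(master, geom, 1.24e-18, 1.87e6, seed = 1)
#' }
#' @export
gen_assay <- function(master, geom, d_cut, c_sat_cut,
                      times_min = c(1, 2, 5, 10, 15, 20, 30, 45, 60, 120, 360, 1440),
                      n_batches = 2, reps_per_batch = 3, cv = 0.10,
                      dose_ug = applied_dose(0.2, 375, geom$n_droplets),
                      seed = NULL) {
  stopifnot(inherits(geom, "disk_geometry"))
  if (cv < 0) abort("`cv` must be non-negative.")
  if (is.unsorted(times_min, strictly = TRUE)) abort("`times_min` must be strictly increasing.")
  if (any(times_min < 0)) abort("times must be non-negative.")
  sc <- reference_scales(geom, d_cut, c_sat_cut)
  t_s <- times_min * 60
  Tq <- t_s / sc$t_ref_s
  if (max(Tq) > max(master$T) * (1 + 1e-9) || (min(Tq[Tq > 0]) < min(master$T) / 1e3))
    abort("sample times fall outside the master curve; simulate a wider T range.")
  Mfun <- master_interpolator(master)
  design <- tidyr::expand_grid(
    time_min = times_min,
    batch = seq_len(n_batches),
    replicate = seq_len(reps_per_batch))
  tl0 <- geom$n_droplets * sc$m_ref_ug * Mfun(design$time_min * 60 / sc$t_ref_s)
  if (any(tl0 > dose_ug))
    warn("noiseless uptake exceeds the applied dose at some times; check parameters.")
  lw0 <- pmax(dose_ug - tl0, 0)
  draw <- function(n) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  gen <- function() {
    out <- design
    out$mass_TL_ug <- tl0 * draw(nrow(design))
    out$mass_LW_ug <- lw0 * draw(nrow(design))
    out[, c("time_min", "mass_LW_ug", "mass_TL_ug", "batch", "replicate")]
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(out,
            truth = list(d_cut = d_cut, c_sat_cut = c_sat_cut,
                         t_ref_s = sc$t_ref_s, m_ref_ug = sc$m_ref_ug),
            dose_ug = dose_ug, cv = cv)
}

#' Generate a perturbed synthetic deposit observation
#'
#' Perturbs each field of a [deposit_observation()] template by independent
#' multiplicative lognormal noise (mean 1, per-field coefficient of
#' variation), then re-imposes the type's invariants: the ring area
#' fraction is clamped inside (0, 1) - generation fails if its noisy value
#' cannot be repaired to a valid fraction - and area closure holds by
#' construction since the interior area is derived from the total and the
#' fraction.
#'
#' @param template A one-row tibble from [deposit_observation()].
#' @param cv A single coefficient of variation applied to every field, or a
#'   named vector giving per-field values (fields absent from the vector are
#'   left unperturbed).
#' @param seed Integer seed; same seed, same output.
#' @return A one-row tibble with the same columns as the template.
#' @examples
#' gen_deposit(deposit_observation(), cv = 0.05, seed = 42)
#' @export
gen_deposit <- function(template, cv = 0.05, seed = NULL) {
  validate_deposit(template)
  fields <- names(template)
  cvs <- if (length(cv) == 1 && is.null(names(cv))) setNames(rep(cv, length(fields)), fields)
         else { bad <- setdiff(names(cv), fields)
                if (length(bad)) abort(sprintf("unknown fields in `cv`: %s", paste(bad, collapse = ", ")))
                out <- setNames(rep(0, length(fields)), fields); out[names(cv)] <- cv; out }
  if (any(cvs < 0)) abort("coefficients of variation must be non-negative.")
  gen <- function() {
    out <- template
    for (f in fields) {
      if (cvs[[f]] == 0) next
      sdlog <- sqrt(log(1 + cvs[[f]]^2))
      out[[f]] <- template[[f]] * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
    # invariant repair: the fraction must stay inside (0, 1)
    if (out$ring_area_fraction >= 1) {
      if (template$ring_area_fraction >= 1) abort("cannot repair ring_area_fraction to (0, 1).")
      out$ring_area_fraction <- 1 - (1 - template$ring_area_fraction) / 2
    }
    validate_deposit(out)
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
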