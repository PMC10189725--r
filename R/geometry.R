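#' Droplet-deposit / cuticle geometry
#'
#' Bundles the geometry of a droplet-array uptake experiment: the radius of
#' the (coffee-ring pinned) deposit contact disk, the cuticle thickness, and
#' the number of droplets applied per leaf. The key derived quantity is the
#' dimensionless cuticle thickness `z_ratio` (cuticle thickness divided by
#' deposit radius), which fully determines the shape of the dimensionless
#' uptake curve. Also derived are the dimensionless disk contact area
#' (`a_disk` = pi) and the lateral area of the cylinder extruded from the
#' contact disk through the cuticle (`a_cyl` = 2 * pi * z_ratio).
#'
#' @param r_dep Deposit (contact disk) radius in metres. Maize assays in the
#'   motivating experiments had `r_dep` close to 450e-6 m.
#' @param z_max Cuticle thickness in metres (e.g. 50e-9 m for maize).
#' @param n_droplets Droplets applied per leaf; uptake is modelled as the sum
#'   of `n_droplets` independent single-droplet uptakes.
#'
#' @return An object of class `disk_geometry`: a list with elements `r_dep`,
#'   `z_max`, `n_droplets`, `z_ratio`, `a_disk` and `a_cyl`.
#'
#' @examples
#' geom <- disk_geometry(r_dep = 450e-6, z_max = 50e-9)
#' geom$z_ratio # about 1.1e-4
#' @export
disk_geometry <- function(r_dep, z_max, n_droplets = 20) {
  stopifnot(is.numeric(r_dep), length(r_dep) == 1,
            is.numeric(z_max), length(z_max) == 1,
            is.numeric(n_droplets), length(n_droplets) == 1)
  if (!is.finite(r_dep) || r_dep <= 0) abort("`r_dep` must be a positive length in metres.")
  if (!is.finite(z_max) || z_max <= 0) abort("`z_max` must be a positive length in metres.")
  if (!is.finite(n_droplets) || n_droplets < 1) abort("`n_droplets` must be >= 1.")
  z_ratio <- z_max / r_dep
  structure(
    list(r_dep = r_dep, z_max = z_max, n_droplets = n_droplets,
         z_ratio = z_ratio, a_disk = pi, a_cyl = 2 * pi * z_ratio),
    class = "disk_geometry"
  )
}

#' @export
print.disk_geometry <- function(x, ...) {
  cat("<disk_geometry>\n")
  cat(sprintf("  deposit radius r_dep : %.4g m\n", x$r_dep))
  cat(sprintf("  cuticle depth  z_max : %.4g m\n", x$z_max))
  cat(sprintf("  droplets per leaf    : %g\n", x$n_droplets))
  cat(sprintf("  z_ratio (z_max/r_dep): %.4g\n", x$z_ratio))
  invisible(x)
}

#' Reference time and mass scales
#'
#' Converts transport parameters to the two scales that map the dimensionless
#' uptake curve onto laboratory units: the reference time
#' `t_ref = r_dep^2 / D_cut` (the time for the expected squared Brownian
#' displacement in the cuticle to reach `r_dep^2`, up to the 3-D factor of 6)
#' and the reference mass `m_ref = c_sat_cut * r_dep^3` (the mass of active
#' ingredient in a saturated cube of cuticle with side `r_dep`).
#'
#' `c_sat_cut` is in ppm interpreted as mass per volume, g m^-3 (equivalently
#' mg L^-1), consistent with a cuticle density near 1 g cm^-3.
#'
#' @param geom A [disk_geometry()].
#' @param d_cut Cuticular diffusion coefficient, m^2 s^-1.
#' @param c_sat_cut Cuticular saturation concentration, ppm (g m^-3).
#'
#' @return A one-row tibble with `t_ref_s`, `m_ref_g` and `m_ref_ug`.
#'
#' @examples
#' geom <- disk_geometry(450e-6, 50e-9)
#' reference_scales(geom, d_cut = 1.24e-18, c_sat_cut = 1.87e6)
#' @export
reference_scales <- function(geom, d_cut, c_sat_cut) {
  stopifnot(inherits(geom, "disk_geometry"))
  if (!is.finite(d_cut) || d_cut <= 0) abort("`d_cut` must be positive (m^2 s^-1).")
  if (!is.finite(c_sat_cut) || c_sat_cut <= 0) abort("`c_sat_cut` must be positive (ppm, g m^-3).")
  t_ref <- geom$r_dep^2 / d_cut
  m_ref <- c_sat_cut * geom$r_dep^3
  tibble(t_ref_s = t_ref, m_ref_g = m_ref, m_ref_ug = m_ref * 1e6)
}

#' Onset of longitudinal saturation
#'
#' Nominal dimensionless time at which the cuticle volume directly beneath
#' the contact disk saturates and the uptake rate leaves the disk-type
#' (Cottrell / Shoup-Szabo) regime: `T = 0.5 * z_ratio^2`.
#'
#' @param z_ratio Dimensionless cuticle thickness (z_max / r_dep), or a
#'   [disk_geometry()].
#' @return Dimensionless time of regime transition.
#' @examples
#' transition_time(1.1111e-4)
#' @export
transition_time <- function(z_ratio) {
  z <- as_z_ratio(z_ratio)
  0.5 * z^2
}

# accept either a bare positive number or a disk_geometry
as_z_ratio <- function(z_ratio) {
  if (inherits(z_ratio, "disk_geometry")) z_ratio <- z_ratio$z_ratio
  if (!is.numeric(z_ratio) || length(z_ratio) != 1 || !is.finite(z_ratio) || z_ratio <= 0)
    abort("`z_ratio` must be a single positive number (or a disk_geometry).")
  z_ratio
}
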