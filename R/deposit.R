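#' Per-particle mass from volume and solid density
#'
#' @param particle_volume_um3 Mean particle volume, cubic micrometres.
#' @param solid_density_g_cm3 Density of the solid active ingredient,
#'   g cm^-3.
#' @return Per-particle mass in picograms. (Numerically `volume * density`:
#'   1 um^3 at 1 g cm^-3 is exactly 1 pg.)
#' @examples
#' particle_mass(2.3, 1.5) # 3.45 pg
#' @export
particle_mass <- function(particle_volume_um3, solid_density_g_cm3) {
  check_pos(particle_volume_um3, "particle_volume_um3")
  check_pos(solid_density_g_cm3, "solid_density_g_cm3")
  particle_volume_um3 * solid_density_g_cm3
}

#' Interior particle surface density
#'
#' Mass of particulate deposit per unit area in the deposit interior, from
#' the particle count density and the per-particle mass.
#'
#' @param count_density_cm2 Particles per square centimetre.
#' @inheritParams particle_mass
#' @return Surface density in micrograms per square centimetre.
#' @examples
#' interior_particle_density(3.48e5, 2.3, 1.5) # about 1.2 ug cm^-2
#' @export
interior_particle_density <- function(count_density_cm2, particle_volume_um3,
                                      solid_density_g_cm3) {
  if (is.null(count_density_cm2) || any(is.na(count_density_cm2)))
    abort("insufficient data: a particle count density is required.")
  if (any(count_density_cm2 < 0)) abort("`count_density_cm2` must be non-negative.")
  pp_pg <- particle_mass(particle_volume_um3, solid_density_g_cm3)
  count_density_cm2 * pp_pg * 1e-6 # pg -> ug
}

#' Mean interparticle spacing from surface density
#'
#' Converts a particulate surface density and per-particle mass into a mean
#' centre-to-centre spacing, assuming particles occupy a regular lattice:
#' the area per particle is `mass / density`, and the spacing is the lattice
#' constant of a square (default) or hexagonal lattice with that area per
#' site.
#'
#' @param surface_density_ug_cm2 Particulate surface density, ug cm^-2.
#' @param particle_mass_pg Per-particle mass, picograms.
#' @param lattice `"square"` (spacing = sqrt(area)) or `"hexagonal"`
#'   (spacing = sqrt(2 * area / sqrt(3))).
#' @return Spacing in micrometres.
#' @examples
#' spacing_from_density(1.2, 3.45) # about 17 um
#' @export
spacing_from_density <- function(surface_density_ug_cm2, particle_mass_pg,
                                 lattice = c("square", "hexagonal")) {
  lattice <- match.arg(lattice)
  check_pos(surface_density_ug_cm2, "surface_density_ug_cm2")
  check_pos(particle_mass_pg, "particle_mass_pg")
  area_cm2 <- (particle_mass_pg * 1e-6) / surface_density_ug_cm2
  if (lattice == "hexagonal") area_cm2 <- 2 * area_cm2 / sqrt(3)
  sqrt(area_cm2) * 1e4 # cm -> um
}

#' Aqueous diffusion-zone overlap time
#'
#' Time for the aqueous diffusion zones of neighbouring dissolving particles
#' to overlap significantly: `t = x_sep^2 / D_aq`. Beyond this time the
#' concentration at the cuticle surface is effectively uniform and uptake
#' can be modelled as transfer across the whole contact disk.
#'
#' @param x_sep_um Mean interparticle separation, micrometres.
#' @param d_aq Aqueous diffusion coefficient, m^2 s^-1.
#' @return Overlap time in seconds.
#' @examples
#' overlap_time(17.2, 1e-10) # about 3 s
#' @export
overlap_time <- function(x_sep_um, d_aq = 1e-10) {
  check_pos(x_sep_um, "x_sep_um")
  check_pos(d_aq, "d_aq")
  (x_sep_um * 1e-6)^2 / d_aq
}

#' Mass fraction deposited in the coffee ring
#'
#' Partitions the dried deposit's mass between the peripheral ring and the
#' interior, given the two surface densities and the area split. The ring
#' area is taken as `ring_area_fraction * a_total_mm2` (the interior as the
#' remainder), so any small closure mismatch between independently measured
#' areas is absorbed rather than propagated.
#'
#' @param a_total_mm2 Total deposit area (ring plus interior), mm^2.
#' @param ring_area_fraction Fraction of the total area occupied by the
#'   ring, in (0, 1).
#' @param interior_density_ug_cm2,ring_density_ug_cm2 Particulate surface
#'   densities, ug cm^-2.
#' @return Fraction of deposited mass in the ring, in `[0, 1]`.
#' @examples
#' ring_mass_fraction(0.64, 0.16, 1.2, 58.4) # about 0.90
#' @export
ring_mass_fraction <- function(a_total_mm2, ring_area_fraction,
                               interior_density_ug_cm2, ring_density_ug_cm2) {
  check_pos(a_total_mm2, "a_total_mm2")
  if (any(ring_area_fraction <= 0) || any(ring_area_fraction >= 1))
    abort("`ring_area_fraction` must lie strictly between 0 and 1.")
  if (any(interior_density_ug_cm2 < 0) || any(ring_density_ug_cm2 < 0))
    abort("densities must be non-negative.")
  a_ring <- ring_area_fraction * a_total_mm2 * 0.01      # mm^2 -> cm^2
  a_int <- (1 - ring_area_fraction) * a_total_mm2 * 0.01
  m_ring <- ring_density_ug_cm2 * a_ring
  m_int <- interior_density_ug_cm2 * a_int
  m_ring / (m_ring + m_int)
}

#' Applied dose of active ingredient
#'
#' Total mass applied to a leaf: droplet volume times suspension
#' concentration (ppm read as mg L^-1) times droplet count.
#'
#' @param droplet_volume_ul Volume per droplet, microlitres.
#' @param concentration_ppm Suspension concentration, ppm (mg L^-1).
#' @param n_droplets Droplets per leaf.
#' @return Total applied mass in micrograms.
#' @examples
#' applied_dose(0.2, 375, 20) # 1.5 ug
#' @export
applied_dose <- function(droplet_volume_ul, concentration_ppm, n_droplets = 20) {
  check_pos(droplet_volume_ul, "droplet_volume_ul")
  if (any(concentration_ppm < 0)) abort("`concentration_ppm` must be non-negative.")
  if (any(n_droplets < 1)) abort("`n_droplets` must be >= 1.")
  droplet_volume_ul * concentration_ppm * 1e-3 * n_droplets
}

#' Deposit observation template
#'
#' A one-row tibble of deposit-characterisation measurements in the units
#' used throughout this module. Defaults are the measured values for the
#' maize / SC-fungicide system that motivates the package: total deposit
#' area 0.64 mm^2 of which 16 % is ring, ring density 58.4 ug cm^-2,
#' interior density 1.2 ug cm^-2, mean particle volume 2.3 um^3, solid
#' density 1.5 g cm^-3, interparticle separation 17.2 um, 0.075 ug applied
#' per droplet.
#'
#' @param a_total_mm2,ring_area_fraction,ring_density_ug_cm2,
#'   interior_density_ug_cm2,particle_volume_um3,solid_density_g_cm3,
#'   x_sep_um,applied_mass_per_droplet_ug Field values; see above.
#' @return A one-row tibble.
#' @export
deposit_observation <- function(a_total_mm2 = 0.64, ring_area_fraction = 0.16,
                                ring_density_ug_cm2 = 58.4,
                                interior_density_ug_cm2 = 1.2,
                                particle_volume_um3 = 2.3,
                                solid_density_g_cm3 = 1.5,
                                x_sep_um = 17.2,
                                applied_mass_per_droplet_ug = 0.075) {
  obs <- tibble(a_total_mm2, ring_area_fraction, ring_density_ug_cm2,
                interior_density_ug_cm2, particle_volume_um3,
                solid_density_g_cm3, x_sep_um, applied_mass_per_droplet_ug)
  validate_deposit(obs)
  obs
}

validate_deposit <- function(obs) {
  with(obs, {
    if (a_total_mm2 <= 0 || ring_density_ug_cm2 <= 0 || interior_density_ug_cm2 <= 0 ||
        particle_volume_um3 <= 0 || solid_density_g_cm3 <= 0 || x_sep_um <= 0 ||
        applied_mass_per_droplet_ug <= 0)
      abort("deposit observation fields must be positive.")
    if (ring_area_fraction <= 0 || ring_area_fraction >= 1)
      abort("`ring_area_fraction` must lie strictly between 0 and 1.")
  })
  invisible(obs)
}

#' Derived deposit metrics
#'
#' Computes every derived quantity of the deposit-characterisation module
#' from a [deposit_observation()] row: per-particle mass, the ring mass
#' fraction, the spacing implied by the interior density (square-lattice
#' convention), and the aqueous diffusion-zone overlap time of the measured
#' spacing.
#'
#' @param obs A one-row tibble from [deposit_observation()].
#' @param d_aq Aqueous diffusion coefficient for the overlap time, m^2 s^-1.
#' @return A one-row tibble: `particle_mass_pg`, `ring_mass_fraction`,
#'   `x_sep_implied_um`, `overlap_time_s`.
#' @examples
#' deposit_metrics(deposit_observation())
#' @export
deposit_metrics <- function(obs, d_aq = 1e-10) {
  validate_deposit(obs)
  pp <- particle_mass(obs$particle_volume_um3, obs$solid_density_g_cm3)
  tibble(
    particle_mass_pg = pp,
    ring_mass_fraction = ring_mass_fraction(
      obs$a_total_mm2, obs$ring_area_fraction,
      obs$interior_density_ug_cm2, obs$ring_density_ug_cm2),
    x_sep_implied_um = spacing_from_density(obs$interior_density_ug_cm2, pp),
    overlap_time_s = overlap_time(obs$x_sep_um, d_aq)
  )
}

check_pos <- function(x, nm) {
  if (any(!is.finite(x)) || any(x <= 0))
    abort(sprintf("`%s` must be positive and finite.", nm))
  invisible(x)
}
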