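## First-order process kinetics: settling, heteroaggregation, deposition.

## unchecked internal kernels (vectorised) ------------------------------------

## Stokes settling with buoyancy handling: particles lighter than the
## medium do not settle and the velocity is clamped to zero, continuously.
.settling_v <- function(radius, particle_density, medium_density, viscosity) {
  v <- 2 * .const$g * radius^2 * (particle_density - medium_density) /
    (9 * viscosity)
  v[v < 0] <- 0
  v
}

## Terminal velocity with Schiller-Naumann drag correction, fixed-point
## iterated from the Stokes start: Cd = 24/Re (1 + 0.15 Re^0.687).  Stokes
## is only valid for Re < ~0.1; the largest modelled beads reach Re ~ 100
## in air.  Converges to Stokes for small Re.
.terminal_v <- function(radius, particle_density, medium_density, viscosity,
                        model = "schiller_naumann") {
  v0 <- .settling_v(radius, particle_density, medium_density, viscosity)
  if (identical(model, "stokes") || all(v0 == 0)) return(v0)
  d <- 2 * radius
  buoy <- v0 == 0
  v <- v0
  v[buoy] <- 1e-300   # keep the iteration finite; reset below
  dd <- particle_density - medium_density
  dd[buoy] <- 0
  for (it in 1:40) {
    re <- medium_density * v * d / viscosity
    re[re < 1e-12] <- 1e-12
    cd <- 24 / re * (1 + 0.15 * re^0.687)
    v_new <- sqrt(4 * .const$g * d * dd / (3 * cd * medium_density))
    delta <- max(abs(v_new - v) / (v + 1e-300))
    v <- v_new
    if (delta < 1e-12) break
  }
  v[buoy] <- 0
  v
}

## Smoluchowski collision rate coefficient: Brownian (perikinetic) +
## laminar shear (orthokinetic) + differential settling, m3/s.
.collision_k <- function(r1, r2, v1, v2, temperature, viscosity, shear_rate) {
  brown <- 2 * .const$k_B * temperature * (r1 + r2)^2 / (3 * viscosity * r1 * r2)
  shear <- (4 / 3) * shear_rate * (r1 + r2)^3
  dsett <- pi * (r1 + r2)^2 * abs(v1 - v2)
  brown + shear + dsett
}

## volume-equivalent 1:1 aggregate of bead and host
.aggregate_props <- function(r_b, rho_b, r_h, rho_h) {
  v3 <- r_b^3 + r_h^3
  list(radius = v3^(1 / 3),
       density = (rho_b * r_b^3 + rho_h * r_h^3) / v3)
}

## exported operations --------------------------------------------------------

#' Stokes settling velocity with buoyancy handling
#'
#' Terminal velocity of a small sphere in a quiescent fluid,
#' `v = 2 g r^2 (rho_p - rho_m) / (9 mu)`.  Plastic lighter than the
#' medium does not settle: the velocity is zero (not negative) for
#' `rho_p <= rho_m`, and the function is continuous at neutral buoyancy.
#'
#' @param radius Particle radius, m (> 0), vectorised.
#' @param particle_density Particle (or aggregate) density, kg/m3.
#' @param medium_density Fluid density, kg/m3.
#' @param viscosity Dynamic viscosity of the fluid, Pa s.
#' @param drag `"stokes"` for the uncorrected creeping-flow law, or
#'   `"schiller_naumann"` for the drag-corrected terminal velocity used in
#'   system assembly by default (the two agree for Reynolds numbers below
#'   about 0.1; the largest modelled beads leave the creeping-flow regime,
#'   particularly in air).
#' @return Settling velocity, m/s (>= 0).
#' @examples
#' settling_velocity(10e-6, 1302, 1000, 1e-3)  # 6.58e-5 m/s
#' settling_velocity(10e-6, 854, 1000, 1e-3)   # buoyant: 0
#' @export
settling_velocity <- function(radius, particle_density, medium_density,
                              viscosity, drag = c("stokes",
                                                  "schiller_naumann")) {
  drag <- match.arg(drag)
  for (v in list(radius, particle_density, medium_density, viscosity))
    if (any(!is.finite(v)) || any(v <= 0))
      abort("all settling_velocity() inputs must be positive and finite.")
  .terminal_v(radius, particle_density, medium_density, viscosity,
              model = drag)
}

#' Properties of a 1:1 plastic/natural-particle heteroaggregate
#'
#' The aggregate of one bead and one host particle is represented as the
#' volume-equivalent sphere: `radius^3 = r_bead^3 + r_host^3`, with the
#' volume-weighted mean density.  The density is therefore always a convex
#' combination of the component densities, which is what makes a buoyant
#' bead sink once it picks up a sufficiently dense host.
#'
#' @param particle A [plastic_particle()] (or list with `radius`, `density`).
#' @param host A [natural_particle()] (or list with `radius`, `density`).
#' @return A list of class `sb_aggregate` with `radius` (m) and `density`
#'   (kg/m3).
#' @examples
#' b <- plastic_particle(6e-6, 900)
#' s <- natural_particle("coarse_spm", 3e-6, 2500)
#' heteroaggregate_properties(b, s)  # density ~1077.8, radius ~6.24 um
#' @export
heteroaggregate_properties <- function(particle, host) {
  if (!is.finite(particle$radius) || particle$radius <= 0 ||
      !is.finite(host$radius) || host$radius <= 0)
    abort("particle and host radii must be positive.")
  out <- .aggregate_props(particle$radius, particle$density,
                          host$radius, host$density)
  structure(out, class = "sb_aggregate")
}

#' Critical bead radius for heteroaggregate settling
#'
#' For a buoyant bead (lighter than water) attached 1:1 to a dense host,
#' the aggregate is denser than water only while the bead is small.  The
#' neutral-buoyancy radius is
#' `r* = r_host * ((rho_host - rho_w) / (rho_w - rho_p))^(1/3)`:
#' aggregates of beads smaller than `r*` settle, larger ones float.
#'
#' @param particle_density Polymer density, kg/m3; must be below
#'   `water_density`.
#' @param host A [natural_particle()]; must be denser than water.
#' @param water_density Water density, kg/m3.
#' @return Critical radius, m.
#' @examples
#' spm <- natural_particle("coarse_spm", 3e-6, 2500)
#' critical_settling_radius(960, spm, 1000) * 1e6  # ~10.04 um
#' @export
critical_settling_radius <- function(particle_density, host,
                                     water_density = 1000) {
  if (!is.finite(particle_density) || particle_density >= water_density)
    abort("`particle_density` must be below `water_density` (buoyant bead).")
  if (host$density <= water_density)
    abort("host must be denser than water.")
  host$radius * ((host$density - water_density) /
                   (water_density - particle_density))^(1 / 3)
}

#' Collision rate coefficient between two particles
#'
#' Sum of the three classical collision kernels: Brownian motion
#' `2 k_B T (r1+r2)^2 / (3 mu r1 r2)`, laminar fluid shear
#' `(4/3) G (r1+r2)^3` and differential settling `pi (r1+r2)^2 |v1-v2|`.
#'
#' @param r1,r2 Particle radii, m (> 0).
#' @param v1,v2 Settling velocities, m/s (>= 0).
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param shear_rate Fluid shear rate G, 1/s (>= 0).
#' @return Collision rate coefficient, m3/s.
#' @examples
#' collision_rate_coefficient(1e-6, 1e-6, 0, 0, 293, 1e-3, 0)  # 8kT/(3mu)
#' @export
collision_rate_coefficient <- function(r1, r2, v1, v2, temperature,
                                       viscosity, shear_rate = 0) {
  if (any(!is.finite(c(r1, r2))) || any(c(r1, r2) <= 0))
    abort("radii must be positive and finite.")
  if (any(!is.finite(c(v1, v2))) || any(c(v1, v2) < 0))
    abort("velocities must be finite and >= 0.")
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0))
    abort("`shear_rate` must be finite and >= 0.")
  if (any(!is.finite(temperature)) || any(temperature < 0))
    abort("`temperature` must be >= 0.")
  .collision_k(r1, r2, v1, v2, temperature, viscosity, shear_rate)
}

#' Pseudo-first-order heteroaggregation rate constant
#'
#' Attachment of the free plastic species to one natural-particle class:
#' `k_het = alpha_het * K_coll * n_host`, with the collision coefficient
#' evaluated at the compartment's temperature, viscosity and shear rate
#' and with the Stokes settling velocities of bead and host in that
#' medium.  Natural-particle concentrations are treated as a fixed
#' landscape property, so the rate is first order in the plastic.
#'
#' @param particle A [plastic_particle()].
#' @param host A [natural_particle()] with its `number_concentration` set
#'   for the compartment.
#' @param compartment A single compartment row of an `sb_landscape` (or a
#'   list with `temperature`, `viscosity`, `medium_density`, `shear_rate`).
#' @return Rate constant, 1/s.
#' @export
heteroaggregation_rate <- function(particle, host, compartment) {
  if (is.null(host$number_concentration) ||
      !is.finite(host$number_concentration))
    abort("host `number_concentration` is missing for this compartment.")
  v_b <- .settling_v(particle$radius, particle$density,
                     compartment$medium_density, compartment$viscosity)
  v_h <- .settling_v(host$radius, host$density,
                     compartment$medium_density, compartment$viscosity)
  K <- .collision_k(particle$radius, host$radius, v_b, v_h,
                    compartment$temperature, compartment$viscosity,
                    compartment$shear_rate)
  particle$alpha_het * K * host$number_concentration
}

#' Sedimentation rate constant of a water-column species
#'
#' First-order transfer from a water compartment to its sediment partner:
#' the species' Stokes settling velocity divided by the water depth.  The
#' free species uses the bead itself (zero for buoyant polymer), the
#' aggregated species use the 1:1 volume-equivalent aggregate with the
#' compartment's colloid or coarse-SPM class.
#'
#' @param compartment A water compartment row of an `sb_landscape`.
#' @param form One of the three species forms.
#' @param particle A [plastic_particle()].
#' @param landscape The `sb_landscape` the compartment belongs to (used to
#'   look up the natural-particle classes).
#' @return Rate constant, 1/s.
#' @export
sedimentation_rate <- function(compartment, form, particle, landscape) {
  if (!identical(compartment$class, "water"))
    abort(sprintf("`%s` is not a water compartment.", compartment$id))
  form <- match.arg(form, .species_forms)
  props <- .species_props(particle, compartment$id, landscape)[[form]]
  v <- .settling_v(props$radius, props$density,
                   compartment$medium_density, compartment$viscosity)
  v / compartment$depth
}

## effective (radius, density) of each species form in a compartment
.species_props <- function(particle, compartment_id, landscape) {
  hosts <- landscape$particles[
    landscape$particles$compartment_id == compartment_id, ]
  pick <- function(kinds, label = NULL) {
    h <- hosts[hosts$kind %in% kinds, ]
    if (!is.null(label) && nrow(h) > 1) h <- h[h$label == label, ]
    if (!nrow(h)) return(NULL)
    h[1, ]
  }
  colloid <- pick(c("colloid", "aerosol"), "fine")
  coarse  <- pick(c("coarse_spm", "aerosol", "grain"), "coarse")
  agg <- function(h) {
    if (is.null(h)) list(radius = particle$radius, density = particle$density)
    else .aggregate_props(particle$radius, particle$density, h$radius, h$density)
  }
  list(
    free = list(radius = particle$radius, density = particle$density),
    colloid_heteroaggregate = agg(colloid),
    coarse_attached = agg(coarse)
  )
}

#' Atmospheric deposition rate constants
#'
#' Dry deposition combines gravitational settling in air (the same Stokes
#' expression as in water, so the shared term is strictly increasing with
#' radius in the super-micron regime) with a Brownian diffusion velocity
#' `D / delta` across a laminar boundary layer.  Wet deposition is the
#' rain rate times a scavenging ratio over the mixing height.  Both are
#' apportioned over the receiving surfaces by area fraction.
#'
#' @param particle A [plastic_particle()].
#' @param air The air compartment row.
#' @param receiving The receiving surface compartment row.
#' @param landscape The `sb_landscape` (for the scavenging ratio and
#'   boundary-layer thickness).
#' @param form Species form in air (sets the aggregate properties).
#' @return Named numeric vector `c(k_dry =, k_wet =)`, 1/s.
#' @export
air_deposition_rates <- function(particle, air, receiving, landscape,
                                 form = "free") {
  if (!identical(air$class, "air"))
    abort(sprintf("`%s` is not an air compartment.", air$id))
  form <- match.arg(form, .species_forms)
  props <- .species_props(particle, air$id, landscape)[[form]]
  v_dep <- .deposition_velocity(props$radius, props$density, air,
                                landscape$params$air_boundary_layer_m)
  frac <- receiving$area / air$area
  if (frac > 1 + 1e-9)
    abort(sprintf("receiving surface `%s` larger than its air compartment.",
                  receiving$id))
  k_dry <- v_dep / air$depth * frac
  k_wet <- air$rain_rate * landscape$params$scavenging_ratio / air$depth * frac
  c(k_dry = k_dry, k_wet = k_wet)
}

.deposition_velocity <- function(radius, density, air, boundary_layer,
                                 model = "stokes") {
  v_g <- .terminal_v(radius, density, air$medium_density, air$viscosity,
                     model = model)
  D <- .const$k_B * air$temperature / (6 * pi * air$viscosity * radius)
  v_g + D / boundary_layer
}

#' Soil- and sediment-water exchange rate constants
#'
#' Soil to water: mobile species (free and colloid-aggregated) are carried
#' by surface runoff water, `k_runoff = Q_runoff / V_soil_water`; the
#' grain-attached species moves only with eroded solids,
#' `k_erosion = v_erosion / depth`.  Sediment to water: resuspension at
#' the rate implied by the natural-solids balance (gross SPM settling flux
#' minus net accretion); burial of the net accreted layer is a permanent
#' sink, `k_burial = v_accretion / depth` (flux over inventory in all
#' cases).
#'
#' @param compartment A soil or sediment compartment row.
#' @param partner_water Its receiving/overlying water compartment row.
#' @param landscape The `sb_landscape`.
#' @return A tibble with columns `process`, `forms` (comma-separated
#'   species the rate applies to) and `rate` (1/s).
#' @export
surface_exchange_rates <- function(compartment, partner_water, landscape) {
  p <- landscape$params
  if (compartment$class == "soil") {
    rain <- landscape$compartments$rain_rate[
      landscape$compartments$class == "air" &
        landscape$compartments$scale == compartment$scale][1]
    if (!is.finite(rain))
      abort(sprintf("no air compartment with rain rate for scale `%s`",
                    compartment$scale))
    k_runoff <- p$runoff_fraction * rain /
      (compartment$depth * compartment$water_content)
    k_erosion <- (p$erosion_mm_per_year * 1e-3 / .const$sec_per_year) /
      compartment$depth
    return(tibble(
      process = c("runoff", "erosion"),
      forms = c("free,colloid_heteroaggregate", "coarse_attached"),
      rate = c(k_runoff, k_erosion)
    ))
  }
  if (compartment$class == "sediment") {
    rates <- .sediment_exchange(compartment, partner_water, landscape)
    return(tibble(
      process = c("resuspension", "burial"),
      forms = c("all", "all"),
      rate = c(rates$k_resuspension, rates$k_burial)
    ))
  }
  abort(sprintf("`%s` is neither soil nor sediment.", compartment$id))
}

## resuspension and burial of sediment material, from the natural-solids
## balance of the overlying water: gross settling flux of SPM in excess of
## the net accretion flux returns to the water column.
.sediment_exchange <- function(sediment, water, landscape) {
  spm <- landscape$particles[
    landscape$particles$compartment_id == water$id &
      landscape$particles$kind == "coarse_spm", ]
  gross_flux <- if (nrow(spm)) {
    conc_mass <- spm$number_concentration[1] *
      sphere_mass(spm$radius[1], spm$density[1])         # kg/m3
    v_spm <- .settling_v(spm$radius[1], spm$density[1],
                         water$medium_density, water$viscosity)
    conc_mass * v_spm                                     # kg/m2/s
  } else 0
  net_flux <- sediment$net_accretion * sediment$dry_bulk_density
  resusp_flux <- max(gross_flux - net_flux, 0)
  inventory_per_area <- sediment$depth * sediment$dry_bulk_density
  list(k_resuspension = resusp_flux / inventory_per_area,
       k_burial = sediment$net_accretion / sediment$depth)
}

#' Fragmentation plus degradation removal rate
#'
#' Fragmentation (breakup into sizes below the modelled class) and
#' degradation are pure first-order removal: the lost mass is not tracked
#' as smaller particles.  Air is always zero.
#'
#' @param particle A [plastic_particle()].
#' @param medium One of the compartment media (e.g. `"freshwater"`,
#'   `"marine_sediment"`, `"natural_soil"`, `"air"`).
#' @return Rate constant `k_frag + k_deg`, 1/s.
#' @examples
#' p <- plastic_particle(1e-5, 1000, k_frag = 2.7e-8)
#' fragmentation_degradation_rate(p, "seawater")  # 2.7e-8
#' fragmentation_degradation_rate(p, "air")       # 0
#' @export
fragmentation_degradation_rate <- function(particle, medium) {
  if (!medium %in% .media)
    abort(sprintf("unknown medium `%s`", medium))
  cls <- .medium_class[[medium]]
  particle$k_frag[[cls]] + particle$k_deg[[cls]]
}

#' Inter-scale advection rate constants
#'
#' Every advective link of the landscape (air-air and water-water flows
#' between nested scales, rivers discharging to sea, and the bidirectional
#' ocean-current exchange that keeps the global ocean from acting as a
#' one-way sink) becomes a first-order constant
#' `k = volumetric flow / source volume`, applied identically to all three
#' species forms.
#'
#' @param landscape An `sb_landscape`.
#' @return A tibble with `from`, `to`, `flow` (m3/s) and `rate` (1/s).
#' @export
advection_rates <- function(landscape) {
  fl <- landscape$flows
  if (!nrow(fl)) return(tibble(from = character(), to = character(),
                               flow = numeric(), rate = numeric()))
  vol <- setNames(landscape$compartments$volume, landscape$compartments$id)
  fl$rate <- fl$flow / vol[fl$from]
  fl
}
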