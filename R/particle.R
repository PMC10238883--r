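## Particle domain types and spherical mass/number conversions.

#' Define a plastic particle
#'
#' Creates the description of the modelled plastic particle: a sphere of
#' given radius and polymer density, with an attachment efficiency applied
#' to all heteroaggregation events and first-order fragmentation and
#' degradation rate constants per broad medium class (water, sediment,
#' soil).  Fragmentation and degradation in air are fixed to zero: the
#' atmospheric residence time of the particle is far too short for either
#' process to matter.
#'
#' @param radius Particle radius in metres (> 0).
#' @param density Polymer density in kg/m3 (> 0).
#' @param alpha_het Dimensionless attachment efficiency in (0, 1], the
#'   probability that a collision with a natural particle leads to
#'   permanent attachment.
#' @param k_frag First-order fragmentation rate constant(s), 1/s.  Either a
#'   single value used for water, sediment and soil, or a named vector with
#'   elements `water`, `sediment`, `soil`.
#' @param k_deg First-order degradation rate constant(s), 1/s, same shape
#'   as `k_frag`.
#' @return An object of class `sb_particle`: a list with fields `radius`,
#'   `density`, `alpha_het`, `k_frag`, `k_deg` (both per-medium-class named
#'   vectors including the forced `air = 0`) and `shape = "sphere"`.
#' @examples
#' p <- plastic_particle(radius = 50e-6, density = 950, alpha_het = 0.01)
#' sphere_mass(p$radius, p$density)
#' @export
plastic_particle <- function(radius, density, alpha_het = 1,
                             k_frag = 0, k_deg = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L,
            is.numeric(density), length(density) == 1L,
            is.numeric(alpha_het), length(alpha_het) == 1L)
  if (!is.finite(radius) || radius <= 0)
    abort("`radius` must be a positive, finite length in metres.")
  if (!is.finite(density) || density <= 0)
    abort("`density` must be a positive, finite density in kg/m3.")
  if (!is.finite(alpha_het) || alpha_het <= 0 || alpha_het > 1)
    abort("`alpha_het` must lie in (0, 1].")
  structure(
    list(
      radius    = radius,
      density   = density,
      alpha_het = alpha_het,
      k_frag    = .per_medium_rate(k_frag, "k_frag"),
      k_deg     = .per_medium_rate(k_deg, "k_deg"),
      shape     = "sphere"
    ),
    class = "sb_particle"
  )
}

## expand a scalar or named rate vector over the medium classes; air is
## always forced to zero.
.per_medium_rate <- function(k, what) {
  classes <- c("water", "sediment", "soil")
  if (is.null(names(k))) {
    if (length(k) != 1L)
      abort(sprintf("`%s` must be a single value or a named vector.", what))
    out <- setNames(rep(as.numeric(k), 3L), classes)
  } else {
    bad <- setdiff(names(k), c(classes, "air"))
    if (length(bad))
      abort(sprintf("Unknown medium class in `%s`: %s", what,
                    paste(bad, collapse = ", ")))
    if (any(as.numeric(k[names(k) == "air"]) != 0))
      abort(sprintf("`%s` must be zero in air.", what))
    out <- setNames(numeric(3L), classes)
    keep <- intersect(names(k), classes)
    out[keep] <- as.numeric(k[keep])
  }
  if (any(!is.finite(out)) || any(out < 0))
    abort(sprintf("`%s` values must be finite and >= 0.", what))
  c(out, air = 0)
}

#' @export
print.sb_particle <- function(x, ...) {
  cat(sprintf(
    "<sb_particle> sphere, radius %.3g um, density %.4g kg/m3, alpha_het %.3g\n",
    x$radius * 1e6, x$density, x$alpha_het))
  cat(sprintf("  k_frag (1/s): water %.3g, sediment %.3g, soil %.3g\n",
              x$k_frag[["water"]], x$k_frag[["sediment"]], x$k_frag[["soil"]]))
  cat(sprintf("  k_deg  (1/s): water %.3g, sediment %.3g, soil %.3g\n",
              x$k_deg[["water"]], x$k_deg[["sediment"]], x$k_deg[["soil"]]))
  invisible(x)
}

#' Define a natural particle class
#'
#' Natural particulates are the collision partners of the plastic particle:
#' colloids and coarse suspended particulate matter (SPM) in water, fine
#' and coarse aerosol in air, and grains in soil.
#'
#' @param kind One of `"colloid"`, `"coarse_spm"`, `"aerosol"`, `"grain"`.
#' @param radius Radius in metres (> 0).
#' @param density Density in kg/m3 (> 0).
#' @param number_concentration Number concentration in 1/m3 (>= 0).
#' @return A list of class `sb_natural_particle`.
#' @export
natural_particle <- function(kind, radius, density, number_concentration = 0) {
  kind <- match.arg(kind, c("colloid", "coarse_spm", "aerosol", "grain"))
  if (!is.finite(radius) || radius <= 0)
    abort("natural particle `radius` must be positive and finite.")
  if (!is.finite(density) || density <= 0)
    abort("natural particle `density` must be positive and finite.")
  if (!is.finite(number_concentration) || number_concentration < 0)
    abort("`number_concentration` must be finite and >= 0.")
  structure(list(kind = kind, radius = radius, density = density,
                 number_concentration = number_concentration),
            class = "sb_natural_particle")
}

#' Mass of a spherical particle
#'
#' @param radius Radius in metres (> 0), vectorised.
#' @param density Density in kg/m3 (> 0), vectorised.
#' @return Mass in kg: `density * (4/3) * pi * radius^3`.
#' @examples
#' sphere_mass(100e-6, 1000)   # 4.18879e-9 kg
#' @export
sphere_mass <- function(radius, density) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    abort("`radius` must be positive and finite.")
  if (any(!is.finite(density)) || any(density <= 0))
    abort("`density` must be positive and finite.")
  density * (4 / 3) * pi * radius^3
}

#' Convert plastic mass to particle number
#'
#' Mass and number concentrations are interconverted assuming spherical
#' particles of the bead's radius and polymer density.  For aggregated
#' species the tracked mass is plastic mass only, so the same conversion
#' applies to every species form.
#'
#' @param mass Plastic mass in kg (>= 0), vectorised.
#' @param particle An [plastic_particle()] object (or any list with
#'   `radius` and `density`).
#' @return Particle count (dimensionless).
#' @examples
#' p <- plastic_particle(100e-6, 1000)
#' mass_to_number(1, p)   # ~2.387e8 beads per kg
#' @export
mass_to_number <- function(mass, particle) {
  if (any(!is.finite(mass)) || any(mass < 0))
    abort("`mass` must be finite and >= 0.")
  mass / sphere_mass(particle$radius, particle$density)
}

#' Convert particle number to plastic mass
#'
#' Inverse of [mass_to_number()].
#'
#' @param number Particle count (>= 0), vectorised.
#' @param particle An [plastic_particle()] object.
#' @return Mass in kg.
#' @export
number_to_mass <- function(number, particle) {
  if (any(!is.finite(number)) || any(number < 0))
    abort("`number` must be finite and >= 0.")
  number * sphere_mass(particle$radius, particle$density)
}
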