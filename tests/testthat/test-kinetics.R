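# Process kinetics: settling, aggregation, collision kernels, deposition,
# surface exchange, advection.

test_that("settling velocity follows Stokes and clamps buoyant particles", {
  # hand-evaluated Stokes formula
  expect_equal(settling_velocity(10e-6, 1302, 1000, 1e-3), 6.5814e-5,
               tolerance = 1e-4)
  expect_equal(settling_velocity(10e-6, 1000, 1000, 1e-3), 0)
  expect_equal(settling_velocity(10e-6, 854, 1000, 1e-3), 0)
  # continuity at neutral buoyancy
  eps <- 1e-6
  expect_lt(settling_velocity(10e-6, 1000 + eps, 1000, 1e-3), 1e-12)
  expect_error(settling_velocity(-1e-6, 1000, 1000, 1e-3), "positive")
  expect_error(settling_velocity(1e-6, Inf, 1000, 1e-3), "finite")
})

test_that("drag-corrected terminal velocity matches Stokes at low Reynolds
           and stays below it at high Reynolds", {
  # creeping flow: both laws agree
  expect_equal(settling_velocity(5e-6, 1200, 1000, 1e-3,
                                 drag = "schiller_naumann"),
               settling_velocity(5e-6, 1200, 1000, 1e-3), tolerance = 1e-3)
  # a 625 um bead in air is far outside the creeping-flow regime
  v_stokes <- settling_velocity(625e-6, 1100, 1.23, 1.81e-5)
  v_sn <- settling_velocity(625e-6, 1100, 1.23, 1.81e-5,
                            drag = "schiller_naumann")
  expect_lt(v_sn, 0.2 * v_stokes)
  expect_gt(v_sn, 0)
  # self-consistency: the converged velocity satisfies the drag balance
  d <- 2 * 625e-6
  re <- 1.23 * v_sn * d / 1.81e-5
  cd <- 24 / re * (1 + 0.15 * re^0.687)
  expect_equal(v_sn, sqrt(4 * 9.80665 * d * (1100 - 1.23) / (3 * cd * 1.23)),
               tolerance = 1e-8)
})

test_that("heteroaggregate properties are the volume-equivalent mixture", {
  b <- plastic_particle(6e-6, 900)
  s <- natural_particle("coarse_spm", 3e-6, 2500)
  agg <- heteroaggregate_properties(b, s)
  expect_equal(agg$density, 1077.78, tolerance = 1e-4)
  expect_equal(agg$radius, 6.2403e-6, tolerance = 1e-4)
  # exact volume additivity
  expect_equal(agg$radius^3, b$radius^3 + s$radius^3)
  # label exchange symmetry
  agg2 <- heteroaggregate_properties(
    list(radius = 3e-6, density = 2500), list(radius = 6e-6, density = 900))
  expect_equal(agg2$density, agg$density)
  expect_equal(agg2$radius, agg$radius)
  # degenerate mixture: equal densities stay put
  same <- heteroaggregate_properties(plastic_particle(6e-6, 1200),
                                     natural_particle("colloid", 1e-7, 1200))
  expect_equal(same$density, 1200)
  # limit: a huge bead dominates the mixture
  big <- heteroaggregate_properties(plastic_particle(1e-3, 900), s)
  expect_equal(big$density, 900, tolerance = 1e-6)
  # density is always a convex combination
  for (rb in c(1e-6, 1e-5, 1e-4)) {
    a <- heteroaggregate_properties(plastic_particle(rb, 870), s)
    expect_gte(a$density, 870)
    expect_lte(a$density, 2500)
  }
})

test_that("critical settling radius matches the closed form", {
  spm <- natural_particle("coarse_spm", 3e-6, 2500)
  expect_equal(critical_settling_radius(960, spm, 1000), 10.0417e-6,
               tolerance = 1e-4)
  expect_equal(critical_settling_radius(854, spm, 1000), 6.5219e-6,
               tolerance = 1e-4)
  # approaching neutral polymer density the cutoff diverges
  expect_gt(critical_settling_radius(999.9, spm, 1000), 50e-6)
  expect_gt(critical_settling_radius(999.999, spm, 1000),
            critical_settling_radius(999.9, spm, 1000))
  expect_error(critical_settling_radius(1100, spm, 1000), "buoyant")
  expect_error(critical_settling_radius(900,
                                        natural_particle("colloid", 1e-7, 950),
                                        1000), "denser")
})

test_that("critical radius is consistent with the sedimentation rate", {
  l <- toy_landscape()
  water <- l$compartments[l$compartments$id == "water", ]
  spm <- natural_particle("coarse_spm", 3e-6, 2500)
  for (rho in c(860, 900, 950, 990)) {
    rstar <- critical_settling_radius(rho, spm, 1000)
    for (f in c(0.5, 0.9, 0.999, 1.001, 1.1, 2)) {
      p <- plastic_particle(f * rstar, rho, alpha_het = 0.1)
      k <- sedimentation_rate(water, "coarse_attached", p, l)
      if (f < 1 - 1e-6) expect_gt(k, 0)
      if (f > 1 + 1e-6) expect_equal(k, 0)
    }
    # the free buoyant bead never settles
    p <- plastic_particle(100e-6, rho)
    expect_equal(sedimentation_rate(water, "free", p, l), 0)
  }
})

test_that("collision rate coefficient sums the three kernels", {
  kB <- 1.380649e-23
  # equal radii, no shear, equal velocities: Brownian reduces to 8kT/(3 mu)
  expect_equal(collision_rate_coefficient(1e-6, 1e-6, 0, 0, 293, 1e-3, 0),
               8 * kB * 293 / (3 * 1e-3), tolerance = 1e-12)
  expect_equal(collision_rate_coefficient(1e-6, 1e-6, 0, 0, 293, 1e-3, 0),
               1.0785e-17, tolerance = 1e-4)
  # T -> 0 with no shear and equal velocities: everything vanishes
  expect_equal(collision_rate_coefficient(1e-6, 2e-6, 1e-5, 1e-5, 0, 1e-3, 0),
               0)
  # differential settling adds pi (r1+r2)^2 |dv| exactly
  base <- collision_rate_coefficient(1e-6, 3e-6, 0, 0, 285, 1e-3, 10)
  with_dv <- collision_rate_coefficient(1e-6, 3e-6, 0, 2e-5, 285, 1e-3, 10)
  expect_equal(with_dv - base, pi * (4e-6)^2 * 2e-5, tolerance = 1e-10)
  # symmetry in the two particles
  expect_equal(collision_rate_coefficient(1e-6, 5e-6, 1e-6, 3e-5, 285, 1e-3, 10),
               collision_rate_coefficient(5e-6, 1e-6, 3e-5, 1e-6, 285, 1e-3, 10))
  expect_error(collision_rate_coefficient(1e-6, 1e-6, 0, 0, 285, 1e-3, -1),
               "shear")
})

test_that("heteroaggregation rate is alpha x kernel x concentration", {
  comp <- list(temperature = 293, viscosity = 1e-3, medium_density = 1000,
               shear_rate = 0)
  host <- natural_particle("colloid", 1e-6, 1000, number_concentration = 1e10)
  # alpha = 0 boundary: no aggregation (list input bypasses the (0,1] check)
  p0 <- list(radius = 1e-6, density = 1000, alpha_het = 0)
  expect_equal(heteroaggregation_rate(p0, host, comp), 0)
  # alpha = 1 with the Brownian-only kernel: k = K * n
  p1 <- list(radius = 1e-6, density = 1000, alpha_het = 1)
  expect_equal(heteroaggregation_rate(p1, host, comp), 1.0785e-7,
               tolerance = 1e-4)
  # linear in host number concentration
  host2 <- natural_particle("colloid", 1e-6, 1000, 2e10)
  expect_equal(heteroaggregation_rate(p1, host2, comp),
               2 * heteroaggregation_rate(p1, host, comp))
  expect_error(
    heteroaggregation_rate(p1, list(radius = 1e-6, density = 1000), comp),
    "number_concentration")
})

test_that("air deposition combines settling, diffusion and washout", {
  l <- cached_default_landscape()
  air <- l$compartments[l$compartments$id == "regional_air", ]
  fw <- l$compartments[l$compartments$id == "regional_freshwater", ]
  p10 <- plastic_particle(10e-6, 1200)
  p100 <- plastic_particle(100e-6, 1200)
  k10 <- air_deposition_rates(p10, air, fw, l)
  k100 <- air_deposition_rates(p100, air, fw, l)
  # larger particles deposit faster in the super-micron regime
  expect_gt(k100[["k_dry"]], k10[["k_dry"]])
  # wet deposition does not depend on size
  expect_equal(k10[["k_wet"]], k100[["k_wet"]])
  expect_gt(k10[["k_wet"]], 0)
  # no rain, no washout
  dry_air <- air
  dry_air$rain_rate <- 0
  expect_equal(air_deposition_rates(p10, dry_air, fw, l)[["k_wet"]], 0)
  # the gravitational term is the Stokes settling velocity in air (the
  # Brownian term is negligible at 10 um)
  v_g <- settling_velocity(10e-6, 1200, air$medium_density, air$viscosity)
  k_expected <- v_g / air$depth * fw$area / air$area
  expect_equal(k10[["k_dry"]], k_expected, tolerance = 1e-3)
})

test_that("surface exchange rates are flux over inventory", {
  l <- cached_default_landscape()
  soil <- l$compartments[l$compartments$id == "regional_natural_soil", ]
  fw <- l$compartments[l$compartments$id == "regional_freshwater", ]
  ex <- surface_exchange_rates(soil, fw, l)
  rain <- l$compartments$rain_rate[l$compartments$id == "regional_air"]
  expect_equal(ex$rate[ex$process == "runoff"],
               0.25 * rain / (soil$depth * soil$water_content))
  expect_equal(ex$rate[ex$process == "erosion"],
               (0.03e-3 / 31557600) / soil$depth)

  sed <- l$compartments[l$compartments$id == "regional_freshwater_sediment", ]
  exs <- surface_exchange_rates(sed, fw, l)
  # burial = net accretion velocity / sediment depth
  expect_equal(exs$rate[exs$process == "burial"],
               sed$net_accretion / sed$depth)
  expect_gte(exs$rate[exs$process == "resuspension"], 0)
  expect_error(surface_exchange_rates(fw, soil, l), "neither")
})

test_that("advection rates are flow over source volume and oceans return", {
  l <- cached_default_landscape()
  adv <- advection_rates(l)
  expect_true(all(adv$rate >= 0))
  v_fw <- l$compartments$volume[l$compartments$id == "regional_freshwater"]
  k_riv <- adv$rate[adv$from == "regional_freshwater"]
  expect_equal(unname(k_riv), 215 / v_fw)
  # bidirectional ocean exchange: the global ocean is not a one-way sink
  expect_true(any(adv$from == "global_seawater" &
                    adv$to == "continental_seawater" & adv$flow > 0))
  # zero flows give zero constants
  l2 <- toy_landscape()
  expect_equal(nrow(advection_rates(l2)), 0)
})
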