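# Stochastic scenario inputs: triangular draws, particle sampling, STP
# routing.

test_that("triangular draws have the analytic mean and respect bounds", {
  spec <- triangular_spec(0, 1, 2)
  set.seed(1)
  x <- rtriangular(2e4, spec)
  expect_true(all(x >= 0 & x <= 2))
  # mean = (low + mode + high) / 3, within 3 sigma / sqrt(n)
  sdx <- sd(x)
  expect_lt(abs(mean(x) - 1), 3 * sdx / sqrt(length(x)))
  # degenerate spec is a constant
  expect_equal(rtriangular(10, triangular_spec(3, 3, 3)), rep(3, 10))
  # inverse CDF returns the mode at its own cumulative probability
  s2 <- triangular_spec(2, 5, 11)
  f_mode <- (5 - 2) / (11 - 2)
  expect_equal(qtriangular(f_mode, s2), 5)
  expect_equal(qtriangular(c(0, 1), s2), c(2, 11))
  expect_error(triangular_spec(2, 1, 3), "low <= mode <= high")
})

test_that("sampled particle properties cover the configured box", {
  sc <- cached_default_scenario()
  set.seed(2)
  draws <- sample_particle_properties(2e4, sc)
  r_um <- draws$radius * 1e6
  expect_true(all(r_um >= 1 & r_um <= 625))
  expect_true(all(draws$density >= 854 & draws$density <= 1302))
  expect_true(all(draws$alpha >= 1e-4 & draws$alpha <= 1))
  # both halves of the radius range are hit
  expect_gt(sum(r_um < 313), 1000)
  expect_gt(sum(r_um > 313), 1000)
  # uniform density: fraction below water density = (1000-854)/(1302-854)
  frac <- mean(draws$density < 1000)
  expect_equal(frac, 0.3259, tolerance = 0.03)
  # log-uniform alpha: half the draws below the geometric midpoint
  expect_equal(mean(draws$alpha < 1e-2), 0.5, tolerance = 0.03)
})

test_that("removal constants stay in range, air is zero, media independent", {
  sc <- cached_default_scenario()
  set.seed(3)
  k <- sample_removal_constants(2e4, sc)
  for (cls in c("water", "sediment", "soil")) {
    v <- k[[paste0("k_frag_", cls)]]
    expect_true(all(v >= 1.6e-9 & v <= 1.3e-7))
  }
  # independence across media: correlation compatible with zero
  expect_lt(abs(cor(k$k_frag_water, k$k_frag_soil)), 3 / sqrt(nrow(k)))
  # a particle built from the draws has zero air removal
  p <- plastic_particle(1e-5, 1000,
                        k_frag = c(water = k$k_frag_water[1],
                                   sediment = k$k_frag_sediment[1],
                                   soil = k$k_frag_soil[1]))
  expect_equal(fragmentation_degradation_rate(p, "air"), 0)
})

test_that("STP routing splits sewage and conserves mass", {
  l <- cached_default_landscape()
  sc <- cached_default_scenario()
  flows <- c("PCCP.sewage.regional" = 10)
  # efficiency 0.5, sludge share 0.5 of captured: 5 t/y effluent,
  # 2.5 t/y sludge, 2.5 t/y destroyed
  sc_even <- sc
  routed <- route_emissions_via_stp(flows, 0.5, sc_even, l)
  em <- routed$emissions
  kg <- tonnes_per_year_to_kg_s(10)
  expect_equal(em$kg_s[em$compartment_id == "regional_freshwater"], 0.5 * kg)
  expect_equal(em$kg_s[em$compartment_id == "regional_agricultural_soil"],
               0.25 * kg)
  expect_equal(routed$removed_kg_s, 0.25 * kg)
  # fraction bookkeeping: effluent 0.1, sludge 0.45, removed 0.45
  routed2 <- route_emissions_via_stp(flows, 0.9, sc_even, l)
  expect_equal(sum(routed2$emissions$kg_s) + routed2$removed_kg_s, kg,
               tolerance = 1e-12)
  # zero sewage contributes nothing
  routed0 <- route_emissions_via_stp(c("PCCP.sewage.regional" = 0), 0.9,
                                     sc_even, l)
  expect_equal(nrow(routed0$emissions), 0)
  # unknown route rejected
  expect_error(route_emissions_via_stp(c("x.pipeline.regional" = 1), 0.9,
                                       sc_even, l), "route")
  # mass conservation across a full random draw
  set.seed(4)
  fl <- as.matrix(sample_emission_rates(1, sc))[1, ]
  routed3 <- route_emissions_via_stp(fl, 0.93, sc, l)
  expect_equal(sum(routed3$emissions$kg_s) + routed3$removed_kg_s,
               tonnes_per_year_to_kg_s(sum(fl)), tolerance = 1e-12)
})

test_that("scenario sampling is reproducible under a fixed seed", {
  sc <- cached_default_scenario()
  set.seed(7); a <- sample_particle_properties(100, sc)
  set.seed(7); b <- sample_particle_properties(100, sc)
  expect_identical(a, b)
  set.seed(7); e1 <- sample_emission_rates(50, sc)
  set.seed(7); e2 <- sample_emission_rates(50, sc)
  expect_identical(e1, e2)
})

test_that("scenario loading validates its blocks", {
  expect_error(load_scenario(list(particle = NULL)), "particle")
  sc <- cached_default_scenario()
  expect_s3_class(sc, "sb_scenario")
  expect_setequal(unique(sc$sectors$sector),
                  c("abrasives", "PCCP", "paints_coatings",
                    "soaps_detergents", "agriculture", "oil_gas"))
  expect_true(all(sc$sectors$low <= sc$sectors$mode &
                    sc$sectors$mode <= sc$sectors$high))
})
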