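# Monte Carlo engine, sensitivity, percentiles, counterfactual.

make_fake_run <- function(inputs, outputs) {
  structure(list(inputs = inputs, outputs = outputs,
                 failures = tibble::tibble(iteration = integer()),
                 n = nrow(inputs), seed = 0L, config_hash = "x"),
            class = "sb_mc_run")
}

test_that("a fully degenerate scenario collapses onto a deterministic run", {
  l <- cached_default_landscape()
  sc <- degenerate_scenario(radius_um = 5, density = 1200, alpha = 0.01,
                            k_frag = 2.7e-8, tonnage = 10)
  run <- run_monte_carlo(l, sc, n = 1, seed = 123)
  expect_equal(nrow(run$failures), 0)
  # manual single evaluation of the same sample
  p <- plastic_particle(5e-6, 1200, 0.01, k_frag = 2.7e-8)
  e <- tibble::tibble(compartment_id = "regional_freshwater",
                      kg_s = tonnes_per_year_to_kg_s(10))
  pec <- concentrations_from_masses(
    steady_state_masses(assemble_system(l, p), e), l, p)
  tot <- total_particulate_pec(pec)
  got <- run$outputs[order(run$outputs$compartment_id), ]
  want <- tot[order(tot$compartment_id), ]
  expect_equal(got$mass_total, want$mass_concentration, tolerance = 1e-10)
  expect_equal(got$number_total, want$number_concentration,
               tolerance = 1e-10)
})

test_that("runs with the same seed reproduce both tables exactly", {
  l <- cached_default_landscape()
  sc <- cached_default_scenario()
  r1 <- run_monte_carlo(l, sc, n = 40, seed = 9)
  r2 <- run_monte_carlo(l, sc, n = 40, seed = 9)
  expect_identical(r1$inputs, r2$inputs)
  expect_identical(r1$outputs, r2$outputs)
  r3 <- run_monte_carlo(l, sc, n = 40, seed = 10)
  expect_false(identical(r1$inputs, r3$inputs))
})

test_that("per-iteration totals equal the three-species sum", {
  l <- cached_default_landscape()
  run <- run_monte_carlo(l, cached_default_scenario(), n = 25, seed = 5)
  with(run$outputs,
       expect_equal(mass_total, mass_free + mass_colloid + mass_coarse))
  expect_true(all(run$outputs$mass_total >= 0, na.rm = TRUE))
})

test_that("iterations without a steady state are recorded, not dropped", {
  l <- cached_default_landscape()
  # buoyant bead above the settling cutoff with zero removal: the water
  # cycle keeps every emitted kilogram
  sc <- degenerate_scenario(radius_um = 100, density = 900, alpha = 0.01,
                            k_frag = 0, k_deg = 0)
  expect_error(run_monte_carlo(l, sc, n = 3, seed = 1),
               "failed")
  run <- suppressWarnings(
    run_monte_carlo(l, sc, n = 3, seed = 1, max_failure_fraction = 1))
  expect_equal(nrow(run$failures), 3)
  expect_true(all(is.na(run$outputs$mass_total)))
})

test_that("spearman sensitivity reproduces textbook rank correlations", {
  inputs <- tibble::tibble(iteration = 1:4, x = c(1, 2, 3, 4))
  outputs <- tibble::tibble(iteration = 1:4, compartment_id = "c",
                            scale = "regional", medium = "freshwater",
                            basis = "volume",
                            mass_total = c(2, 1, 4, 3))
  run <- make_fake_run(inputs, outputs)
  s <- spearman_sensitivity(run, "c", parameters = "x")
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 4
  expect_equal(s$rho, 0.6)
  # strictly monotone increasing -> 1; reversed -> -1
  outputs$mass_total <- exp(inputs$x)
  expect_equal(spearman_sensitivity(make_fake_run(inputs, outputs), "c",
                                    parameters = "x")$rho, 1)
  outputs$mass_total <- c(9, 4, 1, 0.5)
  expect_equal(spearman_sensitivity(make_fake_run(inputs, outputs), "c",
                                    parameters = "x")$rho, -1)
  # zero-variance input: undefined, reported NA (not 0)
  inputs$flat <- 1
  outputs$mass_total <- c(2, 1, 4, 3)
  s2 <- spearman_sensitivity(make_fake_run(inputs, outputs), "c",
                             parameters = "flat")
  expect_true(is.na(s2$rho))
})

test_that("percentile summary interpolates order statistics", {
  inputs <- tibble::tibble(iteration = 1:100)
  outputs <- tibble::tibble(iteration = 1:100, compartment_id = "c",
                            scale = "regional", medium = "freshwater",
                            basis = "volume",
                            mass_total = as.numeric(1:100),
                            number_total = as.numeric(1:100))
  run <- make_fake_run(inputs, outputs)
  ps <- percentile_summary(run)
  expect_equal(ps$p50[ps$quantity == "mass_total"], 50.5)
  expect_true(all(ps$p5 <= ps$p50 & ps$p50 <= ps$p95))
  # constant output: all percentiles equal
  outputs$mass_total <- outputs$number_total <- 7
  ps2 <- percentile_summary(make_fake_run(inputs, outputs))
  expect_true(all(ps2$p5 == 7 & ps2$p50 == 7 & ps2$p95 == 7))
  expect_error(percentile_summary(run, levels = c(-5, 50)), "levels")
})

test_that("summaries and sensitivities are invariant to iteration order", {
  l <- cached_default_landscape()
  run <- run_monte_carlo(l, cached_default_scenario(), n = 30, seed = 21)
  perm_out <- sample(nrow(run$outputs))
  perm_in <- sample(nrow(run$inputs))
  shuffled <- run
  shuffled$outputs <- run$outputs[perm_out, ]
  shuffled$inputs <- run$inputs[perm_in, ]
  ps1 <- percentile_summary(run)
  ps2 <- percentile_summary(shuffled)
  expect_equal(ps1, ps2)
  s1 <- spearman_sensitivity(run, "regional_freshwater")
  s2 <- spearman_sensitivity(shuffled, "regional_freshwater")
  expect_equal(s1, s2)
})

test_that("zero-removal counterfactual: dissipative case and trapped case", {
  l <- toy_landscape()
  e <- tibble::tibble(compartment_id = "water",
                      kg_s = tonnes_per_year_to_kg_s(1))
  # dense bead: settling + burial still remove mass when frag/deg is zero
  p_dense <- plastic_particle(50e-6, 1400, 0.01, k_frag = 2.7e-8)
  cf <- zero_removal_counterfactual(l, p_dense, e)
  expect_false(cf$singular)
  expect_true(all(cf$ratio$log10_ratio >= -1e-9))
  # buoyant bead above the cutoff: no removal path at all -> unbounded
  p_buoy <- plastic_particle(100e-6, 900, 0.01, k_frag = 2.7e-8)
  horizon <- 3.15576e13   # one million years
  cf2 <- zero_removal_counterfactual(l, p_buoy, e, horizon = horizon)
  expect_true(cf2$singular)
  # everything emitted is retained: total mass ~ E * t
  total <- sum(cf2$mass_at_horizon$mass)
  expect_equal(total, tonnes_per_year_to_kg_s(1) * horizon,
               tolerance = 0.01)
})

test_that("an end-to-end run on the generated toy fixtures succeeds", {
  dir <- withr::local_tempdir()
  paths <- generate_fixtures("toy", dir)
  l <- load_landscape(paths[1])
  sc <- load_scenario(paths[2])
  run <- run_monte_carlo(l, sc, n = 20, seed = 2)
  expect_equal(nrow(run$failures), 0)
  expect_equal(nrow(run$outputs), 20 * 2)
  ps <- percentile_summary(run)
  expect_true(all(ps$p5 <= ps$p95))
})
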