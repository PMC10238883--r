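## Monte Carlo propagation of scenario uncertainty to PECs.

#' Run the Monte Carlo uncertainty propagation
#'
#' For each iteration: sample particle properties, per-medium removal
#' constants, STP efficiency and sector tonnages; route the emissions;
#' assemble the system matrix; solve the steady state; and record the
#' per-compartment PECs split over the three species forms.  Iterations
#' whose system has no steady state are recorded as failures (with `NA`
#' outputs), never silently dropped.
#'
#' @param landscape An `sb_landscape`.
#' @param scenario An `sb_scenario`.
#' @param n Number of iterations (>= 1).
#' @param seed Integer RNG seed; the full run is reproducible from
#'   (scenario, landscape, n, seed).
#' @param max_failure_fraction Error if more than this fraction of
#'   iterations fails (default 1%).
#' @param quiet If `FALSE`, report progress every 1000 iterations.
#' @return An object of class `sb_mc_run`: list with `inputs` (one row per
#'   iteration), `outputs` (one row per iteration x compartment with mass
#'   and number PECs), `failures`, `n`, `seed`, `config_hash`.
#' @export
run_monte_carlo <- function(landscape, scenario, n, seed,
                            max_failure_fraction = 0.01, quiet = TRUE) {
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(as.integer(seed))
  ctx <- prepare_system_context(landscape)

  particles <- sample_particle_properties(n, scenario)
  removals <- sample_removal_constants(n, scenario)
  stp_eff <- rtriangular(n, scenario$stp$efficiency)
  emissions_raw <- sample_emission_rates(n, scenario)

  inputs <- dplyr::bind_cols(
    tibble(iteration = seq_len(n)),
    particles, removals, tibble(stp_efficiency = stp_eff), emissions_raw)

  comps <- landscape$compartments
  n_comp <- nrow(comps)
  dry <- comps$class %in% c("soil", "sediment")
  denom <- ifelse(dry, comps$volume * comps$dry_bulk_density, comps$volume)

  mass_conc <- array(NA_real_, dim = c(n, n_comp, 3))
  failures <- integer(0)
  flow_mat <- as.matrix(emissions_raw)
  router <- .compile_emission_router(scenario, landscape, ctx)

  for (it in seq_len(n)) {
    particle <- plastic_particle(
      radius = particles$radius[it], density = particles$density[it],
      alpha_het = particles$alpha[it],
      k_frag = c(water = removals$k_frag_water[it],
                 sediment = removals$k_frag_sediment[it],
                 soil = removals$k_frag_soil[it]),
      k_deg = c(water = removals$k_deg_water[it],
                sediment = removals$k_deg_sediment[it],
                soil = removals$k_deg_soil[it]))
    e <- router(flow_mat[it, ], stp_eff[it])
    sys <- assemble_system(ctx, particle, audit = FALSE)
    m <- .steady_state_core(sys$A, e)
    if (is.null(m)) {
      failures <- c(failures, it)
    } else {
      ## states are compartment-major with form fastest
      mm <- matrix(m, nrow = 3L)
      mass_conc[it, , ] <- t(mm) / denom
    }
    if (!quiet && it %% 1000 == 0)
      message(sprintf("iteration %d / %d (%d failures)", it, n,
                      length(failures)))
  }
  if (length(failures) > max_failure_fraction * n)
    abort(sprintf("%d of %d Monte Carlo iterations failed (no steady state).",
                  length(failures), n))
  if (length(failures))
    warn(sprintf("%d of %d Monte Carlo iterations had no steady state; recorded as NA.",
                 length(failures), n))

  bead_mass <- sphere_mass(particles$radius, particles$density)
  total <- mass_conc[, , 1] + mass_conc[, , 2] + mass_conc[, , 3]
  if (n == 1) total <- matrix(total, nrow = 1)
  outputs <- tibble(
    iteration = rep(seq_len(n), times = n_comp),
    compartment_id = rep(comps$id, each = n),
    scale = rep(comps$scale, each = n),
    medium = rep(comps$medium, each = n),
    basis = rep(ifelse(dry, "dry_weight", "volume"), each = n),
    mass_free = as.numeric(mass_conc[, , 1]),
    mass_colloid = as.numeric(mass_conc[, , 2]),
    mass_coarse = as.numeric(mass_conc[, , 3]),
    mass_total = as.numeric(total),
    number_total = as.numeric(total / bead_mass)
  )

  structure(list(
    inputs = inputs, outputs = outputs,
    failures = tibble(iteration = failures),
    n = n, seed = as.integer(seed),
    config_hash = rlang::hash(list(scenario = unclass(scenario),
                                   landscape = unclass(landscape), n = n))
  ), class = "sb_mc_run")
}

## Precompiled form of route_emissions_via_stp(): maps a row of raw sector
## tonnages plus an STP efficiency straight onto a per-state emission
## vector.  Kept numerically identical to the public routing operation
## (asserted in the tests).
.compile_emission_router <- function(scenario, landscape, ctx) {
  sectors <- scenario$sectors
  comp_for <- function(scale, medium) {
    id <- landscape$compartments$id[
      landscape$compartments$scale == scale &
        landscape$compartments$medium == medium]
    if (!length(id))
      abort(sprintf("landscape has no `%s` compartment at scale `%s`",
                    medium, scale))
    id[1]
  }
  share <- scenario$stp$sludge_application_fraction
  col <- integer(0); st <- integer(0); type <- integer(0)
  for (k in seq_len(nrow(sectors))) {
    scale <- sectors$scale[k]
    dest <- switch(sectors$route[k],
      air = list(c(comp_for(scale, "air"), 0L)),
      freshwater_direct = list(c(comp_for(scale, "freshwater"), 0L)),
      industrial_soil = list(c(comp_for(scale, "industrial_soil"), 0L)),
      agricultural_soil = list(c(comp_for(scale, "agricultural_soil"), 0L)),
      sewage = list(c(comp_for(scale, "freshwater"), 1L),
                    c(comp_for(scale, "agricultural_soil"), 2L)))
    for (d in dest) {
      col <- c(col, k)
      st <- c(st, ctx$idx[d[1], "free"])
      type <- c(type, as.integer(d[2]))
    }
  }
  conv <- .const$tonnes_per_year_to_kg_s
  n <- ctx$n
  function(flows, stp_efficiency) {
    fac <- ifelse(type == 0L, 1,
                  ifelse(type == 1L, 1 - stp_efficiency,
                         stp_efficiency * share))
    contrib <- flows[col] * conv * fac
    e <- numeric(n)
    for (q in seq_along(contrib)) e[st[q]] <- e[st[q]] + contrib[q]
    e
  }
}

#' @export
print.sb_mc_run <- function(x, ...) {
  cat(sprintf("<sb_mc_run> %d iterations, seed %d, %d failures, %d compartments\n",
              x$n, x$seed, nrow(x$failures),
              length(unique(x$outputs$compartment_id))))
  invisible(x)
}

#' Spearman rank sensitivity of a PEC to the sampled inputs
#'
#' Spearman rank correlation (Pearson correlation of average ranks, ties
#' receiving average ranks) between one model output -- the total
#' particulate PEC of a compartment, mass- or number-based -- and each
#' sampled input parameter.  An input with zero variance has no defined
#' rank correlation and is reported as `NA`, not 0.
#'
#' @param run An `sb_mc_run`.
#' @param target Compartment id whose PEC is the response.
#' @param quantity Output column, default `"mass_total"`.
#' @param parameters Input columns to correlate (default: all sampled
#'   inputs).
#' @param subset Optional logical vector over iterations (e.g. only
#'   low-density beads, only non-zero PECs).
#' @return A tibble `parameter`, `rho`, `n_used`.
#' @examples
#' cor(rank(c(1, 2, 3, 4)), rank(c(2, 1, 4, 3)))  # the rho = 0.6 example
#' @export
spearman_sensitivity <- function(run, target, quantity = "mass_total",
                                 parameters = NULL, subset = NULL) {
  y_tbl <- run$outputs[run$outputs$compartment_id == target, ]
  if (!nrow(y_tbl)) abort(sprintf("unknown target compartment `%s`", target))
  y <- y_tbl[[quantity]][order(y_tbl$iteration)]
  inputs <- run$inputs[order(run$inputs$iteration), ]
  if (is.null(parameters))
    parameters <- setdiff(names(inputs), "iteration")
  keep <- !is.na(y)
  if (!is.null(subset)) keep <- keep & subset
  if (sum(keep) < 3)
    abort("need at least 3 usable iterations for a rank correlation.")
  rho <- vapply(parameters, function(p) {
    x <- inputs[[p]][keep]
    if (length(unique(x)) < 2 || length(unique(y[keep])) < 2)
      return(NA_real_)
    cor(x, y[keep], method = "spearman")
  }, numeric(1))
  tibble(parameter = parameters, rho = unname(rho), n_used = sum(keep))
}

#' Percentile summary of Monte Carlo PECs
#'
#' Empirical percentiles (linear interpolation of order statistics) of the
#' total mass and number PEC per compartment; the conventional reporting
#' levels are the 50th with a 5th-95th range.
#'
#' @param run An `sb_mc_run`.
#' @param levels Percentile levels in [0, 100].
#' @return A tibble: compartment x quantity, one column per level
#'   (`p5`, `p50`, ...).
#' @export
percentile_summary <- function(run, levels = c(5, 50, 95)) {
  if (any(levels < 0 | levels > 100))
    abort("percentile `levels` must lie in [0, 100].")
  levels <- sort(levels)
  long <- tidyr::pivot_longer(
    run$outputs[, c("iteration", "compartment_id", "scale", "medium",
                    "basis", "mass_total", "number_total")],
    cols = c("mass_total", "number_total"),
    names_to = "quantity", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$compartment_id, .data$scale, .data$medium,
                    .data$basis, .data$quantity) |>
    dplyr::summarise(
      value = list(quantile(.data$value, probs = levels / 100, na.rm = TRUE,
                            names = FALSE)),
      .groups = "drop")
  qcols <- as_tibble(setNames(
    as.data.frame(do.call(rbind, out$value)),
    paste0("p", levels)))
  dplyr::bind_cols(out[, setdiff(names(out), "value")], qcols)
}

#' Zero-removal counterfactual
#'
#' Re-solves one scenario sample with all fragmentation and degradation
#' constants set to zero and compares the steady states.  For particles
#' whose only parameterised removal from the water cycle is
#' fragmentation/degradation (buoyant beads above the heteroaggregate
#' settling cutoff), the zeroed system has no steady state: mass
#' accumulates without bound, which is reported through the
#' `singular` flag together with the dynamically integrated mass at a
#' finite horizon.
#'
#' @param landscape An `sb_landscape`.
#' @param particle A [plastic_particle()] (with its default removal
#'   constants set).
#' @param emissions Emissions accepted by [build_emission_vector()].
#' @param horizon Horizon (s) at which the zeroed system's mass is
#'   reported when it has no steady state; default one million years.
#' @return A list of class `sb_counterfactual`: `singular` (logical),
#'   `pec_default` and `pec_zero` (`sb_pec` tibbles; `pec_zero` is `NULL`
#'   when singular), `ratio` (per-compartment tibble with
#'   `log10_ratio` of total mass PECs; for the singular case the ratio at
#'   `horizon`), and `horizon`.
#' @export
zero_removal_counterfactual <- function(landscape, particle, emissions,
                                        horizon = 1e6 * .const$sec_per_year) {
  ctx <- prepare_system_context(landscape)
  sys_def <- assemble_system(ctx, particle, audit = FALSE)
  m_def <- steady_state_masses(sys_def, emissions)
  pec_def <- concentrations_from_masses(m_def, landscape, particle)

  p0 <- particle
  p0$k_frag[] <- 0
  p0$k_deg[] <- 0
  sys0 <- assemble_system(ctx, p0, audit = FALSE)

  m0 <- tryCatch(steady_state_masses(sys0, emissions),
                 plasticfate_singular = function(cnd) NULL)
  singular <- is.null(m0)
  if (singular) {
    traj <- dynamic_masses(sys0, emissions, times = horizon, method = "ode")
    m0 <- traj[, c("compartment_id", "form")]
    m0$mass <- traj$mass
    class(m0) <- c("sb_mass", class(m0))
    pec_zero <- NULL
  }
  pec0 <- concentrations_from_masses(m0, landscape, particle)
  if (!singular) pec_zero <- pec0

  tot_def <- total_particulate_pec(pec_def)
  tot0 <- total_particulate_pec(pec0)
  ratio <- dplyr::left_join(
    tot_def[, c("compartment_id", "scale", "medium", "mass_concentration")],
    tot0[, c("compartment_id", "mass_concentration")],
    by = "compartment_id", suffix = c("_default", "_zero"))
  ratio$log10_ratio <- log10(ratio$mass_concentration_zero /
                               ratio$mass_concentration_default)

  structure(list(singular = singular, pec_default = pec_def,
                 pec_zero = pec_zero, mass_at_horizon = if (singular) m0,
                 ratio = ratio, horizon = horizon),
            class = "sb_counterfactual")
}

#' @export
print.sb_counterfactual <- function(x, ...) {
  if (x$singular) {
    cat("<sb_counterfactual> zero-removal system has NO steady state",
        sprintf("(unbounded accumulation); ratios taken at t = %.3g years\n",
                x$horizon / .const$sec_per_year))
  } else {
    cat("<sb_counterfactual> both systems reach steady state\n")
  }
  print(x$ratio[, c("compartment_id", "log10_ratio")])
  invisible(x)
}
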