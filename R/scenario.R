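## The microbead case-study stochastic input model: uniform particle
## properties, triangular sector emissions with sewage-treatment routing,
## triangular fragmentation/degradation constants.

#' Triangular distribution specification and sampling
#'
#' `triangular_spec()` validates a (low, mode, high) triple; `rtriangular()`
#' draws from it by inverse-CDF transform of uniform variates, which keeps
#' the draws reproducible under a fixed RNG seed.  Degenerate
#' specifications (low = mode = high) are allowed and return the constant.
#'
#' @param low,mode,high The minimum, most likely and maximum value.
#' @return `triangular_spec()`: a list of class `sb_triangular`;
#'   `rtriangular()`: numeric draws; `qtriangular()`: quantiles.
#' @examples
#' spec <- triangular_spec(0, 1, 2)
#' mean(rtriangular(1e4, spec))  # ~ (0 + 1 + 2) / 3
#' @export
triangular_spec <- function(low, mode, high) {
  if (any(!is.finite(c(low, mode, high))))
    abort("triangular spec values must be finite.")
  if (low > mode || mode > high)
    abort(sprintf("triangular spec requires low <= mode <= high, got (%g, %g, %g).",
                  low, mode, high))
  structure(list(low = low, mode = mode, high = high),
            class = "sb_triangular")
}

#' @rdname triangular_spec
#' @param n Number of draws.
#' @param spec A `triangular_spec()`.
#' @export
rtriangular <- function(n, spec) {
  qtriangular(runif(n), spec)
}

#' @rdname triangular_spec
#' @param p Probabilities.
#' @export
qtriangular <- function(p, spec) {
  a <- spec$low; c_ <- spec$mode; b <- spec$high
  if (a == b) return(rep(a, length(p)))
  f <- (c_ - a) / (b - a)
  lower <- p < f
  q <- numeric(length(p))
  q[lower] <- a + sqrt(p[lower] * (b - a) * (c_ - a))
  q[!lower] <- b - sqrt((1 - p[!lower]) * (b - a) * (b - c_))
  q
}

#' Load an emission/uncertainty scenario
#'
#' A scenario document describes the stochastic inputs of the case study:
#' uniform ranges for particle radius, polymer density and attachment
#' efficiency; triangular low/best/high tonnages per emission sector,
#' route and scale; triangular fragmentation and degradation constants per
#' medium class; and the sewage-treatment-plant (STP) split of the sewage
#' route into effluent (to freshwater) and sludge (to agricultural soil).
#'
#' @param config Path to a YAML/JSON file or an equivalent list.
#' @return A validated list of class `sb_scenario`.
#' @export
load_scenario <- function(config) {
  if (is.character(config)) config <- .read_config(config)
  pr <- config$particle %||% abort("scenario is missing a `particle` block.")
  rng <- function(block, what) {
    lo <- as.numeric(block$min %||% abort(sprintf("`%s` needs `min`", what)))
    hi <- as.numeric(block$max %||% abort(sprintf("`%s` needs `max`", what)))
    if (lo > hi) abort(sprintf("`%s`: min > max", what))
    list(min = lo, max = hi, scale = block$scale %||% "linear")
  }
  particle <- list(
    radius_um = rng(pr$radius_um, "particle$radius_um"),
    density_kg_m3 = rng(pr$density_kg_m3, "particle$density_kg_m3"),
    alpha_het = rng(pr$alpha_het, "particle$alpha_het")
  )

  tri <- function(block, what) {
    triangular_spec(
      as.numeric(block$low %||% abort(sprintf("`%s` needs `low`", what))),
      as.numeric(block$mode %||% block$best %||%
                   abort(sprintf("`%s` needs `mode`/`best`", what))),
      as.numeric(block$high %||% abort(sprintf("`%s` needs `high`", what))))
  }
  rem <- config$removal %||% abort("scenario is missing a `removal` block.")
  removal <- list(k_frag = tri(rem$k_frag_per_s, "removal$k_frag_per_s"),
                  k_deg = tri(rem$k_deg_per_s, "removal$k_deg_per_s"))

  stp_cfg <- config$stp %||% abort("scenario is missing an `stp` block.")
  stp <- list(
    efficiency = tri(stp_cfg$efficiency, "stp$efficiency"),
    sludge_application_fraction =
      as.numeric(stp_cfg$sludge_application_fraction %||% 0.5)
  )
  if (stp$sludge_application_fraction < 0 ||
      stp$sludge_application_fraction > 1)
    abort("`stp$sludge_application_fraction` must be in [0, 1].")

  routes <- c("air", "freshwater_direct", "sewage", "industrial_soil",
              "agricultural_soil")
  sectors <- purrr::map_dfr(
    config$sectors %||% abort("scenario is missing `sectors`."),
    function(s) {
      if (!s$route %in% routes)
        abort(sprintf("sector `%s`: unknown route `%s`", s$name, s$route))
      if (!s$scale %in% c("regional", "continental"))
        abort(sprintf("sector `%s`: unknown scale `%s`", s$name, s$scale))
      spec <- tri(s, sprintf("sector %s/%s/%s", s$name, s$route, s$scale))
      tibble(sector = s$name, route = s$route, scale = s$scale,
             low = spec$low, mode = spec$mode, high = spec$high)
    })

  structure(list(name = config$name %||% "scenario", particle = particle,
                 removal = removal, stp = stp, sectors = sectors),
            class = "sb_scenario")
}

#' Packaged synthetic microbead scenario
#'
#' Loads the packaged microbead emission scenario.  The sector tonnages
#' are a synthetic reconstruction (see the fixture file and the methods
#' vignette): they reproduce the published structure of the inventory --
#' six sectors, routes to air/water/sewage/soils, an industrial regional
#' mix versus a more balanced continental mix -- with magnitudes chosen to
#' match the qualitative behaviour reported for the case study, not
#' transcribed from the original supporting tables.
#'
#' @return An `sb_scenario`.
#' @export
default_scenario <- function() {
  load_scenario(system.file("extdata", "scenario_microbeads_synthetic.yaml",
                            package = "plasticfate", mustWork = TRUE))
}

#' Sample particle properties
#'
#' Radius and polymer density are drawn from independent uniform
#' distributions over the configured ranges; the attachment efficiency is
#' drawn log-uniformly by default (it spans four orders of magnitude), with
#' `scale: linear` available in the scenario file.
#'
#' @param n Number of draws.
#' @param scenario An `sb_scenario`.
#' @return A tibble with columns `radius` (m), `density` (kg/m3), `alpha`.
#' @export
sample_particle_properties <- function(n, scenario) {
  pr <- scenario$particle
  draw <- function(r) {
    if (identical(r$scale, "log")) {
      if (r$min <= 0) abort("log-scale sampling requires a positive minimum.")
      exp(runif(n, log(r$min), log(r$max)))
    } else {
      runif(n, r$min, r$max)
    }
  }
  tibble(
    radius = draw(pr$radius_um) * 1e-6,
    density = draw(pr$density_kg_m3),
    alpha = draw(pr$alpha_het)
  )
}

#' Sample sector emission tonnages
#'
#' Independent triangular draws (inverse CDF) for every sector/route/scale
#' entry of the scenario, in tonnes per year.
#'
#' @param n Number of draws.
#' @param scenario An `sb_scenario` (or its `sectors` tibble).
#' @return A tibble with `n` rows; one column per sector entry, named
#'   `<sector>.<route>.<scale>`, unit t/y.
#' @export
sample_emission_rates <- function(n, scenario) {
  sectors <- if (inherits(scenario, "sb_scenario")) scenario$sectors
             else scenario
  draws <- lapply(seq_len(nrow(sectors)), function(k) {
    rtriangular(n, triangular_spec(sectors$low[k], sectors$mode[k],
                                   sectors$high[k]))
  })
  names(draws) <- paste(sectors$sector, sectors$route, sectors$scale,
                        sep = ".")
  tibble::as_tibble(draws)
}

#' Sample fragmentation and degradation constants
#'
#' The fragmentation constant is drawn from its triangular distribution
#' independently for the water, sediment and soil medium classes (the
#' compartments differ in mechanics and exposure); the degradation
#' constant likewise.  Air is always zero.
#'
#' @param n Number of draws.
#' @param scenario An `sb_scenario`.
#' @return A tibble with columns `k_frag_water`, `k_frag_sediment`,
#'   `k_frag_soil`, `k_deg_water`, `k_deg_sediment`, `k_deg_soil` (1/s).
#' @export
sample_removal_constants <- function(n, scenario) {
  out <- list()
  for (cls in c("water", "sediment", "soil")) {
    out[[paste0("k_frag_", cls)]] <- rtriangular(n, scenario$removal$k_frag)
  }
  for (cls in c("water", "sediment", "soil")) {
    out[[paste0("k_deg_", cls)]] <- rtriangular(n, scenario$removal$k_deg)
  }
  tibble::as_tibble(out)
}

#' Route raw sector flows to compartment emissions through the STP
#'
#' Direct routes map straight onto the receiving compartment of their
#' scale.  The sewage route is split by the sewage treatment plant: a
#' fraction `1 - efficiency` passes to freshwater with the effluent, and
#' of the captured fraction a configured share reaches agricultural soil
#' with applied sludge; the remainder (incinerated or landfilled sludge)
#' leaves the modelled system.  Tonnages are converted to kg/s at this
#' boundary.
#'
#' @param flows A named numeric vector of sector tonnages (t/y), names
#'   `<sector>.<route>.<scale>` as produced by [sample_emission_rates()]
#'   (one row).
#' @param stp_efficiency Fraction of sewage-borne plastic captured by the
#'   STP, in [0, 1].
#' @param scenario The `sb_scenario` (for the sludge application share).
#' @param landscape The `sb_landscape` receiving the emissions.
#' @return A list with `emissions` (tibble `compartment_id`, `kg_s`) and
#'   `removed_kg_s` (mass retained in the STP and taken out of the
#'   system).
#' @export
route_emissions_via_stp <- function(flows, stp_efficiency, scenario,
                                    landscape) {
  if (any(flows < 0)) abort("raw sector flows must be >= 0.")
  if (stp_efficiency < 0 || stp_efficiency > 1)
    abort("`stp_efficiency` must be in [0, 1].")
  parts <- strsplit(names(flows), ".", fixed = TRUE)
  comp_for <- function(scale, medium) {
    id <- landscape$compartments$id[
      landscape$compartments$scale == scale &
        landscape$compartments$medium == medium]
    if (!length(id))
      abort(sprintf("landscape has no `%s` compartment at scale `%s`",
                    medium, scale))
    id[1]
  }
  sludge_share <- scenario$stp$sludge_application_fraction
  acc <- list()
  removed <- 0
  push <- function(id, kg_s) {
    acc[[length(acc) + 1]] <<- tibble(compartment_id = id, kg_s = kg_s)
  }
  for (k in seq_along(flows)) {
    route <- parts[[k]][2]; scale <- parts[[k]][3]
    kg_s <- tonnes_per_year_to_kg_s(as.numeric(flows[k]))
    if (kg_s == 0) next
    switch(route,
      air = push(comp_for(scale, "air"), kg_s),
      freshwater_direct = push(comp_for(scale, "freshwater"), kg_s),
      industrial_soil = push(comp_for(scale, "industrial_soil"), kg_s),
      agricultural_soil = push(comp_for(scale, "agricultural_soil"), kg_s),
      sewage = {
        effluent <- (1 - stp_efficiency) * kg_s
        sludge <- stp_efficiency * sludge_share * kg_s
        push(comp_for(scale, "freshwater"), effluent)
        push(comp_for(scale, "agricultural_soil"), sludge)
        removed <- removed + (kg_s - effluent - sludge)
      },
      abort(sprintf("unknown route `%s`", route))
    )
  }
  emissions <- if (length(acc)) {
    dplyr::summarise(dplyr::group_by(dplyr::bind_rows(acc),
                                     .data$compartment_id),
                     kg_s = sum(.data$kg_s), .groups = "drop")
  } else {
    tibble(compartment_id = character(), kg_s = numeric())
  }
  list(emissions = emissions, removed_kg_s = removed)
}
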