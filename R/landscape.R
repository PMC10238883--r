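## Landscape configuration: nested scales of well-mixed compartments.

.landscape_param_defaults <- list(
  runoff_fraction            = 0.25,   # fraction of rainfall leaving soil as surface runoff
  erosion_mm_per_year        = 0.03,   # soil loss as eroded solids
  scavenging_ratio           = 2e5,    # washout ratio for wet deposition
  soil_attachment_rate_per_s = 1e-5,   # first-order attachment of mobile species to soil grains
  air_boundary_layer_m       = 1e-3,   # laminar layer for diffusive dry deposition
  air_heteroaggregation      = TRUE,   # aggregate with aerosol in air
  soil_water_content         = 0.2,    # volumetric water fraction of soil
  drag_model                 = "schiller_naumann"  # or "stokes"
)

.compartment_defaults <- function(medium) {
  cls <- .medium_class[[medium]]
  list(
    temperature_K      = 285,
    viscosity_Pa_s     = if (cls == "air") 1.81e-5 else 1.25e-3,
    medium_density_kg_m3 = switch(medium,
      air = 1.23,
      freshwater = 1000, freshwater_sediment = 1000,
      seawater = 1025, marine_sediment = 1025,
      1000),
    shear_rate_per_s   = switch(medium, freshwater = 10, seawater = 5, 0)
  )
}

#' Load and validate a landscape configuration
#'
#' A landscape is the 'unit world': a set of well-mixed compartments over
#' nested regional, continental and global scales, with per-compartment
#' geometry, medium properties and natural-particle classes, plus the
#' advective flows that link the scales.  Configurations are YAML or JSON
#' documents with unit-bearing keys (`area_m2`, `depth_m`, `radius_um`,
#' ...); all values are converted to SI at load time.
#'
#' @param config Path to a YAML or JSON document, or an equivalent nested
#'   list.
#' @param quiet If `FALSE`, print a one-line validation summary.
#' @return A validated object of class `sb_landscape`: a list with
#'   tibbles `compartments`, `particles` (natural-particle classes) and
#'   `flows` (advective links, m3/s) plus a `params` list of landscape-wide
#'   constants.
#' @seealso [default_landscape()], [toy_landscape()], [enumerate_states()]
#' @export
load_landscape <- function(config, quiet = TRUE) {
  if (is.character(config)) {
    config <- .read_config(config)
  }
  if (!is.list(config) || is.null(config$compartments))
    abort("landscape config must be a list with a `compartments` entry.")

  params <- modifyList(.landscape_param_defaults,
                       config$params %||% list())

  comps <- purrr::map_dfr(config$compartments, .parse_compartment)
  parts <- purrr::map_dfr(config$compartments, .parse_natural_particles)

  flows <- if (length(config$flows %||% list())) {
    purrr::map_dfr(config$flows, function(f) {
      tibble(from = f$from %||% abort("flow without `from`"),
             to   = f$to %||% abort("flow without `to`"),
             flow = as.numeric(f$flow_m3_per_s %||%
                                 abort("flow without `flow_m3_per_s`")))
    })
  } else {
    tibble(from = character(), to = character(), flow = numeric())
  }

  landscape <- structure(
    list(compartments = comps, particles = parts, flows = flows,
         params = params),
    class = "sb_landscape"
  )
  validate_landscape(landscape, quiet = quiet)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

.parse_compartment <- function(x) {
  id <- x$id %||% abort("compartment without `id`")
  medium <- x$medium %||% abort(sprintf("compartment `%s`: missing `medium`", id))
  if (!medium %in% .media)
    abort(sprintf("compartment `%s`: unknown medium `%s`", id, medium))
  scale <- x$scale %||% abort(sprintf("compartment `%s`: missing `scale`", id))
  if (!scale %in% .scales)
    abort(sprintf("compartment `%s`: unknown scale `%s`", id, scale))
  defs <- .compartment_defaults(medium)
  num <- function(key, default = NULL, required = FALSE) {
    v <- x[[key]] %||% default
    if (is.null(v)) {
      if (required) abort(sprintf("compartment `%s`: missing `%s`", id, key))
      return(NA_real_)
    }
    as.numeric(v)
  }
  area  <- num("area_m2", required = TRUE)
  depth <- num("depth_m", required = TRUE)
  if (!is.finite(area) || area <= 0)
    abort(sprintf("compartment `%s`: `area_m2` must be > 0", id))
  if (!is.finite(depth) || depth <= 0)
    abort(sprintf("compartment `%s`: `depth_m` must be > 0", id))
  cls <- .medium_class[[medium]]
  tibble(
    id = id, scale = scale, medium = medium, class = cls,
    area = area, depth = depth, volume = area * depth,
    temperature    = num("temperature_K", defs$temperature_K),
    viscosity      = num("viscosity_Pa_s", defs$viscosity_Pa_s),
    medium_density = num("medium_density_kg_m3", defs$medium_density_kg_m3),
    shear_rate     = num("shear_rate_per_s", defs$shear_rate_per_s),
    rain_rate      = num("rain_mm_per_year") * 1e-3 / .const$sec_per_year,
    dry_bulk_density = num("dry_bulk_density_kg_m3"),
    water_content  = num("water_content",
                         if (cls == "soil") .landscape_param_defaults$soil_water_content),
    net_accretion  = num("net_accretion_mm_per_year") * 1e-3 / .const$sec_per_year,
    sediment_partner = x$sediment_partner %||% NA_character_
  )
}

.parse_natural_particles <- function(x) {
  nps <- x$natural_particles %||% list()
  if (!length(nps)) return(tibble())
  purrr::map_dfr(nps, function(np) {
    kind <- np$kind %||% abort(sprintf("compartment `%s`: natural particle without `kind`", x$id))
    radius <- as.numeric(np$radius_um %||%
                           abort(sprintf("compartment `%s`: natural particle without `radius_um`", x$id))) * 1e-6
    density <- as.numeric(np$density_kg_m3 %||%
                            abort(sprintf("compartment `%s`: natural particle without `density_kg_m3`", x$id)))
    n <- if (!is.null(np$number_per_m3)) {
      as.numeric(np$number_per_m3)
    } else if (!is.null(np$mass_mg_per_L)) {
      # mg/L -> kg/m3 is *1e-3; divide by single-particle mass
      as.numeric(np$mass_mg_per_L) * 1e-3 / sphere_mass(radius, density)
    } else {
      abort(sprintf("compartment `%s`: natural particle `%s` needs `number_per_m3` or `mass_mg_per_L`",
                    x$id, kind))
    }
    tibble(compartment_id = x$id, kind = kind,
           label = np$label %||% kind,
           radius = radius, density = density, number_concentration = n)
  })
}

#' Validate a landscape
#'
#' Re-checks all structural invariants of an `sb_landscape`: positive
#' geometry, exact `volume = area * depth`, water/sediment pairing, flow
#' references and scale-area ordering.  Validation is idempotent: a loaded
#' landscape re-validates unchanged.
#'
#' @param landscape An `sb_landscape`.
#' @param quiet If `FALSE`, print a validation summary.
#' @return The landscape, invisibly unchanged, or an error naming the
#'   offending compartment and field.
#' @export
validate_landscape <- function(landscape, quiet = TRUE) {
  comps <- landscape$compartments
  if (!nrow(comps)) abort("landscape has no compartments.")
  if (anyDuplicated(comps$id))
    abort(sprintf("duplicated compartment id: %s",
                  comps$id[duplicated(comps$id)][1]))

  bad <- abs(comps$volume - comps$area * comps$depth) >
    1e-9 * pmax(comps$volume, 1)
  if (any(bad))
    abort(sprintf("compartment `%s`: volume != area * depth", comps$id[bad][1]))

  for (i in seq_len(nrow(comps))) {
    c_i <- comps[i, ]
    for (f in c("area", "depth", "volume", "temperature", "viscosity",
                "medium_density")) {
      v <- c_i[[f]]
      if (!is.finite(v) || v <= 0)
        abort(sprintf("compartment `%s`: `%s` must be positive and finite",
                      c_i$id, f))
    }
    if (c_i$class %in% c("soil", "sediment") &&
        (!is.finite(c_i$dry_bulk_density) || c_i$dry_bulk_density <= 0))
      abort(sprintf("compartment `%s`: soil/sediment needs positive `dry_bulk_density_kg_m3`",
                    c_i$id))
    if (c_i$class == "air" && (!is.finite(c_i$rain_rate) || c_i$rain_rate < 0))
      abort(sprintf("compartment `%s`: air compartment needs `rain_mm_per_year` >= 0",
                    c_i$id))
    if (c_i$class == "sediment" &&
        (!is.finite(c_i$net_accretion) || c_i$net_accretion < 0))
      abort(sprintf("compartment `%s`: sediment needs `net_accretion_mm_per_year` >= 0",
                    c_i$id))
  }

  ## every water compartment has exactly one sediment partner
  waters <- comps[comps$class == "water", ]
  for (i in seq_len(nrow(waters))) {
    w <- waters[i, ]
    if (is.na(w$sediment_partner))
      abort(sprintf("water compartment `%s` has no `sediment_partner`", w$id))
    p <- comps[comps$id == w$sediment_partner, ]
    if (!nrow(p))
      abort(sprintf("water compartment `%s`: sediment partner `%s` does not exist",
                    w$id, w$sediment_partner))
    if (p$class != "sediment")
      abort(sprintf("water compartment `%s`: partner `%s` is not a sediment",
                    w$id, p$id))
  }
  if (anyDuplicated(stats::na.omit(waters$sediment_partner)))
    abort("a sediment compartment is shared by two water compartments.")
  orphan <- setdiff(comps$id[comps$class == "sediment"],
                    waters$sediment_partner)
  if (length(orphan))
    abort(sprintf("sediment compartment `%s` has no water partner", orphan[1]))

  ## nesting: regional <= continental <= global by air (system) area
  air_area <- setNames(comps$area[comps$medium == "air"],
                       comps$scale[comps$medium == "air"])
  if (all(c("regional", "continental") %in% names(air_area)) &&
      air_area[["regional"]] > air_area[["continental"]])
    abort("regional system area exceeds continental system area.")
  if (all(c("continental", "global") %in% names(air_area)) &&
      air_area[["continental"]] > air_area[["global"]])
    abort("continental system area exceeds global system area.")

  ## flows reference known compartments of the same medium class; the
  ## special destination "sink" marks a terminal outflow
  fl <- landscape$flows
  for (i in seq_len(nrow(fl))) {
    if (!fl$from[i] %in% comps$id)
      abort(sprintf("flow %s -> %s: unknown compartment `%s`",
                    fl$from[i], fl$to[i], fl$from[i]))
    if (!is.finite(fl$flow[i]) || fl$flow[i] < 0)
      abort(sprintf("flow %s -> %s: flow must be finite and >= 0",
                    fl$from[i], fl$to[i]))
    if (identical(fl$to[i], "sink")) next
    if (!fl$to[i] %in% comps$id)
      abort(sprintf("flow %s -> %s: unknown compartment `%s`",
                    fl$from[i], fl$to[i], fl$to[i]))
    cls_from <- comps$class[comps$id == fl$from[i]]
    cls_to   <- comps$class[comps$id == fl$to[i]]
    if (cls_from != cls_to || !cls_from %in% c("air", "water"))
      abort(sprintf("flow %s -> %s: advective flows must link two air or two water compartments",
                    fl$from[i], fl$to[i]))
  }

  ## natural particles are physically sensible
  pp <- landscape$particles
  for (i in seq_len(nrow(pp))) {
    if (!is.finite(pp$radius[i]) || pp$radius[i] <= 0 ||
        !is.finite(pp$density[i]) || pp$density[i] <= 0 ||
        !is.finite(pp$number_concentration[i]) || pp$number_concentration[i] < 0)
      abort(sprintf("compartment `%s`: invalid natural particle `%s`",
                    pp$compartment_id[i], pp$kind[i]))
  }

  if (!quiet)
    message(sprintf("landscape OK: %d compartments over %d scales, %d flows",
                    nrow(comps), length(unique(comps$scale)), nrow(fl)))
  invisible(landscape)
}

#' @export
print.sb_landscape <- function(x, ...) {
  cat(sprintf("<sb_landscape> %d compartments over scales: %s\n",
              nrow(x$compartments),
              paste(unique(x$compartments$scale), collapse = ", ")))
  print(x$compartments[, c("id", "medium", "area", "depth", "volume")])
  invisible(x)
}

#' Packaged default landscape
#'
#' Loads the packaged default landscape: a three-scale (regional,
#' continental, global) system in the style of the EUSES regulatory
#' landscape, with the full eight-compartment set at the regional and
#' continental scales, air/seawater/marine-sediment/soil at the global
#' scale, no lake compartments, and bidirectional ocean-current exchange
#' between the scales.  All dimensions are documented in the fixture file
#' `inst/extdata/landscape_default.yaml`.
#'
#' @return An `sb_landscape`.
#' @export
default_landscape <- function() {
  load_landscape(system.file("extdata", "landscape_default.yaml",
                             package = "plasticfate", mustWork = TRUE))
}

#' Minimal two-compartment toy landscape
#'
#' One freshwater column over one sediment, with river outflow treated as
#' terminal.  Used throughout the tests and examples as the smallest valid
#' landscape.
#'
#' @param depth Water depth, m.
#' @param area Surface area, m2.
#' @return An `sb_landscape`.
#' @export
toy_landscape <- function(depth = 3, area = 1e6) {
  load_landscape(.toy_landscape_config(depth = depth, area = area))
}
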