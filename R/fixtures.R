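## Fixture generation: packaged default configs and minimal toy configs.

.toy_landscape_config <- function(depth = 3, area = 1e6) {
  list(
    compartments = list(
      list(id = "water", scale = "regional", medium = "freshwater",
           area_m2 = area, depth_m = depth,
           sediment_partner = "sediment",
           natural_particles = list(
             list(kind = "colloid", radius_um = 0.1, density_kg_m3 = 2000,
                  number_per_m3 = 1e13),
             list(kind = "coarse_spm", radius_um = 3, density_kg_m3 = 2500,
                  mass_mg_per_L = 15))),
      list(id = "sediment", scale = "regional", medium = "freshwater_sediment",
           area_m2 = area, depth_m = 0.03,
           dry_bulk_density_kg_m3 = 500,
           net_accretion_mm_per_year = 3)
    )
  )
}

.toy_scenario_config <- function() {
  list(
    name = "toy",
    particle = list(
      radius_um = list(min = 1, max = 625),
      density_kg_m3 = list(min = 854, max = 1302),
      alpha_het = list(min = 1e-4, max = 1, scale = "log")
    ),
    removal = list(
      k_frag_per_s = list(low = 1.6e-9, mode = 2.7e-8, high = 1.3e-7),
      k_deg_per_s = list(low = 3e-11, mode = 3e-10, high = 3e-9)
    ),
    stp = list(efficiency = list(low = 0.85, mode = 0.95, high = 0.99),
               sludge_application_fraction = 0.5),
    ## same structure as the packaged sector table, shrunk to two sectors
    sectors = list(
      list(name = "PCCP", route = "freshwater_direct", scale = "regional",
           low = 1, best = 10, high = 50),
      list(name = "abrasives", route = "freshwater_direct",
           scale = "regional", low = 0, best = 2, high = 20)
    )
  )
}

#' Generate configuration fixtures
#'
#' Writes ready-to-run configuration files: `kind = "toy"` emits a minimal
#' two-compartment landscape plus a two-sector scenario with the same
#' structure as the full sector table (for tests and quick starts);
#' `kind = "default"` copies the packaged default landscape and the
#' synthetic microbead scenario.  Regeneration is idempotent: the emitted
#' bytes are identical on every call.
#'
#' @param kind `"toy"` or `"default"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(kind = c("toy", "default"), dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "toy") {
    paths <- file.path(dir, c("landscape_toy.yaml", "scenario_toy.yaml"))
    yaml::write_yaml(.toy_landscape_config(), paths[1])
    yaml::write_yaml(.toy_scenario_config(), paths[2])
  } else {
    src <- system.file("extdata",
                       c("landscape_default.yaml",
                         "scenario_microbeads_synthetic.yaml"),
                       package = "plasticfate", mustWork = TRUE)
    paths <- file.path(dir, basename(src))
    file.copy(src, paths, overwrite = TRUE)
  }
  ## both must load cleanly
  load_landscape(paths[1])
  load_scenario(paths[2])
  invisible(paths)
}
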