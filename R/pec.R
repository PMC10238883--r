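## Predicted environmental concentrations from state masses.

#' Concentrations from masses
#'
#' Converts per-state plastic masses to predicted environmental
#' concentrations (PECs): mass per volume (kg/m3) in air and water, mass
#' per kg dry weight in soils and sediments (mass over volume times dry
#' bulk density), and the corresponding particle-number concentrations via
#' the spherical mass/number conversion of the bead.
#'
#' @param masses An `sb_mass` tibble from [steady_state_masses()] (columns
#'   `compartment_id`, `form`, `mass`).
#' @param landscape The `sb_landscape` the masses refer to.
#' @param particle The [plastic_particle()] (for number conversion).
#' @return A tibble of class `sb_pec`: one row per compartment and form,
#'   with `mass_concentration` (kg/m3 or kg/kg dw), `number_concentration`
#'   (1/m3 or 1/kg dw) and a `basis` column (`"volume"` or
#'   `"dry_weight"`).
#' @export
concentrations_from_masses <- function(masses, landscape, particle) {
  if (any(masses$mass < 0)) abort("masses must be >= 0.")
  comps <- landscape$compartments
  j <- match(masses$compartment_id, comps$id)
  if (anyNA(j)) abort("masses refer to compartments absent from the landscape.")
  cls <- comps$class[j]
  dry <- cls %in% c("soil", "sediment")
  if (any(dry & !is.finite(comps$dry_bulk_density[j])))
    abort("missing dry bulk density for a soil/sediment compartment.")
  denom <- ifelse(dry, comps$volume[j] * comps$dry_bulk_density[j],
                  comps$volume[j])
  out <- tibble(
    compartment_id = masses$compartment_id,
    scale = comps$scale[j],
    medium = comps$medium[j],
    class = cls,
    form = masses$form,
    basis = ifelse(dry, "dry_weight", "volume"),
    mass = masses$mass,
    mass_concentration = masses$mass / denom,
    number_concentration = mass_to_number(masses$mass, particle) / denom
  )
  class(out) <- c("sb_pec", class(out))
  out
}

#' Total particulate PEC
#'
#' The total particulate concentration per compartment is the exact sum of
#' the three tracked species: free plastic, plastic heteroaggregated with
#' natural colloids, and plastic attached to coarse particulate matter.
#'
#' @param pec An `sb_pec` tibble from [concentrations_from_masses()].
#' @return A tibble with one row per compartment: the summed
#'   `mass_concentration` and `number_concentration` plus the per-species
#'   mass concentrations in wide columns.
#' @export
total_particulate_pec <- function(pec) {
  wide <- tidyr::pivot_wider(
    pec[, c("compartment_id", "scale", "medium", "class", "basis", "form",
            "mass_concentration")],
    names_from = "form", values_from = "mass_concentration")
  wide_n <- tidyr::pivot_wider(
    pec[, c("compartment_id", "form", "number_concentration")],
    names_from = "form", values_from = "number_concentration")
  ## elementwise so that total == free + colloid + coarse holds exactly
  wide$mass_concentration <- wide$free + wide$colloid_heteroaggregate +
    wide$coarse_attached
  wide$number_concentration <- wide_n$free[match(wide$compartment_id,
                                                 wide_n$compartment_id)] +
    wide_n$colloid_heteroaggregate[match(wide$compartment_id,
                                         wide_n$compartment_id)] +
    wide_n$coarse_attached[match(wide$compartment_id,
                                 wide_n$compartment_id)]
  wide[, c("compartment_id", "scale", "medium", "class", "basis",
           "mass_concentration", "number_concentration", "free",
           "colloid_heteroaggregate", "coarse_attached")]
}
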