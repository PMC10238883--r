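## State-space enumeration over (compartment x species form).

#' Enumerate the model state space
#'
#' Every compartment carries exactly three particulate species forms:
#' `free` plastic, `colloid_heteroaggregate` (plastic attached to a
#' natural colloid or fine aerosol) and `coarse_attached` (plastic
#' attached to coarse suspended matter, coarse aerosol or soil/sediment
#' grains).  The state vector of the mass balance is the ordered cross
#' product (compartment, form), compartment-major in landscape order, so
#' the mapping is bijective and stable for a fixed landscape.
#'
#' @param landscape An `sb_landscape`.
#' @return A tibble with columns `index`, `compartment_id`, `scale`,
#'   `medium`, `class` and `form`; `3 * n_compartments` rows.
#' @examples
#' nrow(enumerate_states(toy_landscape()))  # 6
#' @export
enumerate_states <- function(landscape) {
  comps <- landscape$compartments
  states <- tidyr::expand_grid(
    compartment_id = comps$id,
    form = .species_forms
  )
  states <- dplyr::left_join(
    states,
    comps[, c("id", "scale", "medium", "class")],
    by = c(compartment_id = "id")
  )
  states$index <- seq_len(nrow(states))
  states[, c("index", "compartment_id", "scale", "medium", "class", "form")]
}

## fast index lookup: matrix [compartment, form] -> state index
.state_index_matrix <- function(states) {
  comp_ids <- unique(states$compartment_id)
  m <- matrix(NA_integer_, nrow = length(comp_ids), ncol = 3,
              dimnames = list(comp_ids, .species_forms))
  m[cbind(match(states$compartment_id, comp_ids),
          match(states$form, .species_forms))] <- states$index
  m
}
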