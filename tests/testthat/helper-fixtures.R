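# Shared fixtures: cached landscapes and generators for random
# compartmental systems.  Everything is built in code at test time.

.shared <- new.env(parent = emptyenv())

cached_default_landscape <- function() {
  if (is.null(.shared$landscape)) .shared$landscape <- default_landscape()
  .shared$landscape
}

cached_default_scenario <- function() {
  if (is.null(.shared$scenario)) .shared$scenario <- default_scenario()
  .shared$scenario
}

# random Metzler (compartmental) matrix with strictly positive removal,
# plus a random non-negative emission vector
random_metzler_system <- function(n_states, seed) {
  set.seed(seed)
  A <- matrix(runif(n_states^2, 0, 1), n_states)
  A[runif(n_states^2) < 0.5] <- 0
  diag(A) <- 0
  sinks <- runif(n_states, 0.1, 1)
  diag(A) <- -(colSums(A) + sinks)
  e <- runif(n_states, 0, 2)
  list(A = A, e = e, sinks = sinks)
}

# wrap a bare matrix as an sb_system so the solvers can be tested on
# hand-constructed examples
fake_system <- function(A) {
  n <- nrow(A)
  structure(list(
    A = A,
    states = tibble::tibble(
      compartment_id = paste0("c", seq_len(n)),
      form = rep("free", n)),
    sinks = -(diag(A) + colSums(A) - diag(A)),
    processes = NULL, context = NULL), class = "sb_system")
}

# a scenario in which every sampled quantity is degenerate, so Monte Carlo
# collapses onto a single deterministic model evaluation
degenerate_scenario <- function(radius_um = 5, density = 1200, alpha = 0.01,
                                k_frag = 2.7e-8, k_deg = 0,
                                tonnage = 10) {
  load_scenario(list(
    name = "degenerate",
    particle = list(
      radius_um = list(min = radius_um, max = radius_um),
      density_kg_m3 = list(min = density, max = density),
      alpha_het = list(min = alpha, max = alpha, scale = "linear")
    ),
    removal = list(
      k_frag_per_s = list(low = k_frag, mode = k_frag, high = k_frag),
      k_deg_per_s = list(low = k_deg, mode = k_deg, high = k_deg)
    ),
    stp = list(efficiency = list(low = 0.9, mode = 0.9, high = 0.9),
               sludge_application_fraction = 0.5),
    sectors = list(
      list(name = "PCCP", route = "freshwater_direct", scale = "regional",
           low = tonnage, best = tonnage, high = tonnage))
  ))
}
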