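## Assembly of the first-order rate matrix A and emission vector e of the
## mass balance dm/dt = A m + e.

#' Precompute the landscape-side assembly context
#'
#' Splits system assembly into a particle-independent part (state indexing,
#' advection, runoff, erosion, resuspension, burial, wet deposition) done
#' once per landscape, and a small particle-dependent remainder evaluated
#' per particle.  Used internally by [assemble_system()] and worth calling
#' explicitly when assembling many systems on one landscape (Monte Carlo).
#'
#' @param landscape An `sb_landscape`.
#' @return An opaque context object (class `sb_context`).
#' @export
prepare_system_context <- function(landscape) {
  comps <- landscape$compartments
  states <- enumerate_states(landscape)
  idx <- .state_index_matrix(states)
  n <- nrow(states)
  p <- landscape$params

  t_i <- integer(0); t_j <- integer(0); t_x <- numeric(0); t_lab <- character(0)
  s_j <- integer(0); s_x <- numeric(0); s_lab <- character(0)
  add <- function(i, j, x, lab) {
    keep <- x > 0
    t_i <<- c(t_i, i[keep]); t_j <<- c(t_j, j[keep]); t_x <<- c(t_x, x[keep])
    t_lab <<- c(t_lab, rep(lab, sum(keep)))
  }
  add_sink <- function(j, x, lab) {
    keep <- x > 0
    s_j <<- c(s_j, j[keep]); s_x <<- c(s_x, x[keep])
    s_lab <<- c(s_lab, rep(lab, sum(keep)))
  }

  forms <- .species_forms
  vol <- setNames(comps$volume, comps$id)

  ## advection: all species forms move with the fluid; `to: sink` marks a
  ## terminal outflow
  fl <- landscape$flows
  for (k in seq_len(nrow(fl))) {
    rate <- fl$flow[k] / vol[[fl$from[k]]]
    if (identical(fl$to[k], "sink")) {
      add_sink(idx[fl$from[k], forms], rep(rate, 3), "advection_out")
    } else {
      add(idx[fl$to[k], forms], idx[fl$from[k], forms], rep(rate, 3),
          "advection_out")
    }
  }

  ## the water compartment that receives soil runoff/erosion at each scale:
  ## freshwater if the scale has one, otherwise seawater
  runoff_target <- function(scale) {
    fw <- comps$id[comps$scale == scale & comps$medium == "freshwater"]
    if (length(fw)) return(fw[1])
    sw <- comps$id[comps$scale == scale & comps$medium == "seawater"]
    if (length(sw)) return(sw[1])
    NA_character_
  }

  soil_rows <- which(comps$class == "soil")
  soil_attach_pairs <- NULL
  for (k in soil_rows) {
    id <- comps$id[k]
    dest <- runoff_target(comps$scale[k])
    ex <- surface_exchange_rates(comps[k, ], NULL, landscape)
    if (!is.na(dest)) {
      k_run <- ex$rate[ex$process == "runoff"]
      add(idx[dest, c("free", "colloid_heteroaggregate")],
          idx[id, c("free", "colloid_heteroaggregate")],
          rep(k_run, 2), "runoff")
      k_ero <- ex$rate[ex$process == "erosion"]
      add(idx[dest, "coarse_attached"], idx[id, "coarse_attached"],
          k_ero, "erosion")
    }
    ## attachment of mobile species to soil grains is particle-dependent
    ## (scaled by alpha_het); record the index pairs
    soil_attach_pairs <- rbind(
      soil_attach_pairs,
      cbind(i = rep(idx[id, "coarse_attached"], 2),
            j = idx[id, c("free", "colloid_heteroaggregate")]))
  }

  sed_rows <- which(comps$class == "sediment")
  for (k in sed_rows) {
    id <- comps$id[k]
    w_id <- comps$id[comps$class == "water" &
                       comps$sediment_partner == id]
    ex <- .sediment_exchange(comps[k, ], comps[comps$id == w_id[1], ],
                             landscape)
    add(idx[w_id[1], forms], idx[id, forms],
        rep(ex$k_resuspension, 3), "resuspension")
    add_sink(idx[id, forms], rep(ex$k_burial, 3), "burial")
  }

  ## air compartments: wet deposition is particle-independent; dry
  ## deposition and aerosol aggregation are evaluated per particle
  air_rows <- which(comps$class == "air")
  air_ctx <- list()
  for (k in air_rows) {
    a <- comps[k, ]
    surf <- comps[comps$scale == a$scale & comps$class != "air", ]
    surf <- surf[surf$class %in% c("water", "soil"), ]
    fracs <- surf$area / a$area
    if (abs(sum(fracs) - 1) > 1e-6)
      abort(sprintf("air compartment `%s`: receiving surface areas cover %.4f of the air area (must be 1)",
                    a$id, sum(fracs)))
    k_wet <- a$rain_rate * p$scavenging_ratio / a$depth
    for (s in seq_len(nrow(surf))) {
      add(idx[surf$id[s], forms], idx[a$id, forms],
          rep(k_wet * fracs[s], 3), "wet_deposition")
    }
    hosts <- landscape$particles[landscape$particles$compartment_id == a$id, ]
    fine <- hosts[hosts$label == "fine", ]
    coarse <- hosts[hosts$label == "coarse", ]
    air_ctx[[a$id]] <- list(
      comp = as.list(a),
      state = idx[a$id, forms],
      surf_ids = surf$id,
      surf_fracs = fracs,
      surf_states = lapply(surf$id, function(sid) idx[sid, forms]),
      fine = if (nrow(fine)) as.list(fine[1, ]) else NULL,
      coarse = if (nrow(coarse)) as.list(coarse[1, ]) else NULL
    )
  }

  ## water compartments: settling and heteroaggregation per particle
  water_rows <- which(comps$class == "water")
  water_ctx <- list()
  for (k in water_rows) {
    w <- comps[k, ]
    hosts <- landscape$particles[landscape$particles$compartment_id == w$id, ]
    colloid <- hosts[hosts$kind == "colloid", ]
    spm <- hosts[hosts$kind == "coarse_spm", ]
    water_ctx[[w$id]] <- list(
      comp = as.list(w),
      state = idx[w$id, forms],
      sed_state = idx[w$sediment_partner, forms],
      colloid = if (nrow(colloid)) as.list(colloid[1, ]) else NULL,
      spm = if (nrow(spm)) as.list(spm[1, ]) else NULL
    )
  }

  ## fragmentation/degradation: per-state medium class
  state_class <- states$class
  ## soils/sediments/waters by class for the removal draw; air stays zero
  structure(list(
    landscape = landscape, states = states, idx = idx, n = n,
    template = list(i = t_i, j = t_j, x = t_x, lab = t_lab),
    template_sinks = list(j = s_j, x = s_x, lab = s_lab),
    soil_attach_pairs = soil_attach_pairs,
    soil_attach_base = p$soil_attachment_rate_per_s,
    air_ctx = air_ctx, water_ctx = water_ctx,
    state_class = state_class,
    params = p
  ), class = "sb_context")
}

#' Assemble the system matrix for one particle
#'
#' Builds the square first-order rate matrix `A` over the state space of
#' (compartment, species form): element `(i, j)`, `i != j`, is the
#' transfer rate constant from state `j` to state `i`; the diagonal is
#' minus the total outflow of each state, including the pure-removal sinks
#' (fragmentation/degradation, burial, terminal outflow).  `A` is a
#' Metzler (compartmental) matrix by construction: non-negative
#' off-diagonals, non-positive diagonals, column-sum deficit equal to the
#' sink rates.
#'
#' @param landscape An `sb_landscape` (or an `sb_context` from
#'   [prepare_system_context()]).
#' @param particle A [plastic_particle()].
#' @param audit If `TRUE`, attach a process audit table mapping every
#'   non-zero element to its process label.
#' @return An object of class `sb_system`: list with `A` (dense matrix),
#'   `states`, `sinks` (per-state total removal rate), `processes` (audit
#'   tibble or `NULL`) and the `context`.
#' @examples
#' sys <- assemble_system(toy_landscape(), plastic_particle(5e-6, 1200))
#' all(diag(sys$A) <= 0)
#' @export
assemble_system <- function(landscape, particle, audit = TRUE) {
  ctx <- if (inherits(landscape, "sb_context")) landscape
         else prepare_system_context(landscape)
  stopifnot(inherits(particle, "sb_particle"))
  forms <- .species_forms

  i <- ctx$template$i; j <- ctx$template$j; x <- ctx$template$x
  lab <- ctx$template$lab
  sj <- ctx$template_sinks$j; sx <- ctx$template_sinks$x
  slab <- ctx$template_sinks$lab

  ## soil attachment (alpha-scaled collision-limited rate)
  if (!is.null(ctx$soil_attach_pairs)) {
    k_att <- particle$alpha_het * ctx$soil_attach_base
    i <- c(i, ctx$soil_attach_pairs[, "i"])
    j <- c(j, ctx$soil_attach_pairs[, "j"])
    x <- c(x, rep(k_att, nrow(ctx$soil_attach_pairs)))
    lab <- c(lab, rep("heteroagg_coarse", nrow(ctx$soil_attach_pairs)))
  }

  ## water columns: heteroaggregation and settling
  drag <- ctx$params$drag_model %||% "schiller_naumann"
  for (w in ctx$water_ctx) {
    cc <- w$comp
    v_bead <- .terminal_v(particle$radius, particle$density,
                          cc$medium_density, cc$viscosity, model = drag)
    props <- list(free = list(radius = particle$radius,
                              density = particle$density))
    for (host_role in c("colloid", "spm")) {
      h <- w[[host_role]]
      form_k <- if (host_role == "colloid") "colloid_heteroaggregate"
                else "coarse_attached"
      if (is.null(h)) { props[[form_k]] <- props$free; next }
      props[[form_k]] <- .aggregate_props(particle$radius, particle$density,
                                          h$radius, h$density)
      v_h <- .terminal_v(h$radius, h$density, cc$medium_density,
                         cc$viscosity, model = drag)
      K <- .collision_k(particle$radius, h$radius, v_bead, v_h,
                        cc$temperature, cc$viscosity, cc$shear_rate)
      k_het <- particle$alpha_het * K * h$number_concentration
      if (k_het > 0) {
        i <- c(i, w$state[[form_k]]); j <- c(j, w$state[["free"]])
        x <- c(x, k_het)
        lab <- c(lab, if (host_role == "colloid") "heteroagg_colloid"
                      else "heteroagg_coarse")
      }
    }
    for (f in forms) {
      pr <- props[[f]]
      v <- .terminal_v(pr$radius, pr$density, cc$medium_density,
                       cc$viscosity, model = drag)
      k_sed <- v / cc$depth
      if (k_sed > 0) {
        i <- c(i, w$sed_state[[f]]); j <- c(j, w$state[[f]])
        x <- c(x, k_sed); lab <- c(lab, "settling")
      }
    }
  }

  ## air: dry deposition per form, aerosol heteroaggregation
  for (a in ctx$air_ctx) {
    cc <- a$comp
    props <- list(free = list(radius = particle$radius,
                              density = particle$density))
    props$colloid_heteroaggregate <- if (!is.null(a$fine))
      .aggregate_props(particle$radius, particle$density,
                       a$fine$radius, a$fine$density) else props$free
    props$coarse_attached <- if (!is.null(a$coarse))
      .aggregate_props(particle$radius, particle$density,
                       a$coarse$radius, a$coarse$density) else props$free
    v_dep <- vapply(forms, function(f) {
      .deposition_velocity(props[[f]]$radius, props[[f]]$density, cc,
                           ctx$params$air_boundary_layer_m, model = drag)
    }, numeric(1))
    for (s in seq_along(a$surf_ids)) {
      k_dry <- v_dep / cc$depth * a$surf_fracs[s]
      i <- c(i, a$surf_states[[s]][forms]); j <- c(j, a$state[forms])
      x <- c(x, k_dry); lab <- c(lab, rep("dry_deposition", 3))
    }
    if (isTRUE(ctx$params$air_heteroaggregation)) {
      v_bead <- .terminal_v(particle$radius, particle$density,
                            cc$medium_density, cc$viscosity, model = drag)
      for (host_role in c("fine", "coarse")) {
        h <- a[[host_role]]
        if (is.null(h)) next
        v_h <- .terminal_v(h$radius, h$density, cc$medium_density,
                           cc$viscosity, model = drag)
        K <- .collision_k(particle$radius, h$radius, v_bead, v_h,
                          cc$temperature, cc$viscosity, 0)
        k_het <- particle$alpha_het * K * h$number_concentration
        form_k <- if (host_role == "fine") "colloid_heteroaggregate"
                  else "coarse_attached"
        if (k_het > 0) {
          i <- c(i, a$state[[form_k]]); j <- c(j, a$state[["free"]])
          x <- c(x, k_het)
          lab <- c(lab, if (host_role == "fine") "heteroagg_colloid"
                        else "heteroagg_coarse")
        }
      }
    }
  }

  ## fragmentation + degradation: pure removal per medium class
  k_fd <- particle$k_frag[ctx$state_class] + particle$k_deg[ctx$state_class]
  keep <- which(k_fd > 0)
  sj <- c(sj, keep); sx <- c(sx, k_fd[keep])
  slab <- c(slab, rep("frag_deg", length(keep)))

  if (any(x < 0) || any(sx < 0)) {
    bad <- unique(c(lab[x < 0], slab[sx < 0]))
    abort(sprintf("negative rate constant computed for process: %s",
                  paste(bad, collapse = ", ")))
  }

  n <- ctx$n
  A <- as.matrix(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n)))
  sinks <- numeric(n)
  if (length(sj)) {
    agg <- rowsum(sx, group = sj)
    sinks[as.integer(rownames(agg))] <- agg[, 1]
  }
  diag(A) <- diag(A) - colSums(A) - sinks

  processes <- NULL
  if (audit) {
    st <- ctx$states
    processes <- tibble(
      process = c(lab, slab),
      from_compartment = st$compartment_id[c(j, sj)],
      from_form = st$form[c(j, sj)],
      to_compartment = c(st$compartment_id[i], rep(NA_character_, length(sj))),
      to_form = c(st$form[i], rep(NA_character_, length(sj))),
      from_state = c(j, sj),
      to_state = c(i, rep(NA_integer_, length(sj))),
      rate = c(x, sx)
    )
  }

  structure(list(A = A, states = ctx$states, sinks = sinks,
                 processes = processes, context = ctx),
            class = "sb_system")
}

#' @export
print.sb_system <- function(x, ...) {
  cat(sprintf("<sb_system> %d states (%d compartments x 3 species forms)\n",
              nrow(x$A), nrow(x$A) / 3))
  cat(sprintf("  non-zero transfers: %d; total sink rate range: [%.3g, %.3g] 1/s\n",
              sum(x$A > 0), min(x$sinks), max(x$sinks)))
  invisible(x)
}

#' Build an emission vector
#'
#' Emissions are injected into the free species of the named compartments
#' only: releases are of pristine plastic.
#'
#' @param system An `sb_system` (or `sb_context`).
#' @param emissions A data frame with columns `compartment_id` and `kg_s`,
#'   or a named numeric vector of kg/s keyed by compartment id.
#' @return A numeric per-state emission vector, kg/s.
#' @export
build_emission_vector <- function(system, emissions) {
  ctx <- if (inherits(system, "sb_system")) system$context else system
  e <- numeric(ctx$n)
  if (is.numeric(emissions) && !is.null(names(emissions))) {
    emissions <- tibble(compartment_id = names(emissions),
                        kg_s = as.numeric(emissions))
  }
  for (k in seq_len(nrow(emissions))) {
    id <- emissions$compartment_id[k]
    if (!id %in% rownames(ctx$idx))
      abort(sprintf("emission to unknown compartment `%s`", id))
    if (emissions$kg_s[k] < 0)
      abort(sprintf("negative emission to `%s`", id))
    e[ctx$idx[id, "free"]] <- e[ctx$idx[id, "free"]] + emissions$kg_s[k]
  }
  e
}
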