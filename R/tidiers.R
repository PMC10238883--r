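## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a system matrix into its process audit table
#'
#' @param x An `sb_system` assembled with `audit = TRUE`.
#' @param ... Unused.
#' @return The audit tibble: one row per non-zero rate constant with its
#'   process label, source and destination state (destination `NA` for
#'   pure-removal sinks).
#' @method tidy sb_system
#' @export
tidy.sb_system <- function(x, ...) {
  if (is.null(x$processes))
    abort("system was assembled with `audit = FALSE`; re-assemble to tidy.")
  x$processes
}

#' @rdname tidy.sb_system
#' @method glance sb_system
#' @export
glance.sb_system <- function(x, ...) {
  tibble(
    n_states = nrow(x$A),
    n_compartments = nrow(x$A) / 3L,
    n_transfers = sum(x$A > 0),
    total_sink_min = min(x$sinks),
    total_sink_max = max(x$sinks)
  )
}

#' @method tidy sb_pec
#' @export
tidy.sb_pec <- function(x, ...) as_tibble(x)

#' @method tidy sb_mc_run
#' @export
tidy.sb_mc_run <- function(x, levels = c(5, 50, 95), ...) {
  percentile_summary(x, levels = levels)
}

#' @method glance sb_mc_run
#' @export
glance.sb_mc_run <- function(x, ...) {
  tibble(n = x$n, seed = x$seed, n_failures = nrow(x$failures),
         n_compartments = length(unique(x$outputs$compartment_id)),
         config_hash = x$config_hash)
}

#' Plot a deterministic PEC result
#'
#' Bar chart of per-compartment concentrations, stacked by species form.
#'
#' @param object An `sb_pec` tibble.
#' @param quantity `"mass_concentration"` or `"number_concentration"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sb_pec
#' @export
autoplot.sb_pec <- function(object, quantity = "mass_concentration", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$compartment_id,
                               y = .data[[quantity]],
                               fill = .data$form)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = paste(quantity,
                            "(kg/m3 volume basis, kg/kg dry-weight basis)"),
                  fill = "species form") +
    ggplot2::theme_minimal()
}

#' Plot the PEC distributions of a Monte Carlo run
#'
#' One box per compartment of the log10 total PEC across iterations,
#' mirroring the conventional presentation of multimedia Monte Carlo
#' output.
#'
#' @param object An `sb_mc_run`.
#' @param quantity `"mass_total"` or `"number_total"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sb_mc_run
#' @export
autoplot.sb_mc_run <- function(object, quantity = "mass_total", ...) {
  dat <- object$outputs[!is.na(object$outputs[[quantity]]) &
                          object$outputs[[quantity]] > 0, ]
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$compartment_id,
                               y = .data[[quantity]])) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("total particulate PEC,", quantity)) +
    ggplot2::theme_minimal()
}
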