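#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_area
#'   geom_col labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot subsystem ATP shares along an energy-demand scan
#'
#' @param object a [demand_scan()] result.
#' @param ... unused.
#' @return a ggplot: stacked subsystem ATP contribution versus demand.
#' @export
autoplot.demand_scan <- function(object, ...) {
  dat <- dplyr::filter(object, .data$status == "optimal",
                       !is.na(.data$subsystem))
  ggplot(dat, aes(x = .data$demand, y = .data$flux,
                  fill = .data$subsystem)) +
    geom_area(position = "stack") +
    labs(x = "ATP maintenance demand (µmol/gDW/h)",
         y = "contributor ATP flux (µmol/gDW/h)",
         fill = "subsystem") +
    theme_minimal()
}

#' Plot a Complex I inhibition scan
#'
#' @param object an [complex1_scan()] result.
#' @param ... unused.
#' @return a ggplot of ATP-synthase and Complex I flux versus inhibition.
#' @export
autoplot.inhibition_scan <- function(object, ...) {
  dat <- object |>
    filter(.data$status == "optimal") |>
    tidyr::pivot_longer(c("complex1_flux", "atps_flux"),
                        names_to = "reaction", values_to = "flux")
  ggplot(dat, aes(x = .data$alpha, y = .data$flux,
                  colour = .data$reaction)) +
    geom_line() + geom_point() +
    labs(x = "Complex I inhibition fraction", y = "flux (µmol/gDW/h)",
         colour = NULL) +
    theme_minimal()
}

#' Plot a substrate availability scan
#'
#' @param object a [substrate_scan()] result.
#' @param ... unused.
#' @return a ggplot of ATP-synthase flux versus the uptake bound.
#' @export
autoplot.substrate_scan <- function(object, ...) {
  dat <- filter(object, .data$status == "optimal")
  ggplot(dat, aes(x = .data$uptake_bound, y = .data$atps_flux)) +
    geom_line() + geom_point() +
    labs(x = sprintf("%s lower bound (µmol/gDW/h)",
                     attr(object, "exchange_id") %||% "uptake"),
         y = "ATP synthase flux (µmol/gDW/h)") +
    theme_minimal()
}

#' Plot control versus PD exchange fluxes of a comparison table
#'
#' @param object a [build_comparison_table()] result.
#' @param ... unused.
#' @return a ggplot of paired exchange fluxes coloured by consistency call.
#' @export
autoplot.csf_comparison <- function(object, ...) {
  dat <- object |>
    tidyr::pivot_longer(c("control_flux", "pd_flux"),
                        names_to = "condition", values_to = "flux") |>
    mutate(condition = sub("_flux$", "", .data$condition))
  ggplot(dat, aes(x = .data$metabolite, y = .data$flux,
                  fill = .data$condition)) +
    geom_col(position = "dodge") +
    facet_wrap(~.data$consistency_label) +
    labs(x = NULL, y = "exchange flux (µmol/gDW/h)",
         fill = NULL) +
    theme_minimal()
}
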