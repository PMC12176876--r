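#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an entropic FBA solution
#'
#' @param x an `entropic_solution`.
#' @param ... unused.
#' @return tibble of per-reaction fluxes (id, vf, vr, net, bounds).
#' @export
tidy.entropic_solution <- function(x, ...) {
  x$fluxes
}

#' One-row summary of an entropic FBA solution
#'
#' @param x an `entropic_solution`.
#' @param ... unused.
#' @return tibble with status, objective value, reaction/metabolite counts
#'   and the mass-balance residual.
#' @export
glance.entropic_solution <- function(x, ...) {
  tibble(status = x$status,
         objective_value = x$objective_value %||% NA_real_,
         n_reactions = nrow(x$fluxes),
         n_metabolites = nrow(x$potentials),
         primal_residual = x$primal_residual %||% NA_real_)
}

#' Tidy an ATP accounting result
#'
#' @param x an `atp_accounting` object.
#' @param ... unused.
#' @return the underlying tibble, contributors and consumers flagged.
#' @export
tidy.atp_accounting <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "atp_accounting")
  out
}

#' One-row summary of an ATP accounting result
#'
#' @param x an `atp_accounting` object.
#' @param ... unused.
#' @return tibble with total production, consumption and counts.
#' @export
glance.atp_accounting <- function(x, ...) {
  tibble(
    total_production = sum(x$atp_rate[x$role == "contributor"]),
    total_consumption = sum(x$atp_rate[x$role == "consumer"]),
    n_contributors = sum(x$role == "contributor"),
    n_consumers = sum(x$role == "consumer"))
}
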