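#' Construct a constraint overlay
#'
#' An overlay collects condition-specific bound edits: absolute replacements
#' (`bound_edits`) and multiplicative rescalings of a named bound
#' (`scale_edits`). Overlays are applied with [apply_overlay()]; the disease
#' overlays used here encode the PD edits: Complex I capacity at 82% of
#' control, dopamine release at one quarter, and removal of the minimum
#' glucose/oxygen uptake requirement.
#'
#' @param bound_edits named list: reaction id -> `list(lower =, upper =)`
#'   (either entry may be omitted).
#' @param scale_edits named list: reaction id ->
#'   `list(bound = "lower"|"upper", factor = <positive real>)`.
#' @return an object of class `constraint_overlay`.
#' @export
constraint_overlay <- function(bound_edits = list(), scale_edits = list()) {
  structure(list(bound_edits = bound_edits, scale_edits = scale_edits),
            class = "constraint_overlay")
}

#' Apply a constraint overlay to a model
#'
#' Returns a new model; the input model is untouched. Absolute edits are
#' idempotent, scale edits compose multiplicatively.
#'
#' @param model a [metabolic_model()].
#' @param overlay a [constraint_overlay()].
#' @return the edited model.
#' @export
apply_overlay <- function(model, overlay) {
  stopifnot(inherits(overlay, "constraint_overlay"))
  ids <- unique(c(names(overlay$bound_edits), names(overlay$scale_edits)))
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("Overlay references unknown reactions: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- model
  for (id in names(overlay$bound_edits)) {
    e <- overlay$bound_edits[[id]]
    out <- set_bounds(out, id, lower = e$lower, upper = e$upper)
  }
  for (id in names(overlay$scale_edits)) {
    e <- overlay$scale_edits[[id]]
    i <- match(id, out$reactions$id)
    if (identical(e$bound, "lower")) {
      out$reactions$lower_bound[i] <- out$reactions$lower_bound[i] * e$factor
    } else if (identical(e$bound, "upper")) {
      out$reactions$upper_bound[i] <- out$reactions$upper_bound[i] * e$factor
    } else {
      abort("scale_edits entries need bound = \"lower\" or \"upper\".")
    }
    if (out$reactions$lower_bound[i] > out$reactions$upper_bound[i]) {
      abort(sprintf("Overlay makes lower > upper for reaction '%s'.", id))
    }
  }
  out
}

#' Literature-derived constraint arithmetic
#'
#' Unit-conversion arithmetic for the quantitative constraints used in the
#' condition-specific neuron models:
#' \describe{
#'   \item{`residual_energy_conversion`}{converts a residual ATP consumption
#'     rate in mu mol/g wet weight/min to mu mol/gDW/h via
#'     `rate * 60 * (1 - water_fraction)`; with the gray-matter water content
#'     0.823 and rate 10 this gives 106.2. `params = c(rate, water_fraction)`.}
#'   \item{`atpm_lower`}{the minimum energy demand, the converted residual rate
#'     reduced by a factor of ten (rat-derived mitochondrial constraints);
#'     `params = c(converted)`; 106.2 -> 10.62.}
#'   \item{`pd_complex1_factor`}{the PD Complex I capacity fraction
#'     `1 - minimum_reported_reduction`; 0.18 -> 0.82.}
#'   \item{`mito_protein_density`}{midpoint of a reported density range in
#'     mg mitochondrial protein per g wet weight; `params = c(lo, hi)`;
#'     (4, 6) -> 5 (non-synaptic), (1, 1.5) -> 1.25 (synaptic).}
#'   \item{`activity_flux`}{converts an enzyme activity (per mg mitochondrial
#'     protein per minute) to a flux bound via the parameterized product
#'     `activity * density_mg_per_gWW * 60`, a unit-bookkeeping configuration
#'     point rather than a hard-coded constant;
#'     `params = c(activity, density_mg_per_gWW)`.}
#' }
#'
#' @param kind one of `"residual_energy_conversion"`, `"atpm_lower"`,
#'   `"pd_complex1_factor"`, `"mito_protein_density"`, `"activity_flux"`.
#' @param params numeric parameters, see Details.
#' @return a single number.
#' @export
derive_literature_constraint <- function(kind, params) {
  kind <- match.arg(kind, c("residual_energy_conversion", "atpm_lower",
                            "pd_complex1_factor", "mito_protein_density",
                            "activity_flux"))
  if (!is.numeric(params) || any(!is.finite(params)) || any(params <= 0)) {
    abort("`params` must be positive finite numbers.")
  }
  switch(kind,
    residual_energy_conversion = {
      if (length(params) != 2L) abort("need params = c(rate, water_fraction)")
      wf <- params[[2]]
      if (wf <= 0 || wf >= 1) abort("water fraction must lie in (0, 1).")
      params[[1]] * 60 * (1 - wf)
    },
    atpm_lower = {
      if (length(params) != 1L) abort("need params = c(converted_rate)")
      params[[1]] / 10
    },
    pd_complex1_factor = {
      if (length(params) != 1L) abort("need params = c(min_reduction)")
      if (params[[1]] >= 1) abort("reduction fraction must be below 1.")
      1 - params[[1]]
    },
    mito_protein_density = {
      if (length(params) != 2L) abort("need params = c(lo, hi)")
      if (params[[1]] > params[[2]]) abort("need lo <= hi.")
      (params[[1]] + params[[2]]) / 2
    },
    activity_flux = {
      if (length(params) != 2L) abort("need params = c(activity, density)")
      params[[1]] * params[[2]] * 60
    })
}
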