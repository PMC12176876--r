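#' Configuration for single-reaction rescue scans
#'
#' @param mode `"inhibit"` (knockout: both bounds to zero) or `"increase"`
#'   (force the net flux in its baseline direction to `increase_factor` times
#'   the baseline magnitude).
#' @param increase_factor flux-forcing multiplier (> 1 in increase mode;
#'   default 1.1).
#' @param demands ATPM lower-bound grid over which the energy criterion is
#'   evaluated.
#' @param atps_id ATP synthase reaction id (oxidative-phosphorylation energy
#'   criterion).
#' @param glycolysis_subsystem subsystem label whose summed contributor ATP
#'   flux forms the glycolytic energy criterion.
#' @param energy_slack fractional tolerance for "approaching control" in the
#'   knockout energy criterion (default 0.05).
#' @param csf_table direction-annotated exchange evaluation set (tibble as
#'   from [read_csf_table()]); may be `NULL` to skip exchange calls.
#' @param generic_exchange_bounds length-2 numeric: relaxed bounds restored on
#'   exchange reactions during increase-mode solves, or `NULL` to keep the
#'   model's own exchange bounds (appropriate when those already are the
#'   generic bounds).
#' @param exchange_penalty diagonal quadratic weight applied to exchange
#'   target fluxes in increase mode (default 1).
#' @param tol flux tolerance for zero-flux and improvement calls.
#' @return a list of class `rescue_config`.
#' @export
rescue_config <- function(mode = c("inhibit", "increase"),
                          increase_factor = 1.1,
                          demands = 10.62,
                          atps_id = "ATPS4mi",
                          glycolysis_subsystem = "Glycolysis",
                          energy_slack = 0.05,
                          csf_table = NULL,
                          generic_exchange_bounds = NULL,
                          exchange_penalty = 1,
                          tol = 1e-4) {
  mode <- match.arg(mode)
  if (mode == "increase" && increase_factor < 1) {
    abort("increase_factor must be at least 1 in increase mode.")
  }
  structure(list(mode = mode, increase_factor = increase_factor,
                 demands = demands, atps_id = atps_id,
                 glycolysis_subsystem = glycolysis_subsystem,
                 energy_slack = energy_slack, csf_table = csf_table,
                 generic_exchange_bounds = generic_exchange_bounds,
                 exchange_penalty = exchange_penalty, tol = tol),
            class = "rescue_config")
}

#' Classify a rescue improvement from a control/PD/rescued flux triple
#'
#' Energy role: improved iff the rescued flux exceeds the PD baseline by more
#' than `tol` (judged against the PD baseline, not control). Exchange role:
#' improved iff the rescued flux moved from the PD baseline in the direction
#' of the control flux, `sign(rescued - pd) == sign(control - pd)`, with both
#' displacement magnitudes above `tol` (overshooting control still counts).
#'
#' @param control_flux,pd_flux,rescued_flux finite fluxes (vectorized).
#' @param role `"energy"` or `"exchange"`.
#' @param tol absolute flux tolerance.
#' @return character vector: `"improved"` or `"not_improved"`.
#' @export
classify_improvement <- function(control_flux, pd_flux, rescued_flux,
                                 role = c("energy", "exchange"),
                                 tol = 1e-4) {
  role <- match.arg(role)
  if (any(!is.finite(c(control_flux, pd_flux, rescued_flux)))) {
    abort("fluxes must be finite.")
  }
  if (role == "energy") {
    ifelse(rescued_flux > pd_flux + tol, "improved", "not_improved")
  } else {
    to_control <- control_flux - pd_flux
    moved <- rescued_flux - pd_flux
    ifelse(abs(to_control) > tol & abs(moved) > tol &
             sign(moved) == sign(to_control),
           "improved", "not_improved")
  }
}

empty_rescue_scan <- function(mode) {
  out <- tibble(reaction_id = character(), energy_improved_all = logical(),
                exchanges_improved = integer(),
                exchanges_worsened = integer(), overall = logical(),
                status = character())
  class(out) <- c("rescue_scan", class(out))
  attr(out, "mode") <- mode
  attr(out, "details") <- list()
  out
}

# moved strictly away from the control direction (or away from an already
# control-matching baseline); used by the composite overall-rescue call
exchange_worsened <- function(control_flux, pd_flux, rescued_flux, tol) {
  to_control <- control_flux - pd_flux
  moved <- rescued_flux - pd_flux
  ifelse(abs(to_control) <= tol,
         abs(rescued_flux - control_flux) > tol,
         abs(moved) > tol & sign(moved) == -sign(to_control))
}

#' Shift in metabolite chemical potentials between two solutions
#'
#' @param baseline,perturbed optimal `entropic_solution`s over the same
#'   metabolite set.
#' @param metabolite_ids subset to report; `NULL` for all.
#' @return named numeric: perturbed potential minus baseline potential.
#' @export
potential_shift <- function(baseline, perturbed, metabolite_ids = NULL) {
  p0 <- chemical_potentials(baseline)
  p1 <- chemical_potentials(perturbed)
  if (!setequal(names(p0), names(p1))) {
    only0 <- setdiff(names(p0), names(p1))
    only1 <- setdiff(names(p1), names(p0))
    abort(paste0("Metabolite sets differ between solutions.",
                 if (length(only0)) paste0(" Only in baseline: ",
                                           paste(only0, collapse = ", ")),
                 if (length(only1)) paste0(" Only in perturbed: ",
                                           paste(only1, collapse = ", "))))
  }
  ids <- metabolite_ids %||% names(p0)
  unknown <- setdiff(ids, names(p0))
  if (length(unknown)) {
    abort(paste0("Unknown metabolites: ", paste(unknown, collapse = ", ")))
  }
  p1[ids] - p0[ids]
}

# reference energy/exchange profile of a model across the demand grid
rescue_reference <- function(model, config, objective = entropic_objective(),
                             control = solver_control()) {
  acc_glyco <- function(md, sol) {
    acc <- atp_accounting(md, sol, tol = config$tol)
    sum(acc$atp_rate[acc$role == "contributor" &
                       acc$subsystem == config$glycolysis_subsystem])
  }
  purrr::map(config$demands, function(d) {
    md <- set_bounds(model, model$atpm_id, lower = d)
    sol <- solve_entropic_fba(md, objective, control)
    if (sol$status != "optimal") {
      return(list(demand = d, status = sol$status))
    }
    list(demand = d, status = "optimal",
         atps_flux = flux_of(sol, config$atps_id),
         glycolysis_atp = acc_glyco(md, sol),
         exchange_fluxes = setNames(sol$fluxes$net,
                                    sol$fluxes$reaction_id),
         solution = sol)
  })
}

# shared evaluation of one perturbed model against PD baseline and control
evaluate_rescue <- function(models_by_demand, reference, pd_baseline_ref,
                            config, objective, control, mode) {
  per_demand <- purrr::map2(models_by_demand, seq_along(config$demands),
    function(mi, k) {
    ref <- reference[[k]]
    pd0 <- pd_baseline_ref[[k]]
    if (!identical(ref$status, "optimal") ||
        !identical(pd0$status, "optimal")) {
      return(list(status = "reference_unavailable"))
    }
    sol <- solve_entropic_fba(mi, objective, control)
    if (sol$status != "optimal") return(list(status = sol$status))
    atps <- flux_of(sol, config$atps_id)
    acc <- atp_accounting(mi, sol, tol = config$tol)
    glyco <- sum(acc$atp_rate[acc$role == "contributor" &
                                acc$subsystem == config$glycolysis_subsystem])
    energy_ok <- if (mode == "inhibit") {
      # knockout criterion: restore toward control levels
      atps >= (1 - config$energy_slack) * ref$atps_flux &&
        glyco >= (1 - config$energy_slack) * ref$glycolysis_atp
    } else {
      # forcing criterion: beat the PD baseline
      classify_improvement(ref$atps_flux, pd0$atps_flux, atps,
                           "energy", config$tol) == "improved"
    }
    exch <- tibble(reaction_id = character(), improvement = character())
    n_improved <- 0L; n_worsened <- 0L
    if (!is.null(config$csf_table) && nrow(config$csf_table)) {
      tab <- config$csf_table
      if (!"blocked" %in% names(tab)) tab$blocked <- FALSE
      keep <- tab$reaction_id %in% names(ref$exchange_fluxes) &
        tab$reaction_id %in% sol$fluxes$reaction_id &
        !(tab$blocked %in% TRUE)
      tab <- tab[keep, ]
      if (nrow(tab)) {
        cfx <- unname(ref$exchange_fluxes[tab$reaction_id])
        pfx <- unname(pd0$exchange_fluxes[tab$reaction_id])
        rfx <- purrr::map_dbl(tab$reaction_id, ~flux_of(sol, .x))
        impr <- classify_improvement(cfx, pfx, rfx, "exchange", config$tol)
        wors <- exchange_worsened(cfx, pfx, rfx, config$tol)
        exch <- tibble(reaction_id = tab$reaction_id, control_flux = cfx,
                       pd_flux = pfx, rescued_flux = rfx,
                       improvement = impr, worsened = wors)
        n_improved <- sum(impr == "improved")
        n_worsened <- sum(wors)
      }
    }
    list(status = "optimal", atps_flux = atps, glycolysis_atp = glyco,
         energy_improved = energy_ok, exchanges = exch,
         n_improved = n_improved, n_worsened = n_worsened,
         solution = sol)
  })

  feasible <- purrr::map_lgl(per_demand, ~identical(.x$status, "optimal"))
  energy_all <- length(per_demand) > 0 && all(feasible) &&
    all(purrr::map_lgl(per_demand[feasible], "energy_improved"))
  n_impr <- if (any(feasible))
    max(purrr::map_int(per_demand[feasible], "n_improved")) else 0L
  n_wors <- if (any(feasible))
    max(purrr::map_int(per_demand[feasible], "n_worsened")) else 0L
  overall <- energy_all && n_impr >= 1L && n_wors == 0L
  list(per_demand = per_demand, feasible = feasible,
       energy_improved_all = energy_all, exchanges_improved = n_impr,
       exchanges_worsened = n_wors, overall = overall)
}

#' Single-reaction knockout rescue scan
#'
#' Individually sets each candidate internal reaction's bounds to (0, 0) in
#' the PD model, re-solves the entropic problem over the configured demand
#' grid, and evaluates the knockout's energy criterion (ATP synthase and
#' summed glycolytic ATP restored to within `energy_slack` of the control
#' reference) and exchange improvements toward control. Knockouts that render
#' the model infeasible are reported as such. Each knockout starts from the
#' pristine PD model, so results are order-independent.
#'
#' @param pd_model the PD [metabolic_model()].
#' @param control_model the matched control model providing reference fluxes.
#' @param config a [rescue_config()] with `mode = "inhibit"`.
#' @param reactions candidate reaction ids (default: all internal reactions).
#' @param objective an [entropic_objective()].
#' @param control a [solver_control()].
#' @return object of class `rescue_scan`: tibble with one row per candidate,
#'   columns `reaction_id`, `energy_improved_all`, `exchanges_improved`,
#'   `exchanges_worsened`, `overall`, `status`; per-demand detail in the
#'   `details` attribute.
#' @export
inhibition_scan <- function(pd_model, control_model, config = rescue_config(),
                            reactions = NULL,
                            objective = entropic_objective(),
                            control = solver_control()) {
  stopifnot(identical(config$mode, "inhibit"))
  if (is.null(reactions)) {
    reactions <- pd_model$reactions$id[!pd_model$reactions$is_exchange]
  }
  if (!length(reactions)) return(empty_rescue_scan("inhibit"))
  reference <- rescue_reference(control_model, config, objective, control)
  pd_ref <- rescue_reference(pd_model, config, objective, control)
  details <- list()
  rows <- purrr::map(reactions, function(rid) {
    models <- purrr::map(config$demands, function(d) {
      set_bounds(set_bounds(pd_model, rid, lower = 0, upper = 0),
                 pd_model$atpm_id, lower = d)
    })
    ev <- evaluate_rescue(models, reference, pd_ref, config, objective,
                          control, mode = "inhibit")
    details[[rid]] <<- ev
    tibble(reaction_id = rid,
           energy_improved_all = ev$energy_improved_all,
           exchanges_improved = ev$exchanges_improved,
           exchanges_worsened = ev$exchanges_worsened,
           overall = ev$overall,
           status = if (all(ev$feasible)) "optimal"
                    else if (any(ev$feasible)) "partially_feasible"
                    else "infeasible")
  })
  out <- bind_rows(rows)
  class(out) <- c("rescue_scan", class(out))
  attr(out, "mode") <- "inhibit"
  attr(out, "details") <- details
  out
}

#' Single-reaction flux-increase rescue scan
#'
#' For each candidate internal reaction with non-negligible baseline net flux,
#' forces the net flux in its baseline direction to `increase_factor` times
#' the baseline magnitude, relaxes exchange bounds to the generic bounds,
#' sets the exchange target fluxes to the PD baseline with a diagonal
#' quadratic penalty (entropy objective retained on internal reactions), and
#' re-solves. Reactions with zero baseline flux are skipped with a reason.
#' Energy improvement is judged against the PD baseline; exchange
#' improvements toward the control reference.
#'
#' @param pd_model the PD [metabolic_model()].
#' @param control_model the matched control model providing reference fluxes.
#' @param config a [rescue_config()] with `mode = "increase"`.
#' @param reactions candidate reaction ids (default: all internal reactions).
#' @param objective an [entropic_objective()] for the baseline solves.
#' @param control a [solver_control()].
#' @return object of class `rescue_scan`; skipped reactions carry status
#'   `"skipped_zero_flux"`.
#' @export
increase_scan <- function(pd_model, control_model,
                          config = rescue_config(mode = "increase"),
                          reactions = NULL,
                          objective = entropic_objective(),
                          control = solver_control()) {
  stopifnot(identical(config$mode, "increase"))
  if (is.null(reactions)) {
    reactions <- pd_model$reactions$id[!pd_model$reactions$is_exchange]
  }
  if (!length(reactions)) return(empty_rescue_scan("increase"))
  reference <- rescue_reference(control_model, config, objective, control)
  pd_ref <- rescue_reference(pd_model, config, objective, control)
  ex_ids <- pd_model$reactions$id[pd_model$reactions$is_exchange]
  gb <- config$generic_exchange_bounds

  relax_model <- function(d) {
    mi <- set_bounds(pd_model, pd_model$atpm_id, lower = d)
    if (!is.null(gb)) {
      for (ex in ex_ids) {
        mi <- set_bounds(mi, ex, lower = gb[1], upper = gb[2])
      }
    }
    mi
  }
  # quadratic penalty pinning exchanges to the PD baseline targets
  objectives <- purrr::map(seq_along(config$demands), function(k) {
    if (!identical(pd_ref[[k]]$status, "optimal")) return(NULL)
    wfx <- pd_ref[[k]]$exchange_fluxes[ex_ids]
    entropic_objective(g = objective$g, h = wfx,
                       H = setNames(rep(config$exchange_penalty,
                                        length(ex_ids)), ex_ids))
  })
  # the unforced relaxed-bounds solve is the reference state for improvement
  # calls, so a forcing factor of 1 reproduces "no improvement" exactly
  relaxed_ref <- purrr::map(seq_along(config$demands), function(k) {
    if (is.null(objectives[[k]])) return(list(status = "reference_unavailable"))
    mi <- relax_model(config$demands[k])
    sol <- solve_entropic_fba(mi, objectives[[k]], control)
    if (sol$status != "optimal") return(list(status = sol$status))
    acc <- atp_accounting(mi, sol, tol = config$tol)
    list(status = "optimal",
         demand = config$demands[k],
         atps_flux = flux_of(sol, config$atps_id),
         glycolysis_atp = sum(acc$atp_rate[
           acc$role == "contributor" &
             acc$subsystem == config$glycolysis_subsystem]),
         exchange_fluxes = setNames(sol$fluxes$net, sol$fluxes$reaction_id),
         solution = sol)
  })

  details <- list()
  rows <- purrr::map(reactions, function(rid) {
    base_fluxes <- purrr::map_dbl(seq_along(config$demands), function(k) {
      if (!identical(relaxed_ref[[k]]$status, "optimal")) return(NA_real_)
      unname(relaxed_ref[[k]]$exchange_fluxes[[rid]])
    })
    if (all(is.na(base_fluxes)) || all(abs(base_fluxes) <= config$tol,
                                       na.rm = TRUE)) {
      return(tibble(reaction_id = rid, energy_improved_all = FALSE,
                    exchanges_improved = 0L, exchanges_worsened = 0L,
                    overall = FALSE, status = "skipped_zero_flux"))
    }
    models <- purrr::map(seq_along(config$demands), function(k) {
      v0 <- base_fluxes[k]
      if (is.na(v0)) return(NULL)
      mi <- relax_model(config$demands[k])
      target <- config$increase_factor * abs(v0) * sign(v0)
      bb <- get_bounds(mi, rid)
      # the existing capacity bound in the forcing direction is respected:
      # a target beyond it makes the forced solve infeasible
      if (v0 > 0) {
        if (target > bb[["upper"]] + 1e-12) return("capacity_exceeded")
        mi <- set_bounds(mi, rid, lower = target)
      } else {
        if (target < bb[["lower"]] - 1e-12) return("capacity_exceeded")
        mi <- set_bounds(mi, rid, upper = target)
      }
      mi
    })
    if (any(purrr::map_lgl(models, ~is.character(.x)))) {
      return(tibble(reaction_id = rid, energy_improved_all = FALSE,
                    exchanges_improved = 0L, exchanges_worsened = 0L,
                    overall = FALSE, status = "infeasible"))
    }
    ev <- evaluate_rescue_multi(models, objectives, reference, relaxed_ref,
                                config, control)
    details[[rid]] <<- ev
    tibble(reaction_id = rid,
           energy_improved_all = ev$energy_improved_all,
           exchanges_improved = ev$exchanges_improved,
           exchanges_worsened = ev$exchanges_worsened,
           overall = ev$overall,
           status = if (all(ev$feasible)) "optimal"
                    else if (any(ev$feasible)) "partially_feasible"
                    else "infeasible")
  })
  out <- bind_rows(rows)
  class(out) <- c("rescue_scan", class(out))
  attr(out, "mode") <- "increase"
  attr(out, "details") <- details
  out
}

# like evaluate_rescue but with a per-demand objective (increase mode)
evaluate_rescue_multi <- function(models, objectives, reference, pd_ref,
                                  config, control) {
  per_demand <- purrr::map(seq_along(models), function(k) {
    mi <- models[[k]]
    if (is.null(mi)) return(list(status = "reference_unavailable"))
    ev <- evaluate_rescue(list(mi), reference[k], pd_ref[k], config,
                          objectives[[k]], control, mode = "increase")
    ev$per_demand[[1]]
  })
  feasible <- purrr::map_lgl(per_demand, ~identical(.x$status, "optimal"))
  energy_all <- length(per_demand) > 0 && all(feasible) &&
    all(purrr::map_lgl(per_demand[feasible], "energy_improved"))
  n_impr <- if (any(feasible))
    max(purrr::map_int(per_demand[feasible], "n_improved")) else 0L
  n_wors <- if (any(feasible))
    max(purrr::map_int(per_demand[feasible], "n_worsened")) else 0L
  list(per_demand = per_demand, feasible = feasible,
       energy_improved_all = energy_all, exchanges_improved = n_impr,
       exchanges_worsened = n_wors,
       overall = energy_all && n_impr >= 1L && n_wors == 0L)
}
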