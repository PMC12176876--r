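#' Per-reaction net ATP production accounting
#'
#' The net ATP production rate of a reaction is the flux-weighted sum of its
#' stoichiometric coefficients over the ATP species: `sum_m S[m, r] * v_r` for
#' `m` in `atp_species`. Contributors have net production above `tol` with a
#' non-zero flux; consumers have net production below `-tol`. Transporters
#' moving ATP between compartments net to zero and fall in neither set
#' (netting is global across compartments).
#'
#' @param model a [metabolic_model()].
#' @param solution an optimal `entropic_solution` for `model`.
#' @param atp_species metabolite ids counted as ATP; default: every metabolite
#'   flagged `is_atp_species` (base id `"atp"` in any compartment).
#' @param tol flux tolerance for the non-zero-flux classification
#'   (mu mol/gDW/h).
#' @return object of class `atp_accounting`: a tibble with columns
#'   `reaction_id`, `subsystem`, `flux`, `atp_rate`, `role`
#'   (`"contributor"`, `"consumer"`, `"none"`).
#' @export
atp_accounting <- function(model, solution, atp_species = NULL, tol = 1e-6) {
  stopifnot(inherits(solution, "entropic_solution"))
  if (solution$status != "optimal") {
    abort("ATP accounting requires an optimal solution.")
  }
  if (is.null(atp_species)) {
    atp_species <- model$metabolites$id[model$metabolites$is_atp_species]
  }
  if (!length(atp_species)) {
    abort("`atp_species` is empty; configure at least one ATP metabolite.")
  }
  unknown <- setdiff(atp_species, model$metabolites$id)
  if (length(unknown)) {
    abort(paste0("Unknown ATP species: ", paste(unknown, collapse = ", ")))
  }

  S <- stoich_matrix(model)
  coef <- Matrix::colSums(S[atp_species, , drop = FALSE])
  v <- setNames(solution$fluxes$net, solution$fluxes$reaction_id)
  v <- v[model$reactions$id]
  rate <- unname(coef[model$reactions$id] * v)

  out <- tibble(
    reaction_id = model$reactions$id,
    subsystem = model$reactions$subsystem,
    flux = unname(v),
    atp_rate = rate,
    role = dplyr::case_when(
      rate > tol & abs(v) > tol ~ "contributor",
      rate < -tol & abs(v) > tol ~ "consumer",
      TRUE ~ "none"))
  class(out) <- c("atp_accounting", class(out))
  attr(out, "atp_species") <- atp_species
  attr(out, "tol") <- tol
  out
}

#' Subsystem shares of ATP contribution
#'
#' Aggregates contributor ATP production by subsystem. Shares are fractions of
#' total contributor flux; consumers are not counted.
#'
#' @param accounting an [atp_accounting()] result.
#' @return tibble with columns `subsystem`, `flux`, `share`; when no reaction
#'   contributes, shares are `NA` and the attribute `undefined` is `TRUE`.
#' @export
subsystem_shares <- function(accounting) {
  stopifnot(inherits(accounting, "atp_accounting"))
  contr <- dplyr::filter(accounting, .data$role == "contributor")
  if (nrow(contr) == 0L || sum(contr$atp_rate) <= 0) {
    out <- tibble(subsystem = character(), flux = numeric(),
                  share = numeric())
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- contr |>
    group_by(.data$subsystem) |>
    summarise(flux = sum(.data$atp_rate), .groups = "drop") |>
    mutate(share = .data$flux / sum(.data$flux)) |>
    arrange(dplyr::desc(.data$flux))
  attr(out, "undefined") <- FALSE
  out
}

#' Energy-demand scan
#'
#' For each demand value, the lower bound of the ATPM (maintenance) reaction
#' is raised to that demand, the entropic problem re-solved, and contributor
#' ATP production aggregated by subsystem. Infeasible grid points are flagged
#' in the result, never dropped silently.
#'
#' @param model a [metabolic_model()].
#' @param demands numeric vector of ATPM lower-bound values (mu mol/gDW/h);
#'   default 10 to 600 in steps of 10.
#' @param objective an [entropic_objective()].
#' @param atp_species,tol forwarded to [atp_accounting()].
#' @param control a [solver_control()].
#' @return object of class `demand_scan`: tidy tibble with columns `demand`,
#'   `subsystem`, `flux`, `share`, `status`; infeasible demands appear as a
#'   single row with `NA` subsystem and their solver status.
#' @export
demand_scan <- function(model, demands = seq(10, 600, by = 10),
                        objective = entropic_objective(),
                        atp_species = NULL, tol = 1e-6,
                        control = solver_control()) {
  validate_model(model)
  ub_atpm <- get_bounds(model, model$atpm_id)[["upper"]]
  if (any(demands < 0 | demands > ub_atpm)) {
    abort(sprintf("demand values must lie within [0, %g] (ATPM upper bound).",
                  ub_atpm))
  }
  warm <- NULL
  rows <- purrr::map(demands, function(d) {
    md <- set_bounds(model, model$atpm_id, lower = d)
    sol <- solve_entropic_fba(md, objective, control, x_start = warm)
    if (sol$status != "optimal") {
      return(tibble(demand = d, subsystem = NA_character_, flux = NA_real_,
                    share = NA_real_, status = sol$status))
    }
    warm <<- setNames(sol$fluxes$net, sol$fluxes$reaction_id)
    acc <- atp_accounting(md, sol, atp_species = atp_species, tol = tol)
    sh <- subsystem_shares(acc)
    if (isTRUE(attr(sh, "undefined"))) {
      return(tibble(demand = d, subsystem = NA_character_, flux = 0,
                    share = NA_real_, status = "optimal"))
    }
    mutate(sh, demand = d, status = "optimal") |>
      select("demand", "subsystem", "flux", "share", "status")
  })
  out <- bind_rows(rows)
  class(out) <- c("demand_scan", class(out))
  attr(out, "atpm_id") <- model$atpm_id
  out
}

#' Total and per-subsystem contribution at one demand of a scan
#'
#' @param scan a [demand_scan()] result.
#' @param subsystem subsystem label to extract.
#' @return tibble of `demand`, `flux` for that subsystem (feasible points).
#' @export
scan_subsystem_flux <- function(scan, subsystem) {
  stopifnot(inherits(scan, "demand_scan"))
  scan |>
    filter(.data$status == "optimal", .data$subsystem == !!subsystem) |>
    select("demand", "flux")
}
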