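#' Complex I inhibition scan
#'
#' Scales the capacity bound of the Complex I reaction (the bound limiting its
#' active direction) to `(1 - alpha)` times its reference capacity for each
#' inhibition fraction `alpha`, re-solves the entropic problem at a fixed
#' energy demand, and records Complex I and ATP-synthase fluxes. Full
#' inhibition (`alpha = 1`) forces zero Complex I flux. The reference capacity
#' is the bound of the unperturbed model, not the baseline flux. The
#' inflection point is the smallest alpha at which ATP-synthase flux drops
#' more than `drop_fraction` below its `alpha = 0` value.
#'
#' @param model a [metabolic_model()].
#' @param complex1_id id of the Complex I reaction.
#' @param alphas inhibition fractions in `[0, 1]`.
#' @param demand ATPM lower bound applied during the scan (mu mol/gDW/h).
#' @param atps_id id of the ATP synthase reaction.
#' @param drop_fraction relative ATP-synthase flux drop defining the
#'   inflection point (default 0.01).
#' @param objective an [entropic_objective()].
#' @param control a [solver_control()].
#' @return object of class `inhibition_scan`: tibble with columns `alpha`,
#'   `complex1_flux`, `atps_flux`, `status`; attributes `inflection_alpha`,
#'   `demand`, `reference_capacity`.
#' @export
complex1_scan <- function(model, complex1_id, alphas = seq(0, 1, by = 0.1),
                          demand, atps_id, drop_fraction = 0.01,
                          objective = entropic_objective(),
                          control = solver_control()) {
  if (!complex1_id %in% model$reactions$id) {
    abort(sprintf("Unknown reaction '%s'.", complex1_id))
  }
  if (!atps_id %in% model$reactions$id) {
    abort(sprintf("Unknown reaction '%s'.", atps_id))
  }
  if (any(alphas < 0 | alphas > 1)) abort("alphas must lie in [0, 1].")
  bb <- get_bounds(model, complex1_id)
  # capacity = bound limiting the active (positive) direction
  ref <- bb[["upper"]]
  md0 <- set_bounds(model, model$atpm_id, lower = demand)
  warm <- NULL
  rows <- purrr::map(sort(alphas), function(a) {
    cap <- (1 - a) * ref
    mi <- set_bounds(md0, complex1_id,
                     lower = min(bb[["lower"]], cap), upper = cap)
    sol <- solve_entropic_fba(mi, objective, control, x_start = warm)
    if (sol$status != "optimal") {
      return(tibble(alpha = a, complex1_flux = NA_real_,
                    atps_flux = NA_real_, status = sol$status))
    }
    warm <<- setNames(sol$fluxes$net, sol$fluxes$reaction_id)
    tibble(alpha = a, complex1_flux = flux_of(sol, complex1_id),
           atps_flux = flux_of(sol, atps_id), status = "optimal")
  })
  out <- bind_rows(rows)
  base <- out$atps_flux[out$alpha == min(out$alpha)][1]
  dropped <- out$status == "optimal" &
    out$atps_flux < (1 - drop_fraction) * base
  infl <- if (any(dropped, na.rm = TRUE)) min(out$alpha[which(dropped)])
          else NA_real_
  class(out) <- c("inhibition_scan", class(out))
  attr(out, "inflection_alpha") <- infl
  attr(out, "demand") <- demand
  attr(out, "reference_capacity") <- ref
  out
}

#' Substrate availability scan
#'
#' Tightens the uptake capacity of an exchange reaction from its current
#' lower bound toward zero and records ATP-synthase flux at each grid point.
#' (Uptake is negative flux, so the capacity is the lower bound; when the
#' exchange carries a mandatory-uptake upper bound below the grid point, the
#' upper bound is relaxed to the grid point so the constraint set stays
#' consistent.)
#'
#' @param model a [metabolic_model()].
#' @param exchange_id id of the exchange reaction to restrict.
#' @param grid uptake lower-bound values; default 11 points from the current
#'   lower bound to 0.
#' @param demand ATPM lower bound applied during the scan.
#' @param atps_id id of the ATP synthase reaction.
#' @param objective an [entropic_objective()].
#' @param control a [solver_control()].
#' @return object of class `substrate_scan`: tibble with columns `uptake_bound`,
#'   `exchange_flux`, `atps_flux`, `status`.
#' @export
substrate_scan <- function(model, exchange_id, grid = NULL, demand, atps_id,
                           objective = entropic_objective(),
                           control = solver_control()) {
  i <- match(exchange_id, model$reactions$id)
  if (is.na(i)) abort(sprintf("Unknown reaction '%s'.", exchange_id))
  if (!model$reactions$is_exchange[i]) {
    abort(sprintf("'%s' is not an exchange reaction.", exchange_id))
  }
  bb <- get_bounds(model, exchange_id)
  if (bb[["lower"]] >= 0) {
    abort(sprintf("'%s' does not admit uptake (lower bound >= 0).",
                  exchange_id))
  }
  if (is.null(grid)) grid <- seq(bb[["lower"]], 0, length.out = 11)
  md0 <- set_bounds(model, model$atpm_id, lower = demand)
  warm <- NULL
  rows <- purrr::map(grid, function(lo) {
    up <- min(0, max(bb[["upper"]], lo))
    ms <- set_bounds(md0, exchange_id, lower = lo, upper = up)
    sol <- solve_entropic_fba(ms, objective, control, x_start = warm)
    if (sol$status != "optimal") {
      return(tibble(uptake_bound = lo, exchange_flux = NA_real_,
                    atps_flux = NA_real_, status = sol$status))
    }
    warm <<- setNames(sol$fluxes$net, sol$fluxes$reaction_id)
    tibble(uptake_bound = lo, exchange_flux = flux_of(sol, exchange_id),
           atps_flux = flux_of(sol, atps_id), status = "optimal")
  })
  out <- bind_rows(rows)
  class(out) <- c("substrate_scan", class(out))
  attr(out, "exchange_id") <- exchange_id
  attr(out, "demand") <- demand
  out
}
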