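#' Core metabolic function checks
#'
#' Verifies that the model can sustain a positive maintenance (ATPM) flux on
#' each named carbon source: for every test, all other carbon-source uptakes
#' are closed, the named source (plus oxygen, unless the test is anaerobic)
#' is opened, and the maximal achievable ATPM flux is computed with a linear
#' objective. An infeasible base model yields an explicit infeasibility
#' report rather than an error.
#'
#' @param model a [metabolic_model()] with an ATPM-role reaction.
#' @param carbon_sources named list: test name -> exchange reaction id(s) to
#'   leave open. Default covers glucose (aerobic), glucose (anaerobic,
#'   glycolysis only), lactate (aerobic), and an all-closed control.
#' @param oxygen_id oxygen exchange id (default `"EX_o2[e]"`).
#' @param demand_free logical; when `TRUE` (default) the ATPM lower bound and
#'   any mandatory-uptake/-secretion bounds on closed exchanges are relaxed so
#'   the test isolates the carbon source.
#' @param control a [solver_control()].
#' @return tibble with columns `test`, `sources`, `aerobic`, `max_atpm`,
#'   `status`, `pass`.
#' @export
validate_core_functions <- function(model, carbon_sources = NULL,
                                    oxygen_id = "EX_o2[e]",
                                    demand_free = TRUE,
                                    control = solver_control()) {
  validate_model(model)
  ex_ids <- model$reactions$id[model$reactions$is_exchange]
  if (is.null(carbon_sources)) {
    pick <- function(id) intersect(id, ex_ids)
    carbon_sources <- list(
      aerobic_glucose = list(sources = pick("EX_glc_D[e]"), aerobic = TRUE),
      anaerobic_glucose = list(sources = pick("EX_glc_D[e]"),
                               aerobic = FALSE),
      aerobic_lactate = list(sources = pick("EX_lac_L[e]"), aerobic = TRUE),
      no_carbon = list(sources = character(), aerobic = TRUE))
  }

  # carbon-bearing uptakes that the tests toggle: any exchange that admits
  # uptake, except oxygen
  uptake_ids <- model$reactions$id[model$reactions$is_exchange &
                                     model$reactions$lower_bound < 0]
  uptake_ids <- setdiff(uptake_ids, oxygen_id)

  rows <- purrr::imap(carbon_sources, function(spec, nm) {
    m <- model
    if (demand_free) {
      # drop every mandatory demand (maintenance, basal internal activity,
      # forced secretion/uptake) so only the carbon source matters
      m$reactions$lower_bound <- pmin(m$reactions$lower_bound, 0)
      m$reactions$upper_bound <- pmax(m$reactions$upper_bound, 0)
    }
    for (ex in setdiff(uptake_ids, spec$sources)) {
      m <- set_bounds(m, ex, lower = 0)
    }
    if (!spec$aerobic && oxygen_id %in% ex_ids) {
      m <- set_bounds(m, oxygen_id, lower = 0)
    }
    res <- maximize_reaction_flux(m, m$atpm_id, control = control)
    tibble(test = nm,
           sources = paste(spec$sources, collapse = ";"),
           aerobic = spec$aerobic,
           max_atpm = res$value,
           status = res$status,
           pass = identical(res$status, "optimal") && res$value > 1e-6)
  })
  bind_rows(rows)
}

#' Maximal achievable flux of one reaction (linear objective)
#'
#' Solves `max v_target` subject to mass balance, couplings and bounds with
#' the package's interior-point method (linear objective mode). Used by the
#' validity checks; the entropic objective is not applied here.
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction to maximize.
#' @param control a [solver_control()].
#' @return list with `value` (maximal flux, `NA` if infeasible) and `status`.
#' @export
maximize_reaction_flux <- function(model, reaction_id,
                                   control = solver_control()) {
  mats <- assemble_matrices(model)
  ids <- c(mats$internal_ids, mats$exchange_ids)
  n <- length(ids)
  i <- match(reaction_id, ids)
  if (is.na(i)) abort(sprintf("Unknown reaction '%s'.", reaction_id))
  A <- cbind(as.matrix(mats$N), as.matrix(mats$B))
  rownames(A) <- model$metabolites$id
  lb <- c(mats$lb_internal, mats$lb_exchange)
  ub <- c(mats$ub_internal, mats$ub_exchange)
  ce <- rep(0, n); ce[i] <- -1
  Ck <- if (nrow(mats$C) > 0) {
    cbind(as.matrix(mats$C),
          matrix(0, nrow(mats$C), length(mats$exchange_ids)))
  } else NULL
  res <- barrier_solve(A, mats$b, lb, ub, entropic = rep(FALSE, n),
                       g = rep(2, n), ce = ce, h = rep(0, n),
                       Hd = rep(0, n), C = Ck, d = mats$d,
                       control = modifyList(control, list(mu_min = 1e-9)))
  if (res$status != "optimal") {
    return(list(value = NA_real_, status = res$status,
                hint = res$infeasibility_hint %||% NULL))
  }
  list(value = res$x[i], status = "optimal")
}
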