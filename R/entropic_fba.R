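#' Construct an entropic FBA objective
#'
#' The objective is `sum_i g_i (vf_i log vf_i + vr_i log vr_i) + ce' w +
#' 0.5 (x - h)' H (x - h)` over unidirectional internal fluxes `vf, vr` and
#' exchange fluxes `w`. `g` is the entropy weight on internal reactions
#' (default 2 uniformly), `ce` a linear coefficient on exchange reactions, and
#' `h`/`H` an optional diagonal quadratic penalty pulling named reactions
#' toward target fluxes (used by the flux-forcing rescue mode).
#'
#' @param g single positive number or named vector of per-internal-reaction
#'   entropy weights.
#' @param ce named numeric of linear exchange coefficients (default all 0).
#' @param h named numeric of target net fluxes (reaction id -> target).
#' @param H named numeric of nonnegative diagonal penalty weights; every
#'   reaction with `H > 0` must have a target in `h`.
#' @return object of class `entropic_objective`.
#' @export
entropic_objective <- function(g = 2, ce = NULL, h = NULL, H = NULL) {
  if (any(g <= 0)) abort("entropy weights `g` must be strictly positive.")
  if (!is.null(H)) {
    if (any(H < 0)) abort("quadratic penalty weights `H` must be >= 0.")
    needs_h <- names(H)[H > 0]
    if (length(setdiff(needs_h, names(h %||% numeric())))) {
      abort("every reaction with H > 0 needs a target flux in `h`.")
    }
  }
  structure(list(g = g, ce = ce %||% numeric(), h = h %||% numeric(),
                 H = H %||% numeric()),
            class = "entropic_objective")
}

#' Solve the entropic flux balance problem
#'
#' Minimizes the strictly convex entropy objective over unidirectional fluxes
#' subject to mass balance `N (vf - vr) + B w = b`, optional flux couplings
#' `C (vf - vr) <= d`, and box constraints on net fluxes. All internal
#' reactions are split into forward/reverse components; irreversibility is
#' enforced through net-flux bounds only, so the unidirectional components
#' stay strictly positive and the interior product law `vf * vr = exp(-2)`
#' holds for every internal reaction at the optimum.
#'
#' Dual variables are returned with the sign convention of the Lagrangian
#' `objective - y_N' (N v + B w - b) + y_C' (C v - d) - z_l'(x - l) +
#' z_u'(x - u)`; `y_N` prices the mass-balance equality and is interpreted as
#' the chemical potential of each metabolite.
#'
#' @param model a [metabolic_model()].
#' @param objective an [entropic_objective()].
#' @param control a [solver_control()].
#' @param x_start optional named warm-start vector of net fluxes.
#' @return object of class `entropic_solution` with elements `fluxes` (tibble:
#'   reaction id, vf, vr, net, bounds), `potentials` (tibble: metabolite,
#'   potential), `duals` (y_N, y_C, z_v lower/upper), `objective_value`,
#'   `status` (one of `"optimal"`, `"infeasible"`, `"numerical_failure"`).
#' @export
solve_entropic_fba <- function(model, objective = entropic_objective(),
                               control = solver_control(), x_start = NULL) {
  mats <- assemble_matrices(model)
  ni <- length(mats$internal_ids)
  ne <- length(mats$exchange_ids)
  ids <- c(mats$internal_ids, mats$exchange_ids)
  n <- ni + ne

  A <- cbind(as.matrix(mats$N), as.matrix(mats$B))
  colnames(A) <- ids
  lb <- c(mats$lb_internal, mats$lb_exchange)
  ub <- c(mats$ub_internal, mats$ub_exchange)

  g <- rep(0, n)
  gi <- if (length(objective$g) == 1L) rep(objective$g, ni) else {
    if (is.null(names(objective$g))) {
      abort("vector `g` must be named by internal reaction id.")
    }
    gg <- rep(2, ni)
    hit <- match(names(objective$g), mats$internal_ids)
    gg[hit[!is.na(hit)]] <- objective$g[!is.na(hit)]
    gg
  }
  g[seq_len(ni)] <- gi
  entropic <- c(rep(TRUE, ni), rep(FALSE, ne))

  ce <- rep(0, n)
  if (length(objective$ce)) {
    hit <- match(names(objective$ce), ids)
    if (anyNA(hit)) abort("`ce` names unknown reactions.")
    ce[hit] <- objective$ce
  }
  h <- rep(0, n); Hd <- rep(0, n)
  if (length(objective$H)) {
    hit <- match(names(objective$H), ids)
    if (anyNA(hit)) abort("`H` names unknown reactions.")
    Hd[hit] <- objective$H
  }
  if (length(objective$h)) {
    hit <- match(names(objective$h), ids)
    if (anyNA(hit)) abort("`h` names unknown reactions.")
    h[hit] <- objective$h
  }

  Ck <- if (nrow(mats$C) > 0) {
    cbind(as.matrix(mats$C), matrix(0, nrow(mats$C), ne))
  } else NULL

  xs <- NULL
  if (!is.null(x_start)) {
    xs <- rep(NA_real_, n)
    hit <- match(names(x_start), ids)
    xs[hit[!is.na(hit)]] <- x_start[!is.na(hit)]
    xs[is.na(xs)] <- 0
  }

  res <- barrier_solve(A, mats$b, lb, ub, entropic = entropic, g = g,
                       ce = ce, h = h, Hd = Hd, C = Ck, d = mats$d,
                       control = control, x_start = xs,
                       diagnose_infeasible = is.null(xs))
  if (res$status != "optimal" && !is.null(xs)) {
    # a stale warm start can strand the iteration; retry cold
    res <- barrier_solve(A, mats$b, lb, ub, entropic = entropic, g = g,
                         ce = ce, h = h, Hd = Hd, C = Ck, d = mats$d,
                         control = control, x_start = NULL)
  }

  if (res$status != "optimal") {
    sol <- structure(
      list(fluxes = tibble(reaction_id = ids, vf = NA_real_, vr = NA_real_,
                           net = NA_real_, lower_bound = unname(lb),
                           upper_bound = unname(ub),
                           is_exchange = !entropic),
           potentials = tibble(metabolite_id = model$metabolites$id,
                               potential = NA_real_),
           duals = NULL, objective_value = NA_real_,
           status = res$status,
           infeasibility_hint = res$infeasibility_hint %||% NULL,
           model_labels = list(component = model$component,
                               condition = model$condition)),
      class = "entropic_solution")
    return(sol)
  }

  x <- res$x
  v_int <- x[seq_len(ni)]
  w <- x[ni + seq_len(ne)]
  sp <- ent_split(v_int)
  fluxes <- tibble(
    reaction_id = ids,
    vf = c(sp$vf, rep(NA_real_, ne)),
    vr = c(sp$vr, rep(NA_real_, ne)),
    net = c(v_int, w),
    lower_bound = unname(lb), upper_bound = unname(ub),
    is_exchange = !entropic)

  structure(
    list(fluxes = fluxes,
         potentials = tibble(metabolite_id = model$metabolites$id,
                             potential = unname(res$y)),
         duals = list(y_N = setNames(res$y, model$metabolites$id),
                      y_C = setNames(res$y_C, model$couplings$id),
                      z_v_lower = setNames(res$z_lower, ids),
                      z_v_upper = setNames(res$z_upper, ids)),
         objective_value = res$objective,
         primal_residual = res$primal_residual,
         status = "optimal",
         objective = objective,
         model_labels = list(component = model$component,
                             condition = model$condition)),
    class = "entropic_solution")
}

#' @export
print.entropic_solution <- function(x, ...) {
  cat(sprintf("<entropic_solution> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective %.6g, %d reactions", x$objective_value,
                nrow(x$fluxes)))
  }
  cat("\n")
  invisible(x)
}

#' Net flux of one reaction in a solution
#'
#' @param solution an `entropic_solution`.
#' @param reaction_id reaction id.
#' @return the net (internal) or external flux.
#' @export
flux_of <- function(solution, reaction_id) {
  i <- match(reaction_id, solution$fluxes$reaction_id)
  if (is.na(i)) abort(sprintf("Unknown reaction '%s'.", reaction_id))
  solution$fluxes$net[i]
}

#' KKT residuals of an entropic FBA solution
#'
#' Recomputes, from the model and solution, the stationarity residuals of the
#' reduced problem, the primal feasibility residuals (mass balance, couplings,
#' box), and the complementarity products of the bound duals. The worst
#' offending reaction/metabolite per block is named.
#'
#' @param model the solved [metabolic_model()].
#' @param objective the [entropic_objective()] used.
#' @param solution the `entropic_solution` to check.
#' @return tibble with columns `block`, `max_residual`, `worst`.
#' @export
kkt_residuals <- function(model, objective, solution) {
  stopifnot(inherits(solution, "entropic_solution"))
  if (solution$status != "optimal") {
    abort("KKT residuals are only defined for optimal solutions.")
  }
  mats <- assemble_matrices(model)
  ids <- c(mats$internal_ids, mats$exchange_ids)
  ni <- length(mats$internal_ids)
  ne <- length(mats$exchange_ids)

  if (ni + ne == 0L) {
    return(tibble(block = c("stationarity", "mass_balance", "coupling",
                            "complementarity"),
                  max_residual = 0, worst = NA_character_))
  }

  fl <- solution$fluxes[match(ids, solution$fluxes$reaction_id), ]
  x <- fl$net
  v <- x[seq_len(ni)]
  w <- if (ne) x[ni + seq_len(ne)] else numeric()

  g <- if (length(objective$g) == 1L) rep(objective$g, ni) else {
    gg <- rep(2, ni)
    hit <- match(names(objective$g), mats$internal_ids)
    gg[hit[!is.na(hit)]] <- objective$g[!is.na(hit)]
    gg
  }
  ce <- rep(0, ni + ne); h <- rep(0, ni + ne); Hd <- rep(0, ni + ne)
  if (length(objective$ce)) ce[match(names(objective$ce), ids)] <- objective$ce
  if (length(objective$h)) h[match(names(objective$h), ids)] <- objective$h
  if (length(objective$H)) Hd[match(names(objective$H), ids)] <- objective$H

  y <- unname(solution$duals$y_N[model$metabolites$id])
  y_C <- unname(solution$duals$y_C)
  z_lo <- unname(solution$duals$z_v_lower[ids])
  z_up <- unname(solution$duals$z_v_upper[ids])

  A <- cbind(as.matrix(mats$N), as.matrix(mats$B))
  grad <- ce + Hd * (x - h)
  if (ni) {
    s <- ent_split(v)
    grad[seq_len(ni)] <- grad[seq_len(ni)] + (g / 2) * log(s$vf / s$vr)
  }
  stat <- grad - as.vector(crossprod(A, y)) - z_lo + z_up
  if (nrow(mats$C) > 0) {
    Cfull <- cbind(as.matrix(mats$C), matrix(0, nrow(mats$C), ne))
    stat <- stat + as.vector(crossprod(Cfull, y_C))
    coup_res <- pmax(as.vector(Cfull %*% x) - mats$d, 0)
  } else {
    coup_res <- 0
  }

  mb <- as.vector(A %*% x) - mats$b
  lb <- c(mats$lb_internal, mats$lb_exchange)
  ub <- c(mats$ub_internal, mats$ub_exchange)
  comp <- pmax(abs(z_lo * (x - lb)), abs(z_up * (ub - x)))
  comp[!is.finite(comp)] <- 0   # infinite bounds carry zero duals

  worst_of <- function(res, names) {
    if (!length(res) || max(res) == 0) NA_character_
    else names[which.max(res)]
  }
  tibble(
    block = c("stationarity", "mass_balance", "coupling", "complementarity"),
    max_residual = c(max(abs(stat)), max(abs(mb)),
                     max(coup_res), max(comp)),
    worst = c(worst_of(abs(stat), ids),
              worst_of(abs(mb), model$metabolites$id),
              if (nrow(mats$C) > 0) worst_of(coup_res, model$couplings$id)
              else NA_character_,
              worst_of(comp, ids)))
}

#' Metabolite chemical potentials of a solution
#'
#' The dual variable of each metabolite's mass-balance constraint, interpreted
#' as its chemical potential: the marginal objective cost of that metabolite's
#' steady state.
#'
#' @param solution an optimal `entropic_solution`.
#' @param metabolite_ids ids to look up; `NULL` returns the full map.
#' @return named numeric of potentials.
#' @export
chemical_potentials <- function(solution, metabolite_ids = NULL) {
  stopifnot(inherits(solution, "entropic_solution"))
  if (solution$status != "optimal") {
    abort("chemical potentials require an optimal solution.")
  }
  pots <- setNames(solution$potentials$potential,
                   solution$potentials$metabolite_id)
  if (is.null(metabolite_ids)) return(pots)
  unknown <- setdiff(metabolite_ids, names(pots))
  if (length(unknown)) {
    abort(paste0("Unknown metabolites: ", paste(unknown, collapse = ", ")))
  }
  pots[metabolite_ids]
}

#' Export solution tables
#'
#' Writes the per-reaction flux table (id, vf, vr, net, bounds) and the
#' metabolite potential table as tab-separated files.
#'
#' @param solution an `entropic_solution`.
#' @param flux_path,potential_path destination files.
#' @return invisibly, the two paths.
#' @export
export_solution_tables <- function(solution, flux_path, potential_path) {
  write.table(solution$fluxes, flux_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(solution$potentials, potential_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(flux_path, potential_path))
}
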