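#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles the stoichiometry of a compartmented reaction
#' network with flux bounds, subsystem labels, optional flux-coupling
#' constraints and a metabolite accumulation right-hand side. Exchange
#' (boundary) reactions are auto-detected as the columns of the stoichiometric
#' matrix that touch exactly one metabolite pool; their flux sign convention
#' throughout the package is negative = uptake, positive = secretion.
#'
#' @param metabolites tibble with columns `id` (compartment-suffixed, e.g.
#'   `"atp[m]"`), and optionally `name`, `compartment`, `is_atp_species`.
#' @param reactions tibble with columns `id`, and optionally `lower_bound`,
#'   `upper_bound` (mu mol/gDW/h), `subsystem`, `reversible`. Missing bounds
#'   default to (-1000, 1000) for reversible reactions and (0, 1000) for
#'   irreversible ones.
#' @param stoichiometry tibble with columns `reaction_id`, `metabolite_id`,
#'   `coefficient` (signed reals; products positive, substrates negative).
#' @param couplings optional tibble with columns `id`, `rhs` and a list-column
#'   `coefficients` of named numeric vectors (reaction id -> coefficient),
#'   encoding rows of `C (vf - vr) <= d`.
#' @param b optional named numeric of per-metabolite accumulation rates
#'   (defaults to 0, i.e. steady state).
#' @param component `"synaptic"`, `"nonsynaptic"` or `NA`.
#' @param condition `"control"`, `"pd"` or `NA`.
#' @param atpm_id id of the ATP maintenance (energy demand) reaction.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            couplings = NULL, b = NULL,
                            component = NA_character_,
                            condition = NA_character_,
                            atpm_id = "ATPM") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) {
    metabolites$compartment <- met_compartment(metabolites$id)
  }
  if (!"is_atp_species" %in% names(metabolites)) {
    metabolites$is_atp_species <- met_base_id(metabolites$id) == "atp"
  }
  if (anyDuplicated(metabolites$id)) {
    abort(paste0("Duplicate metabolite ids: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(reactions$id)) {
    abort(paste0("Duplicate reaction ids: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]),
                       collapse = ", ")))
  }

  if (!"reversible" %in% names(reactions)) reactions$reversible <- NA
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  # default reversibility from supplied bounds if present, else reversible
  rev_guess <- ifelse(is.na(reactions$lower_bound), TRUE,
                      reactions$lower_bound < 0)
  reactions$reversible <- ifelse(is.na(reactions$reversible), rev_guess,
                                 reactions$reversible)
  reactions$lower_bound <- ifelse(
    is.na(reactions$lower_bound),
    ifelse(reactions$reversible, -1000, 0), reactions$lower_bound)
  reactions$upper_bound <- ifelse(is.na(reactions$upper_bound), 1000,
                                  reactions$upper_bound)

  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad)) {
    abort(paste0("lower_bound > upper_bound for reactions: ",
                 paste(reactions$id[bad], collapse = ", ")))
  }

  dangling_m <- setdiff(stoichiometry$metabolite_id, metabolites$id)
  if (length(dangling_m)) {
    abort(paste0("Stoichiometry references unknown metabolites: ",
                 paste(dangling_m, collapse = ", ")))
  }
  dangling_r <- setdiff(stoichiometry$reaction_id, reactions$id)
  if (length(dangling_r)) {
    abort(paste0("Stoichiometry references unknown reactions: ",
                 paste(dangling_r, collapse = ", ")))
  }

  # exchange reactions touch exactly one metabolite pool
  n_mets <- stoichiometry |>
    distinct(.data$reaction_id, .data$metabolite_id) |>
    dplyr::count(.data$reaction_id)
  ex_ids <- n_mets$reaction_id[n_mets$n == 1L]
  reactions$is_exchange <- reactions$id %in% ex_ids

  if (is.null(b)) b <- setNames(rep(0, nrow(metabolites)), metabolites$id)
  b_full <- setNames(rep(0, nrow(metabolites)), metabolites$id)
  b_full[names(b)] <- b

  if (!is.null(couplings)) {
    couplings <- as_tibble(couplings)
    for (cf in couplings$coefficients) {
      unknown <- setdiff(names(cf), reactions$id)
      if (length(unknown)) {
        abort(paste0("Coupling constraint references unknown reactions: ",
                     paste(unknown, collapse = ", ")))
      }
    }
  } else {
    couplings <- tibble(id = character(), rhs = numeric(),
                        coefficients = list())
  }

  structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, couplings = couplings,
         b = b_full, component = component, condition = condition,
         atpm_id = atpm_id),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_ex <- sum(x$reactions$is_exchange)
  cat(sprintf(
    "<metabolic_model> %d metabolites, %d reactions (%d exchange), %d couplings\n",
    nrow(x$metabolites), nrow(x$reactions), n_ex, nrow(x$couplings)))
  if (!is.na(x$component) || !is.na(x$condition)) {
    cat(sprintf("  component: %s, condition: %s\n", x$component, x$condition))
  }
  invisible(x)
}

#' Validate internal consistency of a metabolic model
#'
#' Checks identifier uniqueness, bound ordering, dangling references and the
#' presence of the designated energy-demand (ATPM) reaction.
#'
#' @param model a [metabolic_model()].
#' @return the model, invisibly; aborts with an informative message otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!model$atpm_id %in% model$reactions$id) {
    abort(sprintf("ATPM-role reaction '%s' not present in the model.",
                  model$atpm_id))
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound)) {
    abort("Model has reactions with lower_bound > upper_bound.")
  }
  invisible(model)
}

#' Full stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return sparse `Matrix` of dimension metabolites x reactions, in model order.
#' @export
stoich_matrix <- function(model) {
  i <- match(model$stoichiometry$metabolite_id, model$metabolites$id)
  j <- match(model$stoichiometry$reaction_id, model$reactions$id)
  Matrix::sparseMatrix(
    i = i, j = j, x = model$stoichiometry$coefficient,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id))
}

#' Assemble the partitioned constraint matrices of a model
#'
#' Splits the stoichiometric matrix into internal (`N`) and exchange (`B`)
#' columns, and returns bound vectors, the accumulation right-hand side and the
#' coupling matrix `C` with right-hand side `d`. Column order is deterministic
#' (model order).
#'
#' @param model a [metabolic_model()].
#' @return list with sparse matrices `N`, `B`, `C`, vectors `b`, `d`,
#'   bound vectors `lb_internal`, `ub_internal`, `lb_exchange`, `ub_exchange`
#'   and the id vectors `internal_ids`, `exchange_ids`.
#' @export
assemble_matrices <- function(model) {
  validate_model(model)
  S <- stoich_matrix(model)
  is_ex <- model$reactions$is_exchange
  internal_ids <- model$reactions$id[!is_ex]
  exchange_ids <- model$reactions$id[is_ex]

  k <- nrow(model$couplings)
  C <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(k, length(internal_ids)),
                            dimnames = list(model$couplings$id, internal_ids))
  if (k > 0) {
    C <- as(C, "CsparseMatrix")
    for (r in seq_len(k)) {
      cf <- model$couplings$coefficients[[r]]
      jj <- match(names(cf), internal_ids)
      if (anyNA(jj)) {
        abort("Coupling constraints may only reference internal reactions.")
      }
      C[r, jj] <- unname(cf)
    }
  }

  list(
    N = S[, !is_ex, drop = FALSE],
    B = S[, is_ex, drop = FALSE],
    b = model$b,
    C = C,
    d = model$couplings$rhs,
    lb_internal = setNames(model$reactions$lower_bound[!is_ex], internal_ids),
    ub_internal = setNames(model$reactions$upper_bound[!is_ex], internal_ids),
    lb_exchange = setNames(model$reactions$lower_bound[is_ex], exchange_ids),
    ub_exchange = setNames(model$reactions$upper_bound[is_ex], exchange_ids),
    internal_ids = internal_ids,
    exchange_ids = exchange_ids)
}

#' Set the bounds of one reaction
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction to edit.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return a new model (the input is not modified).
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(sprintf("Unknown reaction '%s'.", reaction_id))
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    abort(sprintf("Bounds edit makes lower > upper for reaction '%s'.",
                  reaction_id))
  }
  model
}

#' Look up the bounds of one reaction
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction id.
#' @return numeric of length 2: (lower, upper).
#' @export
get_bounds <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(sprintf("Unknown reaction '%s'.", reaction_id))
  c(lower = model$reactions$lower_bound[i],
    upper = model$reactions$upper_bound[i])
}
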