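# Small fixture networks and a lazy cache for the (more expensive) toy-model
# solves shared across test files.

# one internal reaction A -> B with fixed exchange fluxes pinning the net flux
single_reaction_model <- function(net = 1) {
  metabolic_model(
    metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "EX_B"),
      lower_bound = c(-net, -1000, -1000),
      upper_bound = c(-net, 1000, 1000)),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_A", "R1", "R1", "EX_B"),
      metabolite_id = c("A", "A", "B", "B"),
      coefficient = c(-1, -1, 1, -1)),
    atpm_id = "R1")
}

# two-internal-reaction chain A -> B -> C with boundary influx fixed
chain_model <- function(net = 1) {
  metabolic_model(
    metabolites = tibble::tibble(id = c("A", "B", "C")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "R2", "EX_C"),
      lower_bound = c(-net, -1000, -1000, -1000),
      upper_bound = c(-net, 1000, 1000, 1000)),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_A", "R1", "R1", "R2", "R2", "EX_C"),
      metabolite_id = c("A", "A", "B", "B", "C", "C"),
      coefficient = c(-1, -1, 1, -1, 1, -1)),
    atpm_id = "R1")
}

# three internal reactions: A -> B (two parallel routes) and B -> C
branched_model <- function(net = 1) {
  metabolic_model(
    metabolites = tibble::tibble(id = c("A", "B", "C")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "R2", "R3", "EX_C"),
      lower_bound = c(-net, -1000, -1000, -1000, -1000),
      upper_bound = c(-net, 1000, 1000, 1000, 1000)),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_A", "R1", "R1", "R2", "R2", "R3", "R3", "EX_C"),
      metabolite_id = c("A", "A", "B", "A", "B", "B", "C", "C"),
      coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1)),
    atpm_id = "R3")
}

vf_closed_form <- function(net) {
  (net + sqrt(net^2 + 4 * exp(-2))) / 2
}

# cache of toy models and baseline solves
.toy_cache <- new.env(parent = emptyenv())

toy_model_cached <- function(component, condition) {
  key <- paste(component, condition, sep = "_")
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- build_toy_model(toy_spec(component, condition))
  }
  .toy_cache[[key]]
}

toy_solution_cached <- function(component, condition, demand = NULL) {
  key <- paste("sol", component, condition, demand %||% "base", sep = "_")
  if (is.null(.toy_cache[[key]])) {
    m <- toy_model_cached(component, condition)
    if (!is.null(demand)) m <- set_bounds(m, "ATPM", lower = demand)
    .toy_cache[[key]] <- solve_entropic_fba(m)
  }
  .toy_cache[[key]]
}

toy_demand_scan_cached <- function(component, condition,
                                   demands = c(10.62, 60, 100)) {
  key <- paste("scan", component, condition,
               paste(demands, collapse = "-"), sep = "_")
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- demand_scan(toy_model_cached(component, condition),
                                     demands = demands)
  }
  .toy_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
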