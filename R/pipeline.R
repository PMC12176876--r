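#' Paths to the packaged reference tables
#'
#' `csf_exchange_table()` returns the direction-annotated PD-CSF exchange
#' table replica for one component (printed control/PD flux pairs, change and
#' consistency labels); `rescue_improvement_table()` returns the published
#' rescue flux triples (control, PD, rescued) with improvement calls;
#' `toy_csf_directions()` returns the toy network's curated CSF direction
#' fixture.
#'
#' @param component `"synaptic"` or `"nonsynaptic"`.
#' @return a tibble (direction columns parsed into list-columns).
#' @export
csf_exchange_table <- function(component = c("synaptic", "nonsynaptic")) {
  component <- match.arg(component)
  path <- system.file("extdata",
                      sprintf("csf_exchange_%s.tsv", component),
                      package = "neurofba")
  read_csf_table(path)
}

#' @rdname csf_exchange_table
#' @export
rescue_improvement_table <- function(component = c("synaptic",
                                                   "nonsynaptic")) {
  component <- match.arg(component)
  path <- system.file("extdata",
                      sprintf("rescue_improvement_%s.tsv", component),
                      package = "neurofba")
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, quote = ""))
}

#' @rdname csf_exchange_table
#' @export
toy_csf_directions <- function() {
  read_csf_table(system.file("extdata", "csf_directions_toy.tsv",
                             package = "neurofba"))
}

#' Configuration for the full toy analysis pipeline
#'
#' @param params a [toy_params()] list for the four variants.
#' @param demands energy-demand grid for the demand scans.
#' @param alphas Complex I inhibition grid.
#' @param scan_demand demand at which the inhibition scan runs.
#' @param rescue_demands named list: component -> rescue-scan demand.
#' @param csf_table exchange direction table for the comparisons (default
#'   the packaged toy fixture).
#' @param output_dir directory for the report bundle (`NULL` for none).
#' @param seed integer seed recorded in the summary.
#' @param rescue_reactions candidate reactions for the rescue scan
#'   (`NULL` for all internal reactions).
#' @param control a [solver_control()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(params = toy_params(),
                       demands = c(10.62, seq(20, 100, by = 20)),
                       alphas = seq(0, 1, by = 0.2),
                       scan_demand = 20,
                       rescue_demands = list(synaptic = 22,
                                             nonsynaptic = 31),
                       csf_table = toy_csf_directions(),
                       output_dir = NULL,
                       seed = 1L,
                       rescue_reactions = NULL,
                       control = solver_control()) {
  structure(list(params = params, demands = demands, alphas = alphas,
                 scan_demand = scan_demand,
                 rescue_demands = rescue_demands, csf_table = csf_table,
                 output_dir = output_dir, seed = as.integer(seed),
                 rescue_reactions = rescue_reactions, control = control),
            class = "run_config")
}

#' Run the full bioenergetic analysis on the four toy variants
#'
#' Builds the four condition-specific models, solves the entropic flux
#' problem for each, runs the energy-demand and Complex I inhibition scans,
#' compares PD exchange fluxes against the CSF direction table, and performs
#' the flux-increase rescue scan on both PD variants. With an output
#' directory, every table is written as UTF-8 tab-separated text along with
#' a JSON run summary; identical configurations produce identical bundles.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the four models, their solutions, scan
#'   tibbles, comparison tables, rescue tables and the summary list.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      tbl_out <- tbl
      if ("directions" %in% names(tbl_out)) {
        tbl_out$directions <- purrr::map_chr(tbl_out$directions,
                                             paste, collapse = ";")
      }
      write.table(tbl_out, file.path(out_dir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  fileEncoding = "UTF-8")
    }
    tbl
  }

  variants <- build_toy_variants(config$params)
  solutions <- purrr::imap(variants, function(m, nm) {
    sol <- solve_entropic_fba(m, control = config$control)
    if (sol$status != "optimal") {
      abort(sprintf("Baseline solve failed for %s (%s).", nm, sol$status))
    }
    emit(sol$fluxes, paste0("fluxes_", nm))
    sol
  })

  scans <- purrr::imap(variants, function(m, nm) {
    sc <- demand_scan(m, demands = config$demands, control = config$control)
    emit(sc, paste0("demand_scan_", nm))
    sc
  })

  inhibition <- purrr::imap(variants, function(m, nm) {
    sc <- complex1_scan(m, "CPLX1m", alphas = config$alphas,
                        demand = config$scan_demand, atps_id = "ATPS4mi",
                        control = config$control)
    emit(sc, paste0("complex1_scan_", nm))
    sc
  })

  comparisons <- list()
  if (!is.null(config$csf_table) && nrow(config$csf_table)) {
    for (comp in c("synaptic", "nonsynaptic")) {
      cmp <- build_comparison_table(
        solutions[[paste0(comp, "_control")]],
        solutions[[paste0(comp, "_pd")]],
        config$csf_table)
      comparisons[[comp]] <- emit(cmp, paste0("csf_comparison_", comp))
    }
  } else {
    warn("No CSF table supplied; comparison stage skipped.")
  }

  rescues <- list()
  for (comp in c("synaptic", "nonsynaptic")) {
    rescue_csf <- if (!is.null(config$csf_table)) {
      dplyr::filter(config$csf_table, .data$reaction_id == "EX_urea[e]")
    }
    cfg <- rescue_config(mode = "increase",
                         demands = config$rescue_demands[[comp]],
                         atps_id = "ATPS4mi",
                         csf_table = rescue_csf,
                         tol = 1e-3)
    rs <- increase_scan(variants[[paste0(comp, "_pd")]],
                        variants[[paste0(comp, "_control")]],
                        cfg, reactions = config$rescue_reactions,
                        control = config$control)
    rescues[[comp]] <- emit(rs, paste0("rescue_increase_", comp))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("neurofba")),
    seed = config$seed,
    tolerances = config$control[c("feasibility_tol", "stationarity_tol")],
    demands = config$demands,
    alphas = config$alphas,
    rescue_demands = config$rescue_demands,
    objective_values = purrr::map_dbl(solutions, "objective_value"),
    rescue_flagged = purrr::map(rescues,
                                ~.x$reaction_id[.x$overall]))
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(models = variants, solutions = solutions,
                 demand_scans = scans, inhibition_scans = inhibition,
                 comparisons = comparisons, rescues = rescues,
                 summary = summary))
}
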