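#' Classify a control-to-PD exchange-flux change
#'
#' Exchange fluxes follow the convention negative = uptake, positive =
#' secretion. The change classes are: `same` (absolute difference within
#' `tol`), `lower_uptake` / `higher_uptake` (both fluxes on the uptake side,
#' magnitude decreased / increased), `lower_excretion` / `higher_excretion`
#' (both on the secretion side), and `sign_change` (strictly opposite signs).
#'
#' @param control_flux,pd_flux finite exchange fluxes (vectorized).
#' @param tol absolute flux tolerance for `same` (default 1e-4, the precision
#'   of 4-decimal flux tables).
#' @return character vector of change classes.
#' @export
classify_exchange_change <- function(control_flux, pd_flux, tol = 1e-4) {
  if (any(!is.finite(control_flux)) || any(!is.finite(pd_flux))) {
    abort("fluxes must be finite.")
  }
  dplyr::case_when(
    abs(pd_flux - control_flux) <= tol ~ "same",
    control_flux <= 0 & pd_flux <= 0 & abs(pd_flux) < abs(control_flux) ~
      "lower_uptake",
    control_flux <= 0 & pd_flux <= 0 ~ "higher_uptake",
    control_flux >= 0 & pd_flux >= 0 & pd_flux < control_flux ~
      "lower_excretion",
    control_flux >= 0 & pd_flux >= 0 ~ "higher_excretion",
    TRUE ~ "sign_change")
}

#' Consistency of a flux change with a CSF metabolite direction
#'
#' A metabolite increased in PD cerebrospinal fluid is consistent with lower
#' uptake or higher excretion in the PD model; a decreased metabolite with
#' higher uptake or lower excretion. Entries carrying conflicting reports
#' (both directions) are consistent if any listed direction matches. `same`
#' changes are not evaluable; a `sign_change` is evaluated permissively
#' against both regimes.
#'
#' @param change_class a class from [classify_exchange_change()] (vectorized).
#' @param directions a character vector (single entry) or list of character
#'   vectors, each a nonempty subset of `c("increased", "decreased")`.
#' @return character vector: `"consistent"`, `"inconsistent"`,
#'   `"not_evaluable"`.
#' @export
consistency_call <- function(change_class, directions) {
  if (!is.list(directions)) directions <- list(directions)
  if (length(directions) == 1L && length(change_class) > 1L) {
    directions <- rep(directions, length(change_class))
  }
  purrr::map2_chr(change_class, directions, function(cls, dirs) {
    dirs <- as.character(dirs)
    if (!length(dirs) || any(!dirs %in% c("increased", "decreased"))) {
      abort("directions must be a nonempty subset of increased/decreased.")
    }
    if (cls == "same") return("not_evaluable")
    if (cls == "sign_change") return("consistent")
    matches <- switch(cls,
      lower_uptake = "increased",
      higher_excretion = "increased",
      higher_uptake = "decreased",
      lower_excretion = "decreased",
      abort(sprintf("unknown change class '%s'", cls)))
    if (matches %in% dirs) "consistent" else "inconsistent"
  })
}

printed_change_label <- function(change_class, blocked = FALSE) {
  ifelse(blocked, "No excrete",
    dplyr::recode(change_class,
                  lower_uptake = "Lower uptake",
                  higher_uptake = "Higher uptake",
                  lower_excretion = "Lower excrete",
                  higher_excretion = "Higher excrete",
                  same = "Same",
                  sign_change = "Sign change"))
}

printed_consistency_label <- function(consistency) {
  dplyr::recode(consistency, consistent = "Yes", inconsistent = "No",
                not_evaluable = "-")
}

#' Read a direction-annotated CSF metabolite table
#'
#' Parses a tab-separated table with columns `metabolite`, `reaction_id`,
#' `directions` (semicolon-separated subset of increased/decreased), and
#' optional `citations`, `control_flux`, `pd_flux`, `blocked`.
#'
#' @param path TSV file.
#' @return tibble with a list-column `directions`.
#' @export
read_csf_table <- function(path) {
  raw <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "#")
  out <- as_tibble(raw)
  out$directions <- strsplit(out$directions, ";", fixed = TRUE)
  if (!"blocked" %in% names(out)) out$blocked <- FALSE
  out
}

#' Compare control and PD exchange fluxes against CSF directions
#'
#' Builds one comparison row per CSF entry whose exchange reaction carries
#' fluxes in both conditions: the control/PD flux pair, the change class, a
#' printed-style label, and the consistency call. Entries whose reaction is
#' absent from either solution are listed in the `missing` attribute; entries
#' marked `blocked` (reaction present but disabled, e.g. dopamine release in
#' non-synaptic models) are labelled `"No excrete"` and not evaluated.
#'
#' Instead of two solutions, `control` and `pd` may be named numeric vectors
#' of exchange fluxes (reaction id -> flux), which allows applying the
#' classifier to published flux tables.
#'
#' @param control,pd optimal `entropic_solution`s or named flux vectors.
#' @param csf_table tibble as returned by [read_csf_table()].
#' @param tol absolute tolerance for the `same` class.
#' @return object of class `csf_comparison`: tibble with columns `metabolite`,
#'   `reaction_id`, `directions`, `control_flux`, `pd_flux`, `change_class`,
#'   `change_label`, `consistency`, `consistency_label`.
#' @export
build_comparison_table <- function(control, pd, csf_table, tol = 1e-4) {
  flux_lookup <- function(x) {
    if (inherits(x, "entropic_solution")) {
      setNames(x$fluxes$net, x$fluxes$reaction_id)
    } else if (is.numeric(x) && !is.null(names(x))) {
      x
    } else {
      abort("control/pd must be entropic solutions or named flux vectors.")
    }
  }
  cf <- flux_lookup(control)
  pf <- flux_lookup(pd)
  if (!nrow(csf_table)) {
    out <- tibble(metabolite = character(), reaction_id = character(),
                  directions = list(), control_flux = numeric(),
                  pd_flux = numeric(), change_class = character(),
                  change_label = character(), consistency = character(),
                  consistency_label = character())
    class(out) <- c("csf_comparison", class(out))
    attr(out, "missing") <- character()
    return(out)
  }
  if (!"blocked" %in% names(csf_table)) csf_table$blocked <- FALSE
  present <- csf_table$reaction_id %in% names(cf) &
    csf_table$reaction_id %in% names(pf)
  missing <- csf_table$reaction_id[!present]
  tab <- csf_table[present, ]
  rows <- purrr::pmap(
    list(tab$metabolite, tab$reaction_id, tab$directions, tab$blocked),
    function(met, rid, dirs, blocked) {
      c0 <- unname(cf[[rid]]); p0 <- unname(pf[[rid]])
      if (isTRUE(blocked)) {
        return(tibble(metabolite = met, reaction_id = rid,
                      directions = list(dirs), control_flux = c0,
                      pd_flux = p0, change_class = "blocked",
                      change_label = "No excrete",
                      consistency = "not_evaluable",
                      consistency_label = "-"))
      }
      cls <- classify_exchange_change(c0, p0, tol)
      cons <- consistency_call(cls, list(dirs))
      tibble(metabolite = met, reaction_id = rid, directions = list(dirs),
             control_flux = c0, pd_flux = p0, change_class = cls,
             change_label = printed_change_label(cls),
             consistency = cons,
             consistency_label = printed_consistency_label(cons))
    })
  out <- bind_rows(rows)
  class(out) <- c("csf_comparison", class(out))
  attr(out, "missing") <- missing
  attr(out, "tol") <- tol
  out
}
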