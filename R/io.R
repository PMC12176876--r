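#' Read a metabolic model from disk
#'
#' Supports the package's documented JSON dialect and an SBML Level 3 subset
#' (core + flux bounds encoded as parameters, as written by [save_model()]).
#' Bounds omitted in the file default to (-1000, 1000) for reversible and
#' (0, 1000) for irreversible reactions.
#'
#' @param path file to read.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' The JSON dialect round-trips every field (stoichiometry, bounds, couplings,
#' accumulation rhs, labels) bit-stably; the SBML writer emits a Level 3
#' Version 1 core document with flux bounds as reaction-local parameters and
#' subsystem/coupling information in annotations.
#'
#' @param model a [metabolic_model()].
#' @param path destination file.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort(sprintf("Unparseable JSON model '%s': %s",
                                  path, conditionMessage(e)))
                  })
  req <- c("metabolites", "reactions")
  missing <- setdiff(req, names(doc))
  if (length(missing)) {
    abort(paste0("JSON model misses required elements: ",
                 paste(missing, collapse = ", ")))
  }
  mets <- bind_rows(lapply(doc$metabolites, function(m) {
    tibble(id = m$id, name = m$name %||% m$id,
           compartment = m$compartment %||% met_compartment(m$id),
           is_atp_species = m$is_atp_species %||%
             (met_base_id(m$id) == "atp"))
  }))
  rxns <- bind_rows(lapply(doc$reactions, function(r) {
    tibble(id = r$id,
           lower_bound = r$lower_bound %||% NA_real_,
           upper_bound = r$upper_bound %||% NA_real_,
           subsystem = r$subsystem %||% "",
           reversible = r$reversible %||% NA)
  }))
  stoich <- bind_rows(lapply(doc$reactions, function(r) {
    cf <- r$stoichiometry
    if (is.null(cf) || !length(cf)) return(NULL)
    tibble(reaction_id = r$id, metabolite_id = names(cf),
           coefficient = as.numeric(unlist(cf)))
  }))
  couplings <- NULL
  if (!is.null(doc$couplings) && length(doc$couplings)) {
    couplings <- bind_rows(lapply(doc$couplings, function(cc) {
      tibble(id = cc$id, rhs = cc$rhs,
             coefficients = list(unlist(cc$coefficients)))
    }))
  }
  b <- NULL
  if (!is.null(doc$b) && length(doc$b)) b <- unlist(doc$b)
  metabolic_model(mets, rxns, stoich, couplings = couplings, b = b,
                  component = doc$component %||% NA_character_,
                  condition = doc$condition %||% NA_character_,
                  atpm_id = doc$atpm_id %||% "ATPM")
}

write_model_json <- function(model, path) {
  by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  reactions <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- by_rxn[[r$id]]
    cf <- if (is.null(st)) NULL else
      as.list(setNames(st$coefficient, st$metabolite_id))
    list(id = r$id, lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem, reversible = r$reversible,
         stoichiometry = cf)
  })
  metabolites <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         is_atp_species = m$is_atp_species)
  })
  couplings <- lapply(seq_len(nrow(model$couplings)), function(i) {
    cc <- model$couplings[i, ]
    list(id = cc$id, rhs = cc$rhs,
         coefficients = as.list(cc$coefficients[[1]]))
  })
  doc <- list(format = "neurofba-model-1",
              component = model$component, condition = model$condition,
              atpm_id = model$atpm_id,
              metabolites = metabolites, reactions = reactions,
              couplings = couplings, b = as.list(model$b))
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("Cannot write model to '%s'.", path))
  invisible(path)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mod <- xml2::xml_add_child(doc, "model",
                             id = sbml_id(paste0("neurofba_",
                                                 model$component %||% "model")))
  comps <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment",
                        id = sbml_id(paste0("c_", cp)), constant = "true")
  }
  sp <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(
      sp, "species", id = sbml_id(paste0("M_", m$id)), name = m$name,
      compartment = sbml_id(paste0("c_", m$compartment)),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false", metaid = m$id)
  }
  rl <- xml2::xml_add_child(mod, "listOfReactions")
  by_rxn <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(
      rl, "reaction", id = sbml_id(paste0("R_", r$id)),
      reversible = tolower(as.character(r$reversible)), fast = "false",
      metaid = r$id)
    notes <- xml2::xml_add_child(rx, "notes")
    bd <- xml2::xml_add_child(
      notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM:", r$subsystem))
    xml2::xml_add_child(bd, "p", paste0("LOWER_BOUND:",
                                        format(r$lower_bound, digits = 17)))
    xml2::xml_add_child(bd, "p", paste0("UPPER_BOUND:",
                                        format(r$upper_bound, digits = 17)))
    st <- by_rxn[[r$id]]
    if (!is.null(st)) {
      sub <- st[st$coefficient < 0, ]
      prod <- st[st$coefficient > 0, ]
      if (nrow(sub)) {
        lor <- xml2::xml_add_child(rx, "listOfReactants")
        for (k in seq_len(nrow(sub))) {
          xml2::xml_add_child(lor, "speciesReference",
                              species = sbml_id(paste0("M_",
                                                       sub$metabolite_id[k])),
                              stoichiometry = format(-sub$coefficient[k],
                                                     digits = 17),
                              constant = "true")
        }
      }
      if (nrow(prod)) {
        lop <- xml2::xml_add_child(rx, "listOfProducts")
        for (k in seq_len(nrow(prod))) {
          xml2::xml_add_child(lop, "speciesReference",
                              species = sbml_id(paste0("M_",
                                                       prod$metabolite_id[k])),
                              stoichiometry = format(prod$coefficient[k],
                                                     digits = 17),
                              constant = "true")
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("Unparseable SBML '%s': %s", path, conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- tibble(
    id = xml2::xml_attr(species, "metaid"),
    name = xml2::xml_attr(species, "name"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  parse_note <- function(node, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    hit <- grep(paste0("^", key, ":"), ps, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, ":"), "", hit[[1]])
  }
  rxns <- bind_rows(lapply(rx_nodes, function(nd) {
    tibble(id = xml2::xml_attr(nd, "metaid"),
           reversible = xml2::xml_attr(nd, "reversible") == "true",
           subsystem = parse_note(nd, "SUBSYSTEM") %||% "",
           lower_bound = suppressWarnings(
             as.numeric(parse_note(nd, "LOWER_BOUND"))),
           upper_bound = suppressWarnings(
             as.numeric(parse_note(nd, "UPPER_BOUND"))))
  }))
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  stoich <- bind_rows(lapply(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "metaid")
    reac <- xml2::xml_find_all(nd, ".//listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(nd, ".//listOfProducts/speciesReference")
    sp2met <- function(s) sub("^M_", "", s)
    rows <- list()
    if (length(reac)) {
      rows <- c(rows, list(tibble(
        reaction_id = rid,
        metabolite_id = sp2met(xml2::xml_attr(reac, "species")),
        coefficient = -as.numeric(xml2::xml_attr(reac, "stoichiometry")))))
    }
    if (length(prod)) {
      rows <- c(rows, list(tibble(
        reaction_id = rid,
        metabolite_id = sp2met(xml2::xml_attr(prod, "species")),
        coefficient = as.numeric(xml2::xml_attr(prod, "stoichiometry")))))
    }
    bind_rows(rows)
  }))
  # species metaid carries the original bracketed id; map M_-mangled refs back
  mangled <- sbml_id(mets$id)
  stoich$metabolite_id <- mets$id[match(stoich$metabolite_id, mangled)]
  metabolic_model(mets, rxns, stoich)
}
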