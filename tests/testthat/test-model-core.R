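test_that("JSON model round trip preserves matrices, bounds and couplings", {
  m <- branched_model()
  m$couplings <- tibble::tibble(
    id = "cp1", rhs = 1.5,
    coefficients = list(c(R1 = 1, R2 = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)

  expect_equal(as.matrix(stoich_matrix(m2)), as.matrix(stoich_matrix(m)))
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$couplings$rhs, m$couplings$rhs)
  expect_equal(m2$couplings$coefficients[[1]], m$couplings$coefficients[[1]])

  # bit-stable re-serialization
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("SBML export is well-formed and round trips the network", {
  m <- toy_model_cached("synaptic", "control")
  path <- withr::local_tempfile(fileext = ".xml")
  save_model(m, path, format = "sbml")

  doc <- xml2::read_xml(path)
  expect_match(xml2::xml_name(doc), "sbml")
  expect_equal(xml2::xml_attr(doc, "level"), "3")

  m2 <- load_model(path, format = "sbml")
  expect_equal(sort(m2$metabolites$id), sort(m$metabolites$id))
  expect_equal(as.matrix(stoich_matrix(m2))[m$metabolites$id,
                                            m$reactions$id],
               as.matrix(stoich_matrix(m)))
  expect_equal(m2$reactions$lower_bound[match(m$reactions$id,
                                              m2$reactions$id)],
               m$reactions$lower_bound)
})

test_that("bounds omitted in a model file default by reversibility", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(metabolites = list(list(id = "A")),
              reactions = list(
                list(id = "R_rev", reversible = TRUE,
                     stoichiometry = list("A" = -1)),
                list(id = "R_irr", reversible = FALSE,
                     stoichiometry = list("A" = 1)),
                list(id = "ATPM", reversible = FALSE,
                     stoichiometry = list("A" = -1))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  m <- load_model(path)
  expect_equal(unname(get_bounds(m, "R_rev")), c(-1000, 1000))
  expect_equal(unname(get_bounds(m, "R_irr")), c(0, 1000))
})

test_that("model validation flags dangling references and bad bounds", {
  mets <- tibble::tibble(id = "A")
  rxns <- tibble::tibble(id = "ATPM", lower_bound = 0, upper_bound = 1)
  st_bad <- tibble::tibble(reaction_id = "ATPM", metabolite_id = "ghost",
                           coefficient = 1)
  expect_error(metabolic_model(mets, rxns, st_bad), "ghost")
  st <- tibble::tibble(reaction_id = "ATPM", metabolite_id = "A",
                       coefficient = -1)
  rxns_bad <- dplyr::mutate(rxns, lower_bound = 2)
  expect_error(metabolic_model(mets, rxns_bad, st), "lower_bound")
})

test_that("matrix assembly partitions internal and exchange columns", {
  m <- branched_model()
  mats <- assemble_matrices(m)
  expect_equal(mats$internal_ids, c("R1", "R2", "R3"))
  expect_equal(mats$exchange_ids, c("EX_A", "EX_C"))
  expect_equal(dim(mats$N), c(3, 3))
  expect_equal(dim(mats$B), c(3, 2))
  expect_equal(nrow(mats$C), 0)
  expect_length(mats$d, 0)
  # mass-balanced internal column sums to zero
  expect_equal(Matrix::colSums(mats$N)[["R1"]], 0)
})

test_that("transport columns of the toy network carry only +1/-1 pairs", {
  m <- toy_model_cached("nonsynaptic", "control")
  S <- stoich_matrix(m)
  for (tr in c("PYRtm", "GLCt", "LACt", "O2t")) {
    col <- S[, tr]
    expect_equal(unname(sort(col[col != 0])), c(-1, 1))
    expect_equal(sum(col), 0)
  }
})

test_that("overlays edit exactly what they name and compose as documented", {
  m <- branched_model()
  m <- set_bounds(m, "R1", lower = 0, upper = 12)

  ov <- constraint_overlay(
    scale_edits = list(R1 = list(bound = "upper", factor = 0.82)))
  m_pd <- apply_overlay(m, ov)
  expect_equal(get_bounds(m_pd, "R1")[["upper"]], 9.84)
  # original untouched, scale edits compose multiplicatively
  expect_equal(get_bounds(m, "R1")[["upper"]], 12)
  expect_equal(get_bounds(apply_overlay(m_pd, ov), "R1")[["upper"]],
               12 * 0.82^2)

  ov_q <- constraint_overlay(
    scale_edits = list(R2 = list(bound = "lower", factor = 0.25)))
  m2 <- set_bounds(m, "R2", lower = 0.8, upper = 1000)
  expect_equal(get_bounds(apply_overlay(m2, ov_q), "R2")[["lower"]], 0.2)

  # absolute edits are idempotent; the empty overlay is the identity
  ov_abs <- constraint_overlay(bound_edits = list(R3 = list(upper = 5)))
  once <- apply_overlay(m, ov_abs)
  expect_identical(apply_overlay(once, ov_abs)$reactions, once$reactions)
  expect_identical(apply_overlay(m, constraint_overlay())$reactions,
                   m$reactions)

  expect_error(apply_overlay(m, constraint_overlay(
    bound_edits = list(R1 = list(lower = 50, upper = 10)))), "R1")
  expect_error(apply_overlay(m, constraint_overlay(
    bound_edits = list(ghost = list(upper = 1)))), "ghost")
})

test_that("literature-derived constraint arithmetic matches printed values", {
  expect_equal(derive_literature_constraint("residual_energy_conversion",
                                            c(10, 0.823)), 106.2)
  expect_equal(derive_literature_constraint("atpm_lower", 106.2), 10.62)
  expect_equal(derive_literature_constraint("pd_complex1_factor", 0.18),
               0.82)
  expect_equal(derive_literature_constraint("mito_protein_density",
                                            c(4, 6)), 5)
  expect_equal(derive_literature_constraint("mito_protein_density",
                                            c(1, 1.5)), 1.25)
  expect_error(derive_literature_constraint("residual_energy_conversion",
                                            c(10, 1.2)), "water")
  expect_error(derive_literature_constraint("atpm_lower", -1), "positive")
})

test_that("core function checks quantify carbon-source ATP capacity", {
  m <- toy_model_cached("nonsynaptic", "control")
  rep <- validate_core_functions(m)

  aerobic <- rep$max_atpm[rep$test == "aerobic_glucose"]
  anaerobic <- rep$max_atpm[rep$test == "anaerobic_glucose"]
  none <- rep$max_atpm[rep$test == "no_carbon"]

  expect_true(rep$pass[rep$test == "aerobic_glucose"])
  expect_true(rep$pass[rep$test == "anaerobic_glucose"])
  expect_gt(aerobic, anaerobic)
  # glycolysis-only oracle: 2 ATP per glucose at the uptake capacity
  glc_cap <- abs(get_bounds(m, "EX_glc_D[e]")[["lower"]])
  expect_equal(anaerobic, 2 * glc_cap, tolerance = 1e-3)
  expect_lt(abs(none), 1e-4)
  expect_false(rep$pass[rep$test == "no_carbon"])
})
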