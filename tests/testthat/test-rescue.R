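test_that("improvement classifier reproduces all published rescue calls", {
  for (comp in c("synaptic", "nonsynaptic")) {
    tab <- rescue_improvement_table(comp)
    calls <- purrr::pmap_chr(
      tab[, c("control_flux", "pd_flux", "rescued_flux", "role")],
      function(control_flux, pd_flux, rescued_flux, role) {
        classify_improvement(control_flux, pd_flux, rescued_flux, role)
      })
    expect_equal(calls == "improved", tab$printed_improvement == "Yes",
                 info = comp)
  }
})

test_that("the exchange rule covers overshoot and zero-change cases", {
  # overshoot past the control level still counts as improvement
  expect_equal(classify_improvement(-16.6588, -16.6238, -17.5047,
                                    "exchange"), "improved")
  # an unchanged flux cannot improve
  expect_equal(classify_improvement(0.3131, 0.2876, 0.2876, "exchange"),
               "not_improved")
  # movement away from control is no improvement
  expect_equal(classify_improvement(-1.8909, -1.2779, -1.2324, "exchange"),
               "not_improved")
  # energy is judged against the PD baseline, not control
  expect_equal(classify_improvement(8.5862, 9.48623, 9.5930, "energy"),
               "improved")
  expect_error(classify_improvement(1, NA, 2, "energy"), "finite")
})

test_that("potential shifts difference the mass-balance duals", {
  sol <- solve_entropic_fba(chain_model(1))
  expect_true(all(potential_shift(sol, sol) == 0))
  expect_length(potential_shift(sol, sol, c("A", "B")), 2)

  sol2 <- solve_entropic_fba(chain_model(2))
  shift <- potential_shift(sol, sol2)
  expect_equal(unname(shift),
               unname(chemical_potentials(sol2) - chemical_potentials(sol)))

  other <- solve_entropic_fba(single_reaction_model(1))
  expect_error(potential_shift(sol, other), "differ")
})

test_that("knocking out the futile leak restores PD energy toward control", {
  csf <- dplyr::filter(toy_csf_directions(), reaction_id == "EX_urea[e]")
  cfg <- rescue_config(mode = "inhibit", demands = 10.62,
                       atps_id = "ATPS4mi", csf_table = csf, tol = 1e-3)
  pd <- toy_model_cached("nonsynaptic", "pd")
  ctrl <- toy_model_cached("nonsynaptic", "control")
  sc <- inhibition_scan(pd, ctrl, cfg,
                        reactions = c("LEAKm", "ATPS4mi", "FUTILEc"))
  expect_true(sc$energy_improved_all[sc$reaction_id == "LEAKm"])
  # knocking out ATP synthase can never rescue energy
  expect_false(sc$energy_improved_all[sc$reaction_id == "ATPS4mi"])

  # the leak knockout lifts ATP synthase to at least the control level
  det <- attr(sc, "details")$LEAKm$per_demand[[1]]
  ctrl_sol <- toy_solution_cached("nonsynaptic", "control", demand = 10.62)
  expect_gte(det$atps_flux, 0.95 * flux_of(ctrl_sol, "ATPS4mi"))

  # empty candidate list gives an empty result
  empty <- inhibition_scan(pd, ctrl, cfg, reactions = character())
  expect_equal(nrow(empty), 0)
})

test_that("knockout scans start from the pristine model each time", {
  csf <- dplyr::filter(toy_csf_directions(), reaction_id == "EX_urea[e]")
  cfg <- rescue_config(mode = "inhibit", demands = 10.62,
                       atps_id = "ATPS4mi", csf_table = csf, tol = 1e-3)
  pd <- toy_model_cached("synaptic", "pd")
  ctrl <- toy_model_cached("synaptic", "control")
  ab <- inhibition_scan(pd, ctrl, cfg, reactions = c("LEAKm", "ODCm"))
  ba <- inhibition_scan(pd, ctrl, cfg, reactions = c("ODCm", "LEAKm"))
  expect_equal(ab[order(ab$reaction_id), ], ba[order(ba$reaction_id), ],
               ignore_attr = TRUE)
})

test_that("a forcing factor of one reproduces the baseline exactly", {
  csf <- dplyr::filter(toy_csf_directions(), reaction_id == "EX_urea[e]")
  cfg <- rescue_config(mode = "increase", increase_factor = 1,
                       demands = 31, atps_id = "ATPS4mi",
                       csf_table = csf, tol = 1e-3)
  sc <- increase_scan(toy_model_cached("nonsynaptic", "pd"),
                      toy_model_cached("nonsynaptic", "control"),
                      cfg, reactions = c("ORNTAm", "PGKc"))
  expect_true(all(!sc$overall))
  expect_true(all(sc$exchanges_improved == 0))
})

test_that("increase scans skip zero-flux and capacity-limited reactions", {
  csf <- dplyr::filter(toy_csf_directions(), reaction_id == "EX_urea[e]")
  cfg <- rescue_config(mode = "increase", demands = 31,
                       atps_id = "ATPS4mi", csf_table = csf, tol = 1e-3)
  sc <- increase_scan(toy_model_cached("nonsynaptic", "pd"),
                      toy_model_cached("nonsynaptic", "control"),
                      cfg, reactions = c("FUTILEc", "ORNtm", "GLNt"))
  expect_equal(sc$status[sc$reaction_id == "FUTILEc"],
               "skipped_zero_flux")
  # uptake chains pinned at their transport capacity cannot be forced
  expect_true(all(sc$status[sc$reaction_id %in% c("ORNtm", "GLNt")] ==
                    "infeasible"))
  expect_true(all(!sc$overall))
})

test_that("forcing the transaminase analog rescues energy and urea", {
  csf <- dplyr::filter(toy_csf_directions(), reaction_id == "EX_urea[e]")
  for (case in list(list("nonsynaptic", 31), list("synaptic", 22))) {
    cfg <- rescue_config(mode = "increase", demands = case[[2]],
                         atps_id = "ATPS4mi", csf_table = csf, tol = 1e-3)
    sc <- increase_scan(toy_model_cached(case[[1]], "pd"),
                        toy_model_cached(case[[1]], "control"),
                        cfg,
                        reactions = c("ORNTAm", "ODCm", "GLUDm",
                                      "UREACLm", "PGKc", "AKGDHm"))
    expect_equal(sc$reaction_id[sc$overall], "ORNTAm", info = case[[1]])
    row <- sc[sc$reaction_id == "ORNTAm", ]
    expect_true(row$energy_improved_all)
    expect_gte(row$exchanges_improved, 1)
    expect_equal(row$exchanges_worsened, 0)
  }
})
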