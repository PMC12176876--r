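test_that("single-reaction solves match the closed-form optimum", {
  sol <- solve_entropic_fba(single_reaction_model(net = 1))
  expect_equal(sol$status, "optimal")
  fl <- sol$fluxes[sol$fluxes$reaction_id == "R1", ]
  expect_equal(fl$vf, vf_closed_form(1), tolerance = 1e-6)
  expect_equal(fl$vr, vf_closed_form(1) - 1, tolerance = 1e-6)

  # zero net flux is the symmetric point vf = vr = exp(-1)
  sol0 <- solve_entropic_fba(single_reaction_model(net = 0))
  fl0 <- sol0$fluxes[sol0$fluxes$reaction_id == "R1", ]
  expect_equal(fl0$vf, exp(-1), tolerance = 1e-6)
  expect_equal(fl0$vr, exp(-1), tolerance = 1e-6)
})

test_that("the two-reaction chain agrees with brute-force minimization", {
  sol <- solve_entropic_fba(chain_model(net = 1))
  expect_equal(sol$status, "optimal")
  for (rid in c("R1", "R2")) {
    expect_equal(sol$fluxes$vf[sol$fluxes$reaction_id == rid],
                 vf_closed_form(1), tolerance = 1e-4)
  }
  # independent oracle: mass balance forces both net fluxes to 1; minimize
  # the entropy of each reaction's unidirectional split numerically
  ent <- function(vf, v) {
    vr <- vf - v
    2 * (vf * log(vf) + vr * log(vr))
  }
  opt <- optimize(ent, c(1 + 1e-12, 5), v = 1)
  expect_equal(sol$fluxes$vf[sol$fluxes$reaction_id == "R1"],
               opt$minimum, tolerance = 1e-4)
})

test_that("three-reaction network matches dense brute-force minimization", {
  sol <- solve_entropic_fba(branched_model(net = 1))
  expect_equal(sol$status, "optimal")
  # oracle: v1 + v2 = 1, v3 = 1 by mass balance; minimize over v1 with each
  # reaction's reduced entropy term F(v) evaluated in closed form
  fent <- function(v) {
    r <- sqrt(v^2 + 4 * exp(-2))
    vf <- (r + v) / 2
    vr <- (r - v) / 2
    2 * (vf * log(vf) + vr * log(vr))
  }
  opt <- optimize(function(v1) fent(v1) + fent(1 - v1) + fent(1),
                  c(-2, 3))
  v1_hat <- opt$minimum   # symmetric split: 0.5
  expect_equal(sol$fluxes$net[sol$fluxes$reaction_id == "R1"], v1_hat,
               tolerance = 1e-4)
  expect_equal(sol$fluxes$net[sol$fluxes$reaction_id == "R3"], 1,
               tolerance = 1e-6)
})

test_that("interior product law and mass balance hold on toy solves", {
  for (case in list(c("synaptic", "control"), c("nonsynaptic", "pd"))) {
    sol <- toy_solution_cached(case[1], case[2])
    internal <- sol$fluxes[!sol$fluxes$is_exchange, ]
    expect_true(all(abs(internal$vf * internal$vr - exp(-2)) < 1e-5))

    m <- toy_model_cached(case[1], case[2])
    mats <- assemble_matrices(m)
    v <- internal$net[match(mats$internal_ids, internal$reaction_id)]
    w <- sol$fluxes$net[match(mats$exchange_ids, sol$fluxes$reaction_id)]
    resid <- as.vector(mats$N %*% v + mats$B %*% w) - mats$b
    expect_lt(max(abs(resid)), 1e-6 * max(1, max(abs(w))))
  }
})

test_that("KKT residuals pass for optima and fail for perturbed solutions", {
  m <- toy_model_cached("nonsynaptic", "control")
  sol <- toy_solution_cached("nonsynaptic", "control")
  res <- kkt_residuals(m, entropic_objective(), sol)
  expect_lte(max(res$max_residual), 1e-6)

  bad <- sol
  i <- match("PGKc", bad$fluxes$reaction_id)
  bad$fluxes$net[i] <- bad$fluxes$net[i] + 0.1
  sp <- neurofba:::ent_split(bad$fluxes$net[i])
  bad$fluxes$vf[i] <- sp$vf
  bad$fluxes$vr[i] <- sp$vr
  res_bad <- kkt_residuals(m, entropic_objective(), bad)
  expect_gt(res_bad$max_residual[res_bad$block == "stationarity"], 1e-3)
})

test_that("solutions are unique across different starting points", {
  m <- toy_model_cached("synaptic", "control")
  sol1 <- toy_solution_cached("synaptic", "control")
  start <- setNames(rep(0.5, nrow(m$reactions)), m$reactions$id)
  sol2 <- solve_entropic_fba(m, x_start = start)
  expect_equal(sol2$status, "optimal")
  expect_equal(sol1$fluxes$vf, sol2$fluxes$vf, tolerance = 1e-5)
  expect_equal(sol1$fluxes$vr, sol2$fluxes$vr, tolerance = 1e-5)
})

test_that("chemical potentials satisfy the stationarity identity", {
  m <- chain_model(net = 1)
  sol <- solve_entropic_fba(m)
  pots <- chemical_potentials(sol)
  expect_length(pots, nrow(m$metabolites))
  expect_identical(chemical_potentials(sol, c("A", "A")),
                   pots[c("A", "A")])
  expect_error(chemical_potentials(sol, "ghost"), "ghost")

  # g log(vf / vr) = 2 (N' y) for interior unconstrained internal reactions
  mats <- assemble_matrices(m)
  y <- unname(pots[m$metabolites$id])
  nt_y <- as.vector(Matrix::crossprod(mats$N, y))
  internal <- sol$fluxes[!sol$fluxes$is_exchange, ]
  lhs <- 2 * log(internal$vf / internal$vr)
  expect_equal(lhs, 2 * nt_y, tolerance = 1e-5)
})

test_that("a tighter quadratic penalty pulls the flux toward its target", {
  m <- single_reaction_model(net = 0)
  m <- set_bounds(m, "EX_A", lower = -5, upper = 0)
  m <- set_bounds(m, "EX_B", lower = 0, upper = 5)
  gaps <- purrr::map_dbl(c(0.1, 1, 10, 100), function(wt) {
    obj <- entropic_objective(h = c(R1 = 2), H = c(R1 = wt))
    sol <- solve_entropic_fba(m, obj)
    abs(flux_of(sol, "R1") - 2)
  })
  expect_true(all(diff(gaps) <= 1e-8))
})

test_that("coupling constraints bind and price correctly", {
  m <- single_reaction_model(net = 0)
  m <- set_bounds(m, "EX_A", lower = -5, upper = 0)
  m <- set_bounds(m, "EX_B", lower = 0, upper = 5)
  m$couplings <- tibble::tibble(id = "cap", rhs = 0.7,
                                coefficients = list(c(R1 = 1)))
  # pull the flux up against the coupling cap
  obj <- entropic_objective(h = c(R1 = 3), H = c(R1 = 50))
  sol <- solve_entropic_fba(m, obj)
  expect_equal(sol$status, "optimal")
  expect_lte(flux_of(sol, "R1"), 0.7 + 1e-6)
  expect_gt(flux_of(sol, "R1"), 0.69)
  expect_gt(sol$duals$y_C[["cap"]], 0)
  res <- kkt_residuals(m, obj, sol)
  expect_lte(max(res$max_residual), 1e-6)
})

test_that("infeasible constraint sets are reported with a hint", {
  m <- single_reaction_model(net = 1)
  m <- set_bounds(m, "EX_B", lower = 5, upper = 10)
  sol <- solve_entropic_fba(m)
  expect_equal(sol$status, "infeasible")
  expect_true(length(sol$infeasibility_hint) > 0)
  expect_error(kkt_residuals(m, entropic_objective(), sol), "optimal")
})

test_that("solution export writes readable flux and potential tables", {
  sol <- solve_entropic_fba(chain_model(1))
  fp <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".tsv")
  export_solution_tables(sol, fp, pp)
  fl <- read.table(fp, sep = "\t", header = TRUE)
  expect_equal(nrow(fl), nrow(sol$fluxes))
  po <- read.table(pp, sep = "\t", header = TRUE)
  expect_equal(nrow(po), nrow(sol$potentials))
})
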