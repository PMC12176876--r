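test_that("net ATP accounting classifies producers, consumers, shuttles", {
  m <- toy_model_cached("nonsynaptic", "control")
  sol <- toy_solution_cached("nonsynaptic", "control")
  acc <- atp_accounting(m, sol)

  role_of <- function(id) acc$role[acc$reaction_id == id]
  rate_of <- function(id) acc$atp_rate[acc$reaction_id == id]

  expect_equal(role_of("PGKc"), "contributor")
  expect_equal(rate_of("PGKc"), flux_of(sol, "PGKc"))
  expect_equal(role_of("ATPS4mi"), "contributor")
  expect_equal(role_of("ATPM"), "consumer")
  expect_equal(rate_of("ATPM"), -flux_of(sol, "ATPM"))
  # the adenine-nucleotide translocator nets to zero across compartments
  expect_equal(rate_of("ANTm"), 0)
  expect_equal(role_of("ANTm"), "none")

  # steady-state conservation: production balances consumption
  expect_lt(abs(sum(acc$atp_rate)), 1e-6)

  # contributors and consumers are disjoint
  expect_equal(sum(acc$role == "contributor" & acc$role == "consumer"), 0)

  expect_error(atp_accounting(m, sol, atp_species = character()), "empty")
  expect_error(atp_accounting(m, sol, atp_species = "ghost"), "ghost")
})

test_that("subsystem shares normalize over contributors only", {
  m <- toy_model_cached("nonsynaptic", "control")
  acc <- atp_accounting(m, toy_solution_cached("nonsynaptic", "control"))
  sh <- subsystem_shares(acc)
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)
  expect_true(all(sh$flux > 0))
  expect_false(attr(sh, "undefined"))

  # a single contributor takes share one
  one <- acc[acc$role == "contributor", ][1, ]
  one$role <- "contributor"
  class(one) <- class(acc)
  sh1 <- subsystem_shares(one)
  expect_equal(sh1$share, 1)

  # no contributors at all flags undefined shares instead of dividing
  none <- acc
  none$role <- "none"
  expect_true(attr(subsystem_shares(none), "undefined"))
})

test_that("demand scans flag infeasible points and keep shares normalized", {
  m <- toy_model_cached("nonsynaptic", "control")
  sc <- demand_scan(m, demands = c(10.62, 60, 550))
  for (d in c(10.62, 60)) {
    sub <- sc[sc$demand == d, ]
    expect_true(all(sub$status == "optimal"))
    expect_equal(sum(sub$share), 1, tolerance = 1e-9)
  }
  # 550 is beyond the network's capacity: flagged, not dropped
  expect_true(all(sc$status[sc$demand == 550] == "infeasible"))
  expect_error(demand_scan(m, demands = 700), "upper bound")
})

test_that("total contribution tracks demand and oxphos plateaus", {
  sc <- toy_demand_scan_cached("nonsynaptic", "control")
  totals <- vapply(c(10.62, 60, 100), function(d) {
    sum(sc$flux[sc$demand == d & sc$status == "optimal"])
  }, numeric(1))
  expect_true(all(diff(totals) > 0))

  ox <- scan_subsystem_flux(sc, "Oxidative phosphorylation")
  gly <- scan_subsystem_flux(sc, "Glycolysis")
  expect_lt(ox$flux[ox$demand == 100],
            1.05 * ox$flux[ox$demand == 60])
  expect_gt(gly$flux[gly$demand == 100],
            2 * gly$flux[gly$demand == 60])
})

test_that("disease and component overlays reorder subsystem shares", {
  share_at_60 <- function(component, condition) {
    sc <- toy_demand_scan_cached(component, condition)
    sc$share[sc$demand == 60 &
               sc$subsystem %in% "Oxidative phosphorylation"]
  }
  # Complex I damage shifts ATP provision from oxphos toward glycolysis
  expect_lt(share_at_60("nonsynaptic", "pd"),
            share_at_60("nonsynaptic", "control"))
  expect_lt(share_at_60("synaptic", "pd"),
            share_at_60("synaptic", "control"))
  # tighter synaptic mitochondrial caps lower the oxphos share
  expect_lt(share_at_60("synaptic", "control"),
            share_at_60("nonsynaptic", "control"))
})
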