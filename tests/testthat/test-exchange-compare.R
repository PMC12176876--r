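test_that("change classification follows the uptake/secretion convention", {
  expect_equal(classify_exchange_change(-1.8909, -1.2779), "lower_uptake")
  expect_equal(classify_exchange_change(-6.3213, -7.2753), "higher_uptake")
  expect_equal(classify_exchange_change(0.2291, 0.1597), "lower_excretion")
  expect_equal(classify_exchange_change(-0.8357, -0.8357), "same")
  expect_equal(classify_exchange_change(0.1, 0.3), "higher_excretion")
  expect_equal(classify_exchange_change(-0.5, 0.5), "sign_change")
  expect_equal(classify_exchange_change(1, 1 + 5e-5), "same")
  expect_error(classify_exchange_change(NA, 1), "finite")
})

test_that("consistency calls map CSF directions onto flux changes", {
  expect_equal(consistency_call("lower_uptake", "increased"), "consistent")
  expect_equal(consistency_call("higher_uptake", "increased"),
               "inconsistent")
  expect_equal(consistency_call("lower_uptake",
                                list(c("increased", "decreased"))),
               "consistent")
  expect_equal(consistency_call("lower_excretion", "decreased"),
               "consistent")
  expect_equal(consistency_call("higher_excretion", "increased"),
               "consistent")
  expect_equal(consistency_call("same", "increased"), "not_evaluable")
  expect_equal(consistency_call("sign_change", "decreased"), "consistent")
  expect_error(consistency_call("lower_uptake", "sideways"), "subset")
})

test_that("swapping conditions flips classes and consistency", {
  set.seed(42)
  a <- runif(200, -10, 10)
  b <- runif(200, -10, 10)
  fwd <- classify_exchange_change(a, b)
  rev <- classify_exchange_change(b, a)
  map <- c(lower_uptake = "higher_uptake", higher_uptake = "lower_uptake",
           lower_excretion = "higher_excretion",
           higher_excretion = "lower_excretion",
           same = "same", sign_change = "sign_change")
  expect_equal(unname(map[fwd]), rev)

  single <- fwd %in% c("lower_uptake", "higher_uptake",
                       "lower_excretion", "higher_excretion")
  cf <- consistency_call(fwd[single], "increased")
  cr <- consistency_call(rev[single], "increased")
  expect_true(all((cf == "consistent") == (cr == "inconsistent")))
})

test_that("the synaptic comparison table reproduces its printed columns", {
  tab <- csf_exchange_table("synaptic")
  cmp <- build_comparison_table(
    setNames(tab$control_flux, tab$reaction_id),
    setNames(tab$pd_flux, tab$reaction_id),
    tab)
  expect_equal(nrow(cmp), 17)
  expect_equal(cmp$change_label, tab$printed_change)
  expect_equal(cmp$consistency_label, tab$printed_consistency)
  expect_equal(sum(cmp$consistency_label == "Yes"), 6)
  expect_equal(sum(cmp$consistency_label == "No"), 3)
  expect_equal(sum(cmp$consistency_label == "-"), 8)
  expect_setequal(
    cmp$metabolite[cmp$consistency_label == "Yes"],
    c("D-Glucose", "L-Methionine", "L-Glutamine", "L-Lysine", "Urea",
      "L-Lactic acid"))
})

test_that("the non-synaptic comparison table reproduces its printed columns", {
  tab <- csf_exchange_table("nonsynaptic")
  cmp <- build_comparison_table(
    setNames(tab$control_flux, tab$reaction_id),
    setNames(tab$pd_flux, tab$reaction_id),
    tab)
  expect_equal(nrow(cmp), 17)
  expect_equal(cmp$change_label, tab$printed_change)
  expect_equal(cmp$consistency_label, tab$printed_consistency)
  # the blocked dopamine-release row is reported, not classified
  expect_equal(cmp$change_label[cmp$reaction_id == "EX_dopa[e]"],
               "No excrete")
  expect_setequal(
    cmp$metabolite[cmp$consistency_label == "Yes"],
    c("D-Glucose", "L-Glutamine", "L-Lysine", "L-Histidine",
      "Glyceric acid", "L-Lactic acid"))
})

test_that("comparison tables handle missing reactions and empty input", {
  empty <- build_comparison_table(c(EX_a = 1), c(EX_a = 1),
                                  tibble::tibble(
                                    metabolite = character(),
                                    reaction_id = character(),
                                    directions = list()))
  expect_equal(nrow(empty), 0)

  tab <- tibble::tibble(metabolite = c("a", "b"),
                        reaction_id = c("EX_a", "EX_missing"),
                        directions = list("increased", "decreased"))
  cmp <- build_comparison_table(c(EX_a = -2), c(EX_a = -1), tab)
  expect_equal(nrow(cmp), 1)
  expect_equal(attr(cmp, "missing"), "EX_missing")
})

test_that("toy solutions produce a comparison table with sensible calls", {
  cmp <- build_comparison_table(
    toy_solution_cached("synaptic", "control"),
    toy_solution_cached("synaptic", "pd"),
    toy_csf_directions())
  expect_gt(nrow(cmp), 5)
  # PD dopamine release drops fourfold: lower excretion, inconsistent with
  # the reported CSF increase
  dopa <- cmp[cmp$reaction_id == "EX_dopa[e]", ]
  expect_equal(dopa$change_class, "lower_excretion")
  expect_equal(dopa$consistency, "inconsistent")
})
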