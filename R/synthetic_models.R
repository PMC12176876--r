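#' Fixture parameters of the toy dopaminergic-neuron network
#'
#' Numeric capacities of the toy network. These are fixture parameters chosen
#' so the toy reproduces the qualitative behaviour of condition-specific
#' neuronal models (oxidative-phosphorylation plateau, PD/control and
#' synaptic/non-synaptic orderings, rescue behaviour of the ornithine
#' transaminase analog); they are not literature values, except where noted
#' (PD Complex I factor 0.82, dopamine one-quarter rule, ATPM bounds
#' 10.62-600 mu mol/gDW/h).
#'
#' @param ... named overrides of individual parameters.
#' @return named list of parameters.
#' @export
toy_params <- function(...) {
  p <- list(
    # oxidative phosphorylation; synaptic mitochondria carry tighter caps
    complex1_cap_synaptic = 6,
    complex1_cap_nonsynaptic = 8,
    pmf_per_complex1 = 4,     # proton-motive charges per Complex I turnover
    pmf_per_qh2 = 6,          # per ubiquinol oxidized by Complex III/IV
    pmf_per_atp = 3,          # ATP synthase stoichiometry
    # PD overlay (literature-derived factors)
    pd_complex1_factor = 0.82,
    pd_dopamine_factor = 0.25,
    # exchange bounds [lower, upper]; negative = uptake
    glc_bounds = c(-45, -0.1),
    o2_bounds = c(-40, -2),
    lac_bounds = c(-6.48, 100),
    tyr_bounds = c(-3, 0),
    akg_bounds = c(-5, 1000),
    pyr_bounds = c(-2, -0.5),
    # fixed amino-acid / ornithine uptakes (identical across conditions)
    orn_uptake = 0.28,
    gln_uptake = 0.5,
    his_uptake = 0.4,
    lys_uptake = 0.4,
    met_uptake = 0.3,
    # capacities
    pyruvate_transport_cap = 3,
    nh4_export_cap = 0.9,     # mitochondrial ammonium export ceiling
    orntam_min = 0.25,        # basal ornithine transaminase activity
    dopamine_release_min = 0.8,
    heat_demand = 1,          # dissipation demand behind the futile branch
    atpm_bounds = c(10.62, 600))
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    abort(paste0("Unknown toy parameters: ", paste(unknown, collapse = ", ")))
  }
  modifyList(p, over)
}

#' Specification of one toy-model variant
#'
#' @param component `"synaptic"` or `"nonsynaptic"`.
#' @param condition `"control"` or `"pd"`.
#' @param params a [toy_params()] list.
#' @param seed integer seed (used only by [jitter_instances()]).
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(component = c("synaptic", "nonsynaptic"),
                     condition = c("control", "pd"),
                     params = toy_params(), seed = 1L) {
  structure(list(component = match.arg(component),
                 condition = match.arg(condition),
                 params = params, seed = as.integer(seed)),
            class = "toy_spec")
}

#' PD constraint overlay for a toy variant
#'
#' Exactly three kinds of edits distinguish PD from control: the Complex I
#' capacity is scaled to the PD factor (82% of control), the dopamine-release
#' minimum is scaled to one quarter (synaptic variants only), and the
#' mandatory minimum uptakes of glucose and oxygen are removed (upper bound
#' of the uptake exchanges set to 0).
#'
#' @param spec a [toy_spec()] (the component decides whether the dopamine
#'   edit applies).
#' @return a [constraint_overlay()].
#' @export
toy_pd_overlay <- function(spec) {
  p <- spec$params
  bound_edits <- list(
    "EX_glc_D[e]" = list(upper = 0),
    "EX_o2[e]" = list(upper = 0))
  scale_edits <- list(
    "CPLX1m" = list(bound = "upper", factor = p$pd_complex1_factor))
  if (spec$component == "synaptic") {
    scale_edits[["EX_dopa[e]"]] <- list(bound = "lower",
                                        factor = p$pd_dopamine_factor)
  }
  constraint_overlay(bound_edits = bound_edits, scale_edits = scale_edits)
}

#' Build one toy dopaminergic-neuron model variant
#'
#' Deterministically constructs the toy network: lumped upper glycolysis with
#' separate phosphoglycerate-kinase and pyruvate-kinase ATP steps, reversible
#' lactate dehydrogenase and a reversible cytosol-mitochondrion NADH shuttle,
#' a lumped citric acid cycle with a substrate-level ATP step and FADH2
#' feeding a Complex II bypass of Complex I, the Complex I -> proton-motive
#' force -> ATP synthase chain with a futile proton leak, an ornithine
#' transaminase axis (competing with a polyamine branch for ornithine)
#' coupled to glutamate dehydrogenase and an ATP-consuming urea-cycle lump,
#' amino-acid degradation lumps with capacity-pinned uptake chains, and (in
#' synaptic variants) a tyrosine -> dopamine release branch. PD variants are
#' obtained by applying [toy_pd_overlay()] to the control build, so the bound
#' difference between conditions is exactly the documented PD edit set.
#'
#' @param spec a [toy_spec()], or the `component` argument of [toy_spec()]
#'   when `condition` is also given.
#' @param condition,params optional shortcuts forwarded to [toy_spec()].
#' @return a [metabolic_model()] labelled with the component and condition.
#' @export
build_toy_model <- function(spec, condition = NULL, params = toy_params()) {
  if (!inherits(spec, "toy_spec")) {
    spec <- toy_spec(spec, condition, params = params)
  }
  p <- spec$params
  syn <- spec$component == "synaptic"
  ci_cap <- if (syn) p$complex1_cap_synaptic else p$complex1_cap_nonsynaptic

  mets <- c(
    "glc_D[c]", "g6p[c]", "g3p[c]", "bpg[c]", "pg3[c]", "pg2[c]",
    "pep[c]", "pyr[c]", "lac_L[c]",
    "nad[c]", "nadh[c]", "atp[c]", "adp[c]", "pi[c]",
    "pyr[m]", "accoa[m]", "nad[m]", "nadh[m]", "fad[m]", "fadh2[m]",
    "q[m]", "qh2[m]", "pmf[m]", "o2[m]", "co2[m]", "h2o[m]",
    "atp[m]", "adp[m]", "pi[m]",
    "akg[m]", "orn[m]", "glu[m]", "nh4[m]", "heat[m]",
    "ptrc[c]",
    "glc_D[e]", "o2[e]", "lac_L[e]", "urea[e]", "orn[e]",
    "his_L[e]", "lys_L[e]", "met_L[e]", "gln_L[e]",
    "his_L[c]", "lys_L[c]", "met_L[c]", "gln_L[c]",
    "nh4[e]", "co2[e]", "h2o[e]", "ptrc[e]", "akg[e]", "pyr[e]")
  if (syn) {
    mets <- c(mets, "tyr_L[c]", "dopa[c]", "tyr_L[e]", "dopa[e]")
  }

  rx <- list()
  add <- function(id, subsystem, lb, ub, stoich) {
    rx[[length(rx) + 1L]] <<- list(id = id, subsystem = subsystem,
                                   lb = lb, ub = ub, stoich = stoich)
  }

  # --- glycolysis -----------------------------------------------------------
  add("HEXc", "Glycolysis", 0, 1000,
      c("glc_D[c]" = -1, "atp[c]" = -1, "g6p[c]" = 1, "adp[c]" = 1))
  add("PFKc", "Glycolysis", 0, 1000,
      c("g6p[c]" = -1, "atp[c]" = -1, "g3p[c]" = 2, "adp[c]" = 1))
  add("GAPDc", "Glycolysis", 0, 1000,
      c("g3p[c]" = -1, "pi[c]" = -1, "nad[c]" = -1,
        "bpg[c]" = 1, "nadh[c]" = 1))
  add("PGKc", "Glycolysis", 0, 1000,
      c("bpg[c]" = -1, "adp[c]" = -1, "pg3[c]" = 1, "atp[c]" = 1))
  add("PGMc", "Glycolysis", 0, 1000, c("pg3[c]" = -1, "pg2[c]" = 1))
  add("ENOc", "Glycolysis", 0, 1000, c("pg2[c]" = -1, "pep[c]" = 1))
  add("PYKc", "Glycolysis", 0, 1000,
      c("pep[c]" = -1, "adp[c]" = -1, "pyr[c]" = 1, "atp[c]" = 1))
  add("LDH_Lc", "Glycolysis", -1000, 1000,
      c("pyr[c]" = -1, "nadh[c]" = -1, "lac_L[c]" = 1, "nad[c]" = 1))

  # --- citric acid cycle ----------------------------------------------------
  add("PDHm", "Citric acid cycle", 0, 1000,
      c("pyr[m]" = -1, "nad[m]" = -1, "accoa[m]" = 1, "nadh[m]" = 1,
        "co2[m]" = 1))
  add("CSTCAm", "Citric acid cycle", 0, 1000,
      c("accoa[m]" = -1, "nad[m]" = -3, "fad[m]" = -1, "adp[m]" = -1,
        "pi[m]" = -1, "nadh[m]" = 3, "fadh2[m]" = 1, "atp[m]" = 1,
        "co2[m]" = 2))
  add("AKGDHm", "Citric acid cycle", 0, 1000,
      c("akg[m]" = -1, "nad[m]" = -2, "fad[m]" = -1, "adp[m]" = -1,
        "pi[m]" = -1, "nadh[m]" = 2, "fadh2[m]" = 1, "atp[m]" = 1,
        "co2[m]" = 2))

  # --- oxidative phosphorylation -------------------------------------------
  add("CPLX1m", "Oxidative phosphorylation", 0, ci_cap,
      c("nadh[m]" = -1, "q[m]" = -1, "nad[m]" = 1, "qh2[m]" = 1,
        "pmf[m]" = p$pmf_per_complex1))
  add("CPLX2m", "Oxidative phosphorylation", 0, 1000,
      c("fadh2[m]" = -1, "q[m]" = -1, "fad[m]" = 1, "qh2[m]" = 1))
  add("CPLX34m", "Oxidative phosphorylation", 0, 1000,
      c("qh2[m]" = -1, "o2[m]" = -0.5, "q[m]" = 1, "h2o[m]" = 1,
        "pmf[m]" = p$pmf_per_qh2))
  add("ATPS4mi", "Oxidative phosphorylation", 0, 1000,
      c("adp[m]" = -1, "pi[m]" = -1, "pmf[m]" = -p$pmf_per_atp,
        "atp[m]" = 1))

  # --- energy demand and futile dissipation --------------------------------
  # a fixed heat demand is met by either a proton leak (draining the
  # proton-motive force) or a futile ATP-hydrolysis cycle; at the entropic
  # optimum both run, so knocking out the leak reallocates dissipation and
  # frees proton-motive flux for ATP synthase
  add("ATPM", "ATP maintenance", p$atpm_bounds[1], p$atpm_bounds[2],
      c("atp[c]" = -1, "adp[c]" = 1, "pi[c]" = 1))
  add("LEAKm", "Proton leak", 0, 1000,
      c("pmf[m]" = -3, "heat[m]" = 1))
  add("FUTILEc", "Miscellaneous", 0, 1000,
      c("atp[c]" = -1, "adp[c]" = 1, "pi[c]" = 1, "heat[m]" = 1))

  # --- ornithine transaminase axis and urea cycle --------------------------
  # ornithine transaminase lumped with glutamate-5-semialdehyde dehydrogenase
  # and the oxidation of both derived glutamates by glutamate dehydrogenase:
  # orn + akg -> glu5sa + glu; glu5sa -> glu (+NADH); 2x glu -> 2x (akg +
  # NADH + NH4). Oxoglutarate is catalytic (net +1) and cancels to one
  # product appearance; the lump releases the ornithine nitrogen as ammonium
  # with three reducing equivalents.
  add("ORNTAm", "Urea cycle", p$orntam_min, 1000,
      c("orn[m]" = -1, "nad[m]" = -3,
        "akg[m]" = 1, "nh4[m]" = 2, "nadh[m]" = 3))
  add("ODCm", "Polyamine metabolism", 0, 1000,
      c("orn[m]" = -1, "ptrc[c]" = 1, "co2[m]" = 1))
  # glutamate from histidine/glutamine degradation is oxidized here
  add("GLUDm", "Glutamate metabolism", 0, 1000,
      c("glu[m]" = -1, "nad[m]" = -1, "akg[m]" = 1, "nadh[m]" = 1,
        "nh4[m]" = 1))
  # urea-cycle lump: two ammonium nitrogens fixed per urea at a cost of two
  # ATP; urea release to the medium is folded in
  add("UREACLm", "Urea cycle", 0, 1000,
      c("nh4[m]" = -2, "co2[m]" = -1, "atp[c]" = -2,
        "urea[e]" = 1, "adp[c]" = 2, "pi[c]" = 2))

  # --- amino-acid degradation lumps (uptake chains capacity-pinned) --------
  add("HISDEG", "Histidine metabolism", 0, 1000,
      c("his_L[c]" = -1, "glu[m]" = 1, "nh4[m]" = 1))
  add("GLNDEG", "Glutamine metabolism", 0, 1000,
      c("gln_L[c]" = -1, "glu[m]" = 1, "nh4[m]" = 1))
  # lysine/methionine degradation is tracked for carbon and redox only; the
  # amino groups leave implicitly with untracked byproducts, keeping these
  # optional fuels decoupled from the mitochondrial ammonium pool
  add("LYSDEG", "Lysine metabolism", 0, 1000,
      c("lys_L[c]" = -1, "nad[m]" = -2, "accoa[m]" = 1, "nadh[m]" = 2))
  add("METDEG", "Methionine metabolism", 0, 1000,
      c("met_L[c]" = -1, "nad[m]" = -1, "accoa[m]" = 1, "nadh[m]" = 1))

  # --- transport ------------------------------------------------------------
  add("GLCt", "Transport, extracellular", 0, 1000,
      c("glc_D[e]" = -1, "glc_D[c]" = 1))
  add("O2t", "Transport, mitochondrial", 0, 1000,
      c("o2[e]" = -1, "o2[m]" = 1))
  add("LACt", "Transport, extracellular", -1000, 1000,
      c("lac_L[e]" = -1, "lac_L[c]" = 1))
  add("PYRtm", "Transport, mitochondrial", 0, p$pyruvate_transport_cap,
      c("pyr[c]" = -1, "pyr[m]" = 1))
  add("PItm", "Transport, mitochondrial", -1000, 1000,
      c("pi[c]" = -1, "pi[m]" = 1))
  add("NADHSm", "Transport, mitochondrial", -1000, 1000,
      c("nadh[c]" = -1, "nad[m]" = -1, "nad[c]" = 1, "nadh[m]" = 1))
  add("ANTm", "Transport, mitochondrial", 0, 1000,
      c("atp[m]" = -1, "adp[c]" = -1, "atp[c]" = 1, "adp[m]" = 1))
  add("ORNtm", "Transport, mitochondrial", 0, p$orn_uptake,
      c("orn[e]" = -1, "orn[m]" = 1))
  add("HISt", "Transport, extracellular", 0, p$his_uptake,
      c("his_L[e]" = -1, "his_L[c]" = 1))
  add("LYSt", "Transport, extracellular", 0, p$lys_uptake,
      c("lys_L[e]" = -1, "lys_L[c]" = 1))
  add("METt", "Transport, extracellular", 0, p$met_uptake,
      c("met_L[e]" = -1, "met_L[c]" = 1))
  add("GLNt", "Transport, extracellular", 0, p$gln_uptake,
      c("gln_L[e]" = -1, "gln_L[c]" = 1))
  add("NH4tm", "Transport, mitochondrial", 0, p$nh4_export_cap,
      c("nh4[m]" = -1, "nh4[e]" = 1))
  add("PYRt", "Transport, extracellular", 0, 1000,
      c("pyr[e]" = -1, "pyr[c]" = 1))
  add("CO2tm", "Transport, mitochondrial", -1000, 1000,
      c("co2[m]" = -1, "co2[e]" = 1))
  add("H2Otm", "Transport, mitochondrial", 0, 1000,
      c("h2o[m]" = -1, "h2o[e]" = 1))
  # putrescine efflux is active (ATP-coupled), making the polyamine branch
  # energy-sensitive relative to the transaminase branch
  add("PTRCt", "Transport, extracellular", 0, 1000,
      c("ptrc[c]" = -1, "atp[c]" = -1.9, "ptrc[e]" = 1, "adp[c]" = 1.9,
        "pi[c]" = 1.9))
  add("AKGtm", "Transport, mitochondrial", -1000, 1000,
      c("akg[e]" = -1, "akg[m]" = 1))

  # --- dopamine branch (synaptic only) -------------------------------------
  if (syn) {
    add("TYRt", "Transport, extracellular", 0, 1000,
        c("tyr_L[e]" = -1, "tyr_L[c]" = 1))
    add("THDDCc", "Tyrosine metabolism", 0, 1000,
        c("tyr_L[c]" = -1, "dopa[c]" = 1))
    add("DOPArel", "Transport, vesicular", 0, 1000,
        c("dopa[c]" = -1, "atp[c]" = -1, "dopa[e]" = 1, "adp[c]" = 1,
          "pi[c]" = 1))
  }

  # --- exchanges ------------------------------------------------------------
  ex <- function(id, met, lb, ub) add(id, "Exchange", lb, ub,
                                      setNames(-1, met))
  ex("EX_glc_D[e]", "glc_D[e]", p$glc_bounds[1], p$glc_bounds[2])
  ex("EX_o2[e]", "o2[e]", p$o2_bounds[1], p$o2_bounds[2])
  ex("EX_lac_L[e]", "lac_L[e]", p$lac_bounds[1], p$lac_bounds[2])
  ex("EX_urea[e]", "urea[e]", 0, 1000)
  ex("EX_orn[e]", "orn[e]", -p$orn_uptake, -p$orn_uptake)
  ex("EX_his_L[e]", "his_L[e]", -p$his_uptake, -p$his_uptake)
  ex("EX_lys_L[e]", "lys_L[e]", -p$lys_uptake, 0)
  ex("EX_met_L[e]", "met_L[e]", -p$met_uptake, 0)
  ex("EX_gln_L[e]", "gln_L[e]", -p$gln_uptake, -p$gln_uptake)
  ex("EX_nh4[e]", "nh4[e]", p$nh4_export_cap, p$nh4_export_cap)
  ex("EX_pyr[e]", "pyr[e]", p$pyr_bounds[1], p$pyr_bounds[2])
  ex("EX_co2[e]", "co2[e]", -5, 1000)
  ex("EX_h2o[e]", "h2o[e]", 0, 1000)
  ex("EX_ptrc[e]", "ptrc[e]", 0, 1000)
  ex("EX_akg[e]", "akg[e]", p$akg_bounds[1], p$akg_bounds[2])
  add("DM_heat[m]", "Exchange", p$heat_demand, 1000, c("heat[m]" = -1))
  if (syn) {
    ex("EX_tyr_L[e]", "tyr_L[e]", p$tyr_bounds[1], p$tyr_bounds[2])
    ex("EX_dopa[e]", "dopa[e]", p$dopamine_release_min, 1000)
  }

  reactions <- bind_rows(lapply(rx, function(r) {
    tibble(id = r$id, lower_bound = r$lb, upper_bound = r$ub,
           subsystem = r$subsystem, reversible = r$lb < 0)
  }))
  stoich <- bind_rows(lapply(rx, function(r) {
    tibble(reaction_id = r$id, metabolite_id = names(r$stoich),
           coefficient = unname(r$stoich))
  }))
  model <- metabolic_model(
    metabolites = tibble(id = mets),
    reactions = reactions, stoichiometry = stoich,
    component = spec$component, condition = "control", atpm_id = "ATPM")

  if (spec$condition == "pd") {
    model <- apply_overlay(model, toy_pd_overlay(spec))
    model$condition <- "pd"
  }
  model
}

#' Build all four toy variants
#'
#' @param params a [toy_params()] list shared by the four builds.
#' @return named list of models: `synaptic_control`, `synaptic_pd`,
#'   `nonsynaptic_control`, `nonsynaptic_pd`.
#' @export
build_toy_variants <- function(params = toy_params()) {
  combos <- expand.grid(component = c("synaptic", "nonsynaptic"),
                        condition = c("control", "pd"),
                        stringsAsFactors = FALSE)
  out <- purrr::pmap(combos, function(component, condition) {
    build_toy_model(toy_spec(component, condition, params = params))
  })
  names(out) <- paste(combos$component, combos$condition, sep = "_")
  out
}

#' Jittered bound instances of a toy variant
#'
#' Produces `n` copies of the model with every finite non-zero bound
#' perturbed multiplicatively by uniform noise in
#' `[1 - amplitude, 1 + amplitude]`; both bounds of a reaction share one
#' factor, so ordering and sign structure are preserved. Identical seeds give
#' identical output.
#'
#' @param spec a [toy_spec()].
#' @param n number of instances.
#' @param seed integer seed.
#' @param amplitude relative noise amplitude in `[0, 0.5)`.
#' @return list of `n` models.
#' @export
jitter_instances <- function(spec, n, seed = spec$seed, amplitude = 0.05) {
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude >= 0.5) {
    abort("amplitude must lie in [0, 0.5).")
  }
  if (n == 0) return(list())
  base <- build_toy_model(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  purrr::map(seq_len(n), function(k) {
    m <- base
    fac <- runif(nrow(m$reactions), 1 - amplitude, 1 + amplitude)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    scale_lb <- is.finite(lb) & lb != 0
    scale_ub <- is.finite(ub) & ub != 0
    m$reactions$lower_bound <- ifelse(scale_lb, lb * fac, lb)
    m$reactions$upper_bound <- ifelse(scale_ub, ub * fac, ub)
    m
  })
}
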