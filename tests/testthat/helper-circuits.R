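## Shared fixtures, built in code: a reduced degradation circuit with an
## algebraic steady-state solution, and an independently hand-composed
## monolithic ODE system for the galactose gate.

## Constitutive reporter + ClpXP degradation pool with *constant* ClpP/ClpX
## supplied as cell-only species and no complex dilution. At steady state
## the binding/proteolysis flux cancels in the ClpXP balance, so
##   ClpXP = kDimF * P0 * X / kDimR
##   R     = (a/kDm * kTl) / (kDp + kBind * ClpXP)
## which gives a closed-form ON/OFF ratio when toggling the ClpX level X.
reducedParams <- function() {
  list(a = 0.02, kTl = 0.05, kDm = 5e-4, kDp = 1e-4,
       kDimF = 1e-3, kDimR = 2e-3, kBind = 2e-3, kDegr = 0.1, P0 = 50)
}

reducedDegradationCircuit <- function(p = reducedParams()) {
  cc <- CircuitModel(
    "reduced",
    compartments = list(CompartmentDef("nucleus"), CompartmentDef("cytoplasm")),
    submodels = list(
      makeTranscriptionUnit("TU_R", PromoterSpec(kMax = p$a), "mRNA_R"),
      makeMrnaPool("pool_mRNA_R", "mRNA_R", "R", p$kTl, p$kDm, p$kDp),
      makeDegradationPool("pool_degradation", targetId = "R",
                          kDimF = p$kDimF, kDimR = p$kDimR, kBind = p$kBind,
                          kDegr = p$kDegr, kDil = 0)
    ))
  cc <- connectSpecies(cc, "mRNA_R", "cytoplasm", producer = "TU_R",
                       consumers = "pool_mRNA_R")
  cc <- connectSpecies(cc, "R", "cytoplasm", producer = "pool_mRNA_R",
                       consumers = "pool_degradation")
  cc <- connectSpecies(cc, "ClpP", "cytoplasm", consumers = "pool_degradation",
                       initialAmount = p$P0, constant = TRUE)
  cc <- connectSpecies(cc, "ClpX", "cytoplasm", consumers = "pool_degradation",
                       initialAmount = 0, constant = TRUE)
  cc
}

setClpXLevel <- function(circuit, value) {
  i <- match("ClpX", vapply(circuit@connecting, function(s) s@speciesId, ""))
  circuit@connecting[[i]]@initialAmount <- value
  circuit
}

reducedSteadyStateR <- function(p, X) {
  clpxp <- p$kDimF * p$P0 * X / p$kDimR
  (p$a / p$kDm * p$kTl) / (p$kDp + p$kBind * clpxp)
}

## Hand-composed monolithic ODE system for the galactose gate, written from
## the reaction scheme (not from the flattener): three PolII-driven
## transcription units, three ribosome-limited translation pools, and the
## ClpXP degradation cycle with recycling, complex dilution and growth
## decay. State order matches the names below.
handGalactoseDerivs <- function(galactosePresent) {
  p <- galactoseDefaults()
  kX <- if (galactosePresent) p$pGAL1_induced else p$pGAL1_basal
  hP <- p$PolII / (p$K_polII + p$PolII)
  hR <- p$rib / (p$K_rib + p$rib)
  function(t, y, parms) {
    with(as.list(y), {
      dmG <- p$k_tc_GFP * hP - p$k_dm * mG
      dmP <- p$k_tc_ClpP * hP - p$k_dm * mP
      dmX <- kX * hP - p$k_dm * mX
      dG <- p$k_tl * hR * mG - p$k_dp * G - p$k_bind * XP * G
      dP <- p$k_tl * hR * mP - p$k_dp * P - p$k_dim_f * P * X + p$k_dim_r * XP
      dX <- p$k_tl * hR * mX - p$k_dp * X - p$k_dim_f * P * X + p$k_dim_r * XP
      dXP <- p$k_dim_f * P * X - p$k_dim_r * XP - p$k_bind * XP * G +
        p$k_degr * XPG - p$k_dil * XP
      dXPG <- p$k_bind * XP * G - p$k_degr * XPG - p$k_dil * XPG
      list(c(mG = dmG, mP = dmP, mX = dmX, G = dG, P = dP, X = dX,
             dXP = dXP, dXPG = dXPG))
    })
  }
}

handGalactoseState0 <- function() {
  c(mG = 0, mP = 0, mX = 0, G = 0, P = 0, X = 0, XP = 0, XPG = 0)
}

## maps the hand system's state names onto the flat model's species ids
handToFlatNames <- c(mG = "mRNA_GFP", mP = "mRNA_ClpP", mX = "mRNA_ClpX",
                     G = "GFP", P = "ClpP", X = "ClpX", XP = "ClpXP",
                     XPG = "ClpXP_GFP")

## tiny production/decay motif as a ready-made flat model
productionDecayFlat <- function(kIn = 2, kOut = 0.05) {
  sm <- SubmodelSpec(
    "motif", "mrna_pool", "cytoplasm",
    species = list(SpeciesDef("X", "cytoplasm")),
    reactions = list(
      ReactionDef("production_X", massActionLaw(kIn), products = c(X = 1)),
      ReactionDef("decay_X", massActionLaw(kOut), reactants = c(X = 1))
    ))
  flattenCircuit(CircuitModel(
    "motif_cell", compartments = list(CompartmentDef("cytoplasm")),
    submodels = list(sm)))
}
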