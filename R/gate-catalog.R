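## Turn-key construction of the two ClpXP NOT-gate circuits: a
## galactose-responsive gate (7 modules, polymerase/ribosome pools kept as
## cell-only species) and a beta-estradiol-responsive gate (9 modules, one
## extra transcription unit for the chimeric activator LHV, polymerases and
## ribosomes neglected).
##
## Units throughout: molecule counts and seconds. Default rate constants are
## order-of-magnitude choices for yeast (mRNA half-life ~20 min, protein
## half-life ~2 h, transcription/translation initiation in the 1e-2..1e-1
## range, bimolecular binding 1e-4..1e-2 per molecule per second, fast
## proteolysis 0.1/s); all are overridable and the gate-relevant ones are
## exposed to the optimizer.

#' Default kinetic parameters of the galactose NOT gate
#'
#' @return named list of defaults; see the package vignette for units and
#'   rationale.
#' @export
galactoseDefaults <- function() {
  list(
    k_tc_GFP = 0.02,       # weak constitutive reporter promoter (mRNA/s)
    k_tc_ClpP = 0.05,      # strong constitutive promoter (mRNA/s)
    pGAL1_induced = 0.05,  # pGAL1 initiation, galactose present (mRNA/s)
    pGAL1_basal = 5e-4,    # pGAL1 leak, galactose absent (1:100)
    PolII = 100, K_polII = 50,      # polymerase amount / half-saturation
    rib = 1000, K_rib = 500,        # ribosome amount / half-saturation
    k_tl = 0.05,           # translation initiation (protein/mRNA/s)
    k_dm = log(2) / 1200,  # mRNA decay, half-life 20 min
    k_dp = log(2) / 7200,  # protein decay, half-life 2 h
    k_dim_f = 1e-3, k_dim_r = 1e-3, # ClpP+ClpX dimerization
    k_bind = 1e-3,         # irreversible ClpXP-target binding
    k_degr = 0.1,          # fast proteolysis
    k_dil = 1e-4           # growth dilution of the complexes
  )
}

#' Default kinetic parameters of the beta-estradiol NOT gate
#'
#' Polymerases and ribosomes are neglected, so constitutive rates already
#' fold in the (constant) Hill occupancies of the galactose model.
#'
#' @return named list of defaults.
#' @export
estradiolDefaults <- function() {
  list(
    k_tc_GFP = 0.0133, k_tc_ClpP = 0.033, k_tc_LHV = 0.033,
    pClpX_basal = 3e-4,    # leaky minimal promoter upstream of ClpX
    pClpX_max = 0.033,     # fully LHVe-activated initiation
    K_LHVe = 50,           # LHVe half-saturation at the operators
    k_tl = 0.033,
    k_dm = log(2) / 1200, k_dp = log(2) / 7200,
    k_be = 1e-4,           # LHV + hormone binding (/molecule/s)
    k_d_LHVe = 1e-4,       # first-order LHVe decay (settable to 0)
    e_on = 2000,           # saturating hormone amount (molecules)
    k_dim_f = 1e-3, k_dim_r = 1e-3, k_bind = 1e-3, k_degr = 0.1, k_dil = 1e-4
  )
}

applyOverrides <- function(defaults, overrides) {
  if (!length(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop(sprintf("unknown parameter override(s): %s", paste(bad, collapse = ", ")))
  defaults[names(overrides)] <- overrides
  defaults
}

#' Build the galactose-responsive NOT gate
#'
#' Seven modules: three nuclear transcription units (reporter, ClpP, ClpX),
#' three cytoplasmic mRNA pools, and the degradation pool. Six connecting
#' species (three mRNAs and the three proteins) each link one producer to
#' one consumer; RNA polymerase II and the ribosomes are cell-only species
#' without a producer, feeding the transcription units and pools through
#' replaced-element links only. Galactose is not a species: its presence
#' toggles the pGAL1 transcription-initiation rate (see [setGalactose()]).
#' The gate is built in the galactose-absent state.
#'
#' @param overrides named list of parameter overrides (see
#'   [galactoseDefaults()]).
#' @param includePolIIRib keep polymerase/ribosome dependencies (the
#'   published model of this gate does); `FALSE` folds their constant Hill
#'   occupancies into the rates and drops the two cell-only species.
#' @return a [CircuitModel-class].
#' @export
buildGalactoseNotGate <- function(overrides = list(), includePolIIRib = TRUE) {
  p <- applyOverrides(galactoseDefaults(), overrides)
  occP <- p$PolII / (p$K_polII + p$PolII)   # constant PolII occupancy
  occR <- p$rib / (p$K_rib + p$rib)
  tuProm <- function(kMax)
    if (includePolIIRib)
      PromoterSpec(kMax = kMax, polIIDependent = TRUE, KPolII = p$K_polII)
    else PromoterSpec(kMax = kMax * occP)
  kTl <- if (includePolIIRib) p$k_tl else p$k_tl * occR

  tus <- list(
    makeTranscriptionUnit("TU_GFP", tuProm(p$k_tc_GFP), "mRNA_GFP"),
    makeTranscriptionUnit("TU_ClpP", tuProm(p$k_tc_ClpP), "mRNA_ClpP"),
    makeTranscriptionUnit("TU_ClpX", tuProm(p$pGAL1_basal), "mRNA_ClpX")
  )
  pools <- list(
    makeMrnaPool("pool_mRNA_GFP", "mRNA_GFP", "GFP", kTl, p$k_dm, p$k_dp,
                 ribDependent = includePolIIRib, KRib = p$K_rib),
    makeMrnaPool("pool_mRNA_ClpP", "mRNA_ClpP", "ClpP", kTl, p$k_dm, p$k_dp,
                 ribDependent = includePolIIRib, KRib = p$K_rib),
    makeMrnaPool("pool_mRNA_ClpX", "mRNA_ClpX", "ClpX", kTl, p$k_dm, p$k_dp,
                 ribDependent = includePolIIRib, KRib = p$K_rib)
  )
  deg <- makeDegradationPool("pool_degradation", kDimF = p$k_dim_f,
                             kDimR = p$k_dim_r, kBind = p$k_bind,
                             kDegr = p$k_degr, kDil = p$k_dil)
  circuit <- CircuitModel(
    "galactose_not_gate",
    compartments = list(CompartmentDef("nucleus"), CompartmentDef("cytoplasm")),
    submodels = c(tus, pools, list(deg)),
    parameters = c(pGAL1_induced = if (includePolIIRib) p$pGAL1_induced else
                     p$pGAL1_induced * occP,
                   pGAL1_basal = if (includePolIIRib) p$pGAL1_basal else
                     p$pGAL1_basal * occP,
                   galactose_present = 0)
  )
  for (tag in c("GFP", "ClpP", "ClpX")) {
    circuit <- connectSpecies(circuit, paste0("mRNA_", tag), "cytoplasm",
                              producer = paste0("TU_", tag),
                              consumers = paste0("pool_mRNA_", tag))
    circuit <- connectSpecies(circuit, tag, "cytoplasm",
                              producer = paste0("pool_mRNA_", tag),
                              consumers = "pool_degradation")
  }
  if (includePolIIRib) {
    circuit <- connectSpecies(circuit, "PolII", "nucleus",
                              consumers = c("TU_GFP", "TU_ClpP", "TU_ClpX"),
                              initialAmount = p$PolII, constant = TRUE)
    circuit <- connectSpecies(circuit, "rib", "cytoplasm",
                              consumers = c("pool_mRNA_GFP", "pool_mRNA_ClpP",
                                            "pool_mRNA_ClpX"),
                              initialAmount = p$rib, constant = TRUE)
  }
  circuit
}

#' Toggle galactose on the galactose NOT gate
#'
#' Sets the pGAL1 transcription-initiation rate (in module TU_ClpX) to its
#' induced value when galactose is present and to its basal leak when
#' absent; nothing else changes, and toggling twice restores the original
#' parameterization.
#'
#' @param circuit a circuit built by [buildGalactoseNotGate()].
#' @param present logical: galactose in the medium?
#' @return the toggled circuit.
#' @export
setGalactose <- function(circuit, present) {
  need <- c("pGAL1_induced", "pGAL1_basal", "galactose_present")
  if (!all(need %in% names(circuit@parameters)) ||
      !"TU_ClpX" %in% vapply(circuit@submodels, function(s) s@id, ""))
    stop("setGalactose: not a galactose NOT-gate circuit")
  k <- unname(circuit@parameters[if (present) "pGAL1_induced" else "pGAL1_basal"])
  circuit <- setParam(circuit, "TU_ClpX/transcription_mRNA_ClpX/k", k)
  circuit@parameters["galactose_present"] <- as.numeric(present)
  circuit
}

#' Build the beta-estradiol-responsive NOT gate
#'
#' Nine modules: four nuclear transcription units (reporter, ClpP, ClpX, and
#' the chimeric activator LHV), four cytoplasmic mRNA pools, and the
#' degradation pool. Polymerases and ribosomes are neglected. Nine
#' connecting species: the four mRNAs, the three proteins and the hormone
#' input `e` (all cytoplasmic; `e` is a constant boundary species with no
#' producer), plus the hormone-bound activator `LHVe` in the nucleus, which
#' links its producing pool (where `LHV + e -> LHVe` forms) to TU_ClpX
#' (where it activates transcription through a non-cooperative Hill term);
#' every reaction involving LHVe lives in those two modules. The gate is
#' built with hormone level 0 (see [setEstradiol()]).
#'
#' @param overrides named list of parameter overrides (see
#'   [estradiolDefaults()]).
#' @return a [CircuitModel-class].
#' @export
buildEstradiolNotGate <- function(overrides = list()) {
  p <- applyOverrides(estradiolDefaults(), overrides)
  tus <- list(
    makeTranscriptionUnit("TU_GFP", PromoterSpec(kMax = p$k_tc_GFP), "mRNA_GFP"),
    makeTranscriptionUnit("TU_ClpP", PromoterSpec(kMax = p$k_tc_ClpP), "mRNA_ClpP"),
    makeTranscriptionUnit("TU_ClpX",
                          PromoterSpec(kBasal = p$pClpX_basal,
                                       kMax = p$pClpX_max,
                                       activator = "LHVe", KAct = p$K_LHVe),
                          "mRNA_ClpX"),
    makeTranscriptionUnit("TU_LHV", PromoterSpec(kMax = p$k_tc_LHV), "mRNA_LHV")
  )
  lhvPool <- makeMrnaPool(
    "pool_mRNA_LHV", "mRNA_LHV", "LHV", p$k_tl, p$k_dm, p$k_dp,
    proteinRole = "internal",
    extraSpecies = list(
      SpeciesDef("e", "cytoplasm", constant = TRUE, role = "input"),
      SpeciesDef("LHVe", "nucleus", role = "output")
    ),
    extraReactions = list(
      ReactionDef("binding_LHVe", massActionLaw(p$k_be),
                  reactants = c(LHV = 1, e = 1), products = c(LHVe = 1)),
      ReactionDef("decay_LHVe", massActionLaw(p$k_d_LHVe),
                  reactants = c(LHVe = 1))
    )
  )
  pools <- list(
    makeMrnaPool("pool_mRNA_GFP", "mRNA_GFP", "GFP", p$k_tl, p$k_dm, p$k_dp),
    makeMrnaPool("pool_mRNA_ClpP", "mRNA_ClpP", "ClpP", p$k_tl, p$k_dm, p$k_dp),
    makeMrnaPool("pool_mRNA_ClpX", "mRNA_ClpX", "ClpX", p$k_tl, p$k_dm, p$k_dp),
    lhvPool
  )
  deg <- makeDegradationPool("pool_degradation", kDimF = p$k_dim_f,
                             kDimR = p$k_dim_r, kBind = p$k_bind,
                             kDegr = p$k_degr, kDil = p$k_dil)
  circuit <- CircuitModel(
    "estradiol_not_gate",
    compartments = list(CompartmentDef("nucleus"), CompartmentDef("cytoplasm")),
    submodels = c(tus, pools, list(deg)),
    parameters = c(e_on = p$e_on)
  )
  for (tag in c("GFP", "ClpP", "ClpX", "LHV")) {
    circuit <- connectSpecies(circuit, paste0("mRNA_", tag), "cytoplasm",
                              producer = paste0("TU_", tag),
                              consumers = paste0("pool_mRNA_", tag))
  }
  for (tag in c("GFP", "ClpP", "ClpX")) {
    circuit <- connectSpecies(circuit, tag, "cytoplasm",
                              producer = paste0("pool_mRNA_", tag),
                              consumers = "pool_degradation")
  }
  circuit <- connectSpecies(circuit, "e", "cytoplasm",
                            consumers = "pool_mRNA_LHV",
                            initialAmount = 0, constant = TRUE)
  circuit <- connectSpecies(circuit, "LHVe", "nucleus",
                            producer = "pool_mRNA_LHV",
                            consumers = "TU_ClpX")
  circuit
}

#' Set the beta-estradiol level of the estradiol NOT gate
#'
#' The hormone input is a constant boundary species in the cell cytoplasm;
#' this sets its amount (0 = input absent).
#'
#' @param circuit a circuit built by [buildEstradiolNotGate()].
#' @param level hormone amount in molecules (>= 0).
#' @return the modified circuit.
#' @export
setEstradiol <- function(circuit, level) {
  if (level < 0) stop("setEstradiol: level must be >= 0")
  ids <- vapply(circuit@connecting, function(s) s@speciesId, "")
  i <- match("e", ids)
  if (is.na(i)) stop("setEstradiol: circuit has no hormone input species 'e'")
  circuit@connecting[[i]]@initialAmount <- level
  circuit
}

#' Analysis specification for a catalog gate
#'
#' Bundles everything the steady-state analysis and the optimizer need for a
#' named catalog gate: a builder, the input setter with its off/on settings,
#' the reporter id, a direct sweep setter with a default 10-point input
#' grid, and the documented free-parameter set with its bounds (the induced
#' transcription rate of the input-controlled promoter, the dimerization,
#' target-binding and proteolysis rates, the reporter decay rate, and — for
#' the hormone gate — the hormone-activator binding rate).
#'
#' @param gate `"galactose"` or `"estradiol"`.
#' @return a list with `build`, `inputSetter`, `offValue`, `onValue`,
#'   `outputSpecies`, `sweepSetter`, `sweepValues`, `freeParameters`,
#'   `bounds`.
#' @export
gateAnalysisSpec <- function(gate = c("galactose", "estradiol")) {
  gate <- match.arg(gate)
  if (gate == "galactose") {
    defs <- galactoseDefaults()
    list(
      build = buildGalactoseNotGate,
      inputSetter = function(circuit, value) setGalactose(circuit, value >= 0.5),
      offValue = 0, onValue = 1,
      outputSpecies = "GFP",
      sweepSetter = function(circuit, value)
        setParam(circuit, "TU_ClpX/transcription_mRNA_ClpX/k", value),
      sweepValues = 10^seq(log10(defs$pGAL1_basal), log10(defs$pGAL1_induced),
                           length.out = 10),
      freeParameters = c("params/pGAL1_induced",
                         "pool_degradation/dimerization_ClpXP_f/k",
                         "pool_degradation/binding_GFP/k",
                         "pool_degradation/proteolysis_GFP/k",
                         "pool_mRNA_GFP/decay_GFP/k"),
      bounds = list(
        "params/pGAL1_induced" = c(1e-4, 0.2),
        "pool_degradation/dimerization_ClpXP_f/k" = c(1e-5, 1e-2),
        "pool_degradation/binding_GFP/k" = c(1e-5, 1e-2),
        "pool_degradation/proteolysis_GFP/k" = c(1e-3, 1),
        "pool_mRNA_GFP/decay_GFP/k" = c(1e-5, 1e-3)
      )
    )
  } else {
    defs <- estradiolDefaults()
    list(
      build = buildEstradiolNotGate,
      inputSetter = setEstradiol,
      offValue = 0, onValue = defs$e_on,
      outputSpecies = "GFP",
      sweepSetter = setEstradiol,
      sweepValues = seq(0, defs$e_on, length.out = 10),
      freeParameters = c("TU_ClpX/transcription_mRNA_ClpX/k",
                         "pool_mRNA_LHV/binding_LHVe/k",
                         "pool_degradation/dimerization_ClpXP_f/k",
                         "pool_degradation/binding_GFP/k",
                         "pool_degradation/proteolysis_GFP/k",
                         "pool_mRNA_GFP/decay_GFP/k"),
      bounds = list(
        "TU_ClpX/transcription_mRNA_ClpX/k" = c(1e-4, 0.2),
        "pool_mRNA_LHV/binding_LHVe/k" = c(1e-6, 1e-2),
        "pool_degradation/dimerization_ClpXP_f/k" = c(1e-5, 1e-2),
        "pool_degradation/binding_GFP/k" = c(1e-5, 1e-2),
        "pool_degradation/proteolysis_GFP/k" = c(1e-3, 1),
        "pool_mRNA_GFP/decay_GFP/k" = c(1e-5, 1e-3)
      )
    )
  }
}
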