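## Builders for the three module kinds (transcription unit, mRNA pool,
## degradation pool) and for the cell-level connecting species that wire
## them together. Builders are deterministic: identical arguments yield
## identical submodels with a stable ordering of species, reactions, ports.

#' Promoter specification
#'
#' Transcription-initiation kinetics of a transcription unit. The reaction
#' rate is `kBasal + kMax * Hill(activator)` when an activator is given,
#' `kMax` otherwise; if `polIIDependent`, the whole rate is additionally
#' multiplied by the non-cooperative Hill term in RNA polymerase II. A
#' galactose-style induction is NOT a species: it is realized by toggling
#' `kMax` between an induced and a basal value (see [setGalactose()]).
#'
#' @param kBasal leaky transcription-initiation rate (mRNA/s), `0 <= kBasal
#'   <= kMax`.
#' @param kMax activated transcription-initiation rate (mRNA/s).
#' @param activator species id of the transcriptional activator, or NA for a
#'   constitutive promoter.
#' @param KAct half-saturation of the activator (molecules).
#' @param polIIDependent multiply the rate by the Hill term in PolII?
#' @param KPolII half-saturation for PolII (molecules).
#' @return a `PromoterSpec` (plain list).
#' @export
PromoterSpec <- function(kBasal = 0, kMax, activator = NA_character_,
                         KAct = NA_real_, polIIDependent = FALSE,
                         KPolII = 50) {
  if (kBasal < 0 || kMax < kBasal)
    stop("PromoterSpec requires 0 <= kBasal <= kMax")
  if (!is.na(activator) && (is.na(KAct) || KAct <= 0))
    stop("an activated promoter requires KAct > 0")
  structure(list(kBasal = kBasal, kMax = kMax, activator = activator,
                 KAct = KAct, polIIDependent = polIIDependent,
                 KPolII = KPolII), class = "PromoterSpec")
}

promoterLaw <- function(promoter, polIIId = "PolII") {
  if (!is.na(promoter$activator)) {
    a2 <- if (promoter$polIIDependent) polIIId else NA_character_
    K2 <- if (promoter$polIIDependent) promoter$KPolII else NA_real_
    hillLaw(k = promoter$kMax, K = promoter$KAct,
            activator = promoter$activator, kBasal = promoter$kBasal,
            activator2 = a2, K2 = K2)
  } else if (promoter$polIIDependent) {
    ## constitutive but PolII-driven: kMax * PolII/(K+PolII)
    hillLaw(k = promoter$kMax, K = promoter$KPolII, activator = polIIId,
            kBasal = promoter$kBasal)
  } else {
    ## constitutive, polymerases neglected: zero-order synthesis
    massActionLaw(promoter$kMax + promoter$kBasal)
  }
}

#' Build a transcription-unit submodel
#'
#' A TU lives in the nucleus, takes RNA polymerase II and/or a
#' transcriptional activator as input, and delivers one mRNA as output. The
#' mRNA species is assigned to the (usually cytoplasmic) pool compartment
#' even though the unit itself is nuclear. Every input/output species gets a
#' port named `port_<speciesId>`.
#'
#' @param id submodel id (e.g. `"TU_GFP"`).
#' @param promoter a [PromoterSpec()].
#' @param mrnaId id of the emitted mRNA species.
#' @param mrnaCompartment compartment the mRNA is assigned to.
#' @param hostCompartment compartment hosting the unit (default `"nucleus"`).
#' @param polIIId id of the polymerase species when `polIIDependent`.
#' @return a [SubmodelSpec-class] of kind `"TU"`.
#' @export
makeTranscriptionUnit <- function(id, promoter, mrnaId,
                                  mrnaCompartment = "cytoplasm",
                                  hostCompartment = "nucleus",
                                  polIIId = "PolII") {
  species <- list()
  if (promoter$polIIDependent)
    species <- c(species, list(SpeciesDef(polIIId, hostCompartment,
                                          constant = TRUE, role = "input")))
  if (!is.na(promoter$activator))
    species <- c(species, list(SpeciesDef(promoter$activator, hostCompartment,
                                          role = "input")))
  species <- c(species, list(SpeciesDef(mrnaId, mrnaCompartment,
                                        role = "output")))
  law <- promoterLaw(promoter, polIIId)
  mods <- lawSpecies(law)
  rx <- ReactionDef(paste0("transcription_", mrnaId), law,
                    products = structure(1, names = mrnaId),
                    modifiers = mods)
  ports <- lapply(vapply(species, function(s) s@id, ""), PortDef)
  SubmodelSpec(id, "TU", hostCompartment, species = species,
               reactions = list(rx), ports = ports)
}

#' Build an mRNA-pool submodel
#'
#' The cytoplasmic pool where a protein is synthesized from its mRNA:
#' translation (optionally ribosome-activated through a Hill term),
#' first-order mRNA decay and first-order protein decay, plus any extra
#' reactions (used for the hormone-binding step in the activator pool of the
#' beta-estradiol gate). Extra species referenced by `extraReactions` must be
#' supplied via `extraSpecies`.
#'
#' @param id submodel id (e.g. `"pool_mRNA_GFP"`).
#' @param mrnaId input mRNA species id.
#' @param proteinId output protein species id.
#' @param kTl translation rate constant (protein per mRNA per s, times the
#'   ribosome Hill term when `ribDependent`).
#' @param kDm first-order mRNA decay rate (/s).
#' @param kDp first-order protein decay rate (/s).
#' @param ribDependent multiply translation by `rib/(KRib + rib)`?
#' @param KRib ribosome half-saturation (molecules).
#' @param ribId ribosome species id.
#' @param hostCompartment default `"cytoplasm"`.
#' @param proteinRole `"output"` (default: the protein is exported through a
#'   port) or `"internal"` (it only feeds this pool's own extra reactions,
#'   as the free activator does in the hormone-binding pool).
#' @param extraSpecies list of [SpeciesDef-class] beyond the mRNA/protein.
#' @param extraReactions list of [ReactionDef-class] beyond the three
#'   standard ones.
#' @return a [SubmodelSpec-class] of kind `"mrna_pool"`.
#' @export
makeMrnaPool <- function(id, mrnaId, proteinId, kTl, kDm, kDp,
                         ribDependent = FALSE, KRib = 500, ribId = "rib",
                         hostCompartment = "cytoplasm",
                         proteinRole = "output",
                         extraSpecies = list(), extraReactions = list()) {
  stopifnot(kTl >= 0, kDm >= 0, kDp >= 0)
  species <- list(SpeciesDef(mrnaId, hostCompartment, role = "input"))
  if (ribDependent)
    species <- c(species, list(SpeciesDef(ribId, hostCompartment,
                                          constant = TRUE, role = "input")))
  species <- c(species,
               list(SpeciesDef(proteinId, hostCompartment, role = proteinRole)),
               extraSpecies)
  ids <- vapply(species, function(s) s@id, "")
  for (r in extraReactions) {
    refs <- unique(c(names(r@reactants), names(r@products), r@modifiers,
                     lawSpecies(r@law)))
    bad <- setdiff(refs, ids)
    if (length(bad))
      stop(sprintf("extra reaction '%s' references undeclared species: %s",
                   r@id, paste(bad, collapse = ", ")))
  }
  ## translation: rate kTl*[mRNA]*Hill(rib) when ribosome-limited, else
  ## kTl*[mRNA] (encoded as a pure basal term scaled by the template so the
  ## mRNA is a modifier, never consumed)
  tlLaw <- if (ribDependent)
    hillLaw(k = kTl, K = KRib, activator = ribId, scaleSpecies = mrnaId)
  else
    hillLaw(k = 0, K = 1, activator = mrnaId, kBasal = kTl,
            scaleSpecies = mrnaId)
  rxs <- list(
    ReactionDef(paste0("translation_", proteinId), tlLaw,
                products = structure(1, names = proteinId),
                modifiers = unique(lawSpecies(tlLaw))),
    ReactionDef(paste0("decay_", mrnaId), massActionLaw(kDm),
                reactants = structure(1, names = mrnaId)),
    ReactionDef(paste0("decay_", proteinId), massActionLaw(kDp),
                reactants = structure(1, names = proteinId))
  )
  rxs <- c(rxs, extraReactions)
  ports <- lapply(ids[vapply(species, function(s) s@role != "internal", TRUE)],
                  PortDef)
  SubmodelSpec(id, "mrna_pool", hostCompartment, species = species,
               reactions = rxs, ports = ports)
}

#' Build the ClpXP degradation-pool submodel
#'
#' ClpP and ClpX dimerize (reversibly, stored as a forward/backward pair of
#' irreversible reactions) into the ClpXP protease, which binds the
#' ssrA-tagged target irreversibly and degrades it quickly, releasing free
#' ClpXP (the enzyme acts catalytically; the released peptides are not
#' tracked). Both complexes are diluted first order by growth (`kDil`, set 0
#' for a minimal model). Ports expose ClpP, ClpX and the target.
#'
#' @param id submodel id (default `"pool_degradation"`).
#' @param clppId,clpxId,targetId species ids.
#' @param kDimF,kDimR dimerization forward (/molecule/s) and backward (/s)
#'   rates.
#' @param kBind irreversible ClpXP-target binding rate (/molecule/s).
#' @param kDegr proteolysis rate (/s), fast.
#' @param kDil first-order dilution of the complexes (/s).
#' @param hostCompartment default `"cytoplasm"`.
#' @return a [SubmodelSpec-class] of kind `"degradation_pool"`.
#' @export
makeDegradationPool <- function(id = "pool_degradation", clppId = "ClpP",
                                clpxId = "ClpX", targetId = "GFP",
                                kDimF = 1e-3, kDimR = 1e-3, kBind = 1e-3,
                                kDegr = 0.1, kDil = 1e-4,
                                hostCompartment = "cytoplasm") {
  stopifnot(kBind > 0, kDegr > 0, kDimF >= 0, kDimR >= 0, kDil >= 0)
  complexId <- paste0(clpxId, clppId)         # "ClpXClpP" -> keep "ClpXP" for defaults
  if (clppId == "ClpP" && clpxId == "ClpX") complexId <- "ClpXP"
  boundId <- paste0(complexId, "_", targetId)
  species <- list(
    SpeciesDef(clppId, hostCompartment, role = "input"),
    SpeciesDef(clpxId, hostCompartment, role = "input"),
    SpeciesDef(targetId, hostCompartment, role = "input"),
    SpeciesDef(complexId, hostCompartment, role = "internal"),
    SpeciesDef(boundId, hostCompartment, role = "internal")
  )
  rxs <- list(
    ReactionDef(paste0("dimerization_", complexId, "_f"), massActionLaw(kDimF),
                reactants = structure(c(1, 1), names = c(clppId, clpxId)),
                products = structure(1, names = complexId), reversible = TRUE),
    ReactionDef(paste0("dimerization_", complexId, "_b"), massActionLaw(kDimR),
                reactants = structure(1, names = complexId),
                products = structure(c(1, 1), names = c(clppId, clpxId)),
                reversible = TRUE),
    ReactionDef(paste0("binding_", targetId), massActionLaw(kBind),
                reactants = structure(c(1, 1), names = c(complexId, targetId)),
                products = structure(1, names = boundId)),
    ReactionDef(paste0("proteolysis_", targetId), massActionLaw(kDegr),
                reactants = structure(1, names = boundId),
                products = structure(1, names = complexId)),
    ReactionDef(paste0("dilution_", complexId), massActionLaw(kDil),
                reactants = structure(1, names = complexId)),
    ReactionDef(paste0("dilution_", boundId), massActionLaw(kDil),
                reactants = structure(1, names = boundId))
  )
  ports <- lapply(c(clppId, clpxId, targetId), PortDef)
  SubmodelSpec(id, "degradation_pool", hostCompartment, species = species,
               reactions = rxs, ports = ports)
}

#' Register a connecting species in the cell model
#'
#' Adds the "helper" copy of a species to the cell model, with one
#' replaced-by link to the producing submodel's port (if any) and one
#' replaced-element link per consuming submodel's port. `producer = NULL`
#' yields a cell-only species (polymerase, ribosomes, the hormone input)
#' linked via replaced-element objects only. Each named submodel must expose
#' the port `port_<speciesId>`.
#'
#' @param circuit a [CircuitModel-class].
#' @param speciesId id of the species being connected.
#' @param compartment cell-level compartment of the helper copy.
#' @param producer producing submodel id, or NULL.
#' @param consumers character vector of consuming submodel ids.
#' @param initialAmount cell copy amount (inherited by the flat species).
#' @param constant fixed boundary species?
#' @return the circuit with the new [ConnectingSpecies-class] appended.
#' @export
connectSpecies <- function(circuit, speciesId, compartment, producer = NULL,
                           consumers = character(), initialAmount = 0,
                           constant = FALSE) {
  if (speciesId %in% vapply(circuit@connecting, function(s) s@speciesId, ""))
    stop(sprintf("species '%s' is already connected", speciesId))
  portId <- paste0("port_", speciesId)
  for (smId in c(producer, consumers)) {
    sm <- getSubmodel(circuit, smId)
    if (!portId %in% portIds(sm))
      stop(sprintf("submodel '%s' has no port '%s'", smId, portId))
  }
  prod <- if (is.null(producer)) character() else c(producer, portId)
  cons <- lapply(consumers, function(smId) c(smId, portId))
  cs <- new("ConnectingSpecies", speciesId = speciesId,
            compartment = compartment, initialAmount = initialAmount,
            constant = constant, producer = prod, consumers = cons)
  circuit@connecting <- c(circuit@connecting, list(cs))
  validObject(circuit)
  circuit
}

## ---- parameter paths -------------------------------------------------------

#' Get or set a kinetic parameter by path
#'
#' Parameters are addressed as `"<submodelId>/<reactionId>/<slot>"` where
#' slot is one of `k`, `kBasal`, `K`, `K2`, or as `"params/<name>"` for the
#' circuit's global constants. Used by the optimizer's free-parameter set.
#'
#' @param circuit a [CircuitModel-class].
#' @param path parameter path string.
#' @param value replacement value (setter only).
#' @return the value (getter) or the modified circuit (setter).
#' @export
getParam <- function(circuit, path) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (p[1] == "params") {
    if (!p[2] %in% names(circuit@parameters))
      stop(sprintf("no global parameter '%s'", p[2]))
    return(unname(circuit@parameters[p[2]]))
  }
  if (length(p) != 3) stop("parameter path must be submodel/reaction/slot or params/name")
  sm <- getSubmodel(circuit, p[1])
  i <- match(p[2], reactionIds(sm))
  if (is.na(i)) stop(sprintf("no reaction '%s' in submodel '%s'", p[2], p[1]))
  slot(sm@reactions[[i]]@law, p[3])
}

#' @rdname getParam
#' @export
setParam <- function(circuit, path, value) {
  p <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (p[1] == "params") {
    if (!p[2] %in% names(circuit@parameters))
      stop(sprintf("no global parameter '%s'", p[2]))
    circuit@parameters[p[2]] <- value
    return(circuit)
  }
  if (length(p) != 3) stop("parameter path must be submodel/reaction/slot or params/name")
  ids <- vapply(circuit@submodels, function(s) s@id, "")
  si <- match(p[1], ids)
  if (is.na(si)) stop(sprintf("no submodel '%s'", p[1]))
  ri <- match(p[2], reactionIds(circuit@submodels[[si]]))
  if (is.na(ri)) stop(sprintf("no reaction '%s' in submodel '%s'", p[2], p[1]))
  law <- circuit@submodels[[si]]@reactions[[ri]]@law
  slot(law, p[3]) <- value
  validObject(law)
  circuit@submodels[[si]]@reactions[[ri]]@law <- law
  circuit
}
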