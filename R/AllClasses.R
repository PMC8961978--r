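#' @import methods
NULL

## Central data structures for hierarchical circuit models.
##
## A CircuitModel is a cell-level container: compartments, a flat list of
## submodels (one hierarchy level: cell -> submodels), and the cell-level
## "connecting" species that join submodel ports via replaced-by /
## replaced-element links. Submodels own their species, reactions and ports.

#' Kinetic rate law
#'
#' A rate form attached to a reaction: either mass action
#' (rate = k * prod(reactant^stoichiometry), total molecularity at most 2)
#' or Hill activation without cooperativity
#' (rate = (kBasal + k * A/(K + A)) * optional second Hill factor * optional
#' linear scale species). The Hill coefficient is structurally fixed at 1:
#' the slot exists as a documented extension point, but any other value is
#' rejected by the validity method.
#'
#' @slot form `"massAction"` or `"hillActivation"`.
#' @slot k maximal rate constant (per time; per time per molecule for
#'   bimolecular mass action).
#' @slot kBasal basal (leaky) rate added to the Hill term; 0 for mass action.
#' @slot K half-saturation constant in molecules (Hill only).
#' @slot n Hill coefficient, fixed at 1.
#' @slot activator species id driving the Hill term (Hill only).
#' @slot activator2,K2 optional second multiplicative Hill factor (used when a
#'   promoter depends on both a transcription factor and RNA polymerase II).
#' @slot scaleSpecies optional species whose amount multiplies the rate
#'   linearly (e.g. the mRNA template in a ribosome-activated translation).
#' @export
setClass("KineticLaw", representation(
  form = "character",
  k = "numeric",
  kBasal = "numeric",
  K = "numeric",
  n = "numeric",
  activator = "character",
  activator2 = "character",
  K2 = "numeric",
  scaleSpecies = "character"
), prototype(
  form = "massAction", k = 0, kBasal = 0, K = NA_real_, n = 1,
  activator = NA_character_, activator2 = NA_character_, K2 = NA_real_,
  scaleSpecies = NA_character_
))

setValidity("KineticLaw", function(object) {
  msg <- character()
  if (!object@form %in% c("massAction", "hillActivation"))
    msg <- c(msg, sprintf("unknown law form '%s'", object@form))
  if (is.na(object@k) || object@k < 0) msg <- c(msg, "k must be >= 0")
  if (object@kBasal < 0) msg <- c(msg, "kBasal must be >= 0")
  if (!identical(object@n, 1)) {
    if (object@n != 1)
      msg <- c(msg, "Hill coefficient n is fixed at 1 (no cooperativity)")
  }
  if (object@form == "hillActivation") {
    if (is.na(object@K) || object@K <= 0)
      msg <- c(msg, "hillActivation requires K > 0")
    if (is.na(object@activator))
      msg <- c(msg, "hillActivation requires an activator species")
    if (!is.na(object@activator2) && (is.na(object@K2) || object@K2 <= 0))
      msg <- c(msg, "second Hill factor requires K2 > 0")
  } else {
    if (!is.na(object@K) || !is.na(object@activator))
      msg <- c(msg, "massAction laws carry no K/activator")
  }
  if (length(msg)) msg else TRUE
})

#' Compartment definition
#'
#' @slot id compartment identifier (e.g. `"nucleus"`, `"cytoplasm"`).
#' @slot size dimensionless volume, default 1 (amounts are molecule counts).
#' @export
setClass("CompartmentDef",
  representation(id = "character", size = "numeric"),
  prototype(size = 1))

setValidity("CompartmentDef", function(object) {
  if (length(object@id) != 1 || !nzchar(object@id)) return("id required")
  if (object@size <= 0) return("compartment size must be > 0")
  TRUE
})

#' Species definition
#'
#' @slot id species identifier.
#' @slot compartment id of the hosting compartment. An output species of a
#'   nuclear transcription unit may live in a different compartment than the
#'   unit itself (a nuclear gene emitting a cytoplasmic mRNA).
#' @slot initialAmount molecule count, >= 0.
#' @slot constant TRUE for fixed boundary inputs (polymerase, ribosome,
#'   hormone level).
#' @slot role one of `"input"`, `"output"`, `"internal"`; drives automatic
#'   port creation (every non-internal species gets a port).
#' @export
setClass("SpeciesDef", representation(
  id = "character", compartment = "character", initialAmount = "numeric",
  constant = "logical", role = "character"
), prototype(initialAmount = 0, constant = FALSE, role = "internal"))

setValidity("SpeciesDef", function(object) {
  msg <- character()
  if (length(object@id) != 1 || !nzchar(object@id)) msg <- c(msg, "id required")
  if (object@initialAmount < 0) msg <- c(msg, "initialAmount must be >= 0")
  if (!object@role %in% c("input", "output", "internal"))
    msg <- c(msg, "role must be input/output/internal")
  if (length(msg)) msg else TRUE
})

#' Port definition
#'
#' A comp-package interface object exposing one species of a submodel for
#' cross-model linking. Ports are always named `port_<speciesId>` so that
#' cross-file references are deterministic.
#'
#' @slot id port identifier, `"port_" + species id`.
#' @slot speciesRef id of the exposed species.
#' @export
setClass("PortDef", representation(id = "character", speciesRef = "character"))

setValidity("PortDef", function(object) {
  if (!identical(object@id, paste0("port_", object@speciesRef)))
    return(sprintf("port id must be 'port_%s'", object@speciesRef))
  TRUE
})

#' Reaction definition
#'
#' Reversible processes are stored as two irreversible reactions with paired
#' ids (suffixes `_f`/`_b`); the `reversible` flag is metadata marking such a
#' half-pair and never affects ODE assembly.
#'
#' @slot id reaction identifier.
#' @slot reactants named integer vector: species id -> stoichiometry.
#' @slot products named integer vector: species id -> stoichiometry.
#' @slot modifiers species ids appearing in the rate law but not consumed or
#'   produced (templates, activators).
#' @slot law a [KineticLaw-class].
#' @slot reversible metadata flag: this reaction is one half of a reversible
#'   pair.
#' @export
setClass("ReactionDef", representation(
  id = "character", reactants = "numeric", products = "numeric",
  modifiers = "character", law = "KineticLaw", reversible = "logical"
), prototype(reactants = numeric(), products = numeric(),
             modifiers = character(), reversible = FALSE))

setValidity("ReactionDef", function(object) {
  msg <- character()
  if (length(object@id) != 1 || !nzchar(object@id)) msg <- c(msg, "id required")
  st <- c(object@reactants, object@products)
  if (length(st) && (any(st <= 0) || any(st != round(st))))
    msg <- c(msg, "stoichiometries must be positive integers")
  if (length(object@reactants) && is.null(names(object@reactants)))
    msg <- c(msg, "reactants must be a named vector")
  if (length(object@products) && is.null(names(object@products)))
    msg <- c(msg, "products must be a named vector")
  if (length(msg)) msg else TRUE
})

#' Submodel specification
#'
#' One circuit module: a transcription unit (`"TU"`), an mRNA pool
#' (`"mrna_pool"`), or the degradation pool (`"degradation_pool"`), with its
#' species, reactions, and ports. Hierarchy depth is fixed at one: submodels
#' do not nest.
#'
#' @slot id submodel identifier (also the XML file stem on disk).
#' @slot kind `"TU"`, `"mrna_pool"`, or `"degradation_pool"`.
#' @slot hostCompartment compartment the module itself sits in.
#' @slot species list of [SpeciesDef-class].
#' @slot reactions list of [ReactionDef-class].
#' @slot ports list of [PortDef-class].
#' @export
setClass("SubmodelSpec", representation(
  id = "character", kind = "character", hostCompartment = "character",
  species = "list", reactions = "list", ports = "list"
), prototype(species = list(), reactions = list(), ports = list()))

setValidity("SubmodelSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("TU", "mrna_pool", "degradation_pool"))
    msg <- c(msg, "kind must be TU/mrna_pool/degradation_pool")
  if (!all(vapply(object@species, is, TRUE, class2 = "SpeciesDef")))
    msg <- c(msg, "species must be SpeciesDef objects")
  if (!all(vapply(object@reactions, is, TRUE, class2 = "ReactionDef")))
    msg <- c(msg, "reactions must be ReactionDef objects")
  if (!all(vapply(object@ports, is, TRUE, class2 = "PortDef")))
    msg <- c(msg, "ports must be PortDef objects")
  sid <- vapply(object@species, function(s) s@id, "")
  if (anyDuplicated(sid)) msg <- c(msg, "duplicate species ids")
  pref <- vapply(object@ports, function(p) p@speciesRef, "")
  if (anyDuplicated(pref)) msg <- c(msg, "at most one port per species")
  if (length(msg)) msg else TRUE
})

#' Cell-level connecting species
#'
#' A "helper" species instantiated in the cell model whose role is to join
#' ports of two or more submodels: at most one replaced-by link to the
#' producing submodel's port, plus one replaced-element link per consuming
#' submodel's port. Cell-only species (RNA polymerase II, ribosomes, the
#' hormone input) have no producer and only replaced-element links.
#'
#' @slot speciesId id of the species (identical in every linked copy).
#' @slot compartment cell-level compartment of the helper copy.
#' @slot initialAmount cell copy's amount; the flattened species inherits it.
#' @slot constant TRUE for fixed boundary inputs.
#' @slot producer character(0), or c(submodel id, port id) of the
#'   replaced-by link.
#' @slot consumers list of c(submodel id, port id) replaced-element links.
#' @export
setClass("ConnectingSpecies", representation(
  speciesId = "character", compartment = "character",
  initialAmount = "numeric", constant = "logical",
  producer = "character", consumers = "list"
), prototype(initialAmount = 0, constant = FALSE,
             producer = character(), consumers = list()))

setValidity("ConnectingSpecies", function(object) {
  msg <- character()
  if (!length(object@producer) %in% c(0, 2))
    msg <- c(msg, "producer must be empty or c(submodel, port)")
  ok <- vapply(object@consumers, function(x)
    is.character(x) && length(x) == 2, TRUE)
  if (!all(ok)) msg <- c(msg, "each consumer must be c(submodel, port)")
  if (object@initialAmount < 0) msg <- c(msg, "initialAmount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hierarchical circuit model
#'
#' The cell-level container: global compartments, submodels, connecting
#' species, and a map of named global constants (used e.g. for the induced
#' and basal transcription-initiation rates a gate input toggles between).
#'
#' @slot id model identifier.
#' @slot compartments list of [CompartmentDef-class].
#' @slot submodels list of [SubmodelSpec-class].
#' @slot connecting list of [ConnectingSpecies-class].
#' @slot parameters named numeric vector of global constants.
#' @export
setClass("CircuitModel", representation(
  id = "character", compartments = "list", submodels = "list",
  connecting = "list", parameters = "numeric"
), prototype(compartments = list(), submodels = list(), connecting = list(),
             parameters = structure(numeric(), names = character())))

setValidity("CircuitModel", function(object) {
  msg <- character()
  if (!all(vapply(object@compartments, is, TRUE, class2 = "CompartmentDef")))
    msg <- c(msg, "compartments must be CompartmentDef objects")
  if (!all(vapply(object@submodels, is, TRUE, class2 = "SubmodelSpec")))
    msg <- c(msg, "submodels must be SubmodelSpec objects")
  if (!all(vapply(object@connecting, is, TRUE, class2 = "ConnectingSpecies")))
    msg <- c(msg, "connecting must be ConnectingSpecies objects")
  if (anyDuplicated(vapply(object@submodels, function(s) s@id, "")))
    msg <- c(msg, "submodel ids must be unique")
  if (anyDuplicated(vapply(object@compartments, function(cc) cc@id, "")))
    msg <- c(msg, "compartment ids must be unique")
  if (length(object@parameters) && is.null(names(object@parameters)))
    msg <- c(msg, "parameters must be named")
  if (length(msg)) msg else TRUE
})

#' Flattened model
#'
#' The comp hierarchy resolved into a single species/reaction list with
#' exactly one instance of every connected species, ready for ODE assembly.
#' Unconnected submodel species keep their local id, prefixed with
#' `<submodelId>__` only on collision.
#'
#' @slot id model id.
#' @slot species list of [SpeciesDef-class] with globally unique ids.
#' @slot reactions list of [ReactionDef-class]; flattening never creates or
#'   destroys reactions.
#' @slot compartments list of [CompartmentDef-class].
#' @slot provenance data.frame mapping flat ids to (submodel, original id).
#' @export
setClass("FlatModel", representation(
  id = "character", species = "list", reactions = "list",
  compartments = "list", provenance = "data.frame"
))

#' Simulated trajectory
#'
#' @slot times strictly increasing time points (seconds).
#' @slot states matrix (times x species) of molecule counts; tiny negative
#'   integrator undershoot (>= -1e-9) is clipped to 0.
#' @slot speciesOrder column order of `states`.
#' @export
setClass("Trajectory", representation(
  times = "numeric", states = "matrix", speciesOrder = "character"))

setValidity("Trajectory", function(object) {
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  TRUE
})

#' NOT-gate steady-state report
#'
#' Steady-state reporter output at the two input settings and their ratio.
#' For a NOT gate the output at the *off* input is the gate's ON level, so
#' `ratio = outputAtInputOff / outputAtInputOn` is the ON/OFF ratio; a ratio
#' of at least 2 is conventionally taken as a functional Boolean gate.
#'
#' @slot outputSpecies id of the tagged reporter.
#' @slot offInputLevel,onInputLevel the two input settings.
#' @slot outputAtInputOff steady-state output with input absent (gate ON).
#' @slot outputAtInputOn steady-state output with input present (gate OFF).
#' @slot ratio ON/OFF ratio (Inf with a warning if the denominator is 0).
#' @export
setClass("GateReport", representation(
  outputSpecies = "character",
  offInputLevel = "numeric", onInputLevel = "numeric",
  outputAtInputOff = "numeric", outputAtInputOn = "numeric",
  ratio = "numeric"))
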