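## SBML Level 3 Version 1 (+ comp Version 1) serialization. A circuit is
## written as one XML file per submodel plus a main "cell.xml" whose
## external model definitions reference the submodel files by relative
## path; each connecting species carries its replaced-by / replaced-element
## links, referencing the remote ports by port id. The reader inverts the
## writer field-by-field and also accepts files that attach replacements to
## submodel elements rather than species.
##
## Law structure (form, activator, scale species, basal term), submodel
## kind and species roles are carried in a small tool-namespace annotation
## alongside the standard MathML, so round trips are exact; foreign files
## without the annotation fall back to structural inference.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_COMP_NS <- "http://www.sbml.org/sbml/level3/version1/comp/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
CIRCOMP_NS <- "http://r-circomp.org/annotations/v1"

sbmlNsMap <- c(s = SBML_CORE_NS, c = SBML_COMP_NS, m = MATHML_NS,
               a = CIRCOMP_NS)

num2str <- function(x) sprintf("%.17g", x)
bool2str <- function(x) if (isTRUE(x)) "true" else "false"

newSbmlRoot <- function(withComp = TRUE) {
  if (withComp)
    xml2::xml_new_root("sbml", xmlns = SBML_CORE_NS,
                       "xmlns:comp" = SBML_COMP_NS,
                       "xmlns:ci" = CIRCOMP_NS,
                       level = "3", version = "1", "comp:required" = "true")
  else
    xml2::xml_new_root("sbml", xmlns = SBML_CORE_NS,
                       "xmlns:ci" = CIRCOMP_NS,
                       level = "3", version = "1")
}

## ---- writers ---------------------------------------------------------------

addCompartments <- function(model, compartments) {
  if (!length(compartments)) return(invisible())
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in compartments)
    xml2::xml_add_child(loc, "compartment", id = cp@id,
                        size = num2str(cp@size), constant = "true")
}

addSpecies <- function(parent, sp) {
  node <- xml2::xml_add_child(parent, "species", id = sp@id,
                              compartment = sp@compartment,
                              initialAmount = num2str(sp@initialAmount),
                              hasOnlySubstanceUnits = "true",
                              boundaryCondition = bool2str(sp@constant),
                              constant = bool2str(sp@constant))
  ann <- xml2::xml_add_child(node, "annotation")
  xml2::xml_add_child(ann, "ci:speciesInfo", role = sp@role)
  node
}

mathCi <- function(parent, id) xml2::xml_add_child(parent, "ci", id)

## MathML for the two law forms, using local-parameter ids k / k_basal / K / K2
lawMath <- function(kl, reaction) {
  law <- reaction@law
  math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
  if (law@form == "massAction") {
    n <- sum(reaction@reactants)
    if (n == 0) {
      mathCi(math, "k")
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      mathCi(ap, "k")
      for (s in names(reaction@reactants))
        for (i in seq_len(reaction@reactants[[s]])) mathCi(ap, s)
    }
    return(invisible())
  }
  ## hillActivation: (k_basal + k*A/(K+A)) [* A2/(K2+A2)] [* scale]
  factors <- 1 + (!is.na(law@activator2)) + (!is.na(law@scaleSpecies))
  top <- if (factors > 1) {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    ap
  } else math
  hill <- xml2::xml_add_child(top, "apply")
  xml2::xml_add_child(hill, "plus")
  mathCi(hill, "k_basal")
  frac <- xml2::xml_add_child(hill, "apply")
  xml2::xml_add_child(frac, "divide")
  num <- xml2::xml_add_child(frac, "apply")
  xml2::xml_add_child(num, "times")
  mathCi(num, "k")
  mathCi(num, law@activator)
  den <- xml2::xml_add_child(frac, "apply")
  xml2::xml_add_child(den, "plus")
  mathCi(den, "K")
  mathCi(den, law@activator)
  if (!is.na(law@activator2)) {
    f2 <- xml2::xml_add_child(top, "apply")
    xml2::xml_add_child(f2, "divide")
    mathCi(f2, law@activator2)
    d2 <- xml2::xml_add_child(f2, "apply")
    xml2::xml_add_child(d2, "plus")
    mathCi(d2, "K2")
    mathCi(d2, law@activator2)
  }
  if (!is.na(law@scaleSpecies)) mathCi(top, law@scaleSpecies)
  invisible()
}

addReaction <- function(parent, r) {
  node <- xml2::xml_add_child(parent, "reaction", id = r@id,
                              reversible = "false", fast = "false")
  if (length(r@reactants)) {
    lor <- xml2::xml_add_child(node, "listOfReactants")
    for (s in names(r@reactants))
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = num2str(r@reactants[[s]]),
                          constant = "true")
  }
  if (length(r@products)) {
    lop <- xml2::xml_add_child(node, "listOfProducts")
    for (s in names(r@products))
      xml2::xml_add_child(lop, "speciesReference", species = s,
                          stoichiometry = num2str(r@products[[s]]),
                          constant = "true")
  }
  if (length(r@modifiers)) {
    lom <- xml2::xml_add_child(node, "listOfModifiers")
    for (s in r@modifiers)
      xml2::xml_add_child(lom, "modifierSpeciesReference", species = s)
  }
  kl <- xml2::xml_add_child(node, "kineticLaw")
  law <- r@law
  ann <- xml2::xml_add_child(kl, "annotation")
  annAttrs <- list("ci:law", form = law@form,
                   k = num2str(law@k), kBasal = num2str(law@kBasal),
                   reversiblePair = bool2str(r@reversible))
  if (!is.na(law@K)) annAttrs$K <- num2str(law@K)
  if (!is.na(law@activator)) annAttrs$activator <- law@activator
  if (!is.na(law@activator2)) annAttrs$activator2 <- law@activator2
  if (!is.na(law@K2)) annAttrs$K2 <- num2str(law@K2)
  if (!is.na(law@scaleSpecies)) annAttrs$scale <- law@scaleSpecies
  do.call(xml2::xml_add_child, c(list(ann), annAttrs))
  lawMath(kl, r)
  lolp <- xml2::xml_add_child(kl, "listOfLocalParameters")
  xml2::xml_add_child(lolp, "localParameter", id = "k", value = num2str(law@k))
  if (law@form == "hillActivation") {
    xml2::xml_add_child(lolp, "localParameter", id = "k_basal",
                        value = num2str(law@kBasal))
    xml2::xml_add_child(lolp, "localParameter", id = "K", value = num2str(law@K))
    if (!is.na(law@K2))
      xml2::xml_add_child(lolp, "localParameter", id = "K2",
                          value = num2str(law@K2))
  }
  node
}

writeSubmodelFile <- function(sm, compartments, path) {
  doc <- newSbmlRoot(withComp = TRUE)
  model <- xml2::xml_add_child(doc, "model", id = sm@id)
  ann <- xml2::xml_add_child(model, "annotation")
  xml2::xml_add_child(ann, "ci:moduleInfo", kind = sm@kind,
                      hostCompartment = sm@hostCompartment)
  used <- unique(c(sm@hostCompartment,
                   vapply(sm@species, function(s) s@compartment, "")))
  addCompartments(model, Filter(function(cp) cp@id %in% used, compartments))
  if (length(sm@species)) {
    los <- xml2::xml_add_child(model, "listOfSpecies")
    for (sp in sm@species) addSpecies(los, sp)
  }
  if (length(sm@reactions)) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    for (r in sm@reactions) addReaction(lor, r)
  }
  if (length(sm@ports)) {
    lop <- xml2::xml_add_child(model, "comp:listOfPorts")
    for (p in sm@ports)
      xml2::xml_add_child(lop, "comp:port", "comp:id" = p@id,
                          "comp:idRef" = p@speciesRef)
  }
  xml2::write_xml(doc, path)
}

#' Write a circuit as hierarchical SBML Level 3 + comp files
#'
#' Emits one XML file per submodel (named `<submodelId>.xml`) plus the main
#' `cell.xml`, whose external model definitions reference the submodel files
#' by relative path and whose species carry the replaced-by (producer) and
#' replaced-element (consumer) links of every connecting species. The write
#' aborts if the circuit fails [validateWiring()].
#'
#' @param circuit a [CircuitModel-class].
#' @param directory output directory (created if missing).
#' @return the file layout: list with `directory`, `mainFile`,
#'   `submodelFiles`.
#' @export
writeCircuit <- function(circuit, directory) {
  rep <- validateWiring(circuit)
  if (any(rep$severity == "error"))
    stop(sprintf("refusing to write '%s': %d wiring error(s), first: %s",
                 circuit@id, sum(rep$severity == "error"),
                 rep$message[rep$severity == "error"][1]))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))

  subFiles <- character()
  for (sm in circuit@submodels) {
    f <- paste0(sm@id, ".xml")
    writeSubmodelFile(sm, circuit@compartments, file.path(directory, f))
    subFiles <- c(subFiles, f)
  }

  doc <- newSbmlRoot(withComp = TRUE)
  if (length(circuit@submodels)) {
    loemd <- xml2::xml_add_child(doc, "comp:listOfExternalModelDefinitions")
    for (sm in circuit@submodels)
      xml2::xml_add_child(loemd, "comp:externalModelDefinition",
                          "comp:id" = paste0(sm@id, "_def"),
                          "comp:source" = paste0(sm@id, ".xml"),
                          "comp:modelRef" = sm@id)
  }
  model <- xml2::xml_add_child(doc, "model", id = circuit@id)
  addCompartments(model, circuit@compartments)
  if (length(circuit@connecting)) {
    los <- xml2::xml_add_child(model, "listOfSpecies")
    for (cs in circuit@connecting) {
      sp <- SpeciesDef(cs@speciesId, cs@compartment, cs@initialAmount,
                       cs@constant, role = "internal")
      node <- addSpecies(los, sp)
      if (length(cs@consumers)) {
        lore <- xml2::xml_add_child(node, "comp:listOfReplacedElements")
        for (cons in cs@consumers)
          xml2::xml_add_child(lore, "comp:replacedElement",
                              "comp:submodelRef" = cons[1],
                              "comp:portRef" = cons[2])
      }
      if (length(cs@producer) == 2)
        xml2::xml_add_child(node, "comp:replacedBy",
                            "comp:submodelRef" = cs@producer[1],
                            "comp:portRef" = cs@producer[2])
    }
  }
  if (length(circuit@parameters)) {
    lopar <- xml2::xml_add_child(model, "listOfParameters")
    for (nm in names(circuit@parameters))
      xml2::xml_add_child(lopar, "parameter", id = nm,
                          value = num2str(circuit@parameters[[nm]]),
                          constant = "true")
  }
  if (length(circuit@submodels)) {
    losm <- xml2::xml_add_child(model, "comp:listOfSubmodels")
    for (sm in circuit@submodels)
      xml2::xml_add_child(losm, "comp:submodel", "comp:id" = sm@id,
                          "comp:modelRef" = paste0(sm@id, "_def"))
  }
  xml2::write_xml(doc, file.path(directory, "cell.xml"))
  list(directory = directory, mainFile = "cell.xml",
       submodelFiles = subFiles)
}

#' Export a flattened model as plain SBML Level 3
#'
#' A single SBML document without any comp constructs, importable by
#' standard ODE simulators.
#'
#' @param flat a [FlatModel-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportFlatSbml <- function(flat, path) {
  doc <- newSbmlRoot(withComp = FALSE)
  model <- xml2::xml_add_child(doc, "model", id = flat@id)
  addCompartments(model, flat@compartments)
  if (length(flat@species)) {
    los <- xml2::xml_add_child(model, "listOfSpecies")
    for (sp in flat@species) addSpecies(los, sp)
  }
  if (length(flat@reactions)) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    for (r in flat@reactions) addReaction(lor, r)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- readers ---------------------------------------------------------------

xattr <- function(node, name) {
  if (inherits(node, "xml_missing")) return(NA_character_)
  v <- xml2::xml_attrs(node)
  ## attribute may appear with or without a namespace prefix
  hit <- which(names(v) == name | sub("^.*:", "", names(v)) == name)
  if (!length(hit)) NA_character_ else unname(v[hit[1]])
}

xfind <- function(node, xpath) xml2::xml_find_all(node, xpath, ns = sbmlNsMap)
xfind1 <- function(node, xpath) xml2::xml_find_first(node, xpath, ns = sbmlNsMap)

parseLaw <- function(rxNode, rxId) {
  ann <- xfind1(rxNode, "./s:kineticLaw/s:annotation/a:law")
  lp <- xfind(rxNode, "./s:kineticLaw/s:listOfLocalParameters/s:localParameter")
  lpv <- structure(as.numeric(vapply(lp, xattr, "", "value")),
                   names = vapply(lp, xattr, "", "id"))
  if (!inherits(ann, "xml_missing")) {
    form <- xattr(ann, "form")
    mk <- function(nm) {
      v <- xattr(ann, nm)
      if (is.na(v)) NA_real_ else as.numeric(v)
    }
    law <- new("KineticLaw", form = form, k = mk("k"), kBasal = mk("kBasal"),
               K = mk("K"), n = 1, activator = xattr(ann, "activator"),
               activator2 = xattr(ann, "activator2"), K2 = mk("K2"),
               scaleSpecies = xattr(ann, "scale"))
    rev <- identical(xattr(ann, "reversiblePair"), "true")
    return(list(law = law, reversible = rev))
  }
  ## tolerant fallback: a bare local parameter 'k' is read as mass action
  if ("k" %in% names(lpv) && !"K" %in% names(lpv))
    return(list(law = massActionLaw(unname(lpv["k"])), reversible = FALSE))
  stop(sprintf("reaction '%s': kinetic law outside the supported subset", rxId))
}

parseSpeciesNode <- function(node) {
  init <- xattr(node, "initialAmount")
  role <- xattr(xfind1(node, "./s:annotation/a:speciesInfo"), "role")
  SpeciesDef(
    id = xattr(node, "id"),
    compartment = xattr(node, "compartment"),
    initialAmount = if (is.na(init)) 0 else as.numeric(init),
    constant = identical(xattr(node, "constant"), "true"),
    role = if (is.na(role)) "internal" else role
  )
}

parseReactionNode <- function(node) {
  rxId <- xattr(node, "id")
  refs <- function(xpath) {
    nodes <- xfind(node, xpath)
    if (!length(nodes)) return(numeric())
    st <- vapply(nodes, function(x) {
      v <- xattr(x, "stoichiometry")
      if (is.na(v)) 1 else as.numeric(v)
    }, 0)
    structure(st, names = vapply(nodes, xattr, "", "species"))
  }
  ## equal species references are collapsed (A + A is stoichiometry 2)
  collapse <- function(v) {
    if (!length(v)) return(v)
    tapplyv <- tapply(v, names(v), sum)
    structure(as.numeric(tapplyv), names = names(tapplyv))
  }
  lw <- parseLaw(node, rxId)
  ReactionDef(
    rxId, lw$law,
    reactants = collapse(refs("./s:listOfReactants/s:speciesReference")),
    products = collapse(refs("./s:listOfProducts/s:speciesReference")),
    modifiers = vapply(xfind(node, "./s:listOfModifiers/s:modifierSpeciesReference"),
                       xattr, "", "species"),
    reversible = lw$reversible
  )
}

reportUnsupported <- function(modelNode, where) {
  bad <- c("listOfRules", "listOfEvents", "listOfFunctionDefinitions",
           "listOfConstraints", "listOfInitialAssignments")
  for (b in bad) {
    if (!inherits(xfind1(modelNode, paste0("./s:", b)), "xml_missing"))
      warning(sprintf("%s: unsupported SBML construct <%s> ignored", where, b))
  }
}

parseCompartmentNodes <- function(modelNode) {
  lapply(xfind(modelNode, "./s:listOfCompartments/s:compartment"), function(x) {
    sz <- xattr(x, "size")
    CompartmentDef(xattr(x, "id"), if (is.na(sz)) 1 else as.numeric(sz))
  })
}

parseSubmodelFile <- function(path) {
  doc <- xml2::read_xml(path)
  modelNode <- xfind1(doc, "./s:model")
  if (inherits(modelNode, "xml_missing"))
    stop(sprintf("'%s': no <model> element", path))
  id <- xattr(modelNode, "id")
  reportUnsupported(modelNode, path)
  species <- lapply(xfind(modelNode, "./s:listOfSpecies/s:species"),
                    parseSpeciesNode)
  reactions <- lapply(xfind(modelNode, "./s:listOfReactions/s:reaction"),
                      parseReactionNode)
  ports <- lapply(xfind(modelNode, "./c:listOfPorts/c:port"), function(x) {
    pid <- xattr(x, "id"); ref <- xattr(x, "idRef")
    if (!identical(pid, paste0("port_", ref)))
      stop(sprintf("'%s': port id '%s' does not match species '%s'",
                   path, pid, ref))
    PortDef(ref)
  })
  info <- xfind1(modelNode, "./s:annotation/a:moduleInfo")
  if (!inherits(info, "xml_missing")) {
    kind <- xattr(info, "kind")
    host <- xattr(info, "hostCompartment")
  } else {
    kind <- if (startsWith(id, "TU")) "TU"
    else if (grepl("degradation", id)) "degradation_pool" else "mrna_pool"
    host <- if (kind == "TU") "nucleus" else "cytoplasm"
    ## infer roles from structure when the annotation is absent: a species
    ## is an output if some reaction produces it with positive net
    ## stoichiometry (a translation template appearing on both sides is not)
    produced <- unique(unlist(lapply(reactions, function(r) {
      net <- r@products
      for (nm in names(r@reactants))
        net[nm] <- (if (nm %in% names(net)) net[[nm]] else 0) - r@reactants[[nm]]
      names(net)[net > 0]
    })))
    ported <- vapply(ports, function(p) p@speciesRef, "")
    species <- lapply(species, function(sp) {
      if (sp@id %in% ported)
        sp@role <- if (sp@id %in% produced) "output" else "input"
      sp
    })
  }
  list(spec = SubmodelSpec(id, kind, host, species = species,
                           reactions = reactions, ports = ports),
       compartments = parseCompartmentNodes(modelNode))
}

#' Read a hierarchical SBML Level 3 + comp circuit
#'
#' Parses the main cell file, resolves every external model definition
#' relative to it, and reconstructs the [CircuitModel-class] so that
#' writing it again is structurally identical. Replacement links are
#' accepted both on the cell species (where this package writes them) and
#' on submodel elements. Unsupported SBML constructs are reported as
#' warnings, never silently dropped.
#'
#' @param mainFile path to `cell.xml`.
#' @return a [CircuitModel-class].
#' @export
readCircuit <- function(mainFile) {
  if (!file.exists(mainFile)) stop(sprintf("file '%s' does not exist", mainFile))
  doc <- xml2::read_xml(mainFile)
  dir <- dirname(mainFile)

  ext <- list()
  for (x in xfind(doc, "./c:listOfExternalModelDefinitions/c:externalModelDefinition"))
    ext[[xattr(x, "id")]] <- list(source = xattr(x, "source"),
                                  modelRef = xattr(x, "modelRef"))

  modelNode <- xfind1(doc, "./s:model")
  if (inherits(modelNode, "xml_missing"))
    stop(sprintf("'%s': no <model> element", mainFile))
  reportUnsupported(modelNode, mainFile)
  circuitId <- xattr(modelNode, "id")
  compartments <- parseCompartmentNodes(modelNode)

  pars <- xfind(modelNode, "./s:listOfParameters/s:parameter")
  parameters <- structure(as.numeric(vapply(pars, xattr, "", "value")),
                          names = vapply(pars, xattr, "", "id"))

  submodels <- list()
  for (x in xfind(modelNode, "./c:listOfSubmodels/c:submodel")) {
    smId <- xattr(x, "id")
    ref <- xattr(x, "modelRef")
    def <- ext[[ref]]
    if (is.null(def) && ref %in% names(ext) == FALSE) {
      ## tolerate modelRef pointing straight at an external definition id
      hit <- Filter(function(d) identical(d$modelRef, ref), ext)
      if (length(hit)) def <- hit[[1]]
    }
    if (is.null(def))
      stop(sprintf("submodel '%s': unresolvable external model definition '%s'",
                   smId, ref))
    src <- file.path(dir, def$source)
    if (!file.exists(src))
      stop(sprintf("submodel '%s': referenced file '%s' is missing", smId, src))
    parsed <- parseSubmodelFile(src)
    spec <- parsed$spec
    spec@id <- smId
    submodels[[length(submodels) + 1L]] <- spec
    for (cp in parsed$compartments)
      if (!cp@id %in% vapply(compartments, function(z) z@id, ""))
        compartments <- c(compartments, list(cp))
  }

  connectingList <- list()
  for (node in xfind(modelNode, "./s:listOfSpecies/s:species")) {
    sp <- parseSpeciesNode(node)
    rb <- xfind1(node, "./c:replacedBy")
    producer <- if (inherits(rb, "xml_missing")) character() else
      c(xattr(rb, "submodelRef"), xattr(rb, "portRef"))
    consumers <- lapply(
      xfind(node, "./c:listOfReplacedElements/c:replacedElement"),
      function(x) c(xattr(x, "submodelRef"), xattr(x, "portRef")))
    connectingList[[length(connectingList) + 1L]] <-
      new("ConnectingSpecies", speciesId = sp@id, compartment = sp@compartment,
          initialAmount = sp@initialAmount, constant = sp@constant,
          producer = producer, consumers = consumers)
  }

  CircuitModel(circuitId, compartments = compartments, submodels = submodels,
               connecting = connectingList, parameters = parameters)
}

#' Read a plain (flat) SBML Level 3 file
#'
#' Inverse of [exportFlatSbml()]: parses a single non-hierarchical SBML
#' document into a [FlatModel-class] for simulation.
#'
#' @param path path to the SBML file.
#' @return a [FlatModel-class].
#' @export
readFlatSbml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  doc <- xml2::read_xml(path)
  modelNode <- xfind1(doc, "./s:model")
  if (inherits(modelNode, "xml_missing"))
    stop(sprintf("'%s': no <model> element", path))
  reportUnsupported(modelNode, path)
  species <- lapply(xfind(modelNode, "./s:listOfSpecies/s:species"),
                    parseSpeciesNode)
  reactions <- lapply(xfind(modelNode, "./s:listOfReactions/s:reaction"),
                      parseReactionNode)
  new("FlatModel", id = xattr(modelNode, "id"), species = species,
      reactions = reactions,
      compartments = parseCompartmentNodes(modelNode),
      provenance = data.frame(flatId = character(), submodel = character(),
                              originalId = character(), kind = character(),
                              stringsAsFactors = FALSE))
}
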