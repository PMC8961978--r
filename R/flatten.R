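## Resolving the one-level comp hierarchy into a single reaction network.
## Every connecting species (the cell copy plus its submodel copies linked
## through ports) collapses to one flat species carrying the cell copy's id,
## compartment and initial amount; unconnected submodel species keep their
## local id, prefixed with "<submodelId>__" only on collision. Flattening
## never creates or destroys reactions.

#' Flatten a hierarchical circuit
#'
#' @param circuit a [CircuitModel-class]; must pass [validateWiring()] with
#'   no errors (the flattener aborts otherwise).
#' @return a [FlatModel-class].
#' @export
flattenCircuit <- function(circuit) {
  rep <- validateWiring(circuit)
  if (any(rep$severity == "error"))
    stop(sprintf("cannot flatten '%s': %d wiring error(s), first: %s",
                 circuit@id, sum(rep$severity == "error"),
                 rep$message[rep$severity == "error"][1]))

  subIds <- vapply(circuit@submodels, function(s) s@id, "")
  connIds <- vapply(circuit@connecting, function(s) s@speciesId, "")

  ## (submodel, localId) -> flat id for every connected copy
  renameKey <- character()
  for (cs in circuit@connecting) {
    links <- cs@consumers
    if (length(cs@producer) == 2) links <- c(list(cs@producer), links)
    for (lk in links) {
      sm <- circuit@submodels[[match(lk[1], subIds)]]
      p <- sm@ports[[match(lk[2], portIds(sm))]]
      renameKey[paste0(lk[1], "\r", p@speciesRef)] <- cs@speciesId
    }
  }

  ## submodel copies of one connecting species must agree on initial amount
  for (cs in circuit@connecting) {
    links <- cs@consumers
    if (length(cs@producer) == 2) links <- c(list(cs@producer), links)
    inits <- vapply(links, function(lk) {
      sm <- circuit@submodels[[match(lk[1], subIds)]]
      sm@species[[match(cs@speciesId, speciesIds(sm))]]@initialAmount
    }, 0)
    if (length(inits) > 1 && diff(range(inits)) > 0)
      warning(sprintf("submodel copies of connecting species '%s' disagree on initial amount; using the cell copy's",
                      cs@speciesId))
  }

  ## unconnected species: collision-aware flat ids
  unconn <- list()  # list of c(submodel, localId)
  for (sm in circuit@submodels) {
    for (sp in sm@species) {
      if (is.na(renameKey[paste0(sm@id, "\r", sp@id)]))
        unconn[[length(unconn) + 1L]] <- c(sm@id, sp@id)
    }
  }
  localIds <- vapply(unconn, `[`, "", 2)
  needPrefix <- localIds %in% connIds | localIds %in% localIds[duplicated(localIds)]
  flatUnconn <- ifelse(needPrefix,
                       paste0(vapply(unconn, `[`, "", 1), "__", localIds),
                       localIds)
  for (i in seq_along(unconn))
    renameKey[paste0(unconn[[i]][1], "\r", unconn[[i]][2])] <- flatUnconn[i]
  stopifnot(!anyDuplicated(c(connIds, flatUnconn)))

  ## species list: connecting species first (cell copy wins), then the rest
  species <- lapply(circuit@connecting, function(cs)
    SpeciesDef(cs@speciesId, cs@compartment, cs@initialAmount, cs@constant,
               role = "internal"))
  prov <- data.frame(flatId = connIds,
                     submodel = rep("cell", length(connIds)),
                     originalId = connIds,
                     kind = rep("species", length(connIds)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(unconn)) {
    smId <- unconn[[i]][1]; localId <- unconn[[i]][2]
    sm <- circuit@submodels[[match(smId, subIds)]]
    sp <- sm@species[[match(localId, speciesIds(sm))]]
    sp@id <- flatUnconn[i]
    species <- c(species, list(sp))
    prov <- rbind(prov, data.frame(flatId = flatUnconn[i], submodel = smId,
                                   originalId = localId, kind = "species",
                                   stringsAsFactors = FALSE))
  }

  ## reactions: rewrite species references, prefix ids only on collision
  allRxIds <- unlist(lapply(circuit@submodels, reactionIds))
  dupRx <- allRxIds[duplicated(allRxIds)]
  reactions <- list()
  for (sm in circuit@submodels) {
    for (r in sm@reactions) {
      ren <- function(ids) {
        if (!length(ids)) return(ids)
        vapply(ids, function(id) renameKey[[paste0(sm@id, "\r", id)]], "")
      }
      if (length(r@reactants)) names(r@reactants) <- ren(names(r@reactants))
      if (length(r@products)) names(r@products) <- ren(names(r@products))
      r@modifiers <- unname(ren(r@modifiers))
      law <- r@law
      if (!is.na(law@activator) && law@form == "hillActivation")
        law@activator <- unname(ren(law@activator))
      if (!is.na(law@activator2)) law@activator2 <- unname(ren(law@activator2))
      if (!is.na(law@scaleSpecies)) law@scaleSpecies <- unname(ren(law@scaleSpecies))
      r@law <- law
      orig <- r@id
      if (orig %in% dupRx) r@id <- paste0(sm@id, "__", orig)
      reactions <- c(reactions, list(r))
      prov <- rbind(prov, data.frame(flatId = r@id, submodel = sm@id,
                                     originalId = orig, kind = "reaction",
                                     stringsAsFactors = FALSE))
    }
  }
  stopifnot(length(reactions) ==
              sum(vapply(circuit@submodels, function(s) length(s@reactions), 0L)))

  new("FlatModel", id = circuit@id, species = species, reactions = reactions,
      compartments = circuit@compartments, provenance = prov)
}

#' Count model entities under both conventions
#'
#' Entity counts of a hierarchical circuit: number of modules, unique
#' species after flattening, total species objects summed over the submodel
#' files plus the cell file, reactions, and the cell-level connecting
#' species (total, split into producer-linked helpers vs producer-less
#' cell-only species, and by compartment). Both species-counting conventions
#' are exposed because published per-model totals may follow either.
#'
#' @param model a [CircuitModel-class] or [FlatModel-class].
#' @return named list of counts.
#' @export
countEntities <- function(model) {
  if (is(model, "FlatModel")) {
    return(list(nModules = 0L, nSpeciesUnique = length(model@species),
                nSpeciesTotal = length(model@species),
                nReactions = length(model@reactions),
                nConnecting = 0L, nConnectingProducer = 0L,
                nConnectingCellOnly = 0L,
                nConnectingByCompartment = integer()))
  }
  stopifnot(is(model, "CircuitModel"))
  flat <- flattenCircuit(model)
  perSub <- vapply(model@submodels, function(s) length(s@species), 0L)
  hasProd <- vapply(model@connecting, function(s) length(s@producer) == 2, TRUE)
  comp <- vapply(model@connecting, function(s) s@compartment, "")
  byComp <- if (length(comp)) {
    tab <- table(comp)
    structure(as.integer(tab), names = names(tab))
  } else integer()
  list(
    nModules = length(model@submodels),
    nSpeciesUnique = length(flat@species),
    nSpeciesTotal = sum(perSub) + length(model@connecting),
    nReactions = length(flat@reactions),
    nConnecting = length(model@connecting),
    nConnectingProducer = sum(hasProd),
    nConnectingCellOnly = sum(!hasProd),
    nConnectingByCompartment = byComp
  )
}
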