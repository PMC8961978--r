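## Constructors, accessors and structural validation for the circuit
## intermediate representation.

#' @rdname CompartmentDef-class
#' @param id compartment id.
#' @param size dimensionless volume (> 0), default 1.
#' @export
CompartmentDef <- function(id, size = 1) {
  new("CompartmentDef", id = id, size = size)
}

#' @rdname SpeciesDef-class
#' @param id species id.
#' @param compartment hosting compartment id.
#' @param initialAmount molecule count (>= 0).
#' @param constant fixed boundary species?
#' @param role `"input"`, `"output"` or `"internal"`.
#' @export
SpeciesDef <- function(id, compartment, initialAmount = 0, constant = FALSE,
                       role = "internal") {
  new("SpeciesDef", id = id, compartment = compartment,
      initialAmount = initialAmount, constant = constant, role = role)
}

#' @rdname PortDef-class
#' @param speciesRef id of the species the port exposes; the port id is
#'   always `port_<speciesRef>`.
#' @export
PortDef <- function(speciesRef) {
  new("PortDef", id = paste0("port_", speciesRef), speciesRef = speciesRef)
}

#' @rdname ReactionDef-class
#' @param id reaction id.
#' @param reactants,products named numeric vectors (species -> stoichiometry).
#' @param modifiers species ids used by the rate law only.
#' @param law a [KineticLaw-class].
#' @param reversible metadata: half of a reversible pair?
#' @export
ReactionDef <- function(id, law, reactants = numeric(), products = numeric(),
                        modifiers = character(), reversible = FALSE) {
  new("ReactionDef", id = id, reactants = reactants, products = products,
      modifiers = modifiers, law = law, reversible = reversible)
}

#' @rdname SubmodelSpec-class
#' @param id,kind,hostCompartment,species,reactions,ports see slots.
#' @export
SubmodelSpec <- function(id, kind, hostCompartment, species = list(),
                         reactions = list(), ports = list()) {
  new("SubmodelSpec", id = id, kind = kind, hostCompartment = hostCompartment,
      species = species, reactions = reactions, ports = ports)
}

#' @rdname CircuitModel-class
#' @param id,compartments,submodels,connecting,parameters see slots.
#' @export
CircuitModel <- function(id, compartments = list(), submodels = list(),
                         connecting = list(),
                         parameters = structure(numeric(), names = character())) {
  if (length(parameters)) parameters <- unlist(parameters)
  new("CircuitModel", id = id, compartments = compartments,
      submodels = submodels, connecting = connecting, parameters = parameters)
}

## ---- accessors -------------------------------------------------------------

#' Accessors for circuit containers
#'
#' Small generics over the S4 containers: submodels and connecting species of
#' a circuit, species/reaction/port ids of a submodel or flat model.
#'
#' @param x a [CircuitModel-class], [SubmodelSpec-class] or
#'   [FlatModel-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("submodels", function(x) standardGeneric("submodels"))
#' @rdname accessors
#' @export
setMethod("submodels", "CircuitModel", function(x) {
  structure(x@submodels, names = vapply(x@submodels, function(s) s@id, ""))
})

#' @rdname accessors
#' @export
setGeneric("connecting", function(x) standardGeneric("connecting"))
#' @rdname accessors
#' @export
setMethod("connecting", "CircuitModel", function(x) {
  structure(x@connecting,
            names = vapply(x@connecting, function(s) s@speciesId, ""))
})

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @rdname accessors
#' @export
setMethod("speciesIds", "SubmodelSpec", function(x)
  vapply(x@species, function(s) s@id, ""))
#' @rdname accessors
#' @export
setMethod("speciesIds", "FlatModel", function(x)
  vapply(x@species, function(s) s@id, ""))

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setMethod("reactionIds", "SubmodelSpec", function(x)
  vapply(x@reactions, function(r) r@id, ""))
#' @rdname accessors
#' @export
setMethod("reactionIds", "FlatModel", function(x)
  vapply(x@reactions, function(r) r@id, ""))

#' @rdname accessors
#' @export
setGeneric("portIds", function(x) standardGeneric("portIds"))
#' @rdname accessors
#' @export
setMethod("portIds", "SubmodelSpec", function(x)
  vapply(x@ports, function(p) p@id, ""))

getSubmodel <- function(circuit, id) {
  ids <- vapply(circuit@submodels, function(s) s@id, "")
  i <- match(id, ids)
  if (is.na(i)) stop(sprintf("no submodel '%s' in circuit '%s'", id, circuit@id))
  circuit@submodels[[i]]
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "SubmodelSpec", function(object) {
  cat(sprintf("SubmodelSpec '%s' (%s, in %s)\n", object@id, object@kind,
              object@hostCompartment))
  cat(sprintf("  %d species: %s\n", length(object@species),
              paste(speciesIds(object), collapse = ", ")))
  cat(sprintf("  %d reactions, %d ports\n",
              length(object@reactions), length(object@ports)))
})

setMethod("show", "CircuitModel", function(object) {
  cat(sprintf("CircuitModel '%s'\n", object@id))
  cat(sprintf("  compartments: %s\n",
              paste(vapply(object@compartments, function(x) x@id, ""),
                    collapse = ", ")))
  kinds <- table(vapply(object@submodels, function(s) s@kind, ""))
  cat(sprintf("  %d submodels (%s)\n", length(object@submodels),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  np <- sum(vapply(object@connecting, function(s) length(s@producer) == 2, TRUE))
  cat(sprintf("  %d connecting species (%d producer-linked, %d cell-only)\n",
              length(object@connecting), np, length(object@connecting) - np))
})

setMethod("show", "FlatModel", function(object) {
  cat(sprintf("FlatModel '%s': %d species, %d reactions, %d compartments\n",
              object@id, length(object@species), length(object@reactions),
              length(object@compartments)))
})

setMethod("show", "GateReport", function(object) {
  cat(sprintf("GateReport for '%s'\n", object@outputSpecies))
  cat(sprintf("  input off (%g): output %.6g   [gate ON]\n",
              object@offInputLevel, object@outputAtInputOff))
  cat(sprintf("  input on  (%g): output %.6g   [gate OFF]\n",
              object@onInputLevel, object@outputAtInputOn))
  cat(sprintf("  ON/OFF ratio: %.4f\n", object@ratio))
})

## ---- wiring validation -----------------------------------------------------

issue <- function(severity, code, message) {
  data.frame(severity = severity, code = code, message = message,
             stringsAsFactors = FALSE)
}

#' Validate the wiring of a hierarchical circuit
#'
#' Checks every structural invariant of the composition scheme: unique ids,
#' resolvable compartment and species references, one port per species, every
#' ported species connected at most once, at most one producer (replaced-by)
#' link per connecting species, and matching species ids across linked ports.
#' Problems are reported, never raised: the return value is a data.frame with
#' one row per violation (`severity`, stable `code`, `message`); a circuit is
#' well-formed iff the report has zero rows. The check is pure: calling it
#' twice returns identical reports.
#'
#' @param circuit a [CircuitModel-class].
#' @return data.frame with columns `severity`, `code`, `message`.
#' @export
validateWiring <- function(circuit) {
  rep <- list()
  add <- function(...) rep[[length(rep) + 1L]] <<- issue(...)
  compIds <- vapply(circuit@compartments, function(x) x@id, "")
  subIds <- vapply(circuit@submodels, function(s) s@id, "")
  if (anyDuplicated(subIds))
    add("error", "DUPLICATE_SUBMODEL",
        sprintf("duplicate submodel ids: %s",
                paste(unique(subIds[duplicated(subIds)]), collapse = ", ")))

  for (sm in circuit@submodels) {
    sid <- speciesIds(sm)
    if (!sm@hostCompartment %in% compIds)
      add("error", "UNKNOWN_COMPARTMENT",
          sprintf("submodel '%s' hosted in undeclared compartment '%s'",
                  sm@id, sm@hostCompartment))
    for (sp in sm@species) {
      if (!sp@compartment %in% compIds)
        add("error", "UNKNOWN_COMPARTMENT",
            sprintf("species '%s' in submodel '%s' placed in undeclared compartment '%s'",
                    sp@id, sm@id, sp@compartment))
      if (sp@compartment != sm@hostCompartment &&
          !sp@role %in% c("output", "input"))
        add("warning", "COMPARTMENT_MISMATCH",
            sprintf("internal species '%s' of '%s' lies outside the host compartment",
                    sp@id, sm@id))
    }
    for (p in sm@ports) {
      if (!p@speciesRef %in% sid)
        add("error", "DANGLING_PORT",
            sprintf("port '%s' of submodel '%s' references undeclared species '%s'",
                    p@id, sm@id, p@speciesRef))
    }
    ported <- vapply(sm@ports, function(p) p@speciesRef, "")
    for (sp in sm@species) {
      if (sp@role != "internal" && !sp@id %in% ported)
        add("error", "MISSING_PORT",
            sprintf("%s-role species '%s' of submodel '%s' has no port",
                    sp@role, sp@id, sm@id))
    }
    for (r in sm@reactions) {
      refs <- unique(c(names(r@reactants), names(r@products), r@modifiers,
                       lawSpecies(r@law)))
      bad <- setdiff(refs, sid)
      if (length(bad))
        add("error", "UNDECLARED_SPECIES",
            sprintf("reaction '%s' of submodel '%s' references undeclared species: %s",
                    r@id, sm@id, paste(bad, collapse = ", ")))
    }
  }

  seen <- character()
  portUse <- character()  # "<submodel>:<port>" already claimed by a connection
  for (cs in circuit@connecting) {
    if (cs@speciesId %in% seen)
      add("error", "DUPLICATE_CONNECTION",
          sprintf("species '%s' connected more than once", cs@speciesId))
    seen <- c(seen, cs@speciesId)
    if (!cs@compartment %in% compIds)
      add("error", "UNKNOWN_COMPARTMENT",
          sprintf("connecting species '%s' placed in undeclared compartment '%s'",
                  cs@speciesId, cs@compartment))
    links <- cs@consumers
    if (length(cs@producer) == 2) links <- c(list(cs@producer), links)
    nprod <- as.integer(length(cs@producer) == 2)
    ## a producer link duplicated into the consumer list is a second producer
    for (cons in cs@consumers) {
      if (length(cs@producer) == 2 && identical(cons, cs@producer))
        add("error", "DUPLICATE_PRODUCER",
            sprintf("species '%s': producer port also listed as consumer",
                    cs@speciesId))
    }
    for (lk in links) {
      smId <- lk[1]; portId <- lk[2]
      if (!smId %in% subIds) {
        add("error", "UNKNOWN_SUBMODEL",
            sprintf("connecting species '%s' references unknown submodel '%s'",
                    cs@speciesId, smId))
        next
      }
      sm <- circuit@submodels[[match(smId, subIds)]]
      pids <- portIds(sm)
      if (!portId %in% pids) {
        add("error", "DANGLING_PORT",
            sprintf("connecting species '%s' references missing port '%s' in submodel '%s'",
                    cs@speciesId, portId, smId))
        next
      }
      p <- sm@ports[[match(portId, pids)]]
      if (p@speciesRef != cs@speciesId)
        add("error", "SPECIES_MISMATCH",
            sprintf("port '%s' of '%s' exposes '%s', not connecting species '%s'",
                    portId, smId, p@speciesRef, cs@speciesId))
      key <- paste0(smId, ":", portId)
      if (key %in% portUse)
        add("error", "PORT_REUSED",
            sprintf("port '%s' of submodel '%s' referenced by more than one connection",
                    portId, smId))
      portUse <- c(portUse, key)
    }
    if (length(cs@producer) == 0 && length(cs@consumers) == 0)
      add("warning", "UNLINKED_SPECIES",
          sprintf("connecting species '%s' has no links", cs@speciesId))
  }
  if (length(rep)) do.call(rbind, rep) else
    issue(character(), character(), character())[0, ]
}

## species ids a law depends on beyond reactants
lawSpecies <- function(law) {
  out <- character()
  if (law@form == "hillActivation") {
    out <- c(out, law@activator)
    if (!is.na(law@activator2)) out <- c(out, law@activator2)
    if (!is.na(law@scaleSpecies)) out <- c(out, law@scaleSpecies)
  }
  out
}

## ---- structural equality ---------------------------------------------------

#' Structural equality of two circuits
#'
#' Field-by-field comparison ignoring list ordering (elements are matched by
#' id). Used by the serialization round-trip checks.
#'
#' @param a,b [CircuitModel-class] objects.
#' @return TRUE or FALSE.
#' @export
circuitIdentical <- function(a, b) {
  isTRUE(all.equal(normalizeCircuit(a), normalizeCircuit(b),
                   tolerance = 1e-12))
}

normalizeCircuit <- function(x) {
  ordBy <- function(lst, key) lst[order(vapply(lst, key, ""))]
  sm <- lapply(ordBy(x@submodels, function(s) s@id), function(s) {
    list(id = s@id, kind = s@kind, host = s@hostCompartment,
         species = lapply(ordBy(s@species, function(z) z@id), speciesAsList),
         reactions = lapply(ordBy(s@reactions, function(z) z@id), reactionAsList),
         ports = vapply(ordBy(s@ports, function(z) z@id), function(p) p@speciesRef, ""))
  })
  cs <- lapply(ordBy(x@connecting, function(s) s@speciesId), function(s) {
    cons <- s@consumers[order(vapply(s@consumers, paste, "", collapse = ":"))]
    list(id = s@speciesId, comp = s@compartment, init = s@initialAmount,
         const = s@constant, producer = s@producer, consumers = cons)
  })
  comp <- lapply(ordBy(x@compartments, function(z) z@id),
                 function(z) list(id = z@id, size = z@size))
  pars <- x@parameters[order(names(x@parameters))]
  list(id = x@id, compartments = comp, submodels = sm, connecting = cs,
       parameters = pars)
}

speciesAsList <- function(s)
  list(id = s@id, comp = s@compartment, init = s@initialAmount,
       const = s@constant, role = s@role)

reactionAsList <- function(r) {
  sortByName <- function(v) if (length(v)) v[order(names(v))] else numeric()
  list(id = r@id, reactants = sortByName(r@reactants),
       products = sortByName(r@products),
       modifiers = sort(r@modifiers), reversible = r@reversible,
       law = list(form = r@law@form, k = r@law@k, kBasal = r@law@kBasal,
                  K = r@law@K, activator = r@law@activator,
                  activator2 = r@law@activator2, K2 = r@law@K2,
                  scale = r@law@scaleSpecies))
}
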