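test_that("each connected species occurs exactly once after flattening", {
  flat <- flattenCircuit(buildGalactoseNotGate())
  ids <- speciesIds(flat)
  expect_identical(sum(ids == "mRNA_GFP"), 1L)
  expect_false(anyDuplicated(ids) > 0)
  mrna <- flat@species[[match("mRNA_GFP", ids)]]
  expect_identical(mrna@compartment, "cytoplasm")
})

test_that("flattening never creates or destroys reactions", {
  for (circuit in list(buildGalactoseNotGate(), buildEstradiolNotGate(),
                       reducedDegradationCircuit())) {
    flat <- flattenCircuit(circuit)
    expect_identical(length(flat@reactions),
                     sum(vapply(circuit@submodels,
                                function(s) length(s@reactions), 0L)))
  }
})

test_that("species conservation: unique = declared minus merge events", {
  for (circuit in list(buildGalactoseNotGate(), buildEstradiolNotGate())) {
    flat <- flattenCircuit(circuit)
    declared <- sum(vapply(circuit@submodels,
                           function(s) length(s@species), 0L))
    copies <- vapply(circuit@connecting, function(cs)
      length(cs@consumers) + as.integer(length(cs@producer) == 2), 0L)
    expect_identical(length(flat@species), declared - sum(copies - 1L))
  }
})

test_that("a single unconnected submodel flattens to itself", {
  pool <- makeMrnaPool("p", "mRNA_A", "A", 0.05, 5e-4, 1e-4)
  cc <- CircuitModel("c", compartments = list(CompartmentDef("cytoplasm")),
                     submodels = list(pool))
  flat <- flattenCircuit(cc)
  expect_setequal(speciesIds(flat), speciesIds(pool))
  expect_setequal(reactionIds(flat), reactionIds(pool))
})

test_that("two submodels sharing a helper species merge to the hand-built union", {
  tu <- makeTranscriptionUnit("TU_A", PromoterSpec(kMax = 0.1), "mRNA_A")
  pool <- makeMrnaPool("pool_A", "mRNA_A", "A", 0.05, 5e-4, 1e-4)
  cc <- CircuitModel("c", compartments = list(CompartmentDef("nucleus"),
                                              CompartmentDef("cytoplasm")),
                     submodels = list(tu, pool))
  cc <- connectSpecies(cc, "mRNA_A", "cytoplasm", producer = "TU_A",
                       consumers = "pool_A")
  flat <- flattenCircuit(cc)
  ## hand-derived expectation: one shared mRNA plus the pool's protein,
  ## and the union of the two reaction sets rewritten onto the merged id
  expect_setequal(speciesIds(flat), c("mRNA_A", "A"))
  expect_setequal(reactionIds(flat),
                  c("transcription_mRNA_A", "translation_A",
                    "decay_mRNA_A", "decay_A"))
  tl <- flat@reactions[[match("translation_A", reactionIds(flat))]]
  expect_identical(tl@law@scaleSpecies, "mRNA_A")
})

test_that("flattening an already-flat model is a no-op in effect", {
  flat <- flattenCircuit(buildGalactoseNotGate())
  wrapped <- CircuitModel(
    "rewrapped", compartments = flat@compartments,
    submodels = list(SubmodelSpec("all", "mrna_pool", "cytoplasm",
                                  species = flat@species,
                                  reactions = flat@reactions)))
  flat2 <- flattenCircuit(wrapped)
  expect_setequal(speciesIds(flat2), speciesIds(flat))
  expect_setequal(reactionIds(flat2), reactionIds(flat))
})

test_that("local ids are prefixed only on collision", {
  mk <- function(id) SubmodelSpec(
    id, "mrna_pool", "cytoplasm",
    species = list(SpeciesDef("X", "cytoplasm")),
    reactions = list(ReactionDef("decay_X", massActionLaw(0.1),
                                 reactants = c(X = 1))))
  cc <- CircuitModel("c", compartments = list(CompartmentDef("cytoplasm")),
                     submodels = list(mk("m1"), mk("m2")))
  flat <- flattenCircuit(cc)
  expect_setequal(speciesIds(flat), c("m1__X", "m2__X"))
  expect_setequal(reactionIds(flat), c("m1__decay_X", "m2__decay_X"))
})

test_that("disagreeing submodel copies of a connecting species warn", {
  g <- buildGalactoseNotGate()
  i <- match("TU_GFP", vapply(g@submodels, function(s) s@id, ""))
  j <- match("mRNA_GFP", speciesIds(g@submodels[[i]]))
  g@submodels[[i]]@species[[j]]@initialAmount <- 7
  expect_warning(flattenCircuit(g), "disagree")
})

test_that("flattening aborts on wiring errors", {
  g <- buildGalactoseNotGate()
  g@connecting[[1]]@producer <- c("TU_GFP", "port_missing")
  expect_error(flattenCircuit(g), "wiring error")
})

test_that("entity counts report both conventions and the connection split", {
  ce <- countEntities(buildGalactoseNotGate())
  expect_identical(ce$nModules, 7L)
  expect_identical(ce$nSpeciesUnique, 10L)
  expect_identical(ce$nSpeciesTotal, 28L)
  expect_identical(ce$nReactions, 18L)
  expect_identical(ce$nConnectingProducer, 6L)
  expect_identical(ce$nConnectingCellOnly, 2L)

  ce2 <- countEntities(buildEstradiolNotGate())
  expect_identical(ce2$nModules, 9L)
  expect_identical(ce2$nConnecting, 9L)
  expect_identical(ce2$nConnectingByCompartment,
                   c(cytoplasm = 8L, nucleus = 1L))

  empty <- countEntities(CircuitModel("empty"))
  expect_identical(empty$nModules, 0L)
  expect_identical(empty$nSpeciesUnique, 0L)
  expect_identical(empty$nReactions, 0L)
  expect_identical(empty$nConnecting, 0L)
})
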