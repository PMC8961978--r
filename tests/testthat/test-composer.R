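test_that("a transcription unit exposes its inputs and output through ports", {
  tu <- makeTranscriptionUnit("TU_GFP",
                              PromoterSpec(kMax = 0.02, polIIDependent = TRUE),
                              "mRNA_GFP")
  expect_identical(tu@kind, "TU")
  expect_setequal(portIds(tu), c("port_PolII", "port_mRNA_GFP"))
  expect_identical(reactionIds(tu), "transcription_mRNA_GFP")
  ## the mRNA stays in the cytoplasm even though the unit is nuclear
  mrna <- tu@species[[match("mRNA_GFP", speciesIds(tu))]]
  expect_identical(mrna@compartment, "cytoplasm")
  expect_identical(tu@hostCompartment, "nucleus")
})

test_that("an activator-driven unit without polymerase ports only activator and mRNA", {
  tu <- makeTranscriptionUnit("TU_ClpX",
                              PromoterSpec(kBasal = 3e-4, kMax = 0.033,
                                           activator = "LHVe", KAct = 50),
                              "mRNA_ClpX")
  expect_setequal(portIds(tu), c("port_LHVe", "port_mRNA_ClpX"))
  law <- tu@reactions[[1]]@law
  expect_identical(law@form, "hillActivation")
  expect_identical(law@activator, "LHVe")
  expect_identical(law@kBasal, 3e-4)
})

test_that("a silent gene is a valid unit with zero transcription rate", {
  tu <- makeTranscriptionUnit("TU_0", PromoterSpec(kBasal = 0, kMax = 0),
                              "mRNA_0")
  expect_identical(tu@reactions[[1]]@law@k, 0)
})

test_that("a ribosome-limited mRNA pool has three species, reactions and ports", {
  pool <- makeMrnaPool("pool_mRNA_GFP", "mRNA_GFP", "GFP", 0.05, 5e-4, 1e-4,
                       ribDependent = TRUE)
  expect_identical(length(pool@species), 3L)
  expect_identical(length(pool@reactions), 3L)
  expect_setequal(portIds(pool),
                  c("port_mRNA_GFP", "port_rib", "port_GFP"))
  tl <- pool@reactions[[match("translation_GFP", reactionIds(pool))]]
  expect_identical(tl@law@activator, "rib")
  expect_identical(tl@law@scaleSpecies, "mRNA_GFP")
})

test_that("extra reactions referencing undeclared species are rejected", {
  expect_error(
    makeMrnaPool("p", "mRNA_A", "A", 0.05, 5e-4, 1e-4,
                 extraReactions = list(
                   ReactionDef("bad", massActionLaw(1), reactants = c(Z = 1)))),
    "undeclared")
})

test_that("a no-decay pool grows without bound under constant mRNA", {
  pool <- makeMrnaPool("p", "mRNA_A", "A", kTl = 0.01, kDm = 0, kDp = 0)
  cc <- CircuitModel("c", compartments = list(CompartmentDef("cytoplasm")),
                     submodels = list(pool))
  cc <- connectSpecies(cc, "mRNA_A", "cytoplasm", consumers = "p",
                       initialAmount = 10, constant = TRUE)
  traj <- simulateModel(flattenCircuit(cc), tEnd = 1000, nOut = 11)
  a <- traj@states[, "A"]
  expect_true(all(diff(a) > 0))
  expect_equal(a[11], 0.01 * 10 * 1000, tolerance = 1e-6)
})

test_that("the degradation pool implements the dimerize-bind-degrade cycle", {
  deg <- makeDegradationPool()
  expect_identical(length(deg@species), 5L)
  expect_identical(length(deg@reactions), 6L)
  expect_setequal(portIds(deg), c("port_ClpP", "port_ClpX", "port_GFP"))
  ## the reversible dimerization is stored as a forward/backward pair
  pair <- Filter(function(r) r@reversible, deg@reactions)
  expect_identical(sort(vapply(pair, function(r) r@id, "")),
                   c("dimerization_ClpXP_b", "dimerization_ClpXP_f"))
  ## proteolysis recycles the free protease
  prot <- deg@reactions[[match("proteolysis_GFP", reactionIds(deg))]]
  expect_identical(names(prot@products), "ClpXP")
})

test_that("builders are deterministic", {
  expect_true(circuitIdentical(buildGalactoseNotGate(), buildGalactoseNotGate()))
  expect_true(circuitIdentical(buildEstradiolNotGate(), buildEstradiolNotGate()))
})

test_that("ported species are exactly the non-internal species", {
  mods <- c(buildGalactoseNotGate()@submodels, buildEstradiolNotGate()@submodels)
  for (sm in mods) {
    ported <- vapply(sm@ports, function(p) p@speciesRef, "")
    nonInternal <- speciesIds(sm)[vapply(sm@species,
                                         function(s) s@role != "internal", TRUE)]
    expect_setequal(ported, nonInternal)
  }
})

test_that("connecting demands matching ports and forbids double connection", {
  g <- buildGalactoseNotGate()
  expect_error(connectSpecies(g, "mRNA_GFP", "cytoplasm", producer = "TU_GFP"),
               "already connected")
  expect_error(connectSpecies(g, "nosuch", "cytoplasm", producer = "TU_GFP"),
               "no port")
})

test_that("parameters are addressable by path", {
  g <- buildGalactoseNotGate()
  expect_equal(getParam(g, "pool_degradation/binding_GFP/k"), 1e-3)
  g2 <- setParam(g, "pool_degradation/binding_GFP/k", 5e-3)
  expect_equal(getParam(g2, "pool_degradation/binding_GFP/k"), 5e-3)
  expect_equal(getParam(g, "pool_degradation/binding_GFP/k"), 1e-3) # untouched
  expect_equal(getParam(g, "params/pGAL1_basal"), 5e-4)
  expect_error(setParam(g, "params/nosuch", 1), "no global parameter")
  expect_error(setParam(g, "pool_degradation/nosuch/k", 1), "no reaction")
})
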