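test_that("the galactose gate has the published module and wiring structure", {
  g <- buildGalactoseNotGate()
  kinds <- table(vapply(g@submodels, function(s) s@kind, ""))
  expect_identical(kinds[["TU"]], 3L)
  expect_identical(kinds[["mrna_pool"]], 3L)
  expect_identical(kinds[["degradation_pool"]], 1L)
  expect_identical(length(g@submodels), 7L)
  ## six producer-linked helpers, each one producer + one consumer
  withProd <- Filter(function(cs) length(cs@producer) == 2, g@connecting)
  expect_identical(length(withProd), 6L)
  expect_setequal(vapply(withProd, function(cs) cs@speciesId, ""),
                  c("mRNA_GFP", "mRNA_ClpP", "mRNA_ClpX",
                    "GFP", "ClpP", "ClpX"))
  expect_true(all(vapply(withProd, function(cs) length(cs@consumers) == 1L,
                         TRUE)))
  ## polymerase and ribosomes are cell-only, replaced-element links only
  noProd <- Filter(function(cs) length(cs@producer) == 0, g@connecting)
  expect_setequal(vapply(noProd, function(cs) cs@speciesId, ""),
                  c("PolII", "rib"))
  polII <- g@connecting[[match("PolII",
                               vapply(g@connecting,
                                      function(s) s@speciesId, ""))]]
  expect_identical(length(polII@consumers), 3L)
  expect_identical(polII@compartment, "nucleus")
  expect_true(polII@constant)
  ## galactose is not a species anywhere
  expect_false("galactose" %in% unlist(lapply(g@submodels, speciesIds)))
  expect_identical(nrow(validateWiring(g)), 0L)
})

test_that("toggling galactose moves only the pGAL1 rate and is an involution", {
  g <- buildGalactoseNotGate()
  gOn <- setGalactose(g, TRUE)
  expect_equal(getParam(gOn, "TU_ClpX/transcription_mRNA_ClpX/k"),
               unname(g@parameters["pGAL1_induced"]))
  expect_false(circuitIdentical(g, gOn))
  gBack <- setGalactose(gOn, FALSE)
  expect_true(circuitIdentical(g, gBack))
  ## nothing but TU_ClpX differs between the two states
  same <- vapply(seq_along(g@submodels), function(i)
    isTRUE(all.equal(g@submodels[[i]], gOn@submodels[[i]])), TRUE)
  ids <- vapply(g@submodels, function(s) s@id, "")
  expect_identical(ids[!same], "TU_ClpX")
  expect_error(setGalactose(buildEstradiolNotGate(), TRUE), "not a galactose")
})

test_that("galactose switches the gate from high to low reporter output", {
  spec <- gateAnalysisSpec("galactose")
  report <- onOffRatio(spec$build(), spec$inputSetter, 0, 1, "GFP")
  expect_gt(report@outputAtInputOff, report@outputAtInputOn)
  expect_gt(report@ratio, 1)
})

test_that("the estradiol gate has nine modules and nine connecting species", {
  e <- buildEstradiolNotGate()
  kinds <- table(vapply(e@submodels, function(s) s@kind, ""))
  expect_identical(kinds[["TU"]], 4L)
  expect_identical(kinds[["mrna_pool"]], 4L)
  expect_identical(kinds[["degradation_pool"]], 1L)
  tus <- Filter(function(s) s@kind == "TU", e@submodels)
  expect_true(all(vapply(tus, function(s)
    s@hostCompartment == "nucleus", TRUE)))
  pools <- Filter(function(s) s@kind != "TU", e@submodels)
  expect_true(all(vapply(pools, function(s)
    s@hostCompartment == "cytoplasm", TRUE)))
  ## no polymerase/ribosome species anywhere
  allSpecies <- unlist(lapply(e@submodels, speciesIds))
  expect_false(any(c("PolII", "rib") %in% allSpecies))
  expect_identical(length(e@connecting), 9L)
  comp <- vapply(e@connecting, function(cs) cs@compartment, "")
  expect_identical(sum(comp == "cytoplasm"), 8L)
  expect_identical(sum(comp == "nucleus"), 1L)
  expect_identical(nrow(validateWiring(e)), 0L)
})

test_that("the hormone input is a constant producer-less species feeding one pool", {
  e <- buildEstradiolNotGate()
  cs <- connecting(e)[["e"]]
  expect_true(cs@constant)
  expect_identical(length(cs@producer), 0L)
  expect_identical(cs@consumers, list(c("pool_mRNA_LHV", "port_e")))
})

test_that("the hormone-bound activator is nuclear and confined to two modules", {
  e <- buildEstradiolNotGate()
  cs <- connecting(e)[["LHVe"]]
  expect_identical(cs@compartment, "nucleus")
  expect_identical(cs@producer[1], "pool_mRNA_LHV")
  expect_identical(cs@consumers[[1]][1], "TU_ClpX")
  touching <- Filter(function(sm) "LHVe" %in% unlist(
    lapply(sm@reactions, function(r)
      c(names(r@reactants), names(r@products), r@modifiers))), e@submodels)
  expect_setequal(vapply(touching, function(s) s@id, ""),
                  c("TU_ClpX", "pool_mRNA_LHV"))
})

test_that("setting the hormone level changes only the boundary amount", {
  e <- buildEstradiolNotGate()
  e2 <- setEstradiol(e, 1500)
  expect_identical(connecting(e2)[["e"]]@initialAmount, 1500)
  expect_identical(connecting(e)[["e"]]@initialAmount, 0)
  expect_error(setEstradiol(e, -1), ">= 0")
})

test_that("the estradiol gate responds as a NOT gate", {
  spec <- gateAnalysisSpec("estradiol")
  report <- onOffRatio(spec$build(), spec$inputSetter, 0,
                       estradiolDefaults()$e_on, "GFP")
  expect_gt(report@outputAtInputOff, report@outputAtInputOn)
  expect_gt(report@ratio, 1)
})

test_that("a leak-free ClpX promoter makes no ClpX mRNA without hormone", {
  e <- buildEstradiolNotGate(overrides = list(pClpX_basal = 0))
  st <- steadyState(flattenCircuit(setEstradiol(e, 0)))
  expect_equal(unname(st["mRNA_ClpX"]), 0, tolerance = 1e-9)
})

test_that("unknown parameter overrides are refused", {
  expect_error(buildGalactoseNotGate(overrides = list(nosuch = 1)), "unknown")
  expect_error(buildEstradiolNotGate(overrides = list(nosuch = 1)), "unknown")
})
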