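test_that("the assembled derivative matches hand stoichiometry", {
  flat <- productionDecayFlat(kIn = 3, kOut = 0.2)
  sys <- buildOdes(flat)
  expect_equal(unname(sys$derivs(c(X = 0))), 3)
  expect_equal(unname(sys$derivs(c(X = 10))), 3 - 0.2 * 10)
})

test_that("first-order decay follows its closed form", {
  sm <- SubmodelSpec("m", "mrna_pool", "cytoplasm",
                     species = list(SpeciesDef("X", "cytoplasm",
                                               initialAmount = 100)),
                     reactions = list(ReactionDef("decay_X",
                                                  massActionLaw(0.03),
                                                  reactants = c(X = 1))))
  flat <- flattenCircuit(CircuitModel("c",
                                      compartments = list(CompartmentDef("cytoplasm")),
                                      submodels = list(sm)))
  traj <- simulateModel(flat, tEnd = 100, nOut = 26, reltol = 1e-10,
                        abstol = 1e-12)
  expect_equal(traj@states[, "X"], 100 * exp(-0.03 * traj@times),
               tolerance = 1e-6)
})

test_that("bimolecular binding conserves its two totals", {
  sm <- SubmodelSpec("m", "degradation_pool", "cytoplasm",
                     species = list(SpeciesDef("A", "cytoplasm", 30),
                                    SpeciesDef("B", "cytoplasm", 20),
                                    SpeciesDef("C", "cytoplasm", 0)),
                     reactions = list(ReactionDef("bind",
                                                  massActionLaw(1e-3),
                                                  reactants = c(A = 1, B = 1),
                                                  products = c(C = 1))))
  flat <- flattenCircuit(CircuitModel("c",
                                      compartments = list(CompartmentDef("cytoplasm")),
                                      submodels = list(sm)))
  traj <- simulateModel(flat, tEnd = 2000, nOut = 50, reltol = 1e-10,
                        abstol = 1e-12)
  expect_equal(traj@states[, "A"] + traj@states[, "C"],
               rep(30, 50), tolerance = 1e-8)
  expect_equal(traj@states[, "B"] + traj@states[, "C"],
               rep(20, 50), tolerance = 1e-8)
})

test_that("scaling all rate constants rescales time", {
  build <- function(scale) {
    sm <- SubmodelSpec(
      "m", "mrna_pool", "cytoplasm",
      species = list(SpeciesDef("A", "cytoplasm", 0),
                     SpeciesDef("B", "cytoplasm", 50),
                     SpeciesDef("C", "cytoplasm", 0)),
      reactions = list(
        ReactionDef("make_A", massActionLaw(0.1 * scale),
                    products = c(A = 1)),
        ReactionDef("decay_A", massActionLaw(0.01 * scale),
                    reactants = c(A = 1)),
        ReactionDef("bind", massActionLaw(0.002 * scale),
                    reactants = c(A = 1, B = 1), products = c(C = 1))
      ))
    flattenCircuit(CircuitModel("c",
                                compartments = list(CompartmentDef("cytoplasm")),
                                submodels = list(sm)))
  }
  times <- seq(0, 400, length.out = 11)
  t1 <- simulateModel(build(1), times = times, reltol = 1e-10, abstol = 1e-12)
  t2 <- simulateModel(build(10), times = times / 10, reltol = 1e-10,
                      abstol = 1e-12)
  expect_equal(t2@states, t1@states, tolerance = 1e-6)
})

test_that("all-zero rates give a constant trajectory", {
  flat <- productionDecayFlat(kIn = 0, kOut = 0)
  traj <- simulateModel(flat, tEnd = 1000, nOut = 5)
  expect_true(all(traj@states == 0))
})

test_that("trajectories stay non-negative everywhere", {
  for (circuit in list(buildGalactoseNotGate(),
                       setEstradiol(buildEstradiolNotGate(), 2000))) {
    traj <- simulateModel(flattenCircuit(circuit), tEnd = 1e5, nOut = 60)
    expect_true(all(traj@states >= 0))
  }
})

test_that("a production/decay pair reaches its analytic steady state", {
  flat <- productionDecayFlat(kIn = 2, kOut = 0.05)
  st <- steadyState(flat)
  expect_equal(unname(st["X"]), 40, tolerance = 1e-6)
})

test_that("a zero-rate system returns its initial state immediately", {
  flat <- productionDecayFlat(kIn = 0, kOut = 0)
  flat@species[[1]]@initialAmount <- 17
  expect_identical(unname(steadyState(flat)["X"]), 17)
})

test_that("steady-state search errors out when the budget is exhausted", {
  ## pure zero-order production never settles
  sm <- SubmodelSpec("m", "mrna_pool", "cytoplasm",
                     species = list(SpeciesDef("X", "cytoplasm")),
                     reactions = list(ReactionDef("make", massActionLaw(1),
                                                  products = c(X = 1))))
  flat <- flattenCircuit(CircuitModel("c",
                                      compartments = list(CompartmentDef("cytoplasm")),
                                      submodels = list(sm)))
  expect_error(steadyState(flat, tMax = 1e4), "not reached")
})

test_that("flattened and hand-composed monolithic dynamics agree", {
  for (present in c(FALSE, TRUE)) {
    circuit <- setGalactose(buildGalactoseNotGate(), present)
    flat <- flattenCircuit(circuit)
    times <- seq(0, 5e4, length.out = 26)
    trajFlat <- simulateModel(flat, times = times, reltol = 1e-10,
                              abstol = 1e-12)
    hand <- deSolve::lsoda(handGalactoseState0(), times,
                           handGalactoseDerivs(present), NULL,
                           rtol = 1e-10, atol = 1e-12)
    handStates <- unname(as.matrix(hand)[, -1])
    flatStates <- trajFlat@states[, handToFlatNames]
    expect_equal(unname(flatStates), handStates, tolerance = 1e-6)
  }
})

test_that("the reduced gate matches its algebraic steady-state ratio", {
  p <- reducedParams()
  circuit <- reducedDegradationCircuit(p)
  report <- onOffRatio(circuit, setClpXLevel, offValue = 2, onValue = 200,
                       outputSpecies = "R")
  expected <- reducedSteadyStateR(p, 2) / reducedSteadyStateR(p, 200)
  expect_equal(report@ratio, expected, tolerance = 1e-6)
  expect_equal(report@outputAtInputOff, reducedSteadyStateR(p, 2),
               tolerance = 1e-6)
})

test_that("severing the degradation path forces the ratio to one", {
  g <- setParam(buildGalactoseNotGate(),
                "pool_degradation/binding_GFP/k", 0)
  spec <- gateAnalysisSpec("galactose")
  report <- onOffRatio(g, spec$inputSetter, 0, 1, "GFP")
  expect_equal(report@ratio, 1, tolerance = 1e-6)
})

test_that("both gates are monotone NOT gates across a 10-point input sweep", {
  for (gate in c("galactose", "estradiol")) {
    spec <- gateAnalysisSpec(gate)
    sweep <- inputSweep(spec$build(), spec$sweepSetter, spec$sweepValues,
                        spec$outputSpecies)
    expect_identical(nrow(sweep), 10L)
    expect_true(all(diff(sweep$output) <= 0))
    expect_gt(sweep$output[1] / sweep$output[10], 1)
  }
})
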