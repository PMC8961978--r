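test_that("the galactose gate writes one file per submodel plus the cell file", {
  d <- withr::local_tempdir()
  layout <- writeCircuit(buildGalactoseNotGate(), d)
  expect_identical(layout$mainFile, "cell.xml")
  expect_identical(length(layout$submodelFiles), 7L)
  expect_identical(length(list.files(d, pattern = "\\.xml$")), 8L)
})

test_that("the estradiol gate writes a ten-file layout", {
  d <- withr::local_tempdir()
  writeCircuit(buildEstradiolNotGate(), d)
  expect_identical(length(list.files(d, pattern = "\\.xml$")), 10L)
})

test_that("an empty circuit writes a single valid main file", {
  d <- withr::local_tempdir()
  layout <- writeCircuit(CircuitModel("empty"), d)
  expect_identical(list.files(d), "cell.xml")
  back <- readCircuit(file.path(d, "cell.xml"))
  expect_identical(back@id, "empty")
  expect_identical(length(back@submodels), 0L)
})

test_that("hierarchical serialization round-trips both catalog gates exactly", {
  for (circuit in list(buildGalactoseNotGate(), buildEstradiolNotGate())) {
    d <- withr::local_tempdir()
    writeCircuit(circuit, d)
    back <- readCircuit(file.path(d, "cell.xml"))
    expect_true(circuitIdentical(circuit, back))
  }
})

test_that("a missing submodel file is an unresolvable-reference error", {
  d <- withr::local_tempdir()
  writeCircuit(buildGalactoseNotGate(), d)
  file.remove(file.path(d, "TU_GFP.xml"))
  expect_error(readCircuit(file.path(d, "cell.xml")), "missing")
})

test_that("malformed XML is a parse error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model", f)
  expect_error(readCircuit(f))
})

test_that("writing a miswired circuit is refused", {
  g <- buildGalactoseNotGate()
  g@connecting[[1]]@producer <- c("TU_GFP", "port_missing")
  expect_error(writeCircuit(g, withr::local_tempdir()), "wiring error")
})

test_that("the hand-written two-module toy parses field-by-field", {
  toy <- system.file("extdata", "toy", "cell.xml", package = "circomp")
  circuit <- readCircuit(toy)
  expect_identical(length(circuit@submodels), 2L)
  expect_identical(length(circuit@connecting), 1L)
  sm <- submodels(circuit)
  expect_identical(sm[["TU_X"]]@kind, "TU")
  expect_identical(sm[["pool_X"]]@kind, "mrna_pool")
  ## inferred roles: produced-with-net-gain is output, other ported is input
  tuRoles <- vapply(sm[["TU_X"]]@species, function(s) s@role, "")
  expect_identical(unname(tuRoles), "output")
  poolRoles <- structure(vapply(sm[["pool_X"]]@species, function(s) s@role, ""),
                         names = speciesIds(sm[["pool_X"]]))
  expect_identical(unname(poolRoles["mRNA_X"]), "input")
  cs <- circuit@connecting[[1]]
  expect_identical(cs@speciesId, "mRNA_X")
  expect_identical(cs@producer, c("TU_X", "port_mRNA_X"))
  expect_identical(cs@consumers, list(c("pool_X", "port_mRNA_X")))
  expect_identical(nrow(validateWiring(circuit)), 0L)
  ## laws survive the tolerant fallback with their constants
  k <- getParam(circuit, "TU_X/transcription_mRNA_X/k")
  expect_equal(k, 0.01)
  ## and the parsed toy simulates to its analytic steady state
  st <- steadyState(flattenCircuit(circuit))
  expect_equal(unname(st["X"]), (0.01 / 5e-4) * 0.05 / 1e-4, tolerance = 1e-6)
})

test_that("flat export contains each merged species once and simulates identically", {
  flat <- flattenCircuit(buildGalactoseNotGate())
  f <- withr::local_tempfile(fileext = ".xml")
  exportFlatSbml(flat, f)
  doc <- xml2::read_xml(f)
  ## no comp namespace, hence no hierarchical constructs
  expect_false(any(grepl("/comp/", unlist(xml2::xml_ns(doc)))))
  sp <- xml2::xml_find_all(doc, ".//d1:species",
                           xml2::xml_ns(doc))
  ids <- vapply(sp, function(x) xml2::xml_attr(x, "id"), "")
  expect_identical(sum(ids == "mRNA_GFP"), 1L)
  back <- readFlatSbml(f)
  t1 <- simulateModel(flat, tEnd = 20000, nOut = 21)
  t2 <- simulateModel(back, tEnd = 20000, nOut = 21)
  expect_equal(t2@states[, t1@speciesOrder], t1@states, tolerance = 1e-10)
})

test_that("an empty flat model exports to a valid zero-reaction document", {
  flat <- flattenCircuit(CircuitModel("empty"))
  f <- withr::local_tempfile(fileext = ".xml")
  exportFlatSbml(flat, f)
  back <- readFlatSbml(f)
  expect_identical(length(back@reactions), 0L)
})

test_that("unsupported SBML constructs are reported, not dropped silently", {
  d <- withr::local_tempdir()
  writeCircuit(buildGalactoseNotGate(), d)
  f <- file.path(d, "cell.xml")
  doc <- xml2::read_xml(f)
  model <- xml2::xml_find_first(doc, ".//d1:model", xml2::xml_ns(doc))
  xml2::xml_add_child(model, "listOfEvents")
  xml2::write_xml(doc, f)
  expect_warning(readCircuit(f), "listOfEvents")
})
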