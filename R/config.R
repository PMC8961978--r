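## Loading circuit definitions from a structured text config (YAML or JSON)
## that mirrors the builder arguments one-to-one.

#' Build a circuit from a structured config
#'
#' The config (YAML or JSON file, or an equivalent nested list) mirrors the
#' builder arguments: `compartments`, `transcription_units` (each with a
#' `promoter` block), `mrna_pools`, `degradation_pools`, and `connections`.
#' See `inst/extdata/toy_config.yaml` for a complete example.
#'
#' @param config path to a YAML/JSON file, or a list.
#' @return a [CircuitModel-class].
#' @export
circuitFromConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  g <- function(x, nm, default = NULL) if (!is.null(x[[nm]])) x[[nm]] else default

  compartments <- lapply(g(config, "compartments", list()), function(cp) {
    if (is.character(cp)) CompartmentDef(cp)
    else CompartmentDef(cp$id, g(cp, "size", 1))
  })

  submodels <- list()
  for (tu in g(config, "transcription_units", list())) {
    pr <- tu$promoter
    if (is.null(pr)) stop(sprintf("TU '%s': missing promoter block", tu$id))
    promoter <- PromoterSpec(
      kBasal = g(pr, "k_basal", 0), kMax = pr$k_max,
      activator = g(pr, "activator", NA_character_),
      KAct = g(pr, "K_act", NA_real_),
      polIIDependent = isTRUE(g(pr, "polII_dependent", FALSE)),
      KPolII = g(pr, "K_polII", 50))
    submodels <- c(submodels, list(makeTranscriptionUnit(
      tu$id, promoter, tu$mrna,
      mrnaCompartment = g(tu, "mrna_compartment", "cytoplasm"),
      hostCompartment = g(tu, "host_compartment", "nucleus"))))
  }
  for (pl in g(config, "mrna_pools", list())) {
    submodels <- c(submodels, list(makeMrnaPool(
      pl$id, pl$mrna, pl$protein, kTl = pl$k_tl, kDm = pl$k_dm, kDp = pl$k_dp,
      ribDependent = isTRUE(g(pl, "rib_dependent", FALSE)),
      KRib = g(pl, "K_rib", 500),
      hostCompartment = g(pl, "host_compartment", "cytoplasm"))))
  }
  for (dp in g(config, "degradation_pools", list())) {
    submodels <- c(submodels, list(makeDegradationPool(
      dp$id, clppId = g(dp, "clpp", "ClpP"), clpxId = g(dp, "clpx", "ClpX"),
      targetId = g(dp, "target", "GFP"),
      kDimF = g(dp, "k_dim_f", 1e-3), kDimR = g(dp, "k_dim_r", 1e-3),
      kBind = g(dp, "k_bind", 1e-3), kDegr = g(dp, "k_degr", 0.1),
      kDil = g(dp, "k_dil", 1e-4),
      hostCompartment = g(dp, "host_compartment", "cytoplasm"))))
  }

  circuit <- CircuitModel(g(config, "id", "circuit"),
                          compartments = compartments, submodels = submodels,
                          parameters = unlist(g(config, "parameters",
                                                structure(numeric(), names = character()))))
  for (cn in g(config, "connections", list())) {
    circuit <- connectSpecies(
      circuit, cn$species, cn$compartment,
      producer = g(cn, "producer", NULL),
      consumers = unlist(g(cn, "consumers", character())),
      initialAmount = g(cn, "initial_amount", 0),
      constant = isTRUE(g(cn, "constant", FALSE)))
  }
  circuit
}
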