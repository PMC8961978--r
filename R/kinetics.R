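## Rate-law forms shared by every reaction in both gate models: mass action
## (molecularity <= 2) and Hill activation without cooperativity. Promoters
## and mRNAs are driven by their activator (a transcription factor, RNA
## polymerase II, or ribosomes) through the n = 1 Hill term k*A/(K+A).

#' Hill activation rate without cooperativity
#'
#' Computes `k * A / (K + A)`, the activation rate of a promoter or mRNA by
#' activator amount `A` with half-saturation `K`. The rate is bounded in
#' `[0, k)` and monotone non-decreasing in `A`.
#'
#' @param k maximal rate constant (>= 0).
#' @param A activator amount in molecules (>= 0); vectorized.
#' @param K half-saturation constant in molecules (> 0).
#' @return rate in molecules per unit time.
#' @examples
#' hillRate(10, 50, 50)   # half-saturation: k/2
#' hillRate(10, 5000, 50) # approaches k
#' @export
hillRate <- function(k, A, K) {
  if (any(k < 0)) stop("hillRate: k must be >= 0")
  if (any(A < 0)) stop("hillRate: activator amount must be >= 0")
  if (any(K <= 0)) stop("hillRate: K must be > 0")
  k * A / (K + A)
}

#' Mass-action rate
#'
#' Computes `k * prod(amount^stoichiometry)` for a reaction with total
#' molecularity at most 2 (zero-order synthesis, first-order decay, or
#' bimolecular binding).
#'
#' @param k rate constant (>= 0).
#' @param amounts numeric vector of reactant amounts (may be empty for a
#'   zero-order reaction).
#' @param stoich integer stoichiometries, same length as `amounts`
#'   (default all 1).
#' @return rate in molecules per unit time.
#' @examples
#' massActionRate(0.1, c(10, 5)) # bimolecular: 0.1 * 10 * 5
#' massActionRate(2, 3)          # first order: 2 * 3
#' @export
massActionRate <- function(k, amounts = numeric(), stoich = rep(1L, length(amounts))) {
  if (any(k < 0)) stop("massActionRate: k must be >= 0")
  if (any(amounts < 0)) stop("massActionRate: amounts must be >= 0")
  if (sum(stoich) > 2)
    stop("massActionRate: total molecularity > 2 is unsupported")
  if (!length(amounts)) return(k)
  k * prod(amounts^stoich)
}

#' Construct a mass-action kinetic law
#'
#' @param k rate constant.
#' @return a [KineticLaw-class].
#' @export
massActionLaw <- function(k) {
  new("KineticLaw", form = "massAction", k = k)
}

#' Construct a Hill-activation kinetic law
#'
#' Rate form `(kBasal + k * A/(K + A))`, optionally multiplied by a second
#' Hill factor `A2/(K2 + A2)` (a promoter depending on both its activator
#' and RNA polymerase II) and by the amount of a linear scale species (the
#' mRNA template of a translation reaction). All species named here must be
#' listed among the reaction's modifiers or reactants.
#'
#' @param k maximal rate constant.
#' @param K half-saturation of the activator (molecules).
#' @param activator id of the activating species.
#' @param kBasal basal (leaky) rate, default 0.
#' @param activator2,K2 optional second multiplicative Hill factor.
#' @param scaleSpecies optional species multiplying the rate linearly.
#' @return a [KineticLaw-class].
#' @export
hillLaw <- function(k, K, activator, kBasal = 0,
                    activator2 = NA_character_, K2 = NA_real_,
                    scaleSpecies = NA_character_) {
  new("KineticLaw", form = "hillActivation", k = k, kBasal = kBasal,
      K = K, activator = activator, activator2 = activator2, K2 = K2,
      scaleSpecies = scaleSpecies)
}

## Evaluate a reaction's rate at a named state vector. Reactant
## stoichiometries come from the reaction itself for mass action.
evalReactionRate <- function(reaction, state) {
  law <- reaction@law
  if (law@form == "massAction") {
    am <- unname(state[names(reaction@reactants)])
    return(massActionRate(law@k, am, unname(reaction@reactants)))
  }
  A <- unname(state[law@activator])
  r <- law@kBasal + hillRate(law@k, A, law@K)
  if (!is.na(law@activator2))
    r <- r * unname(state[law@activator2]) / (law@K2 + unname(state[law@activator2]))
  if (!is.na(law@scaleSpecies))
    r <- r * unname(state[law@scaleSpecies])
  r
}
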