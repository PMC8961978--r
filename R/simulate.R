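## Deterministic ODE simulation of flattened circuits, steady-state
## extraction, NOT-gate ON/OFF analysis, input titration sweeps, and seeded
## multi-start parameter optimization of the gate ratio.

#' Assemble the ODE right-hand side of a flat model
#'
#' Builds the derivative function `d x / d t = S %*% r(x)` from the flat
#' model's stoichiometry and kinetic laws. Constant (boundary) species get a
#' zero derivative. State amounts are clipped at 0 before rate evaluation so
#' that tiny integrator undershoot cannot produce negative rates.
#'
#' @param flat a [FlatModel-class].
#' @return a list with `derivs(state)` (named state vector in, named
#'   derivative vector out), `deSolveFunc` (the same in [deSolve::lsoda()]
#'   calling convention), `state0` (initial amounts), `constant` (logical
#'   mask), and `speciesOrder`.
#' @export
buildOdes <- function(flat) {
  ids <- speciesIds(flat)
  n <- length(ids)
  state0 <- structure(vapply(flat@species, function(s) s@initialAmount, 0),
                      names = ids)
  constant <- structure(vapply(flat@species, function(s) s@constant, TRUE),
                        names = ids)
  nr <- length(flat@reactions)
  S <- matrix(0, nrow = n, ncol = nr, dimnames = list(ids, NULL))
  rateSpecs <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- flat@reactions[[j]]
    if (length(r@reactants))
      S[names(r@reactants), j] <- S[names(r@reactants), j] - unname(r@reactants)
    if (length(r@products))
      S[names(r@products), j] <- S[names(r@products), j] + unname(r@products)
    law <- r@law
    rateSpecs[[j]] <- if (law@form == "massAction") {
      list(type = 1L, k = law@k,
           idx = match(names(r@reactants), ids),
           st = unname(r@reactants))
    } else if (law@form == "hillActivation") {
      list(type = 2L, k = law@k, kBasal = law@kBasal, K = law@K,
           ia = match(law@activator, ids),
           ia2 = if (is.na(law@activator2)) NA_integer_ else
             match(law@activator2, ids),
           K2 = law@K2,
           isc = if (is.na(law@scaleSpecies)) NA_integer_ else
             match(law@scaleSpecies, ids))
    } else stop(sprintf("unknown law form '%s' in reaction '%s'",
                        law@form, r@id))
  }
  rates <- function(y) {
    y <- pmax(y, 0)
    out <- numeric(nr)
    for (j in seq_len(nr)) {
      rs <- rateSpecs[[j]]
      out[j] <- if (rs$type == 1L) {
        if (length(rs$idx)) rs$k * prod(y[rs$idx]^rs$st) else rs$k
      } else {
        v <- rs$kBasal + rs$k * y[rs$ia] / (rs$K + y[rs$ia])
        if (!is.na(rs$ia2)) v <- v * y[rs$ia2] / (rs$K2 + y[rs$ia2])
        if (!is.na(rs$isc)) v <- v * y[rs$isc]
        v
      }
    }
    out
  }
  derivs <- function(state) {
    dy <- as.vector(S %*% rates(unname(state)))
    dy[constant] <- 0
    structure(dy, names = ids)
  }
  deSolveFunc <- function(t, y, parms) {
    dy <- as.vector(S %*% rates(y))
    dy[constant] <- 0
    list(dy)
  }
  list(derivs = derivs, deSolveFunc = deSolveFunc, state0 = state0,
       constant = constant, speciesOrder = ids)
}

#' Simulate a flat model
#'
#' Stiff-capable deterministic integration with [deSolve::lsoda()].
#' Trajectories are reported with tiny negative undershoot (bounded by
#' 1e-9) clipped to zero.
#'
#' @param flat a [FlatModel-class].
#' @param tEnd end time (seconds), > 0.
#' @param times explicit output times overriding `tEnd`/`nOut`.
#' @param nOut number of output points when `times` is not given.
#' @param state0 optional replacement initial state (named, full length).
#' @param reltol,abstol integrator tolerances.
#' @return a [Trajectory-class].
#' @export
simulateModel <- function(flat, tEnd = NULL, times = NULL, nOut = 200,
                          state0 = NULL, reltol = 1e-8, abstol = 1e-10) {
  sys <- buildOdes(flat)
  if (is.null(times)) {
    if (is.null(tEnd) || tEnd <= 0) stop("tEnd must be > 0")
    times <- seq(0, tEnd, length.out = nOut)
  }
  y0 <- if (is.null(state0)) sys$state0 else state0[sys$speciesOrder]
  out <- deSolve::lsoda(y = y0, times = times, func = sys$deSolveFunc,
                        parms = NULL, rtol = reltol, atol = abstol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integrator failure for '%s' (istate = %d)",
                 flat@id, attr(out, "istate")[1]))
  states <- unname(as.matrix(out)[, -1, drop = FALSE])
  if (min(states) < -1e-6)
    warning(sprintf("trajectory of '%s' dips to %.3g; check tolerances",
                    flat@id, min(states)))
  states <- pmax(states, 0)
  colnames(states) <- sys$speciesOrder
  new("Trajectory", times = as.numeric(out[, 1]), states = states,
      speciesOrder = sys$speciesOrder)
}

#' Steady state by long integration with Newton polishing
#'
#' Integrates in doubling time windows until the largest per-second relative
#' state change drops below `tolRel`, then polishes the result with a few
#' Newton iterations on the ODE right-hand side (numeric Jacobian over the
#' non-constant species) so that closed-form comparisons are limited by
#' arithmetic, not by integration depth. If Newton fails to reduce the
#' residual the integrated state is returned unpolished.
#'
#' @param flat a [FlatModel-class].
#' @param tolRel convergence threshold on `max |dx/dt| / max(|x|, 1)`
#'   (per second), default 1e-8.
#' @param tMax integration-time budget; exceeding it without convergence is
#'   an error.
#' @param state0 optional replacement initial state.
#' @return named steady-state vector.
#' @export
steadyState <- function(flat, tolRel = 1e-8, tMax = 1e9, state0 = NULL) {
  stopifnot(tolRel > 0)
  sys <- buildOdes(flat)
  y <- if (is.null(state0)) sys$state0 else state0[sys$speciesOrder]
  metric <- function(y) {
    dy <- sys$derivs(y)
    max(abs(dy) / pmax(abs(y), 1))
  }
  if (metric(y) < tolRel) return(newtonPolish(sys, y))
  t <- 0; window <- min(2e5, tMax)
  while (t < tMax) {
    window <- min(window, tMax - t)
    out <- deSolve::lsoda(y = y, times = c(0, window), func = sys$deSolveFunc,
                          parms = NULL, rtol = 1e-6, atol = 1e-8,
                          maxsteps = 100000)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("integrator failure for '%s' at t = %g", flat@id, t))
    y <- structure(pmax(as.numeric(out[2, -1]), 0), names = sys$speciesOrder)
    t <- t + window
    window <- window * 4
    ## once the trajectory is close, Newton closes the remaining gap in a
    ## few cheap iterations; accept only if the polished residual converged
    if (metric(y) < 1e-4) {
      polished <- newtonPolish(sys, y)
      if (metric(polished) < tolRel) return(polished)
    }
    if (metric(y) < tolRel) return(y)
  }
  stop(sprintf("steady state of '%s' not reached within t = %g (residual %.3g)",
               flat@id, tMax, metric(y)))
}

newtonPolish <- function(sys, y, maxIter = 8) {
  free <- which(!sys$constant)
  resid <- function(y) sys$derivs(y)[free]
  best <- y; bestNorm <- max(abs(resid(y)))
  for (it in seq_len(maxIter)) {
    f0 <- resid(y)
    if (max(abs(f0)) < 1e-13 * max(1, max(abs(y)))) break
    nJ <- length(free)
    J <- matrix(0, nJ, nJ)
    h <- pmax(abs(y[free]), 1) * 1e-7
    for (k in seq_len(nJ)) {
      yk <- y; yk[free[k]] <- yk[free[k]] + h[k]
      J[, k] <- (resid(yk) - f0) / h[k]
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    yNew <- y
    yNew[free] <- pmax(y[free] + step, 0)
    nrm <- max(abs(resid(yNew)))
    if (!is.finite(nrm) || nrm >= bestNorm) break
    y <- yNew; best <- yNew; bestNorm <- nrm
  }
  best
}

#' Steady-state ON/OFF analysis of a Boolean gate
#'
#' Applies the input setter at the two input settings, flattens each
#' circuit, extracts both steady states, and reports the gate output levels
#' and their ratio `output(input off) / output(input on)` — for a NOT gate
#' the numerator is the gate's ON level. A zero denominator yields an
#' infinite ratio with a warning.
#'
#' @param circuit a [CircuitModel-class].
#' @param inputSetter `function(circuit, value) -> circuit` applying an
#'   input level (e.g. [setGalactose()], [setEstradiol()]).
#' @param offValue,onValue the two input settings.
#' @param outputSpecies id of the reporter in the flat model.
#' @param tolRel,tMax steady-state controls, see [steadyState()].
#' @return a [GateReport-class].
#' @export
onOffRatio <- function(circuit, inputSetter, offValue, onValue,
                       outputSpecies, tolRel = 1e-8, tMax = 1e9) {
  out <- vapply(list(offValue, onValue), function(v) {
    flat <- flattenCircuit(inputSetter(circuit, v))
    st <- steadyState(flat, tolRel = tolRel, tMax = tMax)
    if (!outputSpecies %in% names(st))
      stop(sprintf("output species '%s' not in flat model", outputSpecies))
    unname(st[outputSpecies])
  }, 0)
  ratio <- if (out[2] == 0) {
    warning("gate output is 0 at the ON input; ratio reported as Inf")
    Inf
  } else out[1] / out[2]
  new("GateReport", outputSpecies = outputSpecies,
      offInputLevel = as.numeric(offValue), onInputLevel = as.numeric(onValue),
      outputAtInputOff = out[1], outputAtInputOn = out[2], ratio = ratio)
}

#' Input titration sweep
#'
#' Steady-state output over a vector of input levels (e.g. hormone amounts
#' or induced transcription rates), the simulated counterpart of a wet-lab
#' titration curve.
#'
#' @inheritParams onOffRatio
#' @param values input levels to sweep.
#' @return data.frame with columns `input` and `output`.
#' @export
inputSweep <- function(circuit, inputSetter, values, outputSpecies,
                       tolRel = 1e-8, tMax = 1e9) {
  output <- vapply(values, function(v) {
    st <- steadyState(flattenCircuit(inputSetter(circuit, v)),
                      tolRel = tolRel, tMax = tMax)
    unname(st[outputSpecies])
  }, 0)
  data.frame(input = as.numeric(values), output = output)
}

#' Seeded multi-start optimization of the gate ratio
#'
#' Random multi-start plus local refinement: free parameters (addressed by
#' [setParam()] paths) are searched on the log10 scale within finite
#' positive bounds using L-BFGS-B, from `nStarts` seeded starting points
#' (the current parameterization clipped into bounds, then uniform draws in
#' log-bound space). The objective is either maximizing the ON/OFF ratio or
#' matching a target ratio. The same seed always returns the identical
#' result, and returned parameters never leave the bounds.
#'
#' @inheritParams onOffRatio
#' @param freeParameters character vector of parameter paths (see
#'   [getParam()]).
#' @param bounds named list (or 2-row matrix) of `c(lower, upper)` per free
#'   parameter; all finite and positive.
#' @param objective `"maximize_ratio"` or `"match_target"`.
#' @param target target ratio for `"match_target"`.
#' @param seed integer seed for the multi-start draws.
#' @param nStarts number of starting points.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return list with `parameters` (named best values), `ratio`, `report`
#'   (the [GateReport-class] at the optimum), and `objective`.
#' @export
optimizeRatio <- function(circuit, freeParameters, bounds,
                          objective = c("maximize_ratio", "match_target"),
                          target = NULL, seed = 1, nStarts = 4,
                          inputSetter, offValue, onValue, outputSpecies,
                          tolRel = 1e-8, tMax = 1e9, maxit = 30) {
  objective <- match.arg(objective)
  if (!length(freeParameters)) stop("empty free-parameter set")
  if (is.matrix(bounds))
    bounds <- lapply(seq_len(ncol(bounds)), function(j) bounds[, j])
  bounds <- bounds[freeParameters]
  ok <- vapply(bounds, function(b) length(b) == 2 && all(is.finite(b)) &&
                 all(b > 0) && b[1] <= b[2], TRUE)
  if (any(!ok)) stop("bounds must be finite, positive c(lower, upper) for every free parameter")
  if (objective == "match_target" && (is.null(target) || target <= 0))
    stop("match_target requires a positive target ratio")

  lo <- log10(vapply(bounds, `[`, 0, 1))
  hi <- log10(vapply(bounds, `[`, 0, 2))
  evalObjective <- function(logPar) {
    cc <- circuit
    for (i in seq_along(freeParameters))
      cc <- setParam(cc, freeParameters[i], 10^logPar[i])
    rep <- tryCatch(
      onOffRatio(cc, inputSetter, offValue, onValue, outputSpecies,
                 tolRel = tolRel, tMax = tMax),
      error = function(e) NULL)
    if (is.null(rep) || !is.finite(rep@ratio) || rep@ratio <= 0) return(1e6)
    if (objective == "maximize_ratio") -log(rep@ratio)
    else (log(rep@ratio) - log(target))^2
  }

  current <- vapply(freeParameters, function(p) {
    v <- tryCatch(getParam(circuit, p), error = function(e) NA_real_)
    if (is.na(v) || v <= 0) NA_real_ else log10(v)
  }, 0)
  set.seed(seed)
  starts <- list(pmin(pmax(ifelse(is.na(current), (lo + hi) / 2, current),
                           lo), hi))
  while (length(starts) < nStarts)
    starts[[length(starts) + 1L]] <- lo + stats::runif(length(lo)) * (hi - lo)

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, evalObjective, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(maxit = maxit, factr = 1e9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- structure(10^best$par, names = freeParameters)
  cc <- circuit
  for (i in seq_along(freeParameters))
    cc <- setParam(cc, freeParameters[i], par[[i]])
  report <- onOffRatio(cc, inputSetter, offValue, onValue, outputSpecies,
                       tolRel = tolRel, tMax = tMax)
  list(parameters = par, ratio = report@ratio, report = report,
       objective = objective, objectiveValue = best$value, seed = seed,
       circuit = cc)
}

#' Write a trajectory as CSV
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrajectoryCsv <- function(trajectory, path) {
  df <- data.frame(time = trajectory@times, trajectory@states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a gate report as JSON
#'
#' @param report a [GateReport-class].
#' @return a JSON string.
#' @export
gateReportToJson <- function(report) {
  jsonlite::toJSON(list(
    output_species = report@outputSpecies,
    off_input_level = report@offInputLevel,
    on_input_level = report@onInputLevel,
    output_at_input_off = report@outputAtInputOff,
    output_at_input_on = report@outputAtInputOn,
    ratio = report@ratio
  ), auto_unbox = TRUE, digits = NA)
}
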