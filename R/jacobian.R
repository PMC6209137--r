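#' Sensitivities of predicted measurements to the free fluxes
#'
#' Central finite differences of the full prediction pipeline (labeling
#' solve, measurement map, group normalization) with respect to the free
#' fluxes.  When a perturbation would leave the feasible region (bound or
#' inequality violation, negative exchange), one-sided differencing is used
#' with a warning.
#'
#' @param system a \linkS4class{CumomerSystem}
#' @param param a \linkS4class{FluxParametrization}
#' @param freeValues named numeric; the design point over
#'   \code{freeFluxes(param)} (exchange entries suffixed \code{".xch"})
#' @param mixture a \linkS4class{TracerMixture}
#' @param setup a \linkS4class{MeasurementSetup}
#' @param freeSet names of free fluxes to differentiate (default all)
#' @param h step sizes; default \code{1e-6 * max(1, |v_i|)} per flux
#' @return matrix (#observations x #freeSet) with observation labels as row
#'   names
#' @export
labelingJacobian <- function(system, param, freeValues, mixture, setup,
                             freeSet = names(freeValues), h = NULL) {
  eta <- function(fv) {
    st <- expandFluxState(param, fv, strict = FALSE)
    viol <- attr(st, "violations")
    if (!is.null(viol) && nrow(viol)) return(NULL)
    if (any(st@exchange < 0)) return(NULL)
    predictMeasurements(solveLabeling(system, st, mixture), setup)$value
  }
  base <- eta(freeValues)
  if (is.null(base))
    .stopf("design point violates the flux constraints")
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(freeValues[freeSet]))
  h <- rep_len(h, length(freeSet))
  J <- matrix(0, length(base), length(freeSet),
              dimnames = list(NULL, freeSet))
  # exchange entries may not go negative under perturbation
  isXch <- grepl("\\.xch$", freeSet)
  for (k in seq_along(freeSet)) {
    i <- freeSet[k]
    vp <- freeValues; vp[i] <- vp[i] + h[k]
    vm <- freeValues; vm[i] <- vm[i] - h[k]
    ep <- eta(vp)
    em <- if (isXch[k] && vm[i] < 0) NULL else eta(vm)
    if (!is.null(ep) && !is.null(em)) {
      J[, k] <- (ep - em) / (2 * h[k])
    } else if (!is.null(ep)) {
      .warnf("free flux '%s' at a constraint boundary: one-sided differencing", i)
      J[, k] <- (ep - base) / h[k]
    } else if (!is.null(em)) {
      .warnf("free flux '%s' at a constraint boundary: one-sided differencing", i)
      J[, k] <- (base - em) / h[k]
    } else {
      .stopf("free flux '%s': both perturbations infeasible", i)
    }
  }
  pred <- predictMeasurements(
    solveLabeling(system, expandFluxState(param, freeValues, strict = FALSE),
                  mixture), setup)
  rownames(J) <- paste(pred$group, pred$label, sep = ":")
  J
}
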