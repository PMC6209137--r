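#' Assemble a design evaluation context
#'
#' Bundles the constant part of a design problem: the network and its
#' free-flux parametrization, the reference flux values around which the
#' Fisher information is evaluated, the available tracer species, the
#' candidate measurement groups with their error models, the cost
#' parameters, the number of parallel labeling experiments and the objective
#' set.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param refFree named numeric; reference free fluxes over
#'   \code{freeFluxes(param)}
#' @param species tracer species table (see \code{\link{tracerMixture}})
#' @param setup a \linkS4class{MeasurementSetup} listing all candidate
#'   groups
#' @param costParams see \code{\link{makeCostParams}}
#' @param nCle number of parallel carbon labeling experiments
#' @param objectives \code{"3D"} (DoF, D, -cost) or \code{"5D"} (DoF, D, A,
#'   E, -cost)
#' @param tau1,tau2 identifiability thresholds
#' @param prefer free net fluxes preferred in the parametrization
#' @return a \linkS4class{DesignContext}
#' @export
designContext <- function(network, refFree, species, setup, costParams,
                          nCle = 1L, objectives = c("3D", "5D"),
                          tau1 = 1e-9, tau2 = 1e12, prefer = character()) {
  objectives <- match.arg(objectives)
  param <- stoichiometricAnalysis(network, prefer = prefer)
  system <- buildCumomerCascade(network)
  ctx <- new("DesignContext", network = network, param = param,
             system = system, refFree = refFree, species = species,
             setup = setup, costParams = costParams, nCle = as.integer(nCle),
             criteria = list(tau1 = tau1, tau2 = tau2),
             objectives = objectives)
  # reference point must be expandable
  expandFluxState(param, refFree)
  ctx
}

#' Box bounds of the raw design vector
#'
#' The raw (relaxed, continuous) design vector concatenates, per labeling
#' experiment, the tracer fraction block (one gene per species, in [0,1])
#' and the replicate block (one gene per measurement group, in
#' [0, nRepMax]).
#'
#' @param context a \linkS4class{DesignContext}
#' @return list with \code{lower}, \code{upper} (named numeric)
#' @export
designBounds <- function(context) {
  ns <- nrow(context@species)
  gn <- vapply(context@setup@groups, function(g) g@name, "")
  nm <- unlist(lapply(seq_len(context@nCle), function(cle)
    c(paste0("cle", cle, ".frac.", context@species$name),
      paste0("cle", cle, ".rep.", gn))))
  lower <- stats::setNames(rep(0, length(nm)), nm)
  upper <- stats::setNames(rep(1, length(nm)), nm)
  upper[grep("\\.rep\\.", nm)] <- context@setup@nRepMax
  list(lower = lower, upper = upper)
}

#' Repair and decode a raw design vector
#'
#' Clips the raw vector into its box, renormalizes each experiment's tracer
#' fraction block onto the unit simplex (an all-zero block is repaired to
#' the uniform mixture) and rounds replicate genes to the nearest integer,
#' yielding an executable design.  Optionally snaps fractions and replicate
#' counts to discrete grids (used by the exhaustive-enumeration oracle).
#'
#' @param raw numeric vector matching \code{\link{designBounds}}
#' @param context a \linkS4class{DesignContext}
#' @param fractionGrid optional numeric grid; fraction genes are snapped to
#'   the nearest grid value before normalization
#' @param repLevels optional integer levels replicate counts are snapped to
#' @return list with one element per experiment: \code{fractions} (named,
#'   simplex) and \code{nRep} (named integer)
#' @export
repairAndDecode <- function(raw, context, fractionGrid = NULL, repLevels = NULL) {
  bb <- designBounds(context)
  # fraction genes are only floored at 0 (normalization absorbs any scale);
  # replicate genes are clipped into [0, nRepMax]
  raw <- pmax(raw, bb$lower)
  isRep <- grepl("\\.rep\\.", names(bb$lower))
  raw[isRep] <- pmin(raw[isRep], bb$upper[isRep])
  ns <- nrow(context@species)
  gn <- vapply(context@setup@groups, function(g) g@name, "")
  ng <- length(gn)
  blk <- ns + ng
  lapply(seq_len(context@nCle), function(cle) {
    off <- (cle - 1L) * blk
    fr <- raw[off + seq_len(ns)]
    if (!is.null(fractionGrid))
      fr <- vapply(fr, function(x) fractionGrid[which.min(abs(fractionGrid - x))], 0)
    if (sum(fr) <= 0) fr <- rep(1, ns)    # repaired to uniform mixture
    fr <- fr / sum(fr)
    names(fr) <- context@species$name
    rp <- as.integer(floor(raw[off + ns + seq_len(ng)] + 0.5))
    if (!is.null(repLevels))
      rp <- vapply(rp, function(x) repLevels[which.min(abs(repLevels - x))], 1L)
    rp <- pmin(pmax(rp, 0L), context@setup@nRepMax)
    names(rp) <- gn
    list(fractions = fr, nRep = rp)
  })
}

#' Encode a design back into a raw vector
#'
#' @param design decoded design (list per experiment)
#' @param context a \linkS4class{DesignContext}
#' @return numeric raw vector
#' @export
encodeDesign <- function(design, context) {
  unlist(lapply(design, function(d) c(unname(d$fractions), unname(d$nRep))))
}

#' Evaluate a design to its objective vector
#'
#' Runs the full evaluation loop for one (integer-replicate) design: solve
#' the labeling state per experiment, predict the evaluated measurement
#' groups, apply the error models at the chosen replicate counts, assemble
#' the measurement Jacobian with respect to the free fluxes, run the
#' iterative freezing procedure, compute the optimality criteria and the
#' total cost.  A degenerate design (no evaluated measurements, or a
#' labeling solver failure) is scored with DoF 0 and zero information but
#' keeps its actual cost, so it is retained in the population and dominated
#' naturally.
#'
#' @param design decoded design, see \code{\link{repairAndDecode}}
#' @param context a \linkS4class{DesignContext}
#' @return list with \code{objectives} (named numeric, all-maximize
#'   orientation), \code{p}, \code{frozen}, \code{criteria}, \code{cost}
#'   (breakdown from \code{\link{totalCost}}) and the \code{design}
#' @export
evaluateDesign <- function(design, context) {
  if (length(design) != context@nCle)
    .stopf("design has %d experiment(s), context expects %d",
           length(design), context@nCle)
  cles <- lapply(design, function(d) {
    mix <- tracerMixture(context@species, d$fractions)
    list(mixture = mix, setup = setReplicates(context@setup, d$nRep))
  })
  cost <- totalCost(cles, context@costParams)
  freeSet <- freeFluxes(context@param)

  degenerate <- function() {
    crit <- list(dof = 0L, D = NA_real_, A = NA_real_, E = NA_real_,
                 info = list(D = 0, A = 0, E = 0))
    list(objectives = .objectiveVector(crit, cost$total, context@objectives),
         p = 0L, frozen = freeSet, criteria = crit, cost = cost,
         design = design)
  }

  blocks <- tryCatch({
    lapply(cles, function(cl) {
      pred <- predictMeasurements(
        solveLabeling(context@system,
                      expandFluxState(context@param, context@refFree,
                                      strict = FALSE),
                      cl$mixture),
        cl$setup)
      if (!nrow(pred)) return(NULL)
      pred <- evaluateErrorModel(pred, cl$setup@errorModels)
      J <- labelingJacobian(context@system, context@param, context@refFree,
                            cl$mixture, cl$setup, freeSet = freeSet)
      list(J = J, sd = pred$sd)
    })
  }, error = function(e) e)
  if (inherits(blocks, "error")) return(degenerate())
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) return(degenerate())

  J <- do.call(rbind, lapply(blocks, `[[`, "J"))
  sd <- unlist(lapply(blocks, `[[`, "sd"))
  fr <- iterativeFreeze(J, sd, context@criteria$tau1, context@criteria$tau2)
  if (fr@p == 0L) return(degenerate())
  crit <- evaluateCriteria(fr)
  list(objectives = .objectiveVector(crit, cost$total, context@objectives),
       p = fr@p, frozen = fr@frozen, criteria = crit, cost = cost,
       design = design, fim = fr)
}

.objectiveVector <- function(crit, totalCost, objectives) {
  if (objectives == "3D")
    c(DoF = as.numeric(crit$dof), D = crit$info$D, negCost = -totalCost)
  else
    c(DoF = as.numeric(crit$dof), D = crit$info$D, A = crit$info$A,
      E = crit$info$E, negCost = -totalCost)
}
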