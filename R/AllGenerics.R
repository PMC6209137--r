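#' Accessors and show methods
#'
#' Standard accessors for the package's S4 containers.
#'
#' @param object an S4 object from this package
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("dof", function(object) standardGeneric("dof"))
#' @rdname accessors
#' @export
setGeneric("freeFluxes", function(object) standardGeneric("freeFluxes"))
#' @rdname accessors
#' @export
setGeneric("netFluxes", function(object) standardGeneric("netFluxes"))
#' @rdname accessors
#' @export
setGeneric("exchangeFluxes", function(object) standardGeneric("exchangeFluxes"))
#' @rdname accessors
#' @export
setGeneric("forwardFluxes", function(object) standardGeneric("forwardFluxes"))
#' @rdname accessors
#' @export
setGeneric("backwardFluxes", function(object) standardGeneric("backwardFluxes"))
#' @rdname accessors
#' @export
setGeneric("isotopomerFractions", function(object) standardGeneric("isotopomerFractions"))
#' @rdname accessors
#' @export
setGeneric("cumomerValues", function(object) standardGeneric("cumomerValues"))
#' @rdname accessors
#' @export
setGeneric("archiveEntries", function(object) standardGeneric("archiveEntries"))
#' @rdname accessors
#' @export
setGeneric("archiveObjectives", function(object) standardGeneric("archiveObjectives"))

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicNetwork", function(object) object@metabolites)
#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicNetwork", function(object) object@reactions)
#' @rdname accessors
#' @export
setMethod("dof", "FluxParametrization", function(object) object@dof)
#' @rdname accessors
#' @export
setMethod("freeFluxes", "FluxParametrization", function(object)
  c(object@freeNet, if (length(object@freeExchange))
      paste0(object@freeExchange, ".xch")))
#' @rdname accessors
#' @export
setMethod("netFluxes", "FluxState", function(object) object@net)
#' @rdname accessors
#' @export
setMethod("exchangeFluxes", "FluxState", function(object) object@exchange)
#' @rdname accessors
#' @export
setMethod("forwardFluxes", "FluxState", function(object) {
  xch <- object@exchange
  fwd <- pmax(object@net, 0)
  fwd[names(xch)] <- fwd[names(xch)] + xch
  fwd
})
#' @rdname accessors
#' @export
setMethod("backwardFluxes", "FluxState", function(object) {
  bwd <- pmax(-object@net, 0)
  xch <- object@exchange
  bwd[names(xch)] <- bwd[names(xch)] + xch
  bwd
})
#' @rdname accessors
#' @export
setMethod("isotopomerFractions", "LabelingState", function(object) object@fractions)
#' @rdname accessors
#' @export
setMethod("cumomerValues", "LabelingState", function(object) object@cumomers)
#' @rdname accessors
#' @export
setMethod("archiveEntries", "ParetoArchive", function(object) object@entries)
#' @rdname accessors
#' @export
setMethod("archiveObjectives", "ParetoArchive", function(object) {
  if (!length(object@entries)) return(matrix(numeric(), 0, 0))
  do.call(rbind, lapply(object@entries, function(e) e$objectives))
})

setMethod("show", "MetabolicNetwork", function(object) {
  met <- object@metabolites
  cat(sprintf("MetabolicNetwork '%s': %d metabolites (%d balanced), %d reactions (%d reversible)\n",
              object@name, nrow(met), sum(met$role == "balanced"),
              length(object@reactions),
              sum(vapply(object@reactions, `[[`, TRUE, "reversible"))))
  if (length(object@rates))
    cat("  measured rates:", paste(sprintf("%s=%g", names(object@rates), object@rates),
                                   collapse = ", "), "\n")
})

setMethod("show", "FluxParametrization", function(object) {
  cat(sprintf("FluxParametrization: %d reactions, rank %d, dof %d\n",
              length(object@particular), object@rank, object@dof))
  cat("  free net fluxes:", if (length(object@freeNet))
    paste(object@freeNet, collapse = ", ") else "(none)", "\n")
  cat("  free exchange fluxes:", if (length(object@freeExchange))
    paste(object@freeExchange, collapse = ", ") else "(none)", "\n")
})

setMethod("show", "FluxState", function(object) {
  cat("FluxState\n  net:     ",
      paste(sprintf("%s=%g", names(object@net), round(object@net, 6)), collapse = ", "), "\n")
  if (length(object@exchange))
    cat("  exchange:",
        paste(sprintf("%s=%g", names(object@exchange), round(object@exchange, 6)),
              collapse = ", "), "\n")
})

setMethod("show", "CumomerSystem", function(object) {
  cat(sprintf("CumomerSystem: %d balanced pools, max weight %d\n",
              length(object@pools), object@maxWeight))
  cnt <- table(factor(object@unknowns$weight, levels = seq_len(object@maxWeight)))
  cat("  unknowns per level:", paste(sprintf("w%d:%d", seq_len(object@maxWeight), cnt),
                                     collapse = ", "), "\n")
})

setMethod("show", "LabelingState", function(object) {
  cat(sprintf("LabelingState over %d pools: %s\n", length(object@pools),
              paste(object@pools, collapse = ", ")))
})

setMethod("show", "MeasurementSetup", function(object) {
  cat(sprintf("MeasurementSetup: %d groups on device(s) %s\n",
              length(object@groups),
              paste(unique(vapply(object@groups, function(g) g@device, "")),
                    collapse = ", ")))
  cat("  replicates:", paste(sprintf("%s=%d", names(object@nRep), object@nRep),
                             collapse = ", "), "\n")
})

setMethod("show", "FimResult", function(object) {
  cat(sprintf("FimResult: p = %d identifiable free flux(es)", object@p))
  if (length(object@frozen))
    cat(sprintf(", frozen: %s", paste(object@frozen, collapse = ", ")))
  cat("\n")
  if (object@p > 0)
    cat(sprintf("  lambda_min = %.3g, condition = %.3g\n",
                object@lambdaMin, object@condition))
})

setMethod("show", "TracerMixture", function(object) {
  fr <- object@fractions[object@fractions > 0]
  cat("TracerMixture:", paste(sprintf("%.1f%% %s", 100 * fr, names(fr)),
                              collapse = ", "), "\n")
})

setMethod("show", "DesignContext", function(object) {
  cat(sprintf("DesignContext: %s objectives, %d CLE(s), %d tracer species, %d groups\n",
              object@objectives, object@nCle, nrow(object@species),
              length(object@setup@groups)))
})

setMethod("show", "ParetoArchive", function(object) {
  cat(sprintf("ParetoArchive: %d non-dominated design(s), capacity %d\n",
              length(object@entries), object@capacity))
  if (length(object@entries)) {
    obj <- archiveObjectives(object)
    cat("  ideal point:", paste(sprintf("%s=%.4g", colnames(obj),
                                        apply(obj, 2, max)), collapse = ", "), "\n")
    cat("  nadir point:", paste(sprintf("%s=%.4g", colnames(obj),
                                        apply(obj, 2, min)), collapse = ", "), "\n")
  }
})
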