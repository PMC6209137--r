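#' @import methods
NULL

#' Atom-mapped metabolic network
#'
#' Container for a steady-state metabolic network: metabolite pools with
#' carbon counts and roles, reactions with stoichiometry and per-carbon atom
#' transitions, measured extracellular rates (equality constraints), linear
#' inequality constraints and net-flux bounds.
#'
#' @slot metabolites data.frame with columns \code{name}, \code{carbons},
#'   \code{role} (one of \code{"balanced"}, \code{"input"}, \code{"output"}).
#'   Balanced pools are mass-balanced; input pools feed tracer label into the
#'   network; output pools are unbalanced sinks.
#' @slot reactions list of parsed reactions (see \code{\link{loadNetwork}}).
#' @slot rates named numeric; measured extracellular rates, entered as
#'   equality rows appended to the stoichiometric system.
#' @slot ineq list with matrix \code{A} (columns named by reaction) and
#'   vector \code{b}, encoding \code{A v <= b} on net fluxes.
#' @slot bounds data.frame with columns \code{reaction}, \code{lower},
#'   \code{upper} for net fluxes.
#' @slot name character scalar network label.
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
  representation(
    metabolites = "data.frame",
    reactions   = "list",
    rates       = "numeric",
    ineq        = "list",
    bounds      = "data.frame",
    name        = "character"
  )
)

.validMetabolicNetwork <- function(object) {
  msg <- character()
  met <- object@metabolites
  if (anyDuplicated(met$name))
    msg <- c(msg, sprintf("duplicate metabolite name(s): %s",
                          paste(unique(met$name[duplicated(met$name)]), collapse = ", ")))
  if (any(met$carbons < 0))
    msg <- c(msg, "metabolite carbon counts must be >= 0")
  if (!all(met$role %in% c("balanced", "input", "output")))
    msg <- c(msg, "metabolite role must be balanced/input/output")
  rn <- vapply(object@reactions, `[[`, "", "name")
  if (anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicate reaction name(s): %s",
                          paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  for (rx in object@reactions) {
    for (side in c("educts", "products")) {
      for (p in rx[[side]]) {
        if (!p$met %in% met$name) {
          msg <- c(msg, sprintf("reaction '%s' references undeclared metabolite '%s'",
                                rx$name, p$met))
          next
        }
        nC <- met$carbons[match(p$met, met$name)]
        if (!is.null(p$labels)) {
          if (length(p$labels) != nC)
            msg <- c(msg, sprintf(
              "reaction '%s': atom string for '%s' has %d carbon(s) but the metabolite has %d",
              rx$name, p$met, length(p$labels), nC))
          if (p$coef != 1)
            msg <- c(msg, sprintf(
              "reaction '%s': carbon-carrying metabolite '%s' must have coefficient 1",
              rx$name, p$met))
        }
        if (p$coef <= 0)
          msg <- c(msg, sprintf("reaction '%s': non-positive coefficient for '%s'",
                                rx$name, p$met))
      }
      carriers <- vapply(rx[[side]], function(p) if (is.null(p$labels)) NA_character_ else p$met, "")
      carriers <- carriers[!is.na(carriers)]
      if (anyDuplicated(carriers))
        msg <- c(msg, sprintf(
          "reaction '%s': carbon-carrying metabolite appears more than once on one side", rx$name))
    }
    eLab <- unlist(lapply(rx$educts, `[[`, "labels"))
    pLab <- unlist(lapply(rx$products, `[[`, "labels"))
    if (length(eLab) || length(pLab)) {
      if (anyDuplicated(eLab) || anyDuplicated(pLab) ||
          length(eLab) != length(pLab) || !setequal(eLab, pLab))
        msg <- c(msg, sprintf(
          "reaction '%s': atom map is not a bijection between educt and product carbons",
          rx$name))
    }
  }
  used <- unique(unlist(lapply(object@reactions, function(rx)
    c(vapply(rx$educts, `[[`, "", "met"), vapply(rx$products, `[[`, "", "met")))))
  bal <- met$name[met$role == "balanced"]
  orphan <- setdiff(bal, used)
  if (length(orphan))
    msg <- c(msg, sprintf("balanced metabolite(s) not used in any reaction: %s",
                          paste(orphan, collapse = ", ")))
  if (length(object@rates) && !all(names(object@rates) %in% rn))
    msg <- c(msg, "rates reference unknown reaction(s)")
  if (length(msg)) msg else TRUE
}
setValidity("MetabolicNetwork", .validMetabolicNetwork)

#' Free-flux parametrization of a network
#'
#' Parametrizes all solutions of the flux equality system (metabolite
#' balances plus measured-rate rows) as \code{v = particular + basis \%*\% w},
#' where \code{w} are the values of the free net fluxes themselves.  Exchange
#' fluxes of reversible reactions are additional free coordinates that do not
#' enter the stoichiometry.
#'
#' @slot freeNet character; names of free net fluxes.
#' @slot freeExchange character; reversible reactions whose exchange flux is a
#'   free coordinate (suffixed \code{".xch"} in free-flux vectors).
#' @slot particular named numeric; a particular net-flux solution with free
#'   entries zero.
#' @slot basis matrix (reactions x free net fluxes); kernel basis such that
#'   \code{basis[freeNet, ] == I}.
#' @slot dof integer; \code{dim(v) - rank(S)} of the equality system.
#' @slot rank integer; rank of the equality system.
#' @slot network the parametrized \linkS4class{MetabolicNetwork}.
#' @exportClass FluxParametrization
setClass("FluxParametrization",
  representation(
    freeNet      = "character",
    freeExchange = "character",
    particular   = "numeric",
    basis        = "matrix",
    dof          = "integer",
    rank         = "integer",
    network      = "MetabolicNetwork"
  )
)

#' Net/exchange flux state
#'
#' @slot net named numeric; signed net rate per reaction.
#' @slot exchange named numeric; nonnegative exchange rate per reversible
#'   reaction.  Forward and backward rates derive as
#'   \code{fwd = xch + max(net, 0)}, \code{bwd = xch + max(-net, 0)}.
#' @exportClass FluxState
setClass("FluxState",
  representation(net = "numeric", exchange = "numeric"),
  validity = function(object) {
    if (length(object@exchange) && any(object@exchange < -1e-12))
      "exchange fluxes must be nonnegative" else TRUE
  }
)

#' Cumomer cascade of a network
#'
#' Weight-ordered linear systems for the steady-state labeling balance.  The
#' level-w system involves only weight-w cumomers of balanced pools; its
#' right-hand side collects products of lower-weight and input-pool cumomers,
#' so the cascade is solved level by level.
#'
#' @slot network the underlying \linkS4class{MetabolicNetwork}.
#' @slot pools character; balanced pools carrying carbon (the unknowns).
#' @slot inputPools character; input pools whose cumomers come from the
#'   tracer mixture.
#' @slot unknowns data.frame with columns \code{pool}, \code{mask},
#'   \code{weight}, \code{level.index}; one row per cumomer unknown.
#' @slot levels list; per weight level, assembly terms (built once).
#' @slot fluxTable data.frame of directed fluxes (reaction, direction).
#' @slot consumers list; per pool, indices into \code{fluxTable} of directed
#'   fluxes consuming the pool.
#' @slot maxWeight integer.
#' @exportClass CumomerSystem
setClass("CumomerSystem",
  representation(
    network    = "MetabolicNetwork",
    pools      = "character",
    inputPools = "character",
    unknowns   = "data.frame",
    levels     = "list",
    fluxTable  = "data.frame",
    consumers  = "list",
    maxWeight  = "integer"
  )
)

#' Steady-state labeling state
#'
#' Isotopomer fractions (and cumomer values) per pool.  Isotopomer vectors
#' are indexed by bitmask + 1 where bit i-1 set means carbon i is labeled.
#'
#' @slot fractions named list of numeric vectors (length 2^n per pool).
#' @slot cumomers named list of numeric vectors (same indexing; entry for
#'   mask m is the cumulative fraction labeled at all carbons of m).
#' @slot pools character; pools present (balanced pools plus input pools).
#' @exportClass LabelingState
setClass("LabelingState",
  representation(fractions = "list", cumomers = "list", pools = "character"),
  validity = function(object) {
    msg <- character()
    for (p in names(object@fractions)) {
      x <- object@fractions[[p]]
      if (abs(sum(x) - 1) > 1e-6)
        msg <- c(msg, sprintf("isotopomer fractions of '%s' do not sum to 1", p))
      if (any(x < -1e-8) || any(x > 1 + 1e-8))
        msg <- c(msg, sprintf("isotopomer fractions of '%s' outside [0,1]", p))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Measurement group
#'
#' A set of jointly acquired observations of one pool on one device: a
#' nonnegative linear map over the pool's isotopomer coordinates.
#'
#' @slot device character; device identifier (keys the error model).
#' @slot name character; group identifier.
#' @slot pool character; observed pool.
#' @slot rows matrix (observations x isotopomers of the pool).
#' @slot nPeaks integer; peaks evaluated per acquisition of this group
#'   (enters the analytical cost model).
#' @slot normalize logical; scale the group to sum 1 before comparison
#'   (percentage-scale readout, e.g. mass isotopomer distributions).
#' @exportClass MeasurementGroup
setClass("MeasurementGroup",
  representation(device = "character", name = "character", pool = "character",
                 rows = "matrix", nPeaks = "integer", normalize = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@rows < 0)) msg <- c(msg, "measurement rows must be nonnegative")
    if (object@nPeaks < 1) msg <- c(msg, "nPeaks must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Linear measurement error model
#'
#' Standard deviation model \code{sigma = a(n_rep) * (b1 * eta + b2)} with a
#' replicate scaling factor \code{a(n)} that is >= 1, non-increasing and
#' tends to 1 for many repetitions.
#'
#' @slot device character.
#' @slot b1 numeric; slope of sigma versus measured value (>= 0).
#' @slot b2 numeric; intercept (> 0).
#' @slot repScaling function of the replicate count.
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(device = "character", b1 = "numeric", b2 = "numeric",
                 repScaling = "function"),
  validity = function(object) {
    msg <- character()
    if (object@b1 < 0) msg <- c(msg, "b1 must be >= 0")
    if (object@b2 <= 0) msg <- c(msg, "b2 must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Measurement setup
#'
#' Ordered measurement groups with per-group replicate counts (0 = group not
#' evaluated) and per-device error models.
#'
#' @slot groups list of \linkS4class{MeasurementGroup}.
#' @slot nRep named integer; replicates per group, in \code{[0, nRepMax]}.
#' @slot errorModels named list of \linkS4class{ErrorModel}, keyed by device.
#' @slot nRepMax integer; maximum replicates (bounded by the number of
#'   samples taken per experiment).
#' @exportClass MeasurementSetup
setClass("MeasurementSetup",
  representation(groups = "list", nRep = "integer", errorModels = "list",
                 nRepMax = "integer"),
  validity = function(object) {
    msg <- character()
    gn <- vapply(object@groups, function(g) g@name, "")
    if (anyDuplicated(gn)) msg <- c(msg, "duplicate group names")
    if (!identical(sort(names(object@nRep)), sort(gn)))
      msg <- c(msg, "nRep names must match group names")
    if (any(object@nRep < 0) || any(object@nRep > object@nRepMax))
      msg <- c(msg, "replicate counts must lie in [0, nRepMax]")
    dv <- unique(vapply(object@groups, function(g) g@device, ""))
    if (!all(dv %in% names(object@errorModels)))
      msg <- c(msg, sprintf("missing error model for device(s): %s",
                            paste(setdiff(dv, names(object@errorModels)), collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' Fisher information result
#'
#' FIM and flux covariance on the retained (statistically identifiable) free
#' fluxes after the iterative freezing procedure.
#'
#' @slot fim symmetric PSD matrix on the retained free fluxes.
#' @slot cov its inverse.
#' @slot p integer; effective dimension (number of retained free fluxes).
#' @slot frozen character; free fluxes removed, in removal order.
#' @slot retained character; free fluxes kept.
#' @slot lambdaMin numeric; smallest eigenvalue of the retained FIM.
#' @slot condition numeric; condition number of the retained FIM.
#' @exportClass FimResult
setClass("FimResult",
  representation(fim = "matrix", cov = "matrix", p = "integer",
                 frozen = "character", retained = "character",
                 lambdaMin = "numeric", condition = "numeric")
)

#' Tracer mixture
#'
#' Tracer species (with labeling patterns, purities and prices) together with
#' mixture fractions on the unit simplex.
#'
#' @slot species data.frame with columns \code{name}, \code{pool} (input
#'   pool), \code{pattern} (string of 0/1 per carbon), \code{purity} in
#'   [0,1], \code{price} (money per gram).
#' @slot fractions named numeric; per-species proportions, summing to 1 per
#'   input pool.
#' @exportClass TracerMixture
setClass("TracerMixture",
  representation(species = "data.frame", fractions = "numeric"),
  validity = function(object) {
    msg <- character()
    sp <- object@species
    fr <- object@fractions
    if (!all(names(fr) %in% sp$name))
      msg <- c(msg, "fractions reference unknown species")
    if (any(fr < -1e-9) || any(fr > 1 + 1e-9))
      msg <- c(msg, "fractions must lie in [0,1]")
    if (any(sp$purity < 0 | sp$purity > 1)) msg <- c(msg, "purity must lie in [0,1]")
    if (any(sp$price < 0)) msg <- c(msg, "prices must be >= 0")
    for (pool in unique(sp$pool[sp$name %in% names(fr)])) {
      s <- sum(fr[names(fr) %in% sp$name[sp$pool == pool]])
      if (abs(s - 1) > 1e-6)
        msg <- c(msg, sprintf("fractions for input pool '%s' sum to %g, not 1", pool, s))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Design evaluation context
#'
#' Everything constant during a design search: network and parametrization,
#' reference free fluxes, tracer species, measurement groups and error
#' models, cost parameters, number of parallel labeling experiments, the
#' identifiability thresholds and the objective set.
#'
#' @slot network \linkS4class{MetabolicNetwork}.
#' @slot param \linkS4class{FluxParametrization}.
#' @slot system \linkS4class{CumomerSystem} (cached cascade).
#' @slot refFree named numeric; reference free fluxes (net names plus
#'   \code{".xch"}-suffixed exchange names).
#' @slot species data.frame of tracer species (see
#'   \linkS4class{TracerMixture}).
#' @slot setup \linkS4class{MeasurementSetup} holding all candidate groups
#'   (its nRep acts as the per-group maximum pattern; actual replicates come
#'   from the design vector).
#' @slot costParams list of cost parameters (see \code{\link{makeCostParams}}).
#' @slot nCle integer; number of parallel carbon labeling experiments.
#' @slot criteria list with \code{tau1} (minimal eigenvalue threshold,
#'   relative to the largest) and \code{tau2} (condition bound).
#' @slot objectives character; \code{"3D"} (DoF, D, -cost) or \code{"5D"}
#'   (DoF, D, A, E, -cost).
#' @exportClass DesignContext
setClass("DesignContext",
  representation(
    network = "MetabolicNetwork", param = "FluxParametrization",
    system = "CumomerSystem", refFree = "numeric", species = "data.frame",
    setup = "MeasurementSetup", costParams = "list", nCle = "integer",
    criteria = "list", objectives = "character"
  ),
  validity = function(object) {
    if (!object@objectives %in% c("3D", "5D")) "objectives must be '3D' or '5D'"
    else TRUE
  }
)

#' Pareto archive
#'
#' Bounded archive of mutually non-dominated (design, objective-vector)
#' pairs, truncated by crowding distance.
#'
#' @slot entries list; each entry has \code{design}, \code{objectives}
#'   (named, all-maximize orientation), \code{p}, \code{frozen},
#'   \code{report} (criteria and cost breakdown).
#' @slot capacity integer.
#' @slot meta list; seed, swarm parameters, iteration log.
#' @exportClass ParetoArchive
setClass("ParetoArchive",
  representation(entries = "list", capacity = "integer", meta = "list")
)
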