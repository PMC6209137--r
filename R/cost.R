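#' Cost parameters
#'
#' Assembles the parameters of the experimental and analytical cost model.
#' The default profile describes a scale-down chemostat labeling experiment:
#' 250 mL working volume at 20 g/L substrate (5 g substrate per experiment),
#' up to 10 technical replicates per sample, with glucose tracer prices
#' ranging from 0.30 EUR/g (unlabeled) to 1293.00 EUR/g ([5-13C]).
#' Instrument depreciation is assumed folded into the per-sample price.
#'
#' @param profile currently \code{"default"}
#' @param overrides named list; any parameter may be overridden
#' @return list with elements \code{tracerPrices} (EUR/g, named),
#'   \code{substrateMass} (g per experiment), \code{Cexp} (fixed setup cost,
#'   EUR), \code{Cwork} (EUR/h), \code{tWorkExp} (h for setup/control),
#'   \code{Csample} (EUR per acquired sample), \code{nSamples} (samples per
#'   experiment, also the replicate cap), \code{tWorkAna} (h per peak
#'   evaluation)
#' @export
makeCostParams <- function(profile = "default", overrides = list()) {
  if (!identical(profile, "default"))
    .stopf("unknown cost profile '%s' (available: default)", profile)
  p <- list(
    tracerPrices = c(
      "U"        = 0.30,    # unlabeled glucose, printed sales price
      "1-13C"    = 155.00,
      "2-13C"    = 920.00,
      "3-13C"    = 1100.00,
      "4-13C"    = 1250.00,
      "5-13C"    = 1293.00, # most expensive singly labeled species
      "6-13C"    = 310.00,
      "1,2-13C"  = 630.00,
      "1,6-13C"  = 980.00,
      "U-13C"    = 215.00),
    substrateMass = 5,     # g: 250 mL x 20 g/L
    Cexp = 100,            # EUR, consumables and media
    Cwork = 30,            # EUR/h
    tWorkExp = 2,          # h
    Csample = 50,          # EUR per sample acquisition
    nSamples = 10L,        # samples per CLE; caps replicate counts
    tWorkAna = 0.05        # h per peak evaluation
  )
  for (k in names(overrides)) {
    if (!k %in% names(p)) .stopf("unknown cost parameter '%s'", k)
    p[[k]] <- overrides[[k]]
  }
  stopifnot(all(vapply(p[-1], function(x) all(x >= 0), TRUE)),
            all(p$tracerPrices >= 0))
  p
}

#' Experimental cost of one labeling experiment
#'
#' Substrate cost (mixture-weighted price times substrate mass) plus the
#' fixed setup offset and the wages for setting up and controlling the
#' experiment.
#'
#' @param mixture a \linkS4class{TracerMixture}; species prices are taken
#'   from its species table
#' @param params cost parameters, see \code{\link{makeCostParams}}
#' @return money (same unit as the prices)
#' @export
cleCost <- function(mixture, params) {
  sp <- mixture@species
  fr <- mixture@fractions
  bad <- setdiff(names(fr), sp$name)
  if (length(bad)) .stopf("mixture references unknown species: %s",
                          paste(bad, collapse = ", "))
  prices <- sp$price[match(names(fr), sp$name)]
  params$substrateMass * sum(fr * prices) +
    params$Cexp + params$tWorkExp * params$Cwork
}

#' Analytical cost of one labeling experiment
#'
#' Sample acquisition (\code{nSamples * Csample}) plus peak evaluation:
#' the replicate-weighted peak count of all evaluated groups times the
#' per-peak evaluation time and the wage rate.  Groups with zero replicates
#' contribute nothing.
#'
#' @param setup a \linkS4class{MeasurementSetup}
#' @param params cost parameters
#' @return money
#' @export
analyticalCost <- function(setup, params) {
  nRep <- setup@nRep
  if (any(nRep > params$nSamples))
    .stopf("replicate count exceeds the %d samples taken per experiment",
           params$nSamples)
  peaks <- vapply(setup@groups, function(g) g@nPeaks, 1L)
  names(peaks) <- vapply(setup@groups, function(g) g@name, "")
  params$nSamples * params$Csample +
    sum(nRep[names(peaks)] * peaks) * params$tWorkAna * params$Cwork
}

#' Total cost of a series of labeling experiments
#'
#' @param designs list with one element per experiment, each a list with
#'   \code{mixture} (a \linkS4class{TracerMixture}) and \code{setup} (a
#'   \linkS4class{MeasurementSetup})
#' @param params cost parameters
#' @return list with \code{experimental}, \code{analytical}, \code{total}
#'   and a per-experiment breakdown table
#' @export
totalCost <- function(designs, params) {
  if (!length(designs)) .stopf("need at least one experiment")
  exps <- vapply(designs, function(d) cleCost(d$mixture, params), 0)
  anas <- vapply(designs, function(d) analyticalCost(d$setup, params), 0)
  list(experimental = sum(exps), analytical = sum(anas),
       total = sum(exps) + sum(anas),
       breakdown = data.frame(cle = seq_along(designs),
                              experimental = exps, analytical = anas,
                              total = exps + anas))
}
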