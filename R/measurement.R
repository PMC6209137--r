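#' Construct a measurement group
#'
#' @param device device identifier (keys the error model)
#' @param name group identifier
#' @param pool observed pool
#' @param rows nonnegative matrix (observations x 2^n isotopomers of the
#'   pool); row names label the observations
#' @param nPeaks peaks evaluated per acquisition (defaults to the number of
#'   rows)
#' @param normalize scale the group to sum 1 before comparison
#' @return a \linkS4class{MeasurementGroup}
#' @export
measurementGroup <- function(device, name, pool, rows,
                             nPeaks = nrow(rows), normalize = FALSE) {
  obj <- new("MeasurementGroup", device = device, name = name, pool = pool,
             rows = as.matrix(rows), nPeaks = as.integer(nPeaks),
             normalize = normalize)
  validObject(obj)
  obj
}

#' Construct a linear error model
#'
#' Standard deviation \code{sigma = a(n) * (b1 * eta + b2)}. The default
#' replicate scaling is \code{a(n) = sqrt(n / (n - 1))} for \code{n >= 2}
#' and \code{a(1) = 2}: it is >= 1, non-increasing, and tends to 1 for many
#' repetitions.
#'
#' @param device device identifier
#' @param b1 slope (>= 0)
#' @param b2 intercept (> 0)
#' @param repScaling replicate scaling function a(n)
#' @return an \linkS4class{ErrorModel}
#' @export
errorModel <- function(device, b1, b2,
                       repScaling = function(n) ifelse(n <= 1, 2, sqrt(n / (n - 1)))) {
  obj <- new("ErrorModel", device = device, b1 = b1, b2 = b2,
             repScaling = repScaling)
  validObject(obj)
  obj
}

#' Construct a measurement setup
#'
#' @param groups list of \linkS4class{MeasurementGroup}
#' @param nRep named integer; replicates per group (0 = not evaluated).
#'   Defaults to 1 for every group.
#' @param errorModels list of \linkS4class{ErrorModel} (named by device, or
#'   names are taken from the models)
#' @param nRepMax maximum replicate count (number of samples per experiment)
#' @return a \linkS4class{MeasurementSetup}
#' @export
measurementSetup <- function(groups, nRep = NULL, errorModels, nRepMax = 10L) {
  gn <- vapply(groups, function(g) g@name, "")
  if (is.null(nRep)) nRep <- stats::setNames(rep(1L, length(groups)), gn)
  if (is.null(names(errorModels)))
    names(errorModels) <- vapply(errorModels, function(m) m@device, "")
  obj <- new("MeasurementSetup", groups = groups,
             nRep = stats::setNames(as.integer(nRep), names(nRep)),
             errorModels = errorModels, nRepMax = as.integer(nRepMax))
  validObject(obj)
  obj
}

#' Replace replicate counts of a setup
#'
#' @param setup a \linkS4class{MeasurementSetup}
#' @param nRep named integer over (a subset of) the group names
#' @return the updated setup
#' @export
setReplicates <- function(setup, nRep) {
  setup@nRep[names(nRep)] <- as.integer(nRep)
  validObject(setup)
  setup
}

#' Predict device observations from a labeling state
#'
#' Applies each evaluated group's linear map to the pool's isotopomer
#' fractions; groups with \code{nRep = 0} are excluded; groups flagged
#' \code{normalize} are scaled to sum 1 (percentage-scale readout).
#'
#' @param state a \linkS4class{LabelingState}
#' @param setup a \linkS4class{MeasurementSetup}
#' @return data.frame with one row per observation: \code{group},
#'   \code{device}, \code{label}, \code{value}, \code{nRep}
#' @export
predictMeasurements <- function(state, setup) {
  rows <- list()
  for (g in setup@groups) {
    n <- setup@nRep[[g@name]]
    if (n < 1L) next
    if (!g@pool %in% names(state@fractions))
      .stopf("group '%s' references pool '%s' absent from the labeling state",
             g@name, g@pool)
    x <- state@fractions[[g@pool]]
    if (ncol(g@rows) != length(x))
      .stopf("group '%s': %d columns but pool '%s' has %d isotopomers",
             g@name, ncol(g@rows), g@pool, length(x))
    v <- as.vector(g@rows %*% x)
    if (g@normalize) {
      s <- sum(v)
      if (s <= 1e-12)
        .stopf("group '%s': zero total mass, cannot normalize", g@name)
      v <- v / s
    }
    lab <- rownames(g@rows)
    if (is.null(lab)) lab <- as.character(seq_along(v))
    rows[[length(rows) + 1L]] <- data.frame(
      group = g@name, device = g@device, label = lab, value = v,
      nRep = n, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(group = character(), device = character(),
                      label = character(), value = numeric(), nRep = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Evaluate the measurement error model
#'
#' Computes per-observation standard deviations
#' \code{sigma = a(nRep) * (b1 * eta + b2)} and appends them (with the
#' diagonal covariance \code{sigma^2}) to a prediction table.
#'
#' @param values prediction table from \code{\link{predictMeasurements}}
#' @param models named list of \linkS4class{ErrorModel} keyed by device (a
#'   single model is applied to all rows)
#' @return the table with columns \code{sd} and \code{var} appended
#' @export
evaluateErrorModel <- function(values, models) {
  if (is(models, "ErrorModel")) models <- stats::setNames(list(models), models@device)
  if (!nrow(values)) {
    values$sd <- numeric(); values$var <- numeric()
    return(values)
  }
  sd <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    m <- models[[values$device[i]]]
    if (is.null(m)) .stopf("no error model for device '%s'", values$device[i])
    if (values$nRep[i] < 1L) .stopf("nRep must be >= 1 for evaluated groups")
    sd[i] <- m@repScaling(values$nRep[i]) * (m@b1 * values$value[i] + m@b2)
  }
  values$sd <- sd
  values$var <- sd^2
  values
}

#' Measurement-group templates for the standard analytical platforms
#'
#' Builds the characteristic measurement groups of one pool for the common
#' platform archetypes: full mass isotopomer distribution (MS), joint
#' precursor/fragment mass pairs (tandem MS), per-carbon positional
#' enrichments (13C-NMR), positional enrichments of protonated carbons
#' (1H-NMR), and a single total-enrichment row (IRMS).
#'
#' @param pool pool name
#' @param nCarbons carbon count of the pool
#' @param device device identifier stamped on the groups
#' @param type one of \code{"MS"}, \code{"MSMS"}, \code{"NMR13C"},
#'   \code{"NMR1H"}, \code{"IRMS"}
#' @param fragment integer positions of the fragment ion (MSMS)
#' @param positions observed carbon positions (NMR; defaults to all for
#'   13C-NMR)
#' @param name group name (default derived from pool and type)
#' @return a \linkS4class{MeasurementGroup}
#' @export
makeDeviceTemplates <- function(pool, nCarbons, device = tolower(type),
                                type = c("MS", "MSMS", "NMR13C", "NMR1H", "IRMS"),
                                fragment = NULL, positions = NULL,
                                name = paste0(pool, "_", tolower(type))) {
  type <- match.arg(type)
  if (nCarbons < 1) .stopf("nCarbons must be >= 1")
  masks <- seq_len(2^nCarbons) - 1L
  w <- .popcount(masks)
  rows <- switch(type,
    MS = {
      R <- t(vapply(0:nCarbons, function(k) as.numeric(w == k), numeric(length(masks))))
      rownames(R) <- paste0("M+", 0:nCarbons)
      R
    },
    MSMS = {
      if (is.null(fragment)) .stopf("MSMS template needs fragment positions")
      if (!all(fragment %in% seq_len(nCarbons)))
        .stopf("fragment positions outside 1..%d", nCarbons)
      if (!all(diff(sort(fragment)) == 1))
        .stopf("fragment positions must be a contiguous carbon range")
      fmask <- .bitsMask(sort(fragment))
      wf <- .popcount(bitwAnd(masks, fmask))
      pairs <- expand.grid(m = 0:length(fragment), M = 0:nCarbons)
      pairs <- pairs[pairs$M >= pairs$m &
                     pairs$M - pairs$m <= nCarbons - length(fragment), ]
      R <- t(mapply(function(M, m) as.numeric(w == M & wf == m),
                    pairs$M, pairs$m))
      rownames(R) <- sprintf("M+%d/m+%d", pairs$M, pairs$m)
      R
    },
    NMR13C = {
      if (is.null(positions)) positions <- seq_len(nCarbons)
      R <- t(vapply(positions, function(j)
        as.numeric(bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L),
        numeric(length(masks))))
      rownames(R) <- paste0("C", positions)
      R
    },
    NMR1H = {
      if (is.null(positions)) .stopf("NMR1H template needs protonated positions")
      R <- t(vapply(positions, function(j)
        as.numeric(bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L),
        numeric(length(masks))))
      rownames(R) <- paste0("H", positions)
      R
    },
    IRMS = {
      R <- matrix(w / nCarbons, 1, length(masks))
      rownames(R) <- "enrichment"
      R
    })
  measurementGroup(device, name, pool, rows,
                   normalize = type %in% c("MS", "MSMS"))
}

#' Read a measurement configuration file
#'
#' YAML document with a \code{devices} map (per device: \code{b1},
#' \code{b2}) and a \code{groups} list (per group: \code{name},
#' \code{device}, \code{pool}, \code{type}, optional \code{fragment},
#' \code{positions}, \code{nRep}); top-level \code{nRepMax}.
#'
#' @param path YAML file
#' @param network the network the groups refer to (for carbon counts)
#' @return a \linkS4class{MeasurementSetup}
#' @export
readMeasurementConfig <- function(path, network) {
  cfg <- yaml::read_yaml(path)
  models <- lapply(names(cfg$devices), function(d) {
    dv <- cfg$devices[[d]]
    if (identical(dv$repScaling, "constant"))
      errorModel(d, dv$b1, dv$b2, repScaling = function(n) rep(1, length(n)))
    else errorModel(d, dv$b1, dv$b2)
  })
  names(models) <- names(cfg$devices)
  nC <- stats::setNames(network@metabolites$carbons, network@metabolites$name)
  groups <- lapply(cfg$groups, function(g) {
    makeDeviceTemplates(g$pool, nC[[g$pool]], device = g$device,
                        type = g$type,
                        fragment = g$fragment, positions = g$positions,
                        name = g$name %||% paste0(g$pool, "_", tolower(g$type)))
  })
  nRep <- vapply(cfg$groups, function(g) as.integer(g$nRep %||% 1L), 1L)
  names(nRep) <- vapply(groups, function(g) g@name, "")
  measurementSetup(groups, nRep, models, nRepMax = cfg$nRepMax %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
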