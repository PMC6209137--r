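#' Pareto dominance (all-maximize orientation)
#'
#' \code{a} dominates \code{b} iff \code{a >= b} componentwise with at least
#' one strict improvement.
#'
#' @param a,b numeric objective vectors over the same objective set
#' @return logical scalar
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    .stopf("objective vectors have different lengths (%d vs %d)",
           length(a), length(b))
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    .stopf("objective vectors have different objective sets")
  all(a >= b) && any(a > b)
}

#' Non-dominated subset of a set of objective vectors
#'
#' @param points numeric matrix, one row per point (all-maximize)
#' @return integer indices of the non-dominated rows, in stable order
#' @export
paretoFilter <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(integer())
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (dominates(points[j, ], points[i, ])) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

#' Crowding distance of points in objective space
#'
#' Boundary points get infinite distance and are never truncated.
#'
#' @param points numeric matrix, one row per point
#' @return numeric vector of distances
#' @export
crowdingDistance <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (j in seq_len(ncol(points))) {
    o <- order(points[, j])
    rng <- points[o[n], j] - points[o[1], j]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (points[o[3:n], j] - points[o[1:(n - 2)], j]) / rng
  }
  d
}

.archiveAdd <- function(entries, entry, capacity) {
  objs <- lapply(entries, `[[`, "objectives")
  # rejected if dominated by (or equal to) an archive member
  for (o in objs)
    if (dominates(o, entry$objectives) || isTRUE(all(o == entry$objectives)))
      return(entries)
  keep <- !vapply(objs, function(o) dominates(entry$objectives, o), TRUE)
  entries <- c(entries[keep], list(entry))
  if (length(entries) > capacity) {
    M <- do.call(rbind, lapply(entries, `[[`, "objectives"))
    cd <- crowdingDistance(M)
    entries <- entries[-which.min(cd)]
  }
  entries
}

#' Default swarm parameters
#'
#' Speed-constrained multi-objective PSO settings: swarm of 100 particles,
#' 250 iterations, archive capacity 100, polynomial mutation applied to 15\%
#' of the particles with distribution index 20, velocity constriction from
#' acceleration coefficients drawn in [1.5, 2.5], inertia 0.1, velocities
#' clamped to half the variable range.
#'
#' @param swarmSize,maxIter,archiveCapacity,mutationProb,mutationIndex,seed
#'   overrides of the defaults
#' @return list of parameters
#' @export
swarmParams <- function(swarmSize = 100L, maxIter = 250L,
                        archiveCapacity = 100L, mutationProb = 0.15,
                        mutationIndex = 20, seed = 1L) {
  stopifnot(swarmSize > 0, maxIter > 0, archiveCapacity > 0,
            mutationProb >= 0, mutationProb <= 1, mutationIndex > 0)
  list(swarmSize = as.integer(swarmSize), maxIter = as.integer(maxIter),
       archiveCapacity = as.integer(archiveCapacity),
       mutationProb = mutationProb, mutationIndex = mutationIndex,
       seed = as.integer(seed))
}

.polynomialMutation <- function(x, lower, upper, eta) {
  u <- stats::runif(length(x))
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  pmin(pmax(x + delta * (upper - lower), lower), upper)
}

#' Speed-constrained multi-objective particle swarm optimization
#'
#' Generic SMPSO over a box-bounded continuous decision space with a
#' bounded crowding-distance archive.  All stochastic draws flow from one
#' seeded generator, so runs are bitwise reproducible for a fixed seed.
#'
#' @param fn evaluation function: takes a raw decision vector, returns a
#'   list with a named numeric \code{objectives} element (all-maximize) and
#'   arbitrary further payload stored in the archive entries
#' @param lower,upper box bounds of the decision vector
#' @param params see \code{\link{swarmParams}}
#' @return a \linkS4class{ParetoArchive}; \code{meta$log} records archive
#'   size and ideal/nadir points per iteration
#' @export
smpso <- function(fn, lower, upper, params = swarmParams()) {
  if (params$swarmSize < 1L) .stopf("swarm size must be positive")
  set.seed(params$seed)
  d <- length(lower)
  n <- params$swarmSize
  delta <- (upper - lower) / 2
  X <- matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)), n, d)
  V <- matrix(0, n, d)
  evalOne <- function(x) {
    r <- fn(x)
    r$x <- x
    r
  }
  swarm <- apply(X, 1, evalOne, simplify = FALSE)
  pbest <- swarm
  archive <- list()
  for (s in swarm) archive <- .archiveAdd(archive, s, params$archiveCapacity)
  # fixed hypervolume reference: nadir of the initial swarm (2D logs only)
  initM <- do.call(rbind, lapply(swarm, `[[`, "objectives"))
  refPoint <- apply(initM, 2, min)
  log <- list()
  for (iter in seq_len(params$maxIter)) {
    aM <- do.call(rbind, lapply(archive, `[[`, "objectives"))
    cd <- crowdingDistance(aM)
    for (i in seq_len(n)) {
      # leader: binary crowding tournament over the archive
      k <- sample.int(length(archive), 2, replace = TRUE)
      leader <- archive[[if (cd[k[1]] >= cd[k[2]]) k[1] else k[2]]]$x
      c1 <- stats::runif(1, 1.5, 2.5); c2 <- stats::runif(1, 1.5, 2.5)
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      phi <- c1 + c2
      chi <- if (phi > 4) 2 / (2 - phi - sqrt(phi^2 - 4 * phi)) else 1
      v <- chi * (0.1 * V[i, ] + c1 * r1 * (pbest[[i]]$x - X[i, ]) +
                    c2 * r2 * (leader - X[i, ]))
      v <- pmin(pmax(v, -delta), delta)
      x <- X[i, ] + v
      outl <- x < lower; outu <- x > upper
      x[outl] <- lower[outl]; x[outu] <- upper[outu]
      v[outl | outu] <- -v[outl | outu]
      if (stats::runif(1) < params$mutationProb)
        x <- .polynomialMutation(x, lower, upper, params$mutationIndex)
      V[i, ] <- v
      X[i, ] <- x
    }
    swarm <- apply(X, 1, evalOne, simplify = FALSE)
    for (i in seq_len(n)) {
      newer <- swarm[[i]]; older <- pbest[[i]]
      if (dominates(newer$objectives, older$objectives)) pbest[[i]] <- newer
      else if (!dominates(older$objectives, newer$objectives) &&
               stats::runif(1) < 0.5) pbest[[i]] <- newer
      archive <- .archiveAdd(archive, newer, params$archiveCapacity)
    }
    aM <- do.call(rbind, lapply(archive, `[[`, "objectives"))
    log[[iter]] <- list(iteration = iter, archiveSize = length(archive),
                        ideal = apply(aM, 2, max), nadir = apply(aM, 2, min),
                        hypervolume = if (ncol(aM) == 2)
                          hypervolume2d(aM, refPoint) else NA_real_)
  }
  new("ParetoArchive", entries = archive,
      capacity = params$archiveCapacity,
      meta = list(seed = params$seed, params = params, log = log))
}

#' Dominated hypervolume of a 2-objective point set
#'
#' Area (in all-maximize orientation) dominated by the non-dominated subset
#' of \code{points} and bounded below by \code{ref}.  Points not dominating
#' the reference contribute nothing.
#'
#' @param points numeric matrix with two columns
#' @param ref reference point (length 2)
#' @return nonnegative scalar
#' @export
hypervolume2d <- function(points, ref) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  points <- points[points[, 1] > ref[1] & points[, 2] > ref[2], , drop = FALSE]
  if (!nrow(points)) return(0)
  points <- points[paretoFilter(points), , drop = FALSE]
  o <- order(points[, 1], decreasing = TRUE)
  points <- points[o, , drop = FALSE]
  hv <- 0
  prevY <- ref[2]
  for (i in seq_len(nrow(points))) {
    hv <- hv + (points[i, 1] - ref[1]) * (points[i, 2] - prevY)
    prevY <- points[i, 2]
  }
  hv
}

#' Pareto search over the design space of a context
#'
#' Runs \code{\link{smpso}} on the relaxed design encoding; every raw
#' candidate is repaired onto the feasible set (simplex mixtures, integer
#' replicates) before evaluation, so archive entries are executable
#' protocols.
#'
#' @param context a \linkS4class{DesignContext}
#' @param params see \code{\link{swarmParams}}
#' @param fractionGrid,repLevels optional grids passed to
#'   \code{\link{repairAndDecode}} (used to restrict the search to a
#'   discretized design space)
#' @return a \linkS4class{ParetoArchive} whose entries carry the decoded
#'   designs and the full evaluation reports
#' @export
optimizeDesign <- function(context, params = swarmParams(),
                           fractionGrid = NULL, repLevels = NULL) {
  bb <- designBounds(context)
  fn <- function(x) {
    design <- repairAndDecode(x, context, fractionGrid, repLevels)
    evaluateDesign(design, context)
  }
  smpso(fn, bb$lower, bb$upper, params)
}

#' Exhaustive Pareto front on a discretized design space
#'
#' Enumerates every combination of tracer-fraction grid points and
#' replicate levels (per experiment), evaluates all of them and returns the
#' exact Pareto front of the discretization.  Used as an oracle for the
#' stochastic search.
#'
#' @param context a \linkS4class{DesignContext}
#' @param fractionGrid numeric grid for each fraction gene
#' @param repLevels integer levels for each replicate gene
#' @param maxPoints guard on the enumeration size
#' @return list with \code{front} (list of evaluation results on the
#'   front), \code{objectives} (their matrix) and \code{nEvaluated}
#' @export
exhaustiveFront <- function(context, fractionGrid, repLevels,
                            maxPoints = 1e6) {
  ns <- nrow(context@species)
  ng <- length(context@setup@groups)
  nGene <- context@nCle * (ns + ng)
  total <- (length(fractionGrid)^(ns * context@nCle)) *
    (length(repLevels)^(ng * context@nCle))
  if (total > maxPoints)
    .stopf("grid has %.3g combinations, exceeding the %.3g-point guard",
           total, maxPoints)
  geneLevels <- rep(list(NULL), nGene)
  bb <- designBounds(context)
  isFrac <- grepl("\\.frac\\.", names(bb$lower))
  for (i in seq_len(nGene))
    geneLevels[[i]] <- if (isFrac[i]) fractionGrid else repLevels
  combos <- do.call(expand.grid, c(geneLevels, list(KEEP.OUT.ATTRS = FALSE)))
  seen <- new.env(parent = emptyenv())
  results <- list()
  for (i in seq_len(nrow(combos))) {
    raw <- as.numeric(combos[i, ])
    design <- repairAndDecode(raw, context, fractionGrid, repLevels)
    key <- paste(signif(encodeDesign(design, context), 12), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    r <- evaluateDesign(design, context)
    results[[length(results) + 1L]] <- r
  }
  M <- do.call(rbind, lapply(results, `[[`, "objectives"))
  idx <- paretoFilter(M)
  list(front = results[idx], objectives = M[idx, , drop = FALSE],
       nEvaluated = length(results))
}
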