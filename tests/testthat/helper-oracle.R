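# Independent brute-force labeling oracle: enumerates full isotopomer
# distributions of every balanced pool and solves the (generally nonlinear)
# isotopomer balance by damped fixed-point iteration.  Shares no code with
# the cumomer cascade it is used to check.

oracleInputDist <- function(species, fractions, pool, nCarbons) {
  dist <- rep(0, 2^nCarbons)
  for (nm in names(fractions)) {
    row <- species[species$name == nm, ]
    if (row$pool != pool) next
    bits <- as.integer(strsplit(row$pattern, "")[[1]])
    p <- bits * row$purity
    for (mask in 0:(2^nCarbons - 1)) {
      pr <- 1
      for (j in seq_len(nCarbons)) {
        lab <- bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0
        pr <- pr * if (lab) p[j] else 1 - p[j]
      }
      dist[mask + 1] <- dist[mask + 1] + fractions[[nm]] * pr
    }
  }
  dist
}

bruteForceLabeling <- function(network, fluxes, species, fractions,
                               tol = 1e-13, maxIter = 200000) {
  met <- metabolites(network)
  nC <- setNames(met$carbons, met$name)
  balanced <- met$name[met$role == "balanced" & met$carbons > 0]
  inputs <- met$name[met$role == "input" & met$carbons > 0]
  fwd <- forwardFluxes(fluxes)
  bwd <- backwardFluxes(fluxes)

  # directed reaction list with explicit per-carbon source maps
  directed <- list()
  for (rx in reactions(network)) {
    mk <- function(educts, products, rate) {
      src <- list()
      for (e in educts) if (!is.null(e$labels))
        for (j in seq_along(e$labels)) src[[e$labels[j]]] <- list(met = e$met, pos = j)
      list(educts = Filter(function(e) !is.null(e$labels), educts),
           products = Filter(function(p) !is.null(p$labels), products),
           src = src, rate = rate)
    }
    directed[[length(directed) + 1]] <- mk(rx$educts, rx$products, fwd[[rx$name]])
    if (rx$reversible)
      directed[[length(directed) + 1]] <- mk(rx$products, rx$educts, bwd[[rx$name]])
  }

  dist <- list()
  for (p in inputs) dist[[p]] <- oracleInputDist(species, fractions, p, nC[[p]])
  for (p in balanced) dist[[p]] <- rep(1 / 2^nC[[p]], 2^nC[[p]])

  outflux <- setNames(rep(0, length(balanced)), balanced)
  for (d in directed) for (e in d$educts)
    if (e$met %in% balanced) outflux[[e$met]] <- outflux[[e$met]] + d$rate

  for (iter in seq_len(maxIter)) {
    influx <- lapply(balanced, function(p) rep(0, 2^nC[[p]]))
    names(influx) <- balanced
    for (d in directed) {
      if (d$rate == 0 || !length(d$products)) next
      if (!any(vapply(d$products, function(p) p$met %in% balanced, TRUE))) next
      emets <- vapply(d$educts, function(e) e$met, "")
      combos <- expand.grid(lapply(emets, function(m) 0:(2^nC[[m]] - 1)))
      for (ci in seq_len(nrow(combos))) {
        pr <- d$rate
        for (k in seq_along(emets))
          pr <- pr * dist[[emets[k]]][combos[ci, k] + 1]
        if (pr == 0) next
        for (prod in d$products) {
          if (!prod$met %in% balanced) next
          mask <- 0L
          for (j in seq_along(prod$labels)) {
            s <- d$src[[prod$labels[j]]]
            k <- which(emets == s$met)[1]
            if (bitwAnd(combos[ci, k], bitwShiftL(1L, s$pos - 1L)) != 0)
              mask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
          }
          influx[[prod$met]][mask + 1] <- influx[[prod$met]][mask + 1] + pr
        }
      }
    }
    delta <- 0
    for (p in balanced) {
      newd <- influx[[p]] / outflux[[p]]
      delta <- max(delta, max(abs(newd - dist[[p]])))
      dist[[p]] <- newd
    }
    if (delta < tol) break
  }
  dist
}
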