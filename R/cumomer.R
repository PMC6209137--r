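#' Define a tracer mixture
#'
#' @param species data.frame with columns \code{name}, \code{pool},
#'   \code{pattern} (string of 0/1, one digit per carbon of the input pool),
#'   \code{purity} (probability that a nominally labeled position carries
#'   the label; unlabeled positions carry none — natural abundance is not
#'   modelled), \code{price} (money per gram).
#' @param fractions named numeric; per-species proportions. Fractions must
#'   sum to 1 for every input pool represented.
#' @return a \linkS4class{TracerMixture}
#' @examples
#' sp <- data.frame(name = c("U", "1C"), pool = "Sin",
#'                  pattern = c("00", "10"), purity = c(0.98, 0.99),
#'                  price = c(0.3, 150))
#' tracerMixture(sp, c(U = 0.5, `1C` = 0.5))
#' @export
tracerMixture <- function(species, fractions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  need <- c("name", "pool", "pattern", "purity", "price")
  miss <- setdiff(need, names(species))
  if (length(miss)) .stopf("species table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  bad <- setdiff(names(fractions), species$name)
  if (length(bad)) .stopf("unknown tracer species in mixture: %s",
                          paste(bad, collapse = ", "))
  obj <- new("TracerMixture", species = species, fractions = fractions)
  validObject(obj)
  obj
}

# per-position label probabilities of one species
.speciesProbs <- function(pattern, purity) {
  bits <- as.integer(strsplit(pattern, "")[[1]])
  bits * purity
}

# mixture isotopomer distribution of one input pool
.inputIsotopomers <- function(mixture, pool, nCarbons) {
  sp <- mixture@species
  idx <- which(sp$pool == pool & sp$name %in% names(mixture@fractions))
  if (!length(idx)) .stopf("no tracer species defined for input pool '%s'", pool)
  dist <- rep(0, 2^nCarbons)
  for (i in idx) {
    f <- mixture@fractions[[sp$name[i]]]
    if (f == 0) next
    p <- .speciesProbs(sp$pattern[i], sp$purity[i])
    if (length(p) != nCarbons)
      .stopf("pattern of species '%s' has %d digits, pool '%s' has %d carbons",
             sp$name[i], length(p), pool, nCarbons)
    d <- 1
    for (j in seq_len(nCarbons)) d <- c(d * (1 - p[j]), d * p[j])
    # bit j-1 corresponds to carbon j; the fold above appends the new bit as
    # the highest, matching mask indexing
    dist <- dist + f * d
  }
  dist
}

#' Build the cumomer cascade of a network
#'
#' Assembles, once per network, the weight-ordered linear systems of the
#' steady-state labeling balance.  The level-w system couples only weight-w
#' cumomers of balanced pools; influx terms that span several educts factor
#' into lower-weight cumomers and move to the right-hand side, so the
#' nonlinear isotopomer balance decomposes into a cascade of linear solves.
#'
#' @param network a \linkS4class{MetabolicNetwork}; atom maps must be
#'   complete for all carbon-carrying reactions
#' @return a \linkS4class{CumomerSystem}
#' @export
buildCumomerCascade <- function(network) {
  met <- network@metabolites
  nC <- stats::setNames(met$carbons, met$name)
  pools <- met$name[met$role == "balanced" & met$carbons > 0]
  inputPools <- met$name[met$role == "input" & met$carbons > 0]

  for (rx in network@reactions)
    for (p in c(rx$educts, rx$products))
      if (is.null(p$labels) && nC[[p$met]] > 0)
        .stopf("reaction '%s': carbon-carrying metabolite '%s' lacks an atom map",
               rx$name, p$met)

  # directed fluxes
  ft <- list()
  for (rx in network@reactions) {
    ft[[length(ft) + 1L]] <- list(reaction = rx$name, dir = "fwd",
                                  educts = rx$educts, products = rx$products)
    if (rx$reversible)
      ft[[length(ft) + 1L]] <- list(reaction = rx$name, dir = "bwd",
                                    educts = rx$products, products = rx$educts)
  }
  fluxTable <- data.frame(reaction = vapply(ft, `[[`, "", "reaction"),
                          dir = vapply(ft, `[[`, "", "dir"),
                          stringsAsFactors = FALSE)

  consumers <- stats::setNames(vector("list", length(pools)), pools)
  for (p in pools) consumers[[p]] <- which(vapply(ft, function(d)
    any(vapply(d$educts, function(e) identical(e$met, p) && !is.null(e$labels),
               TRUE)), TRUE))

  # producers per pool: flux index + per-position source (met, position)
  producers <- stats::setNames(vector("list", length(pools)), pools)
  for (k in seq_along(ft)) {
    d <- ft[[k]]
    srcOf <- list()
    for (e in d$educts) if (!is.null(e$labels))
      for (j in seq_along(e$labels)) srcOf[[e$labels[j]]] <- c(e$met, j)
    for (pr in d$products) {
      if (is.null(pr$labels) || !pr$met %in% pools) next
      map <- lapply(pr$labels, function(L) {
        s <- srcOf[[L]]
        if (is.null(s)) .stopf("reaction '%s': product carbon '%s' of '%s' has no educt source",
                               d$reaction, L, pr$met)
        s
      })
      producers[[pr$met]] <- c(producers[[pr$met]],
                               list(list(flux = k, map = map)))
    }
  }

  # unknown enumeration
  rows <- list()
  for (p in pools) {
    n <- nC[[p]]
    masks <- seq_len(2^n - 1L)
    rows[[p]] <- data.frame(pool = p, mask = masks, weight = .popcount(masks),
                            stringsAsFactors = FALSE)
  }
  unknowns <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  maxW <- if (nrow(unknowns)) max(unknowns$weight) else 0L
  unknowns$level.index <- NA_integer_
  key <- function(pool, mask) paste0(pool, ":", mask)
  idxMap <- new.env(parent = emptyenv())
  for (w in seq_len(maxW)) {
    sel <- which(unknowns$weight == w)
    unknowns$level.index[sel] <- seq_along(sel)
    for (i in seq_along(sel))
      assign(key(unknowns$pool[sel[i]], unknowns$mask[sel[i]]), i, envir = idxMap)
  }

  # assembly terms per level
  levels <- vector("list", maxW)
  for (w in seq_len(maxW)) {
    sel <- which(unknowns$weight == w)
    lin <- list(); rhs <- list()
    for (i in seq_along(sel)) {
      P <- unknowns$pool[sel[i]]; T <- unknowns$mask[sel[i]]
      bits <- .maskBits(T, nC[[P]])
      for (prod in producers[[P]]) {
        srcs <- prod$map[bits]
        mets <- vapply(srcs, `[`, "", 1)
        factors <- lapply(split(seq_along(srcs), mets), function(ii) {
          m <- mets[ii[1]]
          pos <- as.integer(vapply(srcs[ii], `[`, "", 2))
          list(met = m, mask = .bitsMask(pos))
        })
        if (length(factors) == 1L && factors[[1]]$met %in% pools) {
          # single balanced source of equal weight: same-level linear term
          col <- get(key(factors[[1]]$met, factors[[1]]$mask), envir = idxMap)
          lin[[length(lin) + 1L]] <- c(row = i, col = col, flux = prod$flux)
        } else {
          for (f in factors)
            if (!f$met %in% pools && !f$met %in% inputPools)
              .stopf("labeling of pool '%s' depends on pool '%s' which is neither balanced nor an input",
                     P, f$met)
          rhs[[length(rhs) + 1L]] <- list(row = i, flux = prod$flux,
                                          factors = factors)
        }
      }
    }
    levels[[w]] <- list(
      rows = data.frame(pool = unknowns$pool[sel], mask = unknowns$mask[sel]),
      linear = if (length(lin)) do.call(rbind, lin) else
        matrix(integer(), 0, 3, dimnames = list(NULL, c("row", "col", "flux"))),
      rhs = rhs)
  }

  new("CumomerSystem", network = network, pools = pools,
      inputPools = inputPools, unknowns = unknowns, levels = levels,
      fluxTable = fluxTable, consumers = consumers,
      maxWeight = as.integer(maxW))
}

#' Solve the steady-state labeling balance
#'
#' Solves the cumomer cascade level by level for a given flux state and
#' tracer mixture and returns per-pool isotopomer fractions.  Requires every
#' balanced pool to have strictly positive total outflux.
#'
#' @param system a \linkS4class{CumomerSystem}
#' @param fluxes a \linkS4class{FluxState}
#' @param mixture a \linkS4class{TracerMixture} covering all input pools
#' @return a \linkS4class{LabelingState}
#' @export
solveLabeling <- function(system, fluxes, mixture) {
  net <- system@network
  metC <- stats::setNames(net@metabolites$carbons, net@metabolites$name)
  ft <- system@fluxTable
  fwd <- forwardFluxes(fluxes); bwd <- backwardFluxes(fluxes)
  fv <- ifelse(ft$dir == "fwd", fwd[ft$reaction], bwd[ft$reaction])
  out <- vapply(system@pools, function(p) sum(fv[system@consumers[[p]]]), 0)
  dead <- names(out)[out <= 1e-12]
  if (length(dead))
    .stopf("degenerate labeling system: pool(s) with no outflux: %s",
           paste(dead, collapse = ", "))

  # known cumomer values: inputs (all masks) filled now, balanced filled as solved
  vals <- new.env(parent = emptyenv())
  inputDist <- list()
  for (p in system@inputPools) {
    dist <- .inputIsotopomers(mixture, p, metC[[p]])
    inputDist[[p]] <- dist
    cum <- .isoToCumomer(dist)
    for (m in seq_along(cum) - 1L) assign(paste0(p, ":", m), cum[m + 1L], envir = vals)
  }
  for (p in system@pools) assign(paste0(p, ":0"), 1, envir = vals)

  for (w in seq_len(system@maxWeight)) {
    lv <- system@levels[[w]]
    nw <- nrow(lv$rows)
    if (!nw) next
    A <- matrix(0, nw, nw)
    b <- numeric(nw)
    diagOut <- out[lv$rows$pool]
    for (i in seq_len(nw)) A[i, i] <- -diagOut[i]
    if (nrow(lv$linear))
      for (t in seq_len(nrow(lv$linear))) {
        r <- lv$linear[t, "row"]; cc <- lv$linear[t, "col"]
        A[r, cc] <- A[r, cc] + fv[lv$linear[t, "flux"]]
      }
    for (t in lv$rhs) {
      prodv <- fv[t$flux]
      for (f in t$factors)
        prodv <- prodv * get(paste0(f$met, ":", f$mask), envir = vals)
      b[t$row] <- b[t$row] - prodv
    }
    u <- tryCatch(solve(A, b), error = function(e)
      .stopf("singular level-%d cumomer system (%s)", w, conditionMessage(e)))
    for (i in seq_len(nw))
      assign(paste0(lv$rows$pool[i], ":", lv$rows$mask[i]), u[i], envir = vals)
  }

  cums <- list(); fracs <- list()
  for (p in system@pools) {
    n <- metC[[p]]
    cum <- vapply(seq_len(2^n) - 1L, function(m)
      get(paste0(p, ":", m), envir = vals), 0)
    iso <- .cumomerToIso(cum)
    iso <- pmin(pmax(iso, 0), 1)
    cums[[p]] <- cum
    fracs[[p]] <- iso / sum(iso)
  }
  for (p in system@inputPools) {
    fracs[[p]] <- inputDist[[p]]
    cums[[p]] <- .isoToCumomer(inputDist[[p]])
  }
  st <- new("LabelingState", fractions = fracs, cumomers = cums,
            pools = c(system@pools, system@inputPools))
  validObject(st)
  st
}

#' Tidy table of isotopomer fractions
#'
#' @param state a \linkS4class{LabelingState}
#' @param pools optional subset of pools
#' @return data.frame with columns \code{pool}, \code{isotopomer}
#'   (bitstring, carbon 1 first), \code{fraction}
#' @export
isotopomerTable <- function(state, pools = state@pools) {
  do.call(rbind, lapply(pools, function(p) {
    x <- state@fractions[[p]]
    n <- as.integer(round(log2(length(x))))
    data.frame(pool = p,
               isotopomer = vapply(seq_along(x) - 1L, .maskString, "", n),
               fraction = x, stringsAsFactors = FALSE)
  }))
}
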