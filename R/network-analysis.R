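#' Stoichiometric matrix of a network
#'
#' Net stoichiometry over the balanced pools (rows) and reactions (columns).
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @return matrix with dimnames (balanced metabolites, reactions)
#' @export
stoichiometricMatrix <- function(network) {
  bal <- network@metabolites$name[network@metabolites$role == "balanced"]
  rn <- vapply(network@reactions, `[[`, "", "name")
  S <- matrix(0, length(bal), length(rn), dimnames = list(bal, rn))
  for (rx in network@reactions) {
    for (p in rx$educts) if (p$met %in% bal)
      S[p$met, rx$name] <- S[p$met, rx$name] - p$coef
    for (p in rx$products) if (p$met %in% bal)
      S[p$met, rx$name] <- S[p$met, rx$name] + p$coef
  }
  S
}

.equalitySystem <- function(network) {
  S <- stoichiometricMatrix(network)
  b <- rep(0, nrow(S))
  if (length(network@rates)) {
    R <- matrix(0, length(network@rates), ncol(S),
                dimnames = list(names(network@rates), colnames(S)))
    for (r in names(network@rates)) R[r, r] <- 1
    S <- rbind(S, R)
    b <- c(b, unname(network@rates))
  }
  list(A = S, b = b)
}

#' Free-flux parametrization of the stoichiometric system
#'
#' Computes the degrees of freedom of the flux equality system (metabolite
#' balances plus measured extracellular rates) and a deterministic free-flux
#' basis: dependent reactions are selected greedily in declaration order, so
#' repeated runs give identical parametrizations; reactions listed in
#' \code{prefer} are tried last and therefore stay free whenever the system
#' permits. Any feasible flux vector is \code{particular + basis \%*\% w}
#' with \code{w} the free net-flux values. Exchange fluxes of all reversible
#' reactions form an additional free subset (they do not enter the
#' stoichiometry).
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param prefer character; reactions preferred as free net fluxes
#' @param tol relative singular-value tolerance for rank decisions
#' @return a \linkS4class{FluxParametrization}
#' @export
stoichiometricAnalysis <- function(network, prefer = character(), tol = 1e-10) {
  eq <- .equalitySystem(network)
  A <- eq$A; b <- eq$b
  rn <- colnames(A)
  bad <- setdiff(prefer, rn)
  if (length(bad)) .stopf("prefer references unknown reaction(s): %s",
                          paste(bad, collapse = ", "))
  ord <- c(setdiff(rn, prefer), intersect(prefer, rn))
  dep <- character()
  rk <- 0L
  for (j in ord) {
    cand <- cbind(A[, dep, drop = FALSE], A[, j])
    r2 <- .matrixRank(cand, tol)
    if (r2 > rk) { dep <- c(dep, j); rk <- r2 }
  }
  dep <- rn[rn %in% dep]                      # restore declaration order
  freeNet <- setdiff(rn, dep)
  rank <- rk
  dofv <- length(rn) - rank
  Ad <- A[, dep, drop = FALSE]
  qrA <- qr(Ad)
  solveDep <- function(rhs) {
    if (!length(dep)) return(numeric(0))
    qr.coef(qrA, rhs)
  }
  vdep <- solveDep(b)
  part <- stats::setNames(rep(0, length(rn)), rn)
  part[dep] <- vdep
  res <- if (length(b)) max(abs(A %*% part - b)) else 0
  if (res > 1e-8 * (1 + max(abs(b))))
    .stopf("infeasible equality system: residual %.3g (no flux distribution satisfies the balances and measured rates)", res)
  basis <- matrix(0, length(rn), length(freeNet), dimnames = list(rn, freeNet))
  for (j in freeNet) {
    basis[j, j] <- 1
    if (length(dep)) basis[dep, j] <- -solveDep(A[, j])
  }
  rev <- vapply(network@reactions, `[[`, TRUE, "reversible")
  new("FluxParametrization",
      freeNet = freeNet, freeExchange = rn[rev], particular = part,
      basis = basis, dof = as.integer(dofv), rank = as.integer(rank),
      network = network)
}

#' Expand free-flux values to a full flux state
#'
#' Maps an assignment of the free fluxes (free net fluxes by reaction name,
#' exchange fluxes by \code{"<reaction>.xch"}) to the full net/exchange flux
#' state.  Omitted exchange entries default to 0.
#'
#' @param param a \linkS4class{FluxParametrization}
#' @param freeValues named numeric over (a subset of) \code{freeFluxes(param)}
#' @param strict if \code{TRUE}, bound or inequality violations raise an
#'   error listing the violated rows; if \code{FALSE} they are attached as a
#'   \code{"violations"} attribute instead
#' @return a \linkS4class{FluxState}
#' @export
expandFluxState <- function(param, freeValues, strict = TRUE) {
  if (any(!is.finite(freeValues))) .stopf("free-flux values must be finite")
  fn <- param@freeNet
  xn <- paste0(param@freeExchange, ".xch")
  unknown <- setdiff(names(freeValues), c(fn, xn))
  if (length(unknown)) .stopf("unknown free flux(es): %s",
                              paste(unknown, collapse = ", "))
  missingNet <- setdiff(fn, names(freeValues))
  if (length(missingNet)) .stopf("missing free net flux value(s): %s",
                                 paste(missingNet, collapse = ", "))
  w <- freeValues[fn]
  net <- param@particular + as.vector(param@basis %*% w)
  names(net) <- names(param@particular)
  xch <- stats::setNames(rep(0, length(param@freeExchange)), param@freeExchange)
  have <- intersect(xn, names(freeValues))
  xch[sub("\\.xch$", "", have)] <- freeValues[have]
  state <- new("FluxState", net = net, exchange = pmax(xch, 0))
  viol <- checkFluxState(state, param@network)
  if (nrow(viol)) {
    if (strict)
      .stopf("constraint violation(s):\n%s",
             paste(sprintf("  %s: %s", viol$constraint, viol$detail), collapse = "\n"))
    attr(state, "violations") <- viol
  }
  state
}

#' Report constraint violations of a flux state
#'
#' Checks net-flux bounds, inequality rows, exchange nonnegativity and the
#' equality system residual.
#'
#' @param state a \linkS4class{FluxState}
#' @param network the \linkS4class{MetabolicNetwork} defining the constraints
#' @param tol feasibility tolerance
#' @return data.frame with columns \code{constraint}, \code{detail}
#' @export
checkFluxState <- function(state, network, tol = 1e-9) {
  out <- list()
  bb <- network@bounds
  v <- state@net[bb$reaction]
  low <- which(v < bb$lower - tol)
  high <- which(v > bb$upper + tol)
  for (i in low) out[[length(out) + 1L]] <- c(
    sprintf("bound:%s", bb$reaction[i]),
    sprintf("net %.6g below lower bound %g", v[i], bb$lower[i]))
  for (i in high) out[[length(out) + 1L]] <- c(
    sprintf("bound:%s", bb$reaction[i]),
    sprintf("net %.6g above upper bound %g", v[i], bb$upper[i]))
  if (nrow(network@ineq$A)) {
    lhs <- as.vector(network@ineq$A %*% state@net[colnames(network@ineq$A)])
    for (i in which(lhs > network@ineq$b + tol))
      out[[length(out) + 1L]] <- c(sprintf("inequality:%d", i),
        sprintf("lhs %.6g exceeds %.6g", lhs[i], network@ineq$b[i]))
  }
  eq <- .equalitySystem(network)
  if (length(eq$b)) {
    res <- max(abs(eq$A %*% state@net[colnames(eq$A)] - eq$b))
    if (res > 1e-8 * (1 + max(abs(eq$b))))
      out[[length(out) + 1L]] <- c("equality",
        sprintf("balance residual %.3g", res))
  }
  if (length(out))
    data.frame(constraint = vapply(out, `[`, "", 1),
               detail = vapply(out, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(constraint = character(), detail = character())
}

#' Extract free-flux values from a flux state
#'
#' Inverse of \code{\link{expandFluxState}} on feasible states.
#'
#' @param param a \linkS4class{FluxParametrization}
#' @param state a \linkS4class{FluxState}
#' @return named numeric over \code{freeFluxes(param)}
#' @export
extractFreeFluxes <- function(param, state) {
  out <- state@net[param@freeNet]
  if (length(param@freeExchange)) {
    xch <- state@exchange[param@freeExchange]
    names(xch) <- paste0(param@freeExchange, ".xch")
    out <- c(out, xch)
  }
  out
}
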