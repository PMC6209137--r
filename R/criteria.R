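#' Fisher information matrix from sensitivities and measurement noise
#'
#' \code{FIM = J' diag(1/sigma^2) J}: measurement rows are weighted by their
#' inverse variances, so noisier observations contribute less information.
#'
#' @param jacobian sensitivity matrix (#observations x #free fluxes)
#' @param sd per-observation standard deviations (> 0)
#' @return symmetric positive semi-definite matrix
#' @export
computeFim <- function(jacobian, sd) {
  if (length(sd) != nrow(jacobian))
    .stopf("sd length %d does not match %d measurement rows",
           length(sd), nrow(jacobian))
  if (any(sd <= 0)) .stopf("all measurement standard deviations must be > 0")
  fim <- crossprod(jacobian / sd)
  (fim + t(fim)) / 2
}

#' Statistical identifiability of the free fluxes
#'
#' The covariance matrix is numerically trustworthy only if the FIM's
#' smallest eigenvalue exceeds \code{tau1} (taken relative to the largest
#' eigenvalue) and its condition number stays below \code{tau2}.
#'
#' @param fim symmetric PSD matrix
#' @param tau1 minimal-eigenvalue threshold, relative to the largest
#' @param tau2 condition-number bound
#' @return list with \code{pass}, \code{lambdaMin}, \code{lambdaMax},
#'   \code{condition}
#' @export
assessIdentifiability <- function(fim, tau1 = 1e-9, tau2 = 1e12) {
  if (!nrow(fim))
    return(list(pass = FALSE, lambdaMin = NA_real_, lambdaMax = NA_real_,
                condition = NA_real_))
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev); lmax <- max(ev)
  cond <- if (lmin > 0) lmax / lmin else Inf
  list(pass = (lmax > 0 && lmin > tau1 * lmax && cond < tau2),
       lambdaMin = lmin, lambdaMax = lmax, condition = cond)
}

# Moore-Penrose pseudo-inverse via symmetric eigendecomposition
.pinv <- function(M, tol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Iterative freezing of non-identifiable fluxes
#'
#' Starting from the full free-flux set, non-identifiable fluxes are frozen
#' (constrained to their nominal values and removed from the FIM) one at a
#' time, beginning with the worst-determined one — the flux with the largest
#' variance on the diagonal of the pseudo-inverse of the current FIM — until
#' the retained FIM passes \code{\link{assessIdentifiability}}.  An empty
#' retained set (p = 0) is a valid outcome.
#'
#' @param jacobian sensitivity matrix with columns named by free flux
#' @param sd per-observation standard deviations
#' @param tau1,tau2 identifiability thresholds, see
#'   \code{\link{assessIdentifiability}}
#' @param zeroTol absolute sensitivity floor: a free flux whose largest
#'   measurement sensitivity is below this is numerically indistinguishable
#'   from unobserved (finite-difference noise) and is frozen first
#' @return a \linkS4class{FimResult}
#' @export
iterativeFreeze <- function(jacobian, sd, tau1 = 1e-9, tau2 = 1e12,
                            zeroTol = 1e-6) {
  retained <- colnames(jacobian)
  if (is.null(retained)) retained <- as.character(seq_len(ncol(jacobian)))
  frozen <- character()
  repeat {
    if (!length(retained)) {
      return(new("FimResult", fim = matrix(0, 0, 0), cov = matrix(0, 0, 0),
                 p = 0L, frozen = frozen, retained = character(),
                 lambdaMin = NA_real_, condition = NA_real_))
    }
    J <- jacobian[, retained, drop = FALSE]
    dead <- apply(abs(J), 2, max) < zeroTol
    if (any(dead)) {
      frozen <- c(frozen, retained[which(dead)[1]])
      retained <- retained[-which(dead)[1]]
      next
    }
    fim <- computeFim(J, sd)
    chk <- assessIdentifiability(fim, tau1, tau2)
    if (chk$pass) {
      cov <- solve(fim)
      cov <- (cov + t(cov)) / 2
      return(new("FimResult", fim = fim, cov = cov,
                 p = length(retained), frozen = frozen, retained = retained,
                 lambdaMin = chk$lambdaMin, condition = chk$condition))
    }
    vars <- diag(.pinv(fim))
    # columns with no usable information are the worst determined
    zero <- apply(abs(J), 2, max) < zeroTol
    worst <- if (any(zero)) which(zero)[1] else which.max(vars)
    frozen <- c(frozen, retained[worst])
    retained <- retained[-worst]
  }
}

#' Covariance-based optimality criteria
#'
#' Scalar summaries of the flux covariance at the design point:
#' \describe{
#'   \item{D}{\code{det(Cov)^(1/(2p))} — geometric mean of the flux standard
#'     deviations (proportional to the confidence ellipsoid volume).}
#'   \item{A}{\code{trace(Cov)/p} — arithmetic mean flux variance.}
#'   \item{E}{\code{lambda_max(Cov)/lambda_min(Cov)} — ellipsoid
#'     conditioning, dimension independent.}
#'   \item{DoF}{\code{p}, the number of statistically identifiable free
#'     fluxes.}
#' }
#' All three dispersion criteria are "smaller is better"; the accompanying
#' information report uses their reciprocals so that larger values mean more
#' informative designs.
#'
#' @param result a \linkS4class{FimResult} (or a covariance matrix with
#'   \code{p = nrow})
#' @return list with \code{dof}, \code{D}, \code{A}, \code{E} and an
#'   \code{info} sub-list of reciprocals (\code{info$D = 1/D} etc.)
#' @export
evaluateCriteria <- function(result) {
  if (is(result, "FimResult")) { cov <- result@cov; p <- result@p }
  else { cov <- as.matrix(result); p <- nrow(cov) }
  if (p == 0L)
    return(list(dof = 0L, D = NA_real_, A = NA_real_, E = NA_real_,
                info = list(D = 0, A = 0, E = 0)))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) .stopf("covariance matrix is not positive definite")
  D <- exp(sum(log(ev)) / (2 * p))
  A <- sum(diag(cov)) / p
  E <- max(ev) / min(ev)
  list(dof = as.integer(p), D = D, A = A, E = E,
       info = list(D = 1 / D, A = 1 / A, E = 1 / E))
}
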