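# bitmask helpers: isotopomer/cumomer vectors are indexed mask + 1,
# bit i-1 set <=> carbon i labeled

.popcount <- function(m) {
  n <- integer(length(m))
  while (any(m > 0L)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

.maskBits <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)

.bitsMask <- function(bits) if (length(bits)) sum(bitwShiftL(1L, bits - 1L)) else 0L

.maskString <- function(mask, n) {
  b <- integer(n)
  b[.maskBits(mask, n)] <- 1L
  paste(b, collapse = "")
}

# cumomer values from isotopomer fractions: cum[T] = sum over iso >= T
.isoToCumomer <- function(x) {
  n <- as.integer(round(log2(length(x))))
  c0 <- x
  if (n >= 1) for (i in 0:(n - 1)) {
    bit <- bitwShiftL(1L, i)
    idx <- which(bitwAnd(seq_along(c0) - 1L, bit) == 0L)
    c0[idx] <- c0[idx] + c0[idx + bit]
  }
  c0
}

# inverse (Moebius) transform: isotopomer fractions from cumomer values
.cumomerToIso <- function(cum) {
  n <- as.integer(round(log2(length(cum))))
  x <- cum
  if (n >= 1) for (i in 0:(n - 1)) {
    bit <- bitwShiftL(1L, i)
    idx <- which(bitwAnd(seq_along(x) - 1L, bit) == 0L)
    x[idx] <- x[idx] - x[idx + bit]
  }
  x
}

# numerical rank with relative singular-value tolerance
.matrixRank <- function(A, tol = 1e-10) {
  if (!length(A) || nrow(A) == 0L || ncol(A) == 0L) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > tol * max(sv))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
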