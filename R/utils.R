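## Numeric helpers shared across the harmonizers.

## Symmetric (spectral) matrix square root; eigenvalues floored.
.symSqrt <- function(S, floor = 1e-10) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, floor)
    e$vectors %*% (sqrt(vals) * t(e$vectors))
}

## Symmetric inverse square root (whitening operator).
.symSqrtInv <- function(S, floor = 1e-10) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, floor)
    e$vectors %*% ((1 / sqrt(vals)) * t(e$vectors))
}

.ridge <- function(S, eps = 1e-8) S + diag(eps, nrow(S))

## Flip columns so the largest-magnitude loading of each is positive.
.fixSigns <- function(V) {
    for (k in seq_len(ncol(V))) {
        j <- which.max(abs(V[, k]))
        if (V[j, k] < 0) V[, k] <- -V[, k]
    }
    V
}

## Deterministic 32-bit child seed from a master seed and an index.
.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587)
}

.mvrnorm <- function(n, mu, Sigma) {
    MASS::mvrnorm(n = n, mu = mu, Sigma = Sigma)
}

## Sample covariance of the rows of X about their mean (ddof = 1).
.rowCov <- function(X) {
    stats::cov(X)
}

## Smallest k such that the first k of (non-negative, descending) values
## reach `fraction` of their total.
.countForFraction <- function(values, fraction) {
    if (fraction <= 0 || fraction > 1)
        stop("variance fraction must lie in (0, 1]")
    tot <- sum(values)
    if (tot <= 0) return(1L)
    cum <- cumsum(values) / tot
    max(1L, which(cum >= fraction - 1e-12)[1])
}
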