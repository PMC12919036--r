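## C-vine machinery for correlation matrices. Partial correlations on the
## vine, drawn as scaled Beta variables with tree-level-dependent shape
## alpha_k = eta + (M - 1 - k) / 2, induce an LKJ(eta) distribution on the
## full correlation matrix; the same map (with tanh-unconstrained partials)
## parameterizes the MCMC sampler.

.vinePairs <- function(M) which(upper.tri(diag(M)), arr.ind = TRUE)

## Partial-to-full correlation recursion (column k = tree level).
.vineToCorr <- function(partials, M) {
    P <- matrix(0, M, M)
    P[upper.tri(P)] <- partials
    R <- diag(M)
    for (k in seq_len(M - 1)) for (l in (k + 1):M) {
        r <- P[k, l]
        if (k > 1) for (t in (k - 1):1)
            r <- r * sqrt((1 - P[t, l]^2) * (1 - P[t, k]^2)) + P[t, l] * P[t, k]
        R[k, l] <- R[l, k] <- r
    }
    R
}

## Draw an LKJ(eta) correlation matrix via the C-vine construction.
.rLKJ <- function(M, eta) {
    pairs <- .vinePairs(M)
    alpha <- eta + (M - 1 - pairs[, 1]) / 2
    partials <- 2 * stats::rbeta(nrow(pairs), alpha, alpha) - 1
    .vineToCorr(partials, M)
}

## Log prior density of unconstrained vine parameters y (partials = tanh(y))
## inducing LKJ(eta) on R, including the tanh Jacobian.
.lkjVineLogPrior <- function(y, M, eta) {
    pairs <- .vinePairs(M)
    alpha <- eta + (M - 1 - pairs[, 1]) / 2
    z <- tanh(y)
    sum(stats::dbeta((z + 1) / 2, alpha, alpha, log = TRUE)) +
        sum(log1p(-z^2))
}

.halfTLogPrior <- function(sigma, df, scale) {
    sum(-(df + 1) / 2 * log1p(sigma^2 / (df * scale^2)))
}

#' MCMC posterior batch effects (LKJ / half-t hierarchical model)
#'
#' Fully Bayesian alternative to [ebPosteriors()]. Fixed effects must already
#' have been removed (the estimator is the second stage of a two-stage
#' design). Per batch i the hierarchical model is
#' Z_ijv ~ N(gamma_iv, D_iv R_iv D_iv) with D_iv = diag(sigma_iv),
#' gamma_iv ~ N(mu_i, tau_i^2 I) with weak hyperpriors
#' (mu_im ~ N(0, 10^2), tau_i^2 ~ Inv-Gamma(2, 1)),
#' sigma_ivm ~ half-t(df = 3, scale = pooled SD of metric m), and
#' R_iv ~ LKJ(eta = 2), decoupling shrinkage of scales and correlations.
#' Sampling uses conjugate Gibbs updates for gamma, mu and tau^2 and
#' adaptive random-walk Metropolis on (log sigma, unconstrained C-vine
#' partial correlations), with step sizes tuned during warmup. Posterior
#' means of gamma_iv and Sigma_iv = D R D are returned; rank-normalized
#' split-Rhat and effective sample sizes are recorded for every gamma and
#' log-sigma coordinate and the fit fails validation (flag, warning) if any
#' Rhat >= 1.01.
#'
#' @param Z n x p x M standardized residual array.
#' @param batchFac batch factor of length n.
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws per chain (default 1000).
#' @param warmup warmup (adaptation) draws per chain (default 1000).
#' @param eta LKJ concentration (default 2).
#' @param halfTDf degrees of freedom of the half-t scale prior (default 3).
#' @param seed integer seed; the sampler is deterministic given it.
#' @param adaptTarget target Metropolis acceptance rate (default 0.25).
#' @return A [BatchPosteriors-class] object with `estimator = "mcmc"` and
#'   `diagnostics` holding `rhat`, `ess`, `pass` and mean acceptance rates.
#' @export
mcmcPosteriors <- function(Z, batchFac, chains = 4L, iter = 1000L,
                           warmup = 1000L, eta = 2, halfTDf = 3,
                           seed = 1L, adaptTarget = 0.25) {
    stopifnot(is.array(Z), length(dim(Z)) == 3)
    ## keep empty levels: a batch with no rows is a prior-only run
    if (!is.factor(batchFac)) batchFac <- factor(batchFac)
    levs <- levels(batchFac)
    n <- dim(Z)[1]; p <- dim(Z)[2]; M <- dim(Z)[3]
    q <- M * (M - 1) / 2
    s0 <- vapply(seq_len(M), function(m) {
        s <- stats::sd(Z[, , m])
        if (!is.finite(s) || s <= 0) 1 else s
    }, 0)
    I <- length(levs)
    gammaStar <- Zbar <- array(0, c(I, p, M),
                               dimnames = list(levs, dimnames(Z)[[2]],
                                               dimnames(Z)[[3]]))
    SigmaStar <- vector("list", I); names(SigmaStar) <- levs
    rhatAll <- essAll <- numeric(0)
    accAll <- numeric(I)
    for (i in seq_len(I)) {
        rows <- which(batchFac == levs[i])
        fit <- .mcmcOneBatch(Z[rows, , , drop = FALSE], chains, iter, warmup,
                             eta, halfTDf, s0, .childSeed(seed, i),
                             adaptTarget)
        gammaStar[i, , ] <- fit$gammaMean
        SigmaStar[[i]] <- fit$SigmaMean
        if (length(rows))
            Zbar[i, , ] <- apply(Z[rows, , , drop = FALSE], c(2, 3), mean)
        names(fit$rhat) <- paste0("b", i, ".", names(fit$rhat))
        rhatAll <- c(rhatAll, fit$rhat)
        essAll <- c(essAll, stats::setNames(fit$ess, names(fit$rhat)))
        accAll[i] <- fit$acceptance
    }
    pass <- all(is.na(rhatAll) | rhatAll < 1.01)
    if (!pass)
        warning("MCMC convergence check failed: max Rhat = ",
                signif(max(rhatAll, na.rm = TRUE), 4))
    new("BatchPosteriors", gammaStar = gammaStar, SigmaStar = SigmaStar,
        Zbar = Zbar, batchLevels = levs,
        featureIds = dimnames(Z)[[2]] %||% sprintf("F%03d", seq_len(p)),
        metricIds = dimnames(Z)[[3]] %||% paste0("M", seq_len(M)),
        estimator = "mcmc",
        iterations = matrix(as.numeric(chains * iter), I, p),
        converged = matrix(pass, I, p),
        diagnostics = list(rhat = rhatAll, ess = essAll, pass = pass,
                           acceptance = accAll))
}

## One batch: Metropolis-within-Gibbs over gamma (p x M), mu (M), tau2,
## log sigma (p x M) and vine partials (p x q).
.mcmcOneBatch <- function(Zi, chains, iter, warmup, eta, halfTDf, s0, seed,
                          adaptTarget) {
    ni <- dim(Zi)[1]; p <- dim(Zi)[2]; M <- dim(Zi)[3]
    q <- M * (M - 1) / 2
    zbar <- if (ni > 0) apply(Zi, c(2, 3), mean) else matrix(0, p, M)
    Craw <- lapply(seq_len(p), function(v)
        if (ni > 0) crossprod(matrix(Zi[, v, ], ncol = M)) else
            matrix(0, M, M))
    npar <- p * M
    gammaDraws <- vector("list", chains)
    lsigDraws <- vector("list", chains)
    gammaSum <- matrix(0, p, M)
    SigmaSum <- array(0, c(p, M, M))
    accTot <- 0
    for (ch in seq_len(chains)) {
        set.seed(.childSeed(seed, ch))
        gamma <- zbar + matrix(stats::rnorm(p * M, 0, 0.1), p, M)
        mu <- colMeans(gamma)
        tau2 <- 1
        lsig <- matrix(0, p, M)
        yv <- matrix(0, p, q)
        lstep <- rep(-1, p)              # log step size, adapted in warmup
        logpostSig <- rep(NA_real_, p)
        chol_ <- vector("list", p)
        for (v in seq_len(p)) {
            lp <- .sigmaLogPost(lsig[v, ], yv[v, ], gamma[v, ], zbar[v, ],
                                Craw[[v]], ni, eta, halfTDf, s0, M)
            logpostSig[v] <- lp$lp
            chol_[[v]] <- lp$chol
        }
        gD <- matrix(NA_real_, iter, npar)
        sD <- matrix(NA_real_, iter, npar)
        accept <- 0; proposals <- 0
        total <- warmup + iter
        for (it in seq_len(total)) {
            ## gamma_v | Sigma_v, mu, tau2  (conjugate MVN)
            for (v in seq_len(p)) {
                Sinv <- chol2inv(chol_[[v]])
                prec <- ni * Sinv + diag(1 / tau2, M)
                cp <- chol(prec)
                mean_ <- backsolve(cp, forwardsolve(t(cp),
                    ni * Sinv %*% zbar[v, ] + mu / tau2))
                gamma[v, ] <- mean_ + backsolve(cp, stats::rnorm(M))
            }
            ## mu | gamma, tau2 and tau2 | gamma, mu
            precMu <- p / tau2 + 1 / 100
            mu <- stats::rnorm(M, (colSums(gamma) / tau2) / precMu,
                               sqrt(1 / precMu))
            rss <- sum(sweep(gamma, 2, mu)^2)
            tau2 <- 1 / stats::rgamma(1, 2 + p * M / 2, 1 + rss / 2)
            ## (log sigma, vine partials) per feature: adaptive RW-MH
            for (v in seq_len(p)) {
                lpCur <- .sigmaLogPost(lsig[v, ], yv[v, ], gamma[v, ],
                                       zbar[v, ], Craw[[v]], ni, eta,
                                       halfTDf, s0, M)
                prop <- c(lsig[v, ], yv[v, ]) +
                    exp(lstep[v]) * stats::rnorm(M + q)
                lpNew <- .sigmaLogPost(prop[seq_len(M)], prop[-seq_len(M)],
                                       gamma[v, ], zbar[v, ], Craw[[v]], ni,
                                       eta, halfTDf, s0, M)
                ratio <- lpNew$lp - lpCur$lp
                aprob <- min(1, exp(ratio))
                if (is.finite(ratio) && stats::runif(1) < aprob) {
                    lsig[v, ] <- prop[seq_len(M)]
                    yv[v, ] <- prop[-seq_len(M)]
                    chol_[[v]] <- lpNew$chol
                    if (it > warmup) accept <- accept + 1
                } else chol_[[v]] <- lpCur$chol
                if (it <= warmup)
                    lstep[v] <- lstep[v] +
                        (aprob - adaptTarget) * 0.5 / it^0.6
                if (it > warmup) proposals <- proposals + 1
            }
            if (it > warmup) {
                k <- it - warmup
                gD[k, ] <- as.numeric(gamma)
                sD[k, ] <- as.numeric(lsig)
                gammaSum <- gammaSum + gamma
                for (v in seq_len(p)) {
                    sig <- exp(lsig[v, ]) * s0
                    R <- .vineToCorr(tanh(yv[v, ]), M)
                    SigmaSum[v, , ] <- SigmaSum[v, , ] +
                        (sig %o% sig) * R
                }
            }
        }
        colnames(gD) <- paste0("gamma.",
                               as.vector(outer(seq_len(p), seq_len(M),
                                               function(a, b)
                                                   paste0("v", a, ".m", b))))
        colnames(sD) <- sub("gamma", "lsigma", colnames(gD))
        gammaDraws[[ch]] <- gD
        lsigDraws[[ch]] <- sD
        accTot <- accTot + if (proposals > 0) accept / proposals else NA_real_
    }
    draws <- lapply(seq_len(chains), function(ch)
        cbind(gammaDraws[[ch]], lsigDraws[[ch]]))
    diag_ <- mcmcDiagnostics(draws)
    list(gammaMean = gammaSum / (chains * iter),
         SigmaMean = SigmaSum / (chains * iter),
         rhat = diag_$rhat, ess = diag_$ess,
         acceptance = accTot / chains)
}

## Log posterior of (log sigma, vine y) given gamma, up to a constant.
.sigmaLogPost <- function(lsig, y, gamma, zbar, Craw, ni, eta, halfTDf, s0,
                          M) {
    sig <- exp(lsig) * s0
    R <- .vineToCorr(tanh(y), M)
    Sigma <- (sig %o% sig) * R
    cS <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cS)) return(list(lp = -Inf, chol = NULL))
    lp <- 0
    if (ni > 0) {
        C <- Craw - ni * (outer(zbar, gamma) + outer(gamma, zbar)) +
            ni * outer(gamma, gamma)
        Sinv <- chol2inv(cS)
        lp <- lp - ni * sum(log(diag(cS))) - 0.5 * sum(Sinv * C)
    }
    lp <- lp + .halfTLogPrior(sig, halfTDf, s0) + sum(lsig)   # + Jacobian
    lp <- lp + .lkjVineLogPrior(y, M, eta)
    list(lp = lp, chol = cS)
}

#' MCMC convergence diagnostics
#'
#' Rank-normalized split-Rhat and effective sample size per parameter,
#' computed from a list of chains (each an iterations x parameters matrix).
#' The fit passes iff every finite Rhat is below 1.01; parameters that are
#' constant across all draws yield `NA` Rhat and are flagged, not failed.
#'
#' @param chains list of numeric matrices with identical dimensions.
#' @return list with `rhat`, `ess` (named per parameter), `pass`, and
#'   `flagged` (names of constant parameters).
#' @references Vehtari, A. et al. (2021) Rank-normalization, folding, and
#'   localization: an improved Rhat for assessing convergence of MCMC.
#'   Bayesian Analysis 16(2).
#' @export
mcmcDiagnostics <- function(chains) {
    stopifnot(is.list(chains), length(chains) >= 2)
    d <- dim(chains[[1]])
    if (any(!vapply(chains, function(x) all(dim(x) == d), TRUE)))
        stop("all chains must share dimensions")
    npar <- d[2]
    pnames <- colnames(chains[[1]]) %||% paste0("par", seq_len(npar))
    rhat <- ess <- stats::setNames(rep(NA_real_, npar), pnames)
    for (j in seq_len(npar)) {
        draws <- vapply(chains, function(x) x[, j], numeric(d[1]))
        r <- .splitRhat(draws)
        rhat[j] <- r$rhat
        ess[j] <- r$ess
    }
    flagged <- pnames[is.na(rhat)]
    pass <- all(is.na(rhat) | rhat < 1.01)
    list(rhat = rhat, ess = ess, pass = pass, flagged = flagged)
}

## draws: iterations x chains matrix for one parameter.
.splitRhat <- function(draws) {
    niter <- nrow(draws)
    half <- floor(niter / 2)
    sp <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(niter - half + 1):niter, , drop = FALSE])
    if (stats::sd(sp) == 0 || !is.finite(stats::sd(sp)))
        return(list(rhat = NA_real_, ess = NA_real_))
    z <- stats::qnorm((rank(sp, ties.method = "average") - 3 / 8) /
                      (length(sp) + 1 / 4))
    zm <- matrix(z, nrow = half)
    m <- ncol(zm); nn <- nrow(zm)
    W <- mean(apply(zm, 2, stats::var))
    B <- nn * stats::var(colMeans(zm))
    varPlus <- (nn - 1) / nn * W + B / nn
    rhat <- sqrt(varPlus / W)
    ## combined-chain autocorrelation, Geyer initial positive sequence
    maxLag <- min(nn - 1, 500)
    acovs <- vapply(seq_len(m), function(c_)
        as.numeric(stats::acf(zm[, c_], lag.max = maxLag, type = "covariance",
                              plot = FALSE, demean = TRUE)$acf),
        numeric(maxLag + 1))
    rho <- 1 - (W - rowMeans(acovs)) / varPlus
    tauSum <- 0
    t <- 2
    while (t + 1 <= length(rho)) {
        pair <- rho[t] + rho[t + 1]
        if (!is.finite(pair) || pair < 0) break
        tauSum <- tauSum + pair
        t <- t + 2
    }
    essVal <- m * nn / (1 + 2 * tauSum)
    list(rhat = rhat, ess = min(essVal, m * nn))
}
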