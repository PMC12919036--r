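#' Method-of-moments hyperparameters for multivariate batch effects
#'
#' Estimates, per batch, the hyperparameters of the conjugate priors on the
#' cross-metric batch effects: gamma_iv ~ N(gammaBar_i, T_i) and
#' Sigma_iv ~ IW(Psi_i, nu_i). The location prior is moment-matched to the
#' across-feature distribution of the batch-feature residual means; the
#' inverse-Wishart degrees of freedom are matched to the across-feature
#' dispersion of the diagonal second moments, solving
#' Var_v(S_iv\[mm\]) = 2 * Sbar_i\[mm\]^2 / (nu - M - 3) per metric and
#' averaging (floored at M + 4), and the scale is set so the prior mean
#' equals the average empirical covariance: Psi_i = (nu_i - M - 1) * Sbar_i.
#'
#' @param Z n x p x M standardized residual array.
#' @param batchFac batch factor of length n.
#' @param nuMax upper cap on the fitted degrees of freedom (guards the
#'   degenerate case of zero across-feature dispersion).
#' @return A [BatchPriors-class] object.
#' @export
momHyperparameters <- function(Z, batchFac, nuMax = 1e6) {
    stopifnot(is.array(Z), length(dim(Z)) == 3)
    batchFac <- droplevels(factor(batchFac))
    levs <- levels(batchFac)
    p <- dim(Z)[2]; M <- dim(Z)[3]
    if (p < 2) stop("across-feature moments need at least 2 features")
    tab <- table(batchFac)
    if (any(tab < M + 2))
        stop("each batch needs n_i >= M + 2 subjects")
    I <- length(levs)
    gammaBar <- matrix(NA_real_, I, M, dimnames = list(levs, dimnames(Z)[[3]]))
    Tmat <- Psi <- vector("list", I)
    nu <- numeric(I)
    for (i in seq_len(I)) {
        rows <- which(batchFac == levs[i])
        Zi <- Z[rows, , , drop = FALSE]
        Zbar <- apply(Zi, c(2, 3), mean)                   # p x M
        gammaBar[i, ] <- colMeans(Zbar)
        Tmat[[i]] <- stats::cov(Zbar)
        Slist <- array(NA_real_, c(p, M, M))
        for (v in seq_len(p))
            Slist[v, , ] <- stats::cov(matrix(Zi[, v, ], ncol = M))
        Sbar <- apply(Slist, c(2, 3), mean)
        nuM <- vapply(seq_len(M), function(m) {
            vS <- stats::var(Slist[, m, m])
            if (!is.finite(vS) || vS <= 0) return(nuMax)
            M + 3 + 2 * Sbar[m, m]^2 / vS
        }, 0)
        nu[i] <- min(max(mean(pmin(nuM, nuMax)), M + 4), nuMax)
        Psi[[i]] <- (nu[i] - M - 1) * Sbar
    }
    new("BatchPriors", gammaBar = gammaBar, Tmat = Tmat, Psi = Psi, nu = nu,
        batchLevels = levs)
}

#' Empirical-Bayes posterior batch effects by fixed-point iteration
#'
#' Computes, per (batch, feature), the conditional posterior means of the
#' cross-metric location effect and covariance under the conjugate
#' normal/inverse-Wishart priors:
#' \deqn{\gamma^* = (n_i \Sigma^{*-1} + \hat T_i^{-1})^{-1}
#'       (n_i \Sigma^{*-1} \bar Z_{iv} + \hat T_i^{-1} \hat\gamma_i)}
#' \deqn{\Sigma^* = \frac{\sum_j (Z_{ijv}-\gamma^*)(Z_{ijv}-\gamma^*)^\top +
#'       \hat\Psi_i}{n_i + \hat\nu_i - M - 1}}
#' The two updates are mutually dependent; they are alternated from
#' \eqn{\gamma^* = \bar Z_{iv}}, \eqn{\Sigma^* = S_{iv}} until the largest
#' elementwise change falls below `tol` (non-convergence is flagged and the
#' last iterate returned). A singular location-prior covariance is handled
#' with a pseudo-inverse (warning).
#'
#' @param Z n x p x M standardized residual array.
#' @param batchFac batch factor of length n.
#' @param priors a [BatchPriors-class] object.
#' @param tol convergence tolerance on the largest parameter change.
#' @param maxIter iteration cap.
#' @return A [BatchPosteriors-class] object with `estimator = "eb"`.
#' @export
ebPosteriors <- function(Z, batchFac, priors, tol = 1e-6, maxIter = 100L) {
    stopifnot(is(priors, "BatchPriors"))
    batchFac <- droplevels(factor(batchFac))
    levs <- levels(batchFac)
    if (!identical(levs, priors@batchLevels))
        stop("priors were estimated for different batch levels")
    p <- dim(Z)[2]; M <- dim(Z)[3]
    I <- length(levs)
    gammaStar <- Zbar <- array(NA_real_, c(I, p, M),
                               dimnames = list(levs, dimnames(Z)[[2]],
                                               dimnames(Z)[[3]]))
    SigmaStar <- vector("list", I); names(SigmaStar) <- levs
    iterations <- converged <- matrix(NA_real_, I, p)
    for (i in seq_len(I)) {
        rows <- which(batchFac == levs[i])
        ni <- length(rows)
        Tinv <- tryCatch(solve(priors@Tmat[[i]]), error = function(e) {
            warning("singular location-prior covariance; using pseudo-inverse")
            MASS::ginv(priors@Tmat[[i]])
        })
        gBar <- priors@gammaBar[i, ]
        Psi <- priors@Psi[[i]]; nu <- priors@nu[i]
        Sig <- array(NA_real_, c(p, M, M))
        for (v in seq_len(p)) {
            Zi <- matrix(Z[rows, v, ], ncol = M)
            zb <- colMeans(Zi)
            Craw <- crossprod(Zi)
            Zbar[i, v, ] <- zb
            g <- zb
            S <- .ridge(stats::cov(Zi))
            ok <- FALSE
            for (it in seq_len(maxIter)) {
                A <- ni * solve(S)
                W <- solve(A + Tinv)
                gNew <- as.numeric(W %*% (A %*% zb + Tinv %*% gBar))
                Cg <- Craw - ni * (outer(zb, gNew) + outer(gNew, zb)) +
                    ni * outer(gNew, gNew)
                SNew <- (Cg + Psi) / (ni + nu - M - 1)
                SNew <- (SNew + t(SNew)) / 2
                delta <- max(abs(gNew - g), abs(SNew - S))
                g <- gNew; S <- SNew
                if (delta < tol) { ok <- TRUE; break }
            }
            if (!ok)
                warning(sprintf(
                    "EB fixed point not converged for batch %s, feature %d",
                    levs[i], v))
            gammaStar[i, v, ] <- g
            Sig[v, , ] <- S
            iterations[i, v] <- it
            converged[i, v] <- ok
        }
        SigmaStar[[i]] <- Sig
    }
    new("BatchPosteriors", gammaStar = gammaStar, SigmaStar = SigmaStar,
        Zbar = Zbar, batchLevels = levs,
        featureIds = dimnames(Z)[[2]] %||% sprintf("F%03d", seq_len(p)),
        metricIds = dimnames(Z)[[3]] %||% paste0("M", seq_len(M)),
        estimator = "eb", iterations = iterations,
        converged = converged == 1, diagnostics = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Whiten residuals with respect to the posterior batch effects
#'
#' Applies the adjustment \eqn{Z^*_{ijv} = \Sigma^{*-1/2}_{iv}
#' (Z_{ijv} - \gamma^*_{iv})} per (batch, feature), where the inverse square
#' root is the symmetric (spectral) one with eigenvalues floored at 1e-10 —
#' whitening is then basis-independent and symmetric under metric
#' reordering. When the posteriors equal the sample moments, the per-batch
#' sample covariance of the output is the identity.
#'
#' @param Z n x p x M residual array on the standardized scale.
#' @param batchFac batch factor of length n.
#' @param posteriors a [BatchPosteriors-class] object.
#' @return The adjusted array, same shape as `Z`.
#' @export
adjustResiduals <- function(Z, batchFac, posteriors) {
    stopifnot(is(posteriors, "BatchPosteriors"))
    batchFac <- droplevels(factor(batchFac))
    levs <- levels(batchFac)
    if (!identical(levs, posteriors@batchLevels))
        stop("posteriors were estimated for different batch levels")
    p <- dim(Z)[2]; M <- dim(Z)[3]
    out <- Z
    for (i in seq_along(levs)) {
        rows <- which(batchFac == levs[i])
        for (v in seq_len(p)) {
            S <- matrix(posteriors@SigmaStar[[i]][v, , ], M, M)
            W <- .symSqrtInv(S)
            centered <- sweep(matrix(Z[rows, v, ], ncol = M), 2,
                              posteriors@gammaStar[i, v, ])
            out[rows, v, ] <- centered %*% W
        }
    }
    out
}

#' Multivariate ComBat harmonization
#'
#' Jointly harmonizes all metrics of each feature: fixed effects are fitted
#' and removed, residuals standardized to a common per-slice scale, the
#' cross-metric batch location and covariance effects estimated by empirical
#' Bayes (conjugate normal/inverse-Wishart priors, method-of-moments
#' hyperparameters; see [momHyperparameters()] and [ebPosteriors()]) or by
#' MCMC ([mcmcPosteriors()]), residuals whitened against the posterior batch
#' covariance ([adjustResiduals()]), and the scale and fixed effects
#' restored. With `recolor = "pooled"` the whitened residuals are
#' re-multiplied by the symmetric square root of the pooled across-batch
#' residual covariance of each feature, for users who want a pooled rather
#' than diagonal residual target; the default applies the whitening
#' literally. A single-batch panel is returned unchanged with a warning.
#'
#' @param data a [PanelData-class] object with I >= 2 batches and
#'   n_i >= M + 2 subjects per batch.
#' @param formula covariate formula passed to [fitFixedEffects()]; ignored
#'   when `model` is given.
#' @param model optional pre-fitted [FixedEffectsModel-class].
#' @param estimator `"eb"` (closed-form empirical Bayes, default) or
#'   `"mcmc"`.
#' @param recolor `"none"` (default) or `"pooled"`.
#' @param standardize `"pooled_sd"` or `"none"`.
#' @param tol,maxIter EB fixed-point stopping rule.
#' @param mcmcControl list of [mcmcPosteriors()] arguments (chains, iter,
#'   warmup, ...) used when `estimator = "mcmc"`.
#' @param seed RNG seed for the MCMC estimator; the EB path is exact.
#' @return list with elements `data` (harmonized [PanelData-class]),
#'   `posteriors` ([BatchPosteriors-class]), `priors` ([BatchPriors-class]
#'   or `NULL` for MCMC), `model`, `standardization`.
#' @examples
#' sim <- simulatePanel(simConfig(n = 120, p = 8, M = 3), seed = 11)
#' h <- mvCombat(sim@observed, ~ age + sex + diagnosis)
#' h$data
#' @export
mvCombat <- function(data, formula = NULL, model = NULL,
                     estimator = c("eb", "mcmc"),
                     recolor = c("none", "pooled"),
                     standardize = c("pooled_sd", "none"),
                     tol = 1e-6, maxIter = 100L, mcmcControl = list(),
                     seed = 1L) {
    estimator <- match.arg(estimator)
    recolor <- match.arg(recolor)
    standardize <- match.arg(standardize)
    stopifnot(is(data, "PanelData"))
    fem <- if (is.null(model)) fitFixedEffects(data, formula) else model
    b <- droplevels(batch(data))
    if (nlevels(b) < 2) {
        warning("single batch: nothing to harmonize, returning input")
        return(list(data = data, posteriors = NULL, priors = NULL,
                    model = fem, standardization = NULL))
    }
    .checkHarmonizable(data, needMultivariate = TRUE)
    Z <- removeFixedEffects(data, fem)
    std <- fitStandardization(Z, mode = standardize)
    Zs <- applyStandardization(Z, std)
    if (estimator == "eb") {
        priors <- momHyperparameters(Zs, b)
        post <- ebPosteriors(Zs, b, priors, tol = tol, maxIter = maxIter)
    } else {
        priors <- NULL
        post <- do.call(mcmcPosteriors,
                        c(list(Z = Zs, batchFac = b, seed = seed),
                          mcmcControl))
    }
    Zadj <- adjustResiduals(Zs, b, post)
    if (recolor == "pooled") {
        p <- dim(Zs)[2]; M <- dim(Zs)[3]
        for (v in seq_len(p)) {
            Spool <- stats::cov(matrix(Zs[, v, ], ncol = M))
            Zadj[, v, ] <- matrix(Zadj[, v, ], ncol = M) %*% .symSqrt(Spool)
        }
    }
    vals <- restoreFixedEffects(invertStandardization(Zadj, std), fem)
    list(data = .replaceValues(data, vals), posteriors = post,
         priors = priors, model = fem, standardization = std)
}

#' @describeIn BatchPriors-class compact display
#' @param object a `BatchPriors` object.
#' @export
setMethod("show", "BatchPriors", function(object) {
    cat("BatchPriors over", length(object@batchLevels), "batches x",
        ncol(object@gammaBar), "metrics\n")
    cat("nu:", paste(signif(object@nu, 4), collapse = ", "), "\n")
})

#' @describeIn BatchPosteriors-class compact display
#' @param object a `BatchPosteriors` object.
#' @export
setMethod("show", "BatchPosteriors", function(object) {
    cat("BatchPosteriors (", object@estimator, "): ",
        length(object@batchLevels), " batches x ",
        length(object@featureIds), " features x ",
        length(object@metricIds), " metrics\n", sep = "")
    if (length(object@diagnostics)) {
        d <- object@diagnostics
        if (!is.null(d$rhat))
            cat("max Rhat:", signif(max(d$rhat, na.rm = TRUE), 4),
                " min ESS:", signif(min(d$ess, na.rm = TRUE), 4), "\n")
    } else if (all(dim(object@converged) > 0)) {
        cat(sum(object@converged), "of", length(object@converged),
            "fixed points converged\n")
    }
})
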