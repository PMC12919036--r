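## Core per-slice ComBat engine: location/scale empirical Bayes across the
## columns of a matrix (slices), with MoM hyperparameters per batch.
## Columns are internally standardized (pooled mean / pooled ddof-1 SD) so
## the engine can be reused on raw residual slices and on PC/latent scores.
.combatSlices <- function(Z, batchFac, eb = TRUE, tol = 1e-6,
                          maxIter = 100L, standardize = TRUE) {
    Z <- as.matrix(Z)
    n <- nrow(Z); q <- ncol(Z)
    batchFac <- droplevels(factor(batchFac))
    levs <- levels(batchFac)
    I <- length(levs)
    if (I < 2) stop("at least two batches are required")
    if (any(table(batchFac) < 2)) stop("a batch with n_i < 2")
    if (standardize) {
        ctr <- colMeans(Z)
        scl <- apply(Z, 2, stats::sd)
        if (any(scl <= 0)) stop("zero-variance slice")
        Zs <- sweep(sweep(Z, 2, ctr), 2, scl, "/")
    } else {
        ctr <- rep(0, q); scl <- rep(1, q)
        Zs <- Z
    }
    gammaStar <- deltaStar <- matrix(NA_real_, I, q,
                                     dimnames = list(levs, colnames(Z)))
    hyper <- vector("list", I); names(hyper) <- levs
    useEB <- eb && q >= 2
    if (eb && q < 2)
        warning("EB pooling needs >= 2 slices; using direct estimates")
    adj <- Zs
    for (i in seq_len(I)) {
        rows <- which(batchFac == levs[i])
        ni <- length(rows)
        Zi <- Zs[rows, , drop = FALSE]
        gHat <- colMeans(Zi)
        dHat <- apply(Zi, 2, stats::var)
        dHat <- pmax(dHat, 1e-12)
        if (useEB) {
            gBar <- mean(gHat); tau2 <- stats::var(gHat)
            mD <- mean(dHat); s2D <- stats::var(dHat)
            lambda <- (2 * s2D + mD^2) / s2D
            theta <- (mD * s2D + mD^3) / s2D
            g <- gHat; d <- dHat
            for (it in seq_len(maxIter)) {
                gNew <- (ni * tau2 * gHat + d * gBar) / (ni * tau2 + d)
                ss <- colSums((Zi - rep(gNew, each = ni))^2)
                dNew <- (theta + 0.5 * ss) / (ni / 2 + lambda - 1)
                delta <- max(abs(gNew - g), abs(dNew - d))
                g <- gNew; d <- dNew
                if (delta < tol) break
            }
            hyper[[i]] <- list(gamma_bar = gBar, tau2 = tau2,
                               lambda = lambda, theta = theta,
                               iterations = it)
        } else {
            g <- gHat; d <- dHat
            hyper[[i]] <- list(gamma_bar = mean(gHat), tau2 = stats::var(gHat),
                               lambda = NA_real_, theta = NA_real_,
                               iterations = 0L)
        }
        gammaStar[i, ] <- g
        deltaStar[i, ] <- d
        adj[rows, ] <- sweep(sweep(Zi, 2, g), 2, sqrt(d), "/")
    }
    out <- sweep(sweep(adj, 2, scl, "*"), 2, ctr, "+")
    list(adjusted = out, gammaStar = gammaStar, deltaStar = deltaStar,
         hyper = hyper, center = ctr, scale = scl)
}

#' Univariate ComBat harmonization per metric
#'
#' The classical per-feature location/scale harmonizer, applied independently
#' to each metric of the panel and used both as a baseline and as the inner
#' engine of CovBat-style score harmonization. For each (feature, metric)
#' slice, fixed-effect residuals are standardized to pooled mean 0 / SD 1,
#' batch-specific additive (normal prior) and multiplicative (inverse-gamma
#' prior) effects are shrunk by empirical Bayes with method-of-moments
#' hyperparameters estimated across the features of the metric, the residual
#' is adjusted to (z - gamma*) / delta*, and the scale and fixed effects are
#' restored. `eb = FALSE` uses the direct batch-wise estimates (no
#' shrinkage). A single-batch panel is returned unchanged with a warning.
#'
#' @param data a [PanelData-class] object.
#' @param formula covariate formula passed to [fitFixedEffects()]; ignored
#'   when `model` is given.
#' @param model optional pre-fitted [FixedEffectsModel-class].
#' @param eb logical, empirical-Bayes shrinkage (default `TRUE`).
#' @param tol,maxIter stopping rule of the EB fixed-point iteration.
#' @return list with elements `data` (harmonized [PanelData-class]),
#'   `effects` ([UVBatchEffects-class], on the standardized scale) and
#'   `model` (the fixed-effects fit).
#' @references Johnson, W.E., Li, C., Rabinovic, A. (2007) Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1), 118-127.
#' @examples
#' sim <- simulatePanel(simConfig(n = 90, p = 6, M = 2), seed = 7)
#' h <- uvCombat(sim@observed, ~ age + sex + diagnosis)
#' h$data
#' @export
uvCombat <- function(data, formula = NULL, model = NULL, eb = TRUE,
                     tol = 1e-6, maxIter = 100L) {
    stopifnot(is(data, "PanelData"))
    fem <- if (is.null(model)) fitFixedEffects(data, formula) else model
    b <- droplevels(batch(data))
    levs <- levels(b)
    p <- nFeatures(data); M <- nMetrics(data)
    if (length(levs) < 2) {
        warning("single batch: nothing to harmonize, returning input")
        eff <- new("UVBatchEffects",
                   gammaStar = array(0, c(1, p, M)),
                   deltaStar = array(1, c(1, p, M)),
                   hyper = list(), batchLevels = levs, eb = eb)
        return(list(data = data, effects = eff, model = fem))
    }
    .checkHarmonizable(data)
    Z <- removeFixedEffects(data, fem)
    gammaStar <- deltaStar <- array(
        NA_real_, c(length(levs), p, M),
        dimnames = list(levs, featureIds(data), metricNames(data)))
    hyper <- vector("list", M); names(hyper) <- metricNames(data)
    Zadj <- Z
    for (m in seq_len(M)) {
        fit <- .combatSlices(Z[, , m], b, eb = eb, tol = tol,
                             maxIter = maxIter)
        Zadj[, , m] <- fit$adjusted
        gammaStar[, , m] <- fit$gammaStar
        deltaStar[, , m] <- fit$deltaStar
        hyper[[m]] <- fit$hyper
    }
    vals <- restoreFixedEffects(Zadj, fem)
    eff <- new("UVBatchEffects", gammaStar = gammaStar,
               deltaStar = deltaStar, hyper = hyper,
               batchLevels = levs, eb = eb)
    list(data = .replaceValues(data, vals), effects = eff, model = fem)
}

#' Univariate CovBat harmonization per metric
#'
#' Two-stage covariance harmonizer: stage 1 is [uvCombat()]; stage 2
#' eigendecomposes the pooled stage-1 residual covariance of each metric
#' (features within a metric treated jointly, metrics independent), retains
#' the smallest number K of leading principal components reaching
#' `varFraction` of total variance, applies the per-slice ComBat engine to
#' the K score columns (intercept-only design: fixed effects were already
#' removed), and reconstructs the residuals before restoring fixed effects.
#'
#' @inheritParams uvCombat
#' @param varFraction fraction of total residual variance whose covariance
#'   structure is harmonized, in (0, 1]; default 0.95.
#' @return list with elements `data` (harmonized [PanelData-class]),
#'   `decompositions` (per-metric [UVCovBatDecomposition-class]), `stage1`
#'   (the [uvCombat()] result) and `model`.
#' @references Chen, A.A. et al. (2022) Mitigating site effects in covariance
#'   for machine learning in neuroimaging data. Human Brain Mapping 43(4).
#' @export
uvCovbat <- function(data, formula = NULL, model = NULL, eb = TRUE,
                     varFraction = 0.95, tol = 1e-6, maxIter = 100L) {
    if (varFraction <= 0 || varFraction > 1)
        stop("varFraction must lie in (0, 1]")
    stage1 <- uvCombat(data, formula = formula, model = model, eb = eb,
                       tol = tol, maxIter = maxIter)
    b <- droplevels(batch(data))
    if (nlevels(b) < 2)
        return(list(data = stage1$data, decompositions = list(),
                    stage1 = stage1, model = stage1$model))
    fem <- stage1$model
    E <- removeFixedEffects(stage1$data, fem)
    p <- nFeatures(data); M <- nMetrics(data)
    decomps <- vector("list", M); names(decomps) <- metricNames(data)
    Eadj <- E
    for (m in seq_len(M)) {
        Em <- E[, , m]
        ctr <- colMeans(Em)
        Ec <- sweep(Em, 2, ctr)
        eg <- eigen(stats::cov(Ec), symmetric = TRUE)
        phi <- .fixSigns(eg$vectors)
        K <- .countForFraction(pmax(eg$values, 0), varFraction)
        scores <- Ec %*% phi
        fit <- .combatSlices(scores[, seq_len(K), drop = FALSE], b, eb = eb,
                             tol = tol, maxIter = maxIter)
        Eadj[, , m] <- Em + (fit$adjusted - scores[, seq_len(K),
                                                   drop = FALSE]) %*%
            t(phi[, seq_len(K), drop = FALSE])
        decomps[[m]] <- new("UVCovBatDecomposition",
                            metric = metricNames(data)[m], rotation = phi,
                            scores = scores, K = as.integer(K),
                            varFraction = varFraction,
                            scoreEffects = fit[c("gammaStar", "deltaStar",
                                                 "hyper")])
    }
    vals <- restoreFixedEffects(Eadj, fem)
    list(data = .replaceValues(data, vals), decompositions = decomps,
         stage1 = stage1, model = fem)
}
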