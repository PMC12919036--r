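#' Covariate-signal preservation after harmonization
#'
#' Fits per-slice linear regressions of the (harmonized) values on the
#' protected covariates and tests the `target` coefficient in every
#' (feature, metric) slice. Discoveries are declared by Benjamini-Hochberg
#' at level `alpha` over all p x M slices. With ground truth available (a
#' logical p x M matrix, or a vector of biomarker feature ids taken to act
#' on all metrics), true positives and the empirical false discovery rate
#' FDR = FP / max(1, discoveries) are reported.
#'
#' @param data a [PanelData-class] object.
#' @param formula covariate formula for the per-slice regressions.
#' @param target name of the tested covariate (default `"diagnosis"`).
#' @param truth `NULL`, a logical p x M matrix of true-effect slices, or a
#'   character/integer vector of true-effect features.
#' @param alpha BH level (default 0.05).
#' @return list with `pvalues` (p x M), `significant` (logical p x M after
#'   BH), `nDiscoveries`, and — when truth is given — `TP`, `FP`, `FDR`.
#' @export
signalPreservation <- function(data, formula, target = "diagnosis",
                               truth = NULL, alpha = 0.05) {
    stopifnot(is(data, "PanelData"))
    cov <- covariates(data)
    formula <- stats::as.formula(formula)
    if (!(target %in% all.vars(formula)))
        stop("'", target, "' is not a term of the formula")
    X <- stats::model.matrix(formula, data = cov)
    tcols <- grep(paste0("^", target), colnames(X))
    if (length(tcols) != 1)
        stop("the target must map to exactly one design column")
    arr <- panelArray(data)
    n <- dim(arr)[1]; p <- dim(arr)[2]; M <- dim(arr)[3]
    Y <- matrix(arr, nrow = n)
    qx <- qr(X)
    B <- qr.coef(qx, Y)
    resid <- Y - X %*% B
    dfRes <- n - qx$rank
    sigma2 <- colSums(resid^2) / dfRes
    XtXinv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * XtXinv[tcols, tcols])
    tval <- B[tcols, ] / se
    pv <- 2 * stats::pt(abs(tval), dfRes, lower.tail = FALSE)
    pmat <- matrix(pv, p, M,
                   dimnames = list(featureIds(data), metricNames(data)))
    padj <- matrix(stats::p.adjust(pmat, method = "BH"), p, M,
                   dimnames = dimnames(pmat))
    sig <- padj <= alpha
    out <- list(pvalues = pmat, significant = sig,
                nDiscoveries = sum(sig))
    if (!is.null(truth)) {
        if (is.matrix(truth)) truthMat <- truth
        else {
            truthMat <- matrix(FALSE, p, M, dimnames = dimnames(pmat))
            truthMat[truth, ] <- TRUE
        }
        out$TP <- sum(sig & truthMat)
        out$FP <- sum(sig & !truthMat)
        out$FDR <- out$FP / max(1, out$nDiscoveries)
    }
    out
}

#' Empirical-Bayes prior adequacy checks
#'
#' Compares the empirical distribution of the estimated additive batch
#' effects with their fitted normal prior (standardized Mahalanobis
#' discrepancies of the batch-feature residual means against
#' N(gammaBar_i, T_i)), and performs a prior predictive check for the
#' covariance prior: Frobenius distances of the per-feature empirical
#' covariances to the inverse-Wishart prior mean are compared with the same
#' distances computed for draws simulated from the fitted IW prior, summarized
#' by the overlap coefficient of the two histograms (shared breaks).
#' Overlap near 1 indicates the EB assumptions are reasonable.
#'
#' @param posteriors a [BatchPosteriors-class] (for the residual means).
#' @param priors a [BatchPriors-class].
#' @param Z the standardized residual array used for the fit.
#' @param batchFac batch factor of length n.
#' @param nDraws IW prior draws per batch for the predictive check.
#' @param seed integer seed for the prior draws.
#' @return list per batch with `locationDiscrepancy` (per-feature
#'   Mahalanobis distances, or `NULL` with `degenerate = TRUE` when T is
#'   singular), `empiricalDist`, `priorDist`, `overlap`.
#' @export
ebPriorChecks <- function(posteriors, priors, Z, batchFac, nDraws = 500L,
                          seed = 1L) {
    stopifnot(is(posteriors, "BatchPosteriors"), is(priors, "BatchPriors"))
    batchFac <- droplevels(factor(batchFac))
    levs <- levels(batchFac)
    M <- ncol(priors@gammaBar)
    p <- dim(Z)[2]
    set.seed(seed)
    out <- vector("list", length(levs)); names(out) <- levs
    for (i in seq_along(levs)) {
        rows <- which(batchFac == levs[i])
        Zbar <- posteriors@Zbar[i, , ]
        Tm <- priors@Tmat[[i]]
        degenerate <- min(eigen(Tm, symmetric = TRUE,
                                only.values = TRUE)$values) < 1e-12
        loc <- NULL
        if (!degenerate) {
            Tinv <- solve(Tm)
            loc <- apply(Zbar, 1, function(z) {
                d <- z - priors@gammaBar[i, ]
                sqrt(max(0, sum(d * (Tinv %*% d))))
            })
        }
        priorMean <- priors@Psi[[i]] / (priors@nu[i] - M - 1)
        empD <- vapply(seq_len(p), function(v) {
            S <- stats::cov(matrix(Z[rows, v, ], ncol = M))
            sqrt(sum((S - priorMean)^2))
        }, 0)
        priD <- vapply(seq_len(nDraws), function(k) {
            S <- drawBatchCovariance("IW", M, list(Psi = priors@Psi[[i]],
                                                   nu = priors@nu[i]))
            sqrt(sum((S - priorMean)^2))
        }, 0)
        breaks <- seq(0, max(empD, priD) * 1.001, length.out = 31)
        h1 <- graphics::hist(empD, breaks = breaks, plot = FALSE)$density
        h2 <- graphics::hist(priD, breaks = breaks, plot = FALSE)$density
        bw <- diff(breaks)[1]
        out[[i]] <- list(locationDiscrepancy = loc,
                         degenerate = degenerate,
                         empiricalDist = empD, priorDist = priD,
                         overlap = sum(pmin(h1, h2)) * bw)
    }
    out
}
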