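#' Per-metric PCA of a residual matrix
#'
#' SVD-based PCA of a column-centered n x p residual matrix. Scores carry
#' the singular-value scale (F = U D), so that the shared-subspace objective
#' downstream weights directions by explained variance; loadings have
#' orthonormal columns with a deterministic sign convention (largest-
#' magnitude loading positive). The retained rank r_m is the smallest count
#' of components reaching `varFraction` of total variance.
#'
#' @param R n x p residual matrix, column-centered (checked to 1e-6).
#' @param varFraction retained-variance fraction in (0, 1]; default 0.95.
#' @return list with `scores` (n x r_m), `loadings` (p x r_m), `r` (rank
#'   retained), `values` (all squared singular values / (n - 1)).
#' @export
metricPCA <- function(R, varFraction = 0.95) {
    R <- as.matrix(R)
    if (nrow(R) < 2) stop("need at least 2 rows")
    if (max(abs(colMeans(R))) > 1e-6)
        stop("residual matrix must be column-centered")
    sv <- svd(R)
    fullRank <- sum(sv$d > max(sv$d) * 1e-12)
    vals <- sv$d^2 / (nrow(R) - 1)
    r <- min(.countForFraction(vals, varFraction), fullRank)
    V <- sv$v[, seq_len(r), drop = FALSE]
    flip <- vapply(seq_len(r), function(k) {
        j <- which.max(abs(V[, k]))
        if (V[j, k] < 0) -1 else 1
    }, 0)
    V <- sweep(V, 2, flip, "*")
    Fm <- sweep(sv$u[, seq_len(r), drop = FALSE], 2,
                sv$d[seq_len(r)] * flip, "*")
    list(scores = Fm, loadings = V, r = r, values = vals)
}

#' Shared orthonormal subspace across metric score matrices
#'
#' Finds the n x r_s orthonormal matrix G minimizing
#' \eqn{\sum_m \|F^{(m)} - G A^{(m)}\|_F^2} subject to \eqn{G^\top G = I},
#' which (by the Rayleigh-Ritz theorem) is spanned by the top r_s
#' eigenvectors of \eqn{S = \sum_m F^{(m)} F^{(m)\top}}; the optimal
#' projections are \eqn{A^{(m)} = G^\top F^{(m)}} and the attained objective
#' equals \eqn{\sum_m \|F^{(m)}\|_F^2 - \mathrm{Tr}(G^\top S G)}.
#'
#' @param Flist list of n x r_m score matrices, one per metric.
#' @param rs integer dimension of the shared subspace, or `NULL` to pick the
#'   smallest count of eigenvalues of S reaching `sharedFraction` of their
#'   total.
#' @param sharedFraction cumulative eigenvalue fraction used when `rs` is
#'   `NULL`; default 0.95.
#' @return list with `G` (n x r_s, orthonormal, sign-fixed), `A` (list of
#'   r_s x r_m), `eigenvalues` (all eigenvalues of S, descending),
#'   `objective` (the attained value of the least-squares criterion).
#' @export
sharedSubspace <- function(Flist, rs = NULL, sharedFraction = 0.95) {
    stopifnot(is.list(Flist), length(Flist) >= 1)
    n <- nrow(Flist[[1]])
    if (any(vapply(Flist, nrow, 0L) != n))
        stop("all score matrices must share the subject count")
    S <- matrix(0, n, n)
    for (Fm in Flist) S <- S + tcrossprod(Fm)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    if (is.null(rs)) rs <- .countForFraction(vals, sharedFraction)
    if (rs > n) stop("rs cannot exceed the subject count")
    ties <- which(abs(diff(vals)) < 1e-12 * max(vals, 1))
    if (rs %in% ties)
        warning("eigenvalue tie at the retained rank; broken by index order")
    G <- .fixSigns(eg$vectors[, seq_len(rs), drop = FALSE])
    A <- lapply(Flist, function(Fm) crossprod(G, Fm))
    obj <- sum(vapply(Flist, function(Fm) sum(Fm^2), 0)) -
        sum(vals[seq_len(rs)])
    list(G = G, A = A, eigenvalues = vals, objective = obj)
}

#' Harmonize shared latent scores across batches
#'
#' Applies the univariate ComBat engine column-wise to the shared score
#' matrix G, treating subjects as observations and latent dimensions as
#' features (intercept-only design: fixed effects were removed before the
#' latent model was built).
#'
#' @param G n x r_s shared score matrix.
#' @param batchFac batch factor of length n.
#' @param eb logical, empirical-Bayes shrinkage across latent dimensions.
#' @return list with `G` (harmonized score matrix, same shape) and
#'   `effects` (per-column ComBat estimates).
#' @export
harmonizeSharedScores <- function(G, batchFac, eb = TRUE) {
    batchFac <- droplevels(factor(batchFac))
    if (nlevels(batchFac) < 2) stop("at least two batches are required")
    fit <- .combatSlices(G, batchFac, eb = eb)
    list(G = fit$adjusted,
         effects = fit[c("gammaStar", "deltaStar", "hyper")])
}

#' Build the latent model of MV-CovBat's second stage
#'
#' Column-centers each metric's residual matrix, runs [metricPCA()], and
#' estimates the shared subspace with [sharedSubspace()], storing everything
#' needed for exact reconstruction (idiosyncratic components and the
#' discarded-component remainder).
#'
#' @param residuals list (per metric) of n x p residual matrices.
#' @param varFraction per-metric PCA retained-variance fraction.
#' @param rs,sharedFraction shared-subspace rank rule (see
#'   [sharedSubspace()]).
#' @param metricIds metric identifiers.
#' @return A [LatentModel-class] object.
#' @export
fitLatentModel <- function(residuals, varFraction = 0.95, rs = NULL,
                           sharedFraction = 0.95,
                           metricIds = names(residuals)) {
    M <- length(residuals)
    if (is.null(metricIds)) metricIds <- paste0("M", seq_len(M))
    centers <- lapply(residuals, colMeans)
    centered <- lapply(residuals, function(R) sweep(R, 2, colMeans(R)))
    pcas <- lapply(centered, metricPCA, varFraction = varFraction)
    Flist <- lapply(pcas, `[[`, "scores")
    shared <- sharedSubspace(Flist, rs = rs, sharedFraction = sharedFraction)
    H <- lapply(seq_len(M), function(m)
        Flist[[m]] - shared$G %*% shared$A[[m]])
    remainder <- lapply(seq_len(M), function(m)
        centered[[m]] - tcrossprod(Flist[[m]], pcas[[m]]$loadings))
    new("LatentModel",
        loadings = lapply(pcas, `[[`, "loadings"), scores = Flist,
        centers = centers, remainder = remainder, G = shared$G,
        A = shared$A, H = H, eigenvalues = shared$eigenvalues,
        varFraction = varFraction,
        sharedFraction = if (is.null(rs)) sharedFraction else NA_real_,
        metricIds = metricIds)
}

#' Reconstruct metric residuals from harmonized shared scores
#'
#' Propagates harmonized shared scores back to each metric's feature space:
#' \eqn{F^{*(m)} = G^* A^{(m)} + H^{(m)}} and
#' \eqn{R^{*(m)} = F^{*(m)} L^{(m)\top}} plus the discarded-component
#' remainder and the column centers, so that `Gstar = G` reproduces the
#' input residuals exactly.
#'
#' @param latent a [LatentModel-class] object.
#' @param Gstar harmonized shared score matrix (same shape as `latent@G`).
#' @return list (per metric) of reconstructed n x p residual matrices.
#' @export
reconstructResiduals <- function(latent, Gstar) {
    stopifnot(is(latent, "LatentModel"))
    if (!all(dim(Gstar) == dim(latent@G))) stop("shape mismatch for Gstar")
    lapply(seq_along(latent@metricIds), function(m) {
        Fstar <- Gstar %*% latent@A[[m]] + latent@H[[m]]
        R <- tcrossprod(Fstar, latent@loadings[[m]]) + latent@remainder[[m]]
        sweep(R, 2, latent@centers[[m]], "+")
    })
}

#' Multivariate CovBat harmonization
#'
#' Two-stage multivariate harmonizer: stage 1 applies [mvCombat()] (EB) to
#' remove per-feature cross-metric batch effects; stage 2 column-centers the
#' stage-1 fixed-effect residuals of each metric, decomposes them with
#' per-metric PCA, estimates the shared orthonormal latent subspace across
#' metrics, harmonizes the shared scores across batches with the univariate
#' ComBat engine, reconstructs the residuals, and restores fixed effects —
#' targeting covariance batch effects across features and, through the
#' shared subspace, across metrics.
#'
#' @inheritParams mvCombat
#' @param varFraction per-metric PCA retained-variance fraction (default
#'   0.95).
#' @param rs shared-subspace dimension; `NULL` (default) selects it by the
#'   cumulative eigenvalue fraction `sharedFraction` of S.
#' @param sharedFraction cumulative eigenvalue fraction for r_s (default
#'   0.95).
#' @param scoreEB empirical-Bayes shrinkage for the score-level ComBat.
#' @return list with elements `data` (harmonized [PanelData-class]),
#'   `latent` ([LatentModel-class]), `scoreEffects`, and `stage1` (the
#'   [mvCombat()] result).
#' @examples
#' sim <- simulatePanel(simConfig(n = 120, p = 8, M = 3,
#'                                scenario = "latent"), seed = 3)
#' h <- mvCovbat(sim@observed, ~ age + sex + diagnosis)
#' h$data
#' @export
mvCovbat <- function(data, formula = NULL, model = NULL,
                     estimator = "eb", varFraction = 0.95, rs = NULL,
                     sharedFraction = 0.95, scoreEB = TRUE,
                     standardize = c("pooled_sd", "none"),
                     tol = 1e-6, maxIter = 100L, seed = 1L,
                     mcmcControl = list()) {
    stage1 <- mvCombat(data, formula = formula, model = model,
                       estimator = estimator, standardize = standardize,
                       tol = tol, maxIter = maxIter, seed = seed,
                       mcmcControl = mcmcControl)
    b <- droplevels(batch(data))
    if (nlevels(b) < 2)
        return(list(data = stage1$data, latent = NULL, scoreEffects = NULL,
                    stage1 = stage1))
    fem <- stage1$model
    E <- removeFixedEffects(stage1$data, fem)
    M <- nMetrics(data)
    residuals <- lapply(seq_len(M), function(m) E[, , m])
    names(residuals) <- metricNames(data)
    latent <- fitLatentModel(residuals, varFraction = varFraction, rs = rs,
                             sharedFraction = sharedFraction,
                             metricIds = metricNames(data))
    harm <- harmonizeSharedScores(latent@G, b, eb = scoreEB)
    Rstar <- reconstructResiduals(latent, harm$G)
    Eadj <- E
    for (m in seq_len(M)) Eadj[, , m] <- Rstar[[m]]
    vals <- restoreFixedEffects(Eadj, fem)
    list(data = .replaceValues(data, vals), latent = latent,
         scoreEffects = harm$effects, stage1 = stage1)
}

#' @describeIn LatentModel-class compact display
#' @param object a `LatentModel`.
#' @export
setMethod("show", "LatentModel", function(object) {
    cat("LatentModel:", length(object@metricIds), "metrics, shared rank",
        ncol(object@G), "\n")
    cat("per-metric ranks:",
        paste(vapply(object@scores, ncol, 0L), collapse = ", "), "\n")
})
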