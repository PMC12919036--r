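#' Distances between two correlation (or covariance) matrices
#'
#' The four matrix-distance criteria used throughout the evaluation battery:
#' Frobenius norm of the difference, element-wise mean squared error, mean
#' absolute difference of descending-sorted eigenvalues, and spectral norm
#' (largest singular value) of the difference. All are zero on identical
#' inputs and invariant under a simultaneous row/column permutation.
#'
#' @param C1,C2 square symmetric matrices of equal dimension.
#' @return named numeric vector `frobenius`, `mse`, `eigen_error`,
#'   `spectral`.
#' @export
correlationMatrixDistances <- function(C1, C2) {
    stopifnot(all(dim(C1) == dim(C2)))
    D <- C1 - C2
    e1 <- sort(eigen((C1 + t(C1)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    e2 <- sort(eigen((C2 + t(C2)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    c(frobenius = sqrt(sum(D^2)),
      mse = mean(D^2),
      eigen_error = mean(abs(e1 - e2)),
      spectral = max(svd(D, nu = 0, nv = 0)$d))
}

## Pooled-feature correlation with within-metric blocks zeroed out, for the
## cross-metric view.
.crossMetricCor <- function(E, p, M, blocks = c("cross", "full")) {
    blocks <- match.arg(blocks)
    C <- stats::cor(E)
    if (blocks == "cross") {
        met <- rep(seq_len(M), each = p)
        C[outer(met, met, "==")] <- 0
    }
    C
}

#' Correlation-structure batch metrics
#'
#' Measures batch effects in (or recovery of) correlation structure.
#' `scope = "within_metric"` uses, per metric, the p x p feature correlation
#' matrix of the fixed-effect residuals; `scope = "cross_metric"` uses the
#' pooled n x (pM) residual matrix's correlation restricted to between-metric
#' blocks (within-metric blocks zeroed; `blocks = "full"` keeps them).
#' `reference = "across_batches"` averages the four distances over all batch
#' pairs (per-batch correlation matrices); `reference = "vs_gold"` compares
#' the pooled correlation of `data` with that of `gold`.
#'
#' @param data a [PanelData-class] object.
#' @param scope `"within_metric"` or `"cross_metric"`.
#' @param reference `"across_batches"` or `"vs_gold"`.
#' @param gold gold-standard [PanelData-class] (required for `"vs_gold"`).
#' @param formula,model fixed-effect specification used to compute
#'   residuals.
#' @param blocks cross-metric block handling (see above).
#' @return For `within_metric`: a matrix (metrics x 4 distances), with the
#'   across-metric mean in attribute `"mean"`. For `cross_metric`: a named
#'   vector of the four distances.
#' @export
correlationDistances <- function(data,
                                 scope = c("within_metric", "cross_metric"),
                                 reference = c("across_batches", "vs_gold"),
                                 gold = NULL, formula = NULL, model = NULL,
                                 blocks = c("cross", "full")) {
    scope <- match.arg(scope)
    reference <- match.arg(reference)
    stopifnot(is(data, "PanelData"))
    b <- droplevels(batch(data))
    if (reference == "across_batches" && any(table(b) < 3))
        stop("need n_i >= 3 per batch to estimate correlations")
    if (reference == "vs_gold" && is.null(gold))
        stop("'gold' is required for reference = 'vs_gold'")
    fem <- if (is.null(model)) fitFixedEffects(data, formula) else model
    Z <- removeFixedEffects(data, fem)
    p <- dim(Z)[2]; M <- dim(Z)[3]
    flat <- matrix(Z, nrow = dim(Z)[1])
    Zg <- NULL
    if (!is.null(gold)) {
        femG <- fitFixedEffects(gold, stats::as.formula(fem@formula))
        Zg <- removeFixedEffects(gold, femG)
    }
    if (scope == "within_metric") {
        res <- matrix(NA_real_, M, 4,
                      dimnames = list(metricNames(data),
                                      c("frobenius", "mse", "eigen_error",
                                        "spectral")))
        for (m in seq_len(M)) {
            if (reference == "across_batches") {
                cors <- lapply(levels(b), function(l)
                    stats::cor(Z[b == l, , m]))
                pairs <- utils::combn(length(cors), 2)
                ds <- apply(pairs, 2, function(ij)
                    correlationMatrixDistances(cors[[ij[1]]], cors[[ij[2]]]))
                res[m, ] <- rowMeans(ds)
            } else {
                res[m, ] <- correlationMatrixDistances(
                    stats::cor(Z[, , m]), stats::cor(Zg[, , m]))
            }
        }
        structure(res, mean = colMeans(res))
    } else {
        if (reference == "across_batches") {
            cors <- lapply(levels(b), function(l)
                .crossMetricCor(flat[b == l, , drop = FALSE], p, M, blocks))
            pairs <- utils::combn(length(cors), 2)
            ds <- apply(pairs, 2, function(ij)
                correlationMatrixDistances(cors[[ij[1]]], cors[[ij[2]]]))
            rowMeans(ds)
        } else {
            correlationMatrixDistances(
                .crossMetricCor(flat, p, M, blocks),
                .crossMetricCor(matrix(Zg, nrow = dim(Zg)[1]), p, M, blocks))
        }
    }
}
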