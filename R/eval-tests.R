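#' Univariate batch-effect tests per slice
#'
#' Runs, on fixed-effect residuals, the standard location tests (one-way
#' ANOVA, Kruskal-Wallis) and scale tests (Levene with mean centering,
#' Bartlett, Fligner-Killeen) for every (feature, metric) slice against the
#' batch factor. Bonferroni correction is applied per test type over all
#' p x M slices. Zero-variance slices yield `NA` with a warning.
#'
#' @param data a [PanelData-class] object.
#' @param formula,model fixed-effect specification (see [fitFixedEffects()]);
#'   `NULL` fits an intercept-only model.
#' @return data.frame with columns feature, metric, test, p, p_bonf.
#' @export
univariateBatchTests <- function(data, formula = NULL, model = NULL) {
    stopifnot(is(data, "PanelData"))
    b <- droplevels(batch(data))
    if (nlevels(b) < 2) stop("at least two batches are required")
    fem <- if (is.null(model)) fitFixedEffects(data, formula) else model
    Z <- removeFixedEffects(data, fem)
    p <- dim(Z)[2]; M <- dim(Z)[3]
    tests <- c("anova", "kruskal", "levene", "bartlett", "fligner")
    out <- expand.grid(feature = featureIds(data),
                       metric = metricNames(data), test = tests,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$p <- NA_real_
    warned <- FALSE
    for (m in seq_len(M)) for (v in seq_len(p)) {
        y <- Z[, v, m]
        if (stats::sd(y) == 0) {
            if (!warned) {
                warning("zero-variance slice(s): p-values set to NA")
                warned <- TRUE
            }
            next
        }
        pv <- c(
            anova = stats::anova(stats::lm(y ~ b))$`Pr(>F)`[1],
            kruskal = stats::kruskal.test(y, b)$p.value,
            levene = car::leveneTest(y, b, center = mean)$`Pr(>F)`[1],
            bartlett = stats::bartlett.test(y, b)$p.value,
            fligner = stats::fligner.test(y, b)$p.value)
        idx <- (match(tests, tests) - 1) * p * M + (m - 1) * p + v
        out$p[idx] <- pv[tests]
    }
    out$p_bonf <- pmin(out$p * (p * M), 1)
    out
}

#' Box's M test for equality of covariance matrices
#'
#' Tests whether the M-variate covariance matrix of `x` is equal across the
#' groups, using the chi-square approximation: the statistic
#' \eqn{M_B = (N - I)\ln|S_{pool}| - \sum_i (n_i - 1)\ln|S_i|} with the
#' standard small-sample correction factor, referred to a chi-square with
#' (I - 1) M (M + 1) / 2 degrees of freedom. Singular group covariances are
#' ridged (1e-8 on the diagonal) with a warning.
#'
#' @param x n x M numeric matrix (rows = observations).
#' @param groups factor of length n with at least two levels, each with
#'   n_i >= M + 2 observations.
#' @return object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
boxMTest <- function(x, groups) {
    x <- as.matrix(x)
    groups <- droplevels(factor(groups))
    I <- nlevels(groups)
    M <- ncol(x)
    N <- nrow(x)
    if (I < 2) stop("need at least two groups")
    tab <- table(groups)
    if (any(tab < M + 2))
        stop("each group needs n_i >= M + 2 observations")
    Spool <- matrix(0, M, M)
    logdets <- numeric(I)
    Slist <- vector("list", I)
    for (i in seq_len(I)) {
        Si <- stats::cov(x[groups == levels(groups)[i], , drop = FALSE])
        di <- determinant(Si, logarithm = TRUE)
        if (di$sign <= 0 || !is.finite(di$modulus)) {
            warning("singular group covariance; ridge added")
            Si <- .ridge(Si)
            di <- determinant(Si, logarithm = TRUE)
        }
        Slist[[i]] <- Si
        logdets[i] <- as.numeric(di$modulus)
        Spool <- Spool + (tab[i] - 1) * Si
    }
    Spool <- Spool / (N - I)
    dp <- determinant(Spool, logarithm = TRUE)
    if (dp$sign <= 0) {
        warning("singular pooled covariance; ridge added")
        dp <- determinant(.ridge(Spool), logarithm = TRUE)
    }
    stat <- (N - I) * as.numeric(dp$modulus) -
        sum((tab - 1) * logdets)
    c1 <- (sum(1 / (tab - 1)) - 1 / (N - I)) *
        (2 * M^2 + 3 * M - 1) / (6 * (M + 1) * (I - 1))
    chi <- stat * (1 - c1)
    df <- (I - 1) * M * (M + 1) / 2
    pval <- stats::pchisq(chi, df, lower.tail = FALSE)
    structure(list(statistic = c("chi-squared" = chi),
                   parameter = c(df = df), p.value = pval,
                   method = "Box's M test of covariance homogeneity",
                   data.name = deparse(substitute(x))),
              class = "htest")
}

#' Multivariate batch tests per feature
#'
#' For every feature, tests the M-dimensional fixed-effect residual vectors
#' across batches: Box's M for covariance differences and MANOVA (Pillai's
#' trace) for multivariate location differences. Bonferroni correction is
#' applied across features.
#'
#' @inheritParams univariateBatchTests
#' @return data.frame with columns feature, boxm_p, boxm_p_bonf, manova_p,
#'   manova_p_bonf.
#' @export
multivariateBatchTests <- function(data, formula = NULL, model = NULL) {
    stopifnot(is(data, "PanelData"))
    b <- droplevels(batch(data))
    if (nlevels(b) < 2) stop("at least two batches are required")
    fem <- if (is.null(model)) fitFixedEffects(data, formula) else model
    Z <- removeFixedEffects(data, fem)
    p <- dim(Z)[2]; M <- dim(Z)[3]
    boxp <- manp <- rep(NA_real_, p)
    for (v in seq_len(p)) {
        X <- matrix(Z[, v, ], ncol = M)
        boxp[v] <- boxMTest(X, b)$p.value
        manp[v] <- manovaBatch(X, b)
    }
    data.frame(feature = featureIds(data), boxm_p = boxp,
               boxm_p_bonf = pmin(boxp * p, 1), manova_p = manp,
               manova_p_bonf = pmin(manp * p, 1),
               stringsAsFactors = FALSE)
}

#' MANOVA batch test (Pillai's trace)
#'
#' @param x n x M numeric matrix.
#' @param groups factor of length n.
#' @return p-value of Pillai's trace for the group effect.
#' @export
manovaBatch <- function(x, groups) {
    x <- as.matrix(x)
    groups <- droplevels(factor(groups))
    fit <- stats::manova(x ~ groups)
    summary(fit, test = "Pillai")$stats["groups", "Pr(>F)"]
}
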