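#' Fit per-slice covariate (fixed-effect) models
#'
#' Estimates the biological covariate effects to be preserved through
#' harmonization, independently for every (feature, metric) slice. Terms are
#' given as a one-sided formula over covariate columns, e.g. `~ age + sex`;
#' wrapping a covariate in `s()` (e.g. `~ s(age) + sex`) requests a penalized
#' smooth fitted with [mgcv::gam]. Bare `s(x)` terms get the package default
#' of a cubic regression spline with basis dimension 10 and GCV-selected
#' penalty. Batch is never part of this design: it would absorb the batch
#' effects that later stages must estimate and remove.
#'
#' @param data a [PanelData-class] object.
#' @param formula one-sided covariate formula, or `NULL`/`~ 1` for an
#'   intercept-only fit.
#' @return A [FixedEffectsModel-class] object.
#' @examples
#' sim <- simulatePanel(simConfig(n = 60, p = 4, M = 2), seed = 1)
#' fem <- fitFixedEffects(sim@observed, ~ age + sex + diagnosis)
#' fem
#' @export
fitFixedEffects <- function(data, formula = NULL) {
    stopifnot(is(data, "PanelData"))
    cov <- covariates(data)
    if (is.null(formula)) formula <- ~ 1
    formula <- stats::as.formula(formula)
    if (length(formula) == 3)
        stop("use a one-sided formula, e.g. ~ age + sex")
    tl <- attr(stats::terms(formula), "term.labels")
    smoothTerms <- grepl("^s\\(", tl)
    kind <- if (any(smoothTerms)) "gam" else "linear"
    missingCov <- setdiff(all.vars(formula), colnames(cov))
    if (length(missingCov))
        stop("covariate(s) not in colData: ",
             paste(missingCov, collapse = ", "))
    arr <- panelArray(data)
    n <- dim(arr)[1]; p <- dim(arr)[2]; M <- dim(arr)[3]
    if (kind == "linear") {
        X <- stats::model.matrix(formula, data = cov)
        qx <- qr(X)
        if (qx$rank < ncol(X))
            stop("rank-deficient fixed-effects design")
        Y <- matrix(arr, nrow = n)
        B <- qr.coef(qx, Y)
        fit <- X %*% B
        coefArr <- array(B, dim = c(ncol(X), p, M),
                         dimnames = list(colnames(X), dimnames(arr)[[2]],
                                         dimnames(arr)[[3]]))
        new("FixedEffectsModel", kind = "linear", formula = formula,
            coefficients = coefArr,
            fitted = array(fit, dim = dim(arr), dimnames = dimnames(arr)),
            models = list(), designNames = colnames(X),
            featureIds = featureIds(data), metricIds = metricNames(data))
    } else {
        for (v in all.vars(formula[[2]])) {
            isSmoothed <- any(vapply(tl[smoothTerms], function(t)
                v %in% all.vars(stats::as.formula(paste("~", t))), TRUE))
            if (isSmoothed && length(unique(cov[[v]])) <= 2)
                stop("smooth term requested on binary covariate '", v, "'")
        }
        rhs <- .defaultSmoothBasis(tl)
        fitArr <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
        models <- vector("list", p * M)
        for (m in seq_len(M)) for (v in seq_len(p)) {
            df <- cov
            df$.y <- arr[, v, m]
            fo <- stats::as.formula(paste(".y ~", rhs))
            g <- mgcv::gam(fo, data = df, method = "GCV.Cp")
            fitArr[, v, m] <- stats::fitted(g)
            models[[(m - 1) * p + v]] <- g
        }
        new("FixedEffectsModel", kind = "gam", formula = formula,
            coefficients = array(0, dim = c(0, p, M)), fitted = fitArr,
            models = models, designNames = character(),
            featureIds = featureIds(data), metricIds = metricNames(data))
    }
}

## Give bare s(x) terms the package default basis.
.defaultSmoothBasis <- function(termLabels) {
    out <- vapply(termLabels, function(t) {
        if (grepl("^s\\([^,()]+\\)$", t))
            sub("\\)$", ', bs = "cr", k = 10)', t)
        else t
    }, "")
    if (!length(out)) "1" else paste(out, collapse = " + ")
}

## Fitted-value operator: stored fit for the training subjects, or a fresh
## prediction when new covariates are supplied.
.femFitted <- function(model, covariates = NULL) {
    if (is.null(covariates)) return(model@fitted)
    p <- length(model@featureIds); M <- length(model@metricIds)
    n <- nrow(covariates)
    missingCov <- setdiff(all.vars(model@formula), colnames(covariates))
    if (length(missingCov))
        stop("covariate(s) absent at transform time: ",
             paste(missingCov, collapse = ", "))
    if (model@kind == "linear" || model@kind == "none") {
        X <- stats::model.matrix(model@formula, data = covariates)
        fit <- X %*% matrix(model@coefficients, nrow = dim(model@coefficients)[1])
        array(fit, dim = c(n, p, M),
              dimnames = list(rownames(covariates), model@featureIds,
                              model@metricIds))
    } else {
        out <- array(NA_real_, dim = c(n, p, M),
                     dimnames = list(rownames(covariates), model@featureIds,
                                     model@metricIds))
        for (m in seq_len(M)) for (v in seq_len(p))
            out[, v, m] <- as.numeric(stats::predict(
                model@models[[(m - 1) * p + v]], newdata = covariates))
        out
    }
}

#' Remove fitted covariate effects from a panel
#'
#' Subtracts the fitted values of a [FixedEffectsModel-class] from the panel,
#' returning the residual tensor that carries the batch-related variation.
#' `restoreFixedEffects()` is the exact inverse.
#'
#' @param data a [PanelData-class] object with the model's covariates.
#' @param model a fitted [FixedEffectsModel-class].
#' @return n x p x M residual array.
#' @seealso [restoreFixedEffects()]
#' @export
removeFixedEffects <- function(data, model) {
    stopifnot(is(data, "PanelData"), is(model, "FixedEffectsModel"))
    arr <- panelArray(data)
    sameSubjects <- identical(dim(arr)[1], dim(model@fitted)[1]) &&
        identical(dimnames(arr)[[1]], dimnames(model@fitted)[[1]])
    fit <- if (sameSubjects) model@fitted else
        .femFitted(model, covariates(data))
    arr - fit
}

#' Restore covariate effects onto adjusted residuals
#'
#' Adds the fitted fixed effects back to a (batch-adjusted) residual tensor,
#' completing the harmonization pipeline.
#'
#' @param Z n x p x M residual array.
#' @param model a fitted [FixedEffectsModel-class].
#' @param covariates optional covariate table for subjects other than the
#'   training subjects; by default the stored fitted values are used.
#' @return n x p x M array of harmonized values.
#' @export
restoreFixedEffects <- function(Z, model, covariates = NULL) {
    stopifnot(is(model, "FixedEffectsModel"))
    fit <- .femFitted(model, covariates)
    if (!all(dim(Z) == dim(fit)))
        stop("residual tensor does not match the model's dimensions")
    Z + fit
}

#' @describeIn FixedEffectsModel-class compact display
#' @param object a `FixedEffectsModel`.
#' @export
setMethod("show", "FixedEffectsModel", function(object) {
    cat("FixedEffectsModel (", object@kind, "): ",
        deparse(object@formula), "\n", sep = "")
    cat(length(object@featureIds), "features x",
        length(object@metricIds), "metrics\n")
})
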