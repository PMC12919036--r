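#' Construct a PanelData object
#'
#' Builds a [PanelData-class] object from an n x p x M value array (subjects x
#' features x metrics) or a named list of n x p matrices (one per metric).
#' Feature and metric identifiers are sorted lexicographically so that all
#' downstream tensors share a deterministic ordering.
#'
#' @param values numeric array with `dim = c(n, p, M)` (optionally carrying
#'   dimnames subject/feature/metric), or a named list of n x p matrices.
#' @param batch vector of batch labels, one per subject (coerced to factor).
#' @param covariates optional `data.frame` (or `DataFrame`) of per-subject
#'   numeric or binary covariate columns.
#' @param featureIds,metricIds optional identifier vectors overriding the
#'   dimnames of `values`.
#' @param subjectIds optional subject identifiers.
#'
#' @return A [PanelData-class] object.
#' @examples
#' arr <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2),
#'              dimnames = list(paste0("s", 1:4), paste0("roi", 1:3),
#'                              c("thick", "area")))
#' pd <- PanelData(arr, batch = c("A", "A", "B", "B"),
#'                 covariates = data.frame(age = c(40, 50, 60, 70)))
#' pd
#' @export
PanelData <- function(values, batch, covariates = NULL, featureIds = NULL,
                      metricIds = NULL, subjectIds = NULL) {
    if (is.list(values) && !is.array(values)) {
        if (is.null(metricIds)) metricIds <- names(values)
        if (is.null(metricIds))
            stop("list-valued 'values' must be named by metric")
        n <- nrow(values[[1]]); p <- ncol(values[[1]])
        arr <- array(NA_real_, dim = c(n, p, length(values)))
        for (m in seq_along(values)) arr[, , m] <- as.matrix(values[[m]])
        if (is.null(featureIds)) featureIds <- colnames(values[[1]])
        if (is.null(subjectIds)) subjectIds <- rownames(values[[1]])
        values <- arr
    }
    stopifnot(is.array(values), length(dim(values)) == 3)
    n <- dim(values)[1]; p <- dim(values)[2]; M <- dim(values)[3]
    dn <- dimnames(values)
    if (is.null(subjectIds))
        subjectIds <- if (!is.null(dn[[1]])) dn[[1]] else paste0("S", seq_len(n))
    if (is.null(featureIds))
        featureIds <- if (!is.null(dn[[2]])) dn[[2]] else
            sprintf("F%03d", seq_len(p))
    if (is.null(metricIds))
        metricIds <- if (!is.null(dn[[3]])) dn[[3]] else paste0("M", seq_len(M))
    featureIds <- as.character(featureIds); metricIds <- as.character(metricIds)
    if (anyDuplicated(featureIds)) stop("duplicated feature identifiers")
    if (anyDuplicated(metricIds)) stop("duplicated metric identifiers")
    if (length(batch) != n)
        stop("'batch' must have one label per subject")
    fo <- order(featureIds); mo <- order(metricIds)
    values <- values[, fo, mo, drop = FALSE]
    featureIds <- featureIds[fo]; metricIds <- metricIds[mo]
    assays <- lapply(seq_len(M), function(m) {
        a <- t(values[, , m])
        dimnames(a) <- list(featureIds, subjectIds)
        a
    })
    names(assays) <- metricIds
    cd <- S4Vectors::DataFrame(batch = factor(batch), row.names = subjectIds)
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        if (nrow(covariates) != n)
            stop("'covariates' must have one row per subject")
        if ("batch" %in% colnames(covariates))
            stop("'batch' is reserved; pass it via the 'batch' argument")
        for (cc in colnames(covariates)) cd[[cc]] <- covariates[[cc]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd)
    new("PanelData", se)
}

setValidity("PanelData", function(object) {
    if (length(SummarizedExperiment::assays(object)) < 1)
        return("PanelData needs at least one assay (metric)")
    if (is.null(SummarizedExperiment::assayNames(object)))
        return("assays must be named by metric")
    if (!("batch" %in% colnames(SummarizedExperiment::colData(object))))
        return("colData must contain a 'batch' column")
    if (!is.factor(SummarizedExperiment::colData(object)$batch))
        return("'batch' must be a factor")
    for (m in SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, m)
        if (!is.numeric(a)) return(sprintf("assay '%s' is not numeric", m))
        if (any(!is.finite(a)))
            return(sprintf("assay '%s' contains non-finite values", m))
    }
    TRUE
})

#' Accessors for PanelData
#'
#' `batch()` returns the per-subject batch factor, `covariates()` the
#' covariate columns of `colData` (everything except `batch`),
#' `metricNames()`/`featureIds()` the ordered identifier vectors, and
#' `nSubjects()`/`nFeatures()`/`nMetrics()` the panel dimensions.
#'
#' @param x a [PanelData-class] object.
#' @param value replacement batch labels (length `nSubjects(x)`).
#' @return See the individual descriptions.
#' @name PanelData-accessors
#' @aliases batch batch<- covariates metricNames featureIds nSubjects
#'   nFeatures nMetrics
NULL

#' @rdname PanelData-accessors
#' @export
setMethod("batch", "PanelData", function(x)
    SummarizedExperiment::colData(x)$batch)

#' @rdname PanelData-accessors
#' @export
setReplaceMethod("batch", "PanelData", function(x, value) {
    SummarizedExperiment::colData(x)$batch <- factor(value)
    validObject(x)
    x
})

#' @rdname PanelData-accessors
#' @export
setMethod("covariates", "PanelData", function(x) {
    cd <- SummarizedExperiment::colData(x)
    as.data.frame(cd[, setdiff(colnames(cd), "batch"), drop = FALSE])
})

#' @rdname PanelData-accessors
#' @export
setMethod("metricNames", "PanelData", function(x)
    SummarizedExperiment::assayNames(x))

#' @rdname PanelData-accessors
#' @export
setMethod("featureIds", "PanelData", function(x) rownames(x))

#' @rdname PanelData-accessors
#' @export
setMethod("nSubjects", "PanelData", function(x) ncol(x))

#' @rdname PanelData-accessors
#' @export
setMethod("nFeatures", "PanelData", function(x) nrow(x))

#' @rdname PanelData-accessors
#' @export
setMethod("nMetrics", "PanelData", function(x)
    length(SummarizedExperiment::assays(x)))

#' Extract the value tensor of a PanelData
#'
#' Returns the n x p x M numeric array (subjects x features x metrics) in the
#' panel's deterministic feature/metric order.
#'
#' @param x a [PanelData-class] object.
#' @return numeric array with dimnames (subject, feature, metric).
#' @name panelArray
#' @export
setMethod("panelArray", "PanelData", function(x) {
    p <- nFeatures(x); n <- nSubjects(x); M <- nMetrics(x)
    arr <- array(NA_real_, dim = c(n, p, M),
                 dimnames = list(colnames(x), rownames(x), metricNames(x)))
    for (m in seq_len(M))
        arr[, , m] <- t(SummarizedExperiment::assay(x, m))
    arr
})

## Internal: same metadata, new values (n x p x M array).
.replaceValues <- function(x, arr) {
    for (m in seq_len(nMetrics(x))) {
        a <- t(arr[, , m])
        dimnames(a) <- dimnames(SummarizedExperiment::assay(x, m))
        SummarizedExperiment::assay(x, m, withDimnames = FALSE) <- a
    }
    validObject(x)
    x
}

## Internal: validate batch structure ahead of harmonization.
.checkHarmonizable <- function(x, needMultivariate = FALSE) {
    b <- batch(x)
    tab <- table(b)
    if (any(tab < 2))
        stop("every batch needs at least 2 subjects; found: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    if (needMultivariate && any(tab < nMetrics(x) + 2))
        stop("multivariate covariance estimation needs n_i >= M + 2 ",
             "subjects per batch")
    invisible(tab)
}

#' @describeIn PanelData-class compact display of dimensions and batches
#' @param object a `PanelData` object.
#' @export
setMethod("show", "PanelData", function(object) {
    cat("PanelData:", nSubjects(object), "subjects x", nFeatures(object),
        "features x", nMetrics(object), "metrics\n")
    cat("metrics:", paste(metricNames(object), collapse = ", "), "\n")
    tab <- table(batch(object))
    cat("batches:", paste(sprintf("%s(n=%d)", names(tab), tab),
                          collapse = ", "), "\n")
    cv <- colnames(covariates(object))
    cat("covariates:",
        if (length(cv)) paste(cv, collapse = ", ") else "(none)", "\n")
})
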