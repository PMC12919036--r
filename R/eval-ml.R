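#' Random-forest batch-prediction AUC for one metric
#'
#' Quantifies residual global batch signal within a metric: a random forest
#' (100 trees, default hyperparameters otherwise) predicts the batch label
#' from the metric's p feature values under stratified 10-fold
#' cross-validation; each fold's one-vs-rest AUC is macro-averaged over
#' batch classes and the fold values averaged. 0.5 is chance (batch effects
#' removed), 1.0 is perfect batch recovery. Seeding is per (metric, fold),
#' derived from `seed`.
#'
#' @param data a [PanelData-class] object with >= 2 batches of >= 10
#'   subjects each.
#' @param metric metric name (or index) whose features are used.
#' @param folds number of stratified CV folds (default 10).
#' @param ntree trees per forest (default 100).
#' @param seed integer master seed.
#' @param engine `"ranger"` (default) or `"randomForest"`; both fit the
#'   same classifier, the former is considerably faster on one thread.
#' @return mean macro AUC (numeric scalar) with per-fold values in
#'   attribute `"folds"`.
#' @export
rfBatchAUC <- function(data, metric, folds = 10L, ntree = 100L, seed = 1L,
                       engine = c("ranger", "randomForest")) {
    engine <- match.arg(engine)
    stopifnot(is(data, "PanelData"))
    if (is.numeric(metric)) metric <- metricNames(data)[metric]
    y <- droplevels(batch(data))
    if (nlevels(y) < 2) stop("at least two batches are required")
    if (any(table(y) < 10))
        stop("each batch needs >= 10 subjects for stratified 10-fold CV")
    X <- t(SummarizedExperiment::assay(data, metric))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    mseed <- .childSeed(seed, match(metric, metricNames(data)))
    set.seed(mseed)
    foldIdx <- caret::createFolds(y, k = folds)
    aucs <- vapply(seq_along(foldIdx), function(k) {
        test <- foldIdx[[k]]
        if (nlevels(droplevels(y[test])) < nlevels(y))
            stop("a batch class is absent from a fold")
        fseed <- .childSeed(mseed, k)
        prob <- if (engine == "ranger") {
            fit <- ranger::ranger(x = X[-test, , drop = FALSE],
                                  y = y[-test], num.trees = ntree,
                                  probability = TRUE, seed = fseed,
                                  num.threads = 1)
            stats::predict(fit, data = X[test, , drop = FALSE],
                           num.threads = 1)$predictions
        } else {
            if (!requireNamespace("randomForest", quietly = TRUE))
                stop("engine 'randomForest' requires the randomForest package")
            set.seed(fseed)
            fit <- randomForest::randomForest(x = X[-test, , drop = FALSE],
                                              y = y[-test], ntree = ntree)
            stats::predict(fit, newdata = X[test, , drop = FALSE],
                           type = "prob")
        }
        classAUC <- vapply(levels(y), function(cl) {
            resp <- factor(y[test] == cl, levels = c(FALSE, TRUE))
            as.numeric(pROC::auc(response = resp,
                                 predictor = prob[, cl],
                                 levels = c("FALSE", "TRUE"),
                                 direction = "<", quiet = TRUE))
        }, 0)
        mean(classAUC)
    }, 0)
    structure(mean(aucs), folds = aucs)
}
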