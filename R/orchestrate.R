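#' Harmonize a panel with a named method
#'
#' Thin dispatcher over the harmonizers, convenient for benchmarking and
#' scripting: `"unharm"` returns the input unchanged; the other methods call
#' [uvCombat()], [uvCovbat()], [mvCombat()] (EB or MCMC) or [mvCovbat()].
#'
#' @param data a [PanelData-class] object.
#' @param method one of `"unharm"`, `"uv-combat"`, `"uv-covbat"`,
#'   `"mv-combat-eb"`, `"mv-combat-mcmc"`, `"mv-covbat"`.
#' @param formula covariate formula for the fixed-effects stage.
#' @param ... further arguments passed to the selected harmonizer.
#' @return list with at least `data` (the harmonized [PanelData-class]);
#'   further elements are the selected harmonizer's fit objects.
#' @export
harmonize <- function(data, method = c("unharm", "uv-combat", "uv-covbat",
                                       "mv-combat-eb", "mv-combat-mcmc",
                                       "mv-covbat"),
                      formula = NULL, ...) {
    method <- match.arg(method)
    switch(method,
        "unharm" = list(data = data),
        "uv-combat" = uvCombat(data, formula = formula, ...),
        "uv-covbat" = uvCovbat(data, formula = formula, ...),
        "mv-combat-eb" = mvCombat(data, formula = formula,
                                  estimator = "eb", ...),
        "mv-combat-mcmc" = mvCombat(data, formula = formula,
                                    estimator = "mcmc", ...),
        "mv-covbat" = mvCovbat(data, formula = formula, ...))
}

#' Run the harmonization-evaluation battery on a panel
#'
#' Computes the requested evaluation components and returns them as a
#' report list: `"multivariate"` (per-feature Box's M and MANOVA with
#' Bonferroni-significant fractions at 0.05), `"univariate"` (five per-slice
#' batch tests with Bonferroni-significant fractions), `"auc"` (per-metric
#' random-forest batch-prediction macro AUC and its mean), `"distances"`
#' (within- and cross-metric correlation distances across batches, and
#' versus the gold standard when supplied), `"signal"` (covariate-signal
#' preservation; requires `formula`, and `truth` for TP/FDR).
#'
#' @param data a [PanelData-class] object (typically harmonized output).
#' @param gold optional gold-standard [PanelData-class].
#' @param formula covariate formula used for residualization and signal
#'   tests.
#' @param truth optional ground truth for [signalPreservation()].
#' @param measures character subset of `c("multivariate", "univariate",
#'   "auc", "distances", "signal")`.
#' @param target covariate tested by the signal component.
#' @param seed seed for the random-forest component.
#' @param aucEngine forest engine, see [rfBatchAUC()].
#' @param alpha significance level for the batch-test summaries.
#' @return list of class `mvEvalReport`.
#' @export
evaluateHarmonization <- function(data, gold = NULL, formula = NULL,
                                  truth = NULL,
                                  measures = c("multivariate", "auc"),
                                  target = "diagnosis", seed = 1L,
                                  aucEngine = "ranger", alpha = 0.05) {
    stopifnot(is(data, "PanelData"))
    fem <- fitFixedEffects(data, formula)
    report <- list()
    if ("multivariate" %in% measures) {
        mv <- multivariateBatchTests(data, model = fem)
        report$multivariate <- list(
            table = mv,
            boxm_sig_frac = mean(mv$boxm_p_bonf <= alpha, na.rm = TRUE),
            manova_sig_frac = mean(mv$manova_p_bonf <= alpha, na.rm = TRUE))
    }
    if ("univariate" %in% measures) {
        uv <- univariateBatchTests(data, model = fem)
        fr <- tapply(uv$p_bonf <= alpha, uv$test, mean, na.rm = TRUE)
        report$univariate <- list(table = uv, sig_frac = fr)
    }
    if ("auc" %in% measures) {
        aucs <- vapply(metricNames(data), function(m)
            as.numeric(rfBatchAUC(data, m, seed = seed,
                                  engine = aucEngine)), 0)
        report$auc <- list(per_metric = aucs, mean = mean(aucs))
    }
    if ("distances" %in% measures) {
        report$distances <- list(
            within_batches = attr(correlationDistances(
                data, "within_metric", "across_batches", model = fem),
                "mean"),
            cross_batches = correlationDistances(
                data, "cross_metric", "across_batches", model = fem))
        if (!is.null(gold)) {
            report$distances$within_gold <- attr(correlationDistances(
                data, "within_metric", "vs_gold", gold = gold,
                model = fem), "mean")
            report$distances$cross_gold <- correlationDistances(
                data, "cross_metric", "vs_gold", gold = gold, model = fem)
        }
    }
    if ("signal" %in% measures) {
        if (is.null(formula))
            stop("the signal component needs a covariate formula")
        report$signal <- signalPreservation(data, formula, target = target,
                                            truth = truth, alpha = alpha)
    }
    class(report) <- "mvEvalReport"
    report
}

## Flatten a report into named scalars for aggregation across replicates.
.reportScalars <- function(report) {
    out <- c()
    if (!is.null(report$multivariate))
        out <- c(out, boxm_sig_frac = report$multivariate$boxm_sig_frac,
                 manova_sig_frac = report$multivariate$manova_sig_frac)
    if (!is.null(report$univariate))
        out <- c(out, stats::setNames(
            as.numeric(report$univariate$sig_frac),
            paste0("uv_", names(report$univariate$sig_frac), "_sig_frac")))
    if (!is.null(report$auc))
        out <- c(out, auc_mean = report$auc$mean)
    if (!is.null(report$distances)) {
        out <- c(out, stats::setNames(
            as.numeric(report$distances$within_batches),
            paste0("dist_within_", names(report$distances$within_batches))))
        out <- c(out, stats::setNames(
            as.numeric(report$distances$cross_batches),
            paste0("dist_cross_", names(report$distances$cross_batches))))
    }
    if (!is.null(report$signal)) {
        out <- c(out, signal_discoveries = report$signal$nDiscoveries)
        if (!is.null(report$signal$FDR))
            out <- c(out, signal_TP = report$signal$TP,
                     signal_FDR = report$signal$FDR)
    }
    out
}

#' Replicated simulate-harmonize-evaluate experiments
#'
#' Runs `replicates` independent simulation replicates of a configuration:
#' each replicate draws a fresh dataset (seed derived deterministically from
#' the master seed and the replicate index), harmonizes it with every
#' requested method, evaluates the requested measures, and the scalar
#' summaries are aggregated into means with 95 percent percentile intervals.
#' A failing harmonizer is recorded for that replicate, not fatal.
#'
#' @param config a [simConfig()] list.
#' @param methods character vector of [harmonize()] method names.
#' @param formula covariate formula for harmonization and evaluation.
#' @param seed master integer seed.
#' @param replicates replicate count (default `config$replicates`).
#' @param measures evaluation components, see [evaluateHarmonization()].
#' @param truthSignal logical: pass the simulation's biomarker truth to the
#'   signal component.
#' @param ... further arguments to [harmonize()].
#' @return list with `summary` (data.frame: method, measure, mean, lo, hi,
#'   n), `replicates` (per-replicate scalar tables) and `errors`.
#' @export
runReplicates <- function(config, methods = c("unharm", "uv-combat",
                                              "mv-combat-eb"),
                          formula = ~ age + sex + diagnosis, seed = 1L,
                          replicates = NULL,
                          measures = c("multivariate", "auc"),
                          truthSignal = TRUE, ...) {
    stopifnot(inherits(config, "simConfig"))
    if (is.null(replicates)) replicates <- config$replicates
    rows <- list()
    errors <- list()
    perRep <- vector("list", replicates)
    for (r in seq_len(replicates)) {
        rseed <- .childSeed(seed, r)
        sim <- simulatePanel(config, seed = rseed)
        truth <- if (truthSignal) sim@truth$biomarkers else NULL
        repRows <- list()
        for (meth in methods) {
            res <- tryCatch(
                harmonize(sim@observed, meth, formula = formula, ...),
                error = function(e) e)
            if (inherits(res, "error")) {
                errors[[length(errors) + 1]] <- list(replicate = r,
                                                     method = meth,
                                                     message = conditionMessage(res))
                next
            }
            rep_ <- tryCatch(
                evaluateHarmonization(res$data, gold = sim@gold,
                                      formula = formula, truth = truth,
                                      measures = measures,
                                      seed = .childSeed(rseed, 97)),
                error = function(e) e)
            if (inherits(rep_, "error")) {
                errors[[length(errors) + 1]] <-
                    list(replicate = r, method = meth,
                         message = conditionMessage(rep_))
                next
            }
            sc <- .reportScalars(rep_)
            repRows[[meth]] <- sc
            rows[[length(rows) + 1]] <-
                data.frame(replicate = r, method = meth,
                           measure = names(sc), value = as.numeric(sc),
                           stringsAsFactors = FALSE)
        }
        perRep[[r]] <- repRows
    }
    long <- do.call(rbind, rows)
    if (is.null(long))
        return(list(summary = data.frame(method = character(),
                                         measure = character(),
                                         mean = numeric(), lo = numeric(),
                                         hi = numeric(), n = integer()),
                    replicates = perRep, errors = errors))
    agg <- do.call(rbind, lapply(split(
        long, list(long$method, long$measure), drop = TRUE),
        function(d) data.frame(
            method = d$method[1], measure = d$measure[1],
            mean = mean(d$value),
            lo = as.numeric(stats::quantile(d$value, 0.025)),
            hi = as.numeric(stats::quantile(d$value, 0.975)),
            n = nrow(d), stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    list(summary = agg, replicates = perRep, errors = errors)
}

#' Benchmark harmonizers over a condition grid
#'
#' Runs [runReplicates()] for each named simulation condition and assembles
#' a compact table (one row per method, one column per condition) of a
#' selected measure, formatted as "mean (lo, hi)". The MCMC estimator is
#' excluded from the default method grid for cost; add
#' `"mv-combat-mcmc"` explicitly to include it.
#'
#' @param conditions named list of [simConfig()] objects.
#' @param methods methods to compare (see [harmonize()]).
#' @param measure which scalar measure to tabulate (default `"auc_mean"`).
#' @param formula,seed,replicates,measures,... passed to [runReplicates()].
#' @return list with `table` (character data.frame, Table-1 shape),
#'   `summaries` (per-condition [runReplicates()] summaries) and `errors`.
#' @export
benchmarkHarmonizers <- function(conditions,
                                 methods = c("unharm", "uv-combat",
                                             "mv-combat-eb"),
                                 measure = "auc_mean",
                                 formula = ~ age + sex + diagnosis,
                                 seed = 1L, replicates = NULL,
                                 measures = c("multivariate", "auc"), ...) {
    stopifnot(is.list(conditions), length(names(conditions)) ==
                  length(conditions))
    summaries <- errors <- vector("list", length(conditions))
    names(summaries) <- names(errors) <- names(conditions)
    for (cn in names(conditions)) {
        rr <- runReplicates(conditions[[cn]], methods = methods,
                            formula = formula, seed = seed,
                            replicates = replicates, measures = measures,
                            ...)
        summaries[[cn]] <- rr$summary
        errors[[cn]] <- rr$errors
    }
    tab <- data.frame(method = methods, stringsAsFactors = FALSE)
    for (cn in names(conditions)) {
        s <- summaries[[cn]]
        s <- s[s$measure == measure, ]
        tab[[cn]] <- vapply(methods, function(m) {
            r <- s[s$method == m, ]
            if (!nrow(r)) return(NA_character_)
            sprintf("%.3f (%.3f, %.3f)", r$mean, r$lo, r$hi)
        }, "")
    }
    list(table = tab, summaries = summaries, errors = errors)
}
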