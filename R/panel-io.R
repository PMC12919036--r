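#' Read multi-metric panel data from a delimited text file
#'
#' Reads a CSV/TSV file in either long layout (one row per subject x feature
#' x metric cell) or wide layout (one row per subject, one column per
#' `<feature>_<metric>` pair) into a [PanelData-class] object. Feature and
#' metric identifiers are ordered lexicographically. Missing cells, `NA`
#' values and subjects carrying more than one batch label are errors; the
#' model underlying the harmonizers has no missingness mechanism, so no
#' imputation is attempted.
#'
#' @param path path to a UTF-8 delimited text file with a header row. The
#'   delimiter is inferred from the extension (`.csv` vs `.tsv`/`.txt`) and
#'   can be overridden with `sep`.
#' @param layout `"long"` or `"wide"`.
#' @param covariates character vector naming covariate columns (must be
#'   listed explicitly; any other non-schema column is an error).
#' @param schema named list mapping the roles `subject`, `batch`, `feature`,
#'   `metric`, `value` to column names; defaults to those role names. For
#'   wide layout only `subject` and `batch` are used.
#' @param sep field separator; `NULL` (default) infers it from `path`.
#'
#' @return A [PanelData-class] object.
#' @seealso [writePanel()]
#' @export
readPanel <- function(path, layout = c("long", "wide"),
                      covariates = character(),
                      schema = list(), sep = NULL) {
    layout <- match.arg(layout)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
            "\t" else ","
    sch <- utils::modifyList(list(subject = "subject", batch = "batch",
                                  feature = "feature", metric = "metric",
                                  value = "value"), schema)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
    need <- if (layout == "long")
        unlist(sch[c("subject", "batch", "feature", "metric", "value")])
    else unlist(sch[c("subject", "batch")])
    miss <- setdiff(c(need, covariates), colnames(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    if (layout == "long") {
        val <- df[[sch$value]]
        if (!is.numeric(val)) stop("'", sch$value, "' must be numeric")
        if (anyNA(val)) stop("NA values are not allowed")
        subj <- as.character(df[[sch$subject]])
        bmap <- unique(df[, c(sch$subject, sch$batch)])
        if (anyDuplicated(bmap[[sch$subject]]))
            stop("subject(s) with multiple batch labels")
        feats <- sort(unique(as.character(df[[sch$feature]])))
        mets <- sort(unique(as.character(df[[sch$metric]])))
        subjects <- unique(subj)
        arr <- array(NA_real_, dim = c(length(subjects), length(feats),
                                       length(mets)),
                     dimnames = list(subjects, feats, mets))
        idx <- cbind(match(subj, subjects),
                     match(as.character(df[[sch$feature]]), feats),
                     match(as.character(df[[sch$metric]]), mets))
        if (anyDuplicated(idx))
            stop("duplicated (subject, feature, metric) cells")
        arr[idx] <- val
        if (anyNA(arr)) stop("missing cells: the panel must be complete")
        cov <- NULL
        if (length(covariates)) {
            cmap <- unique(df[, c(sch$subject, covariates), drop = FALSE])
            if (anyDuplicated(cmap[[sch$subject]]))
                stop("covariates must be constant within subject")
            cov <- cmap[match(subjects, cmap[[sch$subject]]), covariates,
                        drop = FALSE]
            rownames(cov) <- subjects
        }
        PanelData(arr, batch = bmap[[sch$batch]][match(subjects,
                                                       bmap[[sch$subject]])],
                  covariates = cov)
    } else {
        subjects <- as.character(df[[sch$subject]])
        if (anyDuplicated(subjects)) stop("duplicated subject rows")
        valueCols <- setdiff(colnames(df),
                             c(sch$subject, sch$batch, covariates))
        if (!length(valueCols)) stop("no <feature>_<metric> value columns")
        parts <- regmatches(valueCols,
                            regexpr("_(?=[^_]+$)", valueCols, perl = TRUE),
                            invert = TRUE)
        bad <- lengths(parts) != 2
        if (any(bad))
            stop("column(s) not of the form <feature>_<metric>: ",
                 paste(valueCols[bad], collapse = ", "))
        feats <- sort(unique(vapply(parts, `[`, "", 1)))
        mets <- sort(unique(vapply(parts, `[`, "", 2)))
        arr <- array(NA_real_, dim = c(length(subjects), length(feats),
                                       length(mets)),
                     dimnames = list(subjects, feats, mets))
        for (k in seq_along(valueCols)) {
            v <- df[[valueCols[k]]]
            if (!is.numeric(v))
                stop("'", valueCols[k], "' must be numeric")
            if (anyNA(v)) stop("NA values are not allowed")
            arr[, parts[[k]][1], parts[[k]][2]] <- v
        }
        if (anyNA(arr)) stop("missing cells: the panel must be complete")
        cov <- if (length(covariates))
            df[, covariates, drop = FALSE] else NULL
        PanelData(arr, batch = df[[sch$batch]], covariates = cov)
    }
}

#' Write PanelData to a delimited text file
#'
#' Persists the values, batch labels and covariates of a panel losslessly in
#' long or wide layout; `readPanel()` on the result reproduces the panel.
#'
#' @param data a [PanelData-class] object.
#' @param path output path; extension decides the delimiter (`.tsv`/`.txt`
#'   write tabs, anything else commas).
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @seealso [readPanel()]
#' @export
writePanel <- function(data, path, layout = c("long", "wide")) {
    layout <- match.arg(layout)
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    arr <- panelArray(data)
    cov <- covariates(data)
    subjects <- colnames(data)
    if (layout == "long") {
        grid <- expand.grid(subject = subjects, feature = featureIds(data),
                            metric = metricNames(data),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        grid$value <- sprintf("%.17g", as.vector(arr))  # lossless round trip
        grid$batch <- as.character(batch(data))[match(grid$subject, subjects)]
        grid <- grid[, c("subject", "batch", "feature", "metric", "value")]
        for (cc in colnames(cov))
            grid[[cc]] <- cov[[cc]][match(grid$subject, subjects)]
        utils::write.table(grid, path, sep = sep, row.names = FALSE,
                           quote = FALSE, fileEncoding = "UTF-8")
    } else {
        out <- data.frame(subject = subjects,
                          batch = as.character(batch(data)),
                          stringsAsFactors = FALSE, check.names = FALSE)
        for (cc in colnames(cov)) out[[cc]] <- cov[[cc]]
        for (m in metricNames(data))
            for (v in featureIds(data))
                out[[paste0(v, "_", m)]] <- sprintf("%.17g", arr[, v, m])
        utils::write.table(out, path, sep = sep, row.names = FALSE,
                           quote = FALSE, fileEncoding = "UTF-8")
    }
    invisible(path)
}
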