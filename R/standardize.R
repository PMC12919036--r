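#' Fit a per-slice standardization of fixed-effect residuals
#'
#' Residuals of different metrics (and features) live on study-specific
#' scales; before batch-effect estimation each (feature, metric) slice is put
#' on a common scale. `mode = "pooled_sd"` centers each slice at its pooled
#' across-batch mean (approximately zero after fixed-effect removal) and
#' divides by its pooled across-batch sample standard deviation (ddof = 1),
#' mirroring the standardization step of the original per-feature ComBat and
#' making the estimated batch covariances correlation-scale objects that are
#' comparable across metrics. `mode = "none"` is the identity transform.
#'
#' @param Z n x p x M residual array (subjects x features x metrics).
#' @param mode `"pooled_sd"` or `"none"`.
#' @return A [Standardization-class] object.
#' @seealso [applyStandardization()], [invertStandardization()]
#' @export
fitStandardization <- function(Z, mode = c("pooled_sd", "none")) {
    mode <- match.arg(mode)
    stopifnot(is.array(Z), length(dim(Z)) == 3)
    if (any(!is.finite(Z))) stop("residuals must be finite")
    p <- dim(Z)[2]; M <- dim(Z)[3]
    dn <- dimnames(Z)
    center <- matrix(0, p, M, dimnames = dn[2:3])
    scale <- matrix(1, p, M, dimnames = dn[2:3])
    if (mode == "pooled_sd") {
        if (dim(Z)[1] < 2)
            stop("pooled_sd standardization needs at least 2 subjects")
        center[] <- apply(Z, c(2, 3), mean)
        scale[] <- apply(Z, c(2, 3), stats::sd)
        if (any(scale <= 0) || any(!is.finite(scale)))
            stop("zero pooled standard deviation in at least one ",
                 "(feature, metric) slice")
    }
    new("Standardization", center = center, scale = scale, mode = mode)
}

#' Apply or invert a fitted standardization
#'
#' `applyStandardization()` maps residuals Z to (Z - center) / scale per
#' (feature, metric) slice; `invertStandardization()` is its exact inverse,
#' applied after batch adjustment and before fixed effects are restored.
#'
#' @param Z n x p x M residual array.
#' @param std a [Standardization-class] object fitted on a compatible panel.
#' @return The transformed array, same shape as `Z`.
#' @export
applyStandardization <- function(Z, std) {
    .checkStdShape(Z, std)
    n <- dim(Z)[1]
    sweepc <- aperm(array(std@center, dim = c(dim(std@center), n)),
                    c(3, 1, 2))
    sweeps <- aperm(array(std@scale, dim = c(dim(std@scale), n)), c(3, 1, 2))
    (Z - sweepc) / sweeps
}

#' @rdname applyStandardization
#' @export
invertStandardization <- function(Z, std) {
    .checkStdShape(Z, std)
    n <- dim(Z)[1]
    sweepc <- aperm(array(std@center, dim = c(dim(std@center), n)),
                    c(3, 1, 2))
    sweeps <- aperm(array(std@scale, dim = c(dim(std@scale), n)), c(3, 1, 2))
    Z * sweeps + sweepc
}

.checkStdShape <- function(Z, std) {
    stopifnot(is.array(Z), length(dim(Z)) == 3)
    if (dim(Z)[2] != nrow(std@center) || dim(Z)[3] != ncol(std@center))
        stop("standardization was fitted for ", nrow(std@center),
             " features x ", ncol(std@center), " metrics")
    invisible(TRUE)
}
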