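#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @import SummarizedExperiment
NULL

#' PanelData: multi-metric panel data with batch labels
#'
#' `PanelData` extends [SummarizedExperiment::SummarizedExperiment] to hold an
#' n (subjects) x p (features) x M (metrics) panel of numeric measurements:
#' one assay per metric, each a features x subjects matrix, plus a mandatory
#' `batch` column and optional covariate columns in `colData`. It is the
#' universal input and output of every harmonizer in the package.
#'
#' Invariants enforced by the validity method: at least one assay; all assays
#' share dimensions and dimnames; all values finite (no `NA`/`Inf`); `colData`
#' contains a factor column `batch` with one label per subject.
#'
#' @seealso [PanelData()] for construction, [readPanel()] for file input.
#' @export
setClass("PanelData", contains = "SummarizedExperiment")

#' Per-slice centering/scaling transform
#'
#' Stores a center and a positive scale per (feature, metric) slice, used to
#' put fixed-effect residuals on a common scale before batch-effect
#' estimation and to undo that scaling after adjustment.
#'
#' @slot center p x M numeric matrix of per-slice centers.
#' @slot scale p x M numeric matrix of per-slice scales (all > 0).
#' @slot mode `"pooled_sd"` or `"none"`.
#' @export
setClass("Standardization",
    representation(center = "matrix", scale = "matrix", mode = "character"),
    validity = function(object) {
        if (!all(dim(object@center) == dim(object@scale)))
            return("center and scale must have identical dimensions")
        if (any(!is.finite(object@scale)) || any(object@scale <= 0))
            return("all scales must be finite and > 0")
        if (any(!is.finite(object@center)))
            return("all centers must be finite")
        TRUE
    })

#' Fitted covariate (fixed-effect) model for a panel
#'
#' One regression fit per (feature, metric) slice, either ordinary least
#' squares (`kind = "linear"`) or a penalized cubic-regression-spline GAM
#' (`kind = "gam"`). The model captures the biological covariate effects that
#' harmonization must preserve; batch is never part of this design.
#'
#' @slot kind `"linear"`, `"gam"`, or `"none"` (intercept only).
#' @slot formula the covariate formula (right-hand side only).
#' @slot coefficients for linear fits, a k x p x M array of coefficients.
#' @slot fitted n x p x M array of fitted values on the training subjects.
#' @slot models for GAM fits, a list (length p*M) of `mgcv::gam` objects.
#' @slot designNames column names of the linear design matrix.
#' @slot featureIds,metricIds identifier vectors fixing slice order.
#' @export
setClass("FixedEffectsModel",
    representation(kind = "character", formula = "ANY",
                   coefficients = "array", fitted = "array",
                   models = "list", designNames = "character",
                   featureIds = "character", metricIds = "character"))

#' Univariate (per-slice) ComBat batch-effect estimates
#'
#' Additive (`gammaStar`) and multiplicative (`deltaStar`, a variance on the
#' standardized scale) batch effects per (batch, feature, metric), together
#' with the empirical-Bayes hyperparameters estimated across features within
#' each metric: normal prior (gamma_bar, tau2) on the additive effects and
#' inverse-gamma prior (lambda, theta) on the variances.
#'
#' @slot gammaStar,deltaStar I x p x M arrays (deltaStar > 0).
#' @slot hyper list per (batch, metric) of `gamma_bar`, `tau2`, `lambda`,
#'   `theta`.
#' @slot batchLevels batch labels, in order.
#' @slot eb logical; `FALSE` means direct batch-wise estimates (no shrinkage).
#' @export
setClass("UVBatchEffects",
    representation(gammaStar = "array", deltaStar = "array", hyper = "list",
                   batchLevels = "character", eb = "logical"))

#' Univariate CovBat stage-2 decomposition
#'
#' Eigenvectors of the pooled stage-1 residual covariance within one metric,
#' the associated principal-component scores, the retained component count K
#' (smallest count reaching the variance fraction), and the univariate ComBat
#' fit applied to the retained score columns.
#'
#' @slot metric metric identifier this decomposition belongs to.
#' @slot rotation p x p orthonormal eigenvector matrix (sign-fixed).
#' @slot scores n x p PC score matrix.
#' @slot K number of harmonized leading components.
#' @slot varFraction the variance fraction that determined K.
#' @slot scoreEffects `UVBatchEffects` for the K harmonized score columns.
#' @export
setClass("UVCovBatDecomposition",
    representation(metric = "character", rotation = "matrix",
                   scores = "matrix", K = "integer", varFraction = "numeric",
                   scoreEffects = "ANY"))

#' Empirical-Bayes priors for multivariate batch effects
#'
#' Method-of-moments hyperparameters, per batch: the normal prior
#' N(gammaBar_i, T_i) on the cross-metric location effects and the
#' inverse-Wishart prior IW(Psi_i, nu_i) on the cross-metric covariances.
#'
#' @slot gammaBar I x M matrix of prior means.
#' @slot Tmat list (length I) of M x M symmetric PSD prior covariances.
#' @slot Psi list (length I) of M x M symmetric PD inverse-Wishart scales.
#' @slot nu numeric length I, degrees of freedom (> M + 3).
#' @slot batchLevels batch labels, in order.
#' @export
setClass("BatchPriors",
    representation(gammaBar = "matrix", Tmat = "list", Psi = "list",
                   nu = "numeric", batchLevels = "character"),
    validity = function(object) {
        I <- nrow(object@gammaBar)
        if (length(object@Tmat) != I || length(object@Psi) != I ||
            length(object@nu) != I)
            return("gammaBar, Tmat, Psi and nu must agree on the batch count")
        M <- ncol(object@gammaBar)
        for (i in seq_len(I)) {
            if (!isSymmetric(unname(object@Tmat[[i]]), tol = 1e-8))
                return("each T must be symmetric")
            if (min(eigen(object@Psi[[i]], symmetric = TRUE,
                          only.values = TRUE)$values) <= 0)
                return("each Psi must be positive definite")
            if (object@nu[i] <= M + 1)
                return("each nu must exceed M + 1")
        }
        TRUE
    })

#' Posterior multivariate batch-effect estimates
#'
#' Per (batch, feature): the posterior mean location vector gammaStar (length
#' M) and posterior covariance SigmaStar (M x M, positive definite), plus the
#' batch-feature residual means and estimation metadata (iterations/
#' convergence for the EB fixed point; Rhat and effective sample sizes for
#' the MCMC estimator).
#'
#' @slot gammaStar I x p x M array of posterior location effects.
#' @slot SigmaStar list (length I) of p x M x M arrays of posterior
#'   covariances.
#' @slot Zbar I x p x M array of batch-feature residual means.
#' @slot batchLevels batch labels, in order.
#' @slot featureIds,metricIds identifier vectors fixing slice order.
#' @slot estimator `"eb"`, `"mcmc"`, or `"moments"`.
#' @slot iterations,converged EB fixed-point metadata (per batch x feature).
#' @slot diagnostics list; for MCMC: `rhat`, `ess`, `pass`, acceptance rates.
#' @export
setClass("BatchPosteriors",
    representation(gammaStar = "array", SigmaStar = "list", Zbar = "array",
                   batchLevels = "character", featureIds = "character",
                   metricIds = "character", estimator = "character",
                   iterations = "matrix", converged = "matrix",
                   diagnostics = "list"))

#' Shared latent subspace model across metrics
#'
#' MV-CovBat's stage-2 state: per-metric PCA loadings and scores of the
#' column-centered residual matrices, the shared orthonormal score matrix G
#' (top eigenvectors of S = sum_m F^(m) F^(m)'), the projections
#' A^(m) = G' F^(m), the idiosyncratic components H^(m) = F^(m) - G A^(m),
#' and the discarded-component remainders needed for exact reconstruction.
#'
#' @slot loadings list per metric of p x r_m orthonormal loading matrices.
#' @slot scores list per metric of n x r_m score matrices (F = U D).
#' @slot centers list per metric of column means removed before PCA.
#' @slot remainder list per metric of n x p matrices R - F L'.
#' @slot G n x r_s orthonormal shared score matrix.
#' @slot A list per metric of r_s x r_m projection matrices.
#' @slot H list per metric of n x r_m idiosyncratic score components.
#' @slot eigenvalues eigenvalues of S, descending.
#' @slot varFraction,sharedFraction retained-variance fractions for the
#'   per-metric PCAs and for r_s.
#' @slot metricIds metric identifiers, in order.
#' @export
setClass("LatentModel",
    representation(loadings = "list", scores = "list", centers = "list",
                   remainder = "list", G = "matrix", A = "list", H = "list",
                   eigenvalues = "numeric", varFraction = "numeric",
                   sharedFraction = "numeric", metricIds = "character"))

#' Paired gold-standard and unharmonized simulated panels
#'
#' @slot gold batch-free `PanelData` carrying only covariate effects + noise.
#' @slot observed the same panel after batch-effect injection.
#' @slot truth list of ground-truth bookkeeping: the biomarker feature set,
#'   covariate coefficients, and the injected batch parameters (per-(i,v)
#'   gamma/Sigma for feature-wise scenarios; rotations, shifts and latent
#'   covariances for the latent scenario) plus the injected batch term.
#' @slot config the `simConfig` list used to generate the dataset.
#' @export
setClass("SimulatedDataset",
    representation(gold = "PanelData", observed = "PanelData",
                   truth = "list", config = "list"))
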