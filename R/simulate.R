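#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' The defaults are the package's study conditions: I = 3 batches, p = 70
#' features, M = 6 metrics, covariates Age ~ N(50, 10^2), Sex ~
#' Bernoulli(0.5) and diagnosis ~ Bernoulli(0.3) acting on a biomarker
#' subset of 0.6 p features (weak effects on the first two metrics, stronger
#' on the rest), batch location shifts gamma_iv ~ N(gamma_i, T_i) and batch
#' covariances Sigma_iv drawn from an inverse-Wishart (`scenario =
#' "concordant"`), from a weighted mixture of IW/LKJ/FA/AR/CS families
#' (`"misspecified"`, weights 0.20/0.30/0.20/0.20/0.10), or injected through
#' a shared latent subspace (`"latent"`). `condition = "stress"` amplifies
#' the batch effects (location offsets tripled, covariance scale doubled).
#'
#' @param I,p,M,n batches, features, metrics, total subjects (split equally
#'   across batches, remainder to the last).
#' @param scenario `"concordant"`, `"misspecified"` or `"latent"`.
#' @param condition `"regular"` or `"stress"`.
#' @param beta_age,beta_sex age and sex effects per unit (all slices).
#' @param beta_diag_weak,beta_diag_strong diagnosis effect on biomarker
#'   features for metrics 1-2 and 3-M respectively.
#' @param beta_diag optional scalar overriding both diagnosis magnitudes
#'   (used by the controlled latent-space experiments).
#' @param biomarkerFraction fraction of features carrying diagnosis effects.
#' @param gamma_sd SD of the per-batch, per-metric location offsets
#'   gamma_i.
#' @param t_scale T_i = t_scale * I, the feature-level location dispersion.
#' @param iw_nu,iw_scale inverse-Wishart degrees of freedom and prior-mean
#'   scale (IW mean = iw_scale * I) of the batch covariances.
#' @param stress_gamma_mult,stress_cov_mult,stress_nu stress-test
#'   amplification of the location offsets and covariance scale, and the
#'   degrees of freedom used under stress.
#' @param mixtureWeights named weights over the IW/LKJ/FA/AR/CS covariance
#'   families (must sum to 1).
#' @param lkj_eta,fa_q LKJ concentration and factor count of the mixture
#'   families.
#' @param latent list of latent-mechanism parameters: `angle` (rotation
#'   blend in \[0, 1\]), `mu_sd` (latent mean-shift SD), `sigmaG` (latent
#'   noise SD), `varFraction`, `sharedFraction`.
#' @param replicates default replicate count for [runReplicates()].
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(I = 3L, p = 70L, M = 6L, n = 500L,
                      scenario = c("concordant", "misspecified", "latent"),
                      condition = c("regular", "stress"),
                      beta_age = 0.05, beta_sex = 0.5,
                      beta_diag_weak = 0.2, beta_diag_strong = 0.6,
                      beta_diag = NULL, biomarkerFraction = 0.6,
                      gamma_sd = 0.5, t_scale = 0.6,
                      iw_nu = 9, iw_scale = 0.25,
                      stress_gamma_mult = 3, stress_cov_mult = 2.7,
                      stress_nu = 9,
                      mixtureWeights = c(IW = 0.20, LKJ = 0.30, FA = 0.20,
                                         AR = 0.20, CS = 0.10),
                      lkj_eta = 2, fa_q = 2L,
                      latent = list(), replicates = 10L) {
    scenario <- match.arg(scenario)
    condition <- match.arg(condition)
    if (!is.null(beta_diag)) beta_diag_weak <- beta_diag_strong <- beta_diag
    if (abs(sum(mixtureWeights) - 1) > 1e-8)
        stop("mixture weights must sum to 1")
    if (!all(c("IW", "LKJ", "FA", "AR", "CS") %in% names(mixtureWeights)))
        stop("mixture weights must be named IW, LKJ, FA, AR, CS")
    if (iw_nu <= M + 1 || stress_nu <= M + 1)
        stop("inverse-Wishart degrees of freedom must exceed M + 1")
    fa_q <- max(1L, min(as.integer(fa_q), as.integer(M) - 1L))
    latent <- utils::modifyList(
        list(angle = 0.4, mu_sd = 0.4, sigmaG = 0.5,
             varFraction = 0.95, sharedFraction = 0.95), latent)
    if (latent$angle < 0 || latent$angle > 1)
        stop("latent rotation angle scale must lie in [0, 1]")
    cfg <- list(I = as.integer(I), p = as.integer(p), M = as.integer(M),
                n = as.integer(n), scenario = scenario,
                condition = condition, beta_age = beta_age,
                beta_sex = beta_sex, beta_diag_weak = beta_diag_weak,
                beta_diag_strong = beta_diag_strong,
                biomarkerFraction = biomarkerFraction, gamma_sd = gamma_sd,
                t_scale = t_scale, iw_nu = iw_nu, iw_scale = iw_scale,
                stress_gamma_mult = stress_gamma_mult,
                stress_cov_mult = stress_cov_mult, stress_nu = stress_nu,
                mixtureWeights = mixtureWeights, lkj_eta = lkj_eta,
                fa_q = as.integer(fa_q), latent = latent,
                replicates = as.integer(replicates))
    class(cfg) <- "simConfig"
    cfg
}

## Equal split of n across I batches, remainder to the last batch.
.batchSizes <- function(n, I) {
    base <- n %/% I
    sizes <- rep(base, I)
    sizes[I] <- sizes[I] + n - base * I
    sizes
}

#' Generate the batch-free (gold standard) panel
#'
#' Draws covariates, selects the biomarker subset, and builds
#' Y_base = epsilon + beta_age * Age + beta_sex * Sex + beta_diag * D *
#' 1(v in B) with iid N(0, 1) baseline noise. Batch labels are assigned
#' (equal split, remainder to the last batch) but carry no effect in the
#' gold panel.
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed.
#' @return list with `gold` (a [PanelData-class]) and `truth` (biomarker
#'   set, coefficient arrays, batch sizes).
#' @export
genBaseline <- function(config, seed = 1L) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(seed)
    n <- config$n; p <- config$p; M <- config$M
    age <- stats::rnorm(n, 50, 10)
    sex <- stats::rbinom(n, 1, 0.5)
    diag_ <- stats::rbinom(n, 1, 0.3)
    nB <- round(config$biomarkerFraction * p)
    biomarkers <- sort(sample.int(p, nB))
    betaDiag <- matrix(0, p, M)
    weakM <- seq_len(min(2, M))
    betaDiag[biomarkers, weakM] <- config$beta_diag_weak
    if (M > 2)
        betaDiag[biomarkers, (max(weakM) + 1):M] <- config$beta_diag_strong
    eps <- array(stats::rnorm(n * p * M), c(n, p, M))
    arr <- eps
    for (m in seq_len(M)) {
        arr[, , m] <- arr[, , m] + outer(age, rep(config$beta_age, p)) +
            outer(sex, rep(config$beta_sex, p)) +
            outer(diag_, betaDiag[, m])
    }
    sizes <- .batchSizes(n, config$I)
    batchLab <- rep(paste0("site", seq_len(config$I)), times = sizes)
    dimnames(arr) <- list(sprintf("S%04d", seq_len(n)),
                          sprintf("F%03d", seq_len(p)),
                          sprintf("m%02d", seq_len(M)))
    gold <- PanelData(arr, batch = batchLab,
                      covariates = data.frame(age = age, sex = sex,
                                              diagnosis = diag_))
    truth <- list(biomarkers = dimnames(arr)[[2]][biomarkers],
                  biomarkerIdx = biomarkers,
                  beta = list(age = config$beta_age, sex = config$beta_sex,
                              diagnosis = betaDiag),
                  batchSizes = sizes, noise = NULL)
    list(gold = gold, truth = truth)
}

#' Draw one batch covariance matrix from a named family
#'
#' Families: `IW` (inverse-Wishart with scale `Psi`, df `nu`), `LKJ`
#' (correlation from the LKJ(eta) distribution via the C-vine construction,
#' times diagonal scales `sigma`), `FA` (factor-analytic Lambda Lambda' + D
#' with `q` Gaussian factors), `AR` (Sigma_kl = sigma2 * rho^|k-l|), `CS`
#' (compound symmetry sigma2 * \[(1-rho) I + rho 11'\]). Uses the current
#' RNG state. All outputs are positive definite.
#'
#' @param family one of `"IW"`, `"LKJ"`, `"FA"`, `"AR"`, `"CS"`.
#' @param M matrix dimension.
#' @param params named list of family parameters (see Details above):
#'   IW: `Psi`, `nu`; LKJ: `eta`, `sigma` (scalar or length-M);
#'   FA: `q`, `lambda_sd`, `d`; AR/CS: `rho`, `sigma2`.
#' @return M x M positive-definite covariance matrix.
#' @export
drawBatchCovariance <- function(family = c("IW", "LKJ", "FA", "AR", "CS"),
                                M, params = list()) {
    family <- match.arg(family)
    switch(family,
        IW = {
            Psi <- params$Psi %||% diag(M)
            nu <- params$nu %||% (M + 6)
            if (nu <= M + 1) stop("nu must exceed M + 1")
            if (min(eigen(Psi, symmetric = TRUE,
                          only.values = TRUE)$values) <= 0)
                stop("Psi must be positive definite")
            W <- stats::rWishart(1, df = nu, Sigma = solve(Psi))[, , 1]
            solve(W)
        },
        LKJ = {
            eta <- params$eta %||% 2
            sigma <- params$sigma %||% 1
            if (length(sigma) == 1) sigma <- rep(sigma, M)
            R <- .rLKJ(M, eta)
            (sigma %o% sigma) * R
        },
        FA = {
            q <- params$q %||% 2L
            if (q >= M) stop("factor count q must be below M")
            lsd <- params$lambda_sd %||% 1
            d <- params$d %||% 0.5
            L <- matrix(stats::rnorm(M * q, 0, lsd), M, q)
            tcrossprod(L) + diag(rep(d, M))
        },
        AR = {
            rho <- params$rho %||% 0.5
            s2 <- params$sigma2 %||% 1
            if (abs(rho) >= 1) stop("|rho| must be below 1")
            s2 * rho^abs(outer(seq_len(M), seq_len(M), "-"))
        },
        CS = {
            rho <- params$rho %||% 0.3
            s2 <- params$sigma2 %||% 1
            if (rho >= 1 || rho <= -1 / (M - 1))
                stop("compound-symmetry rho out of range")
            s2 * ((1 - rho) * diag(M) + rho * matrix(1, M, M))
        })
}

#' Inject feature-wise batch effects
#'
#' For each batch i and feature v, draws a cross-metric location shift
#' gamma_iv ~ N(gamma_i, T_i) and a covariance Sigma_iv (inverse-Wishart in
#' the model-concordant scenario; a weighted IW/LKJ/FA/AR/CS mixture, family
#' assigned per feature, in the model-misspecified scenario), then adds
#' gamma_iv + N(0, Sigma_iv) noise to every subject of batch i. Under
#' `condition = "stress"` the location offsets are multiplied by
#' `stress_gamma_mult` and the covariance scale by `stress_cov_mult` (with
#' `stress_nu` degrees of freedom). The injected term is recorded so that
#' `observed - gold` reproduces it exactly.
#'
#' @param config a [simConfig()] list.
#' @param baseline result of [genBaseline()].
#' @param seed integer seed.
#' @return A [SimulatedDataset-class] object.
#' @export
genFeatureBatchEffects <- function(config, baseline, seed = 1L) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(seed)
    gold <- baseline$gold
    n <- nSubjects(gold); p <- nFeatures(gold); M <- nMetrics(gold)
    I <- config$I
    b <- batch(gold)
    levs <- levels(b)
    stress <- config$condition == "stress"
    gMult <- if (stress) config$stress_gamma_mult else 1
    cMult <- if (stress) config$stress_cov_mult else 1
    nu <- if (stress) config$stress_nu else config$iw_nu
    scale_ <- config$iw_scale * cMult
    fams <- if (config$scenario == "misspecified")
        sample(names(config$mixtureWeights), p, replace = TRUE,
               prob = config$mixtureWeights)
    else rep("IW", p)
    gammaArr <- array(NA_real_, c(I, p, M),
                      dimnames = list(levs, featureIds(gold),
                                      metricNames(gold)))
    SigmaList <- vector("list", I); names(SigmaList) <- levs
    delta <- array(0, dim = dim(panelArray(gold)))
    for (i in seq_len(I)) {
        rows <- which(b == levs[i])
        gi <- stats::rnorm(M, 0, config$gamma_sd)
        Sig <- array(NA_real_, c(p, M, M))
        for (v in seq_len(p)) {
            gamma_iv <- gMult * (gi + stats::rnorm(M, 0,
                                                   sqrt(config$t_scale)))
            Sigma_iv <- switch(fams[v],
                IW = drawBatchCovariance("IW", M, list(
                    Psi = (nu - M - 1) * scale_ * diag(M), nu = nu)),
                LKJ = drawBatchCovariance("LKJ", M, list(
                    eta = config$lkj_eta,
                    sigma = sqrt(scale_ *
                                 stats::rlnorm(M, -0.045, 0.3)))),
                FA = drawBatchCovariance("FA", M, list(
                    q = config$fa_q,
                    lambda_sd = sqrt(scale_ / (2 * config$fa_q)),
                    d = scale_ / 2)),
                AR = drawBatchCovariance("AR", M, list(
                    rho = stats::runif(1, 0.2, 0.8), sigma2 = scale_)),
                CS = drawBatchCovariance("CS", M, list(
                    rho = stats::runif(1, 0.1, 0.6), sigma2 = scale_)))
            gammaArr[i, v, ] <- gamma_iv
            Sig[v, , ] <- Sigma_iv
            noise <- .mvrnorm(length(rows), gamma_iv, Sigma_iv)
            delta[rows, v, ] <- matrix(noise, ncol = M)
        }
        SigmaList[[i]] <- Sig
    }
    observed <- .replaceValues(gold, panelArray(gold) + delta)
    truth <- baseline$truth
    truth$gamma <- gammaArr
    truth$Sigma <- SigmaList
    truth$families <- fams
    truth$batchTerm <- delta
    new("SimulatedDataset", gold = gold, observed = observed, truth = truth,
        config = unclass(config))
}

#' Inject latent-space batch effects
#'
#' Builds the shared latent subspace of the gold panel's baseline noise
#' (residuals after removing the true covariate effects), then perturbs the
#' shared scores of each batch with a batch-specific rotation (QR of a
#' Gaussian matrix blended with the identity by the `angle` scale and
#' re-orthonormalized by polar decomposition), a batch-specific latent mean
#' shift, and additive latent noise. The perturbation is propagated through
#' the projections A^(m) and loadings L^(m) back to data space and added to
#' the gold panel, inducing correlated covariance distortions across
#' features and metrics.
#'
#' @inheritParams genFeatureBatchEffects
#' @return A [SimulatedDataset-class] object.
#' @export
genLatentBatchEffects <- function(config, baseline, seed = 1L) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(seed)
    gold <- baseline$gold
    truth <- baseline$truth
    n <- nSubjects(gold); p <- nFeatures(gold); M <- nMetrics(gold)
    b <- batch(gold)
    levs <- levels(b)
    arr <- panelArray(gold)
    ## baseline noise = gold minus the generating covariate effects
    cov <- covariates(gold)
    eps <- arr
    for (m in seq_len(M)) {
        eps[, , m] <- eps[, , m] -
            outer(cov$age, rep(config$beta_age, p)) -
            outer(cov$sex, rep(config$beta_sex, p)) -
            outer(cov$diagnosis, truth$beta$diagnosis[, m])
    }
    residuals <- lapply(seq_len(M), function(m)
        sweep(eps[, , m], 2, colMeans(eps[, , m])))
    names(residuals) <- metricNames(gold)
    latent <- fitLatentModel(residuals,
                             varFraction = config$latent$varFraction,
                             sharedFraction = config$latent$sharedFraction,
                             metricIds = metricNames(gold))
    rs <- ncol(latent@G)
    a <- config$latent$angle
    delta <- array(0, dim = dim(arr))
    rot <- mus <- vector("list", length(levs))
    names(rot) <- names(mus) <- levs
    for (i in seq_along(levs)) {
        rows <- which(b == levs[i])
        Q <- qr.Q(qr(matrix(stats::rnorm(rs * rs), rs, rs)))
        Blend <- (1 - a) * diag(rs) + a * Q
        sv <- svd(Blend)
        Ri <- sv$u %*% t(sv$v)                      # polar re-orthonormalize
        ## shift and noise scales are relative to the RMS entry of the
        ## orthonormal score columns (1 / sqrt(n))
        colScale <- 1 / sqrt(n)
        mu_i <- stats::rnorm(rs, 0, config$latent$mu_sd * colScale)
        Gi <- latent@G[rows, , drop = FALSE]
        E <- matrix(stats::rnorm(length(rows) * rs, 0,
                                 config$latent$sigmaG * colScale),
                    length(rows), rs)
        dG <- Gi %*% Ri + matrix(mu_i, length(rows), rs, byrow = TRUE) +
            E - Gi
        for (m in seq_len(M))
            delta[rows, , m] <- delta[rows, , m] +
                dG %*% latent@A[[m]] %*% t(latent@loadings[[m]])
        rot[[i]] <- Ri
        mus[[i]] <- mu_i
    }
    observed <- .replaceValues(gold, arr + delta)
    truth$latent <- list(model = latent, rotations = rot, shifts = mus,
                         sigmaG = config$latent$sigmaG)
    truth$batchTerm <- delta
    new("SimulatedDataset", gold = gold, observed = observed, truth = truth,
        config = unclass(config))
}

#' Simulate a paired gold/observed dataset
#'
#' Convenience wrapper: [genBaseline()] followed by the batch-effect
#' generator selected by `config$scenario` (feature-wise for
#' `"concordant"`/`"misspecified"`, latent-space for `"latent"`).
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed (baseline and batch effects use derived seeds).
#' @return A [SimulatedDataset-class] object.
#' @export
simulatePanel <- function(config, seed = 1L) {
    baseline <- genBaseline(config, seed = .childSeed(seed, 1))
    if (config$scenario == "latent")
        genLatentBatchEffects(config, baseline, seed = .childSeed(seed, 2))
    else
        genFeatureBatchEffects(config, baseline, seed = .childSeed(seed, 2))
}

#' @describeIn SimulatedDataset-class compact display
#' @param object a `SimulatedDataset`.
#' @export
setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset (", object@config$scenario, "/",
        object@config$condition, ")\n", sep = "")
    show(object@observed)
})
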