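test_that("MoM hyperparameters handle degenerate dispersion and recover IW", {
    # identical batch-feature means: prior mean = that constant, T = 0
    Z <- array(0, c(20, 5, 2))
    Z[, , 1] <- 1; Z[, , 2] <- -2
    Z <- Z + array(rep(rnorm(20 * 2, 0, 0.5), times = c(1)), c(20, 5, 2)) * 0
    set.seed(1)
    noise <- array(rnorm(20 * 2, 0, 0.3), c(20, 1, 2))
    for (v in 1:5) Z[, v, ] <- Z[, v, ] + noise[, 1, ]   # same per feature
    pri <- momHyperparameters(Z, factor(rep("A", 20)))
    expect_equal(as.numeric(pri@gammaBar),
                 apply(Z[, 1, ], 2, mean), tolerance = 1e-10)
    expect_lt(max(abs(pri@Tmat[[1]])), 1e-20)

    # parameter recovery: Sigma_iv ~ IW(Psi, nu = 12), M = 4
    set.seed(42)
    M <- 4; p <- 200; ni <- 500; nu <- 12
    Psi <- diag(M) * (nu - M - 1) * 0.8
    Zr <- array(NA_real_, c(ni, p, M))
    for (v in seq_len(p)) {
        S <- drawBatchCovariance("IW", M, list(Psi = Psi, nu = nu))
        Zr[, v, ] <- MASS::mvrnorm(ni, rep(0, M), S)
    }
    pri2 <- momHyperparameters(Zr, factor(rep("A", ni)))
    priorMeanHat <- pri2@Psi[[1]] / (pri2@nu[1] - M - 1)
    priorMean <- Psi / (nu - M - 1)
    relErr <- sqrt(sum((priorMeanHat - priorMean)^2)) /
        sqrt(sum(priorMean^2))
    expect_lt(relErr, 0.1)
    # nu is recovered to the right order
    expect_gt(pri2@nu[1], 9)
    expect_lt(pri2@nu[1], 18)
})

test_that("scalar MoM reduces to the inverse-gamma ComBat moment match", {
    # with M = 1, IW(psi, nu) is IG(nu/2, psi/2); the fitted (nu, psi) must
    # match the classical a/b moment equations a = 2 + m^2/s2, b = m(a - 1)
    set.seed(7)
    ni <- 60; p <- 40
    Z <- array(rnorm(ni * p, 0, rep(sqrt(rgamma(p, 5, 5)), each = ni)),
               c(ni, p, 1))
    pri <- momHyperparameters(Z, factor(rep("A", ni)))
    S <- apply(Z[, , 1], 2, var)
    m <- mean(S); s2 <- var(S)
    aRef <- 2 + m^2 / s2
    bRef <- m * (aRef - 1)
    expect_equal(pri@nu[1] / 2, aRef, tolerance = 1e-8)
    expect_equal(pri@Psi[[1]][1, 1] / 2, bRef, tolerance = 1e-8)
})

test_that("EB posteriors respect the shrinkage limits and the fixed point", {
    set.seed(5)
    ni <- 40; p <- 6; M <- 3
    Z <- array(rnorm(2 * ni * p * M, 0.3), c(2 * ni, p, M))
    b <- factor(rep(c("A", "B"), each = ni))
    pri <- momHyperparameters(Z, b)
    gBar <- pri@gammaBar
    # T -> infinity: no shrinkage, gamma* = batch-feature mean
    priInf <- new("BatchPriors", gammaBar = gBar,
                  Tmat = rep(list(diag(1e8, M)), 2), Psi = pri@Psi,
                  nu = pri@nu, batchLevels = pri@batchLevels)
    postInf <- ebPosteriors(Z, b, priInf)
    expect_lt(max(abs(postInf@gammaStar - postInf@Zbar) /
                  (abs(postInf@Zbar) + 1e-3)), 1e-4)
    # T -> 0: full shrinkage, gamma* = prior mean
    priZero <- new("BatchPriors", gammaBar = gBar,
                   Tmat = rep(list(diag(1e-8, M)), 2), Psi = pri@Psi,
                   nu = pri@nu, batchLevels = pri@batchLevels)
    postZero <- ebPosteriors(Z, b, priZero)
    for (i in 1:2)
        expect_lt(max(abs(sweep(postZero@gammaStar[i, , ], 2, gBar[i, ]))),
                  1e-4)
    # fixed-point residual: substituting the returned values back into the
    # two conditional-posterior equations reproduces them
    post <- ebPosteriors(Z, b, pri, tol = 1e-10, maxIter = 500)
    for (i in 1:2) {
        rows <- which(b == levels(b)[i])
        Tinv <- solve(pri@Tmat[[i]])
        for (v in seq_len(p)) {
            Zi <- Z[rows, v, ]
            g <- post@gammaStar[i, v, ]
            S <- matrix(post@SigmaStar[[i]][v, , ], M, M)
            A <- ni * solve(S)
            gEq <- solve(A + Tinv, A %*% colMeans(Zi) + Tinv %*% gBar[i, ])
            C <- crossprod(sweep(Zi, 2, g))
            SEq <- (C + pri@Psi[[i]]) / (ni + pri@nu[i] - M - 1)
            expect_lt(max(abs(gEq - g)), 1e-8)
            expect_lt(max(abs(SEq - S)), 1e-8)
        }
    }
})

test_that("univariate reduction matches the scalar ComBat posterior mean", {
    # M = 1: gamma* must be the convex combination of the batch mean and the
    # prior mean with weight n / (n + Sigma*/T)
    set.seed(15)
    ni <- 50; p <- 12
    Z <- array(rnorm(2 * ni * p, 0, 1.3), c(2 * ni, p, 1))
    b <- factor(rep(c("A", "B"), each = ni))
    pri <- momHyperparameters(Z, b)
    post <- ebPosteriors(Z, b, pri, tol = 1e-10, maxIter = 500)
    for (i in 1:2) for (v in seq_len(p)) {
        S <- post@SigmaStar[[i]][v, 1, 1]
        Tm <- pri@Tmat[[i]][1, 1]
        w <- ni / (ni + S / Tm)
        ref <- w * post@Zbar[i, v, 1] + (1 - w) * pri@gammaBar[i, 1]
        expect_equal(post@gammaStar[i, v, 1], ref, tolerance = 1e-6)
        # monotone shrinkage: between the two anchors
        expect_true((post@gammaStar[i, v, 1] - post@Zbar[i, v, 1]) *
                    (pri@gammaBar[i, 1] - post@gammaStar[i, v, 1]) >= -1e-12)
    }
})

test_that("whitening adjustments behave as linear algebra dictates", {
    set.seed(25)
    ni <- 50; p <- 3; M <- 3
    Z <- array(rnorm(ni * p * M, 1, 2), c(ni, p, M))
    b <- factor(rep("A", ni))
    mk <- function(gamma, Sigma) {
        gs <- array(0, c(1, p, M)); Sl <- array(0, c(p, M, M))
        for (v in seq_len(p)) { gs[1, v, ] <- gamma[v, ]; Sl[v, , ] <- Sigma[[v]] }
        new("BatchPosteriors", gammaStar = gs, SigmaStar = list(A = Sl),
            Zbar = gs, batchLevels = "A",
            featureIds = paste0("f", 1:p), metricIds = paste0("m", 1:M),
            estimator = "moments", iterations = matrix(0, 1, p),
            converged = matrix(TRUE, 1, p), diagnostics = list())
    }
    # identity posteriors: no change
    post0 <- mk(matrix(0, p, M), rep(list(diag(M)), p))
    expect_identical(adjustResiduals(Z, b, post0), Z)
    # Sigma* = 4I: halves the centered residual
    g <- matrix(1, p, M)
    post4 <- mk(g, rep(list(4 * diag(M)), p))
    expect_equal(adjustResiduals(Z, b, post4),
                 sweep(Z, c(2, 3), array(1, c(p, M))) / 2, tolerance = 1e-12)
    # sample-moment posteriors whiten exactly to identity covariance
    gamma <- t(apply(Z, 2, function(x) colMeans(x)))
    gamma <- apply(Z, c(2, 3), mean)
    Sig <- lapply(seq_len(p), function(v) cov(Z[, v, ]))
    postS <- mk(gamma, Sig)
    W <- adjustResiduals(Z, b, postS)
    for (v in seq_len(p))
        expect_lt(max(abs(cov(W[, v, ]) - diag(M))), 1e-8)
})

test_that("mvCombat with one metric agrees with uvCombat", {
    pd <- makePanel(n = 120, p = 10, M = 1, I = 2, seed = 33,
                    batchShift = 0.5)
    hu <- uvCombat(pd, ~ age + sex)
    hm <- mvCombat(pd, ~ age + sex, tol = 1e-10, maxIter = 500)
    expect_lt(max(abs(panelArray(hu$data) - panelArray(hm$data))), 1e-4)
})

test_that("mvCombat removes covariance batch effects end to end", {
    cfg <- simConfig(n = 210, p = 15, M = 4)
    sim <- simulatePanel(cfg, seed = 3)
    h <- mvCombat(sim@observed, ~ age + sex + diagnosis)
    before <- multivariateBatchTests(sim@observed, ~ age + sex + diagnosis)
    after <- multivariateBatchTests(h$data, ~ age + sex + diagnosis)
    expect_gte(mean(before$boxm_p_bonf <= 0.05), 0.15)
    expect_lt(mean(after$boxm_p_bonf <= 0.05), 0.05)
    # deterministic: same call, same result
    h2 <- mvCombat(sim@observed, ~ age + sex + diagnosis)
    expect_identical(panelArray(h$data), panelArray(h2$data))
    # recolor = pooled is a valid variant and differs from the literal mode
    hp <- mvCombat(sim@observed, ~ age + sex + diagnosis,
                   recolor = "pooled")
    expect_gt(max(abs(panelArray(hp$data) - panelArray(h$data))), 1e-6)
})

test_that("posterior covariance error shrinks with batch size", {
    # Frobenius error of Sigma* against the generating covariance decreases
    # monotonically over n in {50, 150, 500}
    errs <- vapply(c(50, 150, 500), function(n) {
        cfg <- simConfig(n = n, p = 12, M = 3)
        sim <- simulatePanel(cfg, seed = 11)
        h <- mvCombat(sim@observed, ~ age + sex + diagnosis,
                      standardize = "none")
        tot <- 0; cnt <- 0
        for (i in seq_len(3)) for (v in seq_len(12)) {
            SigTrue <- sim@truth$Sigma[[i]][v, , ] + diag(3)  # + baseline
            S <- h$posteriors@SigmaStar[[i]][v, , ]
            tot <- tot + sqrt(sum((S - SigTrue)^2)); cnt <- cnt + 1
        }
        tot / cnt
    }, 0)
    expect_true(all(diff(errs) < 0))
})
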