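test_that("univariate batch tests are calibrated and powered", {
    # null: batch labels carry no effect; rejection rate near alpha
    set.seed(31)
    n <- 150; p <- 250; M <- 2
    pd <- makePanel(n = n, p = p, M = M, I = 2, seed = 31)
    res <- univariateBatchTests(pd)
    rate <- tapply(res$p < 0.05, res$test, mean)
    expect_true(all(rate <= 0.05 + 0.03))
    # a 5-sigma shift is detected decisively
    arr <- panelArray(pd)
    arr[batch(pd) == "B2", 1, 1] <- arr[batch(pd) == "B2", 1, 1] + 5
    pd2 <- PanelData(arr, batch = batch(pd), covariates = covariates(pd))
    res2 <- univariateBatchTests(pd2)
    expect_lt(res2$p[res2$feature == "roi01" & res2$metric == "met1" &
                     res2$test == "anova"], 1e-6)
    # Bonferroni is multiplication by the slice count, capped at 1
    expect_equal(res2$p_bonf, pmin(res2$p * p * M, 1))
})

test_that("Box's M behaves like its chi-square reference", {
    # identical groups: statistic exactly zero
    set.seed(33)
    X <- matrix(rnorm(60), 30, 2)
    same <- boxMTest(rbind(X, X), rep(c("A", "B"), each = 30))
    expect_equal(unname(same$statistic), 0, tolerance = 1e-10)
    # clear difference: I vs 4I at n = 200 per group
    X1 <- MASS::mvrnorm(200, c(0, 0), diag(2))
    X2 <- MASS::mvrnorm(200, c(0, 0), 4 * diag(2))
    strong <- boxMTest(rbind(X1, X2), rep(c("A", "B"), each = 200))
    expect_lt(strong$p.value, 0.01)
    # null calibration against the chi-square approximation at n_i = 100
    pv <- vapply(seq_len(300), function(k) {
        Y <- matrix(rnorm(200 * 3), 200, 3)
        boxMTest(Y, rep(c("A", "B"), each = 100))$p.value
    }, 0)
    expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
    # affine invariance: a common invertible transform leaves M unchanged
    A <- matrix(c(2, 0.5, -1, 1.5, 3, 0, 0.2, -0.7, 1), 3, 3)
    Y <- matrix(rnorm(300 * 3), 300, 3)
    g <- rep(c("A", "B", "C"), each = 100)
    m1 <- boxMTest(Y, g)$statistic
    m2 <- boxMTest(Y %*% A, g)$statistic
    expect_equal(unname(m1), unname(m2), tolerance = 1e-8)
})

test_that("MANOVA detects location differences and stays calibrated", {
    set.seed(35)
    Y <- matrix(rnorm(300 * 3), 300, 3)
    g <- rep(c("A", "B"), each = 150)
    expect_gt(manovaBatch(Y, g), 0.001)
    Y2 <- Y; Y2[g == "B", ] <- Y2[g == "B", ] + 0.5
    expect_lt(manovaBatch(Y2, g), 1e-6)
    pv <- vapply(seq_len(200), function(k) {
        Yn <- matrix(rnorm(120 * 2), 120, 2)
        manovaBatch(Yn, rep(c("A", "B"), each = 60))
    }, 0)
    expect_lt(abs(mean(pv < 0.05) - 0.05), 0.04)
})

test_that("the random-forest AUC separates signal from chance", {
    set.seed(37)
    pd <- makePanel(n = 120, p = 10, M = 1, I = 2, seed = 37)
    # permuted labels: chance level
    aucNull <- rfBatchAUC(pd, "met1", seed = 1)
    expect_gte(aucNull, 0.35)
    expect_lte(aucNull, 0.62)
    # batch defined by a threshold on feature 1: near-perfect
    arr <- panelArray(pd)
    bSep <- ifelse(arr[, 1, 1] > median(arr[, 1, 1]), "hi", "lo")
    pdSep <- PanelData(arr, batch = bSep)
    expect_gt(rfBatchAUC(pdSep, "met1", seed = 1), 0.95)
    # the two engines agree on both regimes
    aucRF <- rfBatchAUC(pdSep, "met1", seed = 1, engine = "randomForest")
    expect_gt(aucRF, 0.95)
    expect_error(rfBatchAUC(makePanel(n = 12, p = 3, M = 1, I = 2), "met1"),
                 ">= 10 subjects")
})

test_that("matrix distances match hand computations and invariances", {
    C <- diag(3)
    expect_true(all(correlationMatrixDistances(C, C) == 0))
    # one off-diagonal pair +/- 0.5: Frobenius = sqrt(2 * 0.25)
    C2 <- C; C2[1, 2] <- C2[2, 1] <- 0.5
    d <- correlationMatrixDistances(C, C2)
    expect_equal(unname(d["frobenius"]), sqrt(0.5), tolerance = 1e-12)
    expect_equal(unname(d["mse"]), 2 * 0.25 / 9, tolerance = 1e-12)
    expect_equal(unname(d["spectral"]), 0.5, tolerance = 1e-12)
    # permutation invariance under simultaneous reordering
    set.seed(39)
    A <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)))
    B <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)))
    pm <- sample(5)
    expect_equal(correlationMatrixDistances(A, B),
                 correlationMatrixDistances(A[pm, pm], B[pm, pm]),
                 tolerance = 1e-10)
})

test_that("signal preservation implements BH and truth bookkeeping", {
    # BH step-up by hand: (0.01, 0.02, 0.5) at q = 0.05 -> first two pass
    expect_identical(which(p.adjust(c(0.01, 0.02, 0.5), "BH") <= 0.05),
                     1:2)
    # all-true strong effects: every slice discovered, FDR 0
    set.seed(41)
    n <- 200; p <- 4; M <- 2
    diag_ <- rbinom(n, 1, 0.4)
    arr <- array(rnorm(n * p * M, 0, 0.5), c(n, p, M)) +
        array(rep(2 * diag_, p * M), c(n, p, M))
    pd <- PanelData(arr, batch = rep(c("A", "B"), length.out = n),
                    covariates = data.frame(diagnosis = diag_))
    sp <- signalPreservation(pd, ~ diagnosis,
                             truth = matrix(TRUE, p, M))
    expect_identical(sp$nDiscoveries, as.integer(p * M))
    expect_identical(sp$TP, as.integer(p * M))
    expect_equal(sp$FDR, 0)
    # null data: discoveries are rare and FDR-bounded
    arr0 <- array(rnorm(n * p * M), c(n, p, M))
    pd0 <- PanelData(arr0, batch = rep(c("A", "B"), length.out = n),
                     covariates = data.frame(diagnosis = diag_))
    sp0 <- signalPreservation(pd0, ~ diagnosis,
                              truth = matrix(FALSE, p, M))
    expect_lte(sp0$nDiscoveries, 1)
})

test_that("EB prior checks validate self-consistent simulations", {
    # data generated exactly from the fitted prior family: high overlap
    set.seed(43)
    ni <- 600; p <- 80; M <- 3; nu <- 12
    Psi <- (nu - M - 1) * diag(M)
    Z <- array(NA_real_, c(ni, p, M))
    for (v in seq_len(p)) {
        S <- drawBatchCovariance("IW", M, list(Psi = Psi, nu = nu))
        g <- rnorm(M, 0, 0.3)
        Z[, v, ] <- MASS::mvrnorm(ni, g, S)
    }
    b <- factor(rep("A", ni))
    pri <- momHyperparameters(Z, b)
    post <- ebPosteriors(Z, b, pri)
    chk <- ebPriorChecks(post, pri, Z, b, seed = 11)
    expect_gt(chk[["A"]]$overlap, 0.8)
    expect_false(chk[["A"]]$degenerate)
    # reproducible given the seed
    chk2 <- ebPriorChecks(post, pri, Z, b, seed = 11)
    expect_identical(chk[["A"]]$priorDist, chk2[["A"]]$priorDist)
    # degenerate T flagged
    priD <- new("BatchPriors", gammaBar = pri@gammaBar,
                Tmat = list(matrix(0, M, M)), Psi = pri@Psi, nu = pri@nu,
                batchLevels = pri@batchLevels)
    chkD <- ebPriorChecks(post, priD, Z, b, seed = 11)
    expect_true(chkD[["A"]]$degenerate)
    expect_null(chkD[["A"]]$locationDiscrepancy)
})
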