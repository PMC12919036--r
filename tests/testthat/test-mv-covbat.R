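test_that("metricPCA is exact on low rank and minimal at the fraction", {
    set.seed(8)
    u <- rnorm(20); v <- rnorm(6)
    R1 <- tcrossprod(u - mean(u), v)
    R1 <- sweep(R1, 2, colMeans(R1))
    pc <- metricPCA(R1, varFraction = 0.5)
    expect_identical(pc$r, 1L)
    expect_lt(max(abs(tcrossprod(pc$scores, pc$loadings) - R1)), 1e-10)
    # full fraction reconstructs exactly
    R2 <- scale(matrix(rnorm(120), 20, 6), scale = FALSE)
    pc2 <- metricPCA(R2, varFraction = 1)
    expect_lt(max(abs(tcrossprod(pc2$scores, pc2$loadings) - R2)), 1e-10)
    # retained fraction >= target, and one fewer component violates it
    pc3 <- metricPCA(R2, varFraction = 0.8)
    fr <- cumsum(pc3$values) / sum(pc3$values)
    expect_gte(fr[pc3$r], 0.8)
    if (pc3$r > 1) expect_lt(fr[pc3$r - 1], 0.8)
    expect_error(metricPCA(R2, varFraction = 0), "fraction")
    expect_error(metricPCA(matrix(rnorm(40), 20, 2) + 5, 0.95),
                 "column-centered")
})

test_that("sharedSubspace solves the trace-maximization problem", {
    set.seed(12)
    # single metric: G spans the leading left singular subspace and the
    # objective equals the discarded squared singular values
    F1 <- scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)
    sv <- svd(F1)
    sh <- sharedSubspace(list(F1), rs = 2)
    expect_lt(max(abs(crossprod(sh$G) - diag(2))), 1e-10)
    expect_equal(sh$objective, sum(sv$d[3:5]^2), tolerance = 1e-8)
    proj <- sh$G %*% crossprod(sh$G, sv$u[, 1:2])
    expect_lt(max(abs(proj - sv$u[, 1:2])), 1e-8)
    # identical rank-1 score matrices: the shared direction is recovered
    g <- rnorm(30); g <- g / sqrt(sum(g^2))
    Fm <- tcrossprod(g, c(3, 1))
    sh2 <- sharedSubspace(list(Fm, Fm, Fm), rs = 1)
    expect_lt(min(sum((sh2$G - g)^2), sum((sh2$G + g)^2)), 1e-16)
    expect_lt(sh2$objective, 1e-10)
    # objective identity: sum ||F||^2 - Tr(G' S G)
    F2 <- matrix(rnorm(40 * 3), 40, 3)
    sh3 <- sharedSubspace(list(F1, F2), rs = 3)
    S <- tcrossprod(F1) + tcrossprod(F2)
    expect_equal(sh3$objective,
                 sum(F1^2) + sum(F2^2) -
                     sum(diag(crossprod(sh3$G, S %*% sh3$G))),
                 tolerance = 1e-8)
    expect_error(sharedSubspace(list(F1), rs = 100), "exceed")
})

test_that("the eigendecomposition beats 1000 random orthonormal candidates", {
    set.seed(14)
    n <- 8
    Flist <- lapply(1:3, function(m) matrix(rnorm(n * 4), n, 4))
    sh <- sharedSubspace(Flist, rs = 2)
    objective <- function(G) {
        sum(vapply(Flist, function(Fm)
            sum((Fm - G %*% crossprod(G, Fm))^2), 0))
    }
    expect_equal(objective(sh$G), sh$objective, tolerance = 1e-8)
    worse <- vapply(seq_len(1000), function(k) {
        G <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
        objective(G) >= sh$objective - 1e-10
    }, TRUE)
    expect_true(all(worse))
})

test_that("shared-score harmonization removes injected latent shifts", {
    set.seed(16)
    n <- 300
    b <- factor(rep(c("A", "B"), each = n / 2))
    G <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    # null case: no batch effect, output stays close
    h0 <- harmonizeSharedScores(G, b)
    expect_lt(max(abs(h0$G - G)), 0.05 * max(abs(G)) + 0.05)
    # shift on batch B, one column: removed exactly without shrinkage and
    # almost entirely with it
    shift <- 0.5 / sqrt(n)
    G2 <- G
    G2[b == "B", 2] <- G2[b == "B", 2] + shift
    h2d <- harmonizeSharedScores(G2, b, eb = FALSE)
    dmd <- abs(mean(h2d$G[b == "A", 2]) - mean(h2d$G[b == "B", 2]))
    expect_lt(dmd, 1e-10)
    h2 <- harmonizeSharedScores(G2, b)
    dm <- abs(mean(h2$G[b == "A", 2]) - mean(h2$G[b == "B", 2]))
    expect_lt(dm, shift / 3)
    expect_error(harmonizeSharedScores(G, factor(rep("A", n))),
                 "two batches")
})

test_that("reconstruction is exact and energy bookkeeping holds", {
    set.seed(18)
    n <- 40; p <- 8
    residuals <- lapply(1:3, function(m)
        scale(matrix(rnorm(n * p), n, p), scale = FALSE))
    lat <- fitLatentModel(residuals, varFraction = 0.9)
    # identity propagation
    back <- reconstructResiduals(lat, lat@G)
    for (m in 1:3) expect_lt(max(abs(back[[m]] - residuals[[m]])), 1e-10)
    # energy bookkeeping: ||R* - R||_F = ||(G* - G) A L'||_F
    Gstar <- lat@G + matrix(rnorm(length(lat@G), 0, 0.01), nrow(lat@G))
    Rstar <- reconstructResiduals(lat, Gstar)
    for (m in 1:3) {
        lhs <- sqrt(sum((Rstar[[m]] - residuals[[m]])^2))
        rhs <- sqrt(sum(((Gstar - lat@G) %*% lat@A[[m]] %*%
                             t(lat@loadings[[m]]))^2))
        expect_equal(lhs, rhs, tolerance = 1e-8)
    }
})

test_that("mvCovbat nests mvCombat and is near-identity on null data", {
    cfg <- simConfig(n = 150, p = 10, M = 3)
    sim <- simulatePanel(cfg, seed = 21)
    h1 <- mvCombat(sim@observed, ~ age + sex + diagnosis)
    h2 <- mvCovbat(sim@observed, ~ age + sex + diagnosis)
    # skipping score harmonization (G* = G) reproduces stage 1 exactly
    E <- removeFixedEffects(h1$data, h1$model)
    lat <- fitLatentModel(lapply(1:3, function(m) E[, , m]))
    Rstar <- reconstructResiduals(lat, lat@G)
    for (m in 1:3) expect_lt(max(abs(Rstar[[m]] - E[, , m])), 1e-10)
    # the full pipeline alters stage-1 output only via the score step
    expect_true(is(h2$latent, "LatentModel"))
    expect_lt(max(abs(crossprod(h2$latent@G) -
                      diag(ncol(h2$latent@G)))), 1e-8)
    # null pipeline: no batch effects anywhere -> output close to input
    pd <- makePanel(n = 300, p = 8, M = 2, I = 2, seed = 23)
    h0 <- mvCovbat(pd, ~ age + sex)
    rel <- max(abs(panelArray(h0$data) - panelArray(pd))) /
        max(abs(panelArray(pd)))
    expect_lt(rel, 0.35)
})

test_that("mvCovbat beats mvCombat on latent-space covariance batch effects", {
    cfg <- simConfig(n = 300, p = 20, M = 3, scenario = "latent")
    sim <- simulatePanel(cfg, seed = 31)
    fo <- ~ age + sex + diagnosis
    h1 <- mvCombat(sim@observed, fo)
    h2 <- mvCovbat(sim@observed, fo)
    d1 <- correlationDistances(h1$data, "cross_metric", "across_batches",
                               formula = fo)
    d2 <- correlationDistances(h2$data, "cross_metric", "across_batches",
                               formula = fo)
    expect_lt(d2[["frobenius"]], d1[["frobenius"]])
})
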