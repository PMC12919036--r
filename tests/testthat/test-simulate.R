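test_that("the baseline generator matches its design", {
    cfg <- simConfig(n = 400, p = 70, M = 6, beta_age = 0, beta_sex = 0,
                     beta_diag_weak = 0, beta_diag_strong = 0)
    bl <- genBaseline(cfg, seed = 2)
    arr <- panelArray(bl$gold)
    # with all coefficients zero, slices are pure N(0, 1) noise
    expect_lt(max(abs(apply(arr[, 1:10, ], c(2, 3), mean))), 4 / sqrt(400))
    expect_lt(abs(sd(arr) - 1), 0.02)
    # biomarker subset size 0.6 p, rounded
    expect_identical(length(bl$truth$biomarkers), 42L)
    # same seed, same tensor
    bl2 <- genBaseline(cfg, seed = 2)
    expect_identical(panelArray(bl2$gold), arr)
    # weak/strong split over metrics
    cfg2 <- simConfig(n = 50, p = 10, M = 6)
    bl3 <- genBaseline(cfg2, seed = 3)
    bm <- bl3$truth$biomarkerIdx
    expect_true(all(bl3$truth$beta$diagnosis[bm, 1:2] == 0.2))
    expect_true(all(bl3$truth$beta$diagnosis[bm, 3:6] == 0.6))
    expect_true(all(bl3$truth$beta$diagnosis[-bm, ] == 0))
})

test_that("covariance families match their closed forms", {
    set.seed(4)
    expect_equal(drawBatchCovariance("AR", 4, list(rho = 0, sigma2 = 2)),
                 2 * diag(4))
    CS <- drawBatchCovariance("CS", 3, list(rho = 0.5, sigma2 = 1))
    expect_equal(CS[lower.tri(CS)], rep(0.5, 3))
    expect_equal(diag(CS), rep(1, 3))
    # IW mean identity: E[Sigma] = Psi / (nu - M - 1)
    M <- 4; nu <- 12; Psi <- 8 * diag(M)
    draws <- replicate(3000, drawBatchCovariance("IW", M,
                                                 list(Psi = Psi, nu = nu)))
    expect_lt(max(abs(apply(draws, c(1, 2), mean) - Psi / (nu - M - 1))),
              0.15)
    # every family yields a PD matrix
    for (fam in c("IW", "LKJ", "FA", "AR", "CS")) {
        S <- drawBatchCovariance(fam, 5)
        expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                  0)
    }
    expect_error(drawBatchCovariance("AR", 3, list(rho = 1.2)), "rho")
    expect_error(drawBatchCovariance("IW", 3, list(nu = 2)), "nu")
})

test_that("feature-wise injection is exactly bookkept", {
    cfg <- simConfig(n = 90, p = 8, M = 3)
    sim <- simulatePanel(cfg, seed = 5)
    # the observed panel is exactly gold plus the recorded batch term
    expect_identical(panelArray(sim@observed),
                     panelArray(sim@gold) + sim@truth$batchTerm)
    expect_lt(max(abs(panelArray(sim@observed) - panelArray(sim@gold) -
                      sim@truth$batchTerm)), 1e-12)
    # batch means of the injected term track the drawn gamma
    b <- batch(sim@gold)
    for (i in 1:3) {
        rows <- which(b == levels(b)[i])
        est <- apply(sim@truth$batchTerm[rows, , , drop = FALSE], c(2, 3),
                     mean)
        expect_lt(max(abs(est - sim@truth$gamma[i, , ])),
                  4 * sqrt(max(sapply(1:8, function(v)
                      max(diag(sim@truth$Sigma[[i]][v, , ])))) /
                      length(rows)) + 0.2)
    }
    # every drawn covariance is PD
    for (i in 1:3) for (v in 1:8)
        expect_gt(min(eigen(sim@truth$Sigma[[i]][v, , ], symmetric = TRUE,
                            only.values = TRUE)$values), 0)
    # near-zero effects give observed ~ gold
    cfg0 <- simConfig(n = 60, p = 4, M = 2, gamma_sd = 0, t_scale = 1e-12,
                      iw_scale = 1e-12)
    sim0 <- simulatePanel(cfg0, seed = 6)
    expect_lt(max(abs(panelArray(sim0@observed) - panelArray(sim0@gold))),
              1e-3)
    # seeded determinism end to end
    sim2 <- simulatePanel(cfg, seed = 5)
    expect_identical(panelArray(sim2@observed), panelArray(sim@observed))
})

test_that("the misspecified mixture assigns families at the stated weights", {
    cfg <- simConfig(n = 60, p = 400, M = 3, scenario = "misspecified")
    sim <- simulatePanel(cfg, seed = 7)
    counts <- table(factor(sim@truth$families,
                           levels = c("IW", "LKJ", "FA", "AR", "CS")))
    expected <- 400 * c(0.20, 0.30, 0.20, 0.20, 0.10)
    # multinomial tolerance: 4 standard deviations
    sds <- sqrt(expected * (1 - expected / 400))
    expect_true(all(abs(as.numeric(counts) - expected) < 4 * sds + 1))
})

test_that("the latent mechanism is exact at zero and detectable otherwise", {
    cfg0 <- simConfig(n = 80, p = 10, M = 3, scenario = "latent",
                      latent = list(angle = 0, mu_sd = 0, sigmaG = 0))
    sim0 <- simulatePanel(cfg0, seed = 8)
    expect_lt(max(abs(panelArray(sim0@observed) - panelArray(sim0@gold))),
              1e-10)
    # nonzero mean shifts are visible on at least one latent direction
    cfg1 <- simConfig(n = 240, p = 10, M = 3, scenario = "latent",
                      latent = list(angle = 0, mu_sd = 2, sigmaG = 0))
    sim1 <- simulatePanel(cfg1, seed = 9)
    lat <- sim1@truth$latent$model
    b <- batch(sim1@observed)
    ## project observed deviations onto the latent basis
    delta <- sim1@truth$batchTerm
    proj <- delta[, , 1] %*% lat@loadings[[1]]
    pv <- suppressWarnings(min(vapply(seq_len(ncol(proj)), function(k)
        anova(lm(proj[, k] ~ b))$`Pr(>F)`[1], 0)))
    expect_lt(pv, 1e-6)
    sim1b <- simulatePanel(cfg1, seed = 9)
    expect_identical(panelArray(sim1b@observed), panelArray(sim1@observed))
})
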