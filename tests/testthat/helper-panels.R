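# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no stored data.

# A small random panel with batch labels and covariates, optionally with an
# additive per-(batch, feature, metric) location shift.
makePanel <- function(n = 60, p = 5, M = 2, I = 2, seed = 1,
                      batchShift = 0) {
    set.seed(seed)
    sizes <- rep(n %/% I, I)
    sizes[I] <- sizes[I] + n - sum(sizes)
    b <- rep(paste0("B", seq_len(I)), times = sizes)
    arr <- array(rnorm(n * p * M), c(n, p, M),
                 dimnames = list(sprintf("s%03d", seq_len(n)),
                                 sprintf("roi%02d", seq_len(p)),
                                 sprintf("met%d", seq_len(M))))
    if (any(batchShift != 0)) {
        shift <- array(rnorm(I * p * M, 0, batchShift), c(I, p, M))
        for (i in seq_len(I))
            arr[b == paste0("B", i), , ] <-
                sweep(arr[b == paste0("B", i), , , drop = FALSE], c(2, 3),
                      shift[i, , ], "+")
    }
    PanelData(arr, batch = b,
              covariates = data.frame(age = rnorm(n, 50, 10),
                                      sex = rbinom(n, 1, 0.5),
                                      diagnosis = rbinom(n, 1, 0.3)))
}

# Panel whose values are an exact linear function of the covariates.
makeNoiselessPanel <- function(n = 40, p = 3, M = 2, seed = 2) {
    set.seed(seed)
    age <- rnorm(n, 50, 10)
    sex <- rbinom(n, 1, 0.5)
    arr <- array(NA_real_, c(n, p, M))
    for (m in seq_len(M)) for (v in seq_len(p))
        arr[, v, m] <- 2 + 3 * age + 0.5 * m * sex
    dimnames(arr) <- list(NULL, sprintf("roi%02d", seq_len(p)),
                          sprintf("met%d", seq_len(M)))
    PanelData(arr, batch = rep(c("B1", "B2"), length.out = n),
              covariates = data.frame(age = age, sex = sex))
}

expect_panel_equal <- function(a, b, tol = 1e-10) {
    expect_lt(max(abs(panelArray(a) - panelArray(b))), tol)
}
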