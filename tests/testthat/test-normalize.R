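test_that("background correction subtracts the negative mean, floored", {
    endo <- matrix(c(100, 30, 5), 3, 1)
    x <- norm_fixture(endo, negatives = 5)
    xb <- backgroundCorrect(x)
    expect_equal(unname(counts(xb)[1:3, 1]), c(95, 25, 0))
    # value equal to the negative mean lands exactly on the floor
    expect_equal(unname(counts(xb)[3, 1]), 0)
    # zero negatives leave the matrix unchanged
    x0 <- norm_fixture(endo, negatives = 0)
    expect_equal(counts(backgroundCorrect(x0))[1:3, ], counts(x0)[1:3, ])
    # applying a stage twice is an error
    expect_error(backgroundCorrect(xb), "already")
    expect_error(backgroundCorrect(x[probeInfo(x)$probe_class !=
                                     "Negative", ]), "Negative")
})

test_that("spike-in factors anchor to the geometric mean of spike means", {
    endo <- matrix(c(12, 40, 8, 12), 2, 2)
    x <- norm_fixture(endo, spike_means = c(10, 40))
    xs <- spikeinNormalize(backgroundCorrect(x))
    f <- normFactors(xs)$spikein
    expect_equal(unname(f), c(2.0, 0.5))
    expect_equal(unname(counts(xs)[1, 1]), 24)   # 12 doubled
    # identical spike means: factors all one, matrix unchanged
    xeq <- norm_fixture(endo, spike_means = c(25, 25))
    xse <- spikeinNormalize(backgroundCorrect(xeq))
    expect_equal(unname(normFactors(xse)$spikein), c(1, 1))
    expect_equal(counts(xse), counts(backgroundCorrect(xeq)))
    # zero spike mean names the offending sample
    xz <- norm_fixture(endo, spike_means = c(0, 40))
    expect_error(spikeinNormalize(backgroundCorrect(xz)), "s1")
    expect_error(spikeinNormalize(backgroundCorrect(x),
                                  spike_ids = "no-such-spike"), "absent")
})

test_that("content normalization uses the top-expressed set and excludes
           hemolysis markers", {
    endo <- matrix(c(4, 16, 16, 64), 2, 2)
    x <- norm_fixture(endo)
    xb <- backgroundCorrect(x)
    xc <- suppressWarnings(contentNormalize(xb))
    f <- normFactors(xc)$content
    # g = (8, 32), reference geomean 16 -> factors (2, 0.5)
    expect_equal(unname(f), c(2.0, 0.5))
    # identical samples: factors one
    xeq <- norm_fixture(matrix(c(4, 16, 4, 16), 2, 2))
    xce <- suppressWarnings(contentNormalize(backgroundCorrect(xeq)))
    expect_equal(unname(normFactors(xce)$content), c(1, 1))
})

test_that("hemolysis exclusion shields the content factor from
           contamination", {
    cc <- cohortConfig(n_pairs = c(PLCO = 40), n_probes = 100,
                       hemolysis_prob = 0, seed = 1)
    x <- generateCohort(cc)
    victim <- colnames(counts(x))[1]
    xh <- x
    m <- counts(xh)
    m[HEMOLYSIS_PROBES, victim] <- m[HEMOLYSIS_PROBES, victim] * 10
    xh <- miRtraj:::.set_counts(xh, m)

    run_content <- function(obj, excl)
        normFactors(contentNormalize(spikeinNormalize(
            backgroundCorrect(obj)), exclude = excl))$content[victim]

    # with the exclusion, the factor is untouched by hemolysis
    f_clean <- run_content(x, HEMOLYSIS_PROBES)
    f_hemo <- run_content(xh, HEMOLYSIS_PROBES)
    expect_lt(abs(f_hemo / f_clean - 1), 0.01)
    # without it, the contaminated markers drag the factor by > 5%
    f_clean0 <- run_content(x, character(0))
    f_hemo0 <- run_content(xh, character(0))
    expect_gt(abs(f_hemo0 / f_clean0 - 1), 0.05)
})

test_that("quantile normalization equalizes sorted vectors", {
    x <- norm_fixture(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
    xq <- quantileNormalize(x)
    expect_equal(unname(counts(xq)[1:3, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(counts(xq)[1:3, 2]), c(2.5, 3.5, 4.5))
    # identical samples are unchanged
    xi <- norm_fixture(matrix(c(5, 1, 9, 5, 1, 9), 3, 2))
    expect_equal(counts(quantileNormalize(xi))[1:3, ], counts(xi)[1:3, ])
    # within-sample ties receive the mean of the targets they span
    xt <- norm_fixture(matrix(c(5, 5, 7, 1, 2, 3), 3, 2))
    qt <- counts(quantileNormalize(xt))
    expect_equal(unname(qt[1:3, 1]), c(3.25, 3.25, 5))
    expect_equal(unname(qt[1:3, 2]), c(3, 3.5, 5))
    # definitional invariant, exact on tie-free (continuous) data
    set.seed(13)
    xc <- norm_fixture(matrix(runif(40 * 25, 1, 1000), 40, 25))
    xq2 <- quantileNormalize(xc)
    endo <- counts(xq2)[probeInfo(xq2)$probe_class == "Endogenous", ]
    sorted <- apply(endo, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))
    # single sample: warning, no-op
    x1 <- norm_fixture(matrix(c(1, 2, 3), 3, 1))
    expect_warning(quantileNormalize(x1), "2 samples")
})

test_that("the pipeline applies stages in the fixed order", {
    cc <- cohortConfig(n_pairs = c(PLCO = 15), n_probes = 60, seed = 3)
    x <- generateCohort(cc)
    xn <- normalizePipeline(x)
    expect_identical(stageTag(xn),
                     c("background", "spikein", "content", "quantile"))
    xn3 <- normalizePipeline(x, list(enable_quantile = FALSE))
    expect_identical(length(stageTag(xn3)), 3L)
    expect_true(all(counts(xn) >= 0))
    # factor provenance is complete
    f <- normFactors(xn)
    expect_identical(length(f$content_set), 50L)
    expect_identical(f$content_excluded, HEMOLYSIS_PROBES)
    expect_true(all(f$spikein > 0) && all(f$content > 0))
})

test_that("rescaling one sample only shifts the geometric-mean anchor", {
    # with geometric-mean anchoring, multiplying one sample's raw counts
    # by c > 0 multiplies every fully normalized value by exactly
    # c^(1/S); relative structure between samples is exactly invariant
    cc <- cohortConfig(n_pairs = c(PLCO = 10), n_probes = 60,
                       background_rate = 0, seed = 21)
    x <- generateCohort(cc)
    S <- ncol(x)
    cfac <- 3.7
    m2 <- counts(x)
    m2[, 4] <- m2[, 4] * cfac
    x2 <- miRtraj:::.set_counts(x, m2)
    n1 <- counts(normalizePipeline(x))
    n2 <- counts(normalizePipeline(x2))
    endo <- probeInfo(x)$probe_class == "Endogenous"
    expect_equal(n2[endo, ], n1[endo, ] * cfac^(1 / S), tolerance = 1e-12)
    # anchoring to the nominal spike input gives strict per-sample
    # invariance instead
    n1n <- counts(normalizePipeline(x, list(spike_ref = "nominal")))
    n2n <- counts(normalizePipeline(x2, list(spike_ref = "nominal")))
    expect_equal(n2n[endo, ], n1n[endo, ], tolerance = 1e-12)
})

test_that("normalization factors invert the simulated extraction
           efficiency", {
    cc <- cohortConfig(n_pairs = c(PLCO = 100), n_probes = 60, seed = 3)
    x <- generateCohort(cc)
    xn <- normalizePipeline(x)
    f <- normFactors(xn)
    lf <- log(f$spikein * f$content)
    le <- log(truthRecord(x)$efficiency)
    expect_lt(cor(le, lf), -0.9)
})
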