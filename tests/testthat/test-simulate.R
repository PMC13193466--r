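test_that("generator is deterministic and rejects invalid configs", {
    cc <- cohortConfig(n_pairs = c(PLCO = 20), n_probes = 40, seed = 11)
    x1 <- generateCohort(cc)
    x2 <- generateCohort(cc)
    expect_identical(counts(x1), counts(x2))
    expect_identical(sampleInfo(x1), sampleInfo(x2))
    # a different seed changes the data
    x3 <- generateCohort(cohortConfig(n_pairs = c(PLCO = 20),
                                      n_probes = 40, seed = 12))
    expect_false(identical(counts(x1), counts(x3)))

    expect_error(cohortConfig(n_pairs = c(PLCO = 0)), "positive")
    expect_error(cohortConfig(hemolysis_prob = 1.5), "probabilities")
    expect_error(cohortConfig(noise_sd = -1), "SDs")
    expect_error(cohortConfig(trajectory_panel = NULL), "panel")
})

test_that("every generated pair satisfies the matching constraints", {
    cc <- cohortConfig(n_pairs = c(PLCO = 60, SCCS = 40, MEC = 50),
                       n_probes = 30, seed = 5)
    man <- sampleInfo(generateCohort(cc))
    out <- validatePairs(man, strict = TRUE)
    expect_identical(nrow(attr(out, "violations")), 0L)
    # pairing structure: exactly one case and one control per pair
    roles <- table(man$pair_id, man$role)
    expect_true(all(roles == 1))
})

test_that("lead-time laws reproduce their stated medians", {
    expect_equal(sampleLeadTime(5, leadTimeLaw("point", value = 5)),
                 rep(5, 5))
    expect_error(sampleLeadTime(1, list(family = "gamma")), "lead_time_law")
    expect_error(leadTimeLaw("weibull"), "arg")

    set.seed(42)
    u <- sampleLeadTime(10000, leadTimeLaw("uniform"))
    expect_true(all(u >= 0.03 & u <= 19.61))
    # order-statistic CI for the median of U(0.03, 19.61)
    expect_gt(median(u), 9.0)
    expect_lt(median(u), 10.6)

    laws <- defaultLeadTimeLaws()
    targets <- c(PLCO = 3.7, SWHS_SMHS = 9.4, SCCS = 6.5, MEC = 8.2)
    set.seed(7)
    for (nm in names(targets)) {
        x <- sampleLeadTime(10000, laws[[nm]])
        expect_true(all(x >= 0.03 & x <= 19.61))
        expect_lt(abs(median(x) - targets[[nm]]), 0.3)
    }
})

test_that("CA19-9 case shift follows the linear ramp", {
    p0 <- list(meanlog = 2.5, sdlog = 0, gamma = 1.5, tau = 3)
    # sdlog 0 exposes the deterministic mean: shift = gamma*(1 - t/tau)
    v <- simulateCA199(c(TRUE, FALSE), c(1.5, 1.5), p0)
    expect_equal(log(v[1]) - log(v[2]), 0.75)
    # at or beyond tau the shift is exactly zero
    v <- simulateCA199(c(TRUE, FALSE), c(3, 3), p0)
    expect_equal(v[1], v[2])
    v <- simulateCA199(c(TRUE, FALSE), c(7, 7), p0)
    expect_equal(v[1], v[2])
    # gamma = 0: case and control distributions identical
    p1 <- list(meanlog = 2.5, sdlog = 0.8, gamma = 0, tau = 3)
    set.seed(1); a <- simulateCA199(rep(TRUE, 500), 1, p1)
    set.seed(1); b <- simulateCA199(rep(FALSE, 500), 1, p1)
    expect_identical(a, b)
    expect_error(simulateCA199(TRUE, 0, p0))
})

test_that("an all-null panel yields null log-ratios after normalization", {
    cc <- cohortConfig(n_pairs = c(PLCO = 100, MEC = 100), n_probes = 40,
                       trajectory_panel = nullTrajectoryPanel(), seed = 8)
    xn <- suppressWarnings(normalizePipeline(generateCohort(cc)))
    man <- sampleInfo(xn)
    ca <- man[man$role == "case", ]
    co <- man[man$role == "control", ]
    co <- co[match(ca$pair_id, co$pair_id), ]
    m <- counts(xn)
    for (p in setdiff(rownames(m), HEMOLYSIS_PROBES)[c(1, 10, 20, 30)]) {
        lr <- pairLogRatio(m[p, ca$sample_id], m[p, co$sample_id])
        se <- sd(lr) / sqrt(length(lr))
        expect_lt(abs(mean(lr)), 3 * se)
    }
})

test_that("spike-in counts identify the true extraction efficiency", {
    cc <- cohortConfig(n_pairs = c(PLCO = 250), n_probes = 40, seed = 3)
    x <- generateCohort(cc)
    eff <- truthRecord(x)$efficiency
    sp <- colMeans(counts(x)[c("ath-miR159a", "cel-miR248",
                               "osa-miR414"), ])
    slope <- coef(lm(log(sp) ~ log(eff)))[2]
    expect_lt(abs(slope - 1), 0.05)
})

test_that("repeated-draw series have the declared design", {
    rs <- simulateRepeatedSeries(n2 = 30, n3 = 20, seed = 2)
    tab <- table(rs$participant_id)
    expect_identical(sum(tab == 2), 30L)
    expect_identical(sum(tab == 3), 20L)
    # draw times distinct within participant
    expect_true(all(tapply(rs$lead_time, rs$participant_id,
                           function(t) !anyDuplicated(t)) > 0))
    expect_identical(rs, simulateRepeatedSeries(n2 = 30, n3 = 20, seed = 2))
})

test_that("truth record suffices to reconstruct expected counts", {
    cc <- cohortConfig(n_pairs = c(PLCO = 40), n_probes = 30, seed = 9,
                       noise_sd = 0)
    x <- generateCohort(cc)
    tr <- truthRecord(x)
    man <- sampleInfo(x)
    panel <- tr$trajectory_panel
    # with noise_sd 0, E[count] = bg + eff * exp(mu + delta); check one
    # signal probe across all samples via Poisson moment bounds
    pid <- panel$probe_id[1]
    delta <- ifelse(man$role == "case",
                    panel$a[1] + panel$b[1] * pmin(man$lead_time_years, 10),
                    0)
    lam <- tr$background_rate + tr$efficiency * exp(tr$mu[pid] + delta)
    obs <- counts(x)[pid, ]
    z <- (obs - lam) / sqrt(lam)
    expect_lt(abs(mean(z)), 4 / sqrt(length(z)))
})
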