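make_manifest <- function(n_pairs, lead = NULL) {
    lead <- lead %||% runif(n_pairs, 0.1, 12)
    data.frame(
        sample_id = c(paste0("P", seq_len(n_pairs), "_case"),
                      paste0("P", seq_len(n_pairs), "_control")),
        pair_id = rep(paste0("P", seq_len(n_pairs)), 2),
        role = rep(c("case", "control"), each = n_pairs),
        lead_time_years = rep(lead, 2))
}

test_that("time-dependent AUC equals the brute-force Mann-Whitney
           oracle", {
    man <- make_manifest(2, lead = c(0.5, 0.8))
    sc <- c(P1_case = 0.9, P2_case = 0.4, P1_control = 0.5,
            P2_control = 0.1)
    a <- timeDependentAUC(sc, man, 1)
    expect_equal(a$auc, 0.75)
    # perfect separation
    sc2 <- c(P1_case = 2, P2_case = 3, P1_control = 0, P2_control = 1)
    expect_equal(timeDependentAUC(sc2, man, 1)$auc, 1.0)
    # random fixtures against the double-loop oracle, with ties
    set.seed(30)
    for (i in 1:25) {
        n <- sample(3:25, 1)
        man <- make_manifest(n)
        sc <- setNames(round(rnorm(2 * n), 1), man$sample_id)
        t <- runif(1, 0.2, 12)
        a <- tryCatch(timeDependentAUC(sc, man, t), error = function(e) NULL)
        keep <- man$lead_time_years <= t & man$role == "case"
        if (is.null(a)) { expect_identical(sum(keep), 0L); next }
        cases <- man$sample_id[keep]
        ctrls <- sub("_case", "_control", cases)
        expect_equal(a$auc, auc_oracle(sc[cases], sc[ctrls]))
        expect_identical(a$n_case_pairs, length(cases))
    }
    expect_error(timeDependentAUC(sc, man, -1))
})

test_that("AUC is invariant under strictly monotone score transforms", {
    set.seed(31)
    man <- make_manifest(40)
    sc <- setNames(rnorm(80), man$sample_id)
    a1 <- timeDependentAUC(sc, man, 5)$auc
    a2 <- timeDependentAUC(exp(2 * sc) + 7, man, 5)$auc
    expect_identical(a1, a2)
})

test_that("risk-score fitting respects the matched design", {
    # balanced null feature: beta near 0, AUC near 0.5
    set.seed(32)
    man <- make_manifest(200)
    f <- matrix(rnorm(400), 400, 1, dimnames =
                list(man$sample_id, "x"))
    fit <- fitRiskScore(f, man)
    expect_true(fit$converged)
    expect_lt(abs(fit$beta), 0.2)
    expect_lt(abs(timeDependentAUC(fit$scores, man, 12)$auc - 0.5), 0.08)
    # feature present in every case, absent in every control: separation
    fs <- matrix(rep(c(1, 0), each = 200), 400, 1,
                 dimnames = list(man$sample_id, "x"))
    sep <- fitRiskScore(fs, man)
    expect_false(sep$converged)
})

test_that("nested models cannot lose conditional likelihood, and added
           signal raises the apparent AUC", {
    cc <- cohortConfig(n_pairs = scale_pairs(250), n_probes = 60, seed = 2)
    xn <- normalizePipeline(generateCohort(cc))
    man <- sampleInfo(xn)
    panel <- defaultTrajectoryPanel()$probe_id
    # in-sample conditional log-likelihood is monotone in the nesting
    ll <- vapply(1:4, function(m) {
        dx <- miRtraj:::.pair_diffs(riskFeatures(xn, m, panel), man)
        clogitFit(dx)$loglik
    }, numeric(1))
    expect_gte(ll[2], ll[1] - 1e-8)
    expect_gte(ll[3], ll[1] - 1e-8)
    expect_gte(ll[4], ll[2] - 1e-8)
    expect_gte(ll[4], ll[3] - 1e-8)
    # models with genuine added signal dominate Model 1 at every horizon
    au <- aucCurve(xn, panel, horizons = c(1, 3, 5, 10))
    for (t in c(1, 3, 5, 10)) {
        a <- au[au$t == t, ]
        expect_gt(a$auc[a$model == 4], a$auc[a$model == 1])
        expect_gt(a$auc[a$model == 3], a$auc[a$model == 1])
    }
})

test_that("bootstrap validation is deterministic and covers chance under
           the null", {
    cc <- cohortConfig(n_pairs = c(PLCO = 60, MEC = 60), n_probes = 30,
                       trajectory_panel = nullTrajectoryPanel(),
                       ca199 = list(meanlog = 2.5, sdlog = 0.8, gamma = 0,
                                    tau = 3),
                       diabetes_or0 = 1, smoking_or = 1, seed = 7)
    xn <- suppressWarnings(normalizePipeline(generateCohort(cc)))
    b1 <- bootstrapValidate(xn, character(0), models = 1:2,
                            horizons = c(2, 5, 10), B = 50, seed = 9)
    b2 <- bootstrapValidate(xn, character(0), models = 1:2,
                            horizons = c(2, 5, 10), B = 50, seed = 9)
    expect_identical(b1, b2)
    # the 95% band covers 0.5 for >= 90% of model-horizon cells
    covers <- b1$ci_low <= 0.5 & 0.5 <= b1$ci_high
    expect_gte(mean(covers), 0.9)
})

test_that("the CA19-9 contribution behaves at its limits", {
    # no CA19-9 effect: contribution near zero
    cc0 <- cohortConfig(n_pairs = scale_pairs(500),
                        n_probes = 60,
                        ca199 = list(meanlog = 2.5, sdlog = 0.8,
                                     gamma = 0, tau = 3), seed = 3)
    xn0 <- normalizePipeline(generateCohort(cc0))
    panel <- defaultTrajectoryPanel()$probe_id
    c0 <- ca199Contribution(xn0, panel, 3)
    expect_lt(abs(c0$contribution), 0.1)
    # no miRNA or covariate signal, strong CA19-9: contribution near one
    cc1 <- cohortConfig(n_pairs = scale_pairs(300), n_probes = 60,
                        trajectory_panel = nullTrajectoryPanel(),
                        ca199 = list(meanlog = 2.5, sdlog = 0.8,
                                     gamma = 3, tau = 12),
                        diabetes_or0 = 1, smoking_or = 1, seed = 3)
    xn1 <- suppressWarnings(normalizePipeline(generateCohort(cc1)))
    c1 <- ca199Contribution(xn1, character(0), 1)
    expect_gt(c1$contribution, 0.85)
    expect_lt(c1$contribution, 1.15)
    # default generator: a proper fraction at t = 1
    contrib <- vapply(1:5, function(s) {
        cc <- cohortConfig(n_pairs = scale_pairs(400), seed = 200 + s)
        xn <- normalizePipeline(generateCohort(cc))
        ca199Contribution(xn, panel, 1)$contribution
    }, numeric(1))
    expect_true(all(contrib > 0 & contrib < 1))
})

test_that("sensitivity filters act atomically on pairs", {
    man <- make_manifest(3, lead = c(0.5, 1.0, 1.5))
    f <- sensitivityFilter(man, "min_lead_1y")
    expect_identical(unique(f$pair_id), "P3")
    expect_identical(sensitivityFilter(man, "none"), man)
    expect_error(sensitivityFilter(man, "early_stage"), "stage")
    # stage-based filter keeps exactly the truth-record early-stage pairs
    x <- generateCohort(cohortConfig(n_pairs = c(PLCO = 50), n_probes = 20,
                                     seed = 10))
    sm <- sampleInfo(x)
    fe <- sensitivityFilter(sm, "early_stage")
    expected <- sm$pair_id[sm$role == "case" & sm$stage %in% c("I", "IIA")]
    expect_setequal(unique(fe$pair_id), expected)
    expect_true(all(table(fe$pair_id) == 2))
})

test_that("out-of-bag AUC shows non-negative optimism on average", {
    opt <- vapply(1:20, function(s) {
        cc <- cohortConfig(n_pairs = scale_pairs(300), n_probes = 60,
                           seed = 300 + s)
        xn <- normalizePipeline(generateCohort(cc))
        panel <- defaultTrajectoryPanel()$probe_id
        app <- aucCurve(xn, panel, models = 4, horizons = 1)
        bt <- bootstrapValidate(xn, panel, models = 4, horizons = 1,
                                B = 50, seed = s)
        bt$auc <= app$auc
    }, logical(1))
    expect_gte(mean(opt), 0.8)
})
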