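#' Lead-time distribution specification
#'
#' Describes the distribution of lead time (years from blood draw to the
#' case's diagnosis) for one cohort. Supported families: `"gamma"`
#' (shape/scale, truncated to `[min, max]` by inverse-CDF sampling),
#' `"uniform"` (on `[min, max]`), and `"point"` (degenerate at `value`).
#'
#' @param family one of `"gamma"`, `"uniform"`, `"point"`.
#' @param shape,scale gamma parameters.
#' @param min,max support bounds (default 0.03 and 19.61 years, the
#'   observed lead-time range of the emulated study population).
#' @param value point-mass location.
#' @return a list of class `lead_time_law`.
#' @export
leadTimeLaw <- function(family = c("gamma", "uniform", "point"),
                        shape = NULL, scale = NULL,
                        min = 0.03, max = 19.61, value = NULL) {
    family <- match.arg(family)
    if (family == "gamma" && (is.null(shape) || is.null(scale) ||
                              shape <= 0 || scale <= 0))
        stop("gamma law requires positive shape and scale", call. = FALSE)
    if (family == "point" && (is.null(value) || value <= 0))
        stop("point law requires a positive value", call. = FALSE)
    if (min <= 0 || max <= min)
        stop("lead-time support must be positive with min < max",
             call. = FALSE)
    structure(list(family = family, shape = shape, scale = scale,
                   min = min, max = max, value = value),
              class = "lead_time_law")
}

#' Default per-cohort lead-time laws
#'
#' Gamma distributions truncated to \[0.03, 19.61\] years, with parameters
#' chosen so the truncated medians match the cohort-specific medians of
#' years from sample collection to diagnosis (3.7, 9.4, 6.5 and 8.2 years
#' for the four cohort groups) and the interquartile ranges are close to
#' the observed ones.
#'
#' @return named list of [leadTimeLaw()] objects.
#' @export
defaultLeadTimeLaws <- function() {
    list(
        PLCO      = leadTimeLaw("gamma", shape = 1.3326, scale = 3.6720),
        SWHS_SMHS = leadTimeLaw("gamma", shape = 3.3947, scale = 3.2733),
        SCCS      = leadTimeLaw("gamma", shape = 2.3546, scale = 3.2836),
        MEC       = leadTimeLaw("gamma", shape = 1.9832, scale = 5.6362))
}

#' Draw lead times from a law
#'
#' @param n number of draws.
#' @param law a [leadTimeLaw()].
#' @return numeric vector of lead times in years, inside the law's support.
#' @examples
#' sampleLeadTime(3, leadTimeLaw("point", value = 5))
#' @export
sampleLeadTime <- function(n, law) {
    if (!inherits(law, "lead_time_law"))
        stop("'law' must be a lead_time_law", call. = FALSE)
    switch(law$family,
        point = rep(law$value, n),
        uniform = stats::runif(n, law$min, law$max),
        gamma = {
            plo <- stats::pgamma(law$min, law$shape, scale = law$scale)
            phi <- stats::pgamma(law$max, law$shape, scale = law$scale)
            stats::qgamma(stats::runif(n, plo, phi), law$shape,
                          scale = law$scale)
        },
        stop("unsupported lead-time family", call. = FALSE))
}

#' Default case/control log-ratio trajectory panel
#'
#' The "scissors" panel: each signal miRNA has a case-minus-control
#' difference on the natural-log scale of `a + b * min(leadtime, 10)` —
#' an intercept `a` at diagnosis and a linear drift `b` per year of lead
#' time, held constant beyond 10 years. Two oncogenic miRNAs (elevated in
#' cases near diagnosis, `a > 0`, `b < 0`) and eleven tumor-suppressive
#' miRNAs (depressed in cases near diagnosis, `a < 0`, `b > 0`) with
#' slope magnitudes of 0.03-0.10 per year, matching the scale reported
#' for pre-diagnostic plasma panels. All other probes are null.
#'
#' @return data.frame with columns `probe_id`, `accession`, `role`
#'   (oncogenic/suppressor), `a`, `b`.
#' @export
defaultTrajectoryPanel <- function() {
    data.frame(
        probe_id = c("hsa-miR-155-5p", "hsa-miR-493-3p",
                     "hsa-let-7g-5p", "hsa-let-7i-5p", "hsa-miR-15b-5p",
                     "hsa-miR-93-5p", "hsa-miR-106a-5p+hsa-miR-17-5p",
                     "hsa-miR-106b-5p", "hsa-miR-181a-5p", "hsa-miR-191-5p",
                     "hsa-miR-199a-3p+hsa-miR-199b-3p", "hsa-miR-223-3p",
                     "hsa-miR-340-5p"),
        accession = c("MIMAT0000646", "MIMAT0003161", "MIMAT0000414",
                      "MIMAT0000415", "MIMAT0000417", "MIMAT0000093",
                      "MIMAT0000103", "MIMAT0000680", "MIMAT0000256",
                      "MIMAT0000440", "MIMAT0000232", "MIMAT0000280",
                      "MIMAT0004692"),
        role = c("oncogenic", "oncogenic", rep("suppressor", 11)),
        a = c(0.425, 0.527, -0.523, -0.447, -0.471, -0.565, -0.570,
              -0.553, -0.630, -0.808, -0.252, -0.499, -0.629),
        b = c(-0.0633, -0.0673, 0.0667, 0.0507, 0.0701, 0.0686, 0.0736,
              0.0896, 0.0936, 0.0862, 0.0294, 0.0628, 0.1008),
        stringsAsFactors = FALSE)
}

#' An all-null trajectory panel
#' @return empty-effect panel (zero rows); every probe behaves as null.
#' @export
nullTrajectoryPanel <- function() {
    p <- defaultTrajectoryPanel()[0, ]
    p
}

# Table-1-like per-cohort covariate distributions (control population)
defaultCovariateTables <- function() {
    list(
        PLCO = list(female = 0.42, age_mean = 67.8, age_sd = 5.3,
                    bmi_mean = 26.7, bmi_sd = 3.9,
                    smoking = c(never = 0.53, former = 0.40, current = 0.07),
                    diabetes = 0.05, family_history = 0.024,
                    race = c(White = 0.89, Black = 0.03, Asian = 0,
                             Others = 0.08),
                    draw_years = c(1993, 2001)),
        SWHS_SMHS = list(female = 0.52, age_mean = 60.8, age_sd = 8.9,
                    bmi_mean = 24.2, bmi_sd = 3.4,
                    smoking = c(never = 0.71, former = 0.06, current = 0.23),
                    diabetes = 0.06, family_history = 0.015,
                    race = c(White = 0, Black = 0, Asian = 1, Others = 0),
                    draw_years = c(1997, 2006)),
        SCCS = list(female = 0.48, age_mean = 56.0, age_sd = 9.8,
                    bmi_mean = 29.7, bmi_sd = 6.9,
                    smoking = c(never = 0.34, former = 0.27, current = 0.39),
                    diabetes = 0.22, family_history = 0.005,
                    race = c(White = 0.23, Black = 0.74, Asian = 0,
                             Others = 0.03),
                    draw_years = c(2001, 2009)),
        MEC = list(female = 0.54, age_mean = 69.2, age_sd = 8.0,
                    bmi_mean = 26.5, bmi_sd = 4.9,
                    smoking = c(never = 0.52, former = 0.39, current = 0.09),
                    diabetes = 0.07, family_history = 0.013,
                    race = c(White = 0.15, Black = 0.19, Asian = 0.37,
                             Others = 0.29),
                    draw_years = c(2001, 2006)))
}

#' Simulate a CA19-9 concentration
#'
#' Stand-in model for the established serum biomarker: log-normal
#' baseline, with cases receiving an additive shift on the log scale of
#' `gamma * max(0, 1 - lead_time / tau)`, so that discrimination is
#' strongest at diagnosis and fades linearly to zero at `tau` years of
#' lead time. The emulated study gives no assay, units or timing for
#' CA19-9; this model is synthetic plumbing with an arbitrary U/mL
#' calibration.
#'
#' @param is_case logical vector.
#' @param lead_time positive numeric vector (years), recycled with
#'   `is_case`.
#' @param params list with `meanlog`, `sdlog`, `gamma`, `tau`.
#' @return numeric vector of concentrations.
#' @examples
#' simulateCA199(c(TRUE, FALSE), 1.5,
#'               list(meanlog = 2.5, sdlog = 0.8, gamma = 1.5, tau = 3))
#' @export
simulateCA199 <- function(is_case, lead_time,
                          params = list(meanlog = 2.5, sdlog = 0.8,
                                        gamma = 1.5, tau = 3)) {
    stopifnot(all(lead_time > 0))
    n <- max(length(is_case), length(lead_time))
    is_case <- rep_len(is_case, n)
    lead_time <- rep_len(lead_time, n)
    shift <- ifelse(is_case,
                    params$gamma * pmax(0, 1 - lead_time / params$tau), 0)
    exp(stats::rnorm(n, params$meanlog + shift, params$sdlog))
}

# the ramp itself, exposed for testing and for truth records
ca199LogShift <- function(lead_time, gamma, tau)
    gamma * pmax(0, 1 - lead_time / tau)

#' Configuration for the synthetic matched-cohort generator
#'
#' Defaults emulate the structure of a five-cohort nested case-control
#' study of 1307 matched pairs: cohort sizes 290/395/154/468, a
#' 798-probe endogenous panel plus 8 negative, 6 positive and 5 spike-in
#' control probes, per-cohort gamma lead-time laws, Table-1-like covariate
#' prevalences with case enrichment for current smoking (constant odds
#' multiplier) and diabetes (odds multiplier ramping up as diagnosis
#' approaches, reflecting prodromal new-onset diabetes), hemolysis
#' contamination of the three red-blood-cell marker miRNAs, and the
#' "scissors" log-ratio trajectory panel.
#'
#' @param n_pairs named integer vector of matched pairs per cohort.
#' @param n_probes number of endogenous probes (default 798).
#' @param lead_time_laws named list of [leadTimeLaw()], one per cohort.
#' @param covariates per-cohort covariate tables
#'   (see `miRtraj:::defaultCovariateTables`).
#' @param trajectory_panel data.frame as [defaultTrajectoryPanel()];
#'   zero rows means every probe is null.
#' @param hemolysis_prob probability a sample is hemolysed.
#' @param hemolysis_meanlog,hemolysis_sdlog log-normal parameters of the
#'   multiplicative hemolysis factor applied to the marker trio.
#' @param background_rate mean negative-control count per sample.
#' @param efficiency_sd SD of per-sample log extraction efficiency.
#' @param noise_sd SD of per-probe log measurement noise.
#' @param positive_noise_sd log noise SD of the positive-control ladder
#'   (hybridization-only, hence tighter than extraction-exposed probes).
#' @param ca199 list with `meanlog`, `sdlog`, `gamma` (case log-shift at
#'   lead time 0) and `tau` (years at which the shift reaches 0).
#' @param diabetes_or0 case/control odds multiplier for diabetes at lead
#'   time 0; decays linearly to 1 at `diabetes_tau` years.
#' @param diabetes_tau see above.
#' @param smoking_or constant case/control odds multiplier for current
#'   smoking.
#' @param stage_probs distribution of case TNM stage at diagnosis.
#' @param seed integer seed; the generator is byte-reproducible given it.
#'
#' @return list of class `cohort_config`.
#' @export
cohortConfig <- function(
    n_pairs = c(PLCO = 290, SWHS_SMHS = 395, SCCS = 154, MEC = 468),
    n_probes = 798,
    lead_time_laws = defaultLeadTimeLaws(),
    covariates = defaultCovariateTables(),
    trajectory_panel = defaultTrajectoryPanel(),
    hemolysis_prob = 0.05,
    hemolysis_meanlog = log(8), hemolysis_sdlog = 0.3,
    background_rate = 10,
    efficiency_sd = 0.35,
    noise_sd = 0.4,
    positive_noise_sd = 0.15,
    ca199 = list(meanlog = 2.5, sdlog = 0.8, gamma = 1.5, tau = 3),
    diabetes_or0 = 3, diabetes_tau = 10,
    smoking_or = 2,
    stage_probs = c(I = 0.10, IIA = 0.15, IIB = 0.25, III = 0.20, IV = 0.30),
    seed = 1L) {
    if (any(n_pairs <= 0) || length(n_pairs) == 0)
        stop("n_pairs must be positive", call. = FALSE)
    if (is.null(names(n_pairs)) || any(!names(n_pairs) %in% names(lead_time_laws)) ||
        any(!names(n_pairs) %in% names(covariates)))
        stop("every cohort in n_pairs needs a lead-time law and covariates",
             call. = FALSE)
    if (n_probes < 1) stop("n_probes must be positive", call. = FALSE)
    if (is.null(trajectory_panel))
        stop("trajectory panel must be a data.frame (possibly 0-row)",
             call. = FALSE)
    probs <- c(hemolysis_prob,
               unlist(lapply(covariates, function(cv)
                   c(cv$female, cv$smoking, cv$diabetes, cv$family_history,
                     cv$race))))
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must lie in [0, 1]", call. = FALSE)
    sds <- c(efficiency_sd, noise_sd, positive_noise_sd, hemolysis_sdlog,
             ca199$sdlog)
    if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
    structure(list(
        n_pairs = n_pairs, n_probes = n_probes,
        lead_time_laws = lead_time_laws, covariates = covariates,
        trajectory_panel = trajectory_panel,
        hemolysis_prob = hemolysis_prob,
        hemolysis_meanlog = hemolysis_meanlog,
        hemolysis_sdlog = hemolysis_sdlog,
        background_rate = background_rate,
        efficiency_sd = efficiency_sd, noise_sd = noise_sd,
        positive_noise_sd = positive_noise_sd,
        ca199 = ca199, diabetes_or0 = diabetes_or0,
        diabetes_tau = diabetes_tau, smoking_or = smoking_or,
        stage_probs = stage_probs, seed = as.integer(seed)),
        class = "cohort_config")
}

# assemble the probe panel: endogenous (signal + hemolysis markers + null
# filler), negatives, positive ladder, spike-ins
.build_panel <- function(config) {
    panel <- config$trajectory_panel
    named <- unique(c(panel$probe_id, HEMOLYSIS_PROBES))
    n_fill <- config$n_probes - length(named)
    if (n_fill < 0)
        stop("n_probes smaller than the named signal/marker probes",
             call. = FALSE)
    endo <- c(named, sprintf("hsa-miR-sim-%04d", seq_len(n_fill)))
    acc <- stats::setNames(rep(NA_character_, length(endo)), endo)
    acc[panel$probe_id] <- panel$accession
    acc["hsa-miR-451a"] <- "MIMAT0001631"
    probes <- data.frame(
        probe_id = c(endo, paste0("NEG_", LETTERS[1:8]),
                     paste0("POS_", LETTERS[1:6]),
                     c("ath-miR159a", "cel-miR248", "cel-miR254",
                       "osa-miR414", "osa-miR442")),
        probe_class = c(rep("Endogenous", length(endo)), rep("Negative", 8),
                        rep("Positive", 6), rep("SpikeIn", 5)),
        accession = c(unname(acc), rep(NA_character_, 19)),
        stringsAsFactors = FALSE)
    probes
}

#' Spike-in probe nominal count levels
#'
#' Expected counts at unit extraction efficiency for the five
#' non-mammalian spike-in oligos (three of which are used for
#' normalization by default).
#' @export
SPIKE_NOMINAL <- c("ath-miR159a" = 8000, "cel-miR248" = 2000,
                   "cel-miR254" = 1500, "osa-miR414" = 4000,
                   "osa-miR442" = 1200)

# positive-control titration ladder (4-fold steps)
POS_NOMINAL <- c(POS_A = 32768, POS_B = 8192, POS_C = 2048,
                 POS_D = 512, POS_E = 128, POS_F = 32)

# case-enriched categorical draws
.enrich_binary <- function(p, or) { o <- p / (1 - p) * or; o / (1 + o) }

#' Generate a synthetic matched cohort
#'
#' Draws matched case-control pairs cohort by cohort (shared cohort, sex,
#' race, age within 2 years, draw date within 90 days), assigns
#' covariates with case enrichment for current smoking and (lead-time
#' ramped) diabetes, simulates CA19-9, and generates a raw count matrix:
#' endogenous counts are Poisson around
#' `background + efficiency * exp(mu_k + delta_ks + noise)` where
#' `delta_ks = a_k + b_k * min(leadtime, 10)` for case samples of signal
#' probes; spike-ins scale with efficiency around their nominal levels;
#' negative controls are Poisson(background); positive controls follow a
#' fixed titration ladder unaffected by extraction. Hemolysed samples have
#' the three red-blood-cell marker miRNAs multiplied by a log-normal
#' factor > 1.
#'
#' @param config a [cohortConfig()].
#' @return a [MiRCountSet-class] with the manifest in `colData` and a
#'   ground-truth record (efficiencies, hemolysis flags/factors, probe
#'   baselines, trajectory panel, CA19-9 model) in
#'   `metadata(x)$truth`, retrievable with [truthRecord()].
#' @examples
#' cc <- cohortConfig(n_pairs = c(PLCO = 10), n_probes = 30, seed = 7)
#' x <- generateCohort(cc)
#' x
#' @export
generateCohort <- function(config) {
    if (!inherits(config, "cohort_config"))
        stop("config must come from cohortConfig()", call. = FALSE)
    with_local_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
    probes <- .build_panel(config)
    endo_ids <- probes$probe_id[probes$probe_class == "Endogenous"]
    n_endo <- length(endo_ids)

    # per-probe baseline log expression: signal and hemolysis-marker
    # miRNAs are well expressed (detected panels are), filler spans the
    # typical plasma dynamic range
    panel <- config$trajectory_panel
    mu <- stats::setNames(stats::rnorm(n_endo, 4, 1.2), endo_ids)
    if (nrow(panel))
        mu[panel$probe_id] <- stats::rnorm(nrow(panel), 5.5, 0.5)
    mu["hsa-miR-320e"] <- 6.8
    mu["hsa-miR-16-5p"] <- 7.6
    mu["hsa-miR-451a"] <- 7.2

    manifests <- list()
    for (cohort in names(config$n_pairs)) {
        n <- config$n_pairs[[cohort]]
        cv <- config$covariates[[cohort]]
        law <- config$lead_time_laws[[cohort]]
        lead <- sampleLeadTime(n, law)
        sex <- ifelse(stats::runif(n) < cv$female, "F", "M")
        race <- sample(names(cv$race), n, replace = TRUE, prob = cv$race)
        age_case <- round(stats::rnorm(n, cv$age_mean, cv$age_sd), 1)
        age_ctrl <- round(age_case + stats::runif(n, -2, 2), 1)
        d0 <- as.Date(sprintf("%d-01-01", cv$draw_years[1]))
        d1 <- as.Date(sprintf("%d-12-31", cv$draw_years[2]))
        date_case <- d0 + floor(stats::runif(n) * as.numeric(d1 - d0 + 1))
        date_ctrl <- date_case + round(stats::runif(n, -90, 90))
        bmi_case <- round(stats::rnorm(n, cv$bmi_mean, cv$bmi_sd), 1)
        bmi_ctrl <- round(stats::rnorm(n, cv$bmi_mean, cv$bmi_sd), 1)
        # diabetes enrichment ramps toward diagnosis (prodromal diabetes)
        or_t <- 1 + (config$diabetes_or0 - 1) *
            pmax(0, 1 - lead / config$diabetes_tau)
        dia_case <- stats::runif(n) < .enrich_binary(cv$diabetes, or_t)
        dia_ctrl <- stats::runif(n) < cv$diabetes
        smk_p <- cv$smoking
        smk_case_p <- cbind(smk_p["never"], smk_p["former"],
                            smk_p["current"] * config$smoking_or)
        smk_case_p <- smk_case_p / rowSums(smk_case_p)
        u <- stats::runif(n)
        smk_case <- ifelse(u < smk_case_p[, 1], "never",
                    ifelse(u < smk_case_p[, 1] + smk_case_p[, 2],
                           "former", "current"))
        u <- stats::runif(n)
        smk_ctrl <- ifelse(u < smk_p["never"], "never",
                    ifelse(u < smk_p["never"] + smk_p["former"],
                           "former", "current"))
        fh_case <- stats::runif(n) < cv$family_history
        fh_ctrl <- stats::runif(n) < cv$family_history
        stage <- sample(names(config$stage_probs), n, replace = TRUE,
                        prob = config$stage_probs)
        pair_id <- sprintf("%s_P%04d", cohort, seq_len(n))
        mk <- function(role, age, date, bmi, smk, dia, fh, stg)
            data.frame(sample_id = paste0(pair_id, "_", role),
                       pair_id = pair_id, cohort = cohort, role = role,
                       sex = sex, race = race, age_at_draw = age,
                       draw_date = date, lead_time_years = lead,
                       bmi = bmi, smoking = smk, diabetes = as.integer(dia),
                       family_history = as.integer(fh),
                       ca199 = NA_real_, stage = stg,
                       stringsAsFactors = FALSE)
        manifests[[cohort]] <- rbind(
            mk("case", age_case, date_case, bmi_case, smk_case, dia_case,
               fh_case, stage),
            mk("control", age_ctrl, date_ctrl, bmi_ctrl, smk_ctrl, dia_ctrl,
               fh_ctrl, NA_character_))
    }
    manifest <- do.call(rbind, manifests)
    manifest <- manifest[order(manifest$pair_id, manifest$role), ]
    rownames(manifest) <- NULL
    is_case <- manifest$role == "case"
    manifest$ca199 <- simulateCA199(is_case, manifest$lead_time_years,
                                    config$ca199)

    n_samp <- nrow(manifest)
    eff <- exp(stats::rnorm(n_samp, 0, config$efficiency_sd))
    hemo <- stats::runif(n_samp) < config$hemolysis_prob
    hfac <- ifelse(hemo, exp(stats::rnorm(n_samp, config$hemolysis_meanlog,
                                          config$hemolysis_sdlog)), 1)

    # case-minus-control log difference per signal probe and sample
    delta <- matrix(0, n_endo, n_samp,
                    dimnames = list(endo_ids, manifest$sample_id))
    if (nrow(panel)) {
        tcap <- pmin(manifest$lead_time_years, 10)
        for (i in seq_len(nrow(panel)))
            delta[panel$probe_id[i], is_case] <-
                panel$a[i] + panel$b[i] * tcap[is_case]
    }
    eps <- matrix(stats::rnorm(n_endo * n_samp, 0, config$noise_sd),
                  n_endo, n_samp)
    lam_endo <- sweep(exp(sweep(eps + delta, 1, mu, "+")), 2, eff, "*")
    for (p in intersect(HEMOLYSIS_PROBES, endo_ids))
        lam_endo[p, ] <- lam_endo[p, ] * hfac
    lam_endo <- lam_endo + config$background_rate

    lam_neg <- matrix(config$background_rate, 8, n_samp)
    eps_pos <- matrix(stats::rnorm(6 * n_samp, 0, config$positive_noise_sd),
                      6, n_samp)
    lam_pos <- config$background_rate + POS_NOMINAL * exp(eps_pos)
    eps_spk <- matrix(stats::rnorm(5 * n_samp, 0, config$noise_sd),
                      5, n_samp)
    lam_spk <- config$background_rate +
        sweep(SPIKE_NOMINAL * exp(eps_spk), 2, eff, "*")

    lam <- rbind(lam_endo, lam_neg, lam_pos, lam_spk)
    cnt <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    dimnames(cnt) <- list(probes$probe_id, manifest$sample_id)

    truth <- list(
        efficiency = stats::setNames(eff, manifest$sample_id),
        hemolysis = stats::setNames(hemo, manifest$sample_id),
        hemolysis_factor = stats::setNames(hfac, manifest$sample_id),
        mu = mu,
        trajectory_panel = panel,
        ca199 = config$ca199,
        ca199_log_shift = stats::setNames(
            ifelse(is_case, ca199LogShift(manifest$lead_time_years,
                                          config$ca199$gamma,
                                          config$ca199$tau), 0),
            manifest$sample_id),
        background_rate = config$background_rate,
        seed = config$seed)

    manifest$draw_date <- as.character(manifest$draw_date)
    MiRCountSet(cnt, probes, manifest,
                metadata = list(truth = truth))
}

#' Simulate repeated-draw log-ratio series
#'
#' Emulates the subset of one cohort with miRNA measured in 2-3 repeated
#' pre-diagnostic blood draws. Operates directly on the per-pair
#' log(case/control) ratio scale for a single miRNA: participant `i`
#' contributes observations
#' `log_ratio = intercept + slope * leadtime + u_i + e`, with
#' random intercept `u_i ~ N(0, sd_u^2)` and residual `e ~ N(0, sd_e^2)`.
#'
#' @param n2,n3 number of participants with 2 and with 3 draws
#'   (defaults 134 and 196, the emulated study subset).
#' @param slope,intercept fixed-effect trajectory.
#' @param sd_u random-intercept SD; `sd_e` residual SD.
#' @param law lead-time law for draw times (distinct within participant).
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `lead_time`, `log_ratio`.
#' @export
simulateRepeatedSeries <- function(n2 = 134, n3 = 196, slope = 0.05,
                                   intercept = -0.3, sd_u = 0.5,
                                   sd_e = 0.8,
                                   law = defaultLeadTimeLaws()$PLCO,
                                   seed = 1L) {
    with_local_seed(seed, {
        nrep <- c(rep(2L, n2), rep(3L, n3))
        id <- sprintf("RPT_%03d", seq_along(nrep))
        out <- lapply(seq_along(nrep), function(i) {
            t <- sort(sampleLeadTime(nrep[i], law))
            while (anyDuplicated(t)) t <- sort(sampleLeadTime(nrep[i], law))
            u <- stats::rnorm(1, 0, sd_u)
            data.frame(participant_id = id[i], lead_time = t,
                       log_ratio = intercept + slope * t + u +
                           stats::rnorm(nrep[i], 0, sd_e))
        })
        do.call(rbind, out)
    })
}
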