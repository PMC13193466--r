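#' Feature matrix for the nested risk models
#'
#' Model 1: age at draw, BMI, smoking (former/current indicators, never =
#' reference), diabetes, family history. Model 2: Model 1 + log CA19-9.
#' Model 3: Model 1 + the trend-significant miRNAs (log2 of normalized
#' value + 0.5, standardized). Model 4: the union of all predictors.
#'
#' @param x a normalized [MiRCountSet-class].
#' @param model integer 1-4.
#' @param mirna_probes probe ids entering Models 3 and 4 (typically the
#'   slope-significant panel from [trendTable()]).
#' @return numeric matrix, one row per sample, named columns.
#' @export
riskFeatures <- function(x, model, mirna_probes = character()) {
    stopifnot(model %in% 1:4)
    manifest <- sampleInfo(x)
    f <- .covariate_matrix(manifest)
    if (model %in% c(2, 4))
        f <- cbind(f, log_ca199 = log(manifest$ca199))
    if (model %in% c(3, 4) && length(mirna_probes)) {
        m <- counts(x)[mirna_probes, , drop = FALSE]
        expr <- t(log2(m + 0.5))
        expr <- scale(expr)
        expr[is.nan(expr)] <- 0
        colnames(expr) <- paste0("mir_", seq_along(mirna_probes))
        f <- cbind(f, expr)
    }
    rownames(f) <- manifest$sample_id
    f
}

#' Fit a risk score by conditional logistic regression
#'
#' Estimates coefficients on the case-minus-control pair differences with
#' [clogitFit()] (faithful to the matched design) and returns the linear
#' predictor `beta' x` for every sample; no intercept is needed for a
#' rank-based discrimination measure.
#'
#' @param features matrix from [riskFeatures()].
#' @param manifest manifest data.frame covering the same samples.
#' @return list: `beta`, `scores` (named by sample id), `converged`.
#' @export
fitRiskScore <- function(features, manifest) {
    dx <- .pair_diffs(features, manifest)
    keep <- apply(dx, 2, function(v) any(v != 0))
    fit <- clogitFit(dx[, keep, drop = FALSE])
    beta <- stats::setNames(rep(0, ncol(features)), colnames(features))
    beta[names(fit$beta)] <- fit$beta
    scores <- drop(features %*% beta)
    list(beta = beta, scores = stats::setNames(scores, rownames(features)),
         converged = fit$converged)
}

# Mann-Whitney AUC with ties counted 1/2, via midranks
.auc_rank <- function(case_scores, control_scores) {
    n1 <- length(case_scores); n0 <- length(control_scores)
    r <- rank(c(case_scores, control_scores))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Time-dependent AUC at a lead-time horizon
#'
#' Cumulative definition: restrict to pairs whose case lead time is at
#' most `t` years, then compute the Mann-Whitney probability that a case
#' score exceeds a control score over all case x control combinations in
#' the restricted set (ties counted 0.5).
#'
#' @param scores named numeric vector of risk scores (all samples).
#' @param manifest manifest data.frame.
#' @param t horizon in years (> 0).
#' @return list: `t`, `auc`, `n_case_pairs`.
#' @export
timeDependentAUC <- function(scores, manifest, t) {
    stopifnot(t > 0)
    cases <- manifest[manifest$role == "case" &
                      manifest$lead_time_years <= t, ]
    if (!nrow(cases))
        stop("no case pairs with lead time <= ", t, call. = FALSE)
    ctrls <- manifest[manifest$role == "control" &
                      manifest$pair_id %in% cases$pair_id, ]
    list(t = t, auc = .auc_rank(scores[cases$sample_id],
                                scores[ctrls$sample_id]),
         n_case_pairs = nrow(cases))
}

#' Apparent time-dependent AUC curves for the nested models
#'
#' Fits each requested model once on all pairs and evaluates the
#' cumulative AUC at each horizon.
#'
#' @param x a normalized [MiRCountSet-class].
#' @param mirna_probes miRNA panel for Models 3/4.
#' @param models integer subset of 1:4.
#' @param horizons lead-time horizons in years.
#' @return data.frame: `model`, `t`, `auc`, `ci_low`, `ci_high` (NA for
#'   apparent curves), `n_case_pairs`, `converged`.
#' @export
aucCurve <- function(x, mirna_probes = character(), models = 1:4,
                     horizons = 1:10) {
    manifest <- sampleInfo(x)
    out <- list()
    for (mod in models) {
        f <- riskFeatures(x, mod, mirna_probes)
        fit <- fitRiskScore(f, manifest)
        for (t in horizons) {
            a <- timeDependentAUC(fit$scores, manifest, t)
            out[[length(out) + 1]] <- data.frame(
                model = mod, t = t, auc = a$auc, ci_low = NA_real_,
                ci_high = NA_real_, n_case_pairs = a$n_case_pairs,
                converged = fit$converged)
        }
    }
    do.call(rbind, out)
}

#' Bootstrap internal validation of the AUC curves
#'
#' Resamples matched pairs (the pair is the resampling unit) with
#' replacement, refits every model on the in-bag pairs, and evaluates the
#' time-dependent AUC on the out-of-bag pairs. Reports the
#' across-replicate mean AUC and 2.5/97.5 percentile interval per model
#' and horizon. Replicates in which a horizon has no out-of-bag case pair
#' are skipped for that horizon and counted.
#'
#' @param x a normalized [MiRCountSet-class].
#' @param mirna_probes miRNA panel for Models 3/4.
#' @param models,horizons as in [aucCurve()].
#' @param B number of bootstrap replicates (>= 50 recommended).
#' @param seed integer seed; output is reproducible given it.
#' @return data.frame: `model`, `t`, `auc` (bootstrap mean), `ci_low`,
#'   `ci_high`, `n_replicates` (contributing), `n_skipped`.
#' @export
bootstrapValidate <- function(x, mirna_probes = character(), models = 1:4,
                              horizons = 1:10, B = 500, seed = 1L) {
    stopifnot(B >= 2)
    manifest <- sampleInfo(x)
    pair_ids <- unique(manifest$pair_id)
    feats <- lapply(models, function(mod) riskFeatures(x, mod, mirna_probes))
    names(feats) <- as.character(models)
    diffs <- lapply(feats, .pair_diffs, manifest = manifest)
    res <- array(NA_real_, dim = c(B, length(models), length(horizons)),
                 dimnames = list(NULL, models, horizons))
    with_local_seed(seed, {
        for (b in seq_len(B)) {
            inbag <- sample(pair_ids, length(pair_ids), replace = TRUE)
            oob <- setdiff(pair_ids, inbag)
            if (!length(oob)) next
            man_oob <- manifest[manifest$pair_id %in% oob, ]
            for (mi in seq_along(models)) {
                f <- feats[[mi]]
                dx <- diffs[[mi]][inbag, , drop = FALSE]
                dx <- dx[, apply(dx, 2, function(v) any(v != 0)),
                         drop = FALSE]
                fit <- tryCatch(clogitFit(dx), error = function(e) NULL)
                if (is.null(fit)) next
                beta <- stats::setNames(rep(0, ncol(f)), colnames(f))
                beta[colnames(dx)] <- fit$beta
                sc <- stats::setNames(drop(f %*% beta), rownames(f))
                for (ti in seq_along(horizons)) {
                    a <- tryCatch(
                        timeDependentAUC(sc, man_oob, horizons[ti]),
                        error = function(e) NULL)
                    if (!is.null(a)) res[b, mi, ti] <- a$auc
                }
            }
        }
    })
    out <- list()
    for (mi in seq_along(models)) for (ti in seq_along(horizons)) {
        v <- res[, mi, ti]
        ok <- !is.na(v)
        out[[length(out) + 1]] <- data.frame(
            model = models[mi], t = horizons[ti],
            auc = mean(v[ok]),
            ci_low = unname(stats::quantile(v[ok], 0.025)),
            ci_high = unname(stats::quantile(v[ok], 0.975)),
            n_replicates = sum(ok), n_skipped = B - sum(ok))
    }
    do.call(rbind, out)
}

#' Share of Model 4 discrimination attributable to CA19-9
#'
#' Defined as the AUC-above-chance share
#' `(AUC4(t) - AUC4_minus(t)) / (AUC4(t) - 0.5)`, where `AUC4_minus`
#' refits Model 4 without the CA19-9 term. This operationalization is one
#' of several possible decompositions; the returned object carries its
#' definition string.
#'
#' @param x a normalized [MiRCountSet-class].
#' @param mirna_probes miRNA panel for Model 4.
#' @param t horizon in years.
#' @return list: `t`, `contribution`, `auc_full`, `auc_reduced`,
#'   `definition`.
#' @export
ca199Contribution <- function(x, mirna_probes, t) {
    stopifnot(t > 0)
    manifest <- sampleInfo(x)
    f4 <- riskFeatures(x, 4, mirna_probes)
    f4m <- f4[, colnames(f4) != "log_ca199", drop = FALSE]
    a4 <- timeDependentAUC(fitRiskScore(f4, manifest)$scores, manifest, t)
    a4m <- timeDependentAUC(fitRiskScore(f4m, manifest)$scores, manifest, t)
    if (a4$auc <= 0.5)
        stop("full-model AUC does not exceed chance; share undefined",
             call. = FALSE)
    list(t = t,
         contribution = (a4$auc - a4m$auc) / (a4$auc - 0.5),
         auc_full = a4$auc, auc_reduced = a4m$auc,
         definition = "(AUC4 - AUC4_without_CA199) / (AUC4 - 0.5)")
}

#' Sensitivity filters on the analysis manifest
#'
#' `early_stage` keeps pairs whose case tumor stage is TNM I or IIA;
#' `min_lead_1y` keeps pairs whose lead time exceeds 1 year (strict);
#' `none` is the identity. Pairs are removed atomically.
#'
#' @param manifest manifest data.frame.
#' @param mode one of `"none"`, `"early_stage"`, `"min_lead_1y"`.
#' @return the filtered manifest.
#' @export
sensitivityFilter <- function(manifest,
                              mode = c("none", "early_stage",
                                       "min_lead_1y")) {
    mode <- match.arg(mode)
    if (mode == "none") return(manifest)
    cases <- manifest[manifest$role == "case", ]
    keep_pairs <- switch(mode,
        early_stage = {
            if (!"stage" %in% colnames(manifest) ||
                all(is.na(cases$stage)))
                stop("early_stage filter requires a stage column",
                     call. = FALSE)
            cases$pair_id[cases$stage %in% c("I", "IIA")]
        },
        min_lead_1y = cases$pair_id[cases$lead_time_years > 1.0])
    manifest[manifest$pair_id %in% keep_pairs, ]
}
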