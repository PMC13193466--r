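#' Decile-code an expression matrix
#'
#' Per probe, cutpoints are the 10th..90th empirical percentiles of the
#' pooled case+control values in the analysis set; scores 1..10 are
#' assigned so that values tied with a cutpoint share the lower decile.
#' Scores are invariant to any strictly monotone transform of a probe's
#' values. A constant probe gets all scores 1 and is flagged degenerate.
#'
#' @param m numeric matrix (probes x samples) of normalized values.
#' @return integer matrix of the same shape with attribute
#'   `"degenerate"`: probe ids with a single distinct value.
#' @export
decileTransform <- function(m) {
    out <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
    degen <- character()
    for (i in seq_len(nrow(m))) {
        v <- m[i, ]
        if (length(unique(v)) < 2) {
            degen <- c(degen, rownames(m)[i])
            next
        }
        q <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1),
                             names = FALSE)
        out[i, ] <- 1L + as.integer(rowSums(outer(v, q, ">")))
    }
    attr(out, "degenerate") <- degen
    out
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the conditional likelihood
#' `L(beta) = prod_i sigmoid(beta' dx_i)`, where `dx_i` is the
#' case-minus-control covariate difference of pair `i`, by Newton-Raphson
#' with analytic gradient and Hessian (tolerance 1e-8 on the score norm,
#' at most 50 iterations). Standard errors come from the inverse observed
#' information. Complete separation (any |beta| > 15) or a singular
#' Hessian flags the fit as non-converged.
#'
#' @param dx numeric matrix of pair differences, one row per pair, one
#'   column per covariate (the first column is conventionally the
#'   exposure of interest).
#' @return list: `beta`, `se`, `vcov`, `loglik`, `iterations`,
#'   `converged`.
#' @examples
#' # 6 pairs where only the case is exposed, 3 where only the control is:
#' fit <- clogitFit(matrix(c(rep(1, 6), rep(-1, 3)), ncol = 1))
#' exp(fit$beta)  # discordant-pair odds ratio 6/3 = 2
#' @export
clogitFit <- function(dx) {
    dx <- as.matrix(dx)
    if (all(dx[, 1] == 0))
        stop("non-identifiable: exposure difference is zero in every pair",
             call. = FALSE)
    p <- ncol(dx)
    beta <- rep(0, p)
    conv <- FALSE
    info <- NULL
    iter <- 0
    for (iter in seq_len(50)) {
        eta <- drop(dx %*% beta)
        mu <- stats::plogis(eta)
        score <- drop(crossprod(dx, 1 - mu))
        w <- mu * (1 - mu)
        info <- crossprod(dx * w, dx)
        if (abs(max(abs(beta))) > 15) break
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step)) break
        beta <- beta + step
        if (sqrt(sum(score^2)) < 1e-8) { conv <- TRUE; break }
    }
    if (max(abs(beta)) > 15) conv <- FALSE
    vc <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, p, p))
    ll <- sum(stats::plogis(drop(dx %*% beta), log.p = TRUE))
    names(beta) <- colnames(dx)
    list(beta = beta, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
         loglik = ll, iterations = iter, converged = conv)
}

#' Assign matched pairs to lead-time windows
#'
#' Each pair goes to exactly one window by the case's lead time, with
#' left-open, right-closed intervals: the default boundaries `c(5, 10)`
#' give windows (0, 5\], (5, 10\] and (10, Inf) — a lead time of exactly
#' 5 years falls in the first window, 10 years in the second.
#'
#' @param manifest data.frame with `pair_id`, `role`, `lead_time_years`.
#' @param breaks increasing numeric vector of inner boundaries (years).
#' @return data.frame `pair_id`, `lead_time_years`, `window` (factor with
#'   labels like `"(0,5]"`).
#' @export
windowStratify <- function(manifest, breaks = c(5, 10)) {
    stopifnot(all(diff(breaks) > 0), all(manifest$lead_time_years > 0))
    cases <- manifest[manifest$role == "case", ]
    edges <- c(0, breaks, Inf)
    labs <- c(sprintf("(%g,%g]", edges[seq_along(breaks)], breaks),
              sprintf(">%g", breaks[length(breaks)]))
    w <- cut(cases$lead_time_years, edges, labels = labs, right = TRUE)
    data.frame(pair_id = cases$pair_id,
               lead_time_years = cases$lead_time_years, window = w,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment with an explicit test count
#'
#' Step-up FDR adjustment in which the multiplier is `m_total`, the full
#' number of tests in the family (e.g. the panel size), which may exceed
#' the number of p-values supplied (probes filtered before testing still
#' count toward the family).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m_total family size; defaults to `length(p)`.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p, m_total = length(p)) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must be in [0, 1]", call. = FALSE)
    if (m_total < length(p))
        stop("m_total must be >= length(p)", call. = FALSE)
    stats::p.adjust(p, method = "BH", n = m_total)
}

# expand manifest covariates to the model matrix used for adjustment
.covariate_matrix <- function(manifest) {
    cbind(age = manifest$age_at_draw,
          bmi = manifest$bmi,
          smoking_former = as.numeric(manifest$smoking == "former"),
          smoking_current = as.numeric(manifest$smoking == "current"),
          diabetes = manifest$diabetes,
          family_history = manifest$family_history)
}

# case-minus-control difference matrix for arbitrary per-sample features
.pair_diffs <- function(features, manifest) {
    ca <- manifest$role == "case"
    co <- manifest$role == "control"
    idx_ca <- order(manifest$pair_id[ca])
    idx_co <- order(manifest$pair_id[co])
    f_ca <- features[ca, , drop = FALSE][idx_ca, , drop = FALSE]
    f_co <- features[co, , drop = FALSE][idx_co, , drop = FALSE]
    stopifnot(identical(manifest$pair_id[ca][idx_ca],
                        manifest$pair_id[co][idx_co]))
    structure(f_ca - f_co,
              dimnames = list(manifest$pair_id[ca][idx_ca],
                              colnames(features)))
}

#' Per-miRNA association table within lead-time windows
#'
#' For each window and endogenous probe: decile-codes the normalized
#' values over the window's pooled cases and controls, fits a conditional
#' logistic regression of case status on the decile score adjusted for
#' age, BMI, smoking (two indicators, never = reference), diabetes and
#' family history, and reports the odds ratio per one-decile increase
#' with Wald 95% CI and p-value. Benjamini-Hochberg adjustment is applied
#' across probes within each window with family size `m_total`.
#'
#' @param x a normalized [MiRCountSet-class] with the manifest in
#'   `colData`.
#' @param breaks lead-time window boundaries (see [windowStratify()]).
#' @param m_total BH family size (default: number of endogenous probes).
#' @param probes optional subset of probe ids to test.
#' @return data.frame (one row per window x probe, sorted by p within
#'   window): `probe_id`, `accession`, `window`, `n_pairs`, `OR`,
#'   `ci_low`, `ci_high`, `p`, `p_fdr`, `converged`, `low_information`
#'   (fewer than 20% of pairs discordant in decile score), `degenerate`.
#' @export
associationTable <- function(x, breaks = c(5, 10), m_total = NULL,
                             probes = NULL) {
    manifest <- sampleInfo(x)
    cls <- probeClass(x)
    endo <- names(cls)[cls == "Endogenous"]
    if (!is.null(probes)) endo <- intersect(endo, probes)
    if (is.null(m_total)) m_total <- sum(cls == "Endogenous")
    m <- counts(x)[endo, , drop = FALSE]
    wdf <- windowStratify(manifest, breaks)
    out <- list()
    for (w in levels(wdf$window)) {
        pairs_w <- wdf$pair_id[wdf$window == w]
        if (!length(pairs_w)) {
            warning("window ", w, " is empty; skipped")
            next
        }
        man_w <- manifest[manifest$pair_id %in% pairs_w, ]
        sub <- m[, man_w$sample_id, drop = FALSE]
        dec <- decileTransform(sub)
        degen <- attr(dec, "degenerate")
        cov_d <- .pair_diffs(.covariate_matrix(man_w), man_w)
        res <- vector("list", length(endo))
        for (i in seq_along(endo)) {
            pid <- endo[i]
            dd <- .pair_diffs(dec[pid, , drop = FALSE] |>
                                  t() |> `colnames<-`("decile"), man_w)
            row <- data.frame(probe_id = pid,
                              accession = probeInfo(x)$accession[
                                  match(pid, probeInfo(x)$probe_id)],
                              window = w, n_pairs = nrow(dd),
                              OR = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p = NA_real_,
                              p_fdr = NA_real_, converged = FALSE,
                              low_information = mean(dd[, 1] != 0) < 0.2,
                              degenerate = pid %in% degen)
            if (!(pid %in% degen) && any(dd[, 1] != 0)) {
                fit <- tryCatch(
                    clogitFit(cbind(dd, cov_d)),
                    error = function(e) NULL)
                if (!is.null(fit) && fit$converged) {
                    b <- fit$beta[1]; se <- fit$se[1]
                    row$OR <- exp(b)
                    row$ci_low <- exp(b - 1.96 * se)
                    row$ci_high <- exp(b + 1.96 * se)
                    row$p <- 2 * stats::pnorm(-abs(b / se))
                    row$converged <- TRUE
                }
            }
            res[[i]] <- row
        }
        res <- do.call(rbind, res)
        ok <- res$converged & !is.na(res$p)
        res$p_fdr[ok] <- bhAdjust(res$p[ok], m_total = m_total)
        res <- res[order(res$p), ]
        out[[w]] <- res
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
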