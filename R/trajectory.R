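#' Per-pair log(case/control) ratio
#'
#' Natural log of the case value over its matched control's value. A
#' pseudocount (default 0.5) is added to both terms only when either
#' value is zero, so the bulk of ratios is not biased. Pairs with both
#' values zero yield 0 and are flagged degenerate.
#'
#' @param case,control non-negative numeric vectors (normalized values).
#' @param pseudocount added to both values of a zero-containing pair.
#' @return numeric vector with attribute `"degenerate"` (logical: both
#'   values were zero).
#' @examples
#' pairLogRatio(20, 10)           # log(2)
#' pairLogRatio(0, 10)            # log(0.5 / 10.5)
#' @export
pairLogRatio <- function(case, control, pseudocount = 0.5) {
    stopifnot(all(case >= 0), all(control >= 0))
    zero <- case == 0 | control == 0
    c_add <- ifelse(zero, pseudocount, 0)
    r <- log((case + c_add) / (control + c_add))
    both0 <- case == 0 & control == 0
    r[both0] <- 0
    attr(r, "degenerate") <- both0
    r
}

#' Linear trend of log-ratios over lead time
#'
#' Ordinary least squares of log(case/control) on lead time with
#' intercept, restricted to pairs with lead time at most `max_lead`
#' (default 10 years, inclusive). Reports the mean and SD of the included
#' log-ratios, the slope per year, its standard error, and a two-sided
#' t-test p-value.
#'
#' @param log_ratios,lead_times numeric vectors of equal length.
#' @param max_lead inclusion threshold in years.
#' @return list: `mean_log_ratio`, `sd_log_ratio`, `beta`, `se`, `p`,
#'   `n_pairs`.
#' @export
trendFit <- function(log_ratios, lead_times, max_lead = 10) {
    keep <- lead_times <= max_lead
    y <- as.numeric(log_ratios[keep])
    t <- lead_times[keep]
    n <- length(y)
    if (n < 3)
        stop("insufficient data: fewer than 3 pairs within the window",
             call. = FALSE)
    sxx <- sum((t - mean(t))^2)
    if (sxx == 0)
        stop("lead times are constant; slope not identifiable",
             call. = FALSE)
    beta <- sum((t - mean(t)) * (y - mean(y))) / sxx
    alpha <- mean(y) - beta * mean(t)
    rss <- sum((y - alpha - beta * t)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    p <- if (se == 0) {
        if (beta == 0) 1 else 0
    } else 2 * stats::pt(-abs(beta / se), df = n - 2)
    list(mean_log_ratio = mean(y), sd_log_ratio = stats::sd(y),
         beta = beta, se = se, p = p, n_pairs = n)
}

#' Random-intercept trend for repeated-draw series
#'
#' Fits `log_ratio_ij = b0 + b1 * leadtime_ij + u_i + e_ij` with
#' participant random intercepts `u_i ~ N(0, s_u^2)` by REML
#' ([lme4::lmer]), and tests `b1` with a Wald z-test. If the mixed fit
#' fails to converge, falls back to pooled OLS with cluster-robust
#' (CR1) standard errors clustered on participant.
#'
#' @param series data.frame with `participant_id`, `lead_time`,
#'   `log_ratio` (at least 2 observations per participant, at least 5
#'   participants).
#' @param max_lead restrict to observations with lead time <= `max_lead`
#'   (default 10).
#' @return list: `beta`, `se`, `p`, `sigma_u`, `sigma_e`, `method`
#'   (`"reml"` or `"ols_cluster"`), `n_participants`, `n_obs`.
#' @export
repeatedTrendFit <- function(series, max_lead = 10) {
    s <- series[series$lead_time <= max_lead, ]
    tab <- table(s$participant_id)
    s <- s[s$participant_id %in% names(tab)[tab >= 2], ]
    if (length(unique(s$participant_id)) < 5)
        stop("need >= 5 participants with >= 2 draws", call. = FALSE)
    fit <- tryCatch(
        suppressWarnings(suppressMessages(
            lme4::lmer(log_ratio ~ lead_time + (1 | participant_id),
                       data = s, REML = TRUE))),
        error = function(e) NULL)
    if (!is.null(fit)) {
        co <- lme4::fixef(fit)
        vc <- as.data.frame(lme4::VarCorr(fit))
        se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
        return(list(beta = unname(co[2]), se = unname(se),
                    p = 2 * stats::pnorm(-abs(co[2] / se)),
                    sigma_u = vc$sdcor[vc$grp == "participant_id"],
                    sigma_e = vc$sdcor[vc$grp == "Residual"],
                    method = "reml",
                    n_participants = length(unique(s$participant_id)),
                    n_obs = nrow(s)))
    }
    # fallback: pooled OLS with CR1 cluster-robust SE on participant
    X <- cbind(1, s$lead_time)
    y <- s$log_ratio
    bread <- solve(crossprod(X))
    b <- drop(bread %*% crossprod(X, y))
    e <- y - drop(X %*% b)
    gs <- split(seq_along(e), s$participant_id)
    meat <- Reduce(`+`, lapply(gs, function(i) {
        u <- crossprod(X[i, , drop = FALSE], e[i])
        tcrossprod(u)
    }))
    G <- length(gs); n <- nrow(X); k <- ncol(X)
    vc <- bread %*% meat %*% bread * (G / (G - 1)) * ((n - 1) / (n - k))
    se <- sqrt(diag(vc))[2]
    list(beta = b[2], se = se, p = 2 * stats::pnorm(-abs(b[2] / se)),
         sigma_u = NA_real_, sigma_e = stats::sd(e),
         method = "ols_cluster",
         n_participants = G, n_obs = n)
}

#' Log-ratio trend table with plotting series
#'
#' For each probe in `probes` (default: the probes significant after FDR
#' in the first lead-time window of `assoc`), computes per-pair
#' log(case/control) ratios of the normalized values, fits the linear
#' trend over lead time up to `max_lead`, and partitions probes by slope
#' sign (negative-slope probes rise toward diagnosis; positive-slope
#' probes fall or reverse).
#'
#' @param x a normalized [MiRCountSet-class].
#' @param probes character vector of probe ids, or `NULL` to derive from
#'   `assoc`.
#' @param assoc an [associationTable()] result (used when `probes` is
#'   `NULL`).
#' @param fdr FDR threshold used to select probes from `assoc`.
#' @param max_lead trend window in years (default 10).
#' @param line_grid lead times at which fitted lines are evaluated for
#'   plotting.
#' @return list with `table` (data.frame: `probe_id`, `mean_log_ratio`,
#'   `sd_log_ratio`, `beta`, `se`, `p`, `n_pairs`, `direction`) and
#'   `lines` (data.frame: `probe_id`, `lead_time`, `fitted`).
#' @export
trendTable <- function(x, probes = NULL, assoc = NULL, fdr = 0.05,
                       max_lead = 10, line_grid = seq(0, 10, by = 0.5)) {
    if (is.null(probes)) {
        if (is.null(assoc))
            stop("provide either 'probes' or 'assoc'", call. = FALSE)
        labs <- unique(as.character(assoc$window))
        lower <- vapply(labs, function(l)
            if (grepl("^\\(", l))
                as.numeric(sub("^\\(([-0-9.]+),.*", "\\1", l)) else Inf,
            numeric(1))
        first_lab <- labs[which.min(lower)]
        sel <- assoc$window == first_lab & !is.na(assoc$p_fdr) &
            assoc$p_fdr < fdr
        probes <- assoc$probe_id[sel]
    }
    if (!length(probes))
        return(list(
            table = data.frame(probe_id = character(),
                               mean_log_ratio = numeric(),
                               sd_log_ratio = numeric(), beta = numeric(),
                               se = numeric(), p = numeric(),
                               n_pairs = integer(),
                               direction = character()),
            lines = data.frame(probe_id = character(),
                               lead_time = numeric(), fitted = numeric())))
    manifest <- sampleInfo(x)
    m <- counts(x)
    ca <- manifest[manifest$role == "case", ]
    co <- manifest[manifest$role == "control", ]
    co <- co[match(ca$pair_id, co$pair_id), ]
    rows <- list(); lines <- list()
    for (pid in probes) {
        lr <- pairLogRatio(m[pid, ca$sample_id], m[pid, co$sample_id])
        ft <- trendFit(lr, ca$lead_time_years, max_lead = max_lead)
        rows[[pid]] <- data.frame(probe_id = pid,
            mean_log_ratio = ft$mean_log_ratio,
            sd_log_ratio = ft$sd_log_ratio, beta = ft$beta, se = ft$se,
            p = ft$p, n_pairs = ft$n_pairs,
            direction = if (ft$beta < 0) "negative" else "positive")
        a <- ft$mean_log_ratio - ft$beta *
            mean(ca$lead_time_years[ca$lead_time_years <= max_lead])
        lines[[pid]] <- data.frame(probe_id = pid, lead_time = line_grid,
                                   fitted = a + ft$beta * line_grid)
    }
    tab <- do.call(rbind, rows); rownames(tab) <- NULL
    list(table = tab, lines = do.call(rbind, lines))
}
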