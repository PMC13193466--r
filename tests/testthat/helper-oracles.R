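# Independent oracles and small fixture builders shared across tests.

# scale the default four-cohort pair counts to a total
scale_pairs <- function(n_total) {
    base <- c(PLCO = 290, SWHS_SMHS = 395, SCCS = 154, MEC = 468)
    round(base * n_total / sum(base))
}

# brute-force O(m^2) Benjamini-Hochberg step-up
bh_oracle <- function(p, m_total = length(p)) {
    ord <- order(p)
    ps <- p[ord]
    k <- length(p)
    adj <- numeric(k)
    for (i in seq_len(k)) {
        cand <- vapply(i:k, function(j) ps[j] * m_total / j, numeric(1))
        adj[i] <- min(1, min(cand))
    }
    out <- numeric(k)
    out[ord] <- adj
    out
}

# brute-force all-pairs Mann-Whitney AUC with ties counted 1/2
auc_oracle <- function(case_scores, control_scores) {
    s <- 0
    for (a in case_scores) for (b in control_scores)
        s <- s + (a > b) + 0.5 * (a == b)
    s / (length(case_scores) * length(control_scores))
}

# conditional log-likelihood of 1:1 pair differences
cond_loglik <- function(beta, dx) sum(stats::plogis(dx %*% beta, log.p = TRUE))

# grid search (iteratively refined) maximizer of the conditional
# likelihood; expands the window while the maximum sits on a boundary
clogit_grid_oracle <- function(dx, half = 8, levels = 6, width = 21) {
    p <- ncol(dx)
    centre <- rep(0, p)
    l <- 1
    while (l <= levels) {
        grids <- lapply(seq_len(p), function(j)
            seq(centre[j] - half, centre[j] + half, length.out = width))
        pts <- as.matrix(expand.grid(grids))
        ll <- apply(pts, 1, cond_loglik, dx = dx)
        best <- pts[which.max(ll), ]
        on_edge <- any(abs(abs(best - centre) - half) < 1e-12)
        centre <- best
        if (on_edge) { half <- half * 2; next }  # re-run this level wider
        half <- half * 4 / (width - 1)   # two grid spacings
        l <- l + 1
    }
    unname(centre)
}

# a small MiRCountSet built by hand (no simulation)
tiny_count_set <- function(values, classes = NULL, sample_ids = NULL) {
    m <- as.matrix(values)
    if (is.null(classes))
        classes <- rep("Endogenous", nrow(m))
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("probe%02d", seq_len(nrow(m)))
    if (!is.null(sample_ids)) colnames(m) <- sample_ids
    MiRCountSet(m, data.frame(probe_id = rownames(m),
                              probe_class = classes))
}

# panel with negatives/spikes/positives around an endogenous block, for
# exercising the normalization chain on hand-made numbers
norm_fixture <- function(endo, negatives = 0, spike_means = NULL) {
    n_s <- ncol(endo)
    spikes <- c("ath-miR159a", "cel-miR248", "osa-miR414")
    spk <- if (is.null(spike_means)) matrix(1000, 3, n_s) else
        matrix(rep(spike_means, each = 3), 3, n_s)
    neg <- matrix(negatives, 2, n_s)
    m <- rbind(endo, spk, neg)
    rownames(m) <- c(rownames(endo) %||%
                         sprintf("hsa-miR-t%02d", seq_len(nrow(endo))),
                     spikes, c("NEG_A", "NEG_B"))
    cls <- c(rep("Endogenous", nrow(endo)), rep("SpikeIn", 3),
             rep("Negative", 2))
    tiny_count_set(m, cls, colnames(endo) %||% paste0("s", seq_len(n_s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
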