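#' Background correction
#'
#' Subtracts, per sample, the arithmetic mean of the negative-control
#' probe counts from every endogenous and spike-in count, flooring at
#' zero. Negative probes are retained (for provenance) but their values
#' are no longer meaningful after this step.
#'
#' @param x a raw [MiRCountSet-class] with at least one Negative probe.
#' @param n_negatives use only the first `n_negatives` negative probes
#'   (default: all present).
#' @return the corrected `MiRCountSet`; stage tag `"background"` appended.
#' @export
setMethod("backgroundCorrect", "MiRCountSet",
          function(x, n_negatives = NULL) {
    cls <- probeClass(x)
    neg_ids <- names(cls)[cls == "Negative"]
    if (!length(neg_ids))
        stop("no Negative probes present", call. = FALSE)
    if (!is.null(n_negatives))
        neg_ids <- neg_ids[seq_len(min(n_negatives, length(neg_ids)))]
    x <- .append_stage(x, "background")
    m <- counts(x)
    bg <- colMeans(m[neg_ids, , drop = FALSE])
    target <- cls[rownames(m)] %in% c("Endogenous", "SpikeIn", "Positive")
    m[target, ] <- pmax(sweep(m[target, , drop = FALSE], 2, bg, "-"), 0)
    fac <- normFactors(x) %||% list()
    fac$background <- stats::setNames(bg, colnames(m))
    S4Vectors::metadata(x)$norm_factors <- fac
    .set_counts(x, m)
})

#' Spike-in normalization
#'
#' Per sample, computes the arithmetic mean `m_s` of the spike-in probe
#' counts and scales all counts by `f_s = ref / m_s`. The default
#' reference is the geometric mean of the `m_s` across samples
#' (`ref = "geomean"`); `ref = "nominal"` instead anchors to the known
#' spike-in input level (mean of [SPIKE_NOMINAL] over the probes used),
#' which makes each sample's normalized values exactly invariant to
#' rescaling of that sample alone.
#'
#' @param x a [MiRCountSet-class], typically background-corrected.
#' @param spike_ids spike probes to use (default the three normalization
#'   spikes: ath-miR159a, cel-miR248, osa-miR414).
#' @param ref `"geomean"` or `"nominal"`.
#' @return the scaled `MiRCountSet`; per-sample factors stored in
#'   `normFactors(x)$spikein`; stage tag `"spikein"` appended.
#' @export
setMethod("spikeinNormalize", "MiRCountSet",
          function(x, spike_ids = c("ath-miR159a", "cel-miR248",
                                    "osa-miR414"),
                   ref = c("geomean", "nominal")) {
    ref <- match.arg(ref)
    x <- .append_stage(x, "spikein")
    m <- counts(x)
    missing <- setdiff(spike_ids, rownames(m))
    if (length(missing))
        stop("spike-in probe(s) absent: ",
             paste(missing, collapse = ", "), call. = FALSE)
    ms <- colMeans(m[spike_ids, , drop = FALSE])
    if (any(ms <= 0))
        stop("zero spike-in mean in sample(s): ",
             paste(colnames(m)[ms <= 0], collapse = ", "), call. = FALSE)
    refval <- switch(ref,
        geomean = geomean(ms),
        nominal = mean(SPIKE_NOMINAL[spike_ids]))
    f <- refval / ms
    m <- sweep(m, 2, f, "*")
    fac <- normFactors(x) %||% list()
    fac$spikein <- stats::setNames(f, colnames(m))
    fac$spikein_ref <- ref
    S4Vectors::metadata(x)$norm_factors <- fac
    .set_counts(x, m)
})

#' Sample content normalization
#'
#' Scales each sample by the geometric mean of a shared content set: the
#' `set_size` endogenous probes with the highest mean count across all
#' samples, excluding the red-blood-cell hemolysis markers
#' ([HEMOLYSIS_PROBES]) so that hemolysed samples are not scaled by their
#' own contamination. Zeros are replaced by 0.5 inside the geometric mean
#' only. The cross-sample reference is the geometric mean of the
#' per-sample geometric means. If fewer than `set_size` eligible probes
#' exist, all of them are used with a warning.
#'
#' @param x a [MiRCountSet-class].
#' @param set_size content set size (default 50).
#' @param exclude probe ids excluded from the content set (default the
#'   hemolysis trio); set to `character()` to disable the exclusion.
#' @return the scaled `MiRCountSet`; factors and the content set stored in
#'   `normFactors(x)`; stage tag `"content"` appended.
#' @export
setMethod("contentNormalize", "MiRCountSet",
          function(x, set_size = 50, exclude = HEMOLYSIS_PROBES) {
    x <- .append_stage(x, "content")
    m <- counts(x)
    cls <- probeClass(x)
    endo <- names(cls)[cls == "Endogenous"]
    eligible <- setdiff(endo, exclude)
    if (length(eligible) < set_size) {
        warning("only ", length(eligible),
                " eligible endogenous probes; using all of them")
        set_size <- length(eligible)
    }
    means <- rowMeans(m[eligible, , drop = FALSE])
    content <- eligible[order(means, decreasing = TRUE)][seq_len(set_size)]
    sub <- m[content, , drop = FALSE]
    sub[sub == 0] <- 0.5
    g <- exp(colMeans(log(sub)))
    if (any(!is.finite(g) | g <= 0))
        stop("content geometric mean undefined in sample(s): ",
             paste(colnames(m)[!is.finite(g) | g <= 0], collapse = ", "),
             call. = FALSE)
    f <- geomean(g) / g
    m <- sweep(m, 2, f, "*")
    fac <- normFactors(x) %||% list()
    fac$content <- stats::setNames(f, colnames(m))
    fac$content_set <- content
    fac$content_excluded <- exclude
    S4Vectors::metadata(x)$norm_factors <- fac
    .set_counts(x, m)
})

#' Quantile normalization
#'
#' Classic rank-mean quantile normalization across the whole sample set,
#' applied to endogenous probes only: each sample's k-th order statistic
#' is replaced by the across-sample mean of k-th order statistics, ties
#' receiving the mean of the values they span (via
#' [limma::normalizeQuantiles]).
#'
#' @param x a [MiRCountSet-class] with at least 2 samples (a single
#'   sample is returned unchanged with a warning).
#' @return the normalized `MiRCountSet`; stage tag `"quantile"` appended.
#' @export
setMethod("quantileNormalize", "MiRCountSet", function(x) {
    x <- .append_stage(x, "quantile")
    if (ncol(x) < 2) {
        warning("quantile normalization needs >= 2 samples; no-op")
        return(x)
    }
    m <- counts(x)
    cls <- probeClass(x)
    endo <- names(cls)[cls == "Endogenous"]
    m[endo, ] <- limma::normalizeQuantiles(m[endo, , drop = FALSE],
                                           ties = TRUE)
    .set_counts(x, m)
})

#' Full normalization pipeline
#'
#' Applies, in this order: background correction, spike-in normalization,
#' content normalization, then (optionally) quantile normalization. The
#' order is fixed — swapping spike-in and content changes the output —
#' and the stage tag records the chain.
#'
#' @param x a raw [MiRCountSet-class].
#' @param config list of options: `negative_count`, `spike_ids`,
#'   `spike_ref`, `content_set_size`, `hemolysis_exclusions`,
#'   `enable_quantile` (default TRUE).
#' @return the normalized `MiRCountSet` with factor provenance in
#'   [normFactors()].
#' @examples
#' x <- generateCohort(cohortConfig(n_pairs = c(PLCO = 15), n_probes = 60,
#'                                  seed = 3))
#' xn <- normalizePipeline(x)
#' stageTag(xn)
#' @export
setMethod("normalizePipeline", "MiRCountSet",
          function(x, config = list()) {
    x <- backgroundCorrect(x, n_negatives = config$negative_count)
    x <- spikeinNormalize(x,
        spike_ids = config$spike_ids %||%
            c("ath-miR159a", "cel-miR248", "osa-miR414"),
        ref = config$spike_ref %||% "geomean")
    x <- contentNormalize(x,
        set_size = config$content_set_size %||% 50,
        exclude = config$hemolysis_exclusions %||% HEMOLYSIS_PROBES)
    if (config$enable_quantile %||% TRUE)
        x <- quantileNormalize(x)
    x
})
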