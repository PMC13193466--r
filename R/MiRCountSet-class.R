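#' @include AllGenerics.R
NULL

#' Container for digital miRNA count data with probe-class annotation
#'
#' `MiRCountSet` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one `counts` assay (probes x samples), probe annotation
#' (`probe_id`, `probe_class`, optional `accession`) in `rowData`, and the
#' sample manifest in `colData`. Raw counts are non-negative integers;
#' normalization steps replace the assay with non-negative reals and append
#' their name to an ordered, append-only stage tag kept in the metadata.
#'
#' Probe classes follow the digital-counting assay layout:
#' \describe{
#'   \item{Endogenous}{human miRNA probes, the analysis targets.}
#'   \item{Negative}{probes with no target; estimate non-specific binding.}
#'   \item{Positive}{synthetic hybridization controls in a titration ladder.}
#'   \item{SpikeIn}{non-mammalian oligos added to plasma at fixed amounts
#'     before extraction; calibrate extraction efficiency.}
#' }
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @aliases MiRCountSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("MiRCountSet", contains = "SummarizedExperiment")

.PROBE_CLASSES <- c("Endogenous", "Negative", "Positive", "SpikeIn")

#' Hemolysis marker miRNAs excluded from content normalization
#'
#' Red-blood-cell derived miRNAs whose plasma levels are inflated by
#' hemolysis; they are excluded from the top-expressed content set so that
#' a hemolysed sample does not drag its own scaling factor.
#'
#' @export
HEMOLYSIS_PROBES <- c("hsa-miR-320e", "hsa-miR-16-5p", "hsa-miR-451a")

setValidity("MiRCountSet", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("probe_id", "probe_class") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'probe_id' and 'probe_class'")
    else {
        if (anyDuplicated(rd$probe_id))
            msg <- c(msg, "duplicate probe_id in panel")
        bad <- setdiff(unique(as.character(rd$probe_class)), .PROBE_CLASSES)
        if (length(bad))
            msg <- c(msg, paste0("unknown probe_class: ",
                                 paste(bad, collapse = ", ")))
    }
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        a <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(a)) || any(a < 0))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MiRCountSet
#'
#' @param counts numeric matrix, probes x samples, non-negative.
#' @param probeInfo data.frame with columns `probe_id`, `probe_class`
#'   (one of Endogenous, Negative, Positive, SpikeIn) and optionally
#'   `accession`; one row per row of `counts`.
#' @param sampleInfo data.frame of per-sample annotation (the manifest);
#'   one row per column of `counts`. May be omitted.
#' @param stageTag character vector of normalization stages already applied
#'   (usually empty for raw data).
#' @param metadata additional metadata list entries.
#'
#' @return a [MiRCountSet-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), 5, 4,
#'             dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
#' pi <- data.frame(probe_id = rownames(m),
#'                  probe_class = c("Endogenous", "Endogenous", "Negative",
#'                                  "Positive", "SpikeIn"))
#' MiRCountSet(m, pi)
#' @export
MiRCountSet <- function(counts, probeInfo, sampleInfo = NULL,
                        stageTag = character(), metadata = list()) {
    counts <- as.matrix(counts)
    stopifnot(nrow(probeInfo) == nrow(counts))
    if (!"accession" %in% colnames(probeInfo))
        probeInfo$accession <- NA_character_
    rownames(counts) <- probeInfo$probe_id
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("S", seq_len(ncol(counts)))
    if (is.null(sampleInfo))
        sampleInfo <- data.frame(sample_id = colnames(counts))
    stopifnot(nrow(sampleInfo) == ncol(counts))
    rownames(sampleInfo) <- colnames(counts)
    md <- c(list(stage_tag = stageTag), metadata)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(probeInfo),
        colData = S4Vectors::DataFrame(sampleInfo),
        metadata = md)
    methods::new("MiRCountSet", se)
}

#' @describeIn MiRCountSet probe annotation as a data.frame.
#' @param x a `MiRCountSet`.
#' @export
setMethod("probeInfo", "MiRCountSet", function(x)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn MiRCountSet probe class vector, named by probe id.
#' @export
setMethod("probeClass", "MiRCountSet", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    stats::setNames(as.character(rd$probe_class), rd$probe_id)
})

#' @describeIn MiRCountSet sample manifest as a data.frame.
#' @export
setMethod("sampleInfo", "MiRCountSet", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn MiRCountSet ordered vector of normalization stages applied.
#' @export
setMethod("stageTag", "MiRCountSet", function(x)
    S4Vectors::metadata(x)$stage_tag)

#' @describeIn MiRCountSet normalization factor provenance (list), if any.
#' @export
setMethod("normFactors", "MiRCountSet", function(x)
    S4Vectors::metadata(x)$norm_factors)

#' @describeIn MiRCountSet simulation ground truth (list), if generated.
#' @export
setMethod("truthRecord", "MiRCountSet", function(x)
    S4Vectors::metadata(x)$truth)

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "MiRCountSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

setMethod("show", "MiRCountSet", function(object) {
    cls <- table(factor(as.character(
        SummarizedExperiment::rowData(object)$probe_class),
        levels = .PROBE_CLASSES))
    cat("MiRCountSet:", nrow(object), "probes x", ncol(object), "samples\n")
    cat("  probe classes:",
        paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
    st <- stageTag(object)
    cat("  stages applied:",
        if (length(st)) paste(st, collapse = " -> ") else "(raw)", "\n")
    si <- sampleInfo(object)
    if ("pair_id" %in% colnames(si))
        cat("  matched pairs:", length(unique(si$pair_id)), "\n")
})

.append_stage <- function(x, stage) {
    st <- stageTag(x)
    if (stage %in% st)
        stop("stage '", stage, "' has already been applied", call. = FALSE)
    S4Vectors::metadata(x)$stage_tag <- c(st, stage)
    x
}

.set_counts <- function(x, m) {
    if (any(m < 0)) stop("internal: negative values produced", call. = FALSE)
    SummarizedExperiment::assays(x, withDimnames = FALSE) <-
        S4Vectors::SimpleList(counts = m)
    x
}
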