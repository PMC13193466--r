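#' Read a probe-count matrix from CSV/TSV
#'
#' Expected layout: one row per probe, columns `probe_id`, `probe_class`
#' (Endogenous/Negative/Positive/SpikeIn), optional `accession`, then one
#' numeric column per sample id. `write` followed by `read` is the
#' identity on values and ordering.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv` -> tab, otherwise comma).
#' @param manifest optional manifest data.frame (or path) whose
#'   `sample_id` order must match the count columns; attached as colData.
#' @return a [MiRCountSet-class].
#' @export
readCountMatrix <- function(path, manifest = NULL) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("probe_id", "probe_class")
    if (!all(need %in% colnames(df)))
        stop("count file must have probe_id and probe_class columns",
             call. = FALSE)
    if (anyDuplicated(df$probe_id))
        stop("duplicate probe_id: ",
             df$probe_id[duplicated(df$probe_id)][1], call. = FALSE)
    bad <- setdiff(unique(df$probe_class), .PROBE_CLASSES)
    if (length(bad))
        stop("unknown probe_class '", bad[1], "'", call. = FALSE)
    meta_cols <- intersect(c("probe_id", "probe_class", "accession"),
                           colnames(df))
    samp_cols <- setdiff(colnames(df), meta_cols)
    m <- as.matrix(df[, samp_cols, drop = FALSE])
    if (!is.numeric(m)) {
        j <- which(!vapply(df[, samp_cols, drop = FALSE], is.numeric,
                           logical(1)))[1]
        stop("non-numeric counts in column '", samp_cols[j], "'",
             call. = FALSE)
    }
    rownames(m) <- df$probe_id
    if (is.character(manifest)) manifest <- readManifest(manifest)
    if (!is.null(manifest)) {
        if (!identical(manifest$sample_id, colnames(m)))
            manifest <- manifest[match(colnames(m), manifest$sample_id), ]
        if (any(is.na(manifest$sample_id)))
            stop("manifest does not cover all count columns", call. = FALSE)
    }
    MiRCountSet(m, df[, meta_cols, drop = FALSE], manifest)
}

#' Write a count matrix to CSV
#'
#' @param x a [MiRCountSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
    df <- cbind(probeInfo(x)[c("probe_id", "probe_class", "accession")],
                as.data.frame(counts(x), check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read / write a sample manifest CSV
#'
#' Columns: `sample_id`, `pair_id`, `cohort`, `role` (case/control),
#' `sex`, `race`, `age_at_draw`, `draw_date` (ISO-8601),
#' `lead_time_years`, `bmi`, `smoking` (never/former/current),
#' `diabetes` (0/1), `family_history` (0/1), `ca199`, optional `stage`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readManifest <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
    utils::write.csv(manifest, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read a minimal RCC (Reporter Code Count) file
#'
#' Parses the bracketed-section, comma-separated RCC dialect with
#' `<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>` and
#' `<Code_Summary>` sections. The Code_Summary section must have columns
#' CodeClass, Name, Accession, Count, with integer counts.
#'
#' @param path file path.
#' @return list with elements `header`, `sample_attributes`,
#'   `lane_attributes` (named character vectors) and `counts`
#'   (data.frame: probe_class, probe_id, accession, count).
#' @export
readRCC <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    sec <- rep(NA_character_, length(lines))
    cur <- NA_character_
    for (i in seq_along(lines)) {
        l <- trimws(lines[i])
        if (grepl("^<[^/].*>$", l)) { cur <- gsub("[<>]", "", l); next }
        if (grepl("^</.*>$", l)) { cur <- NA_character_; next }
        sec[i] <- cur
    }
    grab <- function(name) {
        ls <- trimws(lines[which(sec == name)])
        ls[nzchar(ls)]
    }
    kv <- function(ls) {
        parts <- strsplit(ls, ",")
        stats::setNames(vapply(parts, function(p)
            if (length(p) > 1) p[2] else "", character(1)),
            vapply(parts, `[`, character(1), 1))
    }
    cs <- grab("Code_Summary")
    if (length(cs) < 2)
        stop("RCC file lacks a populated Code_Summary section",
             call. = FALSE)
    hdr <- strsplit(cs[1], ",")[[1]]
    if (!all(c("CodeClass", "Name", "Count") %in% hdr))
        stop("Code_Summary must have CodeClass, Name, Count columns",
             call. = FALSE)
    rows <- strsplit(cs[-1], ",")
    get <- function(r, col) {
        i <- match(col, hdr)
        if (is.na(i) || length(r) < i) NA_character_ else r[i]
    }
    cnt_chr <- vapply(rows, get, character(1), "Count")
    if (any(!grepl("^[0-9]+$", cnt_chr)))
        stop("Code_Summary counts must be integers (got '",
             cnt_chr[!grepl("^[0-9]+$", cnt_chr)][1], "')", call. = FALSE)
    data_cls <- vapply(rows, get, character(1), "CodeClass")
    bad <- setdiff(unique(data_cls), .PROBE_CLASSES)
    if (length(bad))
        stop("unknown CodeClass '", bad[1], "' in RCC", call. = FALSE)
    list(header = kv(grab("Header")),
         sample_attributes = kv(grab("Sample_Attributes")),
         lane_attributes = kv(grab("Lane_Attributes")),
         counts = data.frame(
             probe_class = data_cls,
             probe_id = vapply(rows, get, character(1), "Name"),
             accession = vapply(rows, get, character(1), "Accession"),
             count = as.integer(cnt_chr),
             stringsAsFactors = FALSE))
}

#' Validate the 1:1 matched pairing of a manifest
#'
#' Checks that every `pair_id` has exactly one case and one control, and
#' that matching constraints hold within each pair: identical cohort, sex
#' and race, age at draw within 2 years, draw date within 90 days.
#'
#' @param manifest data.frame (see [readManifest()]).
#' @param strict if `TRUE` (default) any violation is an error; otherwise
#'   violations are attached as a warning and returned.
#' @param age_tol,date_tol matching tolerances (years / days).
#' @return the manifest, invisibly augmented with attribute
#'   `"violations"`: a data.frame (pair_id, criterion) of failed checks.
#' @export
validatePairs <- function(manifest, strict = TRUE, age_tol = 2,
                          date_tol = 90) {
    v <- list()
    note <- function(pair, crit)
        v[[length(v) + 1]] <<- data.frame(pair_id = pair, criterion = crit)
    tab <- split(seq_len(nrow(manifest)), manifest$pair_id)
    for (pid in names(tab)) {
        rows <- manifest[tab[[pid]], ]
        if (nrow(rows) != 2 || !setequal(rows$role, c("case", "control"))) {
            note(pid, "roles")
            next
        }
        ca <- rows[rows$role == "case", ]
        co <- rows[rows$role == "control", ]
        if (!identical(ca$cohort, co$cohort)) note(pid, "cohort")
        if (!identical(ca$sex, co$sex)) note(pid, "sex")
        if (!identical(ca$race, co$race)) note(pid, "race")
        if (abs(ca$age_at_draw - co$age_at_draw) > age_tol) note(pid, "age")
        dd <- abs(as.numeric(as.Date(ca$draw_date) - as.Date(co$draw_date)))
        if (is.na(dd) || dd > date_tol) note(pid, "draw_date")
    }
    viol <- if (length(v)) do.call(rbind, v) else
        data.frame(pair_id = character(), criterion = character())
    if (nrow(viol) && strict)
        stop("pair validation failed for ",
             length(unique(viol$pair_id)), " pair(s); first: ",
             viol$pair_id[1], " [", viol$criterion[1], "]", call. = FALSE)
    if (nrow(viol)) warning(nrow(viol), " matching violation(s) found")
    attr(manifest, "violations") <- viol
    invisible(manifest)
}

#' Default sample QC thresholds
#'
#' The assay vendor's conventions: field-of-view ratio at least 0.75 and
#' binding density within \[0.1, 2.25\]. Binding density is not derivable
#' from a count matrix alone, so a proxy (total counts / `bd_scale`) is
#' used; FOV is only checked when a `fov_ratio` column is present in the
#' sample annotation. Positive-control linearity is the R-squared of log
#' counts against the log titration ladder; the limit-of-detection check
#' requires the second-lowest positive control to exceed the negative
#' mean plus two SD.
#'
#' @param fov_min,bd_range,bd_scale,pos_r2_min,lod_enabled thresholds;
#'   set an entry to `NULL` (or `lod_enabled = FALSE`) to disable it.
#' @return list of thresholds.
#' @export
qcThresholds <- function(fov_min = 0.75, bd_range = c(0.1, 2.25),
                         bd_scale = 160000, pos_r2_min = 0.9,
                         lod_enabled = TRUE) {
    list(fov_min = fov_min, bd_range = bd_range, bd_scale = bd_scale,
         pos_r2_min = pos_r2_min, lod_enabled = lod_enabled)
}

#' Per-sample quality-control report
#'
#' @param x a [MiRCountSet-class] with raw counts (positive and negative
#'   control probes present).
#' @param thresholds from [qcThresholds()].
#' @return data.frame, one row per sample: flags `fov`, `binding_density`,
#'   `pos_linearity`, `lod` (TRUE = pass, NA = not evaluated) and overall
#'   `pass` (fails iff at least one enabled flag fails).
#' @export
qcSample <- function(x, thresholds = qcThresholds()) {
    cls <- probeClass(x)
    if (!any(cls == "Positive") || !any(cls == "Negative"))
        stop("QC requires Positive and Negative control probes",
             call. = FALSE)
    m <- counts(x)
    pos <- m[names(cls)[cls == "Positive"], , drop = FALSE]
    neg <- m[names(cls)[cls == "Negative"], , drop = FALSE]
    si <- sampleInfo(x)
    n <- ncol(m)

    fov <- rep(NA, n)
    if (!is.null(thresholds$fov_min) && "fov_ratio" %in% colnames(si))
        fov <- si$fov_ratio >= thresholds$fov_min

    bd <- rep(NA, n)
    bd_val <- colSums(m) / (thresholds$bd_scale %||% 160000)
    if (!is.null(thresholds$bd_range))
        bd <- bd_val >= thresholds$bd_range[1] &
              bd_val <= thresholds$bd_range[2]

    plin <- rep(NA, n)
    if (!is.null(thresholds$pos_r2_min) && nrow(pos) >= 3) {
        ladder <- log(POS_NOMINAL[rownames(pos)])
        if (any(is.na(ladder)))
            ladder <- log(sort(2^(seq_len(nrow(pos)) * 2), decreasing = TRUE))
        plin <- apply(pos, 2, function(v) {
            lv <- log(pmax(v, 0.5))
            stats::cor(lv, ladder)^2
        }) >= thresholds$pos_r2_min
    }

    lod <- rep(NA, n)
    if (isTRUE(thresholds$lod_enabled) && nrow(pos) >= 2) {
        ord <- order(rowMeans(pos))
        pos2 <- pos[ord[2], ]
        lod <- pos2 > colMeans(neg) + 2 * apply(neg, 2, stats::sd)
    }

    flags <- cbind(fov = fov, binding_density = bd, pos_linearity = plin,
                   lod = lod)
    pass <- apply(flags, 1, function(f) !any(f %in% FALSE))
    data.frame(sample_id = colnames(m), fov = fov, binding_density = bd,
               binding_density_value = bd_val, pos_linearity = plin,
               lod = lod, pass = pass, row.names = NULL)
}

#' Drop QC-failed samples together with their matched pair
#'
#' The matched design cannot use singletons, so removal is atomic at the
#' pair level: if either member fails QC the whole pair is excluded.
#'
#' @param x a [MiRCountSet-class] with `pair_id` in the manifest.
#' @param qc report from [qcSample()].
#' @return the filtered `MiRCountSet`.
#' @export
dropFailedPairs <- function(x, qc) {
    si <- sampleInfo(x)
    bad_pairs <- unique(si$pair_id[match(qc$sample_id[!qc$pass],
                                         si$sample_id)])
    keep <- !(si$pair_id %in% bad_pairs)
    x[, keep]
}
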