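#' Assign per-gene CNV scores from segment tables
#'
#' Each (gene, sample) cell receives the log2 ratio of the CNV segment
#' with the maximal base-pair overlap with the gene's interval in that
#' sample. Genes overlapping no segment in a sample default to 0
#' (copy-neutral). Overlap ties are broken by larger |log2 ratio|, then
#' by leftmost segment start, so the assignment is deterministic.
#'
#' @param segments [GenomicRanges::GRanges] with `sample_id` and
#'   `log2_ratio` metadata columns (e.g. from [readSeg()]).
#' @param genes [GenomicRanges::GRanges] of gene intervals with a
#'   `gene_id` column (e.g. from [readBed()]).
#' @param samples optional sample universe for the output columns
#'   (default: samples present in `segments`).
#' @return A gene x sample numeric matrix of log2 ratios.
#' @export
assignGeneCnv <- function(segments, genes, samples = NULL) {
    if (!all(c("sample_id", "log2_ratio") %in% colnames(mcols(segments))))
        stop("segments need 'sample_id' and 'log2_ratio' metadata columns")
    if (!"gene_id" %in% colnames(mcols(genes)))
        stop("genes need a 'gene_id' metadata column")
    lr <- mcols(segments)$log2_ratio
    if (any(!is.finite(lr)))
        stop("non-finite log2 ratios in segments: rows ",
             paste(head(which(!is.finite(lr)), 10), collapse = ", "))
    if (is.null(samples))
        samples <- unique(as.character(mcols(segments)$sample_id))
    out <- matrix(0, length(genes), length(samples),
                  dimnames = list(mcols(genes)$gene_id, samples))
    if (!length(segments) || !length(genes)) return(out)
    ## disjoint chromosome sets between genes and segments are a valid
    ## no-overlap case, not worth a seqlevel warning
    hits <- suppressWarnings(findOverlaps(genes, segments))
    if (!length(hits)) return(out)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- width(pintersect(genes[q], segments[s]))
    samp <- as.character(mcols(segments)$sample_id[s])
    sampIdx <- match(samp, samples)
    keepSamp <- !is.na(sampIdx)
    df <- data.frame(g = q[keepSamp], sj = sampIdx[keepSamp],
                     ov = ov[keepSamp], lr = lr[s][keepSamp],
                     st = start(segments)[s][keepSamp])
    ord <- order(df$g, df$sj, -df$ov, -abs(df$lr), df$st)
    df <- df[ord, ]
    first <- !duplicated(df[, c("g", "sj")])
    df <- df[first, ]
    out[cbind(df$g, df$sj)] <- df$lr
    out
}

#' Binarize a gene-level CNV matrix into amplification/deletion events
#'
#' Applies the standard symmetric threshold on the log2 ratio scale:
#' amplification present when value >= `threshold`, deletion present
#' when value <= -`threshold` (boundaries inclusive; a log2 ratio of 0.5
#' roughly corresponds to at least one copy gained, -0.5 to one copy
#' lost in a diploid background).
#'
#' @param cnv gene x sample numeric matrix of log2 ratios (from
#'   [assignGeneCnv()]).
#' @param threshold positive log2 cutoff (default 0.5).
#' @return An [EventMatrix-class] stacking one amplification and one
#'   deletion row per gene. Use [filterEvents()] to drop rare/ubiquitous
#'   events.
#' @export
binarizeCnv <- function(cnv, threshold = 0.5) {
    cnv <- as.matrix(cnv)
    if (!is.numeric(threshold) || threshold <= 0)
        stop("'threshold' must be > 0")
    bad <- which(!is.finite(cnv))
    if (length(bad)) {
        ij <- arrayInd(head(bad, 10), dim(cnv))
        stop("non-finite CNV values at: ",
             paste(sprintf("(%s,%s)", rownames(cnv)[ij[, 1]],
                           colnames(cnv)[ij[, 2]]), collapse = ", "))
    }
    amp <- (cnv >= threshold) * 1
    del <- (cnv <= -threshold) * 1
    EventMatrix(rbind(amp, del), rep(rownames(cnv), 2),
                rep(c("amplification", "deletion"), each = nrow(cnv)),
                colnames(cnv))
}

## MAF variant classifications with no protein-sequence consequence
.silentClasses <- c("Silent", "3'UTR", "5'UTR", "Intron", "IGR",
                    "3'Flank", "5'Flank", "RNA")

#' Build a binary mutation matrix from a MAF-like table
#'
#' Drops mutations that do not change the protein product (Silent, UTR,
#' intronic, flanking, IGR, RNA classifications), optionally removes
#' blacklisted genes (e.g. the long genes flagged as recurrent false
#' positives), and collapses the remainder to binary gene x sample
#' presence (multiple qualifying mutations in one gene/sample count
#' once).
#'
#' @param maf data frame with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode` and `Variant_Classification` (see
#'   [readMaf()]).
#' @param blacklist optional character vector of genes to remove.
#' @param samples optional sample universe for the output columns
#'   (default: all barcodes in `maf`, including samples left with no
#'   qualifying mutation).
#' @return A mutation-class [EventMatrix-class].
#' @export
filterSilentMutations <- function(maf, blacklist = NULL, samples = NULL) {
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
              "Variant_Classification")
    miss <- setdiff(need, colnames(maf))
    if (length(miss))
        stop("MAF table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (is.null(samples))
        samples <- unique(as.character(maf$Tumor_Sample_Barcode))
    keep <- !(maf$Variant_Classification %in% .silentClasses)
    if (!is.null(blacklist))
        keep <- keep & !(maf$Hugo_Symbol %in% blacklist)
    kept <- maf[keep, , drop = FALSE]
    genes <- sort(unique(as.character(kept$Hugo_Symbol)))
    v <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    if (nrow(kept)) {
        gi <- match(as.character(kept$Hugo_Symbol), genes)
        si <- match(as.character(kept$Tumor_Sample_Barcode), samples)
        ok <- !is.na(si)
        v[cbind(gi[ok], si[ok])] <- 1
    }
    EventMatrix(v, genes, "mutation", samples)
}

#' Filter events by carrier frequency
#'
#' Keeps an event if and only if its carrier fraction lies in
#' \[`minFrac`, `maxFrac`\] (boundaries inclusive) and its carrier count
#' is at least `minCount`. Events too rare cannot be learned; events
#' near fixation leave too few negative samples.
#'
#' @param events an [EventMatrix-class].
#' @param minFrac,maxFrac carrier-fraction bounds (defaults 0.05 and
#'   0.95).
#' @param minCount minimum carrier count (default 10).
#' @return The filtered [EventMatrix-class]. Re-filtering a filtered
#'   matrix changes nothing.
#' @export
filterEvents <- function(events, minFrac = 0.05, maxFrac = 0.95,
                         minCount = 10L) {
    if (minFrac >= maxFrac)
        stop("'minFrac' must be smaller than 'maxFrac'")
    if (!nrow(events)) stop("empty EventMatrix")
    fr <- carrierFractions(events)
    cc <- carrierCounts(events)
    keep <- fr >= minFrac & fr <= maxFrac & cc >= minCount
    events[keep, ]
}

#' Flag hypermodified samples
#'
#' A sample is flagged when strictly more than `frac` of the genes in
#' the genome carry an alteration (any class) in that sample. Flagged
#' samples are reported, not removed.
#'
#' @param events an [EventMatrix-class].
#' @param genomeSize number of genes in the genome (>= the number of
#'   distinct genes in `events`).
#' @param frac flagging fraction (default 0.005, i.e. 0.5%).
#' @return A named logical vector over samples.
#' @export
flagHypermodified <- function(events, genomeSize, frac = 0.005) {
    if (!is.numeric(genomeSize) || genomeSize <= 0)
        stop("'genomeSize' must be positive")
    nDistinct <- length(unique(rowData(events)$gene_id))
    if (genomeSize < nDistinct)
        stop("'genomeSize' smaller than the number of distinct genes (",
             nDistinct, ") in the events")
    v <- eventValues(events)
    g <- rowData(events)$gene_id
    altered <- vapply(seq_len(ncol(v)), function(j)
        length(unique(g[v[, j] > 0])), integer(1))
    setNames(altered / genomeSize > frac, colnames(v))
}
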