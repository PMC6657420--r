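#' @import methods
#' @importFrom stats median rnorm rbeta rbinom rnbinom rlnorm sd var
#'   quantile wilcox.test cor dist as.dist hclust cutree predict glm
#'   binomial setNames
#' @importFrom utils read.delim write.table head
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps pintersect seqnames
#'   start end width
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData rowData<- colData<-
NULL

#' Expression matrix with a units tag
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one gene x sample assay plus a tag recording whether the values are raw
#' counts, normalized expression, or covariate-regression residuals. The
#' tag lets downstream operations refuse inputs on the wrong scale (for
#' example, Gaussian noise is added on the normalized scale only, and
#' read down-sampling applies to raw counts only).
#'
#' @slot units character scalar, one of `"counts"`, `"normalized"`,
#'   `"residuals"`.
#' @export
setClass("ExprMatrix",
         contains = "SummarizedExperiment",
         representation(units = "character"))

setValidity("ExprMatrix", function(object) {
    msgs <- character()
    if (length(object@units) != 1L ||
        !object@units %in% c("counts", "normalized", "residuals"))
        msgs <- c(msgs, "units must be one of counts/normalized/residuals")
    if (length(SummarizedExperiment::assays(object)) < 1L)
        msgs <- c(msgs, "an assay is required")
    m <- assay(object)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msgs <- c(msgs, "gene and sample identifiers are required")
    else {
        if (anyDuplicated(rownames(m)))
            msgs <- c(msgs, paste0("duplicate gene identifiers: ",
                paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
        if (anyDuplicated(colnames(m)))
            msgs <- c(msgs, "duplicate sample identifiers")
    }
    if (identical(object@units, "counts") &&
        any(m < 0, na.rm = TRUE))
        msgs <- c(msgs, "raw counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct an ExprMatrix
#'
#' @param mat numeric gene x sample matrix with row and column names.
#' @param units `"counts"`, `"normalized"` or `"residuals"`.
#' @param colData optional [S4Vectors::DataFrame] of per-sample annotation.
#' @return An [ExprMatrix-class] object.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ExprMatrix(m, "counts")
#' @export
ExprMatrix <- function(mat, units = c("counts", "normalized", "residuals"),
                       colData = NULL) {
    units <- match.arg(units)
    mat <- as.matrix(mat)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(mat))
    se <- SummarizedExperiment(assays = list(exprs = mat), colData = colData)
    new("ExprMatrix", se, units = units)
}

#' Extract the expression values of an ExprMatrix
#' @param x an [ExprMatrix-class].
#' @return The underlying numeric matrix.
#' @export
exprValues <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
}

#' Units tag of an ExprMatrix
#' @param x an [ExprMatrix-class].
#' @return `"counts"`, `"normalized"` or `"residuals"` (or `NA` for a bare
#'   matrix).
#' @export
exprUnits <- function(x) {
    if (is(x, "ExprMatrix")) x@units else NA_character_
}

setMethod("show", "ExprMatrix", function(object) {
    cat(sprintf("ExprMatrix: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), object@units))
    callNextMethod()
})

## internal: rebuild an object like `x` around a new matrix
.likeExpr <- function(x, mat, units = exprUnits(x)) {
    if (is(x, "ExprMatrix")) {
        ExprMatrix(mat, units = units, colData = colData(x)[colnames(mat), ,
                                                            drop = FALSE])
    } else mat
}

#' Binary gene-event by sample matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose single
#' assay is a 0/1 matrix of alteration events (rows are
#' `"<gene>:<class>"` with class one of mutation, amplification,
#' deletion) by samples. `rowData` carries the gene, the event class and
#' the carrier count/fraction, kept consistent with the assay by the
#' validity method.
#'
#' @export
setClass("EventMatrix", contains = "SummarizedExperiment")

setValidity("EventMatrix", function(object) {
    msgs <- character()
    v <- assay(object)
    if (!all(v %in% c(0, 1)))
        msgs <- c(msgs, "event values must be 0 or 1")
    rd <- rowData(object)
    need <- c("gene_id", "event_class", "carrier_count", "carrier_frac")
    if (!all(need %in% colnames(rd)))
        msgs <- c(msgs, paste("rowData must contain",
                              paste(need, collapse = ", ")))
    else {
        if (!all(rd$event_class %in%
                 c("mutation", "amplification", "deletion")))
            msgs <- c(msgs, "unknown event class")
        if (nrow(v) && !isTRUE(all.equal(unname(rowSums(v)),
                                         unname(as.numeric(rd$carrier_count)))))
            msgs <- c(msgs, "carrier_count inconsistent with assay row sums")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct an EventMatrix
#'
#' @param values binary gene x sample matrix (one row per event).
#' @param geneIds character vector of gene identifiers, one per row of
#'   `values`.
#' @param eventClass `"mutation"`, `"amplification"` or `"deletion"`;
#'   scalar or one per row.
#' @param samples optional sample identifiers (default `colnames(values)`).
#' @return An [EventMatrix-class]; row names are `"<gene>:<class>"`.
#' @export
EventMatrix <- function(values, geneIds, eventClass, samples = NULL) {
    values <- as.matrix(values)
    if (is.null(samples)) samples <- colnames(values)
    if (is.null(samples))
        stop("sample identifiers are required")
    storage.mode(values) <- "double"
    eventClass <- rep_len(eventClass, nrow(values))
    geneIds <- as.character(geneIds)
    stopifnot(length(geneIds) == nrow(values))
    ids <- if (nrow(values)) paste0(geneIds, ":", eventClass)
           else character(0)
    if (anyDuplicated(ids))
        stop("duplicate events: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    dimnames(values) <- list(ids, samples)
    n <- ncol(values)
    cc <- rowSums(values)
    rd <- DataFrame(gene_id = geneIds, event_class = eventClass,
                    carrier_count = as.integer(cc),
                    carrier_frac = if (n) cc / n else numeric(nrow(values)),
                    row.names = ids)
    se <- SummarizedExperiment(assays = list(events = values), rowData = rd)
    new("EventMatrix", se)
}

#' @describeIn EventMatrix event identifiers (`"<gene>:<class>"`).
#' @param x an EventMatrix.
#' @export
eventIds <- function(x) rownames(x)

#' @describeIn EventMatrix event class per row.
#' @export
eventClasses <- function(x) rowData(x)$event_class

#' @describeIn EventMatrix number of carrier samples per event.
#' @export
carrierCounts <- function(x) setNames(rowData(x)$carrier_count, rownames(x))

#' @describeIn EventMatrix carrier fraction per event.
#' @export
carrierFractions <- function(x) setNames(rowData(x)$carrier_frac, rownames(x))

#' @describeIn EventMatrix the binary values matrix.
#' @export
eventValues <- function(x) assay(x)

setMethod("show", "EventMatrix", function(object) {
    cls <- table(factor(eventClasses(object),
                        c("mutation", "amplification", "deletion")))
    cat(sprintf(
        "EventMatrix: %d events (%d mutation, %d amplification, %d deletion) x %d samples\n",
        nrow(object), cls[1], cls[2], cls[3], ncol(object)))
})

#' A transcription factor regulon
#'
#' A transcription factor together with its signed target set. The mode
#' is +1 for targets whose expression moves with TF activity and -1 for
#' repressed targets. Regulons require at least 10 targets (the TF
#' itself excluded) so that activity scores average over a meaningful
#' set.
#'
#' @slot tf TF gene identifier.
#' @slot targets character vector of target gene identifiers.
#' @slot modes numeric vector of +1/-1, parallel to `targets`.
#' @export
setClass("Regulon",
         representation(tf = "character", targets = "character",
                        modes = "numeric"))

setValidity("Regulon", function(object) {
    msgs <- character()
    if (length(object@tf) != 1L) msgs <- c(msgs, "tf must be a scalar")
    if (length(object@targets) != length(object@modes))
        msgs <- c(msgs, "targets and modes must be parallel")
    if (!all(object@modes %in% c(-1, 1)))
        msgs <- c(msgs, "modes must be +1 or -1")
    tg <- setdiff(object@targets, object@tf)
    if (length(tg) < 10L)
        msgs <- c(msgs, "a regulon needs at least 10 targets excluding the TF")
    if (anyDuplicated(object@targets))
        msgs <- c(msgs, "duplicate targets")
    if (length(msgs)) msgs else TRUE
})

#' Construct a Regulon
#' @param tf TF gene identifier.
#' @param targets character vector of target genes (at least 10, TF
#'   excluded).
#' @param modes +1/-1 per target; scalar recycled.
#' @return A [Regulon-class] object.
#' @export
Regulon <- function(tf, targets, modes = 1) {
    new("Regulon", tf = as.character(tf), targets = as.character(targets),
        modes = rep_len(as.numeric(modes), length(targets)))
}

#' @describeIn Regulon the TF identifier.
#' @param x a Regulon.
#' @export
regulonTf <- function(x) x@tf

#' @describeIn Regulon the target gene identifiers.
#' @export
regulonTargets <- function(x) x@targets

#' @describeIn Regulon the +1/-1 target modes, named by target.
#' @export
regulonModes <- function(x) setNames(x@modes, x@targets)

setMethod("show", "Regulon", function(object) {
    cat(sprintf("Regulon %s: %d targets (%d activated, %d repressed)\n",
                object@tf, length(object@targets),
                sum(object@modes > 0), sum(object@modes < 0)))
})

#' A simulated cohort with planted alterations
#'
#' Container returned by [simulateCohort()]: raw counts, the ground-truth
#' event matrix, the regulons and co-expression clusters used to plant
#' signal, CNV segments for copy-number events, the synthetic gene
#' models, and the generating configuration.
#'
#' @slot counts an [ExprMatrix-class] of raw counts.
#' @slot truthEvents an [EventMatrix-class] of planted events.
#' @slot regulons list of [Regulon-class].
#' @slot clusters named list of character vectors (ground-truth
#'   co-expression groups).
#' @slot segments [GenomicRanges::GRanges] of CNV segments with
#'   `sample_id` and `log2_ratio` metadata columns.
#' @slot geneModels [GenomicRanges::GRanges] of gene intervals with a
#'   `gene_id` column.
#' @slot config the generating configuration list.
#' @export
setClass("SimulatedCohort",
         representation(counts = "ExprMatrix", truthEvents = "EventMatrix",
                        regulons = "list", clusters = "list",
                        segments = "GRanges", geneModels = "GRanges",
                        config = "list"))

setValidity("SimulatedCohort", function(object) {
    msgs <- character()
    if (!identical(colnames(object@counts), colnames(object@truthEvents)))
        msgs <- c(msgs, "truth event samples must match count samples")
    genes <- rownames(object@counts)
    for (r in object@regulons)
        if (!all(regulonTargets(r) %in% genes)) {
            msgs <- c(msgs, "regulon targets outside the gene universe")
            break
        }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn SimulatedCohort raw count ExprMatrix.
#' @param x a SimulatedCohort.
#' @export
cohortCounts <- function(x) x@counts

#' @describeIn SimulatedCohort ground-truth EventMatrix.
#' @export
truthEvents <- function(x) x@truthEvents

#' @describeIn SimulatedCohort list of planted regulons.
#' @export
cohortRegulons <- function(x) x@regulons

#' @describeIn SimulatedCohort ground-truth co-expression clusters.
#' @export
cohortClusters <- function(x) x@clusters

#' @describeIn SimulatedCohort CNV segments (GRanges).
#' @export
cohortSegments <- function(x) x@segments

#' @describeIn SimulatedCohort synthetic gene models (GRanges).
#' @export
geneModels <- function(x) x@geneModels

setMethod("show", "SimulatedCohort", function(object) {
    cat(sprintf(
        "SimulatedCohort: %d genes x %d samples, %d events, %d regulons\n",
        nrow(object@counts), ncol(object@counts),
        nrow(object@truthEvents), length(object@regulons)))
})
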