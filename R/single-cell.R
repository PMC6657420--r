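#' Build per-mutation binary contrasts from guide assignments
#'
#' CROP-Seq-style design: cells carrying guides against the same gene
#' are pooled into one positive class per targeted gene, with wild-type
#' (control-guide) cells as the shared negative class. Cells carrying
#' guides for other genes are excluded from that contrast.
#'
#' @param cells an [ExprMatrix-class] of cells (only the column names
#'   are used here).
#' @param guideAssignments data frame with columns `cell_id` and
#'   `target` (the targeted gene, or the control label).
#' @param controlLabel the value of `target` marking control cells
#'   (default `"CTRL"`).
#' @return A named list, one element per targeted gene:
#'   `list(eventId, cellIds, labels)` with labels 1 for targeted cells
#'   and 0 for controls.
#' @export
buildMutationContrasts <- function(cells, guideAssignments,
                                   controlLabel = "CTRL") {
    need <- c("cell_id", "target")
    miss <- setdiff(need, colnames(guideAssignments))
    if (length(miss))
        stop("guide table missing column(s): ",
             paste(miss, collapse = ", "))
    ga <- guideAssignments
    ga <- ga[ga$cell_id %in% colnames(cells), , drop = FALSE]
    ctrl <- as.character(ga$cell_id[ga$target == controlLabel])
    if (!length(ctrl)) stop("no control cells")
    targets <- setdiff(unique(as.character(ga$target)), controlLabel)
    if (!length(targets)) stop("no targeted genes")
    out <- lapply(targets, function(g) {
        pos <- as.character(ga$cell_id[ga$target == g])
        list(eventId = paste0(g, ":mutation"),
             cellIds = c(pos, ctrl),
             labels = c(rep(1L, length(pos)), rep(0L, length(ctrl))))
    })
    names(out) <- targets
    out
}

#' Benchmark expression vs regulon-activity features on single cells
#'
#' For every per-mutation contrast, runs [repeatedEvaluation()] twice —
#' once on gene-expression features and once on regulon-activity
#' features ([regulonActivity()]) — with identical split seeds, so the
#' two feature modes are compared on exactly the same train/test cell
#' partitions. Per-event AUROC distributions are summarized and the two
#' modes are compared with a pooled paired Wilcoxon test over all
#' (event, repetition) pairs.
#'
#' @param cells normalized (and typically covariate-regressed)
#'   [ExprMatrix-class] of cells.
#' @param guideAssignments see [buildMutationContrasts()].
#' @param regulons list of [Regulon-class] objects.
#' @param spec a [modelSpec()].
#' @param reps repetitions per contrast and mode (default 100).
#' @param minCells minimum cells per class for a contrast to be run
#'   (default 10; smaller contrasts are skipped with a warning).
#' @param controlLabel control value in the guide table.
#' @return `list(table, pooled)`: `table` has one row per (event, mode)
#'   with mean/SD AUROC and n; `pooled` is the [pairedWilcoxon()]
#'   result of activity vs expression AUROCs over all pairs
#'   (direction > 0 means activity wins).
#' @export
runCropSeqBenchmark <- function(cells, guideAssignments, regulons,
                                spec = modelSpec(), reps = 100L,
                                minCells = 10L, controlLabel = "CTRL") {
    m <- .asNormalizedMatrix(cells, "runCropSeqBenchmark")
    sig <- buildSignature(cells)
    act <- regulonActivity(sig, regulons)
    contrasts <- buildMutationContrasts(cells, guideAssignments,
                                        controlLabel)
    rows <- list()
    allExpr <- numeric(0)
    allAct <- numeric(0)
    for (ct in contrasts) {
        n1 <- sum(ct$labels == 1)
        n0 <- sum(ct$labels == 0)
        if (min(n1, n0) < minCells) {
            warning("contrast ", ct$eventId, " skipped: ", min(n1, n0),
                    " cells in the smaller class (< ", minCells, ")")
            next
        }
        fx <- m[, ct$cellIds, drop = FALSE]
        fa <- act[, ct$cellIds, drop = FALSE]
        re <- repeatedEvaluation(fx, ct$labels, spec, reps = reps,
                                 eventId = ct$eventId)
        ra <- repeatedEvaluation(fa, ct$labels, spec, reps = reps,
                                 eventId = ct$eventId)
        rows[[length(rows) + 1L]] <- data.frame(
            event = ct$eventId,
            mode = c("expression", "activity"),
            mean_auroc = c(re$mean, ra$mean),
            sd_auroc = c(re$sd, ra$sd),
            n = c(re$n, ra$n))
        pair <- is.finite(re$aurocs) & is.finite(ra$aurocs)
        allExpr <- c(allExpr, re$aurocs[pair])
        allAct <- c(allAct, ra$aurocs[pair])
    }
    if (!length(rows))
        stop("no contrast had enough cells to run")
    list(table = do.call(rbind, rows),
         pooled = pairedWilcoxon(allAct, allExpr))
}
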