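#' Normalize bulk raw counts
#'
#' Variance-stabilizing normalization for bulk counts: each sample's
#' library is scaled to the median library size of the dataset and the
#' scaled counts are log2(x + pseudocount) transformed. The transform is
#' monotone in the input counts within each sample, and two samples that
#' differ only by a scale factor receive identical normalized profiles
#' (as long as the median library size is unaffected).
#'
#' @param counts raw-count [ExprMatrix-class] (or plain matrix).
#' @param pseudocount added before the log (default 1), so a zero count
#'   maps to `log2(pseudocount)` exactly.
#' @return A matrix of the same class tagged `"normalized"`.
#' @export
normalizeCounts <- function(counts, pseudocount = 1) {
    m <- .asCountsMatrix(counts, "normalizeCounts")
    lib <- colSums(m)
    if (any(lib == 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    med <- median(lib)
    scaled <- sweep(m, 2, med / lib, "*")
    out <- log2(scaled + pseudocount)
    .likeExpr(counts, out, units = "normalized")
}

#' Log-normalize single-cell counts
#'
#' The global-scaling normalization standard for single-cell data: each
#' count is divided by its cell's total, multiplied by `scale`, and
#' log-transformed, i.e. value = ln(1 + scale * count / cell_total). A
#' zero count maps to 0 exactly and the result is invariant to scaling
#' all counts of a cell by a constant.
#'
#' @param counts raw-count [ExprMatrix-class] (or plain matrix) of
#'   cells.
#' @param scale scale factor (default 10000).
#' @return A matrix of the same class tagged `"normalized"`. Cells with
#'   zero total counts are dropped with a warning reporting how many.
#' @export
normalizeSingleCell <- function(counts, scale = 10000) {
    m <- .asCountsMatrix(counts, "normalizeSingleCell")
    totals <- colSums(m)
    if (any(totals == 0)) {
        warning(sum(totals == 0), " empty cell(s) dropped")
        m <- m[, totals > 0, drop = FALSE]
        totals <- totals[totals > 0]
    }
    out <- log1p(scale * sweep(m, 2, totals, "/"))
    .likeExpr(counts, out, units = "normalized")
}

#' Regress confounding covariates out of normalized expression
#'
#' Per gene, replaces expression by the ordinary-least-squares residuals
#' of expression on the supplied covariates plus an intercept. Used to
#' remove technical single-cell confounders such as per-cell molecule
#' counts and cell-cycle scores; any numeric covariates aligned to the
#' samples are accepted.
#'
#' @param expr normalized [ExprMatrix-class] (or plain matrix).
#' @param covariates sample x k numeric matrix/data frame aligned to the
#'   columns of `expr` (by rownames when present, otherwise by
#'   position).
#' @return A matrix of the same class tagged `"residuals"`; residuals
#'   are orthogonal to every covariate and to the intercept.
#' @export
regressCovariates <- function(expr, covariates) {
    m <- .asNormalizedMatrix(expr, "regressCovariates")
    cv <- as.matrix(covariates)
    if (nrow(cv) != ncol(m))
        stop("covariates must have one row per sample")
    if (!is.null(rownames(cv)) && !is.null(colnames(m))) {
        if (!all(colnames(m) %in% rownames(cv)))
            stop("covariate rows do not cover all samples")
        cv <- cv[colnames(m), , drop = FALSE]
    }
    X <- cbind(intercept = 1, cv)
    qx <- qr(X)
    if (qx$rank < ncol(X))
        stop("rank-deficient covariates (constant or collinear columns)")
    res <- t(qr.resid(qx, t(m)))
    dimnames(res) <- dimnames(m)
    .likeExpr(expr, res, units = "residuals")
}

#' Keep the highest-variance genes
#'
#' Restricts the matrix to the `k` genes with the largest variance
#' across samples (all genes when fewer than `k`), the standard
#' pre-modeling feature selection. Ties are broken by gene identifier so
#' the selection is deterministic.
#'
#' @param expr normalized [ExprMatrix-class] (or plain matrix).
#' @param k number of genes to keep (default 10000).
#' @return The input restricted to the selected genes, ordered by
#'   decreasing variance.
#' @export
selectTopVariance <- function(expr, k = 10000L) {
    m <- exprValues(expr)
    n <- ncol(m)
    rm <- rowMeans(m)
    rv <- rowSums((m - rm)^2) / max(n - 1L, 1L)
    ord <- order(-rv, rownames(m))
    keep <- ord[seq_len(min(k, nrow(m)))]
    if (is(expr, "SummarizedExperiment")) expr[keep, ]
    else m[keep, , drop = FALSE]
}
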