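#' Build a z-score signature matrix
#'
#' Converts normalized expression into a per-gene signature of deviation
#' from the dataset: each gene's values are centered on its mean across
#' samples and scaled by its population standard deviation (divisor n).
#' Genes with zero variance get an all-zero signature row. This
#' signature is the input to regulon activity scoring.
#'
#' @param expr normalized/residual [ExprMatrix-class] (or plain matrix)
#'   with at least 3 samples.
#' @return A gene x sample numeric matrix; each non-degenerate row has
#'   mean 0 and population SD 1.
#' @export
buildSignature <- function(expr) {
    m <- .asNormalizedMatrix(expr, "buildSignature")
    if (ncol(m) < 3L)
        stop("at least 3 samples are required to build a signature")
    mu <- rowMeans(m)
    sd_pop <- sqrt(pmax(rowMeans(m^2) - mu^2, 0))
    sig <- (m - mu) / ifelse(sd_pop > 0, sd_pop, 1)
    sig[sd_pop == 0, ] <- 0
    sig
}

#' Score regulon activity per sample
#'
#' The activity of a regulon R in sample s summarizes the collective
#' expression change of its target set relative to the dataset mean:
#'
#'   activity(R, s) = sqrt(n_R) * mean over targets t of
#'                    mode(t) * signature(t, s)
#'
#' where n_R is the number of targets present in the signature. Under a
#' null of independent unit-variance signatures the sqrt(n_R) scaling
#' gives every regulon's activity unit variance, so activities are
#' comparable across regulon sizes. Regulons with fewer than 10 usable
#' targets are dropped with a warning.
#'
#' @param signature gene x sample matrix from [buildSignature()].
#' @param regulons list of [Regulon-class] objects.
#' @return A regulon x sample matrix (rows named by TF).
#' @export
regulonActivity <- function(signature, regulons) {
    sig <- exprValues(signature)
    if (inherits(regulons, "Regulon")) regulons <- list(regulons)
    act <- NULL
    kept <- character(0)
    dropped <- character(0)
    for (r in regulons) {
        tg <- regulonTargets(r)
        md <- regulonModes(r)
        use <- tg %in% rownames(sig)
        if (sum(use) < 10L) {
            dropped <- c(dropped, regulonTf(r))
            next
        }
        tg <- tg[use]; md <- md[use]
        nR <- length(tg)
        a <- sqrt(nR) * colSums(sig[tg, , drop = FALSE] * md) / nR
        act <- rbind(act, a)
        kept <- c(kept, regulonTf(r))
    }
    if (length(dropped))
        warning("dropped regulon(s) with < 10 usable targets: ",
                paste(dropped, collapse = ", "))
    if (is.null(act))
        stop("no usable regulons (all have < 10 targets in the signature)")
    dimnames(act) <- list(kept, colnames(sig))
    act
}

#' One-step Tukey biweight robust average
#'
#' Robust location estimate used to aggregate co-expression clusters:
#' with M the median and S the (raw) median absolute deviation,
#' u_i = (x_i - M) / (c*S + eps), weights w_i = (1 - u_i^2)^2 for
#' |u_i| < 1 and 0 otherwise, the estimate is sum(w x) / sum(w).
#' Observations further than c scaled deviations from the median get
#' zero weight, so a single outlier cannot drag the average. Falls back
#' to the median if every weight is zero.
#'
#' @param values numeric vector with at least one finite value
#'   (non-finite values are ignored).
#' @param c biweight tuning constant (default 5).
#' @param eps guard added to c*S so constant vectors are handled
#'   (default 1e-4).
#' @return A single number, always within \[min, max\] of the input.
#' @examples
#' tukeyBiweight(c(1, 1, 1, 1, 100))  # outlier down-weighted to 0 -> 1
#' @export
tukeyBiweight <- function(values, c = 5, eps = 1e-4) {
    x <- values[is.finite(values)]
    if (!length(x))
        stop("empty vector (no finite values)")
    M <- median(x)
    S <- median(abs(x - M))
    u <- (x - M) / (c * S + eps)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(M)
    sum(w * x) / sum(w)
}

#' Detect disjoint co-expression clusters
#'
#' Average-linkage hierarchical clustering on (1 - Pearson correlation)
#' distance, with the tree cut at the height that maximizes the number
#' of clusters of size >= `minSize` (ties resolved toward fewer cuts).
#' Genes falling in smaller groups are left unclustered and excluded
#' from aggregation. Constant genes are treated as uncorrelated with
#' everything.
#'
#' @param expr normalized [ExprMatrix-class] (or plain matrix) with at
#'   least `minSize` genes.
#' @param minSize minimum cluster size (default 10).
#' @return A named list of character vectors (gene identifiers), one per
#'   cluster; possibly empty when no coherent group of `minSize` genes
#'   exists.
#' @export
clusterGenes <- function(expr, minSize = 10L) {
    m <- exprValues(expr)
    if (nrow(m) < minSize)
        stop("fewer genes than 'minSize'")
    sds <- apply(m, 1, sd)
    if (all(sds == 0))
        stop("degenerate expression matrix: all genes constant")
    cc <- suppressWarnings(cor(t(m)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    h <- hclust(as.dist(1 - cc), method = "average")
    kmax <- max(1L, nrow(m) %/% minSize)
    bestK <- 1L
    bestN <- -1L
    for (k in seq_len(kmax)) {
        ct <- cutree(h, k = k)
        nBig <- sum(table(ct) >= minSize)
        if (nBig > bestN) {
            bestN <- nBig
            bestK <- k
        }
    }
    ct <- cutree(h, k = bestK)
    sizes <- table(ct)
    big <- as.integer(names(sizes)[sizes >= minSize])
    clusters <- lapply(big, function(b) rownames(m)[ct == b])
    ## deterministic order: by first member's row position
    if (length(clusters)) {
        ord <- order(vapply(clusters, function(g)
            min(match(g, rownames(m))), numeric(1)))
        clusters <- clusters[ord]
        names(clusters) <- paste0("C", seq_along(clusters))
    } else names(clusters) <- character(0)
    clusters
}

#' Aggregate expression over clusters with the Tukey biweight
#'
#' Each cluster becomes a single variable: its value in a sample is the
#' [tukeyBiweight()] robust average of the member genes' expression in
#' that sample. When all members agree the aggregate equals the plain
#' mean; an outlying member is down-weighted instead of dragging the
#' cluster value.
#'
#' @param expr normalized [ExprMatrix-class] (or plain matrix).
#' @param clusters named list of gene-identifier vectors (from
#'   [clusterGenes()] or [readClusters()]).
#' @param c,eps Tukey biweight parameters (see [tukeyBiweight()]).
#' @return A cluster x sample numeric matrix.
#' @export
aggregateClusters <- function(expr, clusters, c = 5, eps = 1e-4) {
    m <- exprValues(expr)
    if (!length(clusters)) stop("no clusters supplied")
    unknown <- setdiff(unlist(clusters, use.names = FALSE), rownames(m))
    if (length(unknown))
        stop("cluster(s) reference unknown gene(s): ",
             paste(head(unknown, 10), collapse = ", "))
    out <- t(vapply(clusters, function(g)
        apply(m[g, , drop = FALSE], 2, tukeyBiweight, c = c, eps = eps),
        numeric(ncol(m))))
    dimnames(out) <- list(names(clusters), colnames(m))
    out
}
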