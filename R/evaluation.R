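#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) sample
#' pairs in which the positive outscores the negative, with ties counted
#' half. This equals the trapezoidal area under the ROC curve, is
#' invariant under strictly monotone transforms of the scores, and
#' satisfies auroc(-scores) = 1 - auroc(scores).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels; both classes must be present.
#' @return The AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
    if (any(!is.finite(scores)))
        stop("scores must be finite")
    y <- .as01(labels)
    if (length(scores) != length(y))
        stop("scores and labels must have equal length")
    np <- sum(y == 1)
    nn <- sum(y == 0)
    if (np == 0 || nn == 0)
        stop("both classes must be present")
    r <- rank(scores)
    (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Paired two-tailed Wilcoxon signed-rank comparison of two AUROC series
#'
#' Compares two models evaluated over the same repetitions (pairing by
#' rep). Zero differences are dropped; the test is exact for up to 25
#' nonzero pairs and uses the normal approximation with continuity
#' correction above. When every difference is zero, p = 1 and direction
#' = 0 by convention.
#'
#' @param aurocA,aurocB numeric vectors of equal length, paired by
#'   repetition. Pairs with a missing value are dropped.
#' @return `list(p.value, direction, n)` with `direction` the sign of
#'   the median difference A - B and `n` the number of nonzero pairs.
#' @export
pairedWilcoxon <- function(aurocA, aurocB) {
    if (length(aurocA) != length(aurocB))
        stop("paired vectors must have equal length")
    ok <- is.finite(aurocA) & is.finite(aurocB)
    d <- aurocA[ok] - aurocB[ok]
    if (!length(d)) stop("no complete pairs")
    nz <- d[d != 0]
    if (!length(nz))
        return(list(p.value = 1, direction = 0, n = 0L))
    direction <- sign(median(d))
    if (direction == 0) direction <- sign(median(nz))
    w <- suppressWarnings(wilcox.test(nz, exact = length(nz) <= 25,
                                      correct = TRUE))
    list(p.value = w$p.value, direction = direction, n = length(nz))
}

#' Assemble a robustness curve from model results
#'
#' Summarizes AUROCs across perturbation levels and feature modes
#' (expression vs aggregated) into one row per (level, mode): mean
#' AUROC, SD of the AUROC distribution, and the number of repetitions.
#' This is the table behind AUROC-vs-perturbation robustness plots.
#'
#' @param results data frame with columns `level`, `mode`, `auroc` (one
#'   row per repetition).
#' @return A data frame with columns `level`, `mode`, `mean_auroc`,
#'   `sd_auroc`, `n`, sorted by level then mode. `sd_auroc` is 0 when
#'   `n` = 1.
#' @export
robustnessCurve <- function(results) {
    if (is.null(results) || !nrow(as.data.frame(results)))
        stop("empty results")
    results <- as.data.frame(results)
    need <- c("level", "mode", "auroc")
    miss <- setdiff(need, colnames(results))
    if (length(miss))
        stop("results missing column(s): ", paste(miss, collapse = ", "))
    groups <- split(results,
                    list(level = results$level, mode = results$mode),
                    drop = TRUE)
    out <- do.call(rbind, lapply(groups, function(g)
        data.frame(level = g$level[1], mode = g$mode[1],
                   mean_auroc = mean(g$auroc),
                   sd_auroc = if (nrow(g) > 1) sd(g$auroc) else 0,
                   n = nrow(g))))
    out <- out[order(out$level, out$mode), , drop = FALSE]
    rownames(out) <- NULL
    out
}
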