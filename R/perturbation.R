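#' Add Gaussian noise to a normalized expression matrix
#'
#' Every cell of the matrix is independently incremented by a draw from
#' N(0, sigma^2). Noise is applied on the normalized scale; the input is
#' not modified. This is the first of the two information-reduction
#' engines used to probe model robustness, the second being read
#' down-sampling ([downsampleCounts()]).
#'
#' @param expr normalized [ExprMatrix-class] (or plain matrix).
#' @param sigma standard deviation of the noise (>= 0; 0 is the
#'   identity).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return A perturbed matrix of the same class and dimensions.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' noisy <- addGaussianNoise(m, sigma = 1, seed = 1)
#' @export
addGaussianNoise <- function(expr, sigma, seed = NULL) {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma < 0)
        stop("'sigma' must be a single non-negative number")
    m <- .asNormalizedMatrix(expr, "addGaussianNoise")
    if (sigma == 0) return(.likeExpr(expr, m))
    out <- withSeed(seed, m + matrix(rnorm(length(m), 0, sigma),
                                     nrow(m), ncol(m)))
    dimnames(out) <- dimnames(m)
    .likeExpr(expr, out)
}

#' Down-sample read counts with a beta-distributed per-gene factor
#'
#' Emulates shallow sequencing (low-coverage bulk or single-cell): for
#' each gene in each sample an independent down-sampling factor d is
#' drawn from Beta(alpha, beta) and the count is replaced by
#' round(count * d) (half away from zero). beta defaults to 0.1 and
#' alpha is derived per sample from its own total r as
#' alpha = beta * (f/r) / (1 - f/r), so that E\[d\] = f/r and the
#' expected down-sampled total equals the target read count f. With a
#' small beta the factor distribution piles up near 0 and 1, producing
#' complete gene dropouts alongside near-intact genes.
#'
#' @param counts raw-count [ExprMatrix-class] (or plain integer matrix).
#' @param f target read count per sample (>= 1).
#' @param betaShape the beta (second) shape parameter (> 0; default
#'   0.1).
#' @param seed RNG seed.
#' @return A matrix of the same class/dimensions with reduced counts.
#'   Samples whose total is <= `f` are passed through unchanged with a
#'   warning (alpha is undefined there).
#' @examples
#' m <- matrix(rpois(1000, 50), 100, 10,
#'             dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
#' d <- downsampleCounts(m, f = 100, seed = 1)
#' colSums(d)
#' @export
downsampleCounts <- function(counts, f, betaShape = 0.1, seed = NULL) {
    if (!is.numeric(f) || length(f) != 1L || f < 1)
        stop("'f' (target read count) must be >= 1")
    if (!is.numeric(betaShape) || betaShape <= 0)
        stop("'betaShape' must be > 0")
    m <- .asCountsMatrix(counts, "downsampleCounts")
    totals <- colSums(m)
    out <- withSeed(seed, {
        res <- m
        passed <- character(0)
        for (j in seq_len(ncol(m))) {
            r <- totals[j]
            if (f >= r) {
                passed <- c(passed, colnames(m)[j])
                next
            }
            alpha <- betaShape * (f / r) / (1 - f / r)
            d <- rbeta(nrow(m), alpha, betaShape)
            res[, j] <- roundHalfUp(m[, j] * d)
        }
        if (length(passed))
            warning("target reads f=", f, " >= sample total for ",
                    length(passed), " sample(s) (",
                    paste(head(passed, 5), collapse = ", "),
                    if (length(passed) > 5) ", ..." else "",
                    "); passed through unchanged")
        res
    })
    .likeExpr(counts, out)
}

#' Generate a sweep of perturbed matrices over levels and repetitions
#'
#' For each perturbation level and repetition an independently seeded
#' perturbed copy of the input is produced (seed =
#' [seedSchedule()]`(baseSeed, level index, rep)`), so a downstream
#' model run per (level, rep) sees an independent perturbation while the
#' whole sweep stays reproducible from `baseSeed` alone.
#'
#' @param expr input matrix: normalized for `mode = "noise"`, raw counts
#'   for `mode = "downsample"`.
#' @param levels numeric vector of perturbation levels (Gaussian SD, or
#'   target read count f).
#' @param mode `"noise"` or `"downsample"`.
#' @param reps repetitions per level.
#' @param baseSeed base seed for the schedule.
#' @param betaShape passed to [downsampleCounts()].
#' @return A list with one element per (level, rep): `list(matrix,
#'   level, rep, seed)`.
#' @export
perturbationSweep <- function(expr, levels, mode = c("noise", "downsample"),
                              reps = 100L, baseSeed = 1L, betaShape = 0.1) {
    mode <- match.arg(mode)
    if (!length(levels)) stop("'levels' must be non-empty")
    out <- vector("list", length(levels) * reps)
    k <- 0L
    for (i in seq_along(levels)) {
        for (r in seq_len(reps)) {
            sd <- seedSchedule(baseSeed, i, r)
            pm <- switch(mode,
                noise = addGaussianNoise(expr, levels[i], seed = sd),
                downsample = downsampleCounts(expr, levels[i],
                                              betaShape = betaShape,
                                              seed = sd))
            k <- k + 1L
            out[[k]] <- list(matrix = pm, level = levels[i], rep = r,
                             seed = sd)
        }
    }
    out
}
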