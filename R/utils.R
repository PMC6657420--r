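## Internal RNG helpers. All stochastic operations take an explicit seed
## and restore the caller's RNG state, so pipelines are reproducible from
## their configuration alone.

withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    code
}

#' Deterministic seed schedule
#'
#' Derives a distinct, reproducible child seed for each (level, rep) cell
#' of a perturbation sweep or repeated-evaluation loop from a single base
#' seed. All arithmetic stays below 2^31 so results are identical across
#' platforms.
#'
#' @param baseSeed integer base seed.
#' @param level integer level index (1-based; use 1 when there is no
#'   level dimension).
#' @param rep integer repetition index (1-based).
#' @return An integer seed.
#' @export
seedSchedule <- function(baseSeed, level = 1L, rep = 1L) {
    b <- as.numeric(baseSeed) %% 50021
    s <- (b * 40009 + as.numeric(level) * 2017 + as.numeric(rep) * 1) %%
        2147483587
    as.integer(s + 1)
}

## round half away from zero (counts are non-negative here, so half-up)
roundHalfUp <- function(x) floor(x + 0.5)

.asCountsMatrix <- function(x, what = "counts") {
    m <- exprValues(x)
    u <- exprUnits(x)
    if (!is.na(u) && u != "counts")
        stop(what, " requires raw counts, got units '", u, "'")
    if (any(m < 0) || any(m != floor(m)))
        stop(what, " requires non-negative integer counts")
    m
}

.asNormalizedMatrix <- function(x, what = "this operation") {
    m <- exprValues(x)
    u <- exprUnits(x)
    if (!is.na(u) && u == "counts")
        stop(what, " requires normalized expression, got raw counts")
    m
}
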