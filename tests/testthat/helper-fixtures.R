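## Small cohorts and independent oracles shared across test files.

smallCohort <- function(seed = 1, nSamples = 60, nGenes = 300, nTfs = 2,
                        targetsPerTf = 20, drivers = list(),
                        passengers = list(), ...) {
    simulateCohort(cohortSimConfig(
        nSamples = nSamples, nGenes = nGenes, nTfs = nTfs,
        targetsPerTf = targetsPerTf, driverEvents = drivers,
        passengerEvents = passengers, seed = seed, ...))
}

namedMatrix <- function(data, nrow, ncol, prefix = c("g", "s")) {
    matrix(data, nrow, ncol,
           dimnames = list(sprintf("%s%03d", prefix[1], seq_len(nrow)),
                           sprintf("%s%03d", prefix[2], seq_len(ncol))))
}

## exhaustive pair-counting AUROC (ties half-credited)
bruteAuroc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
}

## exhaustive per-base maximal-overlap CNV assignment; ties broken by
## larger |log2 ratio|, then leftmost segment start (coordinates 1-based
## closed, as in the GRanges the package uses)
bruteCnvAssign <- function(segdf, genedf, samples) {
    out <- matrix(0, nrow(genedf), length(samples),
                  dimnames = list(genedf$gene_id, samples))
    for (i in seq_len(nrow(genedf))) {
        gbase <- seq(genedf$start[i], genedf$end[i])
        for (s in samples) {
            segs <- segdf[segdf$sample_id == s &
                          segdf$chrom == genedf$chrom[i], , drop = FALSE]
            bestLr <- 0; bestOv <- 0; bestAbs <- -Inf; bestSt <- Inf
            for (k in seq_len(nrow(segs))) {
                ov <- sum(gbase >= segs$start[k] & gbase <= segs$end[k])
                if (ov == 0) next
                better <- ov > bestOv ||
                    (ov == bestOv && (abs(segs$lr[k]) > bestAbs ||
                     (abs(segs$lr[k]) == bestAbs &&
                      segs$start[k] < bestSt)))
                if (better) {
                    bestOv <- ov; bestLr <- segs$lr[k]
                    bestAbs <- abs(segs$lr[k]); bestSt <- segs$start[k]
                }
            }
            out[i, s] <- bestLr
        }
    }
    out
}

segGRanges <- function(segdf) {
    GenomicRanges::GRanges(segdf$chrom,
                           IRanges::IRanges(segdf$start, segdf$end),
                           sample_id = segdf$sample_id,
                           log2_ratio = segdf$lr)
}

geneGRanges <- function(genedf) {
    GenomicRanges::GRanges(genedf$chrom,
                           IRanges::IRanges(genedf$start, genedf$end),
                           gene_id = genedf$gene_id)
}
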