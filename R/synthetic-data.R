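#' Describe a driver alteration to plant in a simulated cohort
#'
#' A driver event has an expression consequence. For a `"mutation"` event
#' the mutated gene is a regulon's TF: in carrier samples every target of
#' that regulon is shifted by `effectSize` gene-level standard deviations
#' on the log scale, with the sign given by the target's mode. For
#' `"amplification"`/`"deletion"` events the affected gene's expected
#' count is multiplied by the relative dosage `2^log2Ratio`, and matching
#' CNV segments are emitted.
#'
#' @param class `"mutation"`, `"amplification"` or `"deletion"`.
#' @param prevalence carrier probability per sample, in (0, 1).
#' @param effectSize for mutations, the target-gene shift in SD units;
#'   for CNV classes, the magnitude of the segment log2 ratio (sign is
#'   set by the class: positive for amplification, negative for
#'   deletion). Must be >= 0.5 for CNV classes so the planted event is
#'   recoverable at the standard binarization threshold.
#' @param regulon index into the cohort's regulon list (mutation class
#'   only).
#' @param gene affected gene for CNV classes; `NA` picks an unused
#'   non-regulon gene deterministically.
#' @return A list describing the event.
#' @export
driverEvent <- function(class = c("mutation", "amplification", "deletion"),
                        prevalence, effectSize = 1, regulon = NA_integer_,
                        gene = NA_character_) {
    class <- match.arg(class)
    if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
        stop("invalid 'prevalence' (must be in (0,1)): ", prevalence)
    if (!is.numeric(effectSize) || !is.finite(effectSize))
        stop("invalid 'effectSize': must be a finite number")
    if (class == "mutation" && effectSize < 0)
        stop("invalid 'effectSize': must be non-negative for mutations")
    if (class != "mutation" && effectSize < 0.5)
        stop("invalid 'effectSize': CNV drivers need |log2| >= 0.5")
    list(class = class, prevalence = prevalence, effectSize = effectSize,
         regulon = as.integer(regulon), gene = as.character(gene),
         driver = TRUE)
}

#' Describe a passenger alteration (no expression consequence)
#'
#' @param class event class (any of the three).
#' @param prevalence carrier probability per sample, in (0, 1).
#' @param gene affected gene; `NA` picks an unused gene.
#' @return A list describing the event.
#' @export
passengerEvent <- function(class = "mutation", prevalence,
                           gene = NA_character_) {
    class <- match.arg(class, c("mutation", "amplification", "deletion"))
    if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
        stop("invalid 'prevalence' (must be in (0,1)): ", prevalence)
    list(class = class, prevalence = prevalence, effectSize = 0,
         regulon = NA_integer_, gene = as.character(gene), driver = FALSE)
}

#' Configuration for a simulated cohort
#'
#' Counts follow a negative-binomial model with gene-specific baseline
#' means and log-normal gene-to-gene abundance spread. Each TF drives a
#' regulon of `targetsPerTf` signed targets; targets of the same TF share
#' a per-sample latent activity so that they co-vary (pairwise log-scale
#' correlation `rho` when `coupling = TRUE`). Driver events perturb
#' expression as described in [driverEvent()]; passengers are carried
#' with no expression consequence.
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param nTfs number of TF regulons.
#' @param targetsPerTf targets per regulon (>= 10; target sets are drawn
#'   without replacement and are disjoint across TFs).
#' @param driverEvents list of [driverEvent()] specifications.
#' @param passengerEvents list of [passengerEvent()] specifications.
#' @param nbMean baseline expected count per gene (used to derive the
#'   library size when `librarySize` is `NULL`).
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param librarySize expected total reads per sample; default
#'   `nGenes * nbMean`.
#' @param bioSd biological log-scale SD per gene (natural log units).
#' @param rho within-regulon log-expression correlation when coupling is
#'   on.
#' @param coupling logical; couple targets of a TF through a shared
#'   latent activity.
#' @param seed RNG seed.
#' @return A validated configuration list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nSamples, nGenes, nTfs = 4L, targetsPerTf = 50L,
                            driverEvents = list(), passengerEvents = list(),
                            nbMean = 50, nbDispersion = 0.15,
                            librarySize = NULL, bioSd = 0.5, rho = 0.5,
                            coupling = TRUE, seed = 1L) {
    if (!is.numeric(nSamples) || nSamples < 1)
        stop("invalid 'nSamples'")
    if (!is.numeric(nGenes) || nGenes < 1)
        stop("invalid 'nGenes'")
    if (targetsPerTf < 10)
        stop("invalid 'targetsPerTf': a regulon needs at least 10 targets")
    if (nTfs * (targetsPerTf + 1) > nGenes)
        stop("gene universe too small for ", nTfs, " disjoint regulons of ",
             targetsPerTf, " targets")
    if (!is.numeric(nbMean) || nbMean <= 0) stop("invalid 'nbMean'")
    if (!is.numeric(nbDispersion) || nbDispersion <= 0)
        stop("invalid 'nbDispersion'")
    if (is.null(librarySize)) librarySize <- nGenes * nbMean
    if (librarySize < 1) stop("invalid 'librarySize'")
    events <- c(driverEvents, passengerEvents)
    for (ev in events) {
        if (ev$prevalence * nSamples < 1)
            stop("invalid 'prevalence': expected carriers ",
                 "(prevalence * nSamples) must be >= 1")
        if (isTRUE(ev$driver) && ev$class == "mutation" &&
            (is.na(ev$regulon) || ev$regulon < 1 || ev$regulon > nTfs))
            stop("invalid 'regulon' index for driver mutation event")
    }
    structure(list(nSamples = as.integer(nSamples),
                   nGenes = as.integer(nGenes), nTfs = as.integer(nTfs),
                   targetsPerTf = as.integer(targetsPerTf),
                   driverEvents = driverEvents,
                   passengerEvents = passengerEvents, nbMean = nbMean,
                   nbDispersion = nbDispersion, librarySize = librarySize,
                   bioSd = bioSd, rho = rho, coupling = isTRUE(coupling),
                   seed = as.integer(seed)),
              class = "CohortSimConfig")
}

## synthetic genome: one chromosome per 1000 genes, 1 kb genes with 1 kb
## gaps (1-based closed coordinates as used by GRanges)
.syntheticGeneModels <- function(geneIds) {
    n <- length(geneIds)
    i <- seq_len(n) - 1L
    chrom <- paste0("chr", i %/% 1000L + 1L)
    within <- i %% 1000L
    GRanges(chrom, IRanges(start = within * 2000L + 1L,
                           end = within * 2000L + 1000L),
            gene_id = geneIds)
}

#' Simulate a bulk cohort with planted alterations
#'
#' Draws negative-binomial counts with regulon co-expression structure,
#' plants the configured driver and passenger events, and returns the
#' cohort together with its ground truth (event matrix, regulons,
#' co-expression clusters, CNV segments, gene models). Deterministic
#' given `config$seed`.
#'
#' @param config a [cohortSimConfig()] object.
#' @return A [SimulatedCohort-class].
#' @examples
#' cfg <- cohortSimConfig(nSamples = 60, nGenes = 300, nTfs = 2,
#'                        targetsPerTf = 20,
#'                        driverEvents = list(driverEvent("mutation", 0.3,
#'                                            effectSize = 1, regulon = 1)),
#'                        seed = 7)
#' sim <- simulateCohort(cfg)
#' truthEvents(sim)
#' @export
simulateCohort <- function(config) {
    if (!inherits(config, "CohortSimConfig"))
        config <- do.call(cohortSimConfig, config)
    withSeed(config$seed, {
        n <- config$nSamples
        g <- config$nGenes
        geneIds <- sprintf("g%05d", seq_len(g))
        sampleIds <- sprintf("s%04d", seq_len(n))
        tfs <- geneIds[seq_len(config$nTfs)]
        pool <- geneIds[-seq_len(config$nTfs)]
        targetIdx <- sample(length(pool),
                            config$nTfs * config$targetsPerTf)
        targetSets <- split(pool[targetIdx],
                            rep(seq_len(config$nTfs),
                                each = config$targetsPerTf))
        regulons <- vector("list", config$nTfs)
        for (j in seq_len(config$nTfs)) {
            modes <- ifelse(rbinom(config$targetsPerTf, 1, 0.7) == 1, 1, -1)
            regulons[[j]] <- Regulon(tfs[j], targetSets[[j]], modes)
        }
        names(regulons) <- tfs

        ## baseline abundances, scaled to the library size
        w <- rlnorm(g, 0, 0.7)
        mu0 <- setNames(config$librarySize * w / sum(w), geneIds)

        ## log-scale biological variation with regulon coupling
        bio <- config$bioSd
        x <- matrix(rnorm(g * n, 0, bio), g, n,
                    dimnames = list(geneIds, sampleIds))
        z <- matrix(rnorm(config$nTfs * n), config$nTfs, n)
        if (config$coupling) {
            sr <- sqrt(config$rho)
            se <- sqrt(1 - config$rho)
            for (j in seq_len(config$nTfs)) {
                tg <- regulonTargets(regulons[[j]])
                md <- regulonModes(regulons[[j]])
                x[tg, ] <- bio * (md %o% (sr * z[j, ])) +
                    se * x[tg, , drop = FALSE]
                ## the TF itself tracks its own activity
                x[tfs[j], ] <- bio * sr * z[j, ] +
                    se * x[tfs[j], , drop = FALSE]
            }
        }

        ## assign event genes and carriers
        events <- c(config$driverEvents, config$passengerEvents)
        used <- c(tfs, unlist(targetSets, use.names = FALSE),
                  unlist(lapply(events, `[[`, "gene")))
        freePool <- setdiff(geneIds, used[!is.na(used)])
        carrierMat <- NULL
        eventGenes <- character(0)
        eventClasses <- character(0)
        dosage <- matrix(1, g, n, dimnames = dimnames(x))
        for (ev in events) {
            gene <- ev$gene
            if (isTRUE(ev$driver) && ev$class == "mutation") {
                gene <- tfs[ev$regulon]
            } else if (is.na(gene)) {
                if (!length(freePool))
                    stop("no free genes left to assign to events")
                gene <- freePool[1]
                freePool <- freePool[-1]
            }
            if (!gene %in% geneIds)
                stop("event gene outside the gene universe: ", gene)
            carriers <- rbinom(n, 1, ev$prevalence)
            if (isTRUE(ev$driver)) {
                if (ev$class == "mutation") {
                    reg <- regulons[[ev$regulon]]
                    tg <- regulonTargets(reg)
                    md <- regulonModes(reg)
                    idx <- which(carriers == 1)
                    ## effect size is in units of each target's TOTAL
                    ## log-scale SD (biological spread plus the
                    ## delta-method counting-noise contribution), so "1
                    ## SD" means one SD of the gene's observed expression
                    totSd <- sqrt(bio^2 + config$nbDispersion +
                                  1 / (mu0[tg] * exp(bio^2 / 2)))
                    if (length(idx))
                        x[tg, idx] <- x[tg, idx, drop = FALSE] +
                            totSd * ev$effectSize * md
                } else {
                    l2 <- ev$effectSize *
                        if (ev$class == "deletion") -1 else 1
                    dosage[gene, carriers == 1] <- 2^l2
                }
            }
            carrierMat <- rbind(carrierMat, carriers)
            eventGenes <- c(eventGenes, gene)
            eventClasses <- c(eventClasses, ev$class)
        }

        mu <- (mu0 * exp(x)) * dosage
        counts <- matrix(rnbinom(g * n, mu = mu,
                                 size = 1 / config$nbDispersion),
                         g, n, dimnames = list(geneIds, sampleIds))

        truth <- if (length(events)) {
            EventMatrix(carrierMat, eventGenes, eventClasses, sampleIds)
        } else {
            EventMatrix(matrix(0, 0, n, dimnames = list(NULL, sampleIds)),
                        character(0), character(0), sampleIds)
        }
        gm <- .syntheticGeneModels(geneIds)
        cohort <- new("SimulatedCohort",
                      counts = ExprMatrix(counts, "counts"),
                      truthEvents = truth, regulons = regulons,
                      clusters = lapply(regulons, regulonTargets),
                      segments = GRanges(), geneModels = gm,
                      config = unclass(config))
        segs <- GRanges()
        for (ev in c(config$driverEvents)) {
            if (ev$class %in% c("amplification", "deletion"))
                segs <- c(segs, simulateCnvSegments(cohort, ev))
        }
        cohort@segments <- segs
        cohort
    })
}

#' Emit CNV segments matching a planted copy-number event
#'
#' For each carrier sample of a CNV driver event, emits one segment
#' covering the affected gene with the event's log2 ratio, flanked by
#' neutral (log2 = 0) segments tiling the rest of the chromosome.
#' Non-carrier samples receive no segments (absence is neutral). The
#' output feeds [assignGeneCnv()]; the round trip through
#' [binarizeCnv()] reproduces the planted truth row exactly.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param event a [driverEvent()] of CNV class. Its affected gene is
#'   resolved against the cohort's truth events.
#' @return A [GenomicRanges::GRanges] with `sample_id` and `log2_ratio`
#'   metadata columns.
#' @export
simulateCnvSegments <- function(cohort, event) {
    if (!event$class %in% c("amplification", "deletion"))
        stop("event class must be amplification or deletion, got ",
             event$class)
    l2 <- event$effectSize * if (event$class == "deletion") -1 else 1
    truth <- truthEvents(cohort)
    rows <- which(eventClasses(truth) == event$class)
    gene <- event$gene
    if (is.na(gene) || !nzchar(gene)) {
        if (length(rows) != 1L)
            stop("ambiguous CNV event; specify the affected gene")
        gene <- rowData(truth)$gene_id[rows]
    }
    row <- which(rownames(truth) == paste0(gene, ":", event$class))
    if (!length(row))
        stop("no planted ", event$class, " event for gene ", gene)
    carriers <- colnames(truth)[eventValues(truth)[row, ] == 1]
    gm <- geneModels(cohort)
    gi <- gm[mcols(gm)$gene_id == gene]
    if (!length(gi)) stop("gene ", gene, " has no gene model")
    chrom <- as.character(seqnames(gi))
    onChrom <- gm[as.character(seqnames(gm)) == chrom]
    chromEnd <- max(end(onChrom)) + 1000L
    gs <- start(gi); ge <- end(gi)
    segs <- lapply(carriers, function(s) {
        st <- c(if (gs > 1L) 1L else NULL, gs,
                if (ge < chromEnd) ge + 1L else NULL)
        en <- c(if (gs > 1L) gs - 1L else NULL, ge,
                if (ge < chromEnd) chromEnd else NULL)
        lr <- c(if (gs > 1L) 0 else NULL, l2,
                if (ge < chromEnd) 0 else NULL)
        GRanges(chrom, IRanges(st, en), sample_id = s, log2_ratio = lr)
    })
    if (!length(segs)) return(GRanges())
    do.call(c, segs)
}

#' Simulate single cells from a bulk cohort by read down-sampling
#'
#' Each cell is a beta-thinned copy (see [downsampleCounts()]) of its
#' source sample's count profile targeted at `depth` total reads, which
#' produces the depth-dependent dropout characteristic of single-cell
#' sequencing. Cells inherit their source sample's event labels; the
#' source is recorded in `colData(.)$source_sample`.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param cellsPerSample number of cells per source sample.
#' @param depth target reads per cell (>= 1). If it meets or exceeds a
#'   sample's library size, that sample's cells are un-thinned copies
#'   (with a warning, from [downsampleCounts()]).
#' @param dropoutShape beta second shape parameter controlling dropout
#'   burstiness (default 0.1).
#' @param seed RNG seed.
#' @return An [ExprMatrix-class] of raw cell counts.
#' @export
simulateSingleCell <- function(cohort, cellsPerSample, depth,
                               dropoutShape = 0.1, seed = 1L) {
    stopifnot(depth >= 1, cellsPerSample >= 1)
    m <- exprValues(cohortCounts(cohort))
    src <- rep(colnames(m), each = cellsPerSample)
    cells <- m[, src, drop = FALSE]
    colnames(cells) <- paste0(src, "_cell",
                              rep(seq_len(cellsPerSample), ncol(m)))
    out <- downsampleCounts(cells, f = depth, betaShape = dropoutShape,
                            seed = seed)
    ExprMatrix(out, "counts",
               colData = DataFrame(source_sample = src,
                                   row.names = colnames(cells)))
}

#' Expand sample-level events to cell-level labels
#'
#' @param events an [EventMatrix-class] over samples.
#' @param sourceSamples character vector mapping each cell to its source
#'   sample (e.g. `colData(cells)$source_sample`).
#' @param cellIds identifiers for the new columns.
#' @return An [EventMatrix-class] over cells.
#' @export
expandEventsToCells <- function(events, sourceSamples, cellIds = NULL) {
    v <- eventValues(events)[, sourceSamples, drop = FALSE]
    if (is.null(cellIds))
        cellIds <- make.unique(sourceSamples)
    colnames(v) <- cellIds
    EventMatrix(v, rowData(events)$gene_id, eventClasses(events), cellIds)
}
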