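test_that("simulation is deterministic given the seed", {
    drivers <- list(driverEvent("mutation", 0.3, 1, regulon = 1),
                    driverEvent("amplification", 0.2, 1))
    a <- smallCohort(seed = 11, drivers = drivers)
    b <- smallCohort(seed = 11, drivers = drivers)
    expect_identical(exprValues(cohortCounts(a)),
                     exprValues(cohortCounts(b)))
    expect_identical(eventValues(truthEvents(a)),
                     eventValues(truthEvents(b)))
    expect_identical(cohortSegments(a), cohortSegments(b))
    c <- smallCohort(seed = 12, drivers = drivers)
    expect_false(identical(exprValues(cohortCounts(a)),
                           exprValues(cohortCounts(c))))
})

test_that("configuration errors name the offending field", {
    expect_error(driverEvent("mutation", 1.5), "prevalence")
    expect_error(driverEvent("mutation", 0.3, effectSize = NA), "effectSize")
    expect_error(driverEvent("amplification", 0.3, effectSize = 0.2),
                 "effectSize")
    expect_error(cohortSimConfig(100, 50, nTfs = 1, targetsPerTf = 5),
                 "targetsPerTf")
    expect_error(
        cohortSimConfig(10, 100, nTfs = 1, targetsPerTf = 10,
                        driverEvents = list(driverEvent("mutation", 0.01,
                                                        1, regulon = 1))),
        "prevalence")
})

test_that("zero-effect drivers are indistinguishable from noise", {
    tstats <- vapply(1:30, function(seed) {
        sim <- smallCohort(seed = seed, nSamples = 400, nGenes = 12,
                           nTfs = 1, targetsPerTf = 10,
                           drivers = list(driverEvent("mutation", 0.5, 0,
                                                      regulon = 1)))
        nm <- exprValues(normalizeCounts(cohortCounts(sim)))
        y <- eventValues(truthEvents(sim))[1, ]
        g <- regulonTargets(cohortRegulons(sim)[[1]])[1]
        unname(t.test(nm[g, y == 1], nm[g, y == 0])$statistic)
    }, numeric(1))
    expect_gte(mean(abs(tstats) < 4), 0.95)
})

test_that("driver carrier fraction matches the Bernoulli prevalence", {
    fracs <- vapply(1:30, function(seed) {
        sim <- smallCohort(seed = seed, nSamples = 1000, nGenes = 12,
                           nTfs = 1, targetsPerTf = 10,
                           drivers = list(driverEvent("mutation", 0.3, 1,
                                                      regulon = 1)))
        unname(carrierFractions(truthEvents(sim))[1])
    }, numeric(1))
    expect_lt(abs(mean(fracs) - 0.3), 0.05)
})

test_that("regulon targets co-vary above background when coupling is on", {
    sim <- smallCohort(seed = 3, nSamples = 200, nGenes = 200, nTfs = 1,
                       targetsPerTf = 20)
    nm <- exprValues(normalizeCounts(cohortCounts(sim)))
    reg <- cohortRegulons(sim)[[1]]
    tg <- regulonTargets(reg)
    md <- regulonModes(reg)
    ## orient by mode so repressed targets correlate positively too
    sub <- nm[tg, ] * md
    cc <- cor(t(sub))
    within <- cc[upper.tri(cc)]
    others <- setdiff(rownames(nm), c(tg, regulonTf(reg)))
    set.seed(1)
    bg <- replicate(500, {
        p <- sample(others, 2)
        cor(nm[p[1], ], nm[p[2], ])
    })
    expect_gt(median(within), quantile(bg, 0.95))
})

test_that("CNV drivers change the affected gene's dosage", {
    sim <- smallCohort(seed = 9, nSamples = 300, nGenes = 100, nTfs = 1,
                       targetsPerTf = 10,
                       drivers = list(driverEvent("amplification", 0.4, 1),
                                      driverEvent("deletion", 0.4, 1)))
    tr <- truthEvents(sim)
    cnt <- exprValues(cohortCounts(sim))
    ampGene <- SummarizedExperiment::rowData(tr)$gene_id[
        eventClasses(tr) == "amplification"]
    delGene <- SummarizedExperiment::rowData(tr)$gene_id[
        eventClasses(tr) == "deletion"]
    yA <- eventValues(tr)[paste0(ampGene, ":amplification"), ]
    yD <- eventValues(tr)[paste0(delGene, ":deletion"), ]
    ## log2 = +1 doubles, log2 = -1 halves the expected count
    expect_gt(mean(cnt[ampGene, yA == 1]) / mean(cnt[ampGene, yA == 0]),
              1.5)
    expect_lt(mean(cnt[delGene, yD == 1]) / mean(cnt[delGene, yD == 0]),
              0.75)
    expect_error(simulateCnvSegments(sim, driverEvent("mutation", 0.4, 1,
                                                      regulon = 1)),
                 "amplification or deletion")
})

test_that("single-cell mode thins counts and inherits labels", {
    sim <- smallCohort(seed = 2, nSamples = 10, nGenes = 100, nTfs = 1,
                       targetsPerTf = 10,
                       drivers = list(driverEvent("mutation", 0.5, 1,
                                                  regulon = 1)))
    totals <- colSums(exprValues(cohortCounts(sim)))

    ## depth >= source total: cells equal the source profile
    expect_warning(
        full <- simulateSingleCell(sim, cellsPerSample = 2,
                                   depth = max(totals) + 1, seed = 1),
        "passed through")
    src <- SummarizedExperiment::colData(full)$source_sample
    expect_identical(unname(exprValues(full)),
                     unname(exprValues(cohortCounts(sim))[, src]))

    ## zero fraction increases as depth decreases
    zf <- vapply(c(0.5, 0.05), function(fr) {
        cells <- simulateSingleCell(sim, cellsPerSample = 10,
                                    depth = round(fr * min(totals)),
                                    seed = 7)
        mean(exprValues(cells) == 0)
    }, numeric(1))
    expect_lt(zf[1], zf[2])

    ## label bookkeeping: each cell carries its source sample's events
    cells <- simulateSingleCell(sim, cellsPerSample = 3, depth = 500,
                                seed = 3)
    src <- SummarizedExperiment::colData(cells)$source_sample
    ev <- expandEventsToCells(truthEvents(sim), src, colnames(cells))
    expect_identical(unname(eventValues(ev)),
                     unname(eventValues(truthEvents(sim))[, src,
                                                          drop = FALSE]))
})
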