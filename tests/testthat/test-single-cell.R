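test_that("guide assignments become per-gene contrasts with shared controls", {
    cells <- ExprMatrix(namedMatrix(rpois(7 * 10, 5), 7, 10,
                                    c("g", "cell")), "counts")
    ga <- data.frame(cell_id = sprintf("cell%03d", 1:10),
                     target = c("TP53", "TP53", "KRAS", "EGFR", "CTRL",
                                "CTRL", "CTRL", "KRAS", "EGFR", "TP53"))
    ct <- buildMutationContrasts(cells, ga)
    expect_length(ct, 3)
    expect_setequal(names(ct), c("TP53", "KRAS", "EGFR"))
    ## a cell with a guide for gene A appears only in contrast A
    expect_false(any(sprintf("cell%03d", c(3, 8)) %in%
                     ct$TP53$cellIds))
    ## contrast size = carriers + controls
    expect_equal(length(ct$TP53$cellIds), 3 + 3)
    expect_equal(sum(ct$TP53$labels), 3)
    expect_error(buildMutationContrasts(cells, ga[ga$target != "CTRL", ]),
                 "no control cells")
    expect_error(buildMutationContrasts(cells, ga[ga$target == "CTRL", ]),
                 "no targeted genes")
})

test_that("undersized contrasts are skipped, pairing uses shared splits", {
    set.seed(1)
    cells <- ExprMatrix(namedMatrix(rpois(20 * 60, 8), 20, 60,
                                    c("g", "cell")), "counts")
    nm <- normalizeSingleCell(cells)
    regs <- list(Regulon("g001", sprintf("g%03d", 2:13), 1))
    ga <- data.frame(cell_id = sprintf("cell%03d", 1:60),
                     target = c(rep("gX", 25), rep("gY", 5),
                                rep("CTRL", 30)))
    expect_warning(res <- runCropSeqBenchmark(nm, ga, regs,
                                              spec = modelSpec(seed = 2),
                                              reps = 3),
                   "gY:mutation skipped")
    expect_setequal(unique(res$table$event), "gX:mutation")
    ## both feature modes see the same number of completed repetitions
    expect_equal(res$table$n[1], res$table$n[2])
})

test_that("regulon knockouts favor activity features at low depth", {
    ## a TF knocked out in half the cells shifts its 200-target regulon
    ## by 1 SD; cells are read-thinned 30-fold, which drives most genes
    ## to dropout
    cfg <- cohortSimConfig(nSamples = 600, nGenes = 2000, nTfs = 4,
        targetsPerTf = 200,
        driverEvents = list(driverEvent("mutation", 0.5, 1, regulon = 1)),
        seed = 42)
    sim <- simulateCohort(cfg)
    tf <- regulonTf(cohortRegulons(sim)[[1]])
    cells <- simulateSingleCell(sim, cellsPerSample = 1, depth = 3333,
                                seed = 7)
    nm <- suppressWarnings(normalizeSingleCell(cells))
    src <- SummarizedExperiment::colData(cells)$source_sample
    ycell <- as.integer(eventValues(truthEvents(sim))[1, src])
    guides <- data.frame(cell_id = colnames(cells),
                         target = ifelse(ycell == 1, tf, "CTRL"))
    bench <- runCropSeqBenchmark(nm, guides, cohortRegulons(sim),
                                 spec = modelSpec(seed = 5), reps = 50)
    tab <- bench$table
    expect_gt(tab$mean_auroc[tab$mode == "activity"],
              tab$mean_auroc[tab$mode == "expression"])
    expect_lt(bench$pooled$p.value, 0.05)
    expect_equal(bench$pooled$direction, 1)
})

test_that("zero-effect guides give chance performance in both modes", {
    cfg <- cohortSimConfig(nSamples = 300, nGenes = 500, nTfs = 2,
        targetsPerTf = 30,
        driverEvents = list(driverEvent("mutation", 0.5, 0, regulon = 1)),
        seed = 11)
    sim <- simulateCohort(cfg)
    tf <- regulonTf(cohortRegulons(sim)[[1]])
    cells <- simulateSingleCell(sim, cellsPerSample = 1, depth = 2000,
                                seed = 7)
    nm <- suppressWarnings(normalizeSingleCell(cells))
    src <- SummarizedExperiment::colData(cells)$source_sample
    ycell <- as.integer(eventValues(truthEvents(sim))[1, src])
    guides <- data.frame(cell_id = colnames(cells),
                         target = ifelse(ycell == 1, tf, "CTRL"))
    bench <- runCropSeqBenchmark(nm, guides, cohortRegulons(sim),
                                 spec = modelSpec(seed = 5), reps = 10)
    expect_true(all(bench$table$mean_auroc > 0.4 &
                    bench$table$mean_auroc < 0.6))
})
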