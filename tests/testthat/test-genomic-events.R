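test_that("CNV assignment picks the maximally overlapping segment", {
    genes <- geneGRanges(data.frame(gene_id = "gA", chrom = "chr1",
                                    start = 101, end = 200))
    ## unique covering segment
    segs <- segGRanges(data.frame(sample_id = "s1", chrom = "chr1",
                                  start = 1, end = 400, lr = 0.8))
    expect_equal(assignGeneCnv(segs, genes)["gA", "s1"], 0.8)
    ## split coverage: 80 bp vs 20 bp overlap
    segs2 <- segGRanges(data.frame(sample_id = "s1", chrom = "chr1",
                                   start = c(1, 181), end = c(180, 400),
                                   lr = c(0.8, 0.1)))
    expect_equal(assignGeneCnv(segs2, genes)["gA", "s1"], 0.8)
    ## no overlapping segment defaults to neutral
    segs3 <- segGRanges(data.frame(sample_id = "s1", chrom = "chr2",
                                   start = 1, end = 400, lr = 0.9))
    expect_equal(assignGeneCnv(segs3, genes)["gA", "s1"], 0)
})

test_that("CNV assignment agrees with the per-base brute-force oracle", {
    set.seed(42)
    for (trial in 1:25) {
        nG <- sample(3:10, 1)
        nS <- sample(3:12, 1)
        starts <- sort(sample(seq(1, 400, by = 40), nG))
        genedf <- data.frame(gene_id = paste0("g", seq_len(nG)),
                             chrom = sample(c("chr1", "chr2"), nG,
                                            replace = TRUE),
                             start = starts,
                             end = starts + sample(10:35, nG,
                                                   replace = TRUE))
        segdf <- do.call(rbind, lapply(c("sA", "sB"), function(s) {
            st <- sample(1:400, nS, replace = TRUE)
            data.frame(sample_id = s, chrom = sample(c("chr1", "chr2"),
                                                     nS, replace = TRUE),
                       start = st,
                       end = st + sample(5:120, nS, replace = TRUE),
                       lr = round(rnorm(nS), 2))
        }))
        got <- assignGeneCnv(segGRanges(segdf), geneGRanges(genedf),
                             samples = c("sA", "sB"))
        want <- bruteCnvAssign(segdf, genedf, c("sA", "sB"))
        expect_equal(got, want)
    }
})

test_that("CNV binarization is symmetric and boundary-inclusive", {
    cnv <- namedMatrix(c(0.6, -0.7, 0.5, -0.5, 0.49, 0), 6, 1)
    ev <- binarizeCnv(cnv)
    v <- eventValues(ev)
    expect_equal(unname(v[paste0(rownames(cnv), ":amplification"), 1]),
                 c(1, 0, 1, 0, 0, 0))
    expect_equal(unname(v[paste0(rownames(cnv), ":deletion"), 1]),
                 c(0, 1, 0, 1, 0, 0))
    cnv[1, 1] <- NA
    expect_error(binarizeCnv(cnv), "non-finite")
    expect_error(binarizeCnv(matrix(0, 1, 1), threshold = -1), "threshold")
})

test_that("silent mutations are dropped and presence is binary", {
    maf <- data.frame(
        Hugo_Symbol = c("TP53", "TP53", "KRAS", "KRAS", "EGFR"),
        Tumor_Sample_Barcode = c("s1", "s1", "s2", "s2", "s1"),
        Variant_Classification = c("Silent", "Missense_Mutation",
                                   "Missense_Mutation",
                                   "Nonsense_Mutation", "Intron"))
    ev <- filterSilentMutations(maf)
    v <- eventValues(ev)
    expect_equal(v["TP53:mutation", "s1"], 1)  # missense survives silent
    expect_equal(v["KRAS:mutation", "s2"], 1)  # two rows collapse to 1
    expect_false("EGFR:mutation" %in% rownames(v))  # intron-only dropped
    expect_equal(ncol(v), 2)

    allSilent <- maf[maf$Variant_Classification == "Silent", ]
    ev0 <- filterSilentMutations(allSilent)
    expect_equal(nrow(ev0), 0)

    bl <- filterSilentMutations(maf, blacklist = "TP53")
    expect_false("TP53:mutation" %in% rownames(bl))
    expect_error(filterSilentMutations(maf[, 1:2]), "missing column")
})

test_that("event frequency filter applies inclusive boundaries", {
    mk <- function(carriers) c(rep(1, carriers), rep(0, 200 - carriers))
    v <- rbind(mk(9), mk(10), mk(191), mk(100))
    colnames(v) <- paste0("s", 1:200)
    ev <- EventMatrix(v, paste0("g", 1:4), "mutation")
    kept <- filterEvents(ev)
    expect_identical(rownames(kept), c("g2:mutation", "g4:mutation"))
    ## idempotence
    expect_identical(eventValues(filterEvents(kept)), eventValues(kept))
    expect_error(filterEvents(ev, minFrac = 0.5, maxFrac = 0.4), "minFrac")
})

test_that("hypermodification flag uses a strict threshold", {
    nG <- 150
    v <- cbind(c(rep(1, 101), rep(0, nG - 101)),
               c(rep(1, 100), rep(0, nG - 100)),
               rep(0, nG))
    colnames(v) <- c("over", "at", "none")
    ev <- EventMatrix(v, paste0("g", seq_len(nG)), "mutation")
    flags <- flagHypermodified(ev, genomeSize = 20000)
    expect_true(flags["over"])    # 101/20000 = 0.505% > 0.5%
    expect_false(flags["at"])     # exactly 0.5% is not "more than"
    expect_false(flags["none"])
    expect_error(flagHypermodified(ev, genomeSize = 0), "positive")
    expect_error(flagHypermodified(ev, genomeSize = 10), "distinct genes")
})

test_that("planted CNV truth is recovered through the full round trip", {
    sim <- smallCohort(seed = 21, nSamples = 40, nGenes = 150, nTfs = 1,
                       targetsPerTf = 10,
                       drivers = list(driverEvent("amplification", 0.3,
                                                  1.2),
                                      driverEvent("deletion", 0.25, 0.8)))
    cnv <- assignGeneCnv(cohortSegments(sim), geneModels(sim),
                         samples = colnames(truthEvents(sim)))
    ev <- binarizeCnv(cnv)
    tr <- truthEvents(sim)
    for (id in rownames(tr)[eventClasses(tr) != "mutation"])
        expect_equal(eventValues(ev)[id, ], eventValues(tr)[id, ])
})
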