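test_that("signatures are population z-scores", {
    m <- namedMatrix(c(1, 5, 1,
                       2, 5, 2,
                       3, 5, 3), 3, 3)
    sig <- buildSignature(m)
    ## (1,2,3) with population SD sqrt(2/3)
    expect_equal(unname(sig[1, ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
    ## constant gene -> all-zero row
    expect_equal(unname(sig[2, ]), c(0, 0, 0))
    ## non-degenerate rows have mean 0, population SD 1
    expect_equal(mean(sig[1, ]), 0)
    expect_equal(sqrt(mean(sig[1, ]^2)), 1)
    expect_error(buildSignature(m[, 1:2]), "3 samples")
})

test_that("regulon activity is the scaled signed mean of target signatures", {
    genes <- sprintf("g%03d", 1:20)
    sig <- matrix(0, 20, 4, dimnames = list(genes, paste0("s", 1:4)))
    reg <- Regulon("tf1", genes[1:16], 1)
    sig[1:16, 2] <- 0.5
    act <- regulonActivity(sig, list(reg))
    expect_equal(unname(act["tf1", ]), c(0, 0.5 * 4, 0, 0))  # sqrt(16)*0.5
    ## linearity: negating the signature negates activities
    expect_equal(regulonActivity(-sig, list(reg)), -act)
    ## signed modes flip target contributions
    regNeg <- Regulon("tf1", genes[1:16], -1)
    expect_equal(regulonActivity(sig, list(regNeg)), -act)
    ## regulons without enough usable targets are dropped, then error
    tiny <- Regulon("tf2", sprintf("x%02d", 1:12), 1)
    expect_warning(a2 <- regulonActivity(sig, list(reg, tiny)), "tf2")
    expect_identical(rownames(a2), "tf1")
    expect_error(suppressWarnings(regulonActivity(sig, list(tiny))),
                 "no usable regulons")
})

test_that("null activity variance is ~1 regardless of regulon size", {
    set.seed(8)
    for (nR in c(10, 40, 160)) {
        genes <- sprintf("g%04d", seq_len(nR))
        sig <- matrix(rnorm(nR * 1000), nR, 1000,
                      dimnames = list(genes, NULL))
        colnames(sig) <- sprintf("s%04d", 1:1000)
        act <- regulonActivity(sig, list(Regulon("tf", genes, 1)))
        expect_equal(var(act[1, ]), 1, tolerance = 0.2)
    }
})

test_that("tukey biweight down-weights outliers and respects bounds", {
    expect_equal(tukeyBiweight(c(7, 7, 7)), 7)       # constant
    expect_equal(tukeyBiweight(c(1, 2, 3)), 2)       # symmetric
    expect_equal(tukeyBiweight(c(1, 1, 1, 1, 100)), 1)  # outlier weight 0
    expect_error(tukeyBiweight(numeric(0)), "empty")
    expect_error(tukeyBiweight(c(NA, Inf)), "empty")
    set.seed(2)
    for (i in 1:20) {
        x <- rnorm(sample(3:30, 1), sd = sample(1:5, 1))
        tb <- tukeyBiweight(x)
        expect_gte(tb, min(x))
        expect_lte(tb, max(x))
        expect_equal(tukeyBiweight(sample(x)), tb)   # order-invariant
    }
})

test_that("clustering recovers planted co-expression blocks", {
    set.seed(4)
    base1 <- rnorm(40); base2 <- rnorm(40)
    m <- rbind(t(sapply(1:20, function(i) base1 * (1 + 0.01 * i))),
               t(sapply(1:20, function(i) base2 * (1 + 0.01 * i))))
    dimnames(m) <- list(sprintf("g%03d", 1:40), sprintf("s%03d", 1:40))
    cl <- clusterGenes(m, minSize = 10)
    expect_length(cl, 2)
    expect_setequal(cl[[1]], sprintf("g%03d", 1:20))
    expect_setequal(cl[[2]], sprintf("g%03d", 21:40))
    ## clusters are disjoint and each at least minSize
    expect_equal(anyDuplicated(unlist(cl)), 0)
    expect_true(all(lengths(cl) >= 10))

    ## independent genes mixed in never join the planted blocks
    noise <- namedMatrix(rnorm(30 * 40), 30, 40)
    rownames(noise) <- sprintf("n%03d", 1:30)
    cl2 <- clusterGenes(rbind(m, noise), minSize = 10)
    planted <- lapply(cl2, function(g) {
        inA <- sum(g %in% sprintf("g%03d", 1:20))
        inB <- sum(g %in% sprintf("g%03d", 21:40))
        min(inA, inB)
    })
    expect_true(all(unlist(planted) == 0))
    expect_error(clusterGenes(namedMatrix(1, 12, 5)), "degenerate")
})

test_that("cluster aggregation is a robust average", {
    m <- namedMatrix(rep(2, 50), 10, 5)
    cl <- list(C1 = rownames(m))
    agg <- aggregateClusters(m, cl)
    expect_equal(unname(agg["C1", ]), rep(2, 5))  # constant genes
    ## equals the plain mean when members agree exactly
    m2 <- namedMatrix(rep(seq(1, 5), each = 10), 10, 5)
    expect_equal(unname(aggregateClusters(m2, cl)["C1", ]),
                 colMeans(m2), ignore_attr = TRUE)
    ## one extreme outlier moves the aggregate by < 5%
    set.seed(6)
    m3 <- namedMatrix(rnorm(50, mean = 10), 10, 5)
    base <- aggregateClusters(m3, cl)["C1", 1]
    m3[1, 1] <- 1000
    shifted <- aggregateClusters(m3, cl)["C1", 1]
    expect_lt(abs(shifted - base) / abs(base), 0.05)
    expect_error(aggregateClusters(m3, list(C1 = c("nope", rownames(m3)))),
                 "unknown gene")
})
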