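test_that("dropAllZeroGenes removes exactly the silent genes", {
    m <- rbind(a = c(1, 0, 2), b = c(0, 0, 0), c = c(0, 3, 0))
    dz <- dropAllZeroGenes(m)
    expect_identical(rownames(dz$matrix), c("a", "c"))
    expect_identical(unname(dz$removed), 2L)

    dense <- matrix(1:6, 2)
    expect_identical(dropAllZeroGenes(dense)$matrix, dense)

    set.seed(1)
    for (rep in 1:10) {
        x <- matrix(rbinom(25, 1, 0.3), 5)
        if (all(rowSums(x) == 0)) next
        dz <- dropAllZeroGenes(x)
        expect_identical(unname(dz$removed), which(rowSums(x != 0) == 0))
    }
    expect_error(dropAllZeroGenes(matrix(0, 3, 3)), "all genes")
})

test_that("indexZeros matches a brute-force scan", {
    m <- cbind(c(0, 1.2, 0), c(1, 1, 1))
    expect_identical(indexZeros(m), list(c(1L, 3L), integer(0)))

    set.seed(2)
    x <- matrix(rpois(20 * 30, 1), nrow = 30)
    x <- dropAllZeroGenes(x)$matrix
    zi <- indexZeros(x)
    for (i in seq_len(ncol(x)))
        expect_identical(zi[[i]], which(x[, i] == 0))

    expect_error(indexZeros(rbind(c(0, 0), c(1, 2))), "dropAllZeroGenes")
})

test_that("buildNeighborIndex follows distance then index order", {
    xy <- cbind(c(0, 1, 3), 0)
    nb <- buildNeighborIndex(xy, k = 1)
    expect_identical(as.vector(nb), c(2L, 1L, 2L))

    # k >= n-1: every other spot, sorted by distance
    nb2 <- buildNeighborIndex(xy, k = 2)
    expect_identical(nb2[1, ], c(2L, 3L))
    expect_identical(nb2[3, ], c(2L, 1L))

    expect_warning(nbw <- buildNeighborIndex(xy, k = 5), "reduced")
    expect_equal(ncol(nbw), 2)
    expect_error(buildNeighborIndex(xy[1, , drop = FALSE], 1), "at least 2")

    # duplicate coordinates: ties resolved by ascending index
    dup <- rbind(c(0, 0), c(0, 0), c(0, 0))
    nbd <- buildNeighborIndex(dup, k = 2)
    expect_identical(nbd[1, ], c(2L, 3L))
    expect_identical(nbd[2, ], c(1L, 3L))
    expect_identical(nbd[3, ], c(1L, 2L))

    set.seed(3)
    for (rep in 1:10) {
        n <- sample(9:60, 1)
        coords <- cbind(runif(n), runif(n))
        k <- sample(1:7, 1)
        expect_identical(buildNeighborIndex(coords, k), oracleKnn(coords, k))
    }
})

test_that("zeroRatio counts zero neighbors over realized k", {
    x <- rbind(g = c(0, 0, 0, 2, 3, 0))
    nb <- matrix(2:6, nrow = 1)
    expect_equal(zeroRatio(x, nb, 1, 1), 0.6)
    x2 <- rbind(g = c(0, 1, 2, 3, 4, 5))
    expect_equal(zeroRatio(x2, nb, 1, 1), 0)
    x3 <- rbind(g = c(0, 0, 0, 0, 0, 0))
    expect_equal(zeroRatio(x3, nb, 1, 1), 1)
})

test_that("worked example: neighbor means and the biological-zero rule", {
    # spot 1 at the origin; the 5 others are its neighbors
    coords <- cbind(c(0, 1, 2, 3, 4, 5), 0)
    x <- rbind(g = c(0, 0, 2, 4, 6, 8))
    res <- spaMeanImpute(x, coords, k = 5, delta = 0.4)
    # zero ratio 1/5 = 0.2 <= 0.4 -> mean of non-zero neighbors (2+4+6+8)/4
    expect_identical(unname(res$imputed["g", 1]), 5)
    expect_identical(unname(res$decision[1, 1]), 1L)

    x2 <- rbind(g = c(0, 0, 0, 2, 4, 0))
    res2 <- spaMeanImpute(x2, coords, k = 5, delta = 0.4)
    # zero ratio 3/5 = 0.6 > 0.4 -> retained biological zero
    expect_identical(unname(res2$imputed["g", 1]), 0)
    expect_identical(unname(res2$decision[1, 1]), 2L)
})

test_that("imputation preserves non-zeros, is monotone, and accounts sparsity", {
    set.seed(4)
    for (rep in 1:5) {
        inst <- randomInstance(n = 40, g = 25)
        res <- spaMeanImpute(inst$x, inst$coords, k = 5, delta = 0.4)
        nz <- inst$x != 0
        expect_identical(res$imputed[nz], inst$x[nz])       # bit-identical
        expect_true(all(res$imputed >= inst$x))             # monotone
        rep_ <- res$report
        expect_equal(rep_@zeroSparsityBefore - rep_@zeroSparsityAfter,
                     rep_@dropoutDetectedPct, tolerance = 1e-12)
        expect_equal(rep_@nImputed + rep_@nRetainedBiological +
                     rep_@nSkippedAllZero, rep_@nZeroCandidates)
    }
})

test_that("the number of imputed entries is non-decreasing in delta", {
    set.seed(5)
    inst <- randomInstance(n = 50, g = 20)
    counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(d) {
        spaMeanImpute(inst$x, inst$coords, k = 6, delta = d)$report@nImputed
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("delta boundaries behave as specified", {
    set.seed(6)
    inst <- randomInstance(n = 30, g = 20, density = 0.4)
    nb <- buildNeighborIndex(inst$coords, 6)

    # delta = 1: every zero with a non-zero neighbor is imputed; the rest are
    # skipped because their whole neighborhood is zero
    r1 <- spaMeanImpute(inst$x, inst$coords, k = 6, delta = 1)
    stillZero <- r1$imputed == 0 & inst$x == 0
    expect_identical(which(stillZero), which(r1$decision == 3L))
    expect_equal(r1$report@nRetainedBiological, 0)

    # delta = 0: only zeros whose neighborhood has no zeros at all
    r0 <- spaMeanImpute(inst$x, inst$coords, k = 6, delta = 0)
    imputedPos <- which(r0$decision == 1L, arr.ind = TRUE)
    for (rI in seq_len(nrow(imputedPos))) {
        g <- imputedPos[rI, 1]; s <- imputedPos[rI, 2]
        expect_equal(zeroRatio(inst$x, nb, s, g), 0)
    }
})

test_that("frozen-snapshot result is invariant to spot permutation", {
    set.seed(7)
    inst <- randomInstance(n = 35, g = 15)
    res <- spaMeanImpute(inst$x, inst$coords, k = 4, delta = 0.4)
    perm <- sample(35)
    resP <- spaMeanImpute(inst$x[, perm], inst$coords[perm, ],
                          k = 4, delta = 0.4)
    expect_equal(resP$imputed, res$imputed[, perm])
    expect_equal(resP$decision, res$decision[, perm])
})

test_that("sequential mode matches its in-place loop transcription", {
    set.seed(8)
    inst <- randomInstance(n = 30, g = 12)
    res <- spaMeanImpute(inst$x, inst$coords, k = 5, delta = 0.6,
                         sequential = TRUE)
    expect_equal(res$imputed,
                 oracleImputeSequential(inst$x, inst$coords, 5, 0.6),
                 ignore_attr = TRUE)
})

test_that("frozen and sequential semantics can differ", {
    # chain of spots where an early imputation feeds a later neighborhood
    coords <- cbind(c(0, 1, 2, 3), 0)
    x <- rbind(g = c(2, 0, 0, 0))
    frozen <- spaMeanImpute(x, coords, k = 1, delta = 1)$imputed
    seq_ <- spaMeanImpute(x, coords, k = 1, delta = 1,
                          sequential = TRUE)$imputed
    expect_identical(unname(frozen[1, ]), c(2, 2, 0, 0))
    expect_identical(unname(seq_[1, ]), c(2, 2, 2, 2))
})

test_that("all-zero genes are dropped with a warning before imputation", {
    coords <- cbind(1:4, 0)
    x <- rbind(a = c(1, 0, 2, 1), b = c(0, 0, 0, 0))
    expect_warning(res <- spaMeanImpute(x, coords, k = 2, delta = 0.5),
                   "all-zero")
    expect_identical(rownames(res$imputed), "a")
    expect_identical(unname(res$removedGenes), 2L)
})

test_that("misaligned coordinates are rejected", {
    x <- matrix(1, 2, 4)
    expect_error(spaMeanImpute(x, cbind(1:3, 0), k = 1), "match")
    expect_error(spaMeanImpute(x, cbind(1:4, 0), k = 1, delta = 2),
                 "\\[0, 1\\]")
})

test_that("imputed dropouts correlate positively with the held-out truth", {
    se <- simulateSpatialData(nSpots = 600, nGenes = 80, seed = 11)
    se <- normalizeLog1p(se)
    se <- spaMeanImpute(se, k = 6, delta = 0.4)
    msk <- SummarizedExperiment::assay(se, "dropout")
    dec <- SummarizedExperiment::assay(se, "decision")
    imp <- SummarizedExperiment::assay(se, "imputed")
    tru <- SummarizedExperiment::assay(se, "trueCounts")
    pos <- msk & dec == 1L
    expect_gt(sum(pos), 100)
    expect_gt(stats::cor(tru[pos], imp[pos]), 0)
})

test_that("SpotExperiment method requires coordinates and normalization", {
    m <- matrix(rpois(60, 2) + 1, nrow = 6)
    se <- SpotExperiment(m)   # no coords
    expect_error(spaMeanImpute(se), "spatial")
})
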