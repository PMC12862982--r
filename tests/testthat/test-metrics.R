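randomPair <- function(n = 100, kt = 4, kp = 4) {
    list(truth = sample.int(kt, n, replace = TRUE),
         pred = sample.int(kp, n, replace = TRUE))
}

test_that("contingencyTable counts and marginals reconcile", {
    ct <- contingencyTable(c("a", "a", "b", "b"), c(1, 1, 2, 2))
    expect_equal(unname(ct$nij), diag(c(2, 2)), ignore_attr = TRUE)

    ct2 <- contingencyTable(c("a", "a", "a"), c(1, 2, 3))
    expect_equal(dim(ct2$nij), c(1L, 3L))
    expect_true(all(ct2$nij == 1))

    set.seed(1)
    p <- randomPair(200, 5, 7)
    ct3 <- contingencyTable(p$truth, p$pred)
    expect_equal(sum(ct3$nij), 200)
    expect_equal(sum(ct3$a), 200)
    expect_equal(sum(ct3$b), 200)
    for (tv in unique(p$truth))
        expect_equal(unname(ct3$a[match(tv, unique(p$truth))]),
                     sum(p$truth == tv))
    expect_error(contingencyTable(1:3, 1:4), "equal length")
})

test_that("unannotated spots are dropped pairwise", {
    expect_message(ct <- contingencyTable(c(1, 1, NA, 2), c(1, 1, 2, 2)),
                   "unannotated")
    expect_equal(ct$n, 3)
})

test_that("ARI matches hand evaluation, references, and pair enumeration", {
    expect_equal(ariScore(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
    # 2x2 all-ones contingency table, evaluated by hand: -0.5
    expect_equal(ariScore(c("a", "a", "b", "b"), c(1, 2, 1, 2)), -0.5)

    set.seed(2)
    for (rep in 1:20) {
        p <- randomPair(60, sample(2:5, 1), sample(2:5, 1))
        a <- ariScore(p$truth, p$pred)
        expect_equal(a, oracleAri(p$truth, p$pred), tolerance = 1e-12)
        expect_equal(a, mclust::adjustedRandIndex(p$truth, p$pred),
                     tolerance = 1e-12)
    }
    expect_error(ariScore(1, 1), "fewer than 2")
})

test_that("entropy and mutual information follow the Shannon definitions", {
    expect_equal(shannonEntropy(c(1, 1, 2, 2)), log(2))
    expect_equal(shannonEntropy(rep("x", 5)), 0)

    t <- rep(0:1, each = 4)
    pInd <- rep(rep(0:1, each = 2), 2)   # exact product table
    expect_equal(mutualInfo(t, pInd), 0, tolerance = 1e-12)
    expect_equal(mutualInfo(t, t), shannonEntropy(t))

    set.seed(3)
    for (rep in 1:20) {
        p <- randomPair(80)
        expect_equal(mutualInfo(p$truth, p$pred),
                     oracleMI(p$truth, p$pred), tolerance = 1e-12)
        expect_gte(mutualInfo(p$truth, p$pred), 0)
    }
})

test_that("NMI normalizes by the geometric entropy mean", {
    t <- rep(1:3, each = 10)
    expect_equal(nmiScore(t, t), 1)
    expect_equal(nmiScore(t, c(t[11:30], t[1:10])), 1)   # relabeling

    t2 <- rep(0:1, each = 4)
    expect_equal(nmiScore(t2, rep(rep(0:1, each = 2), 2)), 0,
                 tolerance = 1e-12)

    set.seed(4)
    for (rep in 1:20) {
        p <- randomPair(70)
        expect_equal(nmiScore(p$truth, p$pred),
                     oracleMI(p$truth, p$pred) /
                         sqrt(oracleEntropy(p$truth) * oracleEntropy(p$pred)),
                     tolerance = 1e-12)
    }
    expect_warning(v <- nmiScore(rep(1, 5), c(1, 1, 2, 2, 3)), "degenerate")
    expect_equal(v, 0)
})

test_that("AMI corrects MI by its hypergeometric expectation", {
    t <- rep(1:4, each = 5)
    expect_equal(amiScore(t, t), 1)
    set.seed(5)
    for (rep in 1:10) {
        p <- randomPair(60, 3, 4)
        expect_equal(amiScore(p$truth, p$pred), oracleAmi(p$truth, p$pred),
                     tolerance = 1e-9)
    }
})

test_that("homogeneity is 1 for refinements and 0 for a single cluster", {
    t <- c(1, 1, 2, 2)
    expect_equal(homogeneityScore(t, c(1, 2, 3, 4)), 1)  # refinement
    expect_equal(homogeneityScore(t, c(1, 1, 2, 2)), 1)
    expect_equal(homogeneityScore(t, rep(1, 4)), 0)      # H(T|P) = H(T)
    # refinement scores 1 on homogeneity but below 1 on ARI
    expect_lt(ariScore(t, c(1, 2, 3, 4)), 1)

    set.seed(6)
    for (rep in 1:20) {
        p <- randomPair(70)
        expect_equal(homogeneityScore(p$truth, p$pred),
                     1 - oracleCondEntropy(p$truth, p$pred) /
                         oracleEntropy(p$truth),
                     tolerance = 1e-12)
    }
    expect_warning(v <- homogeneityScore(rep(1, 4), c(1, 2, 1, 2)),
                   "single-class")
    expect_equal(v, 1)
})

test_that("all metrics are invariant to label renaming", {
    set.seed(7)
    p <- randomPair(80, 4, 3)
    m0 <- clusteringMetrics(p$truth, p$pred)
    relabelT <- c("d", "c", "b", "a")[p$truth]
    relabelP <- c(30, 10, 20)[p$pred]
    m1 <- suppressWarnings(clusteringMetrics(relabelT, relabelP))
    expect_equal(unname(m1), unname(m0), tolerance = 1e-12)
})

test_that("zeroSparsity counts exact zeros as a percentage", {
    expect_equal(zeroSparsity(matrix(0, 3, 3)), 100)
    expect_equal(zeroSparsity(matrix(1:6, 2)), 0)
    m <- matrix(1, 10, 10)
    m[sample(100, 37)] <- 0
    expect_equal(zeroSparsity(m), 37)
    expect_error(zeroSparsity(matrix(numeric(0), 0, 0)), "empty")

    se <- simulateSpatialData(nSpots = 50, nGenes = 10, seed = 1)
    expect_equal(zeroSparsity(se),
                 zeroSparsity(SummarizedExperiment::assay(se, "counts")))
})

test_that("recoveryStats reports correlations and the recovered fraction", {
    v <- c(1, 2, 3, 4)
    perfect <- recoveryStats(v, v)
    expect_equal(perfect$pcc, 1)
    expect_equal(perfect$src, 1)
    expect_equal(perfect$ktc, 1)
    expect_equal(perfect$recoveredFraction, 1)

    expect_warning(zeroed <- recoveryStats(v, rep(0, 4)), "constant")
    expect_equal(zeroed$recoveredFraction, 0)
    expect_true(is.na(zeroed$pcc))

    # monotone nonlinear distortion: rank correlations stay 1, Pearson drops
    dist <- recoveryStats(v, exp(v))
    expect_equal(dist$src, 1)
    expect_equal(dist$ktc, 1)
    expect_lt(dist$pcc, 1)

    expect_error(recoveryStats(1:3, 1:4), "aligned")
})

test_that("evalRecovery pulls masked positions from the imputed matrix", {
    set.seed(8)
    m <- matrix(rpois(100, 3) + 1, 10)
    mk <- maskNonzero(m, 0.1, seed = 1)
    rs <- evalRecovery(m, mk$evalMask)   # "impute" with the truth itself
    expect_equal(rs$pcc, 1)
    expect_equal(rs$recoveredFraction, 1)
})
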