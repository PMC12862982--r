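#' Contingency table of two labelings
#'
#' Cross-tabulates true classes against predicted clusters, with categories
#' mapped by first appearance. The counts n_ij, the row sums a_i, column sums
#' b_j and the total n are the ingredients of every clustering-agreement
#' metric in the package.
#'
#' @param truth,pred equal-length label vectors (any atomic type; `NA`
#'   entries are dropped pairwise with a message).
#' @return list with `nij` (matrix of counts), `a` (row sums), `b` (column
#'   sums) and `n` (total).
#' @examples
#' contingencyTable(c("a", "a", "b", "b"), c(1, 1, 2, 2))$nij
#' @export
contingencyTable <- function(truth, pred) {
    if (length(truth) != length(pred))
        stop("'truth' (", length(truth), ") and 'pred' (", length(pred),
             ") must have equal length")
    keep <- !is.na(truth) & !is.na(pred)
    if (!all(keep)) {
        message(sum(!keep), " unannotated spot(s) dropped from the label pair")
        truth <- truth[keep]; pred <- pred[keep]
    }
    if (!length(truth))
        stop("no annotated spots left after dropping missing labels")
    tf <- factor(truth, levels = unique(truth))
    pf <- factor(pred, levels = unique(pred))
    nij <- unclass(table(tf, pf))
    dimnames(nij) <- unname(dimnames(nij))
    list(nij = nij, a = rowSums(nij), b = colSums(nij), n = sum(nij))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance:
#' 1 for identical partitions (up to relabeling), approximately 0 in
#' expectation for independent random labelings, negative for agreement
#' below chance.
#'
#' @inheritParams contingencyTable
#' @return numeric in \[-1, 1\].
#' @examples
#' ariScore(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
ariScore <- function(truth, pred) {
    ct <- contingencyTable(truth, pred)
    if (ct$n < 2)
        stop("ARI is undefined for fewer than 2 spots")
    sumNij <- sum(choose(ct$nij, 2))
    sumA <- sum(choose(ct$a, 2))
    sumB <- sum(choose(ct$b, 2))
    expected <- sumA * sumB / choose(ct$n, 2)
    maxIdx <- (sumA + sumB) / 2
    if (maxIdx == expected) return(1)    # both partitions trivial
    (sumNij - expected) / (maxIdx - expected)
}

#' Shannon entropy of a labeling (nats)
#'
#' @param labels label vector.
#' @return non-negative numeric, `-sum(p * log(p))` over the empirical label
#'   frequencies.
#' @examples
#' shannonEntropy(c(1, 1, 2, 2))  # log(2)
#' @export
shannonEntropy <- function(labels) {
    if (!length(labels)) stop("'labels' must be non-empty")
    p <- as.numeric(table(labels)) / length(labels)
    p <- p[p > 0]
    -sum(p * log(p))
}

#' Mutual information between two labelings (nats)
#'
#' `MI(T, P) = H(T) - H(T|P)`, evaluated from the contingency table as
#' `sum_ij (n_ij/n) log(n n_ij / (a_i b_j))`. Always non-negative;
#' `MI(T, T) = H(T)`.
#'
#' @inheritParams contingencyTable
#' @return non-negative numeric.
#' @export
mutualInfo <- function(truth, pred) {
    ct <- contingencyTable(truth, pred)
    .miFromTable(ct)
}

.miFromTable <- function(ct) {
    nij <- ct$nij; n <- ct$n
    ao <- outer(ct$a, ct$b)
    pos <- nij > 0
    sum(nij[pos] / n * log(n * nij[pos] / ao[pos]))
}

.condEntropyTP <- function(ct) {
    # H(T|P) = -sum_ij (nij/n) log(nij/bj)
    nij <- ct$nij; n <- ct$n
    bj <- matrix(ct$b, nrow = nrow(nij), ncol = ncol(nij), byrow = TRUE)
    pos <- nij > 0
    -sum(nij[pos] / n * log(nij[pos] / bj[pos]))
}

#' Normalized mutual information
#'
#' Mutual information normalized by the geometric mean of the two label
#' entropies, `MI / sqrt(H(T) H(P))`; 1 for identical partitions (up to
#' relabeling), 0 for independent labelings. A degenerate single-class
#' labeling on either side is defined as 0 with a warning.
#'
#' @inheritParams contingencyTable
#' @return numeric in \[0, 1\].
#' @export
nmiScore <- function(truth, pred) {
    ct <- contingencyTable(truth, pred)
    ht <- shannonEntropy(rep(seq_along(ct$a), ct$a))
    hp <- shannonEntropy(rep(seq_along(ct$b), ct$b))
    if (ht == 0 || hp == 0) {
        warning("degenerate single-class labeling; NMI defined as 0")
        return(0)
    }
    .miFromTable(ct) / sqrt(ht * hp)
}

# Expected mutual information under the permutation (hypergeometric) model
# with fixed marginals a, b: the conventional chance model for AMI.
.expectedMI <- function(a, b, n) {
    emi <- 0
    lfn <- lgamma(n + 1)
    for (ai in a) {
        for (bj in b) {
            lo <- max(1L, ai + bj - n)
            hi <- min(ai, bj)
            if (hi < lo) next
            nij <- lo:hi
            logP <- lgamma(ai + 1) + lgamma(bj + 1) +
                lgamma(n - ai + 1) + lgamma(n - bj + 1) -
                lfn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
                lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
            emi <- emi + sum(exp(logP) * nij / n * log(n * nij / (ai * bj)))
        }
    }
    emi
}

#' Adjusted mutual information
#'
#' Mutual information corrected for the expected MI of random labelings with
#' the same marginals (hypergeometric model) and normalized by the arithmetic
#' mean of the entropies:
#' `(MI - E[MI]) / (mean(H(T), H(P)) - E[MI])`. 1 for identical partitions,
#' approximately 0 in expectation for independent random labelings; may be
#' negative.
#'
#' @inheritParams contingencyTable
#' @return numeric <= 1.
#' @export
amiScore <- function(truth, pred) {
    ct <- contingencyTable(truth, pred)
    ht <- shannonEntropy(rep(seq_along(ct$a), ct$a))
    hp <- shannonEntropy(rep(seq_along(ct$b), ct$b))
    if (ht == 0 && hp == 0) {
        warning("both labelings are single-class; AMI defined as 1")
        return(1)
    }
    mi <- .miFromTable(ct)
    emi <- .expectedMI(ct$a, ct$b, ct$n)
    denom <- mean(c(ht, hp)) - emi
    if (abs(denom) < .Machine$double.eps * 4) {
        warning("degenerate AMI denominator; defined as 0")
        return(0)
    }
    (mi - emi) / denom
}

#' Homogeneity score
#'
#' `1 - H(T|P) / H(T)`: equals 1 exactly when every predicted cluster
#' contains spots from a single true class (the prediction refines the
#' truth), 0 when the prediction carries no information about the truth.
#' A truth with a single class is defined as 1 with a warning.
#'
#' @inheritParams contingencyTable
#' @return numeric in \[0, 1\].
#' @examples
#' homogeneityScore(c(1, 1, 2, 2), c(1, 2, 3, 4))  # refinement: 1
#' @export
homogeneityScore <- function(truth, pred) {
    ct <- contingencyTable(truth, pred)
    ht <- shannonEntropy(rep(seq_along(ct$a), ct$a))
    if (ht == 0) {
        warning("single-class truth; homogeneity defined as 1")
        return(1)
    }
    1 - .condEntropyTP(ct) / ht
}

#' All four clustering-agreement metrics at once
#'
#' @inheritParams contingencyTable
#' @return named numeric vector with elements `ari`, `nmi`, `ami`, `homo`.
#' @examples
#' clusteringMetrics(rep(1:2, each = 5), rep(1:2, each = 5))
#' @export
clusteringMetrics <- function(truth, pred) {
    c(ari = ariScore(truth, pred),
      nmi = nmiScore(truth, pred),
      ami = amiScore(truth, pred),
      homo = homogeneityScore(truth, pred))
}

#' Percentage of exactly-zero entries
#'
#' @param x matrix or [SpotExperiment-class].
#' @param assayName assay to measure (SpotExperiment method); default
#'   `"counts"`.
#' @param ... passed between methods.
#' @return numeric in \[0, 100\].
#' @examples
#' zeroSparsity(matrix(c(0, 1, 0, 1), 2))  # 50
#' @rdname zeroSparsity
#' @export
setMethod("zeroSparsity", "ANY", function(x, ...) {
    if (length(x) == 0)
        stop("cannot compute sparsity of an empty matrix")
    100 * sum(x == 0) / length(x)
})

#' @rdname zeroSparsity
#' @export
setMethod("zeroSparsity", "SpotExperiment",
    function(x, assayName = "counts", ...) {
    zeroSparsity(SummarizedExperiment::assay(x, assayName))
})

#' Masked-entry recovery statistics
#'
#' Agreement between imputed and held-out true values at masked positions:
#' Pearson (PCC), Spearman (SRC) and Kendall (KTC) correlations, plus the
#' fraction of masked entries assigned a non-zero imputed value. Constant
#' vectors make the correlations undefined; they are returned as `NA` with a
#' warning.
#'
#' @param trueValues numeric vector of the original (pre-mask) values.
#' @param imputedValues numeric vector of the values after imputation, aligned
#'   with `trueValues`.
#' @return named list: `pcc`, `src`, `ktc`, `recoveredFraction`.
#' @examples
#' recoveryStats(c(1, 2, 3), c(1.1, 2.2, 2.9))
#' @export
recoveryStats <- function(trueValues, imputedValues) {
    if (length(trueValues) != length(imputedValues))
        stop("value vectors must be aligned")
    if (!length(trueValues))
        stop("the evaluation mask is empty")
    constant <- stats::sd(trueValues) == 0 || stats::sd(imputedValues) == 0
    if (constant) {
        warning("constant values; correlations are undefined (NA)")
        pcc <- src <- ktc <- NA_real_
    } else {
        pcc <- stats::cor(trueValues, imputedValues, method = "pearson")
        src <- stats::cor(trueValues, imputedValues, method = "spearman")
        ktc <- stats::cor(trueValues, imputedValues, method = "kendall")
    }
    list(pcc = pcc, src = src, ktc = ktc,
         recoveredFraction = mean(imputedValues > 0))
}

#' Recovery statistics from an imputed matrix and an evaluation mask
#'
#' Convenience wrapper around [recoveryStats()] taking the imputed matrix and
#' the `evalMask` data.frame produced by [maskNonzero()].
#'
#' @param imputed genes x spots imputed matrix.
#' @param evalMask data.frame with columns `gene`, `spot`, `value`.
#' @return as [recoveryStats()].
#' @export
evalRecovery <- function(imputed, evalMask) {
    stopifnot(all(c("gene", "spot", "value") %in% colnames(evalMask)))
    got <- imputed[cbind(evalMask$gene, evalMask$spot)]
    recoveryStats(evalMask$value, got)
}
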