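# Independent reference implementations used to cross-check the package.
# These deliberately use different code paths (explicit loops, dhyper, pair
# enumeration) from the vectorized implementations they verify.

# Exhaustive nearest-neighbor search: per-spot distance recomputation and a
# (distance, index) sort.
oracleKnn <- function(coords, k) {
    n <- nrow(coords)
    kEff <- min(k, n - 1)
    nb <- matrix(0L, n, kEff)
    for (i in seq_len(n)) {
        d <- sqrt((coords[, 1] - coords[i, 1])^2 +
                  (coords[, 2] - coords[i, 2])^2)
        ord <- order(d, seq_len(n))
        ord <- ord[ord != i]
        nb[i, ] <- ord[seq_len(kEff)]
    }
    nb
}

# Direct loop transcription of the imputation procedure with frozen-snapshot
# reads: for each spot, find its neighbors, and for each zero gene compute the
# zero ratio across neighbors; impute with the mean of non-zero neighbor
# values when the ratio is at most delta and a non-zero neighbor exists.
oracleImpute <- function(x, coords, k, delta) {
    n <- ncol(x)
    kEff <- min(k, n - 1)
    out <- x
    for (i in seq_len(n)) {
        d <- sqrt((coords[, 1] - coords[i, 1])^2 +
                  (coords[, 2] - coords[i, 2])^2)
        ord <- order(d, seq_len(n))
        ord <- ord[ord != i]
        nb <- ord[seq_len(kEff)]
        for (j in which(x[, i] == 0)) {
            v <- x[j, nb]
            if (sum(v == 0) / kEff <= delta) {
                nzv <- v[v != 0]
                if (length(nzv) > 0) out[j, i] <- mean(nzv)
            }
        }
    }
    out
}

# Sequential variant: reads the matrix as it is being updated, spot by spot.
oracleImputeSequential <- function(x, coords, k, delta) {
    n <- ncol(x)
    kEff <- min(k, n - 1)
    for (i in seq_len(n)) {
        d <- sqrt((coords[, 1] - coords[i, 1])^2 +
                  (coords[, 2] - coords[i, 2])^2)
        ord <- order(d, seq_len(n))
        ord <- ord[ord != i]
        nb <- ord[seq_len(kEff)]
        for (j in which(x[, i] == 0)) {
            v <- x[j, nb]
            if (sum(v == 0) / kEff <= delta) {
                nzv <- v[v != 0]
                if (length(nzv) > 0) x[j, i] <- mean(nzv)
            }
        }
    }
    x
}

# Pair-enumeration ARI: counts agreeing/disagreeing spot pairs directly.
oracleAri <- function(truth, pred) {
    n <- length(truth)
    n11 <- n00 <- n10 <- n01 <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            st <- truth[i] == truth[j]
            sp <- pred[i] == pred[j]
            if (st && sp) n11 <- n11 + 1
            else if (!st && !sp) n00 <- n00 + 1
            else if (st && !sp) n10 <- n10 + 1
            else n01 <- n01 + 1
        }
    }
    den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
    if (den == 0) return(1)
    2 * (n11 * n00 - n10 * n01) / den
}

# Entropy / MI / conditional entropy by explicit counting loops.
oracleEntropy <- function(labels) {
    h <- 0
    for (lv in unique(labels)) {
        p <- mean(labels == lv)
        h <- h - p * log(p)
    }
    h
}

oracleMI <- function(truth, pred) {
    n <- length(truth)
    mi <- 0
    for (tv in unique(truth)) {
        for (pv in unique(pred)) {
            nij <- sum(truth == tv & pred == pv)
            if (nij == 0) next
            ai <- sum(truth == tv)
            bj <- sum(pred == pv)
            mi <- mi + nij / n * log(n * nij / (ai * bj))
        }
    }
    mi
}

oracleCondEntropy <- function(truth, pred) {
    # H(T|P)
    n <- length(truth)
    h <- 0
    for (pv in unique(pred)) {
        sel <- pred == pv
        for (tv in unique(truth[sel])) {
            nij <- sum(truth == tv & sel)
            h <- h - nij / n * log(nij / sum(sel))
        }
    }
    h
}

# Expected MI under fixed marginals via the exact hypergeometric pmf.
oracleExpectedMI <- function(truth, pred) {
    n <- length(truth)
    a <- as.numeric(table(truth))
    b <- as.numeric(table(pred))
    emi <- 0
    for (ai in a) {
        for (bj in b) {
            xs <- max(1, ai + bj - n):min(ai, bj)
            xs <- xs[xs >= 1]
            if (!length(xs)) next
            pr <- stats::dhyper(xs, ai, n - ai, bj)
            emi <- emi + sum(pr * xs / n * log(n * xs / (ai * bj)))
        }
    }
    emi
}

oracleAmi <- function(truth, pred) {
    mi <- oracleMI(truth, pred)
    emi <- oracleExpectedMI(truth, pred)
    ht <- oracleEntropy(truth)
    hp <- oracleEntropy(pred)
    (mi - emi) / (mean(c(ht, hp)) - emi)
}

# 4-neighborhood contiguity check on a lattice: TRUE when every label forms a
# single connected component. Works on the grid layout (integer coordinates).
isContiguous <- function(coords, labels) {
    key <- function(x, y) paste(x, y)
    for (lv in unique(labels)) {
        idx <- which(labels == lv)
        present <- new.env(parent = emptyenv())
        for (i in idx) assign(key(coords[i, 1], coords[i, 2]), i, present)
        seen <- new.env(parent = emptyenv())
        queue <- idx[1]
        assign(key(coords[idx[1], 1], coords[idx[1], 2]), TRUE, seen)
        count <- 0
        while (length(queue)) {
            i <- queue[1]; queue <- queue[-1]
            count <- count + 1
            for (dxy in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
                kk <- key(coords[i, 1] + dxy[1], coords[i, 2] + dxy[2])
                if (!is.null(mget(kk, present, ifnotfound = list(NULL))[[1]]) &&
                    is.null(mget(kk, seen, ifnotfound = list(NULL))[[1]])) {
                    assign(kk, TRUE, seen)
                    queue <- c(queue, get(kk, present))
                }
            }
        }
        if (count != length(idx)) return(FALSE)
    }
    TRUE
}

# Small random count matrix with spot coordinates, for property tests.
randomInstance <- function(n, g, density = 0.5, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    x <- matrix(as.numeric(rpois(n * g, 2) * rbinom(n * g, 1, density)),
                nrow = g)
    # guard: no all-zero gene, so instances exercise imputation not gene drops
    for (j in which(rowSums(x != 0) == 0)) x[j, sample(n, 1)] <- 1
    coords <- cbind(runif(n), runif(n))
    list(x = x, coords = coords)
}
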