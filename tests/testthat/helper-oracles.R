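# Independent brute-force oracles used against the package implementations.
# Each is written from the defining formula, never by calling the function it
# checks.

# BH step-up by the literal min-over-tail definition:
# q_(i) = min_{j >= i} min(p_(j) * n / j, 1) over the sorted order
bhBrute <- function(p) {
    n <- length(p)
    ord <- order(p)
    ps <- p[ord]
    qs <- numeric(n)
    for (i in seq_len(n))
        qs[i] <- min(vapply(i:n, function(j) min(ps[j] * n / j, 1),
                            numeric(1)))
    out <- numeric(n)
    out[ord] <- qs
    out
}

# AUC as explicit pairwise concordance with half credit for ties
aucBrute <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    s <- 0
    for (a in pos) for (b in neg)
        s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
}

# Jaccard distance from the set formula
jaccardBrute <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) return(0)
    1 - sum(a & b) / u
}

# Exhaustive PAM: minimum total cost over all medoid subsets of size k
pamExhaustive <- function(D, k) {
    n <- nrow(D)
    best <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
        cost <- sum(apply(D[, med, drop = FALSE], 1, min))
        if (cost < best) { best <- cost; bestMed <- med }
    }
    list(cost = best, medoids = bestMed)
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings
mwExactEnum <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    obs <- uStat(x, y)
    n <- length(pooled)
    mu <- n1 * (n - n1) / 2
    combs <- utils::combn(n, n1, simplify = FALSE)
    us <- vapply(combs, function(i) uStat(pooled[i], pooled[-i]), numeric(1))
    mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Net benefit from an explicit contingency table
netBenefitBrute <- function(p, y, pt) {
    n <- length(y)
    tp <- sum(p >= pt & y == 1)
    fp <- sum(p >= pt & y == 0)
    tp / n - fp / n * pt / (1 - pt)
}

# Trustworthiness of an embedding at neighborhood size k
trustworthiness <- function(X, Y, k = 5) {
    n <- nrow(X)
    rankX <- t(apply(as.matrix(dist(X)), 1, rank, ties.method = "first"))
    dY <- as.matrix(dist(Y))
    s <- 0
    for (i in seq_len(n)) {
        nnY <- order(dY[i, ])[2:(k + 1)]
        for (j in nnY) {
            r <- rankX[i, j] - 1          # rank among others (self = rank 1)
            if (r > k) s <- s + (r - k)
        }
    }
    1 - 2 / (n * k * (2 * n - 3 * k - 1)) * s
}

# cluster purity of labels vs ground truth
clusterPurity <- function(labels, truth) {
    sum(vapply(unique(labels), function(l)
        max(table(truth[labels == l])), numeric(1))) / length(truth)
}

smallCohort <- function(nP = 12, nC = 8, seed = 11, effectScale = 1) {
    cfg <- simulationConfig(nPatients = nP, nControls = nC,
                            effectSizes = defaultEffectSizes() * effectScale,
                            seed = seed)
    generateCohort(cfg)
}

# three well-separated Gaussian blobs, n per blob, p features
blobData <- function(n = 50, p = 6, sep = 10, seed = 1) {
    withr::with_seed(seed, {
        centers <- matrix(rnorm(3 * p), 3, p)
        centers <- centers / sqrt(rowSums(centers^2)) * sep
        X <- do.call(rbind, lapply(1:3, function(b)
            matrix(rnorm(n * p), n, p) + centers[rep(b, n), ]))
        list(X = X, truth = rep(1:3, each = n))
    })
}
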