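#' Jaccard distance matrix over binary clinical features
#'
#' \code{d(a, b) = 1 - |a AND b| / |a OR b|}. Two all-zero rows are at
#' distance 0 by convention: patients with no recorded findings are
#' identical under this feature set. Rows containing any missing value are
#' excluded and reported in the \code{"excluded"} attribute.
#'
#' @param binaryMatrix samples-by-features matrix with entries in {0, 1, NA}.
#' @return symmetric distance matrix in [0, 1] with zero diagonal over the
#'   complete rows.
#' @export
jaccardDistanceMatrix <- function(binaryMatrix) {
    B <- as.matrix(binaryMatrix)
    if (!all(B %in% c(0, 1, NA))) stop("entries must be 0, 1 or NA")
    complete <- rowSums(is.na(B)) == 0
    excluded <- rownames(B)[!complete]
    B <- B[complete, , drop = FALSE]
    inter <- tcrossprod(B)
    size <- rowSums(B)
    union <- outer(size, size, `+`) - inter
    D <- 1 - inter / union
    D[union == 0] <- 0        # both rows all-zero
    diag(D) <- 0
    dimnames(D) <- list(rownames(B), rownames(B))
    attr(D, "excluded") <- excluded
    D
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson double-centering eigendecomposition; negative eigenvalues are
#' truncated at zero.
#'
#' @param distanceMatrix symmetric distance matrix with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @return samples-by-dims coordinate matrix.
#' @export
classicalMDS <- function(distanceMatrix, dims = 2) {
    D <- as.matrix(distanceMatrix)
    if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric")
    fit <- stats::cmdscale(stats::as.dist(D), k = dims)
    if (ncol(fit) < dims)      # rank-deficient configurations pad with zeros
        fit <- cbind(fit, matrix(0, nrow(fit), dims - ncol(fit)))
    colnames(fit) <- paste0("mds", seq_len(dims))
    fit
}

#' Partitioning around medoids
#'
#' k-medoids clustering on an arbitrary distance matrix, minimizing the sum
#' of distances of every point to its nearest medoid. Small instances
#' (\code{choose(n, k)} medoid sets up to \code{exactLimit}) are solved
#' exactly by enumerating every medoid set — this covers clinical cohorts of
#' the size this package targets; larger instances use the classic BUILD
#' initialization plus SWAP steps until no medoid/non-medoid exchange lowers
#' the total cost. Fully deterministic: every tie is broken by the lowest
#' index.
#'
#' @param distanceMatrix symmetric distance matrix.
#' @param k number of clusters, 2 <= k <= n (k = n gives singletons).
#' @param exactLimit maximum number of candidate medoid sets for the exact
#'   enumeration path (default 20000).
#' @return list with \code{medoids} (indices), \code{labels} (cluster id per
#'   sample, numbered by medoid order), \code{cost} and \code{exact}.
#' @export
pamCluster <- function(distanceMatrix, k, exactLimit = 20000) {
    D <- as.matrix(distanceMatrix)
    n <- nrow(D)
    if (k < 1 || k > n) stop("k out of range (need 1 <= k <= n)")
    totalCost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
    exact <- choose(n, k) <= exactLimit
    if (exact) {
        best <- Inf; med <- seq_len(k)
        for (cand in utils::combn(n, k, simplify = FALSE)) {
            cc <- totalCost(cand)
            if (cc < best - 1e-12) { best <- cc; med <- cand }
        }
        med <- sort(med)
        labels <- apply(D[, med, drop = FALSE], 1, which.min)
        return(list(medoids = unname(med), labels = as.integer(labels),
                    cost = best, exact = TRUE))
    }
    # BUILD: first medoid minimizes total distance; then greedy additions
    med <- which.min(colSums(D))
    while (length(med) < k) {
        best <- c(idx = NA, cost = Inf)
        nearest <- apply(D[, med, drop = FALSE], 1, min)
        for (j in setdiff(seq_len(n), med)) {
            cost <- sum(pmin(nearest, D[, j]))
            if (cost < best["cost"]) best <- c(idx = j, cost = cost)
        }
        med <- c(med, best[["idx"]])
    }
    cost <- totalCost(med)
    # SWAP until local optimum
    repeat {
        improved <- FALSE
        for (mi in seq_along(med)) {
            for (j in setdiff(seq_len(n), med)) {
                cand <- med; cand[mi] <- j
                cc <- totalCost(cand)
                if (cc < cost - 1e-12) {
                    med <- cand; cost <- cc; improved <- TRUE
                }
            }
        }
        if (!improved) break
    }
    med <- sort(med)
    labels <- apply(D[, med, drop = FALSE], 1, which.min)
    list(medoids = unname(med), labels = as.integer(labels),
         cost = totalCost(med), exact = FALSE)
}

#' Feature importance for a clinical partition
#'
#' Permutation importance of each binary feature: permute the feature's
#' column across samples, recompute the Jaccard/PAM partition, and record
#' \code{1 - ARI} against the original partition; the importance is the mean
#' over permutations, clipped at 0. Features whose shuffling does not move
#' the partition score near zero.
#'
#' @param binaryMatrix samples-by-features binary matrix (complete rows).
#' @param labels original cluster labels.
#' @param nPerm permutations per feature (>= 50; default 100).
#' @param seed integer seed.
#' @param k number of clusters to recompute (default: number of distinct
#'   labels).
#' @return named numeric vector of importances, sorted decreasing.
#' @export
clusterFeatureImportance <- function(binaryMatrix, labels, nPerm = 100,
                                     seed = 1L, k = length(unique(labels))) {
    if (nPerm < 50) stop("nPerm must be >= 50")
    if (length(unique(labels)) < 2)
        stop("constant partition: importance undefined")
    B <- as.matrix(binaryMatrix)
    imp <- withr::with_seed(seed, {
        vapply(colnames(B), function(feat) {
            drops <- vapply(seq_len(nPerm), function(p) {
                Bp <- B
                Bp[, feat] <- sample(Bp[, feat])
                lp <- pamCluster(jaccardDistanceMatrix(Bp), k)$labels
                1 - mclust::adjustedRandIndex(labels, lp)
            }, numeric(1))
            max(mean(drops), 0)
        }, numeric(1))
    })
    sort(imp, decreasing = TRUE)
}

#' Map clinical clusters to severity tiers
#'
#' For k = 3 clusters, orders clusters by mean CDS: lowest becomes
#' \code{mild}, middle \code{moderate}, highest \code{severe}. Ties are
#' broken by cluster size (the larger cluster ranks as more severe). For
#' k != 3 tiering is undefined and the labels are returned untiered.
#'
#' @param labels cluster labels per sample.
#' @param cds numeric CDS per sample (same order).
#' @return list with \code{tierPerCluster} (named character) and
#'   \code{tierPerSample}; both NULL with a warning when k != 3.
#' @export
mapSeverity <- function(labels, cds) {
    cl <- sort(unique(labels))
    if (length(cl) != 3) {
        warning("severity tiering is defined for k = 3 only; returning NULL")
        return(list(tierPerCluster = NULL, tierPerSample = NULL))
    }
    meanCds <- vapply(cl, function(c) mean(cds[labels == c]), numeric(1))
    size <- vapply(cl, function(c) sum(labels == c), numeric(1))
    ord <- order(meanCds, size)   # ties: larger cluster -> more severe
    tiers <- c("mild", "moderate", "severe")
    tierPerCluster <- stats::setNames(character(3), cl[ord])
    tierPerCluster[as.character(cl[ord])] <- tiers
    tierPerSample <- tierPerCluster[as.character(labels)]
    list(tierPerCluster = tierPerCluster[as.character(cl)],
         tierPerSample = unname(tierPerSample))
}

#' Cluster patients by binary clinical features
#'
#' Convenience wrapper chaining \code{\link{jaccardDistanceMatrix}},
#' \code{\link{classicalMDS}}, \code{\link{pamCluster}} and (for k = 3)
#' \code{\link{mapSeverity}}.
#'
#' @param binaryMatrix samples-by-features binary matrix.
#' @param k number of clusters (default 3).
#' @param cds optional CDS per retained sample, enabling severity tiers.
#' @return list with \code{distance}, \code{mds}, \code{medoids},
#'   \code{labels}, \code{tiers}, \code{excluded}.
#' @export
clusterClinical <- function(binaryMatrix, k = 3, cds = NULL) {
    D <- jaccardDistanceMatrix(binaryMatrix)
    pam <- pamCluster(D, k)
    tiers <- NULL
    if (!is.null(cds) && k == 3) {
        keep <- setdiff(rownames(binaryMatrix), attr(D, "excluded"))
        if (!is.null(names(cds))) cds <- cds[keep]
        tiers <- mapSeverity(pam$labels, cds)
    }
    list(distance = D, mds = classicalMDS(D), medoids = pam$medoids,
         labels = pam$labels, tiers = tiers, excluded = attr(D, "excluded"))
}
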