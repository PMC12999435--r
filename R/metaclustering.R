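#' Train a self-organizing map on sample immunophenotypes
#'
#' Online Kohonen training: features are z-standardized against the full
#' cohort, the codebook is initialized from randomly drawn samples, and for
#' every presented sample the best-matching unit and its Gaussian grid
#' neighborhood move toward the sample with a linearly decaying learning rate
#' and neighborhood radius. Deterministic for a fixed seed.
#'
#' @param features samples-by-features numeric matrix (finite values).
#' @param grid integer length-2, SOM grid rows x cols (each >= 2).
#' @param epochs full passes over the data (default 200).
#' @param alpha0 initial learning rate (decays linearly to 0.01).
#' @param seed integer seed.
#' @return a \code{SOMModel} list: \code{codebook} (nodes x features, on the
#'   standardized scale), \code{grid}, \code{gridCoords}, \code{center} /
#'   \code{scale} used for standardization, \code{bmu} (training-sample
#'   best-matching units), and the hyperparameters.
#' @export
trainSOM <- function(features, grid = c(4, 4), epochs = 200, alpha0 = 0.5,
                     seed = 1L) {
    X <- as.matrix(features)
    if (any(!is.finite(X))) stop("non-finite features")
    if (length(grid) != 2 || any(grid < 2)) stop("grid must be at least 2x2")
    nNodes <- prod(grid)
    if (nrow(X) < nNodes)
        warning("fewer samples (", nrow(X), ") than SOM nodes (", nNodes, ")")
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
    gridCoords <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                        col = seq_len(grid[2])))
    gridD2 <- as.matrix(stats::dist(gridCoords))^2
    radius0 <- sqrt(sum((grid - 1)^2)) / 2
    n <- nrow(Z)
    total <- epochs * n
    withr::with_seed(seed, {
        codebook <- Z[sample(seq_len(n), nNodes, replace = nNodes > n), ,
                      drop = FALSE]
        rownames(codebook) <- paste0("node", seq_len(nNodes))
        t0 <- 0
        for (ep in seq_len(epochs)) {
            ord <- sample(seq_len(n))
            for (i in ord) {
                frac <- t0 / total
                alpha <- alpha0 * (1 - frac) + 0.01 * alpha0 * frac
                radius <- max(radius0 + (1 - radius0) * frac, 1)
                if (alpha > 0) {
                    d2 <- rowSums(sweep(codebook, 2, Z[i, ])^2)
                    bmu <- which.min(d2)
                    # Gaussian neighborhood with sigma = radius/2, truncated
                    # beyond the radius so the map sharpens as it shrinks
                    h <- exp(-gridD2[bmu, ] / (2 * (radius / 2)^2))
                    h[gridD2[bmu, ] > radius^2] <- 0
                    codebook <- codebook + (alpha * h) *
                        sweep(-codebook, 2, Z[i, ], `+`)
                }
                t0 <- t0 + 1
            }
        }
    })
    bmu <- apply(Z, 1, function(z)
        which.min(rowSums(sweep(codebook, 2, z)^2)))
    structure(list(codebook = codebook, grid = grid, gridCoords = gridCoords,
                   center = ctr, scale = scl, bmu = bmu, epochs = epochs,
                   alpha0 = alpha0, radius0 = radius0, seed = seed,
                   features = colnames(X)),
              class = "SOMModel")
}

#' @export
print.SOMModel <- function(x, ...) {
    cat("SOMModel:", x$grid[1], "x", x$grid[2], "grid,",
        length(x$features), "features,", x$epochs, "epochs, seed", x$seed,
        "\n")
    invisible(x)
}

#' Merge SOM nodes into metaclusters
#'
#' Average-linkage agglomerative clustering of the codebook vectors
#' (Euclidean distance) cut at \code{k}; metacluster labels are renumbered
#' MC1..MCk by descending occupancy of the SOM's training samples (ties by
#' first occurrence).
#'
#' @param som a \code{SOMModel}.
#' @param k number of metaclusters, 2 <= k <= node count (k = node count and
#'   k = 1 are allowed degenerate cuts).
#' @return integer vector mapping each node to a metacluster (names
#'   \code{"MC1"}... on the levels attribute).
#' @export
metacluster <- function(som, k = 8) {
    nNodes <- nrow(som$codebook)
    if (k < 1 || k > nNodes) stop("k out of range")
    cut <- if (k == 1) rep(1L, nNodes)
           else stats::cutree(stats::hclust(stats::dist(som$codebook),
                                            method = "average"), k = k)
    occupancy <- vapply(seq_len(k), function(m)
        sum(cut[som$bmu] == m), integer(1))
    ord <- order(-occupancy, seq_len(k))
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    out <- relabel[cut]
    names(out) <- rownames(som$codebook)
    attr(out, "labels") <- paste0("MC", seq_len(k))
    out
}

#' Assign samples to metaclusters and compute group compositions
#'
#' Samples are standardized with the SOM's stored center/scale, mapped to
#' their nearest codebook node, and inherit that node's metacluster. Group
#' compositions are sample fractions per metacluster (each group sums to 1).
#'
#' @param cohort an \linkS4class{ImmuneCohort} whose subsets match the SOM's
#'   training features.
#' @param som a \code{SOMModel}.
#' @param nodeMap node-to-metacluster map from \code{\link{metacluster}}.
#' @return list with \code{sampleNode}, \code{sampleMetacluster} (factor
#'   MC1..MCk per sample), \code{composition} (metacluster x group fraction
#'   matrix) and \code{k}.
#' @export
assignAndCompose <- function(cohort, som, nodeMap) {
    f <- frequencies(cohort)
    if (!identical(colnames(f), som$features))
        stop("cohort features do not match the SOM training feature set")
    Z <- sweep(sweep(f, 2, som$center), 2, som$scale, `/`)
    node <- apply(Z, 1, function(z)
        which.min(rowSums(sweep(som$codebook, 2, z)^2)))
    k <- max(nodeMap)
    mc <- factor(paste0("MC", nodeMap[node]),
                 levels = paste0("MC", seq_len(k)))
    g <- groupLabels(cohort)
    composition <- vapply(c("patient", "control"), function(grp) {
        tab <- table(mc[g == grp])
        as.numeric(tab) / max(sum(tab), 1)
    }, numeric(k))
    rownames(composition) <- levels(mc)
    list(sampleNode = node, sampleMetacluster = stats::setNames(mc, rownames(f)),
         composition = composition, k = k)
}

#' Metacluster composition differences with bootstrap intervals
#'
#' Point difference (patient minus control) of metacluster occupancy in
#' percentage points, with percentile bootstrap confidence intervals from
#' resampling samples within each group. Differences sum to zero across
#' metaclusters by construction.
#'
#' @param assignment result of \code{\link{assignAndCompose}}.
#' @param labels group labels per sample (patient/control).
#' @param nBoot bootstrap replicates (>= 200; default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame per metacluster: \code{metacluster,
#'   proportionPatient, proportionControl, difference, ciLow, ciHigh}.
#' @export
compositionDifferences <- function(assignment, labels, nBoot = 1000,
                                   seed = 1L, conf = 0.95) {
    if (nBoot < 200) stop("nBoot must be >= 200")
    mc <- assignment$sampleMetacluster
    labels <- as.character(labels)
    iP <- which(labels == "patient"); iC <- which(labels == "control")
    if (!length(iP) || !length(iC)) stop("both groups must be non-empty")
    lev <- levels(mc)
    compOf <- function(i) as.numeric(table(mc[i])) / length(i)
    point <- 100 * (compOf(iP) - compOf(iC))
    alpha <- (1 - conf) / 2
    boot <- withr::with_seed(seed, {
        vapply(seq_len(nBoot), function(b) {
            100 * (compOf(sample(iP, replace = TRUE)) -
                   compOf(sample(iC, replace = TRUE)))
        }, numeric(length(lev)))
    })
    ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha))
    data.frame(metacluster = lev,
               proportionPatient = compOf(iP),
               proportionControl = compOf(iC),
               difference = point,
               ciLow = pmin(ci[1, ], point), ciHigh = pmax(ci[2, ], point),
               stringsAsFactors = FALSE)
}

#' Per-metacluster marker differences (volcano table)
#'
#' Within each metacluster holding at least two samples of each group:
#' per-feature difference of group mean z-scores (z against the full cohort)
#' plus a two-sided Wilcoxon p and a BH q computed over the features of that
#' metacluster. Undersized metaclusters are returned flagged
#' \code{tested = FALSE}.
#'
#' @param cohort an \linkS4class{ImmuneCohort}.
#' @param assignment result of \code{\link{assignAndCompose}}.
#' @return data.frame with \code{metacluster, feature, deltaZ, p, q, tested}.
#' @export
metaclusterMarkerDifferences <- function(cohort, assignment) {
    f <- frequencies(cohort)
    g <- groupLabels(cohort)
    Z <- scale(f)
    Z[, apply(f, 2, stats::sd) == 0] <- 0
    mc <- assignment$sampleMetacluster
    out <- list()
    for (m in levels(mc)) {
        i <- which(mc == m)
        iP <- i[g[i] == "patient"]; iC <- i[g[i] == "control"]
        testable <- length(iP) >= 2 && length(iC) >= 2
        rows <- lapply(colnames(f), function(feat) {
            if (!testable)
                return(data.frame(metacluster = m, feature = feat,
                                  deltaZ = NA_real_, p = NA_real_,
                                  tested = FALSE))
            dz <- mean(Z[iP, feat]) - mean(Z[iC, feat])
            p <- if (stats::sd(c(Z[iP, feat], Z[iC, feat])) == 0) 1 else
                suppressWarnings(stats::wilcox.test(
                    Z[iP, feat], Z[iC, feat])$p.value)
            data.frame(metacluster = m, feature = feat, deltaZ = dz, p = p,
                       tested = TRUE)
        })
        block <- do.call(rbind, rows)
        block$q <- NA_real_
        if (testable) block$q <- bhFDR(block$p)
        out[[m]] <- block
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[, c("metacluster", "feature", "deltaZ", "p", "q", "tested")]
}

#' Metacluster contributions to the IDS
#'
#' For each metacluster, the Pearson correlation between per-sample
#' membership (0/1 indicator) and the per-sample IDS; positive weights mark
#' metaclusters whose members carry high IDS. Metaclusters containing all or
#' no samples, or a constant IDS, yield a flagged \code{NA}.
#'
#' @param assignment result of \code{\link{assignAndCompose}}.
#' @param ids numeric IDS per assigned sample (or a score table from
#'   \code{\link{computeScoreTable}}).
#' @return named numeric vector of weights in [-1, 1] (NA where undefined).
#' @export
metaclusterIdsWeights <- function(assignment, ids) {
    if (is.data.frame(ids)) ids <- stats::setNames(ids$ids, ids$sampleId)
    mc <- assignment$sampleMetacluster
    if (length(ids) != length(mc))
        stop("IDS must be available for all assigned samples")
    vapply(levels(mc), function(m) {
        ind <- as.numeric(mc == m)
        if (stats::sd(ind) == 0 || stats::sd(ids) == 0) return(NA_real_)
        stats::cor(ind, ids)
    }, numeric(1))
}
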