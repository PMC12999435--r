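#' Per-subset patient-versus-control tests with FDR control
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test for every subset: exact
#' when both groups have at most 8 samples (and the data are tie-free),
#' normal approximation with tie correction otherwise. q-values by
#' Benjamini-Hochberg over all subsets tested in the call. Subsets that are
#' constant across the whole cohort have no defined statistic; they are
#' flagged and excluded from the FDR family.
#'
#' @param cohort an \linkS4class{ImmuneCohort} with >= 2 samples per group.
#' @return data.frame with columns \code{subset, statistic, p, q, direction,
#'   medianPatient, medianControl, tested}.
#' @export
compareSubsets <- function(cohort) {
    f <- frequencies(cohort)
    g <- groupLabels(cohort)
    if (sum(g == "patient") < 2 || sum(g == "control") < 2)
        stop("need at least 2 samples per group")
    res <- lapply(colnames(f), function(s) {
        xp <- f[g == "patient", s]; xc <- f[g == "control", s]
        if (stats::sd(c(xp, xc)) == 0)
            return(data.frame(subset = s, statistic = NA_real_, p = NA_real_,
                              direction = 0, medianPatient = stats::median(xp),
                              medianControl = stats::median(xc),
                              tested = FALSE))
        exact <- length(xp) <= 8 && length(xc) <= 8
        wt <- suppressWarnings(stats::wilcox.test(
            xp, xc, alternative = "two.sided", exact = exact, correct = TRUE))
        data.frame(subset = s, statistic = unname(wt$statistic), p = wt$p.value,
                   direction = sign(stats::median(xp) - stats::median(xc)),
                   medianPatient = stats::median(xp),
                   medianControl = stats::median(xc), tested = TRUE)
    })
    out <- do.call(rbind, res)
    out$q <- NA_real_
    out$q[out$tested] <- bhFDR(out$p[out$tested])
    out[, c("subset", "statistic", "p", "q", "direction",
            "medianPatient", "medianControl", "tested")]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order, clipped at 1.
#' @export
bhFDR <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Pairwise subset correlation matrix
#'
#' @param subsetMatrix samples-by-subsets numeric matrix (>= 3 samples).
#' @param method \code{"spearman"} (default, robust for bounded percentages)
#'   or \code{"pearson"}.
#' @return symmetric matrix with unit diagonal; correlations undefined
#'   because of constant columns are \code{NA}, never zero.
#' @export
correlationMatrix <- function(subsetMatrix,
                              method = c("spearman", "pearson")) {
    method <- match.arg(method)
    subsetMatrix <- as.matrix(subsetMatrix)
    if (nrow(subsetMatrix) < 3) stop("need at least 3 samples")
    r <- suppressWarnings(stats::cor(subsetMatrix, method = method,
                                     use = "pairwise.complete.obs"))
    diag(r) <- 1
    r
}

#' Delta-correlation network between patient and control matrices
#'
#' Edges are subset pairs whose correlation change
#' \code{deltaR = rPatient - rControl} reaches \code{threshold} in absolute
#' value; pairs with an undefined correlation in either group never form
#' edges. \code{strongerIn} is \code{"patient"} when the signed correlation is
#' higher in patients (deltaR > 0) and \code{"control"} otherwise, so a
#' positive association that flips negative in patients is reported as
#' stronger in controls.
#'
#' @param matPatient,matControl correlation matrices over an identical,
#'   identically ordered node set.
#' @param threshold minimum |deltaR| for edge inclusion (default 0.4).
#' @return list with \code{edges} (data.frame: nodeA, nodeB, rPatient,
#'   rControl, deltaR, sign, strongerIn), \code{nodes}, \code{degree} and
#'   \code{hubs} (nodes sorted by decreasing degree).
#' @export
deltaNetwork <- function(matPatient, matControl, threshold = 0.4) {
    if (!identical(rownames(matPatient), rownames(matControl)) ||
        !identical(colnames(matPatient), colnames(matControl)))
        stop("matrices must share an identical node set and ordering")
    nodes <- rownames(matPatient)
    idx <- which(upper.tri(matPatient), arr.ind = TRUE)
    rP <- matPatient[idx]; rC <- matControl[idx]
    dR <- rP - rC
    keep <- !is.na(dR) & !is.na(rP) & !is.na(rC) & abs(dR) >= threshold
    edges <- data.frame(nodeA = nodes[idx[keep, 1]],
                        nodeB = nodes[idx[keep, 2]],
                        rPatient = rP[keep], rControl = rC[keep],
                        deltaR = dR[keep], sign = sign(dR[keep]),
                        strongerIn = ifelse(dR[keep] > 0, "patient", "control"),
                        stringsAsFactors = FALSE)
    degree <- stats::setNames(integer(length(nodes)), nodes)
    if (nrow(edges)) {
        tab <- table(c(edges$nodeA, edges$nodeB))
        degree[names(tab)] <- as.integer(tab)
    }
    list(edges = edges, nodes = nodes, degree = degree,
         hubs = names(sort(degree, decreasing = TRUE)))
}

#' Export a delta network
#'
#' Writes the edge list as TSV and, when \code{graphml} is given, as GraphML.
#' @param network result of \code{\link{deltaNetwork}}.
#' @param tsv path for the edge-list TSV.
#' @param graphml optional path for a GraphML export.
#' @return invisibly, the paths written.
#' @export
writeDeltaNetwork <- function(network, tsv, graphml = NULL) {
    utils::write.table(network$edges[, c("nodeA", "nodeB", "rPatient",
                                         "rControl", "deltaR", "strongerIn")],
                       tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(graphml)) {
        gr <- igraph::graph_from_data_frame(
            network$edges, directed = FALSE,
            vertices = data.frame(name = network$nodes,
                                  degree = unname(network$degree)))
        igraph::write_graph(gr, graphml, format = "graphml")
    }
    invisible(c(tsv = tsv, graphml = graphml))
}

# Conditional perplexity-calibrated probabilities for t-SNE (exact, O(n^2)).
.tsneP <- function(D2, perplexity, tol = 1e-5, maxIter = 50) {
    n <- nrow(D2)
    P <- matrix(0, n, n)
    logU <- log(perplexity)
    for (i in seq_len(n)) {
        beta <- 1; lo <- -Inf; hi <- Inf
        d <- D2[i, -i]
        for (it in seq_len(maxIter)) {
            w <- exp(-d * beta)
            sw <- sum(w)
            if (sw == 0) { H <- 0; p <- w }
            else {
                p <- w / sw
                H <- -sum(p[p > 0] * log(p[p > 0]))
            }
            if (abs(H - logU) < tol) break
            if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
            else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
        }
        P[i, -i] <- p
    }
    P
}

#' Two-dimensional t-SNE embedding of samples
#'
#' Exact (dense) t-distributed stochastic neighbor embedding with the
#' standard ingredients: perplexity-calibrated Gaussian input affinities,
#' Student-t output kernel, early exaggeration and momentum gradient descent.
#' Features are z-standardized internally; constant features are dropped.
#' Deterministic for a fixed seed. Intended for the cohort sizes this package
#' targets (tens to a few hundred samples).
#'
#' @param featureMatrix samples-by-features numeric matrix.
#' @param perplexity neighborhood size parameter; requires at least
#'   \code{3 * perplexity} samples.
#' @param seed integer seed for the random initialization.
#' @param maxIter gradient-descent iterations (default 500).
#' @return samples-by-2 coordinate matrix.
#' @export
embed2D <- function(featureMatrix, perplexity = 10, seed = 1L,
                    maxIter = 500) {
    X <- as.matrix(featureMatrix)
    n <- nrow(X)
    if (n < 3 * perplexity)
        stop("need at least 3*perplexity samples (", 3 * perplexity, ")")
    keep <- apply(X, 2, stats::sd) > 0
    X <- scale(X[, keep, drop = FALSE])
    D2 <- as.matrix(stats::dist(X))^2
    P <- .tsneP(D2, perplexity)
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P, 1e-12)
    withr::with_seed(seed, {
        Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    })
    gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    eta <- 200
    for (it in seq_len(maxIter)) {
        ex <- if (it <= 100) 12 else 1
        momentum <- if (it <= 250) 0.5 else 0.8
        dY2 <- as.matrix(stats::dist(Y))^2
        W <- 1 / (1 + dY2); diag(W) <- 0
        Q <- pmax(W / sum(W), 1e-12)
        L <- (ex * P - Q) * W
        G <- 4 * (diag(rowSums(L)) - L) %*% Y
        gain <- ifelse(sign(G) != sign(inc), gain + 0.2, gain * 0.8)
        gain[gain < 0.01] <- 0.01
        inc <- momentum * inc - eta * gain * G
        Y <- Y + inc
        Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(featureMatrix)
    colnames(Y) <- c("tsne1", "tsne2")
    Y
}
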