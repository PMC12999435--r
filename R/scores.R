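#' Geometric mean of positive percent values
#'
#' Adds \code{pseudocount} to every value, then returns
#' \code{exp(mean(log(x + pseudocount)))}; invariant to input order.
#'
#' @param values non-empty numeric vector of non-negative percents.
#' @param pseudocount non-negative offset (must be > 0 if any value is 0).
#' @return positive scalar.
#' @examples
#' geometricMean(c(1, 100))   # 10
#' @export
geometricMean <- function(values, pseudocount = 0) {
    if (length(values) == 0) stop("empty input")
    if (any(!is.finite(values))) stop("non-finite input")
    if (any(values < 0)) stop("negative values are not valid percents")
    x <- values + pseudocount
    if (any(x <= 0)) stop("values must be strictly positive after pseudocount")
    exp(mean(log(x)))
}

#' Immune Dysregulation Score of one sample
#'
#' \code{IDS = log_b( GM(inflammatory) / GM(regulatory) )} where GM is the
#' pseudocount-adjusted geometric mean over the panel's subset frequencies.
#' Antisymmetric under swapping the two panel lists.
#'
#' @param sampleFrequencies named numeric vector of subset frequencies
#'   (percent of parent) containing every panel subset.
#' @param panel a \linkS4class{PanelDefinition}.
#' @return the IDS (dimensionless log-ratio).
#' @export
computeIDS <- function(sampleFrequencies, panel) {
    miss <- setdiff(c(panel@inflammatory, panel@regulatory),
                    names(sampleFrequencies))
    if (length(miss))
        stop("sample is missing panel subsets: ", paste(miss, collapse = ", "))
    if (any(!is.finite(sampleFrequencies[c(panel@inflammatory,
                                           panel@regulatory)])))
        stop("non-finite frequencies")
    gmI <- geometricMean(sampleFrequencies[panel@inflammatory],
                         panel@pseudocount)
    gmR <- geometricMean(sampleFrequencies[panel@regulatory],
                         panel@pseudocount)
    log(gmI / gmR, base = panel@logBase)
}

#' Clinical Dysregulation Score of one patient
#'
#' Sum of present-domain indicators over the configured domains. A row
#' missing any domain yields \code{NA} (the sample is excluded from clinical
#' scoring, mirroring cohorts where only patients with complete clinical
#' records are scored).
#'
#' @param clinicalRow named vector with one 0/1 (or NA) entry per domain.
#' @param domains character vector of domain names.
#' @return integer in 0..length(domains), or NA.
#' @export
computeCDS <- function(clinicalRow, domains) {
    miss <- setdiff(domains, names(clinicalRow))
    if (length(miss))
        stop("clinical row is missing domains: ", paste(miss, collapse = ", "))
    v <- clinicalRow[domains]
    if (!all(v %in% c(0, 1, NA)))
        stop("clinical values must be 0, 1 or NA")
    if (anyNA(v)) return(NA_integer_)
    as.integer(sum(v))
}

#' Per-sample score table
#'
#' Computes, for every sample: the IDS; \code{deltaIds} (IDS minus the
#' control-group mean IDS, so controls centre at zero); \code{proMean} /
#' \code{antiMean} (arithmetic mean of control-standardized frequencies of the
#' inflammatory / regulatory panel subsets); and, for patients with a complete
#' clinical row, the CDS and its z-score over scored patients.
#'
#' @param cohort an \linkS4class{ImmuneCohort} with at least one control.
#' @param panel a \linkS4class{PanelDefinition}.
#' @param domains clinical domain names (default four-domain preset); ignored
#'   when the cohort carries no clinical matrix.
#' @return a \code{data.frame} (one row per sample) with columns
#'   \code{sampleId, group, ids, deltaIds, proMean, antiMean, cds, clinicalZ};
#'   attributes \code{controlStats} (per-subset control mean/sd, control mean
#'   IDS) and \code{panel} record the reference frame.
#' @export
computeScoreTable <- function(cohort, panel = defaultPanel(),
                              domains = clinicalDomains("four")) {
    f <- frequencies(cohort)
    g <- groupLabels(cohort)
    if (!any(g == "control")) stop("cohort contains no controls")
    miss <- setdiff(c(panel@inflammatory, panel@regulatory), colnames(f))
    if (length(miss))
        stop("cohort is missing panel subsets: ", paste(miss, collapse = ", "))
    ids <- apply(f, 1, computeIDS, panel = panel)
    ctrlMeanIds <- mean(ids[g == "control"])
    deltaIds <- ids - ctrlMeanIds
    panelSubsets <- c(panel@inflammatory, panel@regulatory)
    ctrl <- f[g == "control", panelSubsets, drop = FALSE]
    mu <- colMeans(ctrl)
    sd <- apply(ctrl, 2, stats::sd)
    if (any(!is.finite(sd)) || any(sd == 0))
        stop("degenerate control SD for subsets: ",
             paste(panelSubsets[!is.finite(sd) | sd == 0], collapse = ", "))
    z <- sweep(sweep(f[, panelSubsets, drop = FALSE], 2, mu), 2, sd, `/`)
    proMean <- rowMeans(z[, panel@inflammatory, drop = FALSE])
    antiMean <- rowMeans(z[, panel@regulatory, drop = FALSE])
    cds <- rep(NA_integer_, nrow(f))
    clinicalZ <- rep(NA_real_, nrow(f))
    cl <- clinicalMatrix(cohort)
    if (!is.null(cl)) {
        have <- intersect(domains, colnames(cl))
        if (length(have) < length(domains))
            stop("clinical matrix is missing domains: ",
                 paste(setdiff(domains, have), collapse = ", "))
        cds <- apply(cl, 1, computeCDS, domains = domains)
        scored <- which(!is.na(cds) & g == "patient")
        if (length(scored) >= 2 && stats::sd(cds[scored]) > 0) {
            clinicalZ[scored] <- (cds[scored] - mean(cds[scored])) /
                stats::sd(cds[scored])
        }
    }
    out <- data.frame(sampleId = rownames(f), group = unname(g),
                      ids = unname(ids), deltaIds = unname(deltaIds),
                      proMean = unname(proMean), antiMean = unname(antiMean),
                      cds = unname(cds), clinicalZ = unname(clinicalZ),
                      stringsAsFactors = FALSE)
    attr(out, "controlStats") <- list(subsetMean = mu, subsetSd = sd,
                                      meanIds = ctrlMeanIds)
    attr(out, "panel") <- panel
    out
}

#' Inflammatory-to-regulatory ratio normalized against controls
#'
#' The per-sample raw ratio \code{(inflammatory + pc) / (regulatory + pc)}
#' divided by the control-group mean raw ratio, so the control-group mean of
#' the normalized ratio is 1 by construction.
#'
#' @param cohort an \linkS4class{ImmuneCohort}.
#' @param inflammatorySubset,regulatorySubset single subset names.
#' @param pseudocount positive offset added to both frequencies.
#' @return named numeric vector of normalized ratios.
#' @export
ratioVsControls <- function(cohort, inflammatorySubset, regulatorySubset,
                            pseudocount = 0.01) {
    f <- frequencies(cohort)
    g <- groupLabels(cohort)
    if (!any(g == "control")) stop("control group is empty")
    miss <- setdiff(c(inflammatorySubset, regulatorySubset), colnames(f))
    if (length(miss))
        stop("missing subsets: ", paste(miss, collapse = ", "))
    raw <- (f[, inflammatorySubset] + pseudocount) /
        (f[, regulatorySubset] + pseudocount)
    raw / mean(raw[g == "control"])
}

.logContrast <- function(logX, num, den) {
    rowMeans(logX[, num, drop = FALSE]) - rowMeans(logX[, den, drop = FALSE])
}

.cvFolds <- function(y, k, seed) {
    withr::with_seed(seed, {
        folds <- integer(length(y))
        for (cls in unique(y)) {
            i <- which(y == cls)
            folds[i] <- sample(rep_len(seq_len(k), length(i)))
        }
        folds
    })
}

.foldAUC <- function(score, y, folds) {
    aucs <- vapply(sort(unique(folds)), function(f) {
        s <- score[folds == f]; yy <- y[folds == f]
        if (length(unique(yy)) < 2) return(NA_real_)
        .concordanceAUC(s, yy)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
}

# AUC as pairwise concordance with half credit for ties (Mann-Whitney form)
.concordanceAUC <- function(score, y) {
    pos <- score[y == 1]; neg <- score[y == 0]
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

# Greedy forward balance search on a fixed fold assignment; returns the
# selected sets, the (selection-biased) fold AUC and the accepted-step trace.
.greedyBalance <- function(logX, y, folds, maxVars, tol) {
    vars <- colnames(logX)
    crit <- function(num, den)
        .foldAUC(.logContrast(logX, num, den), y, folds)
    best <- list(num = NULL, den = NULL, auc = -Inf)
    for (i in vars) for (j in vars) if (i != j) {
        a <- crit(i, j)
        if (a > best$auc) best <- list(num = i, den = j, auc = a)
    }
    trace <- data.frame(step = 1L, added = paste(best$num, "/", best$den),
                        side = "init", cvAuc = best$auc,
                        stringsAsFactors = FALSE)
    while (length(best$num) + length(best$den) < maxVars) {
        cand <- setdiff(vars, c(best$num, best$den))
        if (!length(cand)) break
        step <- list(auc = best$auc, num = NULL, den = NULL, add = NULL,
                     side = NULL)
        for (v in cand) {
            aN <- crit(c(best$num, v), best$den)
            if (aN > step$auc) step <- list(auc = aN,
                num = c(best$num, v), den = best$den, add = v,
                side = "numerator")
            aD <- crit(best$num, c(best$den, v))
            if (aD > step$auc) step <- list(auc = aD,
                num = best$num, den = c(best$den, v), add = v,
                side = "denominator")
        }
        if (is.null(step$add) || step$auc - best$auc <= tol) break
        best <- list(num = step$num, den = step$den, auc = step$auc)
        trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
            added = step$add, side = step$side, cvAuc = step$auc,
            stringsAsFactors = FALSE))
    }
    list(num = best$num, den = best$den, auc = best$auc, trace = trace)
}

#' Greedy compositional balance selection
#'
#' Simplified forward search in the spirit of compositional balance
#' selection: candidate scores are log-contrasts (mean log of numerator
#' subsets minus mean log of denominator subsets); the search initializes
#' with the single numerator/denominator pair with the best cross-validated
#' AUC against the binary outcome and greedily adds the variable (to either
#' side) with the largest CV-AUC improvement, stopping at \code{maxVars}
#' variables or when the improvement drops to \code{tol} or below.
#'
#' The reported \code{cvAuc} is a nested cross-validation estimate: the
#' whole greedy search is repeated inside each training fold and scored on
#' the held-out fold, so the criterion is protected from selection optimism
#' (on pure-noise features it concentrates around 0.5, not above it).
#'
#' @param features samples-by-subsets matrix of positive frequencies.
#' @param outcome binary vector (0/1 or two-level factor) per sample.
#' @param maxVars maximum total number of selected variables (>= 2).
#' @param cvFolds number of cross-validation folds.
#' @param seed integer seed (drives fold assignment).
#' @param pseudocount offset added before logs.
#' @param tol minimum CV-AUC improvement to keep growing.
#' @return list with \code{numerator}, \code{denominator}, \code{cvAuc}
#'   (nested estimate), \code{selectionAuc} (the biased criterion the search
#'   itself maximized) and a \code{trace} data.frame of the accepted steps.
#' @export
selectBalance <- function(features, outcome, maxVars = 6, cvFolds = 5,
                          seed = 1L, pseudocount = 0.01, tol = 1e-4) {
    features <- as.matrix(features)
    if (ncol(features) < 3) stop("need at least 3 candidate features")
    if (maxVars < 2) stop("maxVars must be >= 2")
    y <- if (is.factor(outcome)) as.integer(outcome) - 1L
         else as.integer(outcome)
    if (length(unique(y)) != 2) stop("outcome must contain both classes")
    y <- as.integer(y == max(y))
    logX <- log(features + pseudocount)
    if (is.null(colnames(logX)))
        colnames(logX) <- paste0("V", seq_len(ncol(logX)))
    folds <- .cvFolds(y, cvFolds, seed)
    sol <- .greedyBalance(logX, y, folds, maxVars, tol)
    # nested evaluation: redo the selection without each outer fold
    outer <- vapply(seq_len(cvFolds), function(f) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
            return(NA_real_)
        innerFolds <- .cvFolds(y[tr], cvFolds, seed + f)
        solF <- .greedyBalance(logX[tr, , drop = FALSE], y[tr], innerFolds,
                               maxVars, tol)
        score <- .logContrast(logX[!tr, , drop = FALSE], solF$num, solF$den)
        .concordanceAUC(score, y[!tr])
    }, numeric(1))
    list(numerator = sol$num, denominator = sol$den,
         cvAuc = mean(outer, na.rm = TRUE), selectionAuc = sol$auc,
         trace = sol$trace)
}
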