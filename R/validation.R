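#' ROC analysis with DeLong interval and Youden operating point
#'
#' AUC is the probability of concordance with half credit for ties
#' (Mann-Whitney convention), the 95% CI is DeLong's, and the Youden-optimal
#' threshold maximizes sensitivity + specificity - 1 over all empirical
#' cutpoints. Backed by \pkg{pROC}.
#'
#' @param scores numeric scores (higher = more patient-like by default).
#' @param labels binary labels: 1/\code{"patient"} = positive class.
#' @return list with \code{auc}, \code{ciLow}, \code{ciHigh},
#'   \code{thresholds}, \code{sensitivity}, \code{specificity},
#'   \code{youden} (threshold, sensitivity, specificity, index).
#' @examples
#' rocAuc(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc   # 0.75
#' @export
rocAuc <- function(scores, labels) {
    y <- if (is.character(labels) || is.factor(labels))
        as.integer(as.character(labels) == "patient") else as.integer(labels)
    if (length(unique(y)) < 2) stop("both classes must be present")
    r <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    # pROC warns that the DeLong interval collapses at AUC == 1; that is the
    # expected degenerate case, not an error
    ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))
    yi <- r$sensitivities + r$specificities - 1
    best <- which.max(yi)   # pROC enumerates all empirical cutpoints
    list(auc = as.numeric(pROC::auc(r)), ciLow = ci[1], ciHigh = ci[3],
         thresholds = r$thresholds, sensitivity = r$sensitivities,
         specificity = r$specificities,
         youden = list(threshold = r$thresholds[best],
                       sensitivity = r$sensitivities[best],
                       specificity = r$specificities[best],
                       index = yi[best]))
}

#' Composite severity model (one-vs-rest logistic or random forest)
#'
#' Fits a class-probability model of severity class on the four composite
#' features (proMean, antiMean, ids, deltaIds — or any numeric feature
#' matrix). \code{"ovr_logistic"} fits one binomial GLM per class and
#' renormalizes the per-class probabilities to sum to one;
#' \code{"random_forest"} wraps \pkg{randomForest}. Deterministic per seed.
#'
#' @param features samples-by-features numeric matrix or data.frame.
#' @param classes factor (or coercible) with >= 2 classes, >= 2 members each.
#' @param kind \code{"ovr_logistic"} or \code{"random_forest"}.
#' @param seed integer seed.
#' @return a \code{CompositeModel}; use \code{\link{predictProbs}} for class
#'   probabilities.
#' @export
fitCompositeModel <- function(features, classes,
                              kind = c("ovr_logistic", "random_forest"),
                              seed = 1L) {
    kind <- match.arg(kind)
    X <- as.data.frame(features)
    if (any(!vapply(X, is.numeric, logical(1))) || any(!is.finite(as.matrix(X))))
        stop("features must be finite numerics")
    y <- factor(classes)
    if (nlevels(y) < 2 || any(table(y) < 2))
        stop("need >= 2 classes with >= 2 members each")
    fit <- withr::with_seed(seed, {
        if (kind == "ovr_logistic") {
            lapply(levels(y), function(cl) {
                suppressWarnings(stats::glm(
                    I(y == cl) ~ ., data = X, family = stats::binomial()))
            })
        } else {
            randomForest::randomForest(x = X, y = y, ntree = 500)
        }
    })
    structure(list(kind = kind, fit = fit, levels = levels(y),
                   featureNames = colnames(X), seed = seed),
              class = "CompositeModel")
}

#' Class probabilities from a composite model
#'
#' @param model a \code{CompositeModel}.
#' @param features new data with the training feature columns.
#' @return samples-by-classes probability matrix, rows summing to 1.
#' @export
predictProbs <- function(model, features) {
    X <- as.data.frame(features)[, model$featureNames, drop = FALSE]
    if (model$kind == "ovr_logistic") {
        p <- vapply(model$fit, function(m)
            stats::predict(m, newdata = X, type = "response"),
            numeric(nrow(X)))
        p <- matrix(p, nrow = nrow(X))
        p <- pmax(p, 1e-12)
        p <- p / rowSums(p)
    } else {
        p <- stats::predict(model$fit, newdata = X, type = "prob")
        p <- pmax(p, 1e-12)
        p <- p / rowSums(p)
    }
    colnames(p) <- model$levels
    rownames(p) <- rownames(X)
    p
}

#' @export
print.CompositeModel <- function(x, ...) {
    cat("CompositeModel (", x$kind, "):", length(x$levels), "classes,",
        length(x$featureNames), "features\n")
    invisible(x)
}

.accuracy <- function(model, X, y) {
    p <- predictProbs(model, X)
    mean(model$levels[max.col(p, ties.method = "first")] == as.character(y))
}

#' Permutation importance (mean decrease accuracy)
#'
#' Mean drop in classification accuracy when one feature column is permuted,
#' averaged over \code{nPerm} permutations. Deterministic per seed.
#'
#' @param model a fitted \code{CompositeModel}.
#' @param features,classes evaluation data.
#' @param nPerm permutations per feature (>= 20).
#' @param seed integer seed.
#' @return named numeric vector, sorted decreasing.
#' @export
permutationImportance <- function(model, features, classes, nPerm = 50,
                                  seed = 1L) {
    if (nPerm < 20) stop("nPerm must be >= 20")
    X <- as.data.frame(features)
    miss <- setdiff(model$featureNames, colnames(X))
    if (length(miss)) stop("features absent from model input: ",
                           paste(miss, collapse = ", "))
    base <- .accuracy(model, X, classes)
    imp <- withr::with_seed(seed, {
        vapply(model$featureNames, function(feat) {
            drops <- vapply(seq_len(nPerm), function(i) {
                Xp <- X
                Xp[[feat]] <- sample(Xp[[feat]])
                base - .accuracy(model, Xp, classes)
            }, numeric(1))
            mean(drops)
        }, numeric(1))
    })
    sort(imp, decreasing = TRUE)
}

#' Decile-binned calibration with intercept and slope
#'
#' Splits samples into \code{nBins} equal-count bins by sorted predicted
#' probability (bin sizes differ by at most one) and reports per-bin mean
#' prediction and observed event rate. The calibration intercept and slope
#' come from a logistic fit of the outcome on logit(prediction). Predictions
#' exactly 0 or 1 are clipped to [1e-6, 1 - 1e-6] and the clipping is
#' reported; constant predictions leave the slope undefined (NA, flagged).
#'
#' @param predProbs predicted probabilities in (0, 1).
#' @param outcomes binary outcomes.
#' @param nBins number of bins (default 10).
#' @return list with \code{bins} (data.frame: bin, n, meanPredicted,
#'   observedRate), \code{intercept}, \code{slope}, \code{nClipped},
#'   \code{degenerate}.
#' @export
calibration <- function(predProbs, outcomes, nBins = 10) {
    p <- as.numeric(predProbs)
    y <- as.integer(outcomes)
    nClipped <- sum(p <= 0 | p >= 1)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    ord <- order(p)
    binId <- integer(length(p))
    binId[ord] <- sort(rep_len(seq_len(nBins), length(p)))
    bins <- do.call(rbind, lapply(seq_len(nBins), function(b) {
        i <- which(binId == b)
        data.frame(bin = b, n = length(i), meanPredicted = mean(p[i]),
                   observedRate = mean(y[i]))
    }))
    degenerate <- stats::sd(p) == 0
    if (degenerate) {
        intercept <- NA_real_; slope <- NA_real_
    } else {
        fit <- suppressWarnings(stats::glm(y ~ stats::qlogis(p),
                                           family = stats::binomial()))
        intercept <- unname(stats::coef(fit)[1])
        slope <- unname(stats::coef(fit)[2])
    }
    list(bins = bins, intercept = intercept, slope = slope,
         nClipped = nClipped, degenerate = degenerate)
}

#' Decision curve (net benefit) analysis
#'
#' Net benefit of treating according to \code{predProbs >= p_t}:
#' \code{TP/n - (FP/n) * p_t / (1 - p_t)}, together with the treat-all and
#' treat-none references.
#'
#' @param predProbs predicted probabilities.
#' @param outcomes binary outcomes.
#' @param thresholds threshold probabilities in (0, 1).
#' @return data.frame with \code{threshold, netBenefit, treatAll, treatNone}.
#' @export
decisionCurve <- function(predProbs, outcomes,
                          thresholds = seq(0.05, 0.95, by = 0.05)) {
    if (!length(thresholds)) stop("empty threshold grid")
    if (any(thresholds <= 0 | thresholds >= 1))
        stop("thresholds must lie in (0, 1)")
    p <- as.numeric(predProbs); y <- as.integer(outcomes)
    n <- length(y); prev <- mean(y)
    rows <- lapply(thresholds, function(pt) {
        treat <- p >= pt
        tp <- sum(treat & y == 1); fp <- sum(treat & y == 0)
        w <- pt / (1 - pt)
        data.frame(threshold = pt,
                   netBenefit = tp / n - (fp / n) * w,
                   treatAll = prev - (1 - prev) * w,
                   treatNone = 0)
    })
    do.call(rbind, rows)
}

#' Model specification helpers for resampling validation
#'
#' A model spec is a list with \code{fit(X, y)} returning a fitted object and
#' \code{score(fit, X)} returning a numeric risk score (binary) or
#' probability matrix (multiclass). \code{binaryLogisticSpec()} is a plain
#' logistic regression on all features; \code{compositeSpec(kind)} wraps
#' \code{\link{fitCompositeModel}}.
#'
#' @param seed integer seed passed to stochastic backends.
#' @return a model spec list.
#' @export
binaryLogisticSpec <- function() {
    list(fit = function(X, y)
             suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                 data = data.frame(y = as.integer(y), X))),
         score = function(fit, X)
             stats::predict(fit, newdata = data.frame(X), type = "response"))
}

#' @rdname binaryLogisticSpec
#' @param kind passed to \code{\link{fitCompositeModel}}.
#' @export
compositeSpec <- function(kind = "ovr_logistic", seed = 1L) {
    list(fit = function(X, y) fitCompositeModel(X, y, kind = kind, seed = seed),
         score = function(fit, X) predictProbs(fit, X))
}

.metricValue <- function(metric, score, y) {
    switch(metric,
        auc = .concordanceAUC(as.numeric(score), as.integer(y)),
        accuracy = {
            lev <- colnames(score)
            mean(lev[max.col(score, ties.method = "first")] ==
                 as.character(y))
        },
        slope = calibration(as.numeric(score), as.integer(y))$slope,
        intercept = calibration(as.numeric(score), as.integer(y))$intercept,
        stop("unknown metric: ", metric))
}

#' Bootstrap optimism correction (Harrell's procedure)
#'
#' Refits the model on \code{B} bootstrap resamples; each resample's optimism
#' is its apparent metric on the bootstrap data minus its metric on the
#' original data, and the corrected metric is the apparent metric minus the
#' mean optimism. Bootstrap draws on which the model fails are skipped and
#' counted.
#'
#' @param spec model spec (see \code{\link{binaryLogisticSpec}}).
#' @param features,outcomes the data.
#' @param metric \code{"auc"}, \code{"accuracy"}, \code{"slope"} or
#'   \code{"intercept"}.
#' @param B bootstrap iterations (>= 200; default 500).
#' @param seed integer seed.
#' @return list with \code{apparent}, \code{optimism}, \code{corrected},
#'   \code{B}, \code{failed}, \code{seed}.
#' @export
bootstrapOptimism <- function(spec, features, outcomes, metric = "auc",
                              B = 500, seed = 1L) {
    if (B < 200) stop("B must be >= 200")
    X <- as.data.frame(features)
    y <- outcomes
    full <- spec$fit(X, y)
    apparent <- .metricValue(metric, spec$score(full, X), y)
    n <- nrow(X)
    res <- withr::with_seed(seed, {
        opt <- numeric(0); failed <- 0L
        for (b in seq_len(B)) {
            i <- sample(n, replace = TRUE)
            val <- try({
                fb <- spec$fit(X[i, , drop = FALSE], y[i])
                mBoot <- .metricValue(metric,
                                      spec$score(fb, X[i, , drop = FALSE]),
                                      y[i])
                mOrig <- .metricValue(metric, spec$score(fb, X), y)
                mBoot - mOrig
            }, silent = TRUE)
            if (inherits(val, "try-error") || !is.finite(val))
                failed <- failed + 1L
            else opt <- c(opt, val)
        }
        list(opt = opt, failed = failed)
    })
    meanOpt <- mean(res$opt)
    list(apparent = apparent, optimism = meanOpt,
         corrected = apparent - meanOpt, B = B, failed = res$failed,
         seed = seed)
}

#' Repeated stratified k-fold cross-validation
#'
#' Class-stratified folds (k reduced with a warning when the smallest class
#' has fewer than k members); out-of-fold metric per fold and repeat,
#' summarized as mean and SD. Deterministic per seed.
#'
#' @inheritParams bootstrapOptimism
#' @param k folds (default 10).
#' @param repeats number of repeats (default 5).
#' @return list with \code{values} (per repeat x fold), \code{mean},
#'   \code{sd}, \code{k}, \code{repeats}, \code{seed}.
#' @export
repeatedCv <- function(spec, features, outcomes, metric = "auc", k = 10,
                       repeats = 5, seed = 1L) {
    X <- as.data.frame(features)
    y <- outcomes
    minClass <- min(table(y))
    if (minClass < k) {
        k <- max(2, minClass)
        warning("reducing k to ", k, " (smallest class size)")
    }
    vals <- withr::with_seed(seed, {
        unlist(lapply(seq_len(repeats), function(r) {
            folds <- .cvFolds(as.character(y), k, seed = sample.int(2^30, 1))
            vapply(seq_len(k), function(f) {
                tr <- folds != f
                if (length(unique(y[!tr])) < 2) return(NA_real_)
                fit <- spec$fit(X[tr, , drop = FALSE], y[tr])
                .metricValue(metric, spec$score(fit, X[!tr, , drop = FALSE]),
                             y[!tr])
            }, numeric(1))
        }))
    })
    list(values = vals, mean = mean(vals, na.rm = TRUE),
         sd = stats::sd(vals, na.rm = TRUE), k = k, repeats = repeats,
         seed = seed)
}
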