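test_that("ROC analysis matches concordance counting and Youden search", {
    r <- rocAuc(c(3, 5, 1, 4), c(1, 1, 0, 0))
    expect_equal(r$auc, 0.75)
    perfect <- rocAuc(c(10, 9, 8, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
    expect_equal(perfect$auc, 1)
    expect_equal(perfect$youden$sensitivity, 1)
    expect_equal(perfect$youden$specificity, 1)
    expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
    withr::with_seed(41, {
        for (i in 1:1000) {
            n <- sample(6:30, 1)
            scores <- sample(1:8, n, replace = TRUE)   # ties guaranteed
            y <- c(0, 1, rbinom(n - 2, 1, 0.5))
            r <- rocAuc(scores, y)
            expect_equal(r$auc, aucBrute(scores, y), tolerance = 1e-12)
            # Youden point equals exhaustive argmax over all cutpoints
            yi <- vapply(c(-Inf, sort(unique(scores)) + 0.5), function(t) {
                sens <- mean(scores[y == 1] > t)
                spec <- mean(scores[y == 0] <= t)
                sens + spec - 1
            }, numeric(1))
            expect_equal(r$youden$index, max(yi), tolerance = 1e-9)
        }
    })
})

test_that("AUC is 0.5 on label-independent scores", {
    withr::with_seed(43, {
        s <- rnorm(1000)
        y <- rbinom(1000, 1, 0.5)
    })
    expect_lt(abs(rocAuc(s, y)$auc - 0.5), 0.05)
})

test_that("composite models emit normalized probabilities and fit separable data", {
    withr::with_seed(47, {
        X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2),
                   matrix(rnorm(40, 12), 20, 2))
        colnames(X) <- c("u", "v")
        y <- rep(c("mild", "moderate", "severe"), each = 20)
    })
    for (kind in c("ovr_logistic", "random_forest")) {
        m <- fitCompositeModel(X, y, kind = kind, seed = 2)
        p <- predictProbs(m, X)
        expect_equal(unname(rowSums(p)), rep(1, 60), tolerance = 1e-9)
        acc <- mean(colnames(p)[max.col(p)] == y)
        expect_equal(acc, 1)
    }
    expect_error(fitCompositeModel(X, rep("one", 60)), ">= 2 classes")
    expect_identical(
        predictProbs(fitCompositeModel(X, y, "random_forest", seed = 5), X),
        predictProbs(fitCompositeModel(X, y, "random_forest", seed = 5), X))
})

test_that("null-label cross-validated accuracy sits at chance", {
    withr::with_seed(53, {
        X <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
        y <- factor(rep(c("mild", "moderate", "severe"), each = 30))
        yPerm <- sample(y)
    })
    cv <- repeatedCv(compositeSpec("ovr_logistic"), X, yPerm,
                     metric = "accuracy", k = 5, repeats = 4, seed = 3)
    expect_lt(abs(cv$mean - 1 / 3), 0.12)
})

test_that("permutation importance ranks a fully predictive feature first", {
    withr::with_seed(59, {
        signal <- rep(c(0, 5, 10), each = 20) + rnorm(60, sd = 0.3)
        X <- data.frame(signal = signal, noise = rnorm(60))
        y <- rep(c("mild", "moderate", "severe"), each = 20)
    })
    m <- fitCompositeModel(X, y, kind = "random_forest", seed = 7)
    imp <- permutationImportance(m, X, y, nPerm = 20, seed = 11)
    expect_equal(names(imp)[1], "signal")
    expect_lt(abs(imp["noise"]), 0.1)
    expect_identical(imp, permutationImportance(m, X, y, nPerm = 20,
                                                seed = 11))
    expect_error(permutationImportance(m, X[, "noise", drop = FALSE], y,
                                       nPerm = 20), "absent")
})

test_that("calibration recovers slope 1 / intercept 0 on calibrated predictions", {
    withr::with_seed(61, {
        p <- runif(5000, 0.02, 0.98)
        y <- rbinom(5000, 1, p)
    })
    cal <- calibration(p, y)
    expect_equal(cal$slope, 1, tolerance = 0.1)
    expect_equal(cal$intercept, 0, tolerance = 0.1)
    expect_equal(sum(cal$bins$n), 5000)
    expect_lte(diff(range(cal$bins$n)), 1)
    expect_true(all(cal$bins$observedRate >= 0 & cal$bins$observedRate <= 1))
    # constant predictions leave the slope undefined but flagged
    calC <- calibration(rep(0.4, 100), rbinom(100, 1, 0.4))
    expect_true(calC$degenerate)
    expect_true(is.na(calC$slope))
    # exact 0/1 predictions are clipped and counted
    calClip <- calibration(c(0, 1, runif(98)), rbinom(100, 1, 0.5))
    expect_equal(calClip$nClipped, 2)
})

test_that("net benefit equals hand-computed contingency tables", {
    p <- c(rep(0.9, 30), rep(0.9, 20), rep(0.1, 50))
    y <- c(rep(1, 30), rep(0, 20), rep(0, 25), rep(1, 25))
    dc <- decisionCurve(p, y, thresholds = 0.2)
    expect_equal(dc$netBenefit, 0.30 - 0.20 * 0.25)
    expect_equal(dc$treatNone, 0)
    withr::with_seed(67, {
        for (i in 1:50) {
            n <- sample(20:60, 1)
            pp <- runif(n)
            yy <- rbinom(n, 1, 0.4)
            pt <- runif(1, 0.05, 0.95)
            expect_equal(decisionCurve(pp, yy, pt)$netBenefit,
                         netBenefitBrute(pp, yy, pt), tolerance = 1e-12)
        }
    })
    # thresholds below every prediction: model == treat-all
    dcAll <- decisionCurve(p, y, thresholds = 0.05)
    expect_equal(dcAll$netBenefit, dcAll$treatAll)
    expect_error(decisionCurve(p, y, numeric(0)), "empty")
    expect_error(decisionCurve(p, y, c(0.5, 1.5)), "\\(0, 1\\)")
})

test_that("bootstrap optimism is an identity and honest under the null", {
    withr::with_seed(71, {
        X <- matrix(rnorm(40 * 4), 40, 4,
                    dimnames = list(NULL, paste0("f", 1:4)))
        y <- rbinom(40, 1, 0.5)
    })
    rep1 <- bootstrapOptimism(binaryLogisticSpec(), X, y, metric = "auc",
                              B = 200, seed = 5)
    expect_equal(rep1$corrected, rep1$apparent - rep1$optimism)
    expect_lt(abs(rep1$corrected - 0.5), 0.07)
    expect_gt(rep1$apparent, rep1$corrected)   # overfit apparent AUC
    expect_identical(rep1, bootstrapOptimism(binaryLogisticSpec(), X, y,
                                             metric = "auc", B = 200,
                                             seed = 5))
    expect_error(bootstrapOptimism(binaryLogisticSpec(), X, y, B = 50),
                 ">= 200")
})

test_that("optimism correction removes most of the apparent-true gap", {
    withr::with_seed(73, {
        gaps <- replicate(8, {
            X <- matrix(rnorm(40 * 4), 40, 4,
                        dimnames = list(NULL, paste0("f", 1:4)))
            y <- rbinom(40, 1, 0.5)
            r <- bootstrapOptimism(binaryLogisticSpec(), X, y,
                                   metric = "auc", B = 200,
                                   seed = sample.int(2^30, 1))
            c(apparent = r$apparent, corrected = r$corrected)
        })
    })
    apparentGap <- mean(gaps["apparent", ]) - 0.5
    correctedGap <- abs(mean(gaps["corrected", ]) - 0.5)
    expect_lt(correctedGap, apparentGap / 2)
})

test_that("repeated CV is stratified, deterministic and honest", {
    withr::with_seed(79, {
        Xsep <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
                      matrix(rnorm(30, 8, 0.3), 15, 2))
        colnames(Xsep) <- c("a", "b")
        ySep <- rep(0:1, each = 15)
        Xnull <- matrix(rnorm(60 * 3), 60, 3,
                        dimnames = list(NULL, c("a", "b", "c")))
        yNull <- rbinom(60, 1, 0.5)
    })
    cvSep <- repeatedCv(binaryLogisticSpec(), Xsep, ySep, metric = "auc",
                        k = 5, repeats = 2, seed = 1)
    expect_equal(cvSep$mean, 1, tolerance = 1e-9)
    cvNull <- repeatedCv(binaryLogisticSpec(), Xnull, yNull, metric = "auc",
                         k = 5, repeats = 4, seed = 2)
    expect_lt(abs(cvNull$mean - 0.5), 0.15)
    expect_identical(cvNull$values,
                     repeatedCv(binaryLogisticSpec(), Xnull, yNull,
                                metric = "auc", k = 5, repeats = 4,
                                seed = 2)$values)
    expect_warning(repeatedCv(binaryLogisticSpec(), Xsep, ySep, k = 20,
                              repeats = 1, seed = 3), "reducing k")
})
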