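test_that("geometric mean matches closed forms", {
    expect_equal(geometricMean(c(4, 4, 4)), 4)
    expect_equal(geometricMean(c(1, 100)), 10)
    expect_equal(geometricMean(c(0, 1), pseudocount = 0.01),
                 exp(0.5 * (log(0.01) + log(1.01))))
    expect_equal(geometricMean(c(3, 7, 11)), geometricMean(c(11, 3, 7)))
    expect_error(geometricMean(numeric(0)), "empty")
    expect_error(geometricMean(c(-1, 2)), "negative")
    expect_error(geometricMean(c(0, 1)), "strictly positive")
})

test_that("IDS balance point, scale shift and panel structure", {
    panel <- defaultPanel(pseudocount = 1e-9)
    v <- c(BCL6pos = 5, ICOSposBCL6pos = 2, CD8posCD25pos = 7,
           Treg = 5, TransitionalBreg = 2, MemoryBreg = 7)
    expect_equal(computeIDS(v, panel), 0, tolerance = 1e-9)
    vE <- v
    vE[panel@inflammatory] <- exp(1) * v[panel@regulatory]
    expect_equal(computeIDS(vE, panel), 1, tolerance = 1e-6)
    expect_error(computeIDS(v[-1], panel), "missing panel subsets")
    # default panel: exactly three subsets per side, disjoint
    expect_length(panel@inflammatory, 3)
    expect_length(panel@regulatory, 3)
    expect_length(intersect(panel@inflammatory, panel@regulatory), 0)
})

test_that("IDS is antisymmetric, log-equivariant and order-invariant", {
    panel <- defaultPanel(pseudocount = 1e-12)
    swapped <- PanelDefinition(inflammatory = panel@regulatory,
                               regulatory = panel@inflammatory,
                               pseudocount = 1e-12)
    withr::with_seed(99, {
        for (i in 1:1000) {
            v <- setNames(exp(runif(6, -3, 3)),
                          c(panel@inflammatory, panel@regulatory))
            ids <- computeIDS(v, panel)
            expect_lt(abs(computeIDS(v, swapped) + ids), 1e-12)
            c0 <- exp(runif(1, -2, 2))
            vs <- v
            vs[panel@inflammatory] <- vs[panel@inflammatory] * c0
            expect_lt(abs(computeIDS(vs, panel) - (ids + log(c0))), 1e-9)
            perm <- PanelDefinition(sample(panel@inflammatory),
                                    sample(panel@regulatory),
                                    pseudocount = 1e-12)
            expect_lt(abs(computeIDS(v, perm) - ids), 1e-12)
        }
    })
})

test_that("score table centres deltaIDS on controls and scores patients", {
    coh <- smallCohort(nP = 15, nC = 8, seed = 4)
    st <- computeScoreTable(coh)
    expect_equal(mean(st$deltaIds[st$group == "control"]), 0,
                 tolerance = 1e-12)
    # control whose ids equals the control mean has deltaIds equal to zero
    expect_equal(st$deltaIds, st$ids - mean(st$ids[st$group == "control"]))
    # clinical z over scored patients: mean 0, sd 1
    z <- st$clinicalZ[!is.na(st$clinicalZ)]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    expect_true(all(is.na(st$cds[st$group == "control"])))
    expect_true(all(st$cds[st$group == "patient"] %in% 0:4))
})

test_that("planted inflammatory effects raise patient deltaIDS", {
    coh <- smallCohort(nP = 40, nC = 20, seed = 21, effectScale = 2)
    st <- computeScoreTable(coh)
    expect_gt(mean(st$deltaIds[st$group == "patient"]), 0)
})

test_that("identical subset values make proMean/antiMean undefined", {
    f <- matrix(5, 10, 6,
                dimnames = list(paste0("S", 1:10),
                                c(defaultPanel()@inflammatory,
                                  defaultPanel()@regulatory)))
    coh <- ImmuneCohort(f, group = rep(c("patient", "control"), each = 5))
    expect_error(computeScoreTable(coh), "degenerate control SD")
})

test_that("CDS counts present domains and respects missingness", {
    doms <- clinicalDomains("four")
    expect_identical(computeCDS(setNames(c(1, 1, 1, 1), doms), doms), 4L)
    expect_identical(computeCDS(setNames(c(0, 0, 0, 0), doms), doms), 0L)
    expect_identical(computeCDS(setNames(c(1, 0, 1, 0), doms), doms), 2L)
    expect_true(is.na(computeCDS(setNames(c(1, NA, 1, 0), doms), doms)))
    expect_identical(computeCDS(setNames(c(1, 0, 1, 0), rev(doms)), doms),
                     computeCDS(setNames(c(1, 0, 1, 0), rev(doms)), rev(doms)))
    expect_error(computeCDS(setNames(c(2, 0, 1, 0), doms), doms), "0, 1")
    expect_error(computeCDS(setNames(1, doms[1]), doms), "missing domains")
    expect_length(clinicalDomains("six"), 6)
})

test_that("normalized ratios are control-centred and homogeneous", {
    coh <- smallCohort(nP = 10, nC = 6, seed = 8)
    r <- ratioVsControls(coh, "BCL6pos", "Treg")
    g <- groupLabels(coh)
    expect_equal(mean(r[g == "control"]), 1, tolerance = 1e-12)
    # doubling patient inflammatory values doubles their normalized ratio
    f <- frequencies(coh)
    f2 <- f
    f2[g == "patient", "BCL6pos"] <- pmin(f2[g == "patient", "BCL6pos"] * 2,
                                          99.9)
    coh2 <- ImmuneCohort(f2, group = unname(g))
    r2 <- ratioVsControls(coh2, "BCL6pos", "Treg", pseudocount = 0)
    r0 <- ratioVsControls(coh, "BCL6pos", "Treg", pseudocount = 0)
    keep <- f[g == "patient", "BCL6pos"] * 2 < 99.9
    expect_equal(unname(r2[g == "patient"][keep]),
                 unname(2 * r0[g == "patient"][keep]), tolerance = 1e-9)
    expect_equal(unname(r2[g == "control"]), unname(r0[g == "control"]))
    # a single control normalizes itself to exactly 1
    one <- ImmuneCohort(f[c(1, 2, 16), ], group = c("patient", "patient",
                                                    "control"))
    expect_equal(unname(ratioVsControls(one, "BCL6pos", "Treg")[3]), 1)
})

test_that("balance search recovers a planted separating pair", {
    withr::with_seed(31, {
        n <- 60
        X <- matrix(exp(rnorm(n * 6)), n, 6,
                    dimnames = list(NULL, paste0("f", 1:6)))
        y <- rep(0:1, each = n / 2)
        # plant a perfectly separating log-ratio between f2 and f5
        lr <- ifelse(y == 1, 2, -2) + rnorm(n, sd = 0.1)
        X[, "f2"] <- X[, "f5"] * exp(lr)
        sol <- selectBalance(X, y, maxVars = 2, cvFolds = 5, seed = 1)
        expect_setequal(c(sol$numerator, sol$denominator), c("f2", "f5"))
        expect_gt(sol$cvAuc, 0.95)
        expect_length(sol$numerator, 1)
        expect_length(sol$denominator, 1)
    })
})

test_that("balance search is honest on pure noise", {
    aucs <- vapply(1:10, function(i) {
        withr::with_seed(1000 + i, {
            X <- matrix(exp(rnorm(60 * 8)), 60, 8,
                        dimnames = list(NULL, paste0("f", 1:8)))
            y <- rep(0:1, each = 30)
        })
        selectBalance(X, y, maxVars = 4, cvFolds = 5, seed = i)$cvAuc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("balance search input contracts", {
    X <- matrix(exp(rnorm(30 * 3)), 30, 3)
    expect_error(selectBalance(X, rep(1, 30), seed = 1), "both classes")
    expect_error(selectBalance(X, rep(0:1, 15), maxVars = 1, seed = 1),
                 "maxVars")
    expect_error(selectBalance(X[, 1:2], rep(0:1, 15), seed = 1),
                 "at least 3")
})

test_that("balance search finds the IDS panel on a planted 3-vs-3 signal", {
    panel <- defaultPanel()
    subsets <- c(panel@inflammatory, panel@regulatory)
    withr::with_seed(77, {
        n <- 200
        y <- rep(0:1, each = n / 2)
        shift <- ifelse(y == 1, 0.45, -0.45)
        # noise centred within each triplet: only the full 3-vs-3 balance
        # cancels it, so the search must grow past any partial solution
        eI <- matrix(rnorm(n * 3, sd = 2), n, 3)
        eI <- eI - rowMeans(eI)
        eR <- matrix(rnorm(n * 3, sd = 2), n, 3)
        eR <- eR - rowMeans(eR)
        X <- exp(cbind(eI + shift, eR - shift) +
                 matrix(rnorm(n * 6, sd = 0.1), n, 6))
        colnames(X) <- c(panel@inflammatory, panel@regulatory)
    })
    sol <- selectBalance(X, y, maxVars = 6, cvFolds = 5, seed = 2)
    expect_setequal(sol$numerator, panel@inflammatory)
    expect_setequal(sol$denominator, panel@regulatory)
    expect_gt(sol$cvAuc, 0.95)
})
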