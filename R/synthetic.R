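#' Simulation configuration for synthetic cohorts
#'
#' Describes a cohort generator on the logit scale: each subset frequency is
#' drawn as \code{100 * plogis(z)} with \code{z} Gaussian around a per-subset
#' baseline; patients additionally receive a signed logit shift scaled by a
#' latent severity in [0, 1], and the same severity drives the Bernoulli
#' probabilities of the binary clinical domains. Defaults mirror the study
#' conditions of the cohort the analysis targets: 39 patients, 17 age-matched
#' controls, reduced Tregs / transitional Bregs / memory Bregs / memory T
#' cells and expanded BCL6+, ICOS+BCL6+ and activated CD8+ subsets.
#'
#' @param nPatients,nControls group sizes (each >= 2).
#' @param subsetNames character, subset identifiers.
#' @param baselineMean,baselineSd per-subset logit-scale location and scale
#'   (recycled if length 1).
#' @param effectSizes named numeric, signed logit shift applied to patients at
#'   severity 1 (scaled linearly by each patient's severity); names must be
#'   subsets of \code{subsetNames}.
#' @param severityShape1,severityShape2 Beta parameters of the latent
#'   severity distribution on [0, 1].
#' @param cellularCoupling how the latent severity scales the cellular
#'   shifts: \code{"inverse"} (default) scales each patient's shift by
#'   \code{1 - severity}, \code{"direct"} by \code{severity}. The default
#'   reproduces the empirical structure the analysis targets, in which the
#'   clinically most burdened patients are not the cellularly most shifted,
#'   so the IDS-versus-clinical-z correlation over patients is negative
#'   while patients as a group remain shifted away from controls.
#' @param clinicalDomains character, clinical domain names.
#' @param clinicalLoadings named list, one \code{c(intercept, slope)} pair per
#'   domain: P(present) = intercept + slope * severity (must stay in [0, 1]).
#' @param correlationStructure optional list with elements \code{patient}
#'   and/or \code{control}, each a subset-by-subset correlation matrix target
#'   on the logit scale.
#' @param geneticCategories optional character pool of genetic labels to
#'   assign to patients.
#' @param seed integer seed; all randomness flows through it.
#' @return a \code{SimulationConfig} (validated list).
#' @seealso \code{\link{generateCohort}}, \code{\link{plantCorrelationFlip}}
#' @export
simulationConfig <- function(nPatients = 39, nControls = 17,
                             subsetNames = defaultSubsetNames(),
                             baselineMean = defaultBaselineMeans()[subsetNames],
                             baselineSd = 0.6,
                             effectSizes = defaultEffectSizes(),
                             severityShape1 = 2, severityShape2 = 2,
                             cellularCoupling = c("inverse", "direct"),
                             clinicalDomains = ImmuneBalance::clinicalDomains("four"),
                             clinicalLoadings = defaultClinicalLoadings(clinicalDomains),
                             correlationStructure = NULL,
                             geneticCategories = NULL,
                             seed = 1L) {
    if (nPatients < 2 || nControls < 2)
        stop("nPatients and nControls must both be >= 2")
    p <- length(subsetNames)
    baselineMean <- rep_len(unname(baselineMean), p)
    baselineSd <- rep_len(unname(baselineSd), p)
    if (any(baselineSd <= 0)) stop("baselineSd must be positive")
    unknown <- setdiff(names(effectSizes), subsetNames)
    if (length(unknown))
        stop("effectSizes name unknown subsets: ",
             paste(unknown, collapse = ", "))
    eff <- stats::setNames(numeric(p), subsetNames)
    eff[names(effectSizes)] <- effectSizes
    if (!is.null(correlationStructure)) {
        for (g in names(correlationStructure)) {
            R <- correlationStructure[[g]]
            if (!identical(dim(R), c(p, p)))
                stop("correlation target for '", g, "' has wrong dimensions")
            .checkPSD(R, g)
        }
    }
    missingLoad <- setdiff(clinicalDomains, names(clinicalLoadings))
    if (length(missingLoad))
        stop("clinicalLoadings missing domains: ",
             paste(missingLoad, collapse = ", "))
    cfg <- list(nPatients = as.integer(nPatients),
                nControls = as.integer(nControls),
                subsetNames = subsetNames,
                baselineMean = stats::setNames(baselineMean, subsetNames),
                baselineSd = stats::setNames(baselineSd, subsetNames),
                effectSizes = eff,
                severityShape1 = severityShape1,
                severityShape2 = severityShape2,
                cellularCoupling = match.arg(cellularCoupling),
                clinicalDomains = clinicalDomains,
                clinicalLoadings = clinicalLoadings[clinicalDomains],
                correlationStructure = correlationStructure,
                geneticCategories = geneticCategories,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

.checkPSD <- function(R, label = "correlation target") {
    if (any(abs(R - t(R)) > 1e-8)) stop(label, ": matrix not symmetric")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
        stop(label, ": correlation target matrix is not positive semi-definite")
    invisible(TRUE)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nPatients, "patients /", x$nControls,
        "controls,", length(x$subsetNames), "subsets,",
        length(x$clinicalDomains), "clinical domains, seed", x$seed, "\n")
    nz <- x$effectSizes[x$effectSizes != 0]
    if (length(nz))
        cat("  nonzero effects:",
            paste(sprintf("%s %+0.2f", names(nz), nz), collapse = ", "), "\n")
    invisible(x)
}

#' Default subset identifiers of the synthetic panel
#'
#' The six IDS panel subsets plus six bystander populations that give the
#' correlation-network and metaclustering stages realistic width.
#' @return character vector of 12 subset names.
#' @export
defaultSubsetNames <- function() {
    c("Treg", "TransitionalBreg", "MemoryBreg", "BCL6pos", "ICOSposBCL6pos",
      "CD8posCD25pos", "MemoryT", "IL17Apos", "CCR6pos", "CXCR5pos",
      "Plasmablast", "CD8posHLADRpos")
}

#' Default per-subset baseline means (logit of percent/100)
#' @return named numeric vector on the logit scale.
#' @export
defaultBaselineMeans <- function() {
    pct <- c(Treg = 4, TransitionalBreg = 6, MemoryBreg = 10, BCL6pos = 8,
             ICOSposBCL6pos = 3, CD8posCD25pos = 5, MemoryT = 35,
             IL17Apos = 2, CCR6pos = 15, CXCR5pos = 12, Plasmablast = 1.5,
             CD8posHLADRpos = 6)
    stats::qlogis(pct / 100)
}

#' Default signed patient effects on the logit scale
#'
#' Signs follow the group differences the analysis is built around:
#' regulatory subsets and memory T cells reduced, Tfh-like and activated
#' CD8+ subsets expanded. Magnitudes are free parameters of the generator.
#' @return named numeric vector of logit shifts at severity 1.
#' @export
defaultEffectSizes <- function() {
    c(Treg = -1.2, TransitionalBreg = -1.2, MemoryBreg = -0.8,
      MemoryT = -0.8, BCL6pos = 1.0, ICOSposBCL6pos = 1.0,
      CD8posCD25pos = 1.0, IL17Apos = 0.8, Plasmablast = 0.6,
      CD8posHLADRpos = 0.6)
}

#' Default severity-to-clinical loadings
#' @param domains character vector of domain names.
#' @return named list of \code{c(intercept, slope)} pairs.
#' @export
defaultClinicalLoadings <- function(domains) {
    slopes <- rep_len(c(0.9, 0.8, 0.7, 0.35, 0.6, 0.5), length(domains))
    out <- lapply(slopes, function(s) c(intercept = 0.05, slope = s))
    stats::setNames(out, domains)
}

.drawLogitMatrix <- function(n, mu, sd, R = NULL) {
    p <- length(sd)
    Z <- matrix(stats::rnorm(n * p), n, p)
    if (!is.null(R)) {
        ev <- eigen(R, symmetric = TRUE)
        L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
        Z <- Z %*% L
    }
    sweep(sweep(Z, 2, sd, `*`), 2, rep_len(mu, p), `+`)
}

#' Generate a synthetic cohort
#'
#' Draws patient and control subset frequencies on the logit scale (optionally
#' with planted within-group correlation), back-transforms to percent, and
#' couples a latent per-patient severity to both the cellular effects and the
#' binary clinical domains. Deterministic for a fixed config (the config's
#' seed drives all randomness).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return an \linkS4class{ImmuneCohort} with latent severity stored for
#'   patients.
#' @examples
#' cfg <- simulationConfig(nPatients = 10, nControls = 5, seed = 7)
#' generateCohort(cfg)
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withr::with_seed(config$seed, {
        nP <- config$nPatients; nC <- config$nControls
        subsets <- config$subsetNames
        severity <- stats::rbeta(nP, config$severityShape1,
                                 config$severityShape2)
        coupling <- if (identical(config$cellularCoupling, "direct"))
            severity else 1 - severity
        muP <- matrix(config$baselineMean, nP, length(subsets), byrow = TRUE) +
            outer(coupling, config$effectSizes)
        zP <- .drawLogitMatrix(nP, 0, config$baselineSd,
                               config$correlationStructure$patient) + muP
        zC <- .drawLogitMatrix(nC, config$baselineMean, config$baselineSd,
                               config$correlationStructure$control)
        freq <- 100 * stats::plogis(rbind(zP, zC))
        ids <- c(sprintf("P%02d", seq_len(nP)), sprintf("C%02d", seq_len(nC)))
        dimnames(freq) <- list(ids, subsets)
        group <- rep(c("patient", "control"), c(nP, nC))
        genetic <- NULL
        if (!is.null(config$geneticCategories))
            genetic <- c(sample(config$geneticCategories, nP, replace = TRUE),
                         rep(NA_character_, nC))
        clin <- generateClinicalFeatures(severity, config$clinicalLoadings,
                                         seed = config$seed + 1L)
        rownames(clin) <- ids[seq_len(nP)]
        ImmuneCohort(freq, group = group, clinical = clin, genetic = genetic,
                     severity = c(severity, rep(NA_real_, nC)),
                     sampleIds = ids)
    })
}

#' Draw binary clinical domains from latent severity
#'
#' Each domain is Bernoulli with success probability
#' \code{intercept + slope * severity}; increasing loadings therefore couple
#' higher severity to more recorded manifestations.
#'
#' @param severity numeric in [0, 1], one value per patient.
#' @param loadings named list of \code{c(intercept, slope)} pairs (or plain
#'   numerics, read as slope with intercept 0), one per domain.
#' @param seed integer seed.
#' @return integer 0/1 matrix, patients in rows, domains in columns.
#' @export
generateClinicalFeatures <- function(severity, loadings, seed = 1L) {
    if (any(severity < 0 | severity > 1))
        stop("severity values must lie in [0, 1]")
    loadings <- lapply(loadings, function(l)
        if (length(l) == 1) c(intercept = 0, slope = unname(l)) else l)
    probs <- vapply(loadings, function(l)
        l[[1]] + l[[2]] * severity, numeric(length(severity)))
    probs <- matrix(probs, nrow = length(severity))
    if (any(probs < -1e-12 | probs > 1 + 1e-12))
        stop("loading transform produced probabilities outside [0, 1]")
    probs <- pmin(pmax(probs, 0), 1)
    withr::with_seed(seed, {
        m <- matrix(as.integer(stats::runif(length(probs)) < probs),
                    nrow = length(severity),
                    dimnames = list(NULL, names(loadings)))
        m
    })
}

#' Plant a patient-versus-control correlation flip
#'
#' Returns a copy of \code{config} whose generated cohorts exhibit the
#' requested within-group logit-scale correlations for one subset pair —
#' the fixture for delta-correlation network tests.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param pair character of length 2, two distinct subset names.
#' @param rControl,rPatient target correlations, each with absolute value < 1.
#' @return the modified \code{SimulationConfig}.
#' @export
plantCorrelationFlip <- function(config, pair, rControl, rPatient) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (length(pair) != 2 || pair[1] == pair[2])
        stop("'pair' must name two distinct subsets")
    if (abs(rControl) >= 1 || abs(rPatient) >= 1)
        stop("correlation targets must have absolute value < 1")
    idx <- match(pair, config$subsetNames)
    if (anyNA(idx)) stop("pair names unknown subsets")
    p <- length(config$subsetNames)
    cs <- config$correlationStructure
    if (is.null(cs)) cs <- list()
    for (g in c("control", "patient")) {
        R <- cs[[g]]
        if (is.null(R)) R <- diag(p)
        r <- if (g == "control") rControl else rPatient
        R[idx[1], idx[2]] <- R[idx[2], idx[1]] <- r
        .checkPSD(R, paste0(g, " correlation target"))
        cs[[g]] <- R
    }
    config$correlationStructure <- cs
    config
}

#' Write a cohort to plain-text tables
#'
#' Emits \code{subsets.csv} (sample_id + one column per subset),
#' \code{labels.csv} (sample_id, group, genetic, severity) and, when clinical
#' data exist, \code{clinical.csv}. UTF-8, "." decimal separator.
#'
#' @param cohort an \linkS4class{ImmuneCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(subsets = file.path(dir, "subsets.csv"),
               labels = file.path(dir, "labels.csv"))
    f <- frequencies(cohort)
    utils::write.csv(data.frame(sample_id = rownames(f), f,
                                check.names = FALSE),
                     paths[["subsets"]], row.names = FALSE, quote = FALSE)
    lab <- data.frame(sample_id = rownames(f),
                      group = unname(groupLabels(cohort)))
    gl <- geneticLabels(cohort)
    if (!is.null(gl)) lab$genetic <- unname(gl)
    sv <- latentSeverity(cohort)
    if (!is.null(sv)) lab$severity <- unname(sv)
    utils::write.csv(lab, paths[["labels"]], row.names = FALSE, quote = FALSE)
    cl <- clinicalMatrix(cohort)
    if (!is.null(cl)) {
        keep <- rowSums(!is.na(cl)) > 0
        paths <- c(paths, clinical = file.path(dir, "clinical.csv"))
        utils::write.csv(data.frame(sample_id = rownames(cl)[keep],
                                    cl[keep, , drop = FALSE],
                                    check.names = FALSE),
                         paths[["clinical"]], row.names = FALSE, quote = FALSE)
    }
    invisible(paths)
}
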