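#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Cohort of post-gated flow-cytometry subset frequencies
#'
#' \code{ImmuneCohort} extends \linkS4class{SummarizedExperiment}: the
#' \code{"frequencies"} assay holds percent-of-parent subset frequencies
#' (subsets as rows, samples as columns, every value strictly inside
#' (0, 100)), and \code{colData} carries the per-sample annotation — the
#' \code{group} label (\code{patient} or \code{control}), an optional binary
#' clinical-domain matrix, optional genetic-diagnosis labels, and, for
#' synthetic cohorts, the latent severity used to generate the sample.
#'
#' @slot assays,colData,... inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{ImmuneCohort}} (constructor),
#'   \code{\link{generateCohort}}, \code{\link{readCohort}}
#' @export
setClass("ImmuneCohort", contains = "SummarizedExperiment")

.validImmuneCohort <- function(object) {
    msg <- NULL
    if (!"frequencies" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'frequencies' is required")
    else {
        f <- SummarizedExperiment::assay(object, "frequencies")
        if (anyNA(f))
            msg <- c(msg, "frequencies contain missing values")
        else if (any(f <= 0 | f >= 100))
            msg <- c(msg, "frequencies must lie strictly within (0, 100)")
    }
    cd <- colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (!all(cd$group %in% c("patient", "control")))
        msg <- c(msg, "group labels must be 'patient' or 'control'")
    if ("clinical" %in% colnames(cd)) {
        cl <- cd$clinical
        if (!is.matrix(cl))
            msg <- c(msg, "'clinical' column must be a matrix")
        else if (!all(cl %in% c(0, 1, NA)))
            msg <- c(msg, "clinical entries must be 0, 1 or NA")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (is.null(msg)) TRUE else msg
}
setValidity("ImmuneCohort", .validImmuneCohort)

#' Construct an ImmuneCohort
#'
#' @param frequencies numeric matrix of percent-of-parent frequencies,
#'   samples in rows and subsets in columns (the conventional orientation of
#'   an exported gating table); values must be strictly inside (0, 100).
#' @param group character or factor, one of \code{"patient"}/\code{"control"}
#'   per sample.
#' @param clinical optional binary (0/1, NA allowed) matrix of clinical
#'   manifestation domains, samples in rows; rows for samples without
#'   clinical data may be all-NA or omitted entirely.
#' @param genetic optional character vector of genetic-diagnosis labels.
#' @param severity optional numeric latent severity in [0, 1] (synthetic
#'   cohorts only).
#' @param sampleIds sample identifiers; defaults to
#'   \code{rownames(frequencies)}.
#' @return an \linkS4class{ImmuneCohort}.
#' @examples
#' f <- matrix(runif(12, 1, 40), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("subset", 1:4)))
#' ImmuneCohort(f, group = c("patient", "patient", "control"))
#' @export
ImmuneCohort <- function(frequencies, group, clinical = NULL, genetic = NULL,
                         severity = NULL, sampleIds = rownames(frequencies)) {
    frequencies <- as.matrix(frequencies)
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(nrow(frequencies)))
    rownames(frequencies) <- sampleIds
    n <- nrow(frequencies)
    group <- as.character(group)
    if (length(group) != n)
        stop("'group' must have one label per sample")
    cd <- DataFrame(group = group, row.names = sampleIds)
    if (!is.null(clinical)) {
        clinical <- as.matrix(clinical)
        if (is.null(rownames(clinical)))
            stop("'clinical' must carry sample ids as rownames")
        full <- matrix(NA_real_, n, ncol(clinical),
                       dimnames = list(sampleIds, colnames(clinical)))
        keep <- intersect(rownames(clinical), sampleIds)
        full[keep, ] <- clinical[keep, , drop = FALSE]
        cd$clinical <- full
    }
    if (!is.null(genetic)) cd$genetic <- as.character(genetic)
    if (!is.null(severity)) {
        sv <- rep(NA_real_, n)
        sv[seq_along(severity)] <- severity
        if (length(severity) == n) sv <- as.numeric(severity)
        cd$severity <- sv
    }
    se <- SummarizedExperiment(
        assays = list(frequencies = t(frequencies)), colData = cd)
    new("ImmuneCohort", se)
}

#' @describeIn ImmuneCohort-class sample-by-subset frequency matrix
#'   (samples in rows).
#' @param x,object an \code{ImmuneCohort}
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @export
setMethod("frequencies", "ImmuneCohort", function(x)
    t(SummarizedExperiment::assay(x, "frequencies")))

#' @describeIn ImmuneCohort-class per-sample group labels.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @export
setMethod("groupLabels", "ImmuneCohort", function(x) {
    g <- colData(x)$group
    stats::setNames(as.character(g), colnames(x))
})

#' @describeIn ImmuneCohort-class binary clinical-domain matrix (samples in
#'   rows), or NULL when the cohort carries none.
#' @export
setGeneric("clinicalMatrix", function(x) standardGeneric("clinicalMatrix"))
#' @export
setMethod("clinicalMatrix", "ImmuneCohort", function(x) {
    cd <- colData(x)
    if (!"clinical" %in% colnames(cd)) return(NULL)
    m <- cd$clinical
    rownames(m) <- colnames(x)
    m
})

#' @describeIn ImmuneCohort-class genetic-diagnosis labels or NULL.
#' @export
setGeneric("geneticLabels", function(x) standardGeneric("geneticLabels"))
#' @export
setMethod("geneticLabels", "ImmuneCohort", function(x) {
    cd <- colData(x)
    if (!"genetic" %in% colnames(cd)) return(NULL)
    stats::setNames(as.character(cd$genetic), colnames(x))
})

#' @describeIn ImmuneCohort-class latent severity (synthetic cohorts) or NULL.
#' @export
setGeneric("latentSeverity", function(x) standardGeneric("latentSeverity"))
#' @export
setMethod("latentSeverity", "ImmuneCohort", function(x) {
    cd <- colData(x)
    if (!"severity" %in% colnames(cd)) return(NULL)
    stats::setNames(as.numeric(cd$severity), colnames(x))
})

#' @describeIn ImmuneCohort-class subset (feature) names.
#' @export
setGeneric("subsetNames", function(x) standardGeneric("subsetNames"))
#' @export
setMethod("subsetNames", "ImmuneCohort", function(x) rownames(x))

#' @export
setMethod("show", "ImmuneCohort", function(object) {
    g <- groupLabels(object)
    cat("ImmuneCohort:", ncol(object), "samples (",
        sum(g == "patient"), "patients /", sum(g == "control"),
        "controls ),", nrow(object), "subsets\n")
    cat("  subsets:", paste(utils::head(rownames(object), 6), collapse = ", "),
        if (nrow(object) > 6) "..." else "", "\n")
    cl <- clinicalMatrix(object)
    if (!is.null(cl))
        cat("  clinical domains:", paste(colnames(cl), collapse = ", "), "\n")
    if (!is.null(latentSeverity(object)))
        cat("  latent severity available (synthetic cohort)\n")
    invisible(NULL)
})

#' Panel definition for the Immune Dysregulation Score
#'
#' Names the inflammatory (numerator) and regulatory (denominator) subsets
#' entering the IDS log-ratio, the pseudocount added to frequencies before
#' taking logs, and the logarithm base.
#'
#' @slot inflammatory character, ordered inflammatory subset names.
#' @slot regulatory character, ordered regulatory subset names.
#' @slot pseudocount numeric, small positive percent value added to all
#'   frequencies before the log (guards against zeros in real gating tables).
#' @slot logBase numeric, base of the logarithm (default natural log).
#' @seealso \code{\link{defaultPanel}}, \code{\link{computeIDS}}
#' @export
setClass("PanelDefinition", representation(
    inflammatory = "character", regulatory = "character",
    pseudocount = "numeric", logBase = "numeric"))

setValidity("PanelDefinition", function(object) {
    msg <- NULL
    if (length(object@inflammatory) == 0 || length(object@regulatory) == 0)
        msg <- c(msg, "both subset lists must be non-empty")
    if (length(intersect(object@inflammatory, object@regulatory)) > 0)
        msg <- c(msg, "inflammatory and regulatory lists must be disjoint")
    if (object@pseudocount <= 0)
        msg <- c(msg, "pseudocount must be > 0")
    if (object@logBase <= 0 || object@logBase == 1)
        msg <- c(msg, "logBase must be positive and != 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PanelDefinition
#'
#' @param inflammatory,regulatory character vectors of subset names.
#' @param pseudocount positive percent value added before logs (default 0.01
#'   percentage points).
#' @param logBase logarithm base (default \code{exp(1)}).
#' @return a \linkS4class{PanelDefinition}.
#' @export
PanelDefinition <- function(inflammatory, regulatory, pseudocount = 0.01,
                            logBase = exp(1)) {
    new("PanelDefinition", inflammatory = inflammatory,
        regulatory = regulatory, pseudocount = pseudocount, logBase = logBase)
}

#' Default six-subset IDS panel
#'
#' Inflammatory side: BCL6+ Tfh-like cells, ICOS+BCL6+ cells and activated
#' CD8+CD25+ T cells. Regulatory side: CD4+CD25hiCD127loFOXP3+ Tregs,
#' transitional Bregs and memory Bregs.
#'
#' @inheritParams PanelDefinition
#' @return a \linkS4class{PanelDefinition} with three subsets per side.
#' @export
defaultPanel <- function(pseudocount = 0.01, logBase = exp(1)) {
    PanelDefinition(
        inflammatory = c("BCL6pos", "ICOSposBCL6pos", "CD8posCD25pos"),
        regulatory = c("Treg", "TransitionalBreg", "MemoryBreg"),
        pseudocount = pseudocount, logBase = logBase)
}

#' @export
setMethod("show", "PanelDefinition", function(object) {
    cat("PanelDefinition\n")
    cat("  inflammatory:", paste(object@inflammatory, collapse = ", "), "\n")
    cat("  regulatory:  ", paste(object@regulatory, collapse = ", "), "\n")
    cat("  pseudocount:", object@pseudocount,
        " log base:", format(object@logBase, digits = 6), "\n")
    invisible(NULL)
})

#' Clinical manifestation domain presets
#'
#' The \code{"four"} preset covers the composite clinical dysregulation
#' score's manifestations (range 0-4): autoimmunity, chronic inflammation,
#' lymphoproliferation, malignancy. The \code{"six"} preset is the extended
#' domain list: autoimmune/inflammatory features, malignancy, lymphadenopathy,
#' recurrent infections, hypo-/hypergammaglobulinemia, hepatosplenomegaly.
#' Every domain is coded 0 = absent, 1 = present.
#'
#' @param preset \code{"four"} (default) or \code{"six"}.
#' @return character vector of domain names.
#' @export
clinicalDomains <- function(preset = c("four", "six")) {
    preset <- match.arg(preset)
    switch(preset,
        four = c("autoimmunity", "chronic_inflammation",
                 "lymphoproliferation", "malignancy"),
        six = c("autoimmune_inflammatory", "malignancy", "lymphadenopathy",
                "recurrent_infections", "dysgammaglobulinemia",
                "hepatosplenomegaly"))
}
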