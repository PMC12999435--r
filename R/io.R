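#' Read a cohort from CSV tables
#'
#' Expects header rows, \code{sample_id} as the first column, UTF-8 with "."
#' decimal separator. Subset values outside (0, 100) are rejected with the
#' offending row and column named; samples absent from the clinical table are
#' tolerated (their CDS is simply undefined).
#'
#' @param subsetCsv path to the samples-by-subsets frequency table.
#' @param labelsCsv path to the labels table (columns \code{sample_id},
#'   \code{group}, optional \code{genetic}, \code{severity}).
#' @param clinicalCsv optional path to the binary clinical-domain table.
#' @return an \linkS4class{ImmuneCohort}.
#' @export
readCohort <- function(subsetCsv, labelsCsv, clinicalCsv = NULL) {
    sub <- utils::read.csv(subsetCsv, check.names = FALSE)
    if (colnames(sub)[1] != "sample_id")
        stop("first column of the subset table must be 'sample_id'")
    ids <- as.character(sub$sample_id)
    if (anyDuplicated(ids))
        stop("duplicate sample IDs: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    f <- as.matrix(sub[, -1, drop = FALSE])
    if (!is.numeric(f)) stop("unparseable numerics in the subset table")
    bad <- which(f <= 0 | f >= 100, arr.ind = TRUE)
    if (nrow(bad))
        stop("subset value out of (0,100) at row '", ids[bad[1, 1]],
             "', column '", colnames(f)[bad[1, 2]], "'")
    rownames(f) <- ids
    lab <- utils::read.csv(labelsCsv)
    lab <- lab[match(ids, lab$sample_id), ]
    if (anyNA(lab$sample_id)) stop("labels table is missing samples")
    if (!all(lab$group %in% c("patient", "control")))
        stop("group labels must be 'patient' or 'control'")
    clinical <- NULL
    if (!is.null(clinicalCsv)) {
        cl <- utils::read.csv(clinicalCsv, check.names = FALSE)
        clinical <- as.matrix(cl[, -1, drop = FALSE])
        rownames(clinical) <- as.character(cl$sample_id)
    }
    ImmuneCohort(f, group = lab$group, clinical = clinical,
                 genetic = if ("genetic" %in% colnames(lab)) lab$genetic,
                 severity = if ("severity" %in% colnames(lab)) lab$severity,
                 sampleIds = ids)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; parsed with \pkg{yaml} (JSON is valid
#'   YAML).
#' @return a named list of pipeline parameters.
#' @export
readPipelineConfig <- function(path) {
    yaml::read_yaml(path)
}

.writeCsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Chains the stages on one cohort: score table (IDS, deltaIDS, proMean,
#' antiMean, CDS, clinical z); per-subset group tests with FDR; a 2D t-SNE
#' embedding of the samples;
#' patient/control correlation matrices and the delta-correlation network;
#' SOM metaclustering with composition differences, marker volcano table and
#' IDS weights; Jaccard/PAM clinical clustering with severity tiers; and IDS
#' validation (ROC with DeLong CI and Youden point, IDS-clinicalZ Pearson
#' correlation, bootstrap-optimism-corrected and repeated-CV AUC of a
#' composite patient-versus-control logistic model). All artifacts are
#' written as plain text under \code{outDir}; the manifest records the seed
#' and a hash of the configuration, and isolates the timestamp so repeated
#' runs are byte-identical elsewhere.
#'
#' @param cohort an \linkS4class{ImmuneCohort} (e.g. from
#'   \code{\link{generateCohort}} or \code{\link{readCohort}}).
#' @param outDir output directory, created if needed.
#' @param panel a \linkS4class{PanelDefinition}.
#' @param domains clinical domain names.
#' @param seed integer seed for all stochastic stages.
#' @param deltaThreshold |deltaR| edge-inclusion threshold.
#' @param somGrid,somEpochs,k SOM geometry, training epochs and metacluster
#'   count.
#' @param kClinical number of clinical clusters.
#' @param nBoot bootstrap replicates for composition CIs.
#' @param optimismB bootstrap iterations for optimism correction.
#' @return invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(cohort, outDir, panel = defaultPanel(),
                        domains = clinicalDomains("four"), seed = 1L,
                        deltaThreshold = 0.4, somGrid = c(4, 4),
                        somEpochs = 50, k = 8, kClinical = 3, nBoot = 1000,
                        optimismB = 500) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    g <- groupLabels(cohort)
    f <- frequencies(cohort)
    log <- c(sprintf("samples in: %d (%d patients, %d controls)",
                     length(g), sum(g == "patient"), sum(g == "control")))

    scores <- computeScoreTable(cohort, panel, domains)
    .writeCsv(scores, file.path(outDir, "scores.csv"))
    cs <- attr(scores, "controlStats")
    jsonlite::write_json(
        list(panel = list(inflammatory = panel@inflammatory,
                          regulatory = panel@regulatory,
                          pseudocount = panel@pseudocount,
                          logBase = panel@logBase),
             controlMeanIds = cs$meanIds,
             controlSubsetMean = as.list(cs$subsetMean),
             controlSubsetSd = as.list(cs$subsetSd), seed = seed),
        file.path(outDir, "score_meta.json"), auto_unbox = TRUE, digits = NA)

    tests <- compareSubsets(cohort)
    .writeCsv(tests, file.path(outDir, "subset_tests.csv"))

    corP <- correlationMatrix(f[g == "patient", , drop = FALSE])
    corC <- correlationMatrix(f[g == "control", , drop = FALSE])
    net <- deltaNetwork(corP, corC, threshold = deltaThreshold)
    writeDeltaNetwork(net, file.path(outDir, "delta_network.tsv"),
                      file.path(outDir, "delta_network.graphml"))
    log <- c(log, sprintf("delta network: %d edges at |deltaR| >= %.2f",
                          nrow(net$edges), deltaThreshold))

    perp <- min(10, max(2, floor((nrow(f) - 1) / 3)))
    emb <- embed2D(f, perplexity = perp, seed = seed)
    .writeCsv(data.frame(sampleId = rownames(f), group = unname(g),
                         tsne1 = emb[, 1], tsne2 = emb[, 2]),
              file.path(outDir, "embedding.csv"))

    som <- trainSOM(f, grid = somGrid, epochs = somEpochs, seed = seed)
    nodeMap <- metacluster(som, k = k)
    assign <- assignAndCompose(cohort, som, nodeMap)
    compDiff <- compositionDifferences(assign, g, nBoot = nBoot, seed = seed)
    .writeCsv(compDiff, file.path(outDir, "metacluster_composition.csv"))
    volcano <- metaclusterMarkerDifferences(cohort, assign)
    .writeCsv(volcano, file.path(outDir, "metacluster_volcano.csv"))
    w <- metaclusterIdsWeights(assign, scores)
    .writeCsv(data.frame(metacluster = names(w), idsWeight = unname(w)),
              file.path(outDir, "metacluster_ids_weights.csv"))
    .writeCsv(data.frame(node = rownames(som$codebook), som$gridCoords,
                         metacluster = paste0("MC", unname(nodeMap)),
                         som$codebook, check.names = FALSE),
              file.path(outDir, "som_codebook.csv"))
    .writeCsv(data.frame(sampleId = names(assign$sampleMetacluster),
                         node = unname(assign$sampleNode),
                         metacluster = as.character(assign$sampleMetacluster)),
              file.path(outDir, "metacluster_assignment.csv"))

    cl <- clinicalMatrix(cohort)
    clinical <- NULL
    validation <- list(seed = seed)
    if (!is.null(cl)) {
        pat <- g == "patient"
        clB <- cl[pat & rowSums(is.na(cl)) == 0, , drop = FALSE]
        log <- c(log, sprintf(
            "clinical scoring: %d of %d patients with complete domains",
            nrow(clB), sum(pat)))
        cds <- scores$cds[match(rownames(clB), scores$sampleId)]
        clinical <- clusterClinical(clB, k = kClinical, cds = cds)
        out <- data.frame(sampleId = rownames(clB),
                          cluster = clinical$labels,
                          tier = if (is.null(clinical$tiers)) NA_character_
                                 else clinical$tiers$tierPerSample)
        .writeCsv(out, file.path(outDir, "clinical_clusters.csv"))
        imp <- clusterFeatureImportance(clB, clinical$labels, nPerm = 50,
                                        seed = seed)
        jsonlite::write_json(
            list(medoids = rownames(clB)[clinical$medoids],
                 importances = as.list(imp)),
            file.path(outDir, "clinical_cluster_meta.json"),
            auto_unbox = TRUE, digits = NA)
        cc <- stats::complete.cases(scores$ids, scores$clinicalZ)
        if (sum(cc) >= 3) {
            ct <- stats::cor.test(scores$ids[cc], scores$clinicalZ[cc],
                                  method = "pearson")
            validation$idsClinicalR <- unname(ct$estimate)
            validation$idsClinicalP <- ct$p.value
        }
    } else {
        log <- c(log, "no clinical table: clinical stages skipped")
    }

    roc <- rocAuc(scores$ids, g)
    validation$idsAuc <- roc$auc
    validation$idsAucCi <- c(roc$ciLow, roc$ciHigh)
    validation$youden <- roc$youden
    compX <- scores[, c("proMean", "antiMean", "ids", "deltaIds")]
    yBin <- as.integer(g == "patient")
    opt <- bootstrapOptimism(binaryLogisticSpec(), compX, yBin,
                             metric = "auc", B = optimismB, seed = seed)
    validation$compositeApparentAuc <- opt$apparent
    validation$compositeCorrectedAuc <- opt$corrected
    cv <- repeatedCv(binaryLogisticSpec(), compX, yBin, metric = "auc",
                     k = min(10, min(table(yBin))), repeats = 5, seed = seed)
    validation$compositeCvAucMean <- cv$mean
    validation$compositeCvAucSd <- cv$sd
    jsonlite::write_json(validation, file.path(outDir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)

    cfgHash <- .configHash(list(panel@inflammatory, panel@regulatory,
                                panel@pseudocount, panel@logBase, domains,
                                seed, deltaThreshold, somGrid, somEpochs, k,
                                kClinical, nBoot, optimismB, dim(f)))
    writeLines(c(sprintf("config_hash: %s", cfgHash),
                 sprintf("seed: %d", seed), log),
               file.path(outDir, "summary.txt"))
    writeLines(sprintf("timestamp: %s", format(Sys.time(), usetz = TRUE)),
               file.path(outDir, "manifest.txt"))
    invisible(list(scores = scores, tests = tests, network = net, som = som,
                   nodeMap = nodeMap, assignment = assign,
                   compositionDifferences = compDiff, volcano = volcano,
                   idsWeights = w, clinical = clinical,
                   validation = validation))
}

.configHash <- function(x) {
    s <- paste(utils::capture.output(utils::str(x)), collapse = "")
    sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFFF)
}
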