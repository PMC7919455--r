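# End-to-end driver: divergence -> normalization -> polymorphism ->
# expression -> enrichment -> classification, with a run manifest.

#' Pipeline configuration
#'
#' Paths and parameters for \code{\link{runPipeline}}.  Only the alignment
#' FASTA and the output directory are required; missing optional inputs
#' degrade gracefully (no polymorphism table -> empty PSG list with a
#' warning; no expression matrix -> no tissue gene sets; no GMT -> enrichment
#' restricted to tissue sets, if any).
#'
#' @param alignmentFasta Per-gene codon alignment FASTA
#'   (\code{<gene>|<taxon>} ids, one \code{ancestor} record per gene).
#' @param outDir Output directory.
#' @param polymorphismTsv Optional polymorphism TSV (gene, class, maf).
#' @param expressionTsv Optional gene x tissue expression TSV.
#' @param geneSetGmt Optional GMT of annotation gene sets.
#' @param taxon Focal taxon for selection statistics and extremes.
#' @param kappa Site-counting transition/transversion weight.
#' @param mafMax MAF cutoff for the polymorphism screen (NULL = all SNPs).
#' @param zThreshold Specificity cutoff for tissue gene sets.
#' @param sdThreshold Extreme-gene cutoff on the omega_GC12 scale.
#' @param nDraws Bootstrap draws per enrichment test.
#' @param nBins Matching-grid bins per covariate axis.
#' @param kCandidates Candidate cluster counts.
#' @param seed Seed for all stochastic stages.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(alignmentFasta, outDir,
                           polymorphismTsv = NULL, expressionTsv = NULL,
                           geneSetGmt = NULL, taxon = "hs", kappa = 1,
                           mafMax = NULL, zThreshold = 2, sdThreshold = 2,
                           nDraws = 10000, nBins = 10, kCandidates = 2:6,
                           seed = 1L) {
    cfg <- list(alignmentFasta = alignmentFasta, outDir = outDir,
                polymorphismTsv = polymorphismTsv,
                expressionTsv = expressionTsv, geneSetGmt = geneSetGmt,
                taxon = taxon, kappa = kappa, mafMax = mafMax,
                zThreshold = zThreshold, sdThreshold = sdThreshold,
                nDraws = nDraws, nBins = nBins, kCandidates = kCandidates,
                seed = as.integer(seed))
    if (!file.exists(alignmentFasta)) {
        stop("alignment FASTA not found: ", alignmentFasta)
    }
    for (p in c(polymorphismTsv, expressionTsv, geneSetGmt)) {
        if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    }
    structure(cfg, class = "PipelineConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
}

#' Run the full evolutionary-pressure pipeline
#'
#' Executes divergence estimation, GC12 normalization, McDonald-Kreitman
#' statistics, expression specificity, gene-set enrichment, clustering and
#' PSG/SCG extraction, writing every output table plus a JSON manifest
#' (inputs, parameters, seed, package version) under \code{config$outDir}.
#' Identical config and seed produce byte-identical outputs.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return (Invisibly) a list with the in-memory results (\code{divergence},
#'   \code{omega}, \code{selection}, \code{specificity}, \code{enrichment},
#'   \code{clusters}, \code{extremes}, \code{partition}) and \code{paths}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    outPath <- function(f) file.path(config$outDir, f)
    paths <- character()
    set.seed(config$seed)

    aln <- .stage("load_alignments", readCodonAlignments(config$alignmentFasta))
    div <- .stage("divergence", estimateDivergence(aln, kappa = config$kappa))
    writeTsv(div, paths["divergence"] <- outPath("divergence.tsv"))

    omega <- .stage("normalization", omegaGC12Table(div))
    omegaDf <- do.call(rbind, lapply(colnames(omega), function(tx)
        data.frame(gene = rownames(omega), taxon = tx,
                   omegaRaw = omegaRaw(omega)[, tx],
                   gc12 = rowData(omega)$gc12,
                   omegaGC12 = omegaGC12(omega)[, tx],
                   stringsAsFactors = FALSE)))
    rownames(omegaDf) <- NULL
    writeTsv(omegaDf, paths["omega"] <- outPath("omega.tsv"))

    selection <- NULL
    if (!is.null(config$polymorphismTsv)) {
        poly <- .stage("polymorphism_read",
                       readPolymorphismTable(config$polymorphismTsv))
        selection <- .stage("polymorphism",
                            selectionStats(poly, div, taxon = config$taxon,
                                           mafMax = config$mafMax))
        writeTsv(selection, paths["selection"] <- outPath("selection.tsv"))
    }

    specificity <- NULL
    tissueSets <- list()
    if (!is.null(config$expressionTsv)) {
        mat <- .stage("expression_read",
                      readExpressionMatrix(config$expressionTsv))
        specificity <- .stage("expression", specificityZ(mat))
        specDf <- data.frame(gene = rownames(specificity$z),
                             tau = specificity$tau,
                             specificity$z, check.names = FALSE)
        writeTsv(specDf, paths["specificity"] <- outPath("specificity.tsv"))
        tissueSets <- tissueGeneSets(specificity, config$zThreshold)
        if (length(tissueSets)) {
            writeGmt(tissueSets, paths["tissueSets"] <- outPath("tissue_sets.gmt"),
                     descriptions = rep("tissue-specific", length(tissueSets)))
        }
    }

    annotationSets <- if (!is.null(config$geneSetGmt)) {
        .stage("gene_sets", readGmt(config$geneSetGmt))
    } else list()
    enrichSets <- c(annotationSets, tissueSets)

    enrichment <- NULL
    if (length(enrichSets)) {
        enrichment <- .stage("enrichment",
            enrichGeneSets(omega, enrichSets, taxon = config$taxon,
                           nDraws = config$nDraws, nBins = config$nBins,
                           seed = config$seed))
        writeTsv(enrichment, paths["enrichment"] <- outPath("enrichment.tsv"))
    }

    clusters <- NULL
    if (ncol(omega) >= 2 && sum(complete.cases(omegaGC12(omega))) >= 100) {
        clusters <- .stage("classify_cluster",
            clusterGenes(omega, kCandidates = config$kCandidates,
                         orderTaxon = config$taxon))
        writeTsv(clusters$summary,
                 paths["clusterSummary"] <- outPath("cluster_summary.tsv"))
    }

    extremes <- .stage("classify_extremes",
        extremeGenes(omega, selection, sdThreshold = config$sdThreshold,
                     taxon = config$taxon))
    writeLines(extremes$psg, paths["psg"] <- outPath("psg.txt"))
    writeLines(extremes$scg, paths["scg"] <- outPath("scg.txt"))

    partition <- NULL
    if (length(annotationSets)) {
        partition <- .stage("classify_partition",
            partitionBrainRelated(extremes, annotationSets, rownames(omega)))
        write_json(lapply(partition, function(p) list(
                       n = p$n, inUnion = p$inUnion,
                       categoryCounts = as.list(p$categoryCounts),
                       fisherP = p$fisher$p,
                       oddsRatio = p$fisher$oddsRatio)),
                   paths["partition"] <- outPath("partition.json"),
                   auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    manifest <- list(
        inputs = Filter(Negate(is.null),
                        config[c("alignmentFasta", "polymorphismTsv",
                                 "expressionTsv", "geneSetGmt")]),
        parameters = config[c("taxon", "kappa", "mafMax", "zThreshold",
                              "sdThreshold", "nDraws", "nBins",
                              "kCandidates")],
        seed = config$seed,
        package = as.character(utils::packageVersion("omegaGC")),
        nGenes = nrow(omega), taxa = colnames(omega))
    write_json(manifest, paths["manifest"] <- outPath("manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

    invisible(list(divergence = div, omega = omega, selection = selection,
                   specificity = specificity, enrichment = enrichment,
                   clusters = clusters, extremes = extremes,
                   partition = partition, paths = paths))
}
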