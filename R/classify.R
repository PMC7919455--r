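# Genome partitioning into conserved/divergent clusters and extraction of
# the extreme PSG/SCG lists.

# internal cluster-quality indices on a gene x taxon score matrix
.clusterIndices <- function(mat, d, labels) {
    k <- length(unique(labels))
    n <- nrow(mat)
    centroids <- do.call(rbind, lapply(split(seq_len(n), labels), function(i)
        colMeans(mat[i, , drop = FALSE])))
    grand <- colMeans(mat)
    sizes <- as.vector(table(labels))
    W <- sum(vapply(seq_len(n), function(i)
        sum((mat[i, ] - centroids[as.character(labels[i]), ])^2), numeric(1)))
    B <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
    ch <- (B / (k - 1)) / (W / (n - k))
    # Davies-Bouldin: mean over clusters of the worst dispersion ratio
    disp <- vapply(rownames(centroids), function(cl) {
        i <- which(as.character(labels) == cl)
        mean(sqrt(rowSums(sweep(mat[i, , drop = FALSE], 2,
                                centroids[cl, ])^2)))
    }, numeric(1))
    cd <- as.matrix(dist(centroids))
    db <- mean(vapply(seq_len(k), function(i) {
        max(vapply(seq_len(k)[-i], function(j)
            (disp[i] + disp[j]) / cd[i, j], numeric(1)))
    }, numeric(1)))
    sil <- mean(cluster::silhouette(as.integer(factor(labels)), d)[, "sil_width"])
    c(silhouette = sil, calinskiHarabasz = ch, daviesBouldin = db)
}

#' Hierarchical clustering of the omega_GC12 matrix with k selection
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of genes on
#' their per-taxon omega_GC12 profiles.  The number of clusters is chosen by
#' majority vote of three internal indices -- mean silhouette width (max),
#' Calinski-Harabasz (max) and Davies-Bouldin (min) -- over
#' \code{kCandidates}; ties go to the smaller k.  When the winning partition
#' has mean silhouette below \code{silWarn} a low-separation warning is
#' emitted (single-blob data admit no strong partition).
#'
#' For k = 2 the clusters are labelled \code{"SCG-like"} (lower mean score on
#' \code{orderTaxon}) and \code{"PSG-like"}; for other k they are
#' \code{"C1"..."Ck"} ordered by that mean.
#'
#' @param omega An \code{\linkS4class{OmegaTable}}.
#' @param kCandidates Candidate cluster numbers (default 2:6).
#' @param orderTaxon Taxon used to order/label clusters (default \code{"hs"}).
#' @param silWarn Silhouette threshold for the low-separation warning.
#' @return List of class \code{"ClusterAssignment"}: \code{labels} (named by
#'   gene), \code{k}, \code{votes} (per-index best k), \code{indices} (full
#'   index table), \code{summary} (per cluster x taxon n/mean/median/sd),
#'   \code{excluded} (genes dropped for missing values), \code{lowSeparation}.
#' @export
clusterGenes <- function(omega, kCandidates = 2:6, orderTaxon = "hs",
                         silWarn = 0.25) {
    stopifnot(is(omega, "OmegaTable"))
    mat <- omegaGC12(omega)
    if (ncol(mat) < 2L) stop("need >= 2 taxa for clustering")
    keep <- complete.cases(mat)
    excluded <- sum(!keep)
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) < 100L) stop("need >= 100 fully scored genes, got ", nrow(mat))
    if (!orderTaxon %in% colnames(mat)) {
        stop("orderTaxon '", orderTaxon, "' not present")
    }
    kCandidates <- kCandidates[kCandidates >= 2 & kCandidates < nrow(mat)]
    d <- dist(mat)
    hc <- hclust(d, method = "ward.D2")
    idx <- t(vapply(kCandidates, function(k)
        .clusterIndices(mat, d, cutree(hc, k)), numeric(3)))
    rownames(idx) <- kCandidates
    votes <- c(
        silhouette = kCandidates[which.max(idx[, "silhouette"])],
        calinskiHarabasz = kCandidates[which.max(idx[, "calinskiHarabasz"])],
        daviesBouldin = kCandidates[which.min(idx[, "daviesBouldin"])])
    tally <- table(votes)
    k <- as.integer(names(tally)[which.max(tally)])
    lab <- cutree(hc, k)
    means <- vapply(split(mat[, orderTaxon], lab), mean, numeric(1))
    ord <- order(means)
    newNames <- if (k == 2L) c("SCG-like", "PSG-like")
                else paste0("C", seq_len(k))
    labels <- setNames(newNames[match(lab, as.integer(names(means))[ord])],
                       rownames(mat))
    lowSep <- idx[as.character(k), "silhouette"] < silWarn
    if (lowSep) {
        warning("best partition k = ", k, " has mean silhouette ",
                signif(idx[as.character(k), "silhouette"], 3),
                " (< ", silWarn, "): weak cluster separation")
    }
    summ <- do.call(rbind, lapply(unique(newNames[seq_len(k)]), function(cl) {
        i <- which(labels == cl)
        do.call(rbind, lapply(colnames(mat), function(tx)
            data.frame(cluster = cl, taxon = tx, n = length(i),
                       mean = mean(mat[i, tx]), median = median(mat[i, tx]),
                       sd = sd(mat[i, tx]), stringsAsFactors = FALSE)))
    }))
    structure(list(labels = labels, k = k, votes = votes, indices = idx,
                   summary = summ, excluded = excluded,
                   lowSeparation = lowSep),
              class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
    cat("ClusterAssignment: k =", x$k, "over", length(x$labels), "genes",
        if (x$excluded) paste0("(", x$excluded, " excluded for missing values)"),
        "\n")
    cat("  index votes:", paste(names(x$votes), x$votes, sep = "=",
                                collapse = ", "), "\n")
    print(table(x$labels))
    invisible(x)
}

#' Extract extreme PSG and SCG lists
#'
#' PSGs are genes in the upper tail of the omega_GC12 distribution
#' (score > \code{sdThreshold} on the human taxon) whose divergence is fixed
#' in the modern population (neutrality index < 1); SCGs are the lower tail
#' (score < -\code{sdThreshold}), with no fixation filter.  Candidate PSGs
#' lacking a neutrality index are excluded and reported.
#'
#' @param omega An \code{\linkS4class{OmegaTable}}.
#' @param selection Optional \code{data.frame} from
#'   \code{\link{selectionStats}} (columns \code{gene}, \code{ni}).  When
#'   \code{NULL}, no fixation data are available: the PSG list is empty and a
#'   warning is raised.
#' @param sdThreshold Tail cutoff on the standardized scale (default 2 SD).
#' @param taxon Taxon defining the extremes (default \code{"hs"}).
#' @return List of class \code{"ExtremeGeneLists"}: \code{psg}, \code{scg}
#'   (character vectors), \code{psgNoNi} (upper-tail genes dropped for missing
#'   NI), \code{sdThreshold}, \code{taxon}.
#' @export
extremeGenes <- function(omega, selection = NULL, sdThreshold = 2,
                         taxon = "hs") {
    stopifnot(is(omega, "OmegaTable"))
    if (!taxon %in% colnames(omega)) {
        stop("taxon '", taxon, "' not in OmegaTable")
    }
    z <- omegaGC12(omega)[, taxon]
    z <- z[is.finite(z)]
    upper <- names(z)[z > sdThreshold]
    scg <- names(z)[z < -sdThreshold]
    if (is.null(selection)) {
        warning("no fixation data: PSG list is empty ",
                "(", length(upper), " upper-tail candidates not assessable)")
        psg <- character()
        noNi <- upper
    } else {
        ni <- setNames(selection$ni, selection$gene)[upper]
        noNi <- upper[is.na(ni)]
        psg <- upper[!is.na(ni) & ni < 1]
    }
    structure(list(psg = psg, scg = scg, psgNoNi = noNi,
                   sdThreshold = sdThreshold, taxon = taxon),
              class = "ExtremeGeneLists")
}

#' @export
print.ExtremeGeneLists <- function(x, ...) {
    cat("ExtremeGeneLists (|omega_GC12| >", x$sdThreshold, "on",
        x$taxon, "):\n")
    cat("  PSG (diverged, NI < 1):", length(x$psg), "genes\n")
    cat("  SCG (constrained):     ", length(x$scg), "genes\n")
    if (length(x$psgNoNi)) {
        cat("  upper-tail genes without NI:", length(x$psgNoNi), "\n")
    }
    invisible(x)
}

#' Partition extreme gene lists against annotation sets
#'
#' Counts, for each extreme list, how many members fall in the union of the
#' annotation sets (e.g. brain-specific expression, synaptic, disease) and in
#' each individual category (categories may overlap), and tests the list for
#' over/under-representation of annotated genes with Fisher's exact test over
#' the analyzed universe.
#'
#' @param lists \code{ExtremeGeneLists} from \code{\link{extremeGenes}}.
#' @param annotationSets Named list of gene-id vectors over \code{universe}.
#' @param universe Character vector, the analyzed gene universe.
#' @return Nested list with one element per extreme list (\code{psg},
#'   \code{scg}): \code{n}, \code{inUnion}, \code{categoryCounts},
#'   \code{fisher}.
#' @export
partitionBrainRelated <- function(lists, annotationSets, universe) {
    stopifnot(inherits(lists, "ExtremeGeneLists"))
    if (length(annotationSets) == 0L) {
        stop("empty annotation collection")
    }
    unionSet <- unique(unlist(annotationSets, use.names = FALSE))
    if (length(unionSet) == 0L) {
        stop("annotation union is empty")
    }
    one <- function(members) {
        list(n = length(members),
             inUnion = sum(members %in% unionSet),
             categoryCounts = vapply(annotationSets, function(s)
                 sum(members %in% s), integer(1)),
             fisher = fisherOverlap(members, unionSet, universe))
    }
    list(psg = one(lists$psg), scg = one(lists$scg))
}
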