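#' Container for pairwise ancestor/taxon codon alignments
#'
#' Holds, for every gene, the ancestral coding sequence and one aligned
#' descendant sequence per taxon.  All sequences of a gene have identical
#' length, divisible by 3; the alphabet is A/C/G/T/N/-.  This is the unit of
#' divergence estimation: each (gene, taxon) pair yields one dN/dS estimate
#' against the ancestor.
#'
#' @slot ancestor \code{DNAStringSet} of ancestral CDS, named by gene id.
#' @slot descendants \code{SimpleList} of \code{DNAStringSet}, one element per
#'   taxon, each parallel to \code{ancestor}.
#' @exportClass CodonAlignmentSet
setClass("CodonAlignmentSet",
    representation(ancestor = "DNAStringSet", descendants = "SimpleList"))

setValidity("CodonAlignmentSet", function(object) {
    msgs <- character()
    genes <- names(object@ancestor)
    if (is.null(genes) || anyDuplicated(genes)) {
        msgs <- c(msgs, "ancestor sequences must have unique gene names")
    }
    if (any(width(object@ancestor) %% 3L != 0L)) {
        msgs <- c(msgs, "ancestor sequence lengths must be divisible by 3")
    }
    taxa <- names(object@descendants)
    if (length(object@descendants) &&
        (is.null(taxa) || anyDuplicated(taxa) || any(taxa == "ancestor"))) {
        msgs <- c(msgs, "descendant list must have unique non-'ancestor' taxon names")
    }
    for (tx in taxa) {
        ds <- object@descendants[[tx]]
        if (!is(ds, "DNAStringSet")) {
            msgs <- c(msgs, sprintf("descendants[['%s']] is not a DNAStringSet", tx))
            next
        }
        if (!identical(names(ds), genes)) {
            msgs <- c(msgs, sprintf("taxon '%s' gene names differ from ancestor", tx))
            next
        }
        bad <- which(width(ds) != width(object@ancestor))
        if (length(bad)) {
            msgs <- c(msgs, sprintf(
                "taxon '%s': length mismatch with ancestor for gene(s) %s",
                tx, paste(head(genes[bad], 5), collapse = ", ")))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a CodonAlignmentSet
#'
#' @param ancestor Named \code{DNAStringSet} (or named character vector) of
#'   ancestral CDS.
#' @param descendants Named list of \code{DNAStringSet}/character vectors, one
#'   per taxon, each named by the same gene ids as \code{ancestor}.
#' @return A \code{\linkS4class{CodonAlignmentSet}}.
#' @examples
#' anc <- c(g1 = "ATGTTTAAA")
#' CodonAlignmentSet(anc, list(hs = c(g1 = "ATGTTCAAA")))
#' @export
CodonAlignmentSet <- function(ancestor, descendants) {
    if (!is(ancestor, "DNAStringSet")) ancestor <- DNAStringSet(ancestor)
    descendants <- SimpleList(lapply(descendants, function(x) {
        if (is(x, "DNAStringSet")) x else DNAStringSet(x)
    }))
    new("CodonAlignmentSet", ancestor = ancestor, descendants = descendants)
}

#' @describeIn CodonAlignmentSet-accessors Gene identifiers.
#' @export
geneIds <- function(x) names(x@ancestor)

#' Accessors for CodonAlignmentSet
#'
#' @param x A \code{\linkS4class{CodonAlignmentSet}}.
#' @param taxon Taxon label.
#' @name CodonAlignmentSet-accessors
#' @return \code{geneIds}: character vector; \code{alnTaxa}: character vector
#'   of taxon labels; \code{ancestorSeqs}/\code{taxonSeqs}:
#'   \code{DNAStringSet}.
NULL

#' @describeIn CodonAlignmentSet-accessors Taxon labels.
#' @export
alnTaxa <- function(x) names(x@descendants)

#' @describeIn CodonAlignmentSet-accessors Ancestral sequences.
#' @export
ancestorSeqs <- function(x) x@ancestor

#' @describeIn CodonAlignmentSet-accessors Sequences of one taxon.
#' @export
taxonSeqs <- function(x, taxon) {
    if (!taxon %in% names(x@descendants)) {
        stop("unknown taxon '", taxon, "'")
    }
    x@descendants[[taxon]]
}

setMethod("show", "CodonAlignmentSet", function(object) {
    cat("CodonAlignmentSet with", length(object@ancestor), "genes x",
        length(object@descendants), "taxa\n")
    cat("  taxa:", paste(names(object@descendants), collapse = ", "), "\n")
    w <- width(object@ancestor)
    if (length(w)) {
        cat("  CDS length (nt): ", min(w), "-", max(w),
            " (median ", round(median(w)), ")\n", sep = "")
    }
})

#' Gene x taxon table of omega_GC12 scores
#'
#' Extends \code{SummarizedExperiment}: rows are genes, columns taxa, with
#' assays \code{omegaRaw} (uncorrected dN/dS) and \code{omegaGC12}
#' (GC12-regression residuals Z-standardized per taxon across the analyzed
#' gene universe).  \code{rowData} carries the per-gene GC12 fraction and CDS
#' length used in the correction; the fitted per-taxon regression coefficients
#' sit in \code{metadata(x)$fits}.
#'
#' @exportClass OmegaTable
setClass("OmegaTable", contains = "SummarizedExperiment")

setValidity("OmegaTable", function(object) {
    msgs <- character()
    if (!all(c("omegaRaw", "omegaGC12") %in% assayNames(object))) {
        msgs <- c(msgs, "assays must include 'omegaRaw' and 'omegaGC12'")
    }
    if (!all(c("gc12", "cdsLength") %in% colnames(rowData(object)))) {
        msgs <- c(msgs, "rowData must include 'gc12' and 'cdsLength'")
    } else if (any(rowData(object)$gc12 < 0 | rowData(object)$gc12 > 1,
                   na.rm = TRUE)) {
        msgs <- c(msgs, "gc12 must lie in [0, 1]")
    }
    if ("omegaGC12" %in% assayNames(object)) {
        z <- assay(object, "omegaGC12")
        for (j in seq_len(ncol(z))) {
            v <- z[, j][is.finite(z[, j])]
            if (length(v) > 1 && (abs(mean(v)) > 1e-6 || abs(sd(v) - 1) > 1e-6)) {
                msgs <- c(msgs, sprintf(
                    "omegaGC12 column '%s' is not standardized", colnames(z)[j]))
            }
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn OmegaTable-accessors The omega_GC12 score matrix (genes x taxa).
#' @export
omegaGC12 <- function(x) assay(x, "omegaGC12")

#' Accessors for OmegaTable
#'
#' @param x An \code{\linkS4class{OmegaTable}}.
#' @name OmegaTable-accessors
#' @return Matrices (genes x taxa), per-gene numeric vectors, or the list of
#'   per-taxon fitted GC12-correction coefficients.
NULL

#' @describeIn OmegaTable-accessors The raw dN/dS matrix.
#' @export
omegaRaw <- function(x) assay(x, "omegaRaw")

#' @describeIn OmegaTable-accessors Per-gene GC12 fraction.
#' @export
geneGC12 <- function(x) setNames(rowData(x)$gc12, rownames(x))

#' @describeIn OmegaTable-accessors Per-gene CDS length (nt).
#' @export
cdsLength <- function(x) setNames(rowData(x)$cdsLength, rownames(x))

#' @describeIn OmegaTable-accessors Per-taxon GC12 regression fits.
#' @export
correctionFits <- function(x) metadata(x)$fits

setMethod("show", "OmegaTable", function(object) {
    cat("OmegaTable:", nrow(object), "genes x", ncol(object), "taxa\n")
    cat("  taxa:", paste(colnames(object), collapse = ", "), "\n")
    z <- assay(object, "omegaGC12")
    for (j in seq_len(ncol(z))) {
        v <- z[, j][is.finite(z[, j])]
        cat(sprintf("  %-12s omega_GC12 range [%.2f, %.2f], |z|>2: %d genes\n",
                    colnames(z)[j], min(v), max(v), sum(abs(v) > 2)))
    }
    invisible(NULL)
})
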