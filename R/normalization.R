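# GC12 correction and per-taxon Z-standardization of raw dN/dS.

#' GC content at codon positions 1 and 2
#'
#' Fraction of G/C bases among the first and second positions of each codon.
#' \code{N} (and gap) characters are excluded from both numerator and
#' denominator.
#'
#' @param x Character vector or \code{DNAStringSet} of CDS (lengths divisible
#'   by 3).
#' @return Numeric vector of GC12 fractions in [0, 1].
#' @examples
#' gc12Content("ATGGCC")  # 0.5
#' @export
gc12Content <- function(x) {
    if (is(x, "DNAStringSet")) x <- as.character(x)
    stopifnot(is.character(x))
    vapply(x, function(s) {
        n <- nchar(s)
        if (n == 0L) stop("empty sequence in gc12Content()")
        if (n %% 3L != 0L) {
            stop("sequence length ", n, " is not divisible by 3")
        }
        chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
        pos12 <- chars[(seq_len(n) - 1L) %% 3L != 2L]
        pos12 <- pos12[pos12 %in% c("A", "C", "G", "T")]
        if (length(pos12) == 0L) {
            return(NA_real_)
        }
        mean(pos12 %in% c("G", "C"))
    }, numeric(1), USE.NAMES = !is.null(names(x)))
}

#' GC12-correct and Z-standardize raw dN/dS per taxon
#'
#' For each taxon, fits a Gaussian identity-link GLM (ordinary least squares)
#' of raw dN/dS on GC12, takes the residuals, and standardizes them to mean 0
#' and SD 1 across the analyzed gene universe.  The result, omega_GC12, is a
#' per-taxon Z-score of evolutionary pressure free of the linear GC12
#' mutation-bias confound; positive values indicate divergence beyond the
#' genome-wide trend, negative values constraint.
#'
#' @param divergence A \code{data.frame} as returned by
#'   \code{\link{estimateDivergence}} (columns \code{gene}, \code{taxon},
#'   \code{omegaRaw}, \code{gc12}, \code{cdsLength}).
#' @param minGenes Minimum genes per taxon required to fit the correction.
#' @return An \code{\linkS4class{OmegaTable}} with assays \code{omegaRaw} and
#'   \code{omegaGC12} (genes x taxa) and the per-taxon fit coefficients in
#'   \code{metadata()$fits}.
#' @export
omegaGC12Table <- function(divergence, minGenes = 50) {
    need <- c("gene", "taxon", "omegaRaw", "gc12", "cdsLength")
    if (!all(need %in% colnames(divergence))) {
        stop("divergence table must have columns: ", paste(need, collapse = ", "))
    }
    if (any(!is.finite(divergence$omegaRaw))) {
        stop("non-finite omegaRaw values; apply the zero rule upstream")
    }
    genes <- unique(divergence$gene)
    taxa <- unique(divergence$taxon)
    rawMat <- matrix(NA_real_, length(genes), length(taxa),
                     dimnames = list(genes, taxa))
    zMat <- rawMat
    fits <- vector("list", length(taxa))
    names(fits) <- taxa
    for (tx in taxa) {
        d <- divergence[divergence$taxon == tx, ]
        if (nrow(d) < minGenes) {
            stop("taxon '", tx, "' has ", nrow(d), " genes; need >= ", minGenes)
        }
        if (anyDuplicated(d$gene)) {
            stop("duplicated gene entries for taxon '", tx, "'")
        }
        if (sd(d$gc12) < 1e-12) {
            stop("degenerate design for taxon '", tx,
                 "': GC12 is constant, correction not identifiable")
        }
        fit <- lm(omegaRaw ~ gc12, data = d)
        r <- resid(fit)
        z <- (r - mean(r)) / sd(r)
        rawMat[d$gene, tx] <- d$omegaRaw
        zMat[d$gene, tx] <- z
        fits[[tx]] <- list(coefficients = coef(fit), residualSd = sd(r),
                           nGenes = nrow(d))
    }
    gcByGene <- divergence$gc12[match(genes, divergence$gene)]
    lenByGene <- divergence$cdsLength[match(genes, divergence$gene)]
    se <- SummarizedExperiment(
        assays = list(omegaRaw = rawMat, omegaGC12 = zMat),
        rowData = DataFrame(gc12 = gcByGene, cdsLength = lenByGene,
                            row.names = genes))
    se@metadata <- list(fits = fits)
    new("OmegaTable", se)
}
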