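# Per-gene dN/dS estimation from pairwise codon alignments.

# Split a sequence into codon indices (1..64); NA for codons containing
# anything outside A/C/G/T (gaps, N) and for stop codons.
.codonIndices <- function(seq) {
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    if (n %% 3L != 0L) {
        stop("sequence length ", n, " is not divisible by 3")
    }
    starts <- seq.int(1L, n, by = 3L)
    idx <- .codonIndex(substring(seq, starts, starts + 2L))
    idx[!is.na(idx) & .codonAA()[idx] == "*"] <- NA_integer_
    idx
}

#' Estimate substitution counts and dN/dS for one alignment pair
#'
#' Nei-Gojobori-family counting on a pairwise codon alignment: fractional
#' synonymous/nonsynonymous site counts per codon (averaged between the two
#' sequences), pathway-averaged difference counts, Jukes-Cantor multiple-hit
#' correction \eqn{d = -3/4 \log(1 - 4p/3)}, and the zero-synonymous
#' protection rule: if the synonymous difference count Sd is 0 it is replaced
#' by 1 before computing dS, so dN/dS is always finite.
#'
#' Codons containing a gap, an ambiguous base, or a stop in either sequence
#' are skipped whole and reported in \code{codonsSkipped}.
#'
#' @param ancestor,descendant Aligned CDS strings (equal length, divisible
#'   by 3).
#' @param kappa Transition/transversion ratio for site counting (1 =
#'   equal-weight NG86 counting).
#' @param gene Optional gene id used in error messages.
#' @return Named list with elements \code{nSites}, \code{sSites}, \code{Nd},
#'   \code{Sd}, \code{SdCorrected}, \code{dN}, \code{dS}, \code{omegaRaw},
#'   \code{codonsUsed}, \code{codonsSkipped}, \code{stopPathCodons}.
#' @examples
#' anc <- paste(rep("ATGTTTAAAGGCCTA", 20), collapse = "")
#' des <- sub("TTT", "TTC", anc)  # one synonymous difference
#' estimatePair(anc, des)$Sd
#' @export
estimatePair <- function(ancestor, descendant, kappa = 1, gene = "gene") {
    ia <- .codonIndices(ancestor)
    ib <- .codonIndices(descendant)
    if (length(ia) != length(ib)) {
        stop("unequal alignment lengths for ", gene)
    }
    ok <- !is.na(ia) & !is.na(ib)
    used <- sum(ok)
    if (used == 0L) {
        stop("no usable codons for ", gene)
    }
    siteTab <- .siteTable(kappa)
    diffTab <- .diffTables()
    ia <- ia[ok]
    ib <- ib[ok]
    nSites <- (sum(siteTab[ia, "n"]) + sum(siteTab[ib, "n"])) / 2
    sSites <- (sum(siteTab[ia, "s"]) + sum(siteTab[ib, "s"])) / 2
    pairIdx <- cbind(ia, ib)
    Nd <- sum(diffTab$Nd[pairIdx])
    Sd <- sum(diffTab$Sd[pairIdx])
    stopPathCodons <- sum(diffTab$stopPath[pairIdx])
    if (sSites <= 0) {
        stop("gene ", gene, " has zero synonymous sites; dS undefined")
    }
    SdCorrected <- if (Sd == 0) 1 else Sd
    jc <- function(p, what) {
        if (p >= 0.75) {
            stop("gene ", gene, ": proportion of ", what, " differences p = ",
                 signif(p, 4), " >= 3/4; Jukes-Cantor correction undefined")
        }
        -0.75 * log(1 - 4 * p / 3)
    }
    dN <- jc(Nd / nSites, "nonsynonymous")
    dS <- jc(SdCorrected / sSites, "synonymous")
    list(nSites = nSites, sSites = sSites, Nd = Nd, Sd = Sd,
         SdCorrected = SdCorrected, dN = dN, dS = dS,
         omegaRaw = dN / dS, codonsUsed = used,
         codonsSkipped = length(ok) - used,
         stopPathCodons = stopPathCodons)
}

#' Estimate divergence for every gene x taxon pair of an alignment set
#'
#' Applies \code{\link{estimatePair}} to each (gene, taxon) pairwise alignment
#' against the ancestor and attaches the per-gene GC12 fraction (computed on
#' the ancestral CDS, one value per gene) and CDS length used downstream by
#' the normalization step.
#'
#' @param aln A \code{\linkS4class{CodonAlignmentSet}}.
#' @param kappa Transition/transversion ratio for site counting.
#' @return \code{data.frame} with one row per gene x taxon: \code{gene},
#'   \code{taxon}, \code{nSites}, \code{sSites}, \code{Nd}, \code{Sd},
#'   \code{SdCorrected}, \code{dN}, \code{dS}, \code{omegaRaw},
#'   \code{codonsUsed}, \code{codonsSkipped}, \code{gc12}, \code{cdsLength}.
#' @export
estimateDivergence <- function(aln, kappa = 1) {
    stopifnot(is(aln, "CodonAlignmentSet"))
    genes <- geneIds(aln)
    taxa <- alnTaxa(aln)
    anc <- as.character(ancestorSeqs(aln))
    gc <- gc12Content(anc)
    rows <- vector("list", length(genes) * length(taxa))
    k <- 0L
    for (tx in taxa) {
        des <- as.character(taxonSeqs(aln, tx))
        for (g in seq_along(genes)) {
            est <- estimatePair(anc[[g]], des[[g]], kappa = kappa,
                                gene = paste0(genes[g], "|", tx))
            k <- k + 1L
            rows[[k]] <- data.frame(
                gene = genes[g], taxon = tx,
                nSites = est$nSites, sSites = est$sSites,
                Nd = est$Nd, Sd = est$Sd, SdCorrected = est$SdCorrected,
                dN = est$dN, dS = est$dS, omegaRaw = est$omegaRaw,
                codonsUsed = est$codonsUsed,
                codonsSkipped = est$codonsSkipped,
                gc12 = unname(gc[g]),
                cdsLength = nchar(anc[[g]]),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
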