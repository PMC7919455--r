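# Within-species polymorphism ratios and McDonald-Kreitman statistics.

.checkPolyTable <- function(polyTable) {
    need <- c("gene", "class", "maf")
    if (!is.data.frame(polyTable) || !all(need %in% colnames(polyTable))) {
        stop("polymorphism table must have columns: ",
             paste(need, collapse = ", "))
    }
    badClass <- setdiff(unique(polyTable$class),
                        c("synonymous", "nonsynonymous"))
    if (length(badClass)) {
        stop("unknown consequence class(es): ", paste(badClass, collapse = ", "))
    }
    if (nrow(polyTable) &&
        (any(polyTable$maf <= 0) || any(polyTable$maf > 0.5))) {
        stop("MAF values must lie in (0, 0.5]")
    }
    invisible(polyTable)
}

#' Count polymorphic sites by consequence class under a MAF filter
#'
#' Counts synonymous and nonsynonymous segregating sites per gene, keeping
#' only variants with minor allele frequency strictly below \code{mafMax}
#' (\code{NULL} keeps all variants).  The conventional screens use all SNPs,
#' MAF < 1\% and MAF < 5\%.
#'
#' @param polyTable \code{data.frame} with columns \code{gene}, \code{class}
#'   (\code{"synonymous"}/\code{"nonsynonymous"}) and \code{maf} in (0, 0.5].
#' @param gene Optional single gene id; if given, returns \code{c(Pn, Ps)} for
#'   that gene (zero counts with a warning when the gene is absent).
#' @param mafMax MAF cutoff (strict) or \code{NULL} for no filter.
#' @return With \code{gene}: named vector \code{c(Pn = , Ps = )}.  Otherwise a
#'   \code{data.frame} with one row per gene present in the table.
#' @examples
#' tab <- data.frame(gene = "g1",
#'                   class = c("nonsynonymous", "synonymous", "nonsynonymous"),
#'                   maf = c(0.004, 0.02, 0.2))
#' countPolymorphism(tab, gene = "g1", mafMax = 0.01)  # c(Pn = 1, Ps = 0)
#' @export
countPolymorphism <- function(polyTable, gene = NULL, mafMax = NULL) {
    .checkPolyTable(polyTable)
    if (!is.null(mafMax)) {
        stopifnot(is.numeric(mafMax), length(mafMax) == 1L,
                  mafMax > 0, mafMax <= 0.5)
        polyTable <- polyTable[polyTable$maf < mafMax, , drop = FALSE]
    }
    if (!is.null(gene)) {
        stopifnot(length(gene) == 1L)
        sub <- polyTable[polyTable$gene == gene, , drop = FALSE]
        if (nrow(sub) == 0L && !gene %in% polyTable$gene) {
            warning("gene '", gene, "' not present in polymorphism table; ",
                    "returning zero counts")
        }
        return(c(Pn = sum(sub$class == "nonsynonymous"),
                 Ps = sum(sub$class == "synonymous")))
    }
    if (nrow(polyTable) == 0L) {
        return(data.frame(gene = character(), Pn = integer(), Ps = integer()))
    }
    tab <- table(factor(polyTable$gene),
                 factor(polyTable$class,
                        levels = c("nonsynonymous", "synonymous")))
    data.frame(gene = rownames(tab),
               Pn = as.integer(tab[, "nonsynonymous"]),
               Ps = as.integer(tab[, "synonymous"]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutrality index
#'
#' NI = (Pn/Ps) / (Dn/Ds), the ratio of the within-species polymorphism ratio
#' to the between-species divergence ratio.  NI < 1 marks an excess of fixed
#' nonsynonymous differences (the fixation signature of adaptive evolution);
#' NI > 1 an excess of nonsynonymous polymorphism (segregating, often mildly
#' deleterious variation).  Zero-valued Ps, Dn or Ds are replaced by 1
#' (mirroring the divergence zero rule) so the index is always finite;
#' Pn = 0 yields NI = 0.  All four counts zero is undefined and returns
#' \code{NA}.
#'
#' @param Pn,Ps Nonsynonymous/synonymous polymorphism counts (vectorized).
#' @param Dn,Ds Nonsynonymous/synonymous divergence counts.
#' @return Numeric vector of neutrality indices (>= 0, or NA).
#' @examples
#' neutralityIndex(2, 2, 7, 1)  # 1/7
#' @export
neutralityIndex <- function(Pn, Ps, Dn, Ds) {
    stopifnot(all(c(Pn, Ps, Dn, Ds) >= 0, na.rm = TRUE))
    n <- max(length(Pn), length(Ps), length(Dn), length(Ds))
    Pn <- rep_len(Pn, n); Ps <- rep_len(Ps, n)
    Dn <- rep_len(Dn, n); Ds <- rep_len(Ds, n)
    undefined <- (Pn + Ps + Dn + Ds) == 0
    Ps1 <- ifelse(Ps == 0, 1, Ps)
    Dn1 <- ifelse(Dn == 0, 1, Dn)
    Ds1 <- ifelse(Ds == 0, 1, Ds)
    ni <- (Pn / Ps1) / (Dn1 / Ds1)
    ni[undefined] <- NA_real_
    ni
}

#' Direction of Selection
#'
#' DoS = Dn/(Dn + Ds) - Pn/(Pn + Ps).  Positive under adaptive evolution
#' (divergence enriched for nonsynonymous changes relative to polymorphism),
#' zero under neutrality, negative under segregating slightly deleterious
#' variation.  Exact formula, no zero replacement; if either denominator is
#' zero the statistic is undefined and \code{NA} is returned.
#'
#' @inheritParams neutralityIndex
#' @return Numeric vector of DoS values in [-1, 1] (or NA).
#' @examples
#' directionOfSelection(7, 1, 1, 1)  # 0.375
#' @export
directionOfSelection <- function(Dn, Ds, Pn, Ps) {
    stopifnot(all(c(Pn, Ps, Dn, Ds) >= 0, na.rm = TRUE))
    n <- max(length(Pn), length(Ps), length(Dn), length(Ds))
    Pn <- rep_len(Pn, n); Ps <- rep_len(Ps, n)
    Dn <- rep_len(Dn, n); Ds <- rep_len(Ds, n)
    dDen <- Dn + Ds
    pDen <- Pn + Ps
    out <- ifelse(dDen > 0 & pDen > 0, Dn / dDen - Pn / pDen, NA_real_)
    out
}

#' Per-gene McDonald-Kreitman selection statistics
#'
#' Joins polymorphism counts (at a chosen MAF filter) with divergence counts
#' for one taxon and computes pN/pS, the neutrality index and the Direction of
#' Selection.  Divergence counts are the raw pathway-averaged substitution
#' counts (site normalizations cancel in NI because polymorphism and
#' divergence refer to the same gene).
#'
#' @param polyTable Polymorphism table (see \code{\link{countPolymorphism}}).
#' @param divergence Divergence table from \code{\link{estimateDivergence}}.
#' @param taxon Taxon whose divergence enters the contrast (default
#'   \code{"hs"}, the modern human branch).
#' @param mafMax MAF cutoff or \code{NULL} for all SNPs.
#' @return \code{data.frame}: \code{gene}, \code{mafFilter}, \code{Pn},
#'   \code{Ps}, \code{Dn}, \code{Ds}, \code{pnPs}, \code{ni}, \code{dos},
#'   \code{fixed} (\code{ni < 1}).
#' @export
selectionStats <- function(polyTable, divergence, taxon = "hs",
                           mafMax = NULL) {
    div <- divergence[divergence$taxon == taxon, , drop = FALSE]
    if (nrow(div) == 0L) {
        stop("no divergence rows for taxon '", taxon, "'")
    }
    counts <- countPolymorphism(polyTable, mafMax = mafMax)
    m <- match(div$gene, counts$gene)
    Pn <- ifelse(is.na(m), 0L, counts$Pn[m])
    Ps <- ifelse(is.na(m), 0L, counts$Ps[m])
    ni <- neutralityIndex(Pn, Ps, div$Nd, div$Sd)
    dos <- directionOfSelection(div$Nd, div$Sd, Pn, Ps)
    data.frame(gene = div$gene,
               mafFilter = if (is.null(mafMax)) "all" else
                   format(mafMax, digits = 6),
               Pn = Pn, Ps = Ps, Dn = div$Nd, Ds = div$Sd,
               pnPs = Pn / ifelse(Ps == 0, 1, Ps),
               ni = ni, dos = dos, fixed = !is.na(ni) & ni < 1,
               stringsAsFactors = FALSE)
}
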