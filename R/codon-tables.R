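# Precomputed codon lookup tables for NG86-family counting.
#
# All tables are indexed by codon index 1..64 in the fixed order of
# .allCodons(). Stop codons carry NA so that a stray stop can never silently
# contribute to a count.

.BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
.TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

.allCodons <- function() {
    if (!is.null(.omegaGCCache$codons)) {
        return(.omegaGCCache$codons)
    }
    g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                     stringsAsFactors = FALSE)
    codons <- paste0(g$p1, g$p2, g$p3)
    .omegaGCCache$codons <- codons
    codons
}

.codonAA <- function() {
    if (is.null(.omegaGCCache$aa)) {
        .omegaGCCache$aa <- unname(GENETIC_CODE[.allCodons()])
    }
    .omegaGCCache$aa
}

.codonIndex <- function(codon) {
    match(codon, .allCodons())
}

.isStopCodon <- function(codon) {
    .codonAA()[.codonIndex(codon)] == "*"
}

# the nine single-nucleotide neighbours of a codon
.codonNeighbors <- function(codon) {
    chars <- strsplit(codon, "", fixed = TRUE)[[1]]
    out <- character(9)
    k <- 0L
    for (pos in 1:3) {
        for (b in setdiff(.BASES, chars[pos])) {
            mut <- chars
            mut[pos] <- b
            k <- k + 1L
            out[k] <- paste(mut, collapse = "")
        }
    }
    out
}

# Per-codon fractional nonsynonymous/synonymous site counts.
#
# For each position the three alternative bases are classified against the
# standard genetic code; alternatives that create a stop codon are excluded
# and the position's single site is rescaled over the remaining alternatives,
# optionally weighting transitions by kappa. Every sense codon contributes
# exactly 3 sites.
.buildSiteTable <- function(kappa = 1) {
    codons <- .allCodons()
    aa <- .codonAA()
    nS <- rep(NA_real_, 64)
    nN <- rep(NA_real_, 64)
    for (i in seq_len(64)) {
        if (aa[i] == "*") next
        chars <- strsplit(codons[i], "", fixed = TRUE)[[1]]
        sTot <- 0
        for (pos in 1:3) {
            wSum <- 0
            wSyn <- 0
            for (b in setdiff(.BASES, chars[pos])) {
                mut <- chars
                mut[pos] <- b
                j <- .codonIndex(paste(mut, collapse = ""))
                if (aa[j] == "*") next
                w <- if (b == .TRANSITION[[chars[pos]]]) kappa else 1
                wSum <- wSum + w
                if (aa[j] == aa[i]) wSyn <- wSyn + w
            }
            # every position of a sense codon has at least one sense neighbour
            # under the standard code
            sTot <- sTot + wSyn / wSum
        }
        nS[i] <- sTot
        nN[i] <- 3 - sTot
    }
    cbind(n = nN, s = nS)
}

.siteTable <- function(kappa = 1) {
    key <- paste0("sites_", format(kappa, digits = 12))
    if (is.null(.omegaGCCache[[key]])) {
        .omegaGCCache[[key]] <- .buildSiteTable(kappa)
    }
    .omegaGCCache[[key]]
}

# Enumerate all mutational pathways between two sense codons.
#
# A pathway is an ordering of the differing positions; its steps are
# classified synonymous/nonsynonymous. Pathways passing through a stop codon
# are dropped; if every pathway does, all pathways are used and the pair is
# flagged (the spec's degenerate fallback -- cannot occur between sense codons
# under the standard code at <= 2 differences, rare at 3).
.pairPathwayCounts <- function(a, b) {
    aa <- .codonAA()
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    diffPos <- which(ca != cb)
    d <- length(diffPos)
    if (d == 0L) {
        return(list(Nd = 0, Sd = 0, stopPath = FALSE))
    }
    orders <- switch(d,
        list(diffPos),
        list(diffPos, diffPos[c(2, 1)]),
        {
            p <- diffPos
            list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                 p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
        })
    stepCount <- function(ord, allowStop) {
        cur <- ca
        nd <- 0
        sd <- 0
        for (pos in ord) {
            nxt <- cur
            nxt[pos] <- cb[pos]
            aaCur <- aa[.codonIndex(paste(cur, collapse = ""))]
            aaNxt <- aa[.codonIndex(paste(nxt, collapse = ""))]
            if (aaNxt == "*" && !allowStop) {
                return(NULL)
            }
            if (identical(aaCur, aaNxt)) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
        }
        c(nd, sd)
    }
    counts <- Filter(Negate(is.null), lapply(orders, stepCount, allowStop = FALSE))
    stopPath <- FALSE
    if (length(counts) == 0L) {
        counts <- lapply(orders, stepCount, allowStop = TRUE)
        stopPath <- TRUE
    }
    m <- do.call(rbind, counts)
    list(Nd = mean(m[, 1]), Sd = mean(m[, 2]), stopPath = stopPath)
}

# 64 x 64 lookup matrices of pathway-averaged difference counts
.diffTables <- function() {
    if (!is.null(.omegaGCCache$diff)) {
        return(.omegaGCCache$diff)
    }
    codons <- .allCodons()
    aa <- .codonAA()
    sense <- which(aa != "*")
    Nd <- matrix(NA_real_, 64, 64)
    Sd <- matrix(NA_real_, 64, 64)
    flag <- matrix(FALSE, 64, 64)
    for (i in sense) {
        for (j in sense) {
            if (j < i) next
            pc <- .pairPathwayCounts(codons[i], codons[j])
            Nd[i, j] <- Nd[j, i] <- pc$Nd
            Sd[i, j] <- Sd[j, i] <- pc$Sd
            flag[i, j] <- flag[j, i] <- pc$stopPath
        }
    }
    .omegaGCCache$diff <- list(Nd = Nd, Sd = Sd, stopPath = flag)
    .omegaGCCache$diff
}

.checkCodon <- function(codon, arg = "codon") {
    if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
        stop(arg, " must be a single 3-letter codon string")
    }
    codon <- toupper(codon)
    i <- .codonIndex(codon)
    if (is.na(i)) {
        stop(arg, " '", codon, "' contains characters outside A/C/G/T")
    }
    if (.codonAA()[i] == "*") {
        stop(arg, " '", codon, "' is a stop codon and cannot be counted")
    }
    codon
}

#' Fractional synonymous and nonsynonymous site counts of a codon
#'
#' Classifies each of the nine single-nucleotide neighbours of a sense codon
#' under the standard genetic code.  Neighbours that are stop codons are
#' excluded and each position's site is rescaled over its remaining
#' neighbours, so every sense codon contributes exactly 3 sites.  With
#' \code{kappa != 1}, transitions are weighted \code{kappa}-fold relative to
#' transversions in the per-position fractions (the mutation-opportunity
#' weighting used when the underlying process has transition bias).
#'
#' @param codon A single sense codon, e.g. \code{"TTT"}.
#' @param kappa Transition/transversion rate ratio used to weight neighbours;
#'   the default 1 reproduces classic equal-weight NG86 counting.
#' @return Named numeric vector \code{c(n = , s = )} of nonsynonymous and
#'   synonymous site counts; \code{n + s == 3}.
#' @examples
#' countSites("TTT")  # c(n = 8/3, s = 1/3)
#' countSites("TGG")  # Trp: all sense neighbours nonsynonymous -> c(3, 0)
#' @export
countSites <- function(codon, kappa = 1) {
    codon <- .checkCodon(codon)
    stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
    tab <- .siteTable(kappa)
    i <- .codonIndex(codon)
    c(n = unname(tab[i, "n"]), s = unname(tab[i, "s"]))
}

#' Pathway-averaged substitution counts between two codons
#'
#' Counts nonsynonymous and synonymous differences between two sense codons.
#' Codons differing at one position are classified directly; at two or three
#' positions the synonymous/nonsynonymous step counts are averaged over all
#' mutational pathways that avoid stop-codon intermediates (equal pathway
#' weights).  If every pathway passes through a stop, all pathways are used
#' and the result is flagged via the \code{"stopPath"} attribute.
#'
#' @param codonA,codonB Sense codons.
#' @return Named numeric vector \code{c(Nd = , Sd = )} with
#'   \code{Nd + Sd} equal to the number of differing positions, and a logical
#'   attribute \code{stopPath}.
#' @examples
#' countDifferences("TTT", "TTC")  # one synonymous change
#' countDifferences("TTT", "GTA")  # average over two 2-step pathways
#' @export
countDifferences <- function(codonA, codonB) {
    codonA <- .checkCodon(codonA, "codonA")
    codonB <- .checkCodon(codonB, "codonB")
    tabs <- .diffTables()
    i <- .codonIndex(codonA)
    j <- .codonIndex(codonB)
    out <- c(Nd = tabs$Nd[i, j], Sd = tabs$Sd[i, j])
    attr(out, "stopPath") <- tabs$stopPath[i, j]
    out
}
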