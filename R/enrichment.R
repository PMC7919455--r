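# Gene-set statistics: signed-rank test against the genome mean,
# rank-biserial effect size, covariate-matched bootstrap empirical p-values,
# Bonferroni adjustment and Fisher overlap tests.

# signed ranks of the non-zero values (ties mid-ranked)
.signedRanks <- function(values) {
    v <- values[values != 0 & is.finite(values)]
    r <- rank(abs(v))
    list(v = v, r = r,
         wPlus = sum(r[v > 0]), wMinus = sum(r[v < 0]), n = length(v))
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Tests whether a gene set's omega_GC12 values deviate from 0, the
#' genome-wide mean after per-taxon standardization.  Zeros are dropped
#' (Wilcoxon's original treatment), ties are mid-ranked.  The two-sided p is
#' exact (from the signed-rank distribution) for n <= 25 without ties, and a
#' normal approximation with continuity and tie correction otherwise.
#'
#' @param values Numeric vector (n >= 5 non-zero values).
#' @return List with \code{wPlus}, \code{wMinus} (signed-rank sums),
#'   \code{n} (non-zero values used), \code{p} and \code{method}.
#' @export
signedRankTest <- function(values) {
    sr <- .signedRanks(values)
    if (sr$n == 0L) {
        stop("all values are zero; signed-rank test undefined")
    }
    if (sr$n < 5L) {
        stop("need >= 5 non-zero values, got ", sr$n)
    }
    n <- sr$n
    hasTies <- anyDuplicated(abs(sr$v)) > 0L
    if (n <= 25L && !hasTies) {
        wMin <- min(sr$wPlus, sr$wMinus)
        p <- min(1, 2 * psignrank(wMin, n))
        method <- "exact"
    } else {
        mu <- n * (n + 1) / 4
        tieTab <- table(rank(abs(sr$v)))
        sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(tieTab^3 - tieTab) / 48
        z <- (sr$wPlus - mu - 0.5 * sign(sr$wPlus - mu)) / sqrt(sigma2)
        p <- min(1, 2 * pnorm(-abs(z)))
        method <- "normal-approx"
    }
    list(wPlus = sr$wPlus, wMinus = sr$wMinus, n = n, p = p, method = method)
}

#' Matched-pairs rank-biserial correlation
#'
#' Effect size of the one-sample signed-rank test: the difference between the
#' proportion of signed-rank mass above zero (f) and below zero (u),
#' \eqn{rc = (\sum r^+ - \sum r^-) / (\sum r^+ + \sum r^-) = f - u}, using the
#' same ranks (zeros dropped, ties mid-ranked) as
#' \code{\link{signedRankTest}}.  Ranges over [-1, 1]; negative values mark
#' gene sets more constrained than the genome, positive values more diverged.
#'
#' @param values Numeric vector with at least one non-zero value.
#' @return rc in [-1, 1].
#' @examples
#' rankBiserial(c(5, -1, 4, -2, 3))  # 0.6
#' @export
rankBiserial <- function(values) {
    sr <- .signedRanks(values)
    tot <- sr$wPlus + sr$wMinus
    if (tot == 0) {
        stop("all values are zero; rank-biserial undefined")
    }
    (sr$wPlus - sr$wMinus) / tot
}

# fast internal rc (assumes at least one finite non-zero value)
.rcFast <- function(v) {
    v <- v[v != 0]
    r <- rank(abs(v))
    s <- sum(r)
    (sum(r[v > 0]) - sum(r[v < 0])) / s
}

# joint quantile-bin ids over (gc12, log cdsLength); collapses gracefully
# when quantile breaks are not unique (small universes)
.covariateBins <- function(covariates, nBins) {
    cutQ <- function(x, k) {
        br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1),
                              names = FALSE))
        if (length(br) < 2L) {
            return(rep(1L, length(x)))
        }
        as.integer(cut(x, br, include.lowest = TRUE))
    }
    bg <- cutQ(covariates$gc12, nBins)
    bl <- cutQ(log(covariates$cdsLength), nBins)
    list(gc = bg, len = bl, id = paste(bg, bl, sep = ":"))
}

#' Covariate-matched bootstrap empirical p-value
#'
#' Compares a gene set's statistic (default: rank-biserial correlation of its
#' omega_GC12 values) to its distribution over \code{nDraws} random gene sets
#' of the same size drawn from the analyzed universe, matched to the set's
#' joint (GC12, CDS length) distribution by stratified sampling over a
#' quantile-bin grid.  This is the correction for the GC-content and
#' gene-length biases that confound naive resampling.  The two-sided
#' empirical p is
#' \deqn{p = 2 \min\left(\frac{1 + \sum_i [B_i \ge m]}{N + 1},
#'       \frac{1 + \sum_i [B_i \le m]}{N + 1}\right),}
#' capped at 1, where m is the observed statistic and B_i the draw values.
#'
#' @param values Named numeric vector of scores over the whole gene universe
#'   (names are gene ids).
#' @param setGenes Character vector of member gene ids (subset of
#'   \code{names(values)}).
#' @param covariates \code{data.frame} with columns \code{gene}, \code{gc12},
#'   \code{cdsLength} covering the universe.
#' @param statistic \code{"rc"} (rank-biserial, default) or \code{"mean"}.
#' @param nDraws Number of bootstrap draws (default 10000).
#' @param nBins Bins per covariate axis for the matching grid (default 10,
#'   i.e. decile strata; set \code{match = FALSE} for unmatched resampling).
#' @param match Use covariate matching (default TRUE).
#' @param seed Optional integer seed for reproducible draws.
#' @return List: \code{statistic} (m), \code{p}, \code{nDraws}, \code{nSet},
#'   \code{matched}, and \code{nFallback} (strata that had to borrow
#'   candidates from the nearest bin).
#' @export
matchedBootstrap <- function(values, setGenes, covariates,
                             statistic = c("rc", "mean"),
                             nDraws = 10000, nBins = 10, match = TRUE,
                             seed = NULL) {
    statistic <- match.arg(statistic)
    statFun <- if (statistic == "rc") .rcFast else mean
    universe <- names(values)
    if (is.null(universe)) {
        stop("'values' must be named by gene id")
    }
    setGenes <- unique(setGenes)
    if (!all(setGenes %in% universe)) {
        stop("set contains genes outside the universe: ",
             paste(head(setdiff(setGenes, universe), 5), collapse = ", "))
    }
    k <- length(setGenes)
    if (k == 0L) stop("empty gene set")
    if (length(universe) < 10L * k) {
        stop("universe must be >= 10x the set size (",
             length(universe), " vs ", k, ")")
    }
    if (!is.null(seed)) set.seed(seed)
    m <- statFun(values[setGenes])

    if (match) {
        cv <- covariates[match(universe, covariates$gene), , drop = FALSE]
        if (any(is.na(cv$gc12)) || any(is.na(cv$cdsLength))) {
            stop("covariates missing for some universe genes")
        }
        bins <- .covariateBins(cv, nBins)
        setBinTab <- table(bins$id[universe %in% setGenes])
        binIdx <- split(seq_along(universe), bins$id)
        nFallback <- 0L
        strata <- vector("list", length(setBinTab))
        for (i in seq_along(setBinTab)) {
            id <- names(setBinTab)[i]
            need <- as.integer(setBinTab[[i]])
            pool <- binIdx[[id]]
            if (length(pool) < need) {
                # borrow from the nearest bin on the joint grid
                ref <- as.integer(strsplit(id, ":", fixed = TRUE)[[1]])
                dists <- vapply(names(binIdx), function(b) {
                    bb <- as.integer(strsplit(b, ":", fixed = TRUE)[[1]])
                    sum(abs(bb - ref))
                }, numeric(1))
                for (b in names(sort(dists))) {
                    pool <- unique(c(pool, binIdx[[b]]))
                    if (length(pool) >= need) break
                }
                nFallback <- nFallback + 1L
                warning("stratum ", id, " underpopulated; borrowed from ",
                        "nearest bin(s)")
            }
            strata[[i]] <- list(pool = pool, need = need)
        }
        # assemble all draws at once, stratum by stratum (without
        # replacement within each draw's stratum)
        idxMat <- matrix(0L, nDraws, k)
        col <- 0L
        for (s in strata) {
            P <- length(s$pool)
            need <- s$need
            block <- if (need == P) {
                matrix(rep(s$pool, each = nDraws), nDraws, need)
            } else if (need == 1L) {
                matrix(s$pool[sample.int(P, nDraws, replace = TRUE)], ncol = 1)
            } else if (need == 2L) {
                i <- sample.int(P, nDraws, replace = TRUE)
                j <- sample.int(P - 1L, nDraws, replace = TRUE)
                j <- j + (j >= i)
                cbind(s$pool[i], s$pool[j])
            } else {
                t(vapply(seq_len(nDraws), function(d)
                    s$pool[sample.int(P, need)], integer(need)))
            }
            idxMat[, col + seq_len(need)] <- block
            col <- col + need
        }
        vals <- matrix(values[idxMat], nDraws, k)
        B <- vapply(seq_len(nDraws), function(d) statFun(vals[d, ]),
                    numeric(1))
    } else {
        nFallback <- 0L
        nUni <- length(universe)
        B <- vapply(seq_len(nDraws), function(d)
            statFun(values[sample.int(nUni, k)]), numeric(1))
    }
    p <- 2 * min((1 + sum(B >= m)) / (nDraws + 1),
                 (1 + sum(B <= m)) / (nDraws + 1))
    list(statistic = m, p = min(1, p), nDraws = nDraws, nSet = k,
         matched = match, nFallback = nFallback)
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the family size and caps at 1.  One family per
#' dataset screen (e.g. all tissues of one expression atlas).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param k Family size (defaults to \code{length(p)}).
#' @return Adjusted p-values, elementwise \code{pmin(1, p * k)}.
#' @export
bonferroniAdjust <- function(p, k = length(p)) {
    stopifnot(all(p > 0 & p <= 1, na.rm = TRUE), k >= 1)
    pmin(1, p * k)
}

#' Fisher's exact overlap test between two gene sets
#'
#' Builds the 2x2 membership table of two sets over a common universe and
#' tests for association.  Reports the sample odds ratio (with Haldane 0.5
#' correction when a cell is zero), the exact conditional odds ratio and
#' two-sided p from \code{fisher.test}, and a 95\% CI from the log-OR normal
#' approximation.
#'
#' @param setA,setB Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return List: \code{table}, \code{oddsRatio} (sample), \code{orConditional},
#'   \code{ci95}, \code{p}.
#' @export
fisherOverlap <- function(setA, setB, universe) {
    setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
    if (!all(setA %in% universe) || !all(setB %in% universe)) {
        stop("universe must contain both gene sets")
    }
    inA <- universe %in% setA
    inB <- universe %in% setB
    tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                    sum(!inA & inB), sum(!inA & !inB)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(A = c("in", "out"), B = c("in", "out")))
    ft <- fisher.test(tab)
    orSample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    # Haldane 0.5 correction for the CI (and OR display) when a cell is zero
    t2 <- tab + if (any(tab == 0)) 0.5 else 0
    orHaldane <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    seLog <- sqrt(sum(1 / t2))
    ci <- exp(log(orHaldane) + c(-1, 1) * 1.959964 * seLog)
    list(table = tab, oddsRatio = orSample, orHaldane = orHaldane,
         orConditional = unname(ft$estimate),
         ci95 = ci, p = ft$p.value)
}

#' Enrichment screen over a collection of gene sets
#'
#' For each gene set: one-sample signed-rank test of the members' omega_GC12
#' values against the genome mean (zero), rank-biserial effect size,
#' covariate-matched bootstrap empirical p, and Bonferroni adjustment over the
#' screen (one family per call).
#'
#' @param omega An \code{\linkS4class{OmegaTable}} (or a named numeric vector
#'   of scores plus a \code{covariates} data.frame).
#' @param sets Named list of gene-id vectors.
#' @param taxon Taxon column to test when \code{omega} is an OmegaTable.
#' @param covariates Optional covariate data.frame (required when passing a
#'   bare vector).
#' @param nDraws,nBins,statistic,seed Passed to \code{\link{matchedBootstrap}}.
#' @param minSize Sets with fewer scored members are skipped (default 5).
#' @return \code{data.frame}: \code{set}, \code{n}, \code{rc}, \code{wPlus},
#'   \code{wMinus}, \code{pWilcoxon}, \code{pBootstrap}, \code{pBonferroni},
#'   \code{direction}.
#' @export
enrichGeneSets <- function(omega, sets, taxon = "hs", covariates = NULL,
                           nDraws = 10000, nBins = 10,
                           statistic = c("rc", "mean"), seed = NULL,
                           minSize = 5) {
    statistic <- match.arg(statistic)
    if (is(omega, "OmegaTable")) {
        if (!taxon %in% colnames(omega)) {
            stop("taxon '", taxon, "' not in OmegaTable")
        }
        values <- omegaGC12(omega)[, taxon]
        covariates <- data.frame(gene = rownames(omega),
                                 gc12 = rowData(omega)$gc12,
                                 cdsLength = rowData(omega)$cdsLength)
    } else {
        values <- omega
        if (is.null(covariates)) {
            stop("covariates required when 'omega' is a plain vector")
        }
    }
    values <- values[is.finite(values)]
    if (!is.null(seed)) set.seed(seed)
    rows <- lapply(names(sets), function(nm) {
        members <- intersect(sets[[nm]], names(values))
        if (length(members) < minSize) {
            return(NULL)
        }
        if (length(values) < 10L * length(members)) {
            warning("set '", nm, "' skipped: universe smaller than 10x ",
                    "the set size")
            return(NULL)
        }
        v <- values[members]
        wt <- signedRankTest(v)
        rc <- rankBiserial(v)
        bs <- matchedBootstrap(values, members, covariates,
                               statistic = statistic, nDraws = nDraws,
                               nBins = nBins)
        data.frame(set = nm, n = length(members), rc = rc,
                   wPlus = wt$wPlus, wMinus = wt$wMinus,
                   pWilcoxon = wt$p, pBootstrap = bs$p,
                   direction = if (rc < 0) "conserved" else "diverged",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) {
        stop("no gene set had >= ", minSize, " scored members")
    }
    out$pBonferroni <- bonferroniAdjust(out$pWilcoxon, nrow(out))
    out[, c("set", "n", "rc", "wPlus", "wMinus", "pWilcoxon",
            "pBootstrap", "pBonferroni", "direction")]
}
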