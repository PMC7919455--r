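# Independent oracles and small fixture builders used across the suite.

.GC <- Biostrings::GENETIC_CODE

# Exhaustive pathway enumeration for substitution counting, written
# independently of the package (recursive, translating via GENETIC_CODE).
oracleCountDifferences <- function(a, b, allowStop = FALSE) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    recurse <- function(cur) {
        diffs <- which(cur != cb)
        if (length(diffs) == 0L) {
            return(list(c(0, 0)))
        }
        out <- list()
        for (pos in diffs) {
            nxt <- cur
            nxt[pos] <- cb[pos]
            nxtCodon <- paste(nxt, collapse = "")
            if (.GC[[nxtCodon]] == "*" && !allowStop) next
            step <- if (.GC[[paste(cur, collapse = "")]] == .GC[[nxtCodon]]) {
                c(0, 1)
            } else {
                c(1, 0)
            }
            for (tail in recurse(nxt)) {
                out[[length(out) + 1L]] <- step + tail
            }
        }
        out
    }
    paths <- recurse(ca)
    if (length(paths) == 0L) {
        return(oracleCountDifferences(a, b, allowStop = TRUE))
    }
    m <- do.call(rbind, paths)
    c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# Independent site counting: classify the nine neighbours directly.
oracleCountSites <- function(codon) {
    chars <- strsplit(codon, "")[[1]]
    sTot <- 0
    for (pos in 1:3) {
        nSyn <- 0
        nValid <- 0
        for (base in setdiff(c("A", "C", "G", "T"), chars[pos])) {
            mut <- chars
            mut[pos] <- base
            aa <- .GC[[paste(mut, collapse = "")]]
            if (aa == "*") next
            nValid <- nValid + 1
            if (aa == .GC[[codon]]) nSyn <- nSyn + 1
        }
        sTot <- sTot + nSyn / nValid
    }
    c(n = 3 - sTot, s = sTot)
}

senseCodons <- function() {
    all <- names(.GC)
    all[.GC != "*"]
}

# Hubert-Arabie adjusted Rand index between two label vectors.
adjustedRandIndex <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    n <- comb2(sum(tab))
    expected <- sumI * sumJ / n
    (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}

# Build an OmegaTable directly from a score matrix (columns standardized),
# for tests that exercise downstream stages in isolation.
makeOmegaTable <- function(z, gc12 = NULL, len = NULL, raw = NULL) {
    z <- scale(z)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    if (is.null(rownames(z))) {
        rownames(z) <- sprintf("g%04d", seq_len(nrow(z)))
    }
    if (is.null(colnames(z))) {
        colnames(z) <- c("hs", "neanderthal", "denisovan",
                         "chimp")[seq_len(ncol(z))]
    }
    if (is.null(gc12)) gc12 <- runif(nrow(z), 0.3, 0.7)
    if (is.null(len)) len <- 3 * round(exp(rnorm(nrow(z), 5.7, 0.5)))
    if (is.null(raw)) raw <- z
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(omegaRaw = raw, omegaGC12 = z),
        rowData = S4Vectors::DataFrame(gc12 = gc12, cdsLength = len,
                                       row.names = rownames(z)))
    methods::new("OmegaTable", se)
}

# Small deterministic alignment fixture built from explicit codon strings.
makeAlignment <- function(ancCodons, taxonCodons, taxon = "hs",
                          gene = "g0001") {
    anc <- stats::setNames(paste(ancCodons, collapse = ""), gene)
    des <- stats::setNames(paste(taxonCodons, collapse = ""), gene)
    CodonAlignmentSet(anc, stats::setNames(list(des), taxon))
}
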