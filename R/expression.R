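# Tissue-specificity scoring of expression matrices.

.checkExprMatrix <- function(mat) {
    if (!is.matrix(mat) || !is.numeric(mat)) {
        stop("expression matrix must be a numeric matrix (genes x tissues)")
    }
    if (ncol(mat) < 3L) {
        stop("expression matrix needs >= 3 tissues, got ", ncol(mat))
    }
    if (any(mat < 0, na.rm = TRUE)) {
        stop("expression matrix contains negative values")
    }
    invisible(mat)
}

#' Tissue-specificity Z-scores
#'
#' Log-transforms expression as \code{log(1 + x)} and standardizes each
#' gene's profile across tissues (subtract the gene mean, divide by the gene
#' SD), yielding a specificity Z per gene x tissue.  Genes with zero variance
#' across tissues receive Z = 0 everywhere (neutral, not dropped).  The dual
#' axis -- Z across genes within each tissue, an expression-level rather than
#' specificity score -- is available via \code{axis = "genes"}.
#'
#' @param mat Nonnegative numeric matrix, genes x tissues, with dimnames.
#' @param log Apply the \code{log1p} transform first (default TRUE).
#' @param axis \code{"tissues"} (specificity, default) or \code{"genes"}
#'   (expression level).
#' @return A list of class \code{"SpecificityScores"}: \code{z} (genes x
#'   tissues Z matrix) and \code{tau} (per-gene tau specificity index).
#' @export
specificityZ <- function(mat, log = TRUE, axis = c("tissues", "genes")) {
    .checkExprMatrix(mat)
    axis <- match.arg(axis)
    lx <- if (log) log1p(mat) else mat
    standardizeRows <- function(m) {
        mu <- rowMeans(m)
        s <- apply(m, 1L, sd)
        z <- (m - mu) / ifelse(s > 0, s, 1)
        z[s == 0, ] <- 0
        z
    }
    z <- if (axis == "tissues") standardizeRows(lx) else t(standardizeRows(t(lx)))
    structure(list(z = z, tau = tauIndex(mat), axis = axis),
              class = "SpecificityScores")
}

#' @export
print.SpecificityScores <- function(x, ...) {
    cat("SpecificityScores:", nrow(x$z), "genes x", ncol(x$z),
        if (x$axis == "tissues") "tissues (Z across tissues per gene)\n"
        else "tissues (Z across genes per tissue)\n")
    cat("  genes with Z > 2 in >= 1 tissue:", sum(apply(x$z, 1, max) > 2), "\n")
    invisible(x)
}

#' Tau tissue-specificity index
#'
#' \eqn{\tau = \sum_i (1 - x_i / x_{max}) / (T - 1)} over the \code{T} tissues
#' of a nonnegative expression profile: 0 for uniform expression, 1 for
#' expression confined to a single tissue.  Invariant to positive rescaling of
#' the profile.  All-zero profiles are undefined (\code{NA}).
#'
#' @param x Numeric profile, or a genes x tissues matrix (tau per row).
#' @return Tau in [0, 1] (scalar or per-gene vector).
#' @examples
#' tauIndex(c(1, 0.5, 0))  # 0.75
#' @export
tauIndex <- function(x) {
    if (is.matrix(x)) {
        return(apply(x, 1L, tauIndex))
    }
    stopifnot(is.numeric(x), length(x) >= 2L)
    if (any(x < 0, na.rm = TRUE)) {
        stop("tau requires a nonnegative profile")
    }
    mx <- max(x)
    if (!is.finite(mx) || mx == 0) {
        return(NA_real_)
    }
    sum(1 - x / mx) / (length(x) - 1)
}

#' Genes specifically expressed in one tissue
#'
#' @param scores \code{SpecificityScores} from \code{\link{specificityZ}}.
#' @param tissue Tissue (column) label.
#' @param zThreshold Specificity cutoff; genes with Z strictly above it are
#'   returned (default 2, i.e. two SD above the gene's own cross-tissue mean).
#' @return Character vector of gene ids.
#' @export
specificGenes <- function(scores, tissue, zThreshold = 2) {
    stopifnot(inherits(scores, "SpecificityScores"))
    if (!tissue %in% colnames(scores$z)) {
        stop("unknown tissue '", tissue, "'")
    }
    rownames(scores$z)[scores$z[, tissue] > zThreshold]
}

#' One tissue-specific gene set per tissue
#'
#' @param scores \code{SpecificityScores}.
#' @param zThreshold Specificity cutoff.
#' @return Named list of gene-id vectors (empty sets dropped), suitable for
#'   \code{\link{writeGmt}}.
#' @export
tissueGeneSets <- function(scores, zThreshold = 2) {
    stopifnot(inherits(scores, "SpecificityScores"))
    sets <- lapply(colnames(scores$z), function(tx)
        specificGenes(scores, tx, zThreshold))
    names(sets) <- colnames(scores$z)
    sets[lengths(sets) > 0]
}
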