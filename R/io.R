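# Readers and writers for the pipeline's plain-text formats: per-gene FASTA
# of codon alignments (record ids "<gene>|<taxon>"), tab-separated tables,
# and GMT gene-set files.

#' Read pairwise codon alignments from FASTA
#'
#' Records must be named \code{<gene>|<taxon>} with exactly one
#' \code{ancestor} record per gene; every sequence of a gene must have the
#' same length, divisible by 3.  Violations fail with the offending record
#' named.
#'
#' @param path FASTA file.
#' @return A \code{\linkS4class{CodonAlignmentSet}}.
#' @export
readCodonAlignments <- function(path) {
    seqs <- readDNAStringSet(path)
    ids <- names(seqs)
    parts <- strsplit(ids, "|", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
        stop("record ", bad[1], " ('", ids[bad[1]],
             "'): id is not '<gene>|<taxon>'")
    }
    gene <- vapply(parts, `[`, character(1), 1L)
    taxon <- vapply(parts, `[`, character(1), 2L)
    genes <- unique(gene)
    taxa <- setdiff(unique(taxon), "ancestor")
    ancIdx <- which(taxon == "ancestor")
    if (!setequal(gene[ancIdx], genes) || length(ancIdx) != length(genes)) {
        missing <- setdiff(genes, gene[ancIdx])
        stop("missing or duplicated ancestor record(s): ",
             paste(head(missing, 5), collapse = ", "))
    }
    anc <- seqs[ancIdx]
    names(anc) <- gene[ancIdx]
    anc <- anc[genes]
    descendants <- lapply(taxa, function(tx) {
        i <- which(taxon == tx)
        if (!setequal(gene[i], genes) || length(i) != length(genes)) {
            stop("taxon '", tx, "': records do not cover every gene exactly once")
        }
        ds <- seqs[i]
        names(ds) <- gene[i]
        ds[genes]
    })
    names(descendants) <- taxa
    CodonAlignmentSet(anc, descendants)
}

#' Write a CodonAlignmentSet as FASTA
#'
#' Inverse of \code{\link{readCodonAlignments}} (round-trip exact).
#'
#' @param aln A \code{\linkS4class{CodonAlignmentSet}}.
#' @param path Output FASTA path.
#' @export
writeCodonAlignments <- function(aln, path) {
    stopifnot(is(aln, "CodonAlignmentSet"))
    genes <- geneIds(aln)
    all <- c(setNames(as.character(ancestorSeqs(aln)),
                      paste0(genes, "|ancestor")),
             unlist(lapply(alnTaxa(aln), function(tx)
                 setNames(as.character(taxonSeqs(aln, tx)),
                          paste0(genes, "|", tx)))))
    writeXStringSet(DNAStringSet(all), path, width = 80L)
    invisible(path)
}

#' Read/write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT file.
#' @return \code{readGmt}: named list of gene-id vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short)) {
        stop("GMT line ", short[1], " has fewer than 3 fields")
    }
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[`, character(1), 1L)
    sets
}

#' @rdname readGmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read/write tab-separated pipeline tables
#'
#' TSV with header row, tab separation, '.' decimal, no quoting -- the schema
#' every module writes and re-ingests.
#'
#' @param path TSV file.
#' @return \code{readTsv}: \code{data.frame}.
#' @export
readTsv <- function(path) {
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               check.names = FALSE)
}

#' @rdname readTsv
#' @param x \code{data.frame} to write.
#' @export
writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' Read a polymorphism table (gene, class, maf)
#'
#' @param path TSV with columns \code{gene}, \code{class}, \code{maf}.
#' @return Validated \code{data.frame}.
#' @export
readPolymorphismTable <- function(path) {
    .checkPolyTable(readTsv(path))
}

#' Read a gene x tissue expression matrix
#'
#' @param path TSV: first column gene ids, remaining columns one per tissue.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
readExpressionMatrix <- function(path) {
    df <- readTsv(path)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    storage.mode(mat) <- "double"
    .checkExprMatrix(mat)
    mat
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the alignment FASTA, polymorphism TSV, expression TSV and
#' ground-truth TSV of a \code{\link{simulateDataset}} result.
#'
#' @param sim Result of \code{\link{simulateDataset}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
writeSimulatedData <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(alignments = file.path(dir, "alignments.fa"),
               polymorphism = file.path(dir, "polymorphism.tsv"),
               expression = file.path(dir, "expression.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeCodonAlignments(sim$alignments, paths["alignments"])
    writeTsv(sim$polymorphism, paths["polymorphism"])
    writeTsv(data.frame(gene = rownames(sim$expression),
                        sim$expression, check.names = FALSE),
             paths["expression"])
    writeTsv(sim$truth, paths["truth"])
    paths
}
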