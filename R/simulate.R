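# Synthetic-data generators with known ground truth: ancestral CDS with a
# controllable GC12 distribution, descendant sequences evolved under per-gene
# omega with a GC12-linked bias, segregating-site tables with configurable
# frequency spectra, and expression matrices with spiked tissue-specific
# genes.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators, with defaults that
#' emulate a deep-primate-ancestor comparison: four hominin/primate taxa
#' diverging independently from one ancestor (star phylogeny), ~0.1 expected
#' synonymous substitutions per site per branch, a genome-wide omega mixture
#' dominated by purifying selection with a small positively selected tail,
#' GC12 spanning 0.3-0.7 with a GC-linked distortion of the realized omega,
#' 1000-Genomes-scale polymorphism sampling and a 16-tissue expression panel.
#'
#' @param nGenes Number of genes.
#' @param geneLengthRange Min/max gene length in codons (>= 30).
#' @param gc12Range Min/max target GC12 fraction.
#' @param taxa Taxon labels diverging from the common ancestor.
#' @param branchSubsPerCodon Expected substitution proposals per codon per
#'   branch (~3x the per-site rate).
#' @param omegaAssignment Either a numeric vector of length \code{nGenes} of
#'   true per-gene omega values, or a named numeric vector of mixture
#'   fractions (names are omega values, values are fractions summing to 1).
#' @param kappa Transition/transversion rate ratio of the mutation process.
#'   The default 1 matches the equal-weight pathway estimator; raise it
#'   together with the estimator's \code{kappa} argument.
#' @param gcBiasSlope Strength of the GC12-linked multiplicative distortion of
#'   the realized omega: \code{omegaEff = omega * (1 + slope*(gc12 - 0.5))}.
#'   This is the confound the GC12 regression is designed to remove.
#' @param nChromosomes Sample size (chromosomes) behind the polymorphism
#'   table; MAF resolution is 1/nChromosomes.
#' @param polymorphismRate Expected synonymous segregating sites per
#'   synonymous site.
#' @param nTissues Number of tissues in the expression matrix.
#' @param spikeFraction Fraction of genes made tissue-specific.
#' @param spikeFold Expression fold-change of a spiked gene in its tissue.
#' @param seed RNG seed used by \code{\link{simulateDataset}}.
#' @return Validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGenes = 500,
                             geneLengthRange = c(100, 600),
                             gc12Range = c(0.3, 0.7),
                             taxa = c("hs", "neanderthal", "denisovan", "chimp"),
                             branchSubsPerCodon = 0.35,
                             omegaAssignment = c("0.2" = 0.65, "0.5" = 0.25,
                                                 "1" = 0.08, "2.5" = 0.02),
                             kappa = 1,
                             gcBiasSlope = 2,
                             nChromosomes = 5000,
                             polymorphismRate = 0.03,
                             nTissues = 16,
                             spikeFraction = 0.1,
                             spikeFold = 32,
                             seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes),
                geneLengthRange = as.integer(geneLengthRange),
                gc12Range = gc12Range, taxa = taxa,
                branchSubsPerCodon = branchSubsPerCodon,
                omegaAssignment = omegaAssignment, kappa = kappa,
                gcBiasSlope = gcBiasSlope,
                nChromosomes = as.integer(nChromosomes),
                polymorphismRate = polymorphismRate,
                nTissues = as.integer(nTissues),
                spikeFraction = spikeFraction, spikeFold = spikeFold,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(nGenes > 0, nTissues >= 3, nChromosomes >= 2,
                  length(geneLengthRange) == 2, geneLengthRange[1] >= 30,
                  geneLengthRange[1] <= geneLengthRange[2],
                  length(gc12Range) == 2, all(gc12Range >= 0),
                  all(gc12Range <= 1), gc12Range[1] <= gc12Range[2],
                  branchSubsPerCodon >= 0, kappa > 0,
                  spikeFraction >= 0, spikeFraction <= 1, spikeFold > 0,
                  polymorphismRate > 0, length(taxa) >= 1,
                  !anyDuplicated(taxa), all(taxa != "ancestor"))
        if (!is.null(names(omegaAssignment))) {
            stopifnot(abs(sum(omegaAssignment) - 1) < 1e-8,
                      all(as.numeric(names(omegaAssignment)) >= 0))
        } else {
            stopifnot(length(omegaAssignment) == nGenes,
                      all(omegaAssignment >= 0))
        }
    })
    structure(cfg, class = "SimulationConfig")
}

# sample() without the scalar-x surprise
.sampleFrom <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# draw per-gene true omega values from the assignment spec
.drawOmega <- function(cfg) {
    oa <- cfg$omegaAssignment
    if (is.null(names(oa))) {
        return(as.numeric(oa))
    }
    levels <- as.numeric(names(oa))
    .sampleFrom(levels, cfg$nGenes, replace = TRUE, prob = oa)
}

#' Simulate ancestral coding sequences
#'
#' Builds one CDS per gene: an ATG initiator, no internal stop, no terminal
#' stop, and an exact GC12 budget.  The per-gene target GC12 is drawn
#' uniformly from \code{gc12Range}; G/C placement at codon positions 1-2 hits
#' the rounded target exactly (third positions are uniform over stop-avoiding
#' bases), so the realized GC12 matches the target to within 1/(2L).  An
#' unreachable target (e.g. range (1,1), unattainable because of the ATG
#' start) fails naming the gene.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return Named \code{DNAStringSet} of ancestral CDS with a
#'   \code{"targetGC12"} metadata column... returned via attribute
#'   \code{"targetGC12"}.
#' @export
simulateAncestors <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    nd <- max(4L, nchar(as.character(config$nGenes)))
    genes <- sprintf(paste0("g%0", nd, "d"), seq_len(config$nGenes))
    lens <- .sampleFrom(seq(config$geneLengthRange[1],
                            config$geneLengthRange[2]),
                        config$nGenes, replace = TRUE)
    targets <- runif(config$nGenes, config$gc12Range[1], config$gc12Range[2])
    seqs <- character(config$nGenes)
    for (g in seq_len(config$nGenes)) {
        L <- lens[g]
        budget <- round(targets[g] * 2L * L)
        # the ATG initiator contributes no G/C at codon positions 1-2
        free <- 2L * (L - 1L)
        needGC <- budget
        if (needGC < 0L || needGC > free) {
            stop("gene ", genes[g], ": GC12 target ", signif(targets[g], 3),
                 " unsatisfiable at length ", L, " codons")
        }
        gcSlot <- logical(free)
        gcSlot[sample.int(free, needGC)] <- TRUE
        p1 <- ifelse(gcSlot[c(TRUE, FALSE)],
                     sample(c("G", "C"), L - 1L, replace = TRUE),
                     sample(c("A", "T"), L - 1L, replace = TRUE))
        p2 <- ifelse(gcSlot[c(FALSE, TRUE)],
                     sample(c("G", "C"), L - 1L, replace = TRUE),
                     sample(c("A", "T"), L - 1L, replace = TRUE))
        # third base: uniform over choices that avoid stop codons
        p3 <- vapply(seq_len(L - 1L), function(i) {
            pre <- paste0(p1[i], p2[i])
            allowed <- switch(pre,
                TA = c("C", "T"), TG = c("A", "C", "G", "T")[-1L],
                .BASES)
            .sampleFrom(allowed, 1L)
        }, character(1))
        seqs[g] <- paste0("ATG", paste0(p1, p2, p3, collapse = ""))
    }
    out <- DNAStringSet(setNames(seqs, genes))
    attr(out, "targetGC12") <- setNames(targets, genes)
    out
}

#' Evolve one descendant sequence under a target omega
#'
#' Proposal-acceptance substitution process along one branch.  The number of
#' proposals is Poisson(\code{branchSubsPerCodon} x codons x max(1,
#' omegaEff)); each proposal picks a random site and draws the alternative
#' base with transitions weighted \code{kappa}-fold among the alternatives
#' that do not create a stop codon (stop-creating changes are rejected and
#' the proposal redrawn at the same site, mirroring the stop-rescaled site
#' counting of the estimator).  A synonymous change is accepted with
#' probability \code{min(1, 1/omegaEff)}, a nonsynonymous change with
#' probability \code{min(1, omegaEff)}; together with the rate scaling this
#' keeps the synonymous rate constant across genes and makes the realized
#' nonsynonymous/synonymous rate ratio equal \code{omegaEff} for any
#' \code{omegaEff >= 0}.  \code{omegaEff} is \code{omega} distorted by the
#' GC12-linked bias (\code{gcBiasSlope}).
#'
#' @param ancestor A single CDS (character or \code{DNAString}-like).
#' @param omega True dN/dS target (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param branchSubsPerCodon Expected proposals per codon.
#' @param gcBiasSlope GC12-linked omega distortion (default 0: none).
#' @param seed Optional integer seed.
#' @return List: \code{cds} (descendant sequence), \code{log} (data.frame of
#'   accepted substitutions: \code{codon}, \code{pos}, \code{from}, \code{to},
#'   \code{class}), \code{omegaEff}, \code{nProposed}, \code{nStopRejected}.
#' @export
evolveTaxon <- function(ancestor, omega, kappa = 1, branchSubsPerCodon = 0.35,
                        gcBiasSlope = 0, seed = NULL) {
    stopifnot(omega >= 0, kappa > 0, branchSubsPerCodon >= 0)
    if (!is.null(seed)) set.seed(seed)
    seq <- toupper(as.character(ancestor))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(chars) %/% 3L
    stopifnot(length(chars) == 3L * L)
    gc <- gc12Content(seq)
    omegaEff <- max(0, omega * (1 + gcBiasSlope * (gc - 0.5)))
    pSyn <- if (omegaEff > 1) 1 / omegaEff else 1
    pNon <- min(1, omegaEff)
    aa <- .codonAA()
    nProp <- rpois(1L, branchSubsPerCodon * L * max(1, omegaEff))
    logRows <- vector("list", nProp)
    nStop <- 0L
    nAcc <- 0L
    for (i in seq_len(nProp)) {
        site <- sample.int(3L * L, 1L)
        cdn <- (site - 1L) %/% 3L + 1L
        idx <- (cdn - 1L) * 3L
        cur <- chars[site]
        oldCodon <- paste0(chars[idx + 1L], chars[idx + 2L], chars[idx + 3L])
        alts <- setdiff(.BASES, cur)
        # exclude stop-creating alternatives from the proposal distribution
        # (rejection with redraw at the same site); every position of a
        # sense codon keeps at least one sense alternative
        newAA <- vapply(alts, function(b) {
            newChars <- chars[idx + 1:3]
            newChars[site - idx] <- b
            aa[.codonIndex(paste(newChars, collapse = ""))]
        }, character(1))
        valid <- newAA != "*"
        nStop <- nStop + sum(!valid)
        alts <- alts[valid]
        newAA <- newAA[valid]
        w <- ifelse(alts == .TRANSITION[[cur]], kappa, 1)
        pick <- .sampleFrom(seq_along(alts), 1L, prob = w)
        alt <- alts[pick]
        syn <- identical(aa[.codonIndex(oldCodon)], newAA[[pick]])
        pAcc <- if (syn) pSyn else pNon
        if (pAcc < 1 && runif(1L) > pAcc) next
        chars[site] <- alt
        nAcc <- nAcc + 1L
        logRows[[nAcc]] <- data.frame(
            codon = cdn, pos = site - idx, from = cur, to = alt,
            class = if (syn) "synonymous" else "nonsynonymous",
            stringsAsFactors = FALSE)
    }
    logDf <- if (nAcc) do.call(rbind, logRows[seq_len(nAcc)]) else
        data.frame(codon = integer(), pos = integer(), from = character(),
                   to = character(), class = character(),
                   stringsAsFactors = FALSE)
    list(cds = paste(chars, collapse = ""), log = logDf,
         omegaEff = omegaEff, nProposed = nProp, nStopRejected = nStop)
}

# folded site-frequency spectra over minor-allele counts 1..floor(n/2)
.mafSpectrum <- function(nChrom, shape = c("neutral", "rare"),
                         rareMafScale = 0.005) {
    shape <- match.arg(shape)
    j <- seq_len(nChrom %/% 2L)
    w <- 1 / j + ifelse(j < nChrom - j, 1 / (nChrom - j), 0)
    if (shape == "rare") {
        w <- w * exp(-(j / nChrom) / rareMafScale)
    }
    list(j = j, prob = w / sum(w))
}

#' Simulate a per-gene polymorphism table
#'
#' Draws synonymous and nonsynonymous segregating sites per gene as Poisson
#' counts and assigns each a minor allele frequency from a folded spectrum:
#' synonymous sites follow the standard neutral spectrum (density ~ 1/j,
#' folded), nonsynonymous sites follow either the neutral or a rare-shifted
#' spectrum (neutral density damped by \code{exp(-MAF/rareMafScale)}),
#' reflecting that segregating nonsynonymous variants are mostly deleterious
#' and held at low frequency.
#'
#' @param genes \code{data.frame} with columns \code{gene}, \code{lambdaS}
#'   (expected synonymous segregating sites) and \code{pnPs} (expected
#'   nonsynonymous/synonymous count ratio), plus optionally
#'   \code{nonsynSpectrum} ("rare"/"neutral", default "rare").
#' @param nChromosomes Chromosomes sampled (MAF resolution 1/n).
#' @param rareMafScale MAF e-folding scale of the rare-shifted spectrum.
#' @param seed Optional seed.
#' @return \code{data.frame} with columns \code{gene}, \code{class},
#'   \code{maf} -- one row per segregating site.
#' @export
simulatePolymorphism <- function(genes, nChromosomes = 5000,
                                 rareMafScale = 0.005, seed = NULL) {
    stopifnot(is.data.frame(genes),
              all(c("gene", "lambdaS", "pnPs") %in% colnames(genes)))
    if (nChromosomes < 2) {
        stop("need at least 2 chromosomes")
    }
    if (!is.null(seed)) set.seed(seed)
    if (is.null(genes$nonsynSpectrum)) genes$nonsynSpectrum <- "rare"
    specNeutral <- .mafSpectrum(nChromosomes, "neutral")
    specRare <- .mafSpectrum(nChromosomes, "rare", rareMafScale)
    rows <- lapply(seq_len(nrow(genes)), function(i) {
        nS <- rpois(1L, genes$lambdaS[i])
        nN <- rpois(1L, genes$lambdaS[i] * genes$pnPs[i])
        if (nS + nN == 0L) {
            return(NULL)
        }
        spN <- if (genes$nonsynSpectrum[i] == "rare") specRare else specNeutral
        mafS <- .sampleFrom(specNeutral$j, nS, replace = TRUE,
                            prob = specNeutral$prob) / nChromosomes
        mafN <- .sampleFrom(spN$j, nN, replace = TRUE, prob = spN$prob) /
            nChromosomes
        data.frame(gene = genes$gene[i],
                   class = rep(c("synonymous", "nonsynonymous"), c(nS, nN)),
                   maf = c(mafS, mafN), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) {
        out <- data.frame(gene = character(), class = character(),
                          maf = numeric(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
}

#' Simulate a gene x tissue expression matrix with spiked specific genes
#'
#' Baseline expression is log-normal (per-gene level, per-tissue noise); a
#' \code{spikeFraction} of genes is multiplied by \code{spikeFold} in exactly
#' one randomly chosen tissue each.  The spiked assignments are the ground
#' truth for specificity-recovery tests.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param genes Character vector of gene ids.
#' @param seed Optional seed.
#' @return List: \code{matrix} (genes x tissues, nonnegative),
#'   \code{truth} (data.frame \code{gene}, \code{specificTissue}, NA when not
#'   spiked).
#' @export
simulateExpression <- function(config, genes, seed = NULL) {
    stopifnot(inherits(config, "SimulationConfig"), length(genes) > 0)
    if (!is.null(seed)) set.seed(seed)
    nT <- config$nTissues
    tissues <- sprintf("tissue%02d", seq_len(nT))
    nG <- length(genes)
    level <- rnorm(nG, mean = 3, sd = 1)
    mat <- exp(outer(level, rep(0, nT), "+") +
               matrix(rnorm(nG * nT, 0, 0.5), nG, nT))
    dimnames(mat) <- list(genes, tissues)
    nSpike <- round(config$spikeFraction * nG)
    spiked <- if (nSpike > 0) sample.int(nG, nSpike) else integer()
    spikeTissue <- rep(NA_character_, nG)
    if (nSpike > 0) {
        tIdx <- sample.int(nT, nSpike, replace = TRUE)
        mat[cbind(spiked, tIdx)] <- mat[cbind(spiked, tIdx)] * config$spikeFold
        spikeTissue[spiked] <- tissues[tIdx]
    }
    list(matrix = mat,
         truth = data.frame(gene = genes, specificTissue = spikeTissue,
                            stringsAsFactors = FALSE))
}

# map a true omega to a polymorphism regime: purifying genes carry reduced,
# rare-shifted nonsynonymous polymorphism; positively selected genes keep
# constrained polymorphism (the divergence, not the standing variation, is
# elevated), which is what drives their neutrality index below 1
.polyRegime <- function(trueOmega, sSites, rate) {
    pnPs <- ifelse(trueOmega >= 2, 1.0,
            ifelse(trueOmega >= 1, 1.5, 3 * pmin(trueOmega, 0.4)))
    data.frame(lambdaS = sSites * rate, pnPs = pnPs,
               nonsynSpectrum = ifelse(trueOmega < 1, "rare", "neutral"),
               regime = ifelse(trueOmega >= 2, "adaptive-fixation",
                        ifelse(trueOmega >= 1, "neutral", "purifying")),
               stringsAsFactors = FALSE)
}

#' Simulate a complete ground-truth dataset
#'
#' Runs all four generators under one seed: ancestral CDS, per-taxon
#' descendant sequences evolved under per-gene true omega (star phylogeny,
#' independent branches), a polymorphism table whose per-gene pN/pS reflects
#' the gene's selection regime, and an expression matrix with spiked
#' tissue-specific genes.  Deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return List: \code{alignments} (\code{\linkS4class{CodonAlignmentSet}}),
#'   \code{polymorphism} (data.frame gene/class/maf), \code{expression}
#'   (genes x tissues matrix), \code{truth} (data.frame with per-gene true
#'   omega, per-taxon effective omega, polymorphism regime, specific tissue),
#'   \code{logs} (per gene x taxon substitution logs), \code{config}.
#' @export
simulateDataset <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    anc <- simulateAncestors(config)
    genes <- names(anc)
    trueOmega <- .drawOmega(config)
    ancChar <- as.character(anc)
    gc <- gc12Content(ancChar)
    descendants <- list()
    logs <- list()
    omegaEff <- matrix(NA_real_, length(genes), length(config$taxa),
                       dimnames = list(genes, config$taxa))
    for (tx in config$taxa) {
        out <- vector("character", length(genes))
        for (g in seq_along(genes)) {
            ev <- evolveTaxon(ancChar[[g]], omega = trueOmega[g],
                              kappa = config$kappa,
                              branchSubsPerCodon = config$branchSubsPerCodon,
                              gcBiasSlope = config$gcBiasSlope)
            out[g] <- ev$cds
            omegaEff[g, tx] <- ev$omegaEff
            logs[[paste0(genes[g], "|", tx)]] <- ev$log
        }
        descendants[[tx]] <- setNames(out, genes)
    }
    aln <- CodonAlignmentSet(anc, descendants)
    sSites <- vapply(ancChar, function(s) {
        idx <- .codonIndices(s)
        sum(.siteTable(1)[idx[!is.na(idx)], "s"])
    }, numeric(1))
    regime <- .polyRegime(trueOmega, unname(sSites), config$polymorphismRate)
    poly <- simulatePolymorphism(
        cbind(data.frame(gene = genes, stringsAsFactors = FALSE), regime),
        nChromosomes = config$nChromosomes)
    expr <- simulateExpression(config, genes)
    truth <- data.frame(gene = genes, trueOmega = trueOmega,
                        gc12 = unname(gc), regime = regime$regime,
                        pnPs = regime$pnPs,
                        specificTissue = expr$truth$specificTissue,
                        stringsAsFactors = FALSE)
    list(alignments = aln, polymorphism = poly, expression = expr$matrix,
         truth = truth, omegaEff = omegaEff, logs = logs, config = config)
}
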