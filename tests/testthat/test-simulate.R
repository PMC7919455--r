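# Synthetic-data generators: determinism, constrained construction, the
# acceptance-rejection substitution process and the polymorphism/expression
# regimes.

test_that("ancestor construction hits the GC12 target and is deterministic", {
    cfg <- simulationConfig(nGenes = 1, geneLengthRange = c(30, 30),
                            gc12Range = c(0.5, 0.5), taxa = "hs", seed = 5)
    set.seed(cfg$seed)
    anc <- simulateAncestors(cfg)
    expect_equal(Biostrings::width(anc), 90)
    expect_equal(unname(gc12Content(anc)), 0.5, tolerance = 1 / 60)
    expect_match(as.character(anc[[1]]), "^ATG")
    # no internal or terminal stop codon
    idx <- substring(as.character(anc[[1]]), seq(1, 88, 3), seq(3, 90, 3))
    expect_false(any(idx %in% c("TAA", "TAG", "TGA")))

    set.seed(cfg$seed)
    anc2 <- simulateAncestors(cfg)
    expect_identical(as.character(anc), as.character(anc2))
})

test_that("ancestor ids are unique and realized GC12 spans the range", {
    cfg <- simulationConfig(nGenes = 500, geneLengthRange = c(30, 40),
                            taxa = "hs", seed = 2)
    set.seed(cfg$seed)
    anc <- simulateAncestors(cfg)
    expect_length(anc, 500)
    expect_false(anyDuplicated(names(anc)) > 0)
    gc <- gc12Content(anc)
    expect_lt(min(gc), 0.35)
    expect_gt(max(gc), 0.65)
})

test_that("unsatisfiable GC12 targets fail naming the gene", {
    cfg <- simulationConfig(nGenes = 1, geneLengthRange = c(30, 30),
                            gc12Range = c(1, 1), taxa = "hs")
    set.seed(1)
    expect_error(simulateAncestors(cfg), "g0001.*unsatisfiable|unsatisfiable")
})

test_that("evolveTaxon honours omega = 0 and zero substitution rate", {
    set.seed(9)
    cfg <- simulationConfig(nGenes = 1, geneLengthRange = c(300, 300),
                            taxa = "hs")
    anc <- as.character(simulateAncestors(cfg)[[1]])
    ev0 <- evolveTaxon(anc, omega = 0, branchSubsPerCodon = 1, seed = 10)
    expect_gt(nrow(ev0$log), 0)
    expect_true(all(ev0$log$class == "synonymous"))
    evNone <- evolveTaxon(anc, omega = 1, branchSubsPerCodon = 0, seed = 11)
    expect_identical(evNone$cds, anc)
    expect_equal(nrow(evNone$log), 0)
})

test_that("pooled accepted substitution ratio tracks the target omega", {
    set.seed(21)
    cfg <- simulationConfig(nGenes = 250, geneLengthRange = c(300, 300),
                            taxa = "hs", gcBiasSlope = 0,
                            omegaAssignment = rep(2, 250))
    sim <- simulateDataset(cfg)
    logs <- do.call(rbind, sim$logs)
    anc <- as.character(ancestorSeqs(sim$alignments))
    sites <- vapply(anc, function(s) {
        cdn <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
        rowSums(vapply(cdn, countSites, numeric(2)))
    }, numeric(2))
    ratio <- (sum(logs$class == "nonsynonymous") / sum(sites["n", ])) /
        (sum(logs$class == "synonymous") / sum(sites["s", ]))
    expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("substitution log recounted by the divergence module agrees on single-hit codons", {
    set.seed(13)
    cfg <- simulationConfig(nGenes = 5, geneLengthRange = c(200, 200),
                            taxa = "hs")
    sim <- simulateDataset(cfg)
    anc <- as.character(ancestorSeqs(sim$alignments))
    des <- as.character(taxonSeqs(sim$alignments, "hs"))
    for (g in seq_along(anc)) {
        log <- sim$logs[[paste0(names(anc)[g], "|hs")]]
        hits <- table(log$codon)
        single <- as.integer(names(hits)[hits == 1])
        for (cdn in single) {
            a <- substring(anc[[g]], 3 * cdn - 2, 3 * cdn)
            b <- substring(des[[g]], 3 * cdn - 2, 3 * cdn)
            cls <- log$class[log$codon == cdn]
            d <- countDifferences(a, b)
            expect_equal(unname(d["Nd"]), as.numeric(cls == "nonsynonymous"))
            expect_equal(unname(d["Sd"]), as.numeric(cls == "synonymous"))
        }
    }
})

test_that("polymorphism tables respect regimes, MAF bounds and spectra", {
    genes <- data.frame(gene = c("a", "b"), lambdaS = c(20, 15),
                        pnPs = c(0, 1))
    tab <- simulatePolymorphism(genes, nChromosomes = 5000, seed = 4)
    expect_true(all(tab$maf > 0 & tab$maf <= 0.5))
    expect_true(all(tab$class[tab$gene == "a"] == "synonymous"))
    expect_error(simulatePolymorphism(genes, nChromosomes = 1), "2 chromosomes")

    big <- data.frame(gene = "g", lambdaS = 5000, pnPs = 1,
                      nonsynSpectrum = "rare")
    tabBig <- simulatePolymorphism(big, nChromosomes = 5000, seed = 6)
    rareN <- mean(tabBig$maf[tabBig$class == "nonsynonymous"] < 0.01)
    rareS <- mean(tabBig$maf[tabBig$class == "synonymous"] < 0.01)
    expect_gt(rareN, rareS)
})

test_that("expression spikes are recoverable and the null is calibrated", {
    cfgNull <- simulationConfig(nGenes = 400, taxa = "hs", spikeFraction = 0,
                                nTissues = 8)
    exprNull <- simulateExpression(cfgNull, sprintf("g%03d", 1:400), seed = 8)
    expect_equal(dim(exprNull$matrix), c(400, 8))
    expect_true(all(exprNull$matrix >= 0))
    zNull <- specificityZ(exprNull$matrix)$z
    expect_lte(mean(zNull > 2), 0.05)

    cfg <- simulationConfig(nGenes = 500, taxa = "hs", spikeFraction = 0.1,
                            spikeFold = 32)
    expr <- simulateExpression(cfg, sprintf("g%03d", 1:500), seed = 12)
    sz <- specificityZ(expr$matrix)
    spiked <- !is.na(expr$truth$specificTissue)
    hit <- vapply(which(spiked), function(i)
        sz$z[i, expr$truth$specificTissue[i]] > 2, logical(1))
    expect_gte(mean(hit), 0.95)
    # false positives among unspiked genes, per tissue
    fp <- mean(sz$z[!spiked, ] > 2)
    expect_lte(fp, 0.05)
})

test_that("simulateDataset is deterministic and FASTA round-trips", {
    cfg <- simulationConfig(nGenes = 10, geneLengthRange = c(60, 90),
                            taxa = c("hs", "chimp"), seed = 99)
    sim1 <- simulateDataset(cfg)
    sim2 <- simulateDataset(cfg)
    expect_identical(as.character(ancestorSeqs(sim1$alignments)),
                     as.character(ancestorSeqs(sim2$alignments)))
    expect_identical(sim1$polymorphism, sim2$polymorphism)
    expect_identical(sim1$expression, sim2$expression)

    fa <- tempfile(fileext = ".fa")
    writeCodonAlignments(sim1$alignments, fa)
    back <- readCodonAlignments(fa)
    expect_identical(as.character(ancestorSeqs(back)),
                     as.character(ancestorSeqs(sim1$alignments)))
    expect_identical(as.character(taxonSeqs(back, "chimp")),
                     as.character(taxonSeqs(sim1$alignments, "chimp")))
})
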