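# Codon-level counting and per-gene dN/dS estimation.

test_that("countSites matches direct neighbour enumeration", {
    expect_equal(countSites("TTT"), c(n = 8 / 3, s = 1 / 3))
    # Trp: both stop neighbours excluded, every remaining neighbour changes
    # the amino acid
    expect_equal(countSites("TGG"), c(n = 3, s = 0))
    for (cdn in c("ATG", "AAA", "CTG", "CGA", "TAT", "TCA")) {
        expect_equal(countSites(cdn), oracleCountSites(cdn), tolerance = 1e-12)
    }
    sums <- vapply(senseCodons(), function(cdn) sum(countSites(cdn)),
                   numeric(1))
    expect_equal(unname(sums), rep(3, 61))
})

test_that("countSites rejects stops and ambiguity, supports kappa weighting", {
    expect_error(countSites("TAA"), "stop")
    expect_error(countSites("TTN"), "outside")
    expect_error(countSites("TT"), "3-letter")
    # kappa = 1 reduces to equal weighting; kappa > 1 upweights transitions,
    # which are enriched for synonymous third-position changes
    expect_equal(countSites("TTT", kappa = 1), countSites("TTT"))
    # TTT third position: the transition (TTC) is synonymous, the two
    # transversions are not, so kappa = 4 raises the synonymous fraction
    # from 1/3 to 4/6
    expect_equal(unname(countSites("TTT", kappa = 4)["s"]), 4 / 6)
    expect_equal(sum(countSites("TTT", kappa = 4)), 3)
})

test_that("countDifferences matches worked examples and is symmetric", {
    expect_equal(unname(countDifferences("TTT", "TTC")), c(0, 1),
                 ignore_attr = TRUE)
    expect_equal(unname(countDifferences("AAA", "AAA")), c(0, 0),
                 ignore_attr = TRUE)
    # two pathways TTT->GTT->GTA (nonsyn, syn) and TTT->TTA->GTA
    # (nonsyn, nonsyn)
    d <- countDifferences("TTT", "GTA")
    expect_equal(unname(d), c(1.5, 0.5), ignore_attr = TRUE)
    set.seed(42)
    sense <- senseCodons()
    for (i in 1:50) {
        a <- sample(sense, 1)
        b <- sample(sense, 1)
        ab <- countDifferences(a, b)
        ba <- countDifferences(b, a)
        expect_equal(unname(ab), unname(ba), ignore_attr = TRUE)
        expect_equal(sum(ab), sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
    }
})

test_that("estimatePair handles identity, the zero rule and skipping", {
    anc <- paste(rep(c("ATG", "AAA", "GGC", "CTT", "TCA"), 30), collapse = "")
    est <- estimatePair(anc, anc)
    expect_equal(est$Nd, 0)
    expect_equal(est$Sd, 0)
    expect_equal(est$SdCorrected, 1)
    expect_equal(est$dN, 0)
    expect_equal(est$omegaRaw, 0)
    expect_equal(est$nSites + est$sSites, 3 * est$codonsUsed)

    # gap/N codons excluded whole
    des <- sub("GGC", "G-C", sub("AAA", "ANA", anc))
    est2 <- estimatePair(anc, des)
    expect_equal(est2$codonsSkipped, 2)
    expect_equal(est2$codonsUsed, 148)

    expect_error(estimatePair("---", "AAA"), "no usable codons")
})

test_that("Jukes-Cantor correction matches the closed form at pN = 0.03", {
    # AAA and GAA have identical site structure (8/3 nonsyn, 1/3 syn), so 8
    # nonsynonymous single changes among 100 codons give pN = 8/266.67 = 0.03
    ancC <- rep("AAA", 100)
    desC <- ancC
    desC[1:8] <- "GAA"
    aln <- makeAlignment(ancC, desC)
    est <- estimatePair(as.character(ancestorSeqs(aln)[[1]]),
                        as.character(taxonSeqs(aln, "hs")[[1]]))
    expect_equal(est$Nd / est$nSites, 0.03, tolerance = 1e-12)
    expect_equal(est$dN, -0.75 * log(1 - 4 * 0.03 / 3), tolerance = 1e-12)
    expect_equal(est$dN, 0.030616, tolerance = 1e-4)
})

test_that("omega_raw is invariant to codon order permutation", {
    set.seed(7)
    cfg <- simulationConfig(nGenes = 1, geneLengthRange = c(200, 200),
                            taxa = "hs", gcBiasSlope = 0)
    sim <- simulateDataset(cfg)
    anc <- as.character(ancestorSeqs(sim$alignments)[[1]])
    des <- as.character(taxonSeqs(sim$alignments, "hs")[[1]])
    est <- estimatePair(anc, des)
    splitCodons <- function(s) substring(s, seq(1, nchar(s), 3),
                                         seq(3, nchar(s), 3))
    perm <- sample(200)
    estP <- estimatePair(paste(splitCodons(anc)[perm], collapse = ""),
                         paste(splitCodons(des)[perm], collapse = ""))
    expect_equal(estP$omegaRaw, est$omegaRaw, tolerance = 1e-12)
    expect_equal(estP$Nd, est$Nd, tolerance = 1e-12)
})

test_that("mean estimated omega increases across a true-omega grid", {
    set.seed(11)
    grid <- c(0.2, 0.5, 1, 2)
    means <- vapply(grid, function(w) {
        cfg <- simulationConfig(nGenes = 120, geneLengthRange = c(200, 200),
                                taxa = "hs", gcBiasSlope = 0,
                                omegaAssignment = rep(w, 120))
        sim <- simulateDataset(cfg)
        div <- estimateDivergence(sim$alignments)
        mean(div$omegaRaw)
    }, numeric(1))
    expect_true(all(diff(means) > 0))
    expect_equal(means, grid, tolerance = 0.2)
})

test_that("estimateDivergence covers every gene x taxon pair", {
    set.seed(3)
    cfg <- simulationConfig(nGenes = 12, geneLengthRange = c(60, 90),
                            taxa = c("hs", "chimp"))
    sim <- simulateDataset(cfg)
    div <- estimateDivergence(sim$alignments)
    expect_equal(nrow(div), 24)
    expect_setequal(unique(div$taxon), c("hs", "chimp"))
    # one gc12 value per gene, shared across taxa, computed on the ancestor
    gcHs <- div$gc12[div$taxon == "hs"]
    gcCh <- div$gc12[div$taxon == "chimp"]
    expect_equal(gcHs, gcCh)
    expect_equal(gcHs,
                 unname(gc12Content(ancestorSeqs(sim$alignments))),
                 tolerance = 1e-12)
})
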