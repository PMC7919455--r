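# Clustering of the omega_GC12 matrix and extraction of the PSG/SCG extremes.

.mixtureTable <- function(n = 400, sep = 1, sd = 0.6, corr = 0.4,
                          nTaxa = 4, seed = 71) {
    set.seed(seed)
    labels <- rep(c(-1, 1), each = n / 2)
    shared <- rnorm(n, 0, sqrt(corr) * sd)
    z <- vapply(seq_len(nTaxa), function(t)
        labels * sep + shared + rnorm(n, 0, sqrt(1 - corr) * sd),
        numeric(n))
    list(ot = makeOmegaTable(z), labels = labels)
}

test_that("a two-component world is recovered with k = 2", {
    mix <- .mixtureTable()
    ca <- clusterGenes(mix$ot)
    expect_equal(ca$k, 2)
    expect_setequal(unique(ca$labels), c("SCG-like", "PSG-like"))
    expect_gt(adjustedRandIndex(ca$labels, mix$labels), 0.9)
    # SCG-like cluster sits below PSG-like on the human axis
    m <- ca$summary
    expect_lt(m$mean[m$cluster == "SCG-like" & m$taxon == "hs"],
              m$mean[m$cluster == "PSG-like" & m$taxon == "hs"])
})

test_that("a single Gaussian blob triggers the low-separation warning", {
    set.seed(72)
    ot <- makeOmegaTable(matrix(rnorm(1200), 300, 4))
    expect_warning(ca <- clusterGenes(ot), "separation")
    expect_true(ca$lowSeparation)
})

test_that("clustering is invariant to duplicating every gene", {
    mix <- .mixtureTable(n = 150)
    z <- omegaGC12(mix$ot)
    z2 <- rbind(z, z)
    rownames(z2) <- sprintf("g%04d", seq_len(nrow(z2)))
    ca1 <- clusterGenes(mix$ot)
    ca2 <- clusterGenes(makeOmegaTable(z2))
    # the duplicated copy of each gene lands in the same cluster
    expect_identical(unname(ca2$labels[1:150]), unname(ca2$labels[151:300]))
    expect_equal(ca2$k, ca1$k)
})

test_that("extremeGenes applies the 2SD tail and the NI < 1 filter", {
    set.seed(73)
    n <- 10000
    z <- cbind(hs = rnorm(n))
    ot <- makeOmegaTable(z)
    sel <- data.frame(gene = rownames(ot), ni = 0.5)
    ex <- extremeGenes(ot, sel)
    # upper and lower normal tail mass beyond 2 is ~2.3% each
    expect_gt(length(ex$psg) / n, 0.016)
    expect_lt(length(ex$psg) / n, 0.030)
    expect_gt(length(ex$scg) / n, 0.016)
    expect_lt(length(ex$scg) / n, 0.030)
    expect_length(intersect(ex$psg, ex$scg), 0)

    # fixation filter: NI >= 1 empties the PSG list regardless of omega
    selHigh <- data.frame(gene = rownames(ot), ni = 1.3)
    exHigh <- extremeGenes(ot, selHigh)
    expect_length(exHigh$psg, 0)
    expect_equal(exHigh$scg, ex$scg)

    expect_length(extremeGenes(ot, sel, sdThreshold = Inf)$psg, 0)
    expect_length(extremeGenes(ot, sel, sdThreshold = Inf)$scg, 0)

    # raising the threshold never grows either list
    ex3 <- extremeGenes(ot, sel, sdThreshold = 3)
    expect_true(all(ex3$psg %in% ex$psg))
    expect_true(all(ex3$scg %in% ex$scg))

    # missing fixation data: empty PSG list with an explicit warning
    expect_warning(exNo <- extremeGenes(ot, NULL), "no fixation data")
    expect_length(exNo$psg, 0)
})

test_that("PSG membership depends on NI only through the NI < 1 side", {
    set.seed(74)
    ot <- makeOmegaTable(cbind(hs = rnorm(500)))
    sel1 <- data.frame(gene = rownames(ot), ni = runif(500, 0, 0.99))
    sel2 <- data.frame(gene = rownames(ot), ni = sel1$ni / 2)
    expect_identical(extremeGenes(ot, sel1)$psg, extremeGenes(ot, sel2)$psg)
})

test_that("partitionBrainRelated counts categories over the union", {
    set.seed(75)
    ot <- makeOmegaTable(cbind(hs = rnorm(400)))
    sel <- data.frame(gene = rownames(ot), ni = 0.5)
    ex <- extremeGenes(ot, sel)
    universe <- rownames(ot)
    # annotations covering every gene: brain-related count = list size
    all <- list(everything = universe)
    pAll <- partitionBrainRelated(ex, all, universe)
    expect_equal(pAll$psg$inUnion, length(ex$psg))
    expect_equal(pAll$scg$inUnion, length(ex$scg))

    ann <- list(synaptic = sample(universe, 120),
                disease = sample(universe, 90))
    p <- partitionBrainRelated(ex, ann, universe)
    expect_gte(sum(p$psg$categoryCounts), p$psg$inUnion)
    expect_true(p$scg$fisher$p > 0 && p$scg$fisher$p <= 1)
    expect_error(partitionBrainRelated(ex, list(), universe), "empty")
})
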