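# Signed-rank statistics, rank-biserial effect size, matched bootstrap and
# Fisher overlap.

test_that("signedRankTest matches worked examples and wilcox.test", {
    t1 <- signedRankTest(c(1, 2, 3, 4, 5))
    expect_equal(t1$wPlus, 15)
    expect_equal(t1$wMinus, 0)
    t2 <- signedRankTest(c(-1, 1, -2, 2, 3))
    expect_equal(t2$wPlus + t2$wMinus, 15)

    set.seed(61)
    for (n in c(10, 40)) {
        v <- rnorm(n) + 0.3
        mine <- signedRankTest(v)
        ref <- suppressWarnings(wilcox.test(v, mu = 0, correct = TRUE))
        expect_equal(mine$wPlus, unname(ref$statistic))
        expect_equal(mine$p, ref$p.value, tolerance = 0.02)
    }
    expect_error(signedRankTest(c(0, 0, 0)), "zero")
    expect_error(signedRankTest(c(1, 2)), ">= 5")
})

test_that("rankBiserial equals the signed-rank mass difference", {
    expect_equal(rankBiserial(c(1, 2, 3)), 1)
    expect_equal(rankBiserial(c(-1, 1, -2, 2)), 0)
    expect_equal(rankBiserial(c(5, -1, 4, -2, 3)), 0.6)
    # independent route via the wilcox.test statistic (no ties, no zeros)
    set.seed(62)
    for (i in 1:25) {
        v <- rnorm(30, sd = 2) + runif(1, -1, 1)
        V <- unname(suppressWarnings(wilcox.test(v)$statistic))
        S <- 30 * 31 / 2
        expect_equal(rankBiserial(v), (2 * V - S) / S, tolerance = 1e-12)
        expect_lte(abs(rankBiserial(v)), 1)
    }
})

test_that("matchedBootstrap empirical p edge cases follow the formula", {
    set.seed(63)
    n <- 600
    values <- setNames(rnorm(n), sprintf("g%04d", 1:n))
    cov <- data.frame(gene = names(values), gc12 = runif(n, 0.3, 0.7),
                      cdsLength = 3 * round(exp(rnorm(n, 5.5, 0.4))))
    # the 40 most positive genes: observed rc = 1 exceeds every null draw
    top <- names(sort(values, decreasing = TRUE))[1:40]
    bs <- matchedBootstrap(values, top, cov, nDraws = 400, seed = 64)
    expect_equal(bs$statistic, 1)
    expect_equal(bs$p, 2 / 401)

    # degenerate universe: every draw equals the observed statistic -> cap 1
    constant <- setNames(rep(4, n), names(values))
    bs2 <- matchedBootstrap(constant, sample(names(values), 30), cov,
                            nDraws = 200, seed = 65)
    expect_equal(bs2$p, 1)

    expect_error(matchedBootstrap(values, names(values)[1:100], cov,
                                  nDraws = 10), "10x")
    expect_error(matchedBootstrap(values, "absent", cov), "outside")
})

test_that("matchedBootstrap is deterministic given a seed", {
    set.seed(66)
    n <- 400
    values <- setNames(rnorm(n), sprintf("g%04d", 1:n))
    cov <- data.frame(gene = names(values), gc12 = runif(n, 0.3, 0.7),
                      cdsLength = 3 * round(exp(rnorm(n, 5.5, 0.4))))
    s <- sample(names(values), 25)
    b1 <- matchedBootstrap(values, s, cov, nDraws = 300, seed = 7)
    b2 <- matchedBootstrap(values, s, cov, nDraws = 300, seed = 7)
    expect_identical(b1, b2)
})

test_that("bonferroniAdjust multiplies and caps", {
    expect_equal(bonferroniAdjust(0.01, 20), 0.2)
    expect_equal(bonferroniAdjust(0.2, 10), 1)
    expect_equal(bonferroniAdjust(c(0.3, 0.02), 1), c(0.3, 0.02))
    p <- runif(8)
    expect_true(all(bonferroniAdjust(p) >= p))
})

test_that("fisherOverlap reproduces the 2x2 arithmetic", {
    universe <- sprintf("u%03d", 1:100)
    setA <- universe[1:30]
    setB <- c(universe[1:10], universe[31:60])
    fo <- fisherOverlap(setA, setB, universe)
    expect_equal(unname(fo$table), matrix(c(10, 20, 30, 40), 2, byrow = TRUE))
    expect_equal(fo$oddsRatio, 10 * 40 / (20 * 30), tolerance = 1e-12)
    expect_equal(fo$p, fisher.test(matrix(c(10, 20, 30, 40), 2,
                                          byrow = TRUE))$p.value)

    # perfect association: infinite sample OR, overwhelming p
    half <- universe[1:50]
    fp <- fisherOverlap(half, half, universe)
    expect_true(is.infinite(fp$oddsRatio))
    expect_lt(fp$p, 1e-6)
    expect_error(fisherOverlap(c(setA, "zzz"), setB, universe), "universe")
})

test_that("enrichGeneSets assembles the full result table", {
    set.seed(67)
    z <- matrix(rnorm(1200), 600, 2)
    ot <- makeOmegaTable(z)
    shiftSet <- rownames(ot)[order(omegaGC12(ot)[, "hs"])][1:30]
    randomSet <- sample(rownames(ot), 30)
    res <- enrichGeneSets(ot, list(low = shiftSet, rand = randomSet),
                          nDraws = 500, seed = 68)
    expect_setequal(res$set, c("low", "rand"))
    expect_equal(res$direction[res$set == "low"], "conserved")
    expect_lt(res$rc[res$set == "low"], -0.9)
    expect_true(all(res$pBonferroni >= res$pWilcoxon))
    expect_true(all(res$pBootstrap >= 2 / 501 & res$pBootstrap <= 1))
})
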