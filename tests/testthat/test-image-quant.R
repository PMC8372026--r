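test_that("corrected MFI matches its closed form and preserves negatives", {
    expect_equal(as.numeric(correctedMFI(255, 0)), 100)
    expect_equal(as.numeric(correctedMFI(37, 37)), 0)
    expect_equal(as.numeric(correctedMFI(128, 1)), 127 / 254 * 100)
    expect_equal(as.numeric(correctedMFI(128, 1)), 50)
    # background = 0 reduces to raw/255 * 100
    raw <- c(0, 10, 100, 255)
    expect_equal(as.numeric(correctedMFI(raw, 0)), raw / 255 * 100)
    # strictly increasing in raw intensity
    vals <- as.numeric(correctedMFI(0:255, 40))
    expect_true(all(diff(vals) > 0))
    neg <- correctedMFI(10, 30)
    expect_lt(as.numeric(neg), 0)
    expect_true(attr(neg, "negative"))
    expect_error(correctedMFI(100, 255), "background")
})

test_that("group MFI summaries average per animal, then across animals", {
    rec <- data.frame(
        group = c(rep("g1", 3), rep("g2", 4)),
        animal_id = c("a", "a", "a", "b", "b", "c", "c"),
        raw_intensity = c(10, 20, 30, 10, 10, 30, 30),
        background = 0)
    out <- mfiGroupSummary(rec)
    gs <- out$group_summary
    m1 <- gs$mean[gs$group == "g1"]
    expect_equal(m1, mean(c(10, 20, 30)) / 255 * 100)
    expect_true(is.na(gs$sem[gs$group == "g1"]))   # single animal
    # two animals with means 10 and 30 (a.u.) -> mean 20, SEM 10 on the
    # corrected scale
    m2 <- gs$mean[gs$group == "g2"]
    expect_equal(m2, 20 / 255 * 100)
    expect_equal(gs$sem[gs$group == "g2"], 10 / 255 * 100)
    # per-cell distribution percentages sum to 100 per group
    sums <- tapply(out$cell_distribution$percent,
                   out$cell_distribution$group, sum)
    expect_equal(as.numeric(sums), c(100, 100))
})

test_that("bin histograms follow the basal-to-apical convention", {
    # all cells in the most apical tenth -> bin 10 holds 100%
    apical <- binDistribution(runif(50, 0, 0.09))
    expect_equal(binPercent(apical)[10], 100)
    expect_equal(sum(binCounts(apical)), 50)
    # interior boundary goes to the higher-index (more apical) bin
    edge <- binDistribution(c(0.1, 0.1000001), nBins = 10)
    expect_equal(binCounts(edge)[10], 1L)   # exactly 0.1 -> apical bin 10
    expect_equal(binCounts(edge)[9], 1L)
    # extremes
    ends <- binDistribution(c(0, 1), nBins = 10)
    expect_equal(binCounts(ends)[10], 1L)
    expect_equal(binCounts(ends)[1], 1L)
    # uniform depths spread ~10% per bin
    set.seed(4)
    h <- binDistribution(runif(5000))
    expect_true(all(abs(binPercent(h) - 10) < 2.5))
    expect_equal(sum(binPercent(h)), 100)
    expect_error(binDistribution(numeric(0)), "no depths")
    expect_error(binDistribution(c(0.2, 1.4)), "outside")
})

test_that("merging adjacent bins conserves counts", {
    set.seed(9)
    h <- binDistribution(runif(300), nBins = 10)
    halves <- mergeBins(h, rep(1:2, each = 5))
    expect_equal(sum(binCounts(halves)), sum(binCounts(h)))
    expect_equal(binCounts(halves)[1], sum(binCounts(h)[1:5]))
    expect_equal(sum(binPercent(halves)), 100)
})

test_that("zone fractions partition depths and support the VZ sub-split", {
    expect_equal(unname(zoneFractions(runif(40, 0, 0.3))["VZ"]), 100)
    set.seed(11)
    z <- zoneFractions(runif(4000), boundaries = c(VZ = 0.5, other = 1))
    expect_equal(unname(z["VZ"]), 50, tolerance = 0.1)
    expect_equal(sum(z), 100)
    # inner/outer split partitions the first zone exactly
    d <- runif(500, 0, 0.35)
    zs <- zoneFractions(d, splitFirst = TRUE)
    split <- attr(zs, "split")
    expect_equal(unname(sum(split)), unname(zs["VZ"]))
    expect_error(zoneFractions(c(0.5, 1.2)), "outside")
})

test_that("zone and bin quantification agree on shared boundaries", {
    set.seed(21)
    d <- runif(2000)
    h <- binDistribution(d, nBins = 10)
    z <- zoneFractions(d, boundaries = c(a = 0.2, b = 0.6, c = 1))
    # zones [0,0.2), [0.2,0.6), [0.6,1] vs apical bins 10-9, 8-5, 4-1
    expect_equal(unname(z["a"]), sum(binPercent(h)[9:10]), tolerance = 0.2)
    expect_equal(unname(z["b"]), sum(binPercent(h)[5:8]), tolerance = 0.2)
    expect_equal(unname(z["c"]), sum(binPercent(h)[1:4]), tolerance = 0.2)
})

test_that("colocalization percentage behaves as a conditional frequency", {
    a <- c(TRUE, TRUE, FALSE, TRUE)
    expect_equal(colocalizationFraction(a, a), 100)
    expect_equal(colocalizationFraction(a, !a), 0)
    set.seed(3)
    x <- runif(20000) < 0.5
    y <- runif(20000) < 0.5
    expect_equal(colocalizationFraction(x, y), 50, tolerance = 2)
    expect_error(colocalizationFraction(rep(FALSE, 3), rep(TRUE, 3)),
                 "no positive")
})
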