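test_that("mutual information has the basic information-theoretic properties", {
    set.seed(1)
    x <- rnorm(400)
    y <- rnorm(400)
    expect_equal(as.numeric(mutualInformation(x, y, bins = 5)),
                 as.numeric(mutualInformation(y, x, bins = 5)))   # symmetry
    expect_gte(as.numeric(mutualInformation(x, y)), 0)
    # identity map with b equal-frequency bins carries exactly log(b) nats
    expect_equal(as.numeric(mutualInformation(x, x, bins = 4)), log(4),
                 tolerance = 1e-12)
    expect_equal(as.numeric(mutualInformation(x, 2 * x + 7, bins = 4)),
                 log(4), tolerance = 1e-12)   # monotone-transform invariance
    cst <- mutualInformation(rep(1, 100), rnorm(100))
    expect_equal(as.numeric(cst), 0)
    expect_true(attr(cst, "constant"))
    # default bin rule
    expect_equal(attr(mutualInformation(rnorm(500), rnorm(500)), "bins"),
                 ceiling(sqrt(500 / 5)))
    expect_error(mutualInformation(rnorm(5), rnorm(5)), "8")
})

test_that("permutation p values are smoothed and respect their floor", {
    rn <- simulateRegnet(nTfs = 2, targetsPerTf = 3, nBackground = 5,
                         nCells = 200, dependenceStrength = 0.9, seed = 4)
    rs <- inferRegulons(rn$exprs, rn$tfs, nPerm = 200, seed = 11)
    edges <- miEdges(rs)
    expect_true(all(edges$perm_p >= 1 / 201))
    expect_true(all(edges$adj_perm_p >= edges$perm_p))
    # determinism
    rs2 <- inferRegulons(rn$exprs, rn$tfs, nPerm = 200, seed = 11)
    expect_equal(as.data.frame(miEdges(rs2)), as.data.frame(edges))
    expect_warning(inferRegulons(rn$exprs, rn$tfs, nPerm = 50, seed = 1),
                   "permutations")
})

test_that("independent genes are retained at roughly the nominal rate", {
    set.seed(71)
    nGenes <- 41
    exprs <- matrix(rnorm(nGenes * 300), nGenes, 300,
                    dimnames = list(c("TF", sprintf("g%02d", 1:40)), NULL))
    rs <- inferRegulons(exprs, "TF", nPerm = 500, alpha = 0.05, seed = 5)
    # BH at 0.05 over a global null keeps false edges near zero
    expect_lte(length(regulons(rs)$TF), 4)
})

test_that("bootstrap support filtering keeps strong edges and is recorded", {
    rn <- simulateRegnet(nTfs = 2, targetsPerTf = 4, nBackground = 10,
                         nCells = 400, dependenceStrength = 0.9, seed = 7)
    rs <- inferRegulons(rn$exprs, rn$tfs, nPerm = 300, nBoot = 50,
                        supportMin = 0.95, seed = 3)
    edges <- miEdges(rs)
    expect_true("support" %in% colnames(edges))
    expect_true(all(edges$support >= 0.95))
    # every planted edge survives the bootstrap at this strength
    for (tf in rn$tfs)
        expect_true(all(rn$regulons[[tf]] %in% regulons(rs)[[tf]]))
})

test_that("DPI pruning removes the weak edge of a triangle and only that", {
    edges <- S4Vectors::DataFrame(
        tf = c("A", "A", "B", "B"),
        target = c("B", "t", "t", "u"),
        mi = c(0.9, 0.1, 0.8, 0.5),
        perm_p = 0.001, adj_perm_p = 0.001)
    rs <- new("RegulonSet", edges = edges,
              regulons = list(A = c("B", "t"), B = c("t", "u")),
              params = list())
    pruned <- dpiFilter(rs, epsilon = 0)
    # A->t (0.1) is the weakest edge of triangle A-B-t: removed
    expect_false("t" %in% regulons(pruned)$A)
    expect_true("t" %in% regulons(pruned)$B)     # stronger edges survive
    expect_true("B" %in% regulons(pruned)$A)
    expect_true("u" %in% regulons(pruned)$B)     # non-triangle edge untouched
    # epsilon = 1 disables pruning entirely
    noop <- dpiFilter(rs, epsilon = 1)
    expect_equal(nrow(miEdges(noop)), nrow(edges))
})

test_that("Fisher enrichment matches a direct hypergeometric tail", {
    regs <- list(TFa = sprintf("g%03d", 1:30))
    universe <- sprintf("g%03d", 1:120)
    query <- sprintf("g%03d", c(1:12, 61:80))   # overlap 12, query 32
    mra <- masterRegulatorAnalysis(regs, query, universe)
    tb <- mraTable(mra)
    expect_equal(tb$overlap, 12)
    expect_equal(tb$fisher_p, hyperTail(12, 30, 32, 120), tolerance = 1e-12)
})

test_that("master-regulator calls separate a planted regulon from decoys", {
    universe <- sprintf("g%03d", 1:150)
    regs <- list(hit = universe[1:25],
                 decoy1 = universe[26:50], decoy2 = universe[51:75])
    query <- c(universe[1:20], universe[140:150])  # loads on "hit"
    mra <- masterRegulatorAnalysis(regs, query, universe, alpha = 0.01)
    tb <- mraTable(mra)
    expect_true(tb$is_master[tb$tf == "hit"])
    expect_false(any(tb$is_master[tb$tf != "hit"]))
    expect_equal(tb$tf[1], "hit")   # sorted by adjusted p
    # disjoint query and regulon: enrichment p near 1
    far <- masterRegulatorAnalysis(list(x = universe[1:25]),
                                   universe[100:120], universe)
    expect_gt(mraTable(far)$fisher_p, 0.9)
    expect_error(masterRegulatorAnalysis(regs, "not_in_universe", universe),
                 "subset")
})

test_that("end-to-end inference recovers the planted network accurately", {
    rn <- simulateRegnet(nTfs = 4, targetsPerTf = 6, nBackground = 15,
                         nCells = 400, dependenceStrength = 0.8, seed = 19)
    rs <- inferRegulons(rn$exprs, rn$tfs, nPerm = 500, seed = 2)
    got <- regulons(rs)
    truePairs <- unlist(lapply(rn$tfs, function(tf)
        paste(tf, rn$regulons[[tf]])))
    gotPairs <- unlist(lapply(rn$tfs, function(tf)
        paste(tf, setdiff(got[[tf]], rn$tfs))))
    recall <- mean(truePairs %in% gotPairs)
    precision <- if (length(gotPairs)) mean(gotPairs %in% truePairs) else 0
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.85)
})
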