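test_that("species tree simulation yields valid, reproducible Yule trees", {
    expect_error(simulateSpeciesTree(1, seed = 1), "at least 2")

    t2 <- simulateSpeciesTree(2, seed = 5)
    expect_equal(ape::Ntip(t2), 2L)
    expect_equal(t2$Nnode, 1L)

    t20 <- simulateSpeciesTree(20, seed = 42)
    expect_equal(ape::Ntip(t20), 20L)
    expect_equal(t20$Nnode, 19L)
    expect_true(all(t20$edge.length > 0))
    expect_true(ape::is.rooted(t20))
    expect_true(ape::is.binary(t20))
    expect_identical(sort(t20$tip.label), sprintf("G%04d", 1:20))

    expect_identical(ape::write.tree(simulateSpeciesTree(7, 1)),
                     ape::write.tree(simulateSpeciesTree(7, 1)))
    expect_false(identical(ape::write.tree(simulateSpeciesTree(7, 1)),
                           ape::write.tree(simulateSpeciesTree(7, 2))))
})

test_that("frozen gene content: no rates, full root presence", {
    tr <- simulateSpeciesTree(6, seed = 3)
    cfg <- simulationConfig(nGenomes = 6, nFamilies = 15, gainRate = 0,
                            lossRate = 0, dupRate = 0,
                            rootPresenceProb = 1, seed = 3)
    sim <- simulateGeneContent(tr, cfg)
    expect_true(all(sim$matrix == 1L))
    expect_equal(nrow(trueEvents(sim$truth)), 0L)
    expect_equal(sim$truth@nDropped, 0L)
})

test_that("leaf presence matches the closed-form two-state chain", {
    ## 2-leaf tree, both branches length t, pure loss from a present root
    l <- 1.2; t <- 0.6; nf <- 5000L
    tree <- structure(list(
        edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
        edge.length = c(t, t), Nnode = 1L,
        tip.label = c("G0001", "G0002")), class = "phylo",
        order = "cladewise")
    cfg <- simulationConfig(nGenomes = 2, nFamilies = nf, gainRate = 0,
                            lossRate = l, dupRate = 0,
                            rootPresenceProb = 1, seed = 9)
    sim <- simulateGeneContent(tree, cfg)
    ## observed fraction at one leaf among all families (incl. dropped)
    p <- exp(-l * t)
    sigma <- sqrt(p * (1 - p) / nf)
    frac <- (sum(sim$matrix[, "G0001"] >= 1)) / nf
    expect_lt(abs(frac - p), 3 * sigma)
})

test_that("duplication accounting identity and matrix/truth consistency", {
    tr <- simulateSpeciesTree(8, seed = 21)
    cfg <- simulationConfig(nGenomes = 8, nFamilies = 40, gainRate = 0.3,
                            lossRate = 0.4, dupRate = 0.8,
                            rootPresenceProb = 0.7, seed = 21)
    sim <- simulateGeneContent(tr, cfg)
    ev <- trueEvents(sim$truth)
    expect_gt(max(sim$matrix), 1L)
    expect_equal(sum(ev$type == "duplication"),
                 sum(sim$matrix - (sim$matrix >= 1L)))
    ## replaying the recorded events reproduces the leaf copy counts
    replayed <- replayEvents(sim$truth)
    expect_equal(replayed[rownames(sim$matrix), colnames(sim$matrix)],
                 sim$matrix)
    ## latent states agree with presence
    expect_identical(unname(sim$matrix >= 1L),
                     unname(nodeStates(sim$truth)[, colnames(sim$matrix)]
                            == 1L))
})

test_that("without gains, families absent at the root never appear", {
    tr <- simulateSpeciesTree(10, seed = 4)
    cfg <- simulationConfig(nGenomes = 10, nFamilies = 200, gainRate = 0,
                            lossRate = 0.5, dupRate = 0,
                            rootPresenceProb = 0.5, seed = 4)
    sim <- simulateGeneContent(tr, cfg)
    st <- nodeStates(sim$truth)
    root <- "N1"
    expect_true(all(st[, root] == 1L))   # absent-at-root families dropped
})

test_that("sequence simulation is deterministic and respects divergence", {
    cfg0 <- simulationConfig(nGenomes = 4, nFamilies = 6, gainRate = 0,
                             lossRate = 0, dupRate = 0.4,
                             rootPresenceProb = 1,
                             withinFamilyDivergence = 0, seed = 8)
    s1 <- simulateGenomeSet(cfg0)
    s2 <- simulateGenomeSet(cfg0)
    expect_identical(as.character(sequences(s1$genomes)),
                     as.character(sequences(s2$genomes)))
    ## zero divergence: every member of a family is identical
    fm <- familyMembership(s1$truth)
    for (f in unique(fm)) {
        seqs <- as.character(sequences(s1$genomes)[names(fm)[fm == f]])
        expect_length(unique(seqs), 1L)
    }
    ## FASTA bytes identical for identical seed
    d1 <- tempfile(); d2 <- tempfile()
    writeGenomeSet(s1$genomes, d1); writeGenomeSet(s2$genomes, d2)
    f1 <- list.files(d1, full.names = TRUE)
    f2 <- list.files(d2, full.names = TRUE)
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("between-family identity stays near the random background", {
    cfg <- simulationConfig(nGenomes = 2, nFamilies = 2, gainRate = 0,
                            lossRate = 0, dupRate = 0,
                            rootPresenceProb = 1,
                            withinFamilyDivergence = 0, seqLength = 200,
                            seed = 12)
    sim <- simulateGenomeSet(cfg)
    fm <- familyMembership(sim$truth)
    seqs <- as.character(sequences(sim$genomes))
    a <- strsplit(seqs[names(fm)[fm == "F0001"][1L]], "")[[1L]]
    b <- strsplit(seqs[names(fm)[fm == "F0002"][1L]], "")[[1L]]
    expect_lt(mean(a == b), 0.2)   # expected ~ 1/20
})

test_that("simulation config validates its arguments", {
    expect_error(simulationConfig(nGenomes = 1), "at least 2")
    expect_error(simulationConfig(gainRate = -1), "non-negative")
    expect_error(simulationConfig(rootPresenceProb = 1.4), "\\[0, 1\\]")
})
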