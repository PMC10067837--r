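test_that("the paralogy index is sequences per distinct genome", {
    expect_equal(paralogyIndex(paste0("g", 1:5)), 1.0)
    expect_equal(paralogyIndex(c("g1", "g1", "g2", "g2", "g3", "g3")), 2.0)
    expect_equal(paralogyIndex("g1"), 1.0)
    expect_error(paralogyIndex(character(0)), "empty")
})

test_that("a single-copy tree is returned unsplit", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
    gm <- setNames(paste0("g", 1:4), letters[1:4])
    parts <- parseSubtrees(tr, gm)
    expect_length(parts, 1L)
    expect_identical(parts[[1L]], letters[1:4])
})

test_that("two clean duplicate clades split into the two copies", {
    ## 2g leaves over g genomes: whole ratio g/2 < g = each clade's ratio
    tr <- ape::read.tree(
        text = "(((a1:1,b1:1):1,(c1:1,d1:1):1):1,((a2:1,b2:1):1,(c2:1,d2:1):1):1);")
    gm <- setNames(rep(c("A", "B", "C", "D"), 2),
                   c("a1", "b1", "c1", "d1", "a2", "b2", "c2", "d2"))
    parts <- parseSubtrees(tr, gm)
    expect_length(parts, 2L)
    expect_setequal(vapply(parts, paste, "", collapse = ","),
                    c("a1,b1,c1,d1", "a2,b2,c2,d2"))
    ## exhaustive scoring of all clades confirms the chosen cut
    oracle <- oracleParse(tr, gm)
    expect_identical(canonicalParts(parts), canonicalParts(oracle))
})

test_that("decomposition equals the brute-force cut oracle on mixed trees", {
    ## hand-built 6-leaf mixed tree: one duplicated genome pair inside
    tr <- ape::read.tree(
        text = "(((a1:1,a2:1):1,b1:2):1,((c1:1,d1:1):1,e1:2):1);")
    gm <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D", e1 = "E")
    expect_identical(canonicalParts(parseSubtrees(tr, gm)),
                     canonicalParts(oracleParse(tr, gm)))

    ## randomized small gene trees with paralogy
    for (seed in 1:10) {
        withr::with_seed(seed, {
            n <- sample(4:8, 1L)
            tr <- ape::rtree(n)
            genomes <- paste0("g", sample.int(max(2L, n %/% 2), n,
                                              replace = TRUE))
            gm <- setNames(genomes, tr$tip.label)
        })
        parts <- parseSubtrees(tr, gm)
        oracle <- oracleParse(tr, gm)
        expect_identical(canonicalParts(parts), canonicalParts(oracle))
        ## partition property: each leaf in exactly one part
        expect_setequal(unlist(parts), tr$tip.label)
        expect_equal(sum(lengths(parts)), ape::Ntip(tr))
        ## the minimum part ratio never falls below the input ratio
        ratio <- function(l) length(unique(gm[l]))^2 / length(l)
        expect_gte(min(vapply(parts, ratio, 0)), ratio(tr$tip.label))
    }
})

test_that("refinement reaches a fixed point and repairs bad clusters", {
    sim <- simulateGenomeSet(simulationConfig(
        nGenomes = 8, nFamilies = 6, gainRate = 0, lossRate = 0.1,
        dupRate = 0, rootPresenceProb = 1,
        withinFamilyDivergence = 0.2, seed = 41))
    fm <- familyMembership(sim$truth)
    gmap <- genomeIds(sim$genomes)
    fams <- split(names(fm), fm)
    ## damage the truth: over-split one family, fuse two others
    f1 <- sort(fams[[1L]]); f2 <- sort(fams[[2L]]); f3 <- sort(fams[[3L]])
    clusters <- list(S1 = f1[seq_len(length(f1) %/% 2)],
                     S2 = f1[-seq_len(length(f1) %/% 2)],
                     FU = sort(c(f2, f3)))
    rest <- fams[-(1:3)]
    names(rest) <- paste0("R", seq_along(rest))
    cs <- ClusterSet(clusters = c(clusters, lapply(rest, sort)),
                     genomeMap = gmap)
    cs <- attachSequences(cs, sim$genomes)
    ref <- refineClusters(cs)
    got <- canonicalParts(unname(ref@clusters))
    want <- canonicalParts(unname(lapply(fams, sort)))
    expect_identical(got, want)
    log <- ref@metadata$refinementLog
    expect_gt(log$merges[1L] + log$splits[1L], 0L)
    expect_equal(log$merges[nrow(log)] + log$splits[nrow(log)], 0L)

    ## already-refined input converges immediately with zero operations
    ref2 <- refineClusters(ref)
    expect_equal(nrow(ref2@metadata$refinementLog), 1L)
    expect_equal(sum(ref2@metadata$refinementLog[1L, c("merges",
                                                       "splits")]), 0L)
    ## maxIterations = 0 returns the input partition unchanged
    ref0 <- refineClusters(cs, maxIterations = 0L)
    expect_identical(ref0@clusters, cs@clusters)
})

test_that("AAI is 100 for self, symmetric, and tracks divergence", {
    sim <- simulateGenomeSet(simulationConfig(
        nGenomes = 6, nFamilies = 10, gainRate = 0, lossRate = 0,
        dupRate = 0, rootPresenceProb = 1,
        withinFamilyDivergence = 0.15, seed = 19))
    fm <- familyMembership(sim$truth)
    cs <- ClusterSet(clusters = lapply(split(names(fm), fm), sort),
                     genomeMap = genomeIds(sim$genomes))
    cs <- attachSequences(cs, sim$genomes)
    expect_equal(computeAAI(cs, "G0001", "G0001"), 100)
    ab <- computeAAI(cs, "G0001", "G0002")
    expect_equal(ab, computeAAI(cs, "G0002", "G0001"))
    expect_true(ab > 0 && ab <= 100)
    ## closed-form expectation under the substitution model: per site,
    ## P(identical) = sum_k P(both end in residue k); for a path of
    ## length T with per-branch flip prob 1-exp(-d t) to a random other
    ## residue, a 3-sigma band around the empirical mean must cover it
    tr <- speciesTree(sim$truth)
    tipd <- ape::dist.nodes(tr)[1:6, 1:6]
    Tpath <- tipd[1, 2]
    d <- 0.15
    ## lower bound: survive the whole path, or land on the same residue
    ## by chance (ignores multi-step reversions, which only add identity)
    p_same <- exp(-d * Tpath) + (1 - exp(-d * Tpath)) / 20
    nsites <- 10 * 120
    sigma <- 100 * sqrt(0.25 / nsites)
    expect_gt(ab, 100 * p_same - 3 * sigma)
})

test_that("AAI without shared clusters is an error", {
    cs <- ClusterSet(clusters = list(C1 = c("p1", "p2")),
                     genomeMap = c(p1 = "gA", p2 = "gB", p3 = "gC"),
                     singletons = "p3")
    expect_error(computeAAI(cs, "gA", "gC"), "share no clusters")
})
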