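test_that("transition probabilities follow the two-state closed form", {
    I <- transitionProbability(1, 2, 0)
    expect_equal(unname(I), diag(2))
    ## long times converge to the stationary distribution (l/r, g/r)
    Pinf <- transitionProbability(1, 2, 1e6)
    expect_equal(unname(Pinf[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
    expect_equal(unname(Pinf[2, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
    ## closed-form spot value
    P <- transitionProbability(1, 2, 0.5)
    expect_equal(P["absent", "present"], (1 / 3) * (1 - exp(-1.5)),
                 tolerance = 1e-12)
    expect_equal(rowSums(P), c(absent = 1, present = 1))
    expect_warning(P0 <- transitionProbability(0, 0, 1), "frozen")
    expect_equal(unname(P0), diag(2))
})

test_that("pruning matches hand expansion on a 2-leaf tree", {
    tree <- ape::read.tree(text = "(A:0.4,B:0.7);")
    m <- GainLossModel(0.8, 1.3, rootPrior = 0.35)
    P1 <- transitionProbability(0.8, 1.3, 0.4)
    P2 <- transitionProbability(0.8, 1.3, 0.7)
    byhand <- 0.65 * P1[1, 2] * P2[1, 2] + 0.35 * P1[2, 2] * P2[2, 2]
    expect_equal(patternLikelihood(tree, c(A = 1, B = 1), m), byhand,
                 tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on a 5-leaf tree", {
    tree <- simulateSpeciesTree(5, seed = 14)
    m <- GainLossModel(0.6, 1.1)
    X <- allPatterns(tree)
    lik <- patternLikelihood(tree, X, m)
    for (i in seq_len(nrow(X))) {
        bf <- bruteLikelihood(tree, X[i, ], m)
        expect_lt(abs(lik[i] - bf) / max(bf, 1e-300), 1e-10)
    }
    ## likelihoods over all patterns sum to one
    expect_equal(sum(lik), 1, tolerance = 1e-9)
})

test_that("ascertainment divides by the observability probability", {
    tree <- simulateSpeciesTree(4, seed = 2)
    m <- GainLossModel(0.5, 1.0)
    pat <- setNames(c(1, 0, 1, 0), tree$tip.label)
    raw <- patternLikelihood(tree, pat, m)
    cor <- patternLikelihood(tree, pat, m, ascertainment = TRUE)
    allabs <- bruteLikelihood(tree, setNames(rep(0, 4), tree$tip.label),
                              m)
    expect_equal(cor, raw / (1 - allabs), tolerance = 1e-12)
    ## pure presence: no losses, certain root -> likelihood 1 uncorrected
    m1 <- GainLossModel(0.5, 0, rootPrior = 1)
    allpres <- setNames(rep(1, 4), tree$tip.label)
    expect_equal(patternLikelihood(tree, allpres, m1), 1,
                 tolerance = 1e-12)
})

test_that("doubling branch lengths and halving rates leaves the likelihood", {
    tree <- simulateSpeciesTree(6, seed = 8)
    tree2 <- tree
    tree2$edge.length <- tree$edge.length * 2
    pat <- setNames(c(1, 1, 0, 1, 0, 1), tree$tip.label)
    l1 <- patternLikelihood(tree, pat, GainLossModel(0.8, 1.4))
    l2 <- patternLikelihood(tree2, pat, GainLossModel(0.4, 0.7))
    expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("rate fitting recovers truth and hits bounds when degenerate", {
    tr <- simulateSpeciesTree(20, 1)
    cfg <- simulationConfig(nGenomes = 20, nFamilies = 5000,
                            gainRate = 0.5, lossRate = 1.0, dupRate = 0,
                            rootPresenceProb = 1 / 3, seed = 1)
    sim <- simulateGeneContent(tr, cfg)
    fit <- fitRates(sim$matrix, tr)
    expect_lt(abs(gainRate(fit) - 0.5) / 0.5, 0.15)
    expect_lt(abs(lossRate(fit) - 1.0) / 1.0, 0.15)
    expect_true(is.finite(fit@logLik))

    ## all-present matrix: loss rate driven to the lower bound
    allp <- matrix(1L, 50, 20, dimnames = list(
        paste0("F", 1:50), tr$tip.label))
    fit0 <- fitRates(allp, tr)
    expect_lt(lossRate(fit0), exp(-6) * 1.01)
})

test_that("marginal posteriors agree with enumeration and symmetry", {
    tree <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,C:0.5);")
    m <- GainLossModel(0.7, 1.2)
    for (i in 0:7) {
        pat <- setNames(c(i %% 2, (i %/% 2) %% 2, (i %/% 4) %% 2),
                        c("A", "B", "C"))
        post <- marginalPosteriors(tree, pat, m)
        bf <- brutePosteriors(tree, pat, m)
        expect_equal(unname(post[1, ]), unname(bf), tolerance = 1e-10)
        expect_true(all(post >= 0 & post <= 1))
        expect_equal(unname(post[1, c("A", "B", "C")]), unname(pat))
    }
    ## certain presence everywhere under a loss-free model
    m1 <- GainLossModel(0.3, 0, rootPrior = 1)
    post1 <- marginalPosteriors(tree, c(A = 1, B = 1, C = 1), m1)
    expect_true(all(post1 == 1))
    ## mirror symmetry on a symmetric tree and pattern
    ts <- ape::read.tree(text = "((A:0.4,B:0.4):0.3,(C:0.4,D:0.4):0.3);")
    ps <- marginalPosteriors(ts, c(A = 1, B = 0, C = 1, D = 0),
                             GainLossModel(0.5, 0.5))
    nn <- nodeNames(ts)
    left <- which(nn == "N2"); right <- which(nn == "N3")
    expect_equal(ps[1, left], ps[1, right], tolerance = 1e-12)
})

test_that("event calls apply the strict posterior-change threshold", {
    tree <- ape::read.tree(text = "(A:1,B:1)r;")
    tree$node.label <- "N1"
    post <- matrix(c(0.9, 0.1, 0.3), nrow = 3, ncol = 3,
                   dimnames = list(c("F1", "F2", "F3"),
                                   c("A", "B", "N1")))
    post["F1", ] <- c(0.1, 0.95, 0.9)   # N1 -> A delta -0.8: loss
    post["F2", ] <- c(0.7, 0.5, 0.3)    # delta 0.4: below threshold
    post["F3", ] <- c(0.5, 0.5, 0.5)    # constant: never called
    ev <- callEvents(post, tree)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$family, "F1")
    expect_equal(ev$type, "loss")
    expect_equal(ev$delta, -0.8)
    ## a delta of exactly the threshold magnitude is not called
    post2 <- post; post2["F2", ] <- c(0.75, 0.5, 0.25)  # delta exactly 0.5
    ev2 <- callEvents(post2, tree)
    expect_false("F2" %in% ev2$family)
    ## constant posteriors yield no calls even at threshold zero
    ev0 <- callEvents(post[3, , drop = FALSE], tree, threshold = 0)
    expect_equal(nrow(ev0), 0L)
})

test_that("ancestral content sums posteriors and respects leaves", {
    tree <- simulateSpeciesTree(6, seed = 31)
    cfg <- simulationConfig(nGenomes = 6, nFamilies = 80, gainRate = 0.4,
                            lossRate = 0.6, dupRate = 0,
                            rootPresenceProb = 0.5, seed = 31)
    sim <- simulateGeneContent(tree, cfg)
    fit <- fitRates(sim$matrix, tree)
    post <- marginalPosteriors(tree, sim$matrix, fit)
    ## at a leaf the content equals the observed family count
    acs <- ancestralContentSize(post, "G0001")
    expect_equal(acs$expected, sum(sim$matrix[, "G0001"] >= 1))
    expect_error(ancestralContentSize(post, "nope"), "unknown node")
    ## frozen chain, certain root: root content = number of families
    m0 <- GainLossModel(0, 1e-9, rootPrior = 1)
    allp <- matrix(1L, 10, 6, dimnames = list(paste0("F", 1:10),
                                              tree$tip.label))
    p0 <- marginalPosteriors(tree, allp, m0)
    expect_equal(ancestralContentSize(p0, "N1")$expected, 10,
                 tolerance = 1e-6)
})

test_that("event calls alternate consistently along root-to-leaf paths", {
    tr <- simulateSpeciesTree(12, seed = 9)
    cfg <- simulationConfig(nGenomes = 12, nFamilies = 300,
                            gainRate = 0.1, lossRate = 0.2, dupRate = 0,
                            rootPresenceProb = 1 / 3, seed = 9)
    sim <- simulateGeneContent(tr, cfg)
    fit <- fitRates(sim$matrix, tr)
    post <- marginalPosteriors(tr, sim$matrix, fit)
    ev <- callEvents(post, tr)
    labels <- nodeNames(tr)
    ntip <- ape::Ntip(tr)
    for (f in unique(ev$family)) {
        for (tip in seq_len(ntip)) {
            path <- ape::nodepath(tr, ntip + 1L, tip)
            onpath <- ev[ev$family == f &
                         ev$child %in% labels[path], , drop = FALSE]
            if (nrow(onpath) < 2L) next
            ord <- match(onpath$child, labels[path])
            types <- onpath$type[order(ord)]
            expect_true(all(types[-1L] != types[-length(types)]))
        }
    }
})
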