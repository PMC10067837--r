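## Independent oracles used across the suite.  These deliberately avoid
## the package's own traversal and DP code paths.

## ---- exhaustive two-state likelihood / posteriors ---------------------

## sum over all internal-state assignments of prior * prod(edge probs)
bruteLikelihood <- function(tree, pattern, model) {
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    internal <- (ntip + 1L):nn
    Pm <- lapply(seq_len(nrow(tree$edge)), function(k)
        transitionProbability(gainRate(model), lossRate(model),
                              tree$edge.length[k]))
    total <- 0
    for (mask in 0:(2^length(internal) - 1L)) {
        s <- integer(nn)
        s[internal] <- bitwAnd(bitwShiftR(mask,
                                          seq_along(internal) - 1L), 1L)
        s[seq_len(ntip)] <- pattern[tree$tip.label]
        p <- if (s[ntip + 1L] == 1L) rootPrior(model) else
            1 - rootPrior(model)
        for (k in seq_len(nrow(tree$edge)))
            p <- p * Pm[[k]][s[tree$edge[k, 1L]] + 1L,
                             s[tree$edge[k, 2L]] + 1L]
        total <- total + p
    }
    total
}

## joint P(node present, pattern) / P(pattern) for every node
brutePosteriors <- function(tree, pattern, model) {
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    internal <- (ntip + 1L):nn
    Pm <- lapply(seq_len(nrow(tree$edge)), function(k)
        transitionProbability(gainRate(model), lossRate(model),
                              tree$edge.length[k]))
    tot <- 0
    num <- numeric(nn)
    for (mask in 0:(2^length(internal) - 1L)) {
        s <- integer(nn)
        s[internal] <- bitwAnd(bitwShiftR(mask,
                                          seq_along(internal) - 1L), 1L)
        s[seq_len(ntip)] <- pattern[tree$tip.label]
        p <- if (s[ntip + 1L] == 1L) rootPrior(model) else
            1 - rootPrior(model)
        for (k in seq_len(nrow(tree$edge)))
            p <- p * Pm[[k]][s[tree$edge[k, 1L]] + 1L,
                             s[tree$edge[k, 2L]] + 1L]
        tot <- tot + p
        num[s == 1L] <- num[s == 1L] + p
    }
    setNames(num / tot, nodeNames(tree))
}

## all 2^n leaf patterns of an n-leaf tree, as a matrix
allPatterns <- function(tree) {
    tips <- tree$tip.label
    n <- length(tips)
    X <- as.matrix(expand.grid(rep(list(0:1), n)))
    colnames(X) <- tips
    rownames(X) <- paste0("P", seq_len(nrow(X)))
    X
}

## ---- brute-force subtree decomposition --------------------------------

## clade leaf sets of a rooted tree via ape::prop.part (independent of
## the package's own traversal)
oracleClades <- function(tree) {
    pp <- ape::prop.part(tree)
    clades <- lapply(pp, function(i) tree$tip.label[i])
    c(clades, as.list(tree$tip.label))   # tip "clades" = single leaves
}

## one decomposition step: exhaustively score every clade-vs-complement
## cut; NULL if no cut improves both parts
oracleBestCut <- function(tree, gm) {
    ratio <- function(l) length(unique(gm[l]))^2 / length(l)
    leaves <- tree$tip.label
    rcur <- ratio(leaves)
    best <- NULL
    for (cl in oracleClades(tree)) {
        if (length(cl) == length(leaves)) next
        comp <- setdiff(leaves, cl)
        rc <- ratio(cl); rk <- ratio(comp)
        if (rc > rcur && rk > rcur) {
            cand <- list(cl = sort(cl), comp = sort(comp),
                         m = min(rc, rk), size = length(cl),
                         lab = min(cl))
            if (is.null(best) || cand$m > best$m ||
                (cand$m == best$m && (cand$size > best$size ||
                 (cand$size == best$size && cand$lab < best$lab))))
                best <- cand
        }
    }
    best
}

## full recursive oracle decomposition
oracleParse <- function(tree, gm) {
    rec <- function(tr) {
        if (is.character(tr)) return(list(sort(tr)))
        if (ape::Ntip(tr) == 1L) return(list(tr$tip.label))
        cut <- oracleBestCut(tr, gm)
        if (is.null(cut)) return(list(sort(tr$tip.label)))
        sub1 <- if (length(cut$cl) == 1L) cut$cl else
            ape::keep.tip(tr, cut$cl)
        sub2 <- if (length(cut$comp) == 1L) cut$comp else
            ape::keep.tip(tr, cut$comp)
        c(rec(sub1), rec(sub2))
    }
    rec(tree)
}

## canonical form of a leaf partition for comparisons
canonicalParts <- function(parts) {
    parts <- lapply(parts, sort)
    parts[order(vapply(parts, `[`, "", 1L))]
}

## ---- affine-gap Smith-Waterman score oracle ---------------------------

## 3-state local alignment DP, BLOSUM62, gap open `go` charged on the
## first gap residue (open+extend), `ge` on later ones -- matches the
## pairwiseAlignment(gapOpening=11, gapExtension=1) convention
swScoreOracle <- function(a, b, go = 11, ge = 1) {
    B62 <- blosum62()
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    n <- length(av); m <- length(bv)
    M <- matrix(0, n + 1L, m + 1L)
    Ix <- matrix(-Inf, n + 1L, m + 1L)
    Iy <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - go - ge,
                                      Ix[i, j + 1L] - ge)
            Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - go - ge,
                                      Iy[i + 1L, j] - ge)
            s <- B62[av[i], bv[j]]
            M[i + 1L, j + 1L] <- max(0,
                                     M[i, j] + s,
                                     Ix[i, j] + s,
                                     Iy[i, j] + s)
            best <- max(best, M[i + 1L, j + 1L])
        }
    }
    best
}

## ---- misc -------------------------------------------------------------

## random amino-acid sequence (20-letter alphabet)
randomProtein <- function(n) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    paste(sample(aa, n, replace = TRUE), collapse = "")
}

## the clustering-recovery fixture used by several tests: easy divergence
## so that within-family identity is high and families are recoverable
clusteringFixture <- function() {
    simulateGenomeSet(simulationConfig(
        nGenomes = 20L, nFamilies = 50L, gainRate = 0, lossRate = 0.2,
        dupRate = 0, rootPresenceProb = 1, seqLength = 150L,
        withinFamilyDivergence = 0.2, seed = 101L))
}

## replay recorded truth events down the tree to recover leaf presence
replayEvents <- function(truth) {
    tree <- speciesTree(truth)
    st <- nodeStates(truth)
    ev <- trueEvents(truth)
    labels <- nodeNames(tree)
    ntip <- ape::Ntip(tree)
    fams <- rownames(st)
    root <- ntip + 1L
    pres <- matrix(st[, root], nrow = length(fams),
                   ncol = ntip + tree$Nnode,
                   dimnames = list(fams, labels))
    tr <- ape::reorder.phylo(tree, "cladewise")
    gl <- ev[ev$type %in% c("gain", "loss"), , drop = FALSE]
    for (k in seq_len(nrow(tr$edge))) {
        u <- tr$edge[k, 1L]; v <- tr$edge[k, 2L]
        pres[, v] <- pres[, u]
        here <- gl[gl$child == labels[v], , drop = FALSE]
        if (nrow(here))
            pres[here$family, v] <- ifelse(here$type == "gain", 1L, 0L)
    }
    dups <- ev[ev$type == "duplication", , drop = FALSE]
    counts <- pres[, seq_len(ntip), drop = FALSE]
    if (nrow(dups)) {
        tab <- table(dups$family, dups$child)
        counts[rownames(tab), colnames(tab)] <-
            counts[rownames(tab), colnames(tab)] + as.matrix(tab)
    }
    counts
}
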