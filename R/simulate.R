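#' Simulation configuration
#'
#' Parameters of the synthetic genome-set generator.  The defaults define
#' the generator's standard study conditions: a 20-genome clade with gene
#' gain/loss dynamics dominated by loss (gain 0.5, loss 1.0 per unit
#' branch length, root presence at the stationary probability 1/3),
#' occasional lineage-specific duplications, and protein divergence low
#' enough that within-family similarity stays well above the random
#' between-family background.
#'
#' @param nGenomes number of genomes (tree leaves), at least 2.
#' @param nFamilies number of gene families to simulate.
#' @param gainRate,lossRate,dupRate non-negative per-unit-branch-length
#'   rates of family gain, loss, and copy duplication.
#' @param rootPresenceProb probability a family is present at the root.
#' @param seqLength protein length in residues.
#' @param withinFamilyDivergence expected substitutions per site per unit
#'   branch length within a family.
#' @param seed integer RNG seed; all simulator outputs are pure functions
#'   of the configuration including this seed.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
#' @examples
#' cfg <- simulationConfig(nGenomes = 5, nFamilies = 10, seed = 1)
simulationConfig <- function(nGenomes = 20L, nFamilies = 100L,
                             gainRate = 0.5, lossRate = 1.0,
                             dupRate = 0.05, rootPresenceProb = 1 / 3,
                             seqLength = 120L,
                             withinFamilyDivergence = 0.25, seed = 1L) {
    cfg <- list(nGenomes = as.integer(nGenomes),
                nFamilies = as.integer(nFamilies),
                gainRate = gainRate, lossRate = lossRate,
                dupRate = dupRate, rootPresenceProb = rootPresenceProb,
                seqLength = as.integer(seqLength),
                withinFamilyDivergence = withinFamilyDivergence,
                seed = as.integer(seed))
    rates <- c(cfg$gainRate, cfg$lossRate, cfg$dupRate,
               cfg$withinFamilyDivergence)
    if (any(!is.finite(rates)) || any(rates < 0))
        stop("all rates must be finite and non-negative")
    if (!is.finite(cfg$rootPresenceProb) || cfg$rootPresenceProb < 0 ||
        cfg$rootPresenceProb > 1)
        stop("rootPresenceProb must be in [0, 1]")
    if (cfg$nGenomes < 2L) stop("nGenomes must be at least 2")
    if (cfg$nFamilies < 1L) stop("nFamilies must be positive")
    if (cfg$seqLength < 1L) stop("seqLength must be positive")
    structure(cfg, class = "SimulationConfig")
}

#' Simulate a species tree under a Yule process
#'
#' Starting from a single split, a uniformly chosen extant lineage splits
#' at each step until the tree has \code{nGenomes} leaves.  Every branch
#' length is drawn independently from an exponential distribution with
#' mean 0.1.  Leaves are labelled \code{G0001, G0002, ...} and internal
#' nodes \code{N1, ...} (\code{N1} is the root).
#'
#' @param nGenomes number of leaves, at least 2.
#' @param seed integer RNG seed; identical (nGenomes, seed) yields an
#'   identical tree.
#' @param meanBranchLength mean of the exponential branch-length draw.
#' @return A rooted, bifurcating \code{phylo} with strictly positive
#'   branch lengths.
#' @export
#' @examples
#' tr <- simulateSpeciesTree(5, seed = 42)
simulateSpeciesTree <- function(nGenomes, seed, meanBranchLength = 0.1) {
    nGenomes <- as.integer(nGenomes)
    if (is.na(nGenomes) || nGenomes < 2L)
        stop("nGenomes must be at least 2")
    withSeed(seed, {
        ## topology by random leaf splitting; temp ids are creation order
        children <- list()        # temp id -> c(child1, child2)
        leaves <- c(2L, 3L)       # root = 1 splits into 2, 3
        children[["1"]] <- c(2L, 3L)
        nextId <- 4L
        while (length(leaves) < nGenomes) {
            i <- sample.int(length(leaves), 1L)
            v <- leaves[i]
            children[[as.character(v)]] <- c(nextId, nextId + 1L)
            leaves <- c(leaves[-i], nextId, nextId + 1L)
            nextId <- nextId + 2L
        }
        ## map temp ids to ape numbering: tips 1..n in leaf creation order,
        ## internal nodes n+1.. in preorder from the root
        nTip <- nGenomes
        isLeaf <- !(as.character(seq_len(nextId - 1L)) %in% names(children))
        leafTemp <- sort(which(isLeaf))
        tipNo <- setNames(seq_len(nTip), as.character(leafTemp))
        apeNo <- integer(nextId - 1L)
        apeNo[leafTemp] <- tipNo
        nextInternal <- nTip + 1L
        edge <- matrix(0L, nrow = 2L * nTip - 2L, ncol = 2L)
        k <- 0L
        assign_internal <- function(v) {
            apeNo[v] <<- nextInternal
            nextInternal <<- nextInternal + 1L
        }
        stack <- 1L
        order <- integer(0)
        ## iterative preorder
        while (length(stack)) {
            v <- stack[[length(stack)]]
            stack <- stack[-length(stack)]
            if (!isLeaf[v]) {
                assign_internal(v)
                kids <- children[[as.character(v)]]
                order <- c(order, v)
                stack <- c(stack, rev(kids))
            }
        }
        for (v in order) {
            for (w in children[[as.character(v)]]) {
                k <- k + 1L
                edge[k, ] <- c(apeNo[v], apeNo[w])
            }
        }
        lens <- rexp(nrow(edge), rate = 1 / meanBranchLength)
        ## exponential draws are > 0 almost surely; guard degenerate 0
        lens[lens <= 0] <- .Machine$double.eps
        tree <- structure(list(
            edge = edge, edge.length = lens, Nnode = nTip - 1L,
            tip.label = sprintf("G%04d", seq_len(nTip)),
            node.label = paste0("N", seq_len(nTip - 1L))),
            class = "phylo", order = "cladewise")
        tree
    })
}

## Exact jump-process simulation of the two-state chain along one branch.
## `state` is an integer vector over families; returns end states.
.simBranchStates <- function(state, t, gainRate, lossRate) {
    cur <- state
    timeLeft <- rep(t, length(state))
    active <- rep(TRUE, length(state))
    repeat {
        rate <- ifelse(cur == 1L, lossRate, gainRate)
        idx <- which(active & rate > 0)
        if (!length(idx)) break
        w <- rexp(length(idx), rate = rate[idx])
        flip <- w < timeLeft[idx]
        timeLeft[idx] <- timeLeft[idx] - w
        cur[idx[flip]] <- 1L - cur[idx[flip]]
        active[idx[!flip]] <- FALSE
        if (!any(flip)) break
    }
    cur
}

#' Simulate gene content along a species tree
#'
#' Each family is present at the root with probability
#' \code{rootPresenceProb}, then evolves down every branch under the
#' two-state Markov chain (gain at \code{gainRate}, loss at
#' \code{lossRate}), simulated as an exact jump process so that endpoint
#' transition probabilities match the analytical chain.  A present family
#' on a terminal branch additionally acquires Poisson(dupRate * t) extra
#' copies in that genome.  Net per-edge state changes and per-leaf
#' duplications are recorded as ground-truth events.  Families absent from
#' every leaf are unobservable, dropped from the matrix, and counted.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with \code{matrix} (families x genomes copy counts,
#'   observed families only) and \code{truth} (a
#'   \code{\linkS4class{SimulationTruth}}).
#' @export
#' @examples
#' tr <- simulateSpeciesTree(5, seed = 1)
#' sim <- simulateGeneContent(tr, simulationConfig(nGenomes = 5,
#'     nFamilies = 20, seed = 1))
simulateGeneContent <- function(tree, config) {
    if (is.null(tree$edge.length))
        stop("tree must have branch lengths")
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
    nf <- config$nFamilies
    g <- config$gainRate; l <- config$lossRate
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    labels <- nodeNames(tree)
    famIds <- sprintf("F%04d", seq_len(nf))
    withSeed(config$seed, {
        states <- matrix(0L, nrow = nf, ncol = nn,
                         dimnames = list(famIds, labels))
        root <- ntip + 1L
        states[, root] <- as.integer(runif(nf) < config$rootPresenceProb)
        tree <- ape::reorder.phylo(tree, "cladewise")
        evChild <- character(0); evFam <- character(0); evType <- character(0)
        for (k in seq_len(nrow(tree$edge))) {
            u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
            t <- tree$edge.length[k]
            sv <- .simBranchStates(states[, u], t, g, l)
            states[, v] <- sv
            changed <- which(sv != states[, u])
            if (length(changed)) {
                evChild <- c(evChild, rep(labels[v], length(changed)))
                evFam <- c(evFam, famIds[changed])
                evType <- c(evType,
                            ifelse(sv[changed] == 1L, "gain", "loss"))
            }
        }
        ## terminal-branch duplications: extra copies, one event per copy
        counts <- states[, seq_len(ntip), drop = FALSE]
        if (config$dupRate > 0) {
            for (k in which(tree$edge[, 2L] <= ntip)) {
                v <- tree$edge[k, 2L]
                present <- which(counts[, v] >= 1L)
                if (!length(present)) next
                extra <- rpois(length(present),
                               config$dupRate * tree$edge.length[k])
                dup <- which(extra > 0L)
                if (length(dup)) {
                    counts[present[dup], v] <-
                        counts[present[dup], v] + extra[dup]
                    evChild <- c(evChild,
                                 rep(labels[v], sum(extra[dup])))
                    evFam <- c(evFam, rep(famIds[present[dup]], extra[dup]))
                    evType <- c(evType, rep("duplication", sum(extra[dup])))
                }
            }
        }
        observed <- rowSums(counts) > 0L
        nDropped <- sum(!observed)
        keepFams <- famIds[observed]
        events <- data.frame(child = evChild, family = evFam,
                             type = evType, stringsAsFactors = FALSE)
        events <- events[events$family %in% keepFams, , drop = FALSE]
        events <- events[order(events$family, events$child, events$type), ]
        rownames(events) <- NULL
        truth <- new("SimulationTruth", tree = tree,
                     states = states[observed, , drop = FALSE],
                     counts = counts[observed, , drop = FALSE],
                     events = events,
                     familyMembership = character(0),
                     nDropped = as.integer(nDropped))
        list(matrix = counts[observed, , drop = FALSE], truth = truth)
    })
}

## mutate integer-coded residue matrix (rows = families) with per-site
## substitution probability p to a uniformly chosen different residue
.mutateSeqs <- function(mat, p) {
    if (p <= 0) return(mat)
    hit <- matrix(runif(length(mat)) < p, nrow = nrow(mat))
    n <- sum(hit)
    if (n) {
        shift <- sample.int(19L, n, replace = TRUE)
        mat[hit] <- 1L + (mat[hit] - 1L + shift) %% 20L
    }
    mat
}

#' Simulate protein sequences for a gene-content history
#'
#' Each family gets one random root sequence (uniform over the 20 amino
#' acids).  The family's reference sequence evolves down every branch of
#' the tree by per-site substitution with probability
#' \code{1 - exp(-d * t)} to a uniformly chosen different residue
#' (d = \code{withinFamilyDivergence}); a genome's copy of a family is the
#' reference sequence at that leaf, and duplicate copies inherit the same
#' leaf sequence (duplications arise on terminal branches).  Emits one
#' proteome per genome with protein ids \code{<genome>.<family>.<copy>}.
#'
#' @param truth a \code{\linkS4class{SimulationTruth}} from
#'   \code{\link{simulateGeneContent}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return A list with \code{genomes} (a \code{\linkS4class{GenomeSet}})
#'   and \code{truth} (the input truth with \code{familyMembership}
#'   filled in).
#' @export
simulateSequences <- function(truth, config) {
    tree <- truth@tree
    ntip <- ape::Ntip(tree)
    labels <- nodeNames(tree)
    counts <- truth@counts
    famIds <- rownames(counts)
    nf <- length(famIds)
    L <- config$seqLength
    d <- config$withinFamilyDivergence
    withSeed(config$seed + 1L, {
        ## reference sequences per node, families x L integer codes
        seqAt <- vector("list", ntip + tree$Nnode)
        root <- ntip + 1L
        seqAt[[root]] <- matrix(sample.int(20L, nf * L, replace = TRUE),
                                nrow = nf)
        tree2 <- ape::reorder.phylo(tree, "cladewise")
        for (k in seq_len(nrow(tree2$edge))) {
            u <- tree2$edge[k, 1L]; v <- tree2$edge[k, 2L]
            p <- 1 - exp(-d * tree2$edge.length[k])
            seqAt[[v]] <- .mutateSeqs(seqAt[[u]], p)
        }
        ids <- character(0); genome <- character(0); seqs <- character(0)
        fams <- character(0)
        for (tip in seq_len(ntip)) {
            gname <- tree$tip.label[tip]
            present <- which(counts[, gname] >= 1L)
            if (!length(present)) next
            chars <- matrix(.AA20[seqAt[[tip]][present, , drop = FALSE]],
                            nrow = length(present))
            base <- apply(chars, 1L, paste, collapse = "")
            reps <- counts[present, gname]
            for (j in seq_along(present)) {
                for (cp in seq_len(reps[j])) {
                    ids <- c(ids, sprintf("%s.%s.%d", gname,
                                          famIds[present[j]], cp))
                    genome <- c(genome, gname)
                    seqs <- c(seqs, base[j])
                    fams <- c(fams, famIds[present[j]])
                }
            }
        }
        proteins <- Biostrings::AAStringSet(setNames(seqs, ids))
        gs <- GenomeSet(proteins, genome)
        truth@familyMembership <- setNames(fams, ids)
        list(genomes = gs, truth = truth)
    })
}

#' Run the full simulator
#'
#' Convenience wrapper: species tree, gene content, and sequences in one
#' call.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with \code{tree}, \code{matrix}, \code{truth},
#'   \code{genomes}.
#' @export
#' @examples
#' sim <- simulateGenomeSet(simulationConfig(nGenomes = 4, nFamilies = 10,
#'     seed = 3))
simulateGenomeSet <- function(config) {
    tree <- simulateSpeciesTree(config$nGenomes, config$seed)
    gc <- simulateGeneContent(tree, config)
    sq <- simulateSequences(gc$truth, config)
    list(tree = tree, matrix = gc$matrix, truth = sq$truth,
         genomes = sq$genomes)
}
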