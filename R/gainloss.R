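#' Transition probabilities of the two-state gain/loss chain
#'
#' For gain rate g, loss rate l and elapsed branch length t, with
#' r = g + l:
#' P(absent -> present) = (g/r) (1 - exp(-r t)),
#' P(present -> absent) = (l/r) (1 - exp(-r t)),
#' diagonals are the complements.  With g + l = 0 the chain is frozen and
#' the identity matrix is returned with a warning.
#'
#' @param g,l non-negative gain and loss rates.
#' @param t non-negative elapsed time (branch length).
#' @return 2x2 stochastic matrix with dimnames
#'   \code{c("absent", "present")} (rows = starting state).
#' @export
#' @examples
#' transitionProbability(1, 2, 0.5)["absent", "present"]
transitionProbability <- function(g, l, t) {
    if (g < 0 || l < 0 || t < 0) stop("rates and time must be >= 0")
    r <- g + l
    if (r == 0) {
        warning("g + l = 0: frozen chain, returning identity")
        return(matrix(c(1, 0, 0, 1), 2L, 2L,
                      dimnames = list(c("absent", "present"),
                                      c("absent", "present"))))
    }
    q <- 1 - exp(-r * t)
    p01 <- (g / r) * q
    p10 <- (l / r) * q
    matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
           dimnames = list(c("absent", "present"),
                           c("absent", "present")))
}

## coerce a pattern (named vector / matrix of copy counts or 0/1) to a
## binary matrix, families x tips, columns ordered as tree$tip.label
.asPatternMatrix <- function(tree, pattern) {
    tips <- tree$tip.label
    if (is.null(dim(pattern))) {
        pattern <- matrix(pattern, nrow = 1L,
                          dimnames = list("F1", names(pattern)))
    }
    if (!is.null(colnames(pattern))) {
        if (!all(tips %in% colnames(pattern)))
            stop("pattern does not cover all leaves")
        pattern <- pattern[, tips, drop = FALSE]
    } else if (ncol(pattern) != length(tips)) {
        stop("pattern does not cover all leaves")
    } else {
        colnames(pattern) <- tips
    }
    mode(pattern) <- "numeric"
    (pattern >= 1) * 1
}

## per-edge transition probabilities for a model
.edgeProbs <- function(tree, model) {
    g <- model@gainRate; l <- model@lossRate
    r <- g + l
    t <- tree$edge.length
    if (r == 0) {
        q <- rep(0, length(t))
    } else {
        q <- 1 - exp(-r * t)
    }
    p01 <- if (r == 0) q else (g / r) * q
    p10 <- if (r == 0) q else (l / r) * q
    list(p00 = 1 - p01, p01 = p01, p10 = p10, p11 = 1 - p10)
}

## Felsenstein pruning over a binary pattern matrix.
## Returns per-node conditional likelihoods L0, L1 (families x nodes),
## per-child-node edge messages M0, M1, and per-family likelihoods.
.pruning <- function(tree, X, model) {
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    nf <- nrow(X)
    po <- ape::reorder.phylo(tree, "postorder")
    ep <- .edgeProbs(po, model)
    L0 <- matrix(1, nf, nn); L1 <- matrix(1, nf, nn)
    L0[, seq_len(ntip)] <- 1 - X
    L1[, seq_len(ntip)] <- X
    acc0 <- matrix(1, nf, nn); acc1 <- matrix(1, nf, nn)
    M0 <- matrix(NA_real_, nf, nn); M1 <- matrix(NA_real_, nf, nn)
    done <- rep(FALSE, nn)
    for (k in seq_len(nrow(po$edge))) {
        u <- po$edge[k, 1L]; v <- po$edge[k, 2L]
        if (v > ntip && !done[v]) {   # finalize internal child
            L0[, v] <- acc0[, v]; L1[, v] <- acc1[, v]
            done[v] <- TRUE
        }
        m0 <- ep$p00[k] * L0[, v] + ep$p01[k] * L1[, v]
        m1 <- ep$p10[k] * L0[, v] + ep$p11[k] * L1[, v]
        M0[, v] <- m0; M1[, v] <- m1
        acc0[, u] <- acc0[, u] * m0
        acc1[, u] <- acc1[, u] * m1
    }
    root <- ntip + 1L
    L0[, root] <- acc0[, root]; L1[, root] <- acc1[, root]
    lik <- (1 - model@rootPrior) * L0[, root] +
        model@rootPrior * L1[, root]
    list(L0 = L0, L1 = L1, M0 = M0, M1 = M1, lik = lik, postorder = po,
         edgeProbs = ep)
}

## probability that a family is absent from every leaf under the model
.pAllAbsent <- function(tree, model) {
    X <- matrix(0, 1L, ape::Ntip(tree),
                dimnames = list("Z", tree$tip.label))
    .pruning(tree, X, model)$lik
}

#' Likelihood of phyletic patterns on a tree
#'
#' Computes P(pattern | tree, model) by Felsenstein pruning over the
#' two-state gain/loss chain, combining the root partials with the root
#' presence prior.  With \code{ascertainment = TRUE} the likelihood is
#' conditioned on the family being observed in at least one leaf
#' (divided by 1 - P(all-absent)), matching the fact that unobserved
#' families cannot form clusters.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param pattern named presence vector (or copy counts; binarized at
#'   >= 1), or a families x genomes matrix for many patterns at once.
#' @param model a \code{\linkS4class{GainLossModel}}.
#' @param ascertainment condition on observation in >= 1 leaf.
#' @return A numeric vector of likelihoods (one per pattern row).
#' @export
patternLikelihood <- function(tree, pattern, model,
                              ascertainment = FALSE) {
    X <- .asPatternMatrix(tree, pattern)
    lik <- .pruning(tree, X, model)$lik
    if (ascertainment)
        lik <- lik / (1 - .pAllAbsent(tree, model))
    unname(lik)
}

#' Fit gain and loss rates by maximum likelihood
#'
#' Maximises the summed log-likelihood of the (binarized) phyletic
#' patterns over (g, l), with the root prior fixed at the stationary
#' presence probability g / (g + l) and, by default, the
#' ascertainment correction for unobservable all-absent families.
#' Optimisation is bounded on log-rates in [-6, 6] (L-BFGS-B) from the
#' deterministic start g = l = 1.
#'
#' @param mat phyletic matrix, families x genomes (copy counts or 0/1).
#' @param tree rooted species tree (\code{phylo}) whose tip labels match
#'   the matrix columns.
#' @param ascertainment condition each family's likelihood on observation
#'   in at least one genome.
#' @return A fitted \code{\linkS4class{GainLossModel}} with its
#'   log-likelihood.
#' @export
fitRates <- function(mat, tree, ascertainment = TRUE) {
    X <- .asPatternMatrix(tree, mat)
    key <- apply(X, 1L, paste0, collapse = "")
    uniq <- !duplicated(key)
    U <- X[uniq, , drop = FALSE]
    w <- as.vector(table(key)[key[uniq]])
    negll <- function(par) {
        g <- exp(par[1L]); l <- exp(par[2L])
        model <- GainLossModel(g, l)
        pr <- .pruning(tree, U, model)
        ll <- log(pr$lik)
        if (ascertainment)
            ll <- ll - log(1 - .pAllAbsent(tree, model))
        v <- -sum(w * ll)
        if (!is.finite(v)) 1e10 else v
    }
    opt <- optim(c(0, 0), negll, method = "L-BFGS-B",
                 lower = c(-6, -6), upper = c(6, 6))
    GainLossModel(exp(opt$par[1L]), exp(opt$par[2L]),
                  logLik = -opt$value, ascertainment = ascertainment)
}

#' Marginal posterior presence probabilities at every node
#'
#' Computes P(present at node | pattern, model) for every tree node by
#' the up-down (outside) algorithm: an upward pruning pass followed by a
#' root-to-leaves pass that combines each node's outside probability
#' with its subtree partials.  Leaf posteriors equal the observed states.
#'
#' @inheritParams patternLikelihood
#' @return Matrix, patterns x nodes; columns named by tip labels and
#'   internal node labels (see \code{\link{nodeNames}}).
#' @export
marginalPosteriors <- function(tree, pattern, model) {
    X <- .asPatternMatrix(tree, pattern)
    nf <- nrow(X)
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    pr <- .pruning(tree, X, model)
    po <- pr$postorder
    ep <- pr$edgeProbs
    children <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
    D0 <- matrix(NA_real_, nf, nn); D1 <- matrix(NA_real_, nf, nn)
    root <- ntip + 1L
    D0[, root] <- 1 - model@rootPrior
    D1[, root] <- model@rootPrior
    ## preorder: parents before children
    ord <- rev(seq_len(nrow(po$edge)))
    for (k in ord) {
        u <- po$edge[k, 1L]; v <- po$edge[k, 2L]
        excl0 <- D0[, u]; excl1 <- D1[, u]
        for (k2 in children[[as.character(u)]]) {
            w <- po$edge[k2, 2L]
            if (w == v) next
            excl0 <- excl0 * pr$M0[, w]
            excl1 <- excl1 * pr$M1[, w]
        }
        D0[, v] <- excl0 * ep$p00[k] + excl1 * ep$p10[k]
        D1[, v] <- excl0 * ep$p01[k] + excl1 * ep$p11[k]
    }
    num <- D1 * pr$L1
    den <- D0 * pr$L0 + num
    post <- num / den
    post[den == 0] <- 0
    dimnames(post) <- list(rownames(X), nodeNames(tree))
    post
}

#' Call gain and loss events from posterior changes along edges
#'
#' For every tree edge (parent p, child c) and family, the change
#' delta = P(present at c) - P(present at p) is computed; a gain is
#' called when delta exceeds the threshold, a loss when -delta does
#' (strict inequality).  Output is sorted by family, then child node
#' label.
#'
#' @param posteriors families x nodes posterior matrix from
#'   \code{\link{marginalPosteriors}}.
#' @param tree the same rooted \code{phylo}.
#' @param threshold magnitude a posterior change must exceed.
#' @return data.frame with columns \code{family}, \code{parent},
#'   \code{child}, \code{type} ("gain"/"loss"), \code{delta}.
#' @export
callEvents <- function(posteriors, tree, threshold = 0.5) {
    labels <- nodeNames(tree)
    fams <- rownames(posteriors)
    out <- list()
    for (k in seq_len(nrow(tree$edge))) {
        u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
        delta <- posteriors[, labels[v]] - posteriors[, labels[u]]
        hit <- which(abs(delta) > threshold)
        if (length(hit)) {
            out[[length(out) + 1L]] <- data.frame(
                family = fams[hit], parent = labels[u],
                child = labels[v],
                type = ifelse(delta[hit] > 0, "gain", "loss"),
                delta = unname(delta[hit]), stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) {
        return(data.frame(family = character(0), parent = character(0),
                          child = character(0), type = character(0),
                          delta = numeric(0), stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    res <- res[order(res$family, res$child), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Expected ancestral gene content at a node
#'
#' Sums the posterior presence probabilities of all families at the
#' given node: the expected number of families present in that ancestral
#' (or extant) genome.
#'
#' @param posteriors families x nodes posterior matrix.
#' @param node a node name (tip label or internal node label).
#' @return A list with \code{expected} (the raw sum) and \code{rounded}
#'   (nearest integer).
#' @export
ancestralContentSize <- function(posteriors, node) {
    if (!node %in% colnames(posteriors))
        stop("unknown node: ", node)
    s <- sum(posteriors[, node])
    list(expected = s, rounded = as.integer(round(s)))
}
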