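#' Pairwise identity distances of an MSA
#'
#' Identity is computed over columns where both rows are non-gap; the
#' distance is \code{-ln(max(identity, 0.01))}.  Row pairs sharing no
#' non-gap column get identity 0.
#'
#' @param msa \code{AAStringSet} alignment with at least 2 rows.
#' @return A symmetric distance matrix with row names.
#' @export
msaDistances <- function(msa) {
    n <- length(msa)
    mat <- t(vapply(as.character(msa),
                    function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                    character(Biostrings::width(msa)[1L])))
    nb <- mat != "-"
    D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            sh <- nb[i, ] & nb[j, ]
            id <- if (any(sh)) mean(mat[i, sh] == mat[j, sh]) else 0
            D[i, j] <- D[j, i] <- -log(max(id, 0.01))
        }
    }
    D
}

#' Build a gene tree from a cluster alignment
#'
#' Neighbor joining on the log-corrected identity distance
#' \code{-ln(max(identity, 0.01))} over shared non-gap columns.  Rows are
#' sorted by name before distance computation so the result is
#' deterministic.  Negative NJ branch lengths are clamped to zero.  An
#' external tree builder can be plugged in via \code{treeBuilder}.
#'
#' @param msa \code{AAStringSet} alignment with at least 2 rows.
#' @param treeBuilder optional function \code{AAStringSet -> phylo}
#'   replacing the internal NJ (e.g. a wrapper around an external ML
#'   tool).
#' @return An unrooted \code{phylo} (for 2 rows: a 2-leaf tree whose
#'   leaf-to-leaf path length equals the pairwise distance).
#' @export
buildGeneTree <- function(msa, treeBuilder = NULL) {
    if (length(msa) < 2L) stop("need at least 2 rows")
    if (!is.null(treeBuilder)) return(treeBuilder(msa))
    msa <- msa[order(names(msa))]
    D <- msaDistances(msa)
    if (length(msa) == 2L) {
        d <- D[1L, 2L]
        tree <- structure(list(
            edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
            edge.length = c(d / 2, d / 2), Nnode = 1L,
            tip.label = rownames(D)), class = "phylo",
            order = "cladewise")
        return(tree)
    }
    tree <- ape::nj(D)
    tree$edge.length[tree$edge.length < 0] <- 0
    tree
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' Finds the longest path between two leaves (ties broken by the
#' lexicographically smallest sorted pair of endpoint labels) and places
#' the root halfway along it, so the two root-to-endpoint distances are
#' equal to within 1e-9.  Rooting an already-midpoint-rooted tree returns
#' it unchanged.  If all branch lengths are zero the tree is rooted at
#' the first internal node with a warning.
#'
#' @param tree a \code{phylo} with at least 2 leaves and branch lengths.
#' @return A rooted \code{phylo}.
#' @export
midpointRoot <- function(tree) {
    ntip <- ape::Ntip(tree)
    if (ntip < 2L) stop("need at least 2 leaves")
    if (is.null(tree$edge.length)) stop("tree must have branch lengths")
    if (ntip == 2L) {
        d <- sum(tree$edge.length)
        return(structure(list(
            edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
            edge.length = c(d / 2, d / 2), Nnode = 1L,
            tip.label = tree$tip.label), class = "phylo",
            order = "cladewise"))
    }
    if (all(tree$edge.length <= 0)) {
        warning("all branch lengths are zero; rooting at first internal node")
        if (ape::is.rooted(tree)) return(tree)
        return(ape::root(tree, node = ntip + 1L, resolve.root = TRUE))
    }
    D <- ape::dist.nodes(tree)
    tipD <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
    maxd <- max(tipD)
    cand <- which(tipD >= maxd - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    labs <- tree$tip.label
    keys <- apply(cand, 1L, function(r) {
        p <- sort(c(labs[r[1L]], labs[r[2L]]))
        paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    ## walk from the lexicographically smaller endpoint
    ab <- pick[order(labs[pick])]
    a <- ab[[1L]]; b <- ab[[2L]]
    path <- ape::nodepath(tree, a, b)
    steps <- vapply(seq_len(length(path) - 1L), function(i)
        D[path[i], path[i + 1L]], 0)
    cum <- c(0, cumsum(steps))
    half <- maxd / 2
    tol <- 1e-9
    atNode <- which(abs(cum - half) < tol)
    if (length(atNode)) {
        node <- path[atNode[1L]]
        root <- ntip + 1L
        if (ape::is.rooted(tree) && node == root) return(tree)
        tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
        ## node numbers are preserved for tips; recompute path on tr
        return(.rootAtNode(tr, a, b, half))
    }
    tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
    .rootOnPath(tr, a, b, half)
}

## root `tr` (unrooted) on the a--b path at distance `half` from tip a,
## when the midpoint coincides with a node: re-root on the path edge
## entering that node, at the node's end (avoids the ambiguity of
## resolving a basal multifurcation as the root)
.rootAtNode <- function(tr, a, b, half) {
    D <- ape::dist.nodes(tr)
    path <- ape::nodepath(tr, a, b)
    cum <- c(0, cumsum(vapply(seq_len(length(path) - 1L), function(i)
        D[path[i], path[i + 1L]], 0)))
    i <- which.min(abs(cum - half))
    node <- path[i]
    nb <- if (i > 1L) path[i - 1L] else path[i + 1L]
    row <- which(tr$edge[, 1L] == nb & tr$edge[, 2L] == node)
    if (length(row)) {
        phytools::reroot(tr, node, position = tr$edge.length[row])
    } else {
        row <- which(tr$edge[, 1L] == node & tr$edge[, 2L] == nb)
        phytools::reroot(tr, nb, position = 0)
    }
}

## root `tr` (unrooted) on the a--b path at distance `half` from tip a,
## inside an edge
.rootOnPath <- function(tr, a, b, half) {
    D <- ape::dist.nodes(tr)
    path <- ape::nodepath(tr, a, b)
    steps <- vapply(seq_len(length(path) - 1L), function(i)
        D[path[i], path[i + 1L]], 0)
    cum <- c(0, cumsum(steps))
    k <- max(which(cum < half))
    u <- path[k]; v <- path[k + 1L]
    offset <- half - cum[k]          # distance from u toward v
    row <- which(tr$edge[, 1L] == u & tr$edge[, 2L] == v)
    if (length(row)) {
        child <- v
        pos <- offset                # from the ancestral (edge[,1]) end
    } else {
        row <- which(tr$edge[, 1L] == v & tr$edge[, 2L] == u)
        child <- u
        pos <- tr$edge.length[row] - offset
    }
    out <- phytools::reroot(tr, child, position = pos)
    out
}
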