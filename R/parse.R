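#' Paralogy index of a set of cluster members
#'
#' Average number of member sequences per genome: |sequences| /
#' |distinct genomes|.  Always at least 1.
#'
#' @param genomes character vector, the genome id of each member (one
#'   entry per sequence).
#' @return A number >= 1.
#' @export
#' @examples
#' paralogyIndex(c("g1", "g1", "g2"))  # 1.5
paralogyIndex <- function(genomes) {
    if (!length(genomes)) stop("empty member set")
    length(genomes) / length(unique(genomes))
}

## decomposition objective: taxonomic coverage / paralogy index
## = |genomes|^2 / |sequences|
.coverageRatio <- function(leafGenomes) {
    length(unique(leafGenomes))^2 / length(leafGenomes)
}

#' Parse a rooted gene tree into low-paralogy subtrees
#'
#' Recursively decomposes a rooted gene tree, maximising the ratio of
#' taxonomic coverage (number of distinct genomes) to the paralogy index
#' (sequences per genome); for a leaf set S the objective is
#' |genomes(S)|^2 / |S|.  At each step, every possible edge cut
#' (equivalently, every non-root node's clade C against its complement)
#' is scored; if no cut improves the ratio of both parts over the current
#' tree, the current leaves are emitted as one cluster.  Otherwise the
#' cut maximising min(ratio(C), ratio(complement)) is applied (ties: the
#' larger clade, then the smallest leaf label) and both parts are parsed
#' recursively.  Every input leaf appears in exactly one output part.
#'
#' @param tree rooted \code{phylo}; leaves are cluster member ids.
#' @param genomeMap named character mapping member id to genome id.
#' @return A list of character vectors of member ids (sorted), one per
#'   output subtree.
#' @export
parseSubtrees <- function(tree, genomeMap) {
    if (!all(tree$tip.label %in% names(genomeMap)))
        stop("every leaf needs a genome in genomeMap")
    .parseRec(tree, genomeMap)
}

.parseRec <- function(tr, gm) {
    if (is.character(tr)) return(list(sort(tr)))
    leaves <- tr$tip.label
    if (length(leaves) == 1L) return(list(leaves))
    rcur <- .coverageRatio(gm[leaves])
    ntip <- ape::Ntip(tr)
    root <- ntip + 1L
    nodes <- setdiff(seq_len(ntip + tr$Nnode), root)
    best <- NULL
    for (v in nodes) {
        cl <- tr$tip.label[.cladeTips(tr, v)]
        if (length(cl) == length(leaves)) next
        comp <- setdiff(leaves, cl)
        rc <- .coverageRatio(gm[cl])
        rk <- .coverageRatio(gm[comp])
        if (rc > rcur && rk > rcur) {
            m <- min(rc, rk)
            cand <- list(node = v, cl = cl, comp = comp, m = m,
                         size = length(cl), lab = min(cl))
            if (is.null(best) ||
                m > best$m ||
                (m == best$m && (cand$size > best$size ||
                 (cand$size == best$size && cand$lab < best$lab))))
                best <- cand
        }
    }
    if (is.null(best)) return(list(sort(leaves)))
    subC <- if (length(best$cl) == 1L) best$cl
            else ape::extract.clade(tr, best$node)
    subK <- if (length(best$comp) == 1L) best$comp
            else ape::drop.tip(tr, best$cl)
    c(.parseRec(subC, gm), .parseRec(subK, gm))
}

#' Iteratively refine a ClusterSet
#'
#' Each iteration (i) aligns all clusters, (ii) merges clusters showing
#' full-length profile similarity, and (iii) for every cluster with at
#' least two members builds a gene tree, roots it at the midpoint, and
#' parses it into low-paralogy subtrees; clusters whose parse yields more
#' than one part are split (parts of size one become singletons).
#' Iteration stops when a round performs zero merges and zero splits, or
#' after \code{maxIterations} rounds.  The per-round operation counts are
#' recorded in \code{metadata} as \code{refinementLog}.
#'
#' @param cs a \code{\linkS4class{ClusterSet}} with sequences attached
#'   (see \code{\link{attachSequences}}).
#' @param maxIterations maximum number of refinement rounds; 0 returns
#'   the input unchanged.
#' @param minSpan,minScorePerColumn merge thresholds, see
#'   \code{\link{mergeFullLength}}.
#' @param aligner,treeBuilder optional external-tool hooks.
#' @return The refined \code{ClusterSet}.
#' @export
refineClusters <- function(cs, maxIterations = 5L, minSpan = 0.8,
                           minScorePerColumn = 0.5, aligner = NULL,
                           treeBuilder = NULL) {
    log <- data.frame(iteration = integer(0), merges = integer(0),
                      splits = integer(0))
    if (maxIterations >= 1L) {
        for (iter in seq_len(maxIterations)) {
            cs <- .ensureAlignments(cs, aligner)
            cs <- mergeFullLength(cs, minSpan = minSpan,
                                  minScorePerColumn = minScorePerColumn,
                                  aligner = aligner)
            nm <- cs@metadata$lastMerges
            newClusters <- list(); newAln <- list()
            nsplit <- 0L
            singles <- cs@singletons
            for (id in names(cs@clusters)) {
                mem <- cs@clusters[[id]]
                if (length(mem) < 2L) {
                    newClusters[[id]] <- mem
                    newAln[[id]] <- cs@alignments[[id]]
                    next
                }
                gtree <- buildGeneTree(cs@alignments[[id]],
                                       treeBuilder = treeBuilder)
                rooted <- midpointRoot(gtree)
                parts <- parseSubtrees(rooted, cs@genomeMap)
                if (length(parts) == 1L) {
                    newClusters[[id]] <- mem
                    newAln[[id]] <- cs@alignments[[id]]
                } else {
                    nsplit <- nsplit + 1L
                    pk <- 0L
                    for (p in parts) {
                        if (length(p) == 1L) {
                            singles <- c(singles, p)
                        } else {
                            pk <- pk + 1L
                            newClusters[[sprintf("%s.%d", id, pk)]] <- p
                        }
                    }
                }
            }
            cs <- ClusterSet(clusters = newClusters,
                             genomeMap = cs@genomeMap,
                             singletons = sort(singles),
                             alignments = newAln,
                             metadata = cs@metadata)
            log <- rbind(log, data.frame(iteration = iter, merges = nm,
                                         splits = nsplit))
            if (nm == 0L && nsplit == 0L) break
        }
    }
    cs@metadata$refinementLog <- log
    cs
}
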