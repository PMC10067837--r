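## column residue-frequency matrix (20 x L) of an MSA; frequencies are
## over non-gap residues of each column ('X' and other ambiguity codes
## are ignored); all-gap columns are all-zero
.profileFreqs <- function(msa) {
    cm <- Biostrings::consensusMatrix(msa)
    keep <- intersect(rownames(cm), .AA20)
    f <- matrix(0, nrow = 20L, ncol = ncol(cm),
                dimnames = list(.AA20, NULL))
    f[keep, ] <- cm[keep, , drop = FALSE]
    tot <- colSums(f)
    nz <- tot > 0
    f[, nz] <- sweep(f[, nz, drop = FALSE], 2L, tot[nz], "/")
    f
}

#' Profile-profile similarity of two cluster alignments
#'
#' Each MSA is summarised as per-column residue-frequency vectors; the
#' score of aligning column a to column b is
#' \code{sum_xy f_a(x) f_b(y) BLOSUM62(x, y)}.  The two profiles are
#' aligned globally with a linear per-column gap penalty, and the
#' function reports the total alignment score together with the mutual
#' span coverage: the minimum over the two profiles of (aligned columns /
#' profile length).
#'
#' @param msaA,msaB non-empty \code{AAStringSet} alignments.
#' @param gapPenalty per-column gap penalty of the profile alignment.
#' @return A list with \code{score}, \code{mutual_span_coverage}, and
#'   \code{aligned_columns}.
#' @export
profileSimilarity <- function(msaA, msaB, gapPenalty = 5) {
    if (!length(msaA) || !length(msaB))
        stop("both MSAs must be non-empty")
    fa <- .profileFreqs(msaA)
    fb <- .profileFreqs(msaB)
    B62 <- blosum62()[.AA20, .AA20]
    S <- t(fa) %*% B62 %*% fb          # LA x LB column-pair scores
    la <- nrow(S); lb <- ncol(S)
    ## global DP with linear gaps; the running-max trick vectorises the
    ## serial left-neighbour dependence within each row
    M <- matrix(-Inf, la + 1L, lb + 1L)
    M[1L, ] <- -gapPenalty * (0:lb)
    M[, 1L] <- -gapPenalty * (0:la)
    jj <- seq_len(lb)
    for (i in seq_len(la)) {
        cand <- pmax(M[i, jj] + S[i, ], M[i, jj + 1L] - gapPenalty)
        a <- c(M[i + 1L, 1L], cand) + gapPenalty * (0:lb)
        M[i + 1L, ] <- cummax(a) - gapPenalty * (0:lb)
    }
    ## traceback, preferring diagonal, then up, then left
    i <- la; j <- lb; aligned <- 0L
    tol <- 1e-9
    while (i > 0L && j > 0L) {
        v <- M[i + 1L, j + 1L]
        if (abs(v - (M[i, j] + S[i, j])) < tol) {
            aligned <- aligned + 1L
            i <- i - 1L; j <- j - 1L
        } else if (abs(v - (M[i, j + 1L] - gapPenalty)) < tol) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
    }
    list(score = M[la + 1L, lb + 1L],
         mutual_span_coverage = min(aligned / la, aligned / lb),
         aligned_columns = aligned)
}

## degapped consensus strings of all cluster alignments
.clusterConsensi <- function(cs) {
    vapply(names(cs@clusters), function(id) {
        gsub("-", "", consensusSequence(cs@alignments[[id]]), fixed = TRUE)
    }, "")
}

#' Merge clusters displaying full-length profile similarity
#'
#' Builds a merge graph over aligned clusters: an edge connects two
#' clusters when their profile alignment has mutual span coverage at
#' least \code{minSpan} and score per aligned column at least
#' \code{minScorePerColumn}.  Connected components are merged into single
#' clusters (re-aligned), implementing the merging of clusters that are
#' similar over their full length.  Candidate pairs are prefiltered by
#' shared k-mers between cluster consensus sequences.
#'
#' @param cs a \code{\linkS4class{ClusterSet}} with alignments (aligned
#'   on demand if sequences are attached).
#' @param minSpan minimum mutual span coverage.
#' @param minScorePerColumn minimum score per aligned column.
#' @param k consensus k-mer size of the candidate prefilter.
#' @param aligner optional external aligner hook (see
#'   \code{\link{alignCluster}}).
#' @return The merged \code{ClusterSet}; the number of merge operations
#'   is recorded in \code{metadata(...)$lastMerges} (a merged component
#'   of c clusters counts as c - 1 merges).
#' @export
mergeFullLength <- function(cs, minSpan = 0.8, minScorePerColumn = 0.5,
                            k = 5L, aligner = NULL) {
    if (!length(cs@clusters)) {
        cs@metadata$lastMerges <- 0L
        return(cs)
    }
    cs <- .ensureAlignments(cs, aligner)
    ids <- names(cs@clusters)
    cons <- .clusterConsensi(cs)
    pairs <- .kmerCandidatePairs(Biostrings::AAStringSet(cons), k = k)
    edges <- matrix(integer(0), ncol = 2L)
    if (nrow(pairs)) {
        ok <- logical(nrow(pairs))
        for (r in seq_len(nrow(pairs))) {
            ps <- profileSimilarity(cs@alignments[[pairs[r, 1L]]],
                                    cs@alignments[[pairs[r, 2L]]])
            ok[r] <- ps$mutual_span_coverage >= minSpan &&
                ps$aligned_columns > 0L &&
                ps$score / ps$aligned_columns >= minScorePerColumn
        }
        edges <- pairs[ok, , drop = FALSE]
    }
    if (!nrow(edges)) {
        cs@metadata$lastMerges <- 0L
        return(cs)
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = ids[edges[, 1L]], to = ids[edges[, 2L]]),
        directed = FALSE, vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    newClusters <- list(); newAln <- list()
    nMerges <- 0L
    for (cn in unique(comp)) {
        grp <- sort(ids[comp == cn])
        newId <- grp[1L]
        mem <- sort(unique(unlist(cs@clusters[grp], use.names = FALSE)))
        newClusters[[newId]] <- mem
        if (length(grp) > 1L) {
            nMerges <- nMerges + length(grp) - 1L
            seqs <- cs@metadata$sequences
            newAln[[newId]] <- alignCluster(seqs[mem], aligner = aligner)
        } else {
            newAln[[newId]] <- cs@alignments[[newId]]
        }
    }
    ord <- order(names(newClusters))
    out <- ClusterSet(clusters = newClusters[ord],
                      genomeMap = cs@genomeMap,
                      singletons = cs@singletons,
                      alignments = newAln[ord],
                      metadata = cs@metadata)
    out@metadata$lastMerges <- nMerges
    out
}
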