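## sequences from a GenomeSet or a plain AAStringSet
.asSeqs <- function(x) {
    if (is(x, "GenomeSet")) return(x@proteins)
    if (is(x, "AAStringSet")) return(x)
    stop("expected a GenomeSet or AAStringSet")
}

## candidate unordered pairs (i < j, integer indices) sharing >= 1 k-mer
.kmerCandidatePairs <- function(seqs, k = 5L) {
    n <- length(seqs)
    chars <- as.character(seqs)
    lens <- nchar(chars)
    idx <- rep.int(seq_len(n), pmax(lens - k + 1L, 0L))
    starts <- unlist(lapply(pmax(lens - k + 1L, 0L), seq_len),
                     use.names = FALSE)
    kmers <- substring(chars[idx], starts, starts + k - 1L)
    ## dedupe (sequence, kmer) so repeats within one sequence don't
    ## inflate the group lists
    keep <- !duplicated(paste0(idx, "\r", kmers))
    groups <- split(idx[keep], kmers[keep])
    groups <- groups[lengths(groups) > 1L]
    if (!length(groups)) {
        pairs <- matrix(integer(0), ncol = 2L)
    } else {
        pl <- lapply(groups, function(g) {
            g <- sort.int(g)
            cbind(rep(g, rev(seq_along(g)) - 1L),
                  g[unlist(lapply(seq_along(g)[-1L],
                                  function(i) i:length(g)))])
        })
        pairs <- unique(do.call(rbind, pl))
    }
    ## sequences shorter than k can never seed; pair them with everything
    short <- which(lens < k)
    if (length(short) && n > 1L) {
        extra <- do.call(rbind, lapply(short, function(i) {
            j <- setdiff(seq_len(n), i)
            cbind(pmin(i, j), pmax(i, j))
        }))
        pairs <- unique(rbind(pairs, extra))
    }
    pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' All-versus-all protein similarity search
#'
#' Finds similar protein pairs by k-mer prefiltered Smith-Waterman local
#' alignment under BLOSUM62 (gap open 11, extend 1).  A hit is emitted
#' only if the fractional identity over aligned columns is at least
#' \code{minIdentity} and the aligned span covers at least
#' \code{minCoverage} of \emph{both} sequences.  The hit list is
#' symmetric (every pair appears in both orientations) and contains no
#' self-hits.
#'
#' @param x a \code{\linkS4class{GenomeSet}} or named \code{AAStringSet}
#'   with at least two proteins.
#' @param minIdentity minimum identity fraction in [0, 1].
#' @param minCoverage minimum coverage fraction of each sequence.
#' @param k k-mer size of the prefilter; pairs sharing no k-mer are never
#'   aligned.  Set \code{prefilter = FALSE} to align every pair.
#' @param prefilter logical; disable to perform exhaustive alignment.
#' @return data.frame with columns \code{query_id}, \code{target_id},
#'   \code{identity}, \code{query_coverage}, \code{target_coverage},
#'   \code{score}.
#' @export
allVsAllSimilarity <- function(x, minIdentity = 0.5, minCoverage = 0.5,
                               k = 5L, prefilter = TRUE) {
    seqs <- .asSeqs(x)
    if (length(seqs) < 2L)
        stop("need at least two proteins")
    n <- length(seqs)
    if (prefilter) {
        pairs <- .kmerCandidatePairs(seqs, k = k)
    } else {
        i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
        j <- unlist(lapply(seq_len(n - 1L) + 1L,
                           function(s) s:n), use.names = FALSE)
        pairs <- cbind(i, j)
    }
    ids <- names(seqs)
    wid <- Biostrings::width(seqs)
    out <- vector("list", 0L)
    if (nrow(pairs)) {
        B62 <- blosum62()
        ## batch by the second member of each pair (the subject)
        bySubject <- split(pairs[, 1L], pairs[, 2L])
        res <- lapply(names(bySubject), function(jc) {
            jj <- as.integer(jc)
            ii <- bySubject[[jc]]
            aln <- Biostrings::pairwiseAlignment(
                seqs[ii], seqs[[jj]], substitutionMatrix = B62,
                gapOpening = 11, gapExtension = 1, type = "local")
            pat <- Biostrings::pattern(aln)
            sub <- Biostrings::subject(aln)
            data.frame(
                i = ii, j = jj,
                identity = Biostrings::pid(aln, "PID1") / 100,
                cov_i = (end(pat) - start(pat) + 1L) / wid[ii],
                cov_j = (end(sub) - start(sub) + 1L) / wid[jj],
                score = Biostrings::score(aln))
        })
        hits <- do.call(rbind, res)
        keep <- hits$identity >= minIdentity &
            hits$cov_i >= minCoverage & hits$cov_j >= minCoverage
        hits <- hits[keep, , drop = FALSE]
        if (nrow(hits)) {
            fwd <- data.frame(query_id = ids[hits$i],
                              target_id = ids[hits$j],
                              identity = hits$identity,
                              query_coverage = hits$cov_i,
                              target_coverage = hits$cov_j,
                              score = hits$score,
                              stringsAsFactors = FALSE)
            rev <- data.frame(query_id = ids[hits$j],
                              target_id = ids[hits$i],
                              identity = hits$identity,
                              query_coverage = hits$cov_j,
                              target_coverage = hits$cov_i,
                              score = hits$score,
                              stringsAsFactors = FALSE)
            out <- rbind(fwd, rev)
        }
    }
    if (!length(out))
        out <- data.frame(query_id = character(0),
                          target_id = character(0),
                          identity = numeric(0),
                          query_coverage = numeric(0),
                          target_coverage = numeric(0),
                          score = numeric(0), stringsAsFactors = FALSE)
    out <- out[order(out$query_id, out$target_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Greedy clustering of similarity hits
#'
#' Proteins are sorted by decreasing length (ties by id); the longest
#' unassigned protein becomes a centroid and absorbs every unassigned
#' protein it has a hit with.  Proteins ending up alone are excluded from
#' the cluster set and kept as singletons.
#'
#' @param hits symmetric hit table from \code{\link{allVsAllSimilarity}}.
#' @param x the \code{\linkS4class{GenomeSet}} the hits were computed on.
#' @return A \code{\linkS4class{ClusterSet}}; the singleton count is
#'   available via \code{length(singletons(result))}.
#' @export
greedyCluster <- function(hits, x) {
    seqs <- .asSeqs(x)
    ids <- names(seqs)
    gmap <- if (is(x, "GenomeSet")) genomeIds(x) else
        setNames(rep(NA_character_, length(ids)), ids)
    ord <- ids[order(-Biostrings::width(seqs), ids)]
    adj <- split(hits$target_id, hits$query_id)
    assigned <- setNames(rep(FALSE, length(ids)), ids)
    clusters <- list()
    single <- character(0)
    cid <- 0L
    for (p in ord) {
        if (assigned[[p]]) next
        nb <- adj[[p]]
        nb <- nb[!is.na(nb) & !assigned[nb] & nb != p]
        if (!length(nb)) {
            assigned[[p]] <- TRUE
            single <- c(single, p)
            next
        }
        cid <- cid + 1L
        mem <- c(p, sort(unique(nb)))
        assigned[mem] <- TRUE
        clusters[[sprintf("C%05d", cid)]] <- mem
    }
    ClusterSet(clusters = clusters, genomeMap = gmap,
               singletons = sort(single))
}
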