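## global pairwise alignment of two AAStrings; returns the two aligned
## (gapped) character strings
.globalPair <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1, type = "global")
    list(a = as.character(Biostrings::alignedPattern(aln)),
         b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln))
}

#' Align the members of a cluster (center-star progressive alignment)
#'
#' The center is the member with the maximum summed pairwise global
#' alignment score against all other members (BLOSUM62, gap open 11,
#' extend 1; ties broken by smallest protein id).  Every other member is
#' aligned to the center and the pairwise gap patterns are merged into a
#' single MSA, so that de-gapping any row reproduces the member sequence.
#' An external aligner can be plugged in instead via \code{aligner}.
#'
#' @param seqs named \code{AAStringSet} of cluster members (non-empty).
#' @param aligner optional function \code{AAStringSet -> AAStringSet}
#'   returning an equal-width gapped alignment (e.g. a wrapper around an
#'   external MSA tool); when given, it replaces the internal algorithm.
#' @return \code{AAStringSet} MSA in the input row order.
#' @export
alignCluster <- function(seqs, aligner = NULL) {
    if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
    if (!length(seqs)) stop("cluster must be non-empty")
    if (!is.null(aligner)) return(aligner(seqs))
    n <- length(seqs)
    if (n == 1L) return(seqs)
    B62 <- blosum62()
    if (n == 2L) {
        pr <- .globalPair(seqs[[1L]], seqs[[2L]])
        return(Biostrings::AAStringSet(
            setNames(c(pr$a, pr$b), names(seqs))))
    }
    ## summed pairwise global scores -> center
    tot <- numeric(n)
    for (i in seq_len(n - 1L)) {
        sc <- Biostrings::pairwiseAlignment(
            seqs[(i + 1L):n], seqs[[i]], substitutionMatrix = B62,
            gapOpening = 11, gapExtension = 1, type = "global",
            scoreOnly = TRUE)
        tot[i] <- tot[i] + sum(sc)
        tot[(i + 1L):n] <- tot[(i + 1L):n] + sc
    }
    best <- which(tot == max(tot))
    center <- best[order(names(seqs)[best])][1L]
    others <- setdiff(seq_len(n), center)
    ## align everyone to the center in one vectorized call
    aln <- Biostrings::pairwiseAlignment(
        seqs[others], seqs[[center]], substitutionMatrix = B62,
        gapOpening = 11, gapExtension = 1, type = "global")
    cstrs <- as.character(Biostrings::alignedSubject(aln))
    mstrs <- as.character(Biostrings::alignedPattern(aln))
    m <- Biostrings::width(seqs)[center]
    ## ins[[i]][j+1] = gaps inserted before center residue j+1 (slot j)
    slotOf <- function(cstr) {
        cc <- strsplit(cstr, "", fixed = TRUE)[[1L]]
        isres <- cc != "-"
        slot <- cumsum(isres)        # 0..m; gaps before residue j+1 get j
        tab <- tabulate(slot[!isres] + 1L, nbins = m + 1L)
        list(slot = slot, ins = tab)
    }
    parsed <- lapply(cstrs, slotOf)
    master <- Reduce(pmax, lapply(parsed, `[[`, "ins"))
    pad <- function(str, k) paste0(strrep("-", k), str)
    ## center row
    cres <- strsplit(as.character(seqs[[center]]), "", fixed = TRUE)[[1L]]
    centerRow <- paste0(
        paste0(vapply(seq_len(m), function(j)
            paste0(strrep("-", master[j]), cres[j]), "") , collapse = ""),
        strrep("-", master[m + 1L]))
    rows <- character(n)
    rows[center] <- centerRow
    for (ii in seq_along(others)) {
        p <- parsed[[ii]]
        mm <- strsplit(mstrs[ii], "", fixed = TRUE)[[1L]]
        cc <- strsplit(cstrs[ii], "", fixed = TRUE)[[1L]]
        segs <- character(m + 1L)
        resAt <- character(m)
        gappos <- which(cc == "-")
        if (length(gappos)) {
            bySlot <- split(mm[gappos], p$slot[gappos])
            for (s in names(bySlot))
                segs[as.integer(s) + 1L] <-
                    paste0(bySlot[[s]], collapse = "")
        }
        respos <- which(cc != "-")
        resAt <- mm[respos]
        pieces <- character(2L * m + 1L)
        for (j in seq_len(m)) {
            pieces[2L * j - 1L] <- pad(segs[j],
                                       master[j] - nchar(segs[j]))
            pieces[2L * j] <- resAt[j]
        }
        pieces[2L * m + 1L] <- pad(segs[m + 1L],
                                   master[m + 1L] - nchar(segs[m + 1L]))
        rows[others[ii]] <- paste0(pieces, collapse = "")
    }
    Biostrings::AAStringSet(setNames(rows, names(seqs)))
}

## ensure every cluster of a ClusterSet has a stored alignment
.ensureAlignments <- function(cs, aligner = NULL) {
    seqs <- cs@metadata$sequences
    if (is.null(seqs))
        stop("ClusterSet carries no sequences; use attachSequences()")
    for (id in names(cs@clusters)) {
        if (is.null(cs@alignments[[id]]))
            cs@alignments[[id]] <- alignCluster(seqs[cs@clusters[[id]]],
                                                aligner = aligner)
    }
    cs
}

#' Attach the underlying protein sequences to a ClusterSet
#'
#' Alignment, refinement and AAI computations need the raw sequences;
#' this stores the relevant \code{AAStringSet} in the ClusterSet's
#' metadata.
#'
#' @param cs a \code{\linkS4class{ClusterSet}}
#' @param x a \code{\linkS4class{GenomeSet}} or \code{AAStringSet}
#'   containing (at least) all member and singleton proteins.
#' @return The updated \code{ClusterSet}.
#' @export
attachSequences <- function(cs, x) {
    cs@metadata$sequences <- .asSeqs(x)
    cs
}
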