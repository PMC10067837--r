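#' Consensus sequence of an MSA
#'
#' Per column, the most frequent non-gap residue, ties broken
#' alphabetically; columns containing only gaps yield a gap.
#'
#' @param msa non-empty \code{AAStringSet} alignment.
#' @return A single character string of the alignment width.
#' @export
consensusSequence <- function(msa) {
    if (!length(msa)) stop("MSA must be non-empty")
    cm <- Biostrings::consensusMatrix(msa)
    res <- sort(setdiff(rownames(cm), "-"))
    if (!length(res)) return(strrep("-", ncol(cm)))
    sub <- cm[res, , drop = FALSE]
    top <- apply(sub, 2L, function(col) {
        if (all(col == 0)) "-" else res[which.max(col)]
    })
    paste0(top, collapse = "")
}

#' Select universal low-paralogy marker clusters
#'
#' Returns the clusters in which every genome is present (copy count at
#' least 1) and the number of paralogs beyond one-per-genome does not
#' exceed \code{maxExtraParalogs}.  By default "extra paralogs" counts
#' the total extra sequences across all genomes
#' (\code{sum(counts) - nGenomes}); with \code{perGenome = TRUE} the
#' bound applies to each genome separately (\code{count - 1 <=
#' maxExtraParalogs} for every genome).
#'
#' @param mat phyletic copy-count matrix, clusters x genomes.
#' @param genomes genomes that must all be present; default all columns.
#' @param maxExtraParalogs the paralog budget.
#' @param perGenome apply the budget per genome instead of in total.
#' @return Character vector of selected cluster ids.
#' @export
selectMarkers <- function(mat, genomes = colnames(mat),
                          maxExtraParalogs = 4L, perGenome = FALSE) {
    sub <- mat[, genomes, drop = FALSE]
    full <- rowSums(sub >= 1L) == length(genomes)
    ok <- if (perGenome) {
        apply(sub, 1L, max) - 1L <= maxExtraParalogs
    } else {
        rowSums(sub) - length(genomes) <= maxExtraParalogs
    }
    rownames(mat)[full & ok]
}

#' Select the index ortholog of a genome in a cluster
#'
#' Among the genome's members, returns the one maximising the BLOSUM62
#' score against the alignment consensus, summed over columns where both
#' the member and the consensus have a residue (gap columns contribute
#' 0).  Ties are broken by the smallest protein id.
#'
#' @param msa cluster alignment (\code{AAStringSet}).
#' @param genomeId the genome to pick a representative for.
#' @param genomeMap named character, protein id to genome id.
#' @return The protein id of the index ortholog.
#' @export
selectIndexOrtholog <- function(msa, genomeId, genomeMap) {
    rows <- names(msa)[genomeMap[names(msa)] == genomeId]
    rows <- rows[!is.na(rows)]
    if (!length(rows)) stop("genome ", genomeId, " absent from cluster")
    if (length(rows) == 1L) return(rows)
    cons <- strsplit(consensusSequence(msa), "", fixed = TRUE)[[1L]]
    B62 <- blosum62()
    sc <- vapply(rows, function(r) {
        s <- strsplit(as.character(msa[[r]]), "", fixed = TRUE)[[1L]]
        use <- s != "-" & cons != "-"
        if (!any(use)) return(0)
        sum(B62[cbind(s[use], cons[use])])
    }, 0)
    rows[order(-sc, rows)][1L]
}

#' Column homogeneity relative to the consensus residue
#'
#' For a column with consensus residue c, homogeneity is the mean over
#' non-gap residues r of BLOSUM62(r, c) / BLOSUM62(c, c); it is at most 1
#' and equals 1 for a column uniformly equal to its consensus.  An
#' all-gap column has homogeneity 0 by convention.
#'
#' @param column character vector of residues and "-" gaps.
#' @param consensusResidue the consensus residue of the column; computed
#'   if missing.
#' @return A number <= 1.
#' @export
#' @examples
#' columnHomogeneity(c("A", "A", "W", "W"), "A")  # 0.125
columnHomogeneity <- function(column, consensusResidue = NULL) {
    if (!length(column)) stop("column must be non-empty")
    res <- column[column != "-"]
    if (!length(res)) return(0)
    if (is.null(consensusResidue)) {
        tab <- table(res)
        consensusResidue <- sort(names(tab)[tab == max(tab)])[1L]
    }
    B62 <- blosum62()
    mean(B62[res, consensusResidue]) / B62[consensusResidue,
                                           consensusResidue]
}

#' Filter alignment columns by gap fraction and homogeneity
#'
#' Keeps columns whose gap fraction is at most \code{maxGapFraction} and
#' whose homogeneity (see \code{\link{columnHomogeneity}}) is at least
#' \code{minHomogeneity}; column order is preserved.  The numbers of
#' kept and removed columns are recorded as attributes \code{kept} and
#' \code{removed}.
#'
#' @param msa non-empty \code{AAStringSet} alignment.
#' @param maxGapFraction maximum allowed fraction of gaps per column.
#' @param minHomogeneity minimum column homogeneity.
#' @return The filtered \code{AAStringSet} (possibly of width 0, with a
#'   warning if every column was removed).
#' @export
filterColumns <- function(msa, maxGapFraction = 0.667,
                          minHomogeneity = 0.05) {
    if (!length(msa)) stop("MSA must be non-empty")
    chars <- .msaMatrix(msa)
    nc <- ncol(chars)
    gapFrac <- colMeans(chars == "-")
    hom <- vapply(seq_len(nc), function(j)
        columnHomogeneity(chars[, j]), 0)
    keep <- gapFrac <= maxGapFraction & hom >= minHomogeneity
    if (!any(keep)) {
        warning("all columns removed by filtering")
        out <- Biostrings::AAStringSet(setNames(rep("", length(msa)),
                                                names(msa)))
    } else {
        out <- Biostrings::AAStringSet(apply(
            chars[, keep, drop = FALSE], 1L, paste0, collapse = ""))
        names(out) <- names(msa)
    }
    attr(out, "kept") <- sum(keep)
    attr(out, "removed") <- nc - sum(keep)
    out
}

## MSA as a rows x columns character matrix
.msaMatrix <- function(msa) {
    w <- Biostrings::width(msa)
    if (length(unique(w)) != 1L) stop("MSA rows must have equal length")
    t(vapply(as.character(msa),
             function(s) strsplit(s, "", fixed = TRUE)[[1L]],
             character(w[1L])))
}

#' Concatenate filtered marker alignments into a supermatrix
#'
#' For each genome, the index-ortholog rows of the selected clusters are
#' concatenated in sorted cluster-id order; the partition map records
#' each cluster's column interval (0-based, half-open).
#'
#' @param markerIds cluster ids to concatenate (sorted internally).
#' @param msas named list of (filtered) cluster alignments.
#' @param indexMap named list: \code{indexMap[[clusterId]][[genome]]} is
#'   the index-ortholog protein id (a row name of the cluster MSA).
#' @param genomes character vector fixing the genome order of the rows.
#' @return A \code{\linkS4class{Supermatrix}}.
#' @export
concatenateMarkers <- function(markerIds, msas, indexMap, genomes) {
    markerIds <- sort(markerIds)
    rows <- setNames(rep("", length(genomes)), genomes)
    parts <- data.frame(cluster_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    pos <- 0L
    for (id in markerIds) {
        msa <- msas[[id]]
        if (is.null(msa)) stop("no alignment for cluster ", id)
        w <- if (length(msa)) Biostrings::width(msa)[1L] else 0L
        for (g in genomes) {
            p <- indexMap[[id]][[g]]
            if (is.null(p) || !p %in% names(msa))
                stop("missing index ortholog for cluster ", id,
                     ", genome ", g)
            rows[g] <- paste0(rows[g], as.character(msa[[p]]))
        }
        parts <- rbind(parts, data.frame(
            cluster_id = id, start = pos, end = pos + w,
            stringsAsFactors = FALSE))
        pos <- pos + w
    }
    new("Supermatrix",
        alignment = Biostrings::AAStringSet(rows),
        partitions = parts)
}

#' Build a supermatrix from a refined ClusterSet
#'
#' Convenience pipeline: select universal low-paralogy markers from the
#' phyletic matrix, pick each genome's index ortholog by consensus
#' BLOSUM62 score, filter the marker alignments by gap fraction and
#' homogeneity, and concatenate.
#'
#' @param cs a \code{\linkS4class{ClusterSet}} with sequences attached.
#' @param genomes genome order of the supermatrix rows; default all
#'   genomes in the cluster set, sorted.
#' @param maxExtraParalogs,perGenome marker selection parameters.
#' @param maxGapFraction,minHomogeneity column filter parameters.
#' @return A list: \code{supermatrix} (a
#'   \code{\linkS4class{Supermatrix}}), \code{markers} (selected cluster
#'   ids), \code{indexMap}, and \code{filterStats} (per-marker kept /
#'   removed column counts).
#' @export
buildSupermatrix <- function(cs, genomes = NULL, maxExtraParalogs = 4L,
                             perGenome = FALSE, maxGapFraction = 0.667,
                             minHomogeneity = 0.05) {
    if (is.null(genomes))
        genomes <- sort(unique(unname(cs@genomeMap)))
    mat <- phyleticMatrix(cs, genomes)
    markers <- selectMarkers(mat, genomes,
                             maxExtraParalogs = maxExtraParalogs,
                             perGenome = perGenome)
    if (!length(markers))
        stop("no marker clusters satisfy the selection criteria")
    cs <- .ensureAlignments(cs)
    indexMap <- list(); msas <- list()
    stats <- data.frame(cluster_id = character(0), kept = integer(0),
                        removed = integer(0), stringsAsFactors = FALSE)
    for (id in markers) {
        aln <- cs@alignments[[id]]
        im <- lapply(setNames(genomes, genomes), function(g)
            selectIndexOrtholog(aln, g, cs@genomeMap))
        filt <- filterColumns(aln, maxGapFraction = maxGapFraction,
                              minHomogeneity = minHomogeneity)
        indexMap[[id]] <- im
        msas[[id]] <- filt
        stats <- rbind(stats, data.frame(
            cluster_id = id, kept = attr(filt, "kept"),
            removed = attr(filt, "removed"), stringsAsFactors = FALSE))
    }
    sm <- concatenateMarkers(markers, msas, indexMap, genomes)
    list(supermatrix = sm, markers = markers, indexMap = indexMap,
         filterStats = stats)
}
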