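#' Average amino-acid identity (AAI) between two genomes
#'
#' Mean pairwise percent identity between the two genomes' index
#' orthologs, computed over aligned columns where both rows have a
#' residue, across all clusters containing both genomes.  Symmetric; in
#' (0, 100].
#'
#' @param cs a \code{\linkS4class{ClusterSet}} with sequences attached.
#' @param genomeA,genomeB genome ids.
#' @return AAI as a percentage.
#' @export
computeAAI <- function(cs, genomeA, genomeB) {
    gm <- cs@genomeMap
    shared <- Filter(function(id) {
        g <- gm[cs@clusters[[id]]]
        genomeA %in% g && genomeB %in% g
    }, names(cs@clusters))
    if (!length(shared))
        stop("genomes ", genomeA, " and ", genomeB,
             " share no clusters; AAI undefined")
    cs <- .ensureAlignments(cs)
    ids <- numeric(0)
    for (id in shared) {
        aln <- cs@alignments[[id]]
        pa <- selectIndexOrtholog(aln, genomeA, gm)
        pb <- selectIndexOrtholog(aln, genomeB, gm)
        sa <- strsplit(as.character(aln[[pa]]), "", fixed = TRUE)[[1L]]
        sb <- strsplit(as.character(aln[[pb]]), "", fixed = TRUE)[[1L]]
        use <- sa != "-" & sb != "-"
        if (!any(use)) next
        ids <- c(ids, mean(sa[use] == sb[use]))
    }
    if (!length(ids))
        stop("no aligned columns shared between ", genomeA, " and ",
             genomeB)
    100 * mean(ids)
}
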