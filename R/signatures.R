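## validate a clade definition against a phyletic matrix
.checkClade <- function(mat, clade, outgroup = NULL) {
    if (!length(clade)) stop("clade must be non-empty")
    if (!all(clade %in% colnames(mat)))
        stop("unknown clade genomes: ",
             paste(setdiff(clade, colnames(mat)), collapse = ", "))
    if (is.null(outgroup)) outgroup <- setdiff(colnames(mat), clade)
    if (length(intersect(clade, outgroup)))
        stop("clade and outgroup must be disjoint")
    outgroup
}

#' Clade core: families present in every clade genome
#'
#' @param mat phyletic matrix, families x genomes (copy counts or 0/1;
#'   presence is count >= 1).
#' @param clade character vector of clade genome ids.
#' @return Character vector of family ids.
#' @export
cladeCore <- function(mat, clade) {
    .checkClade(mat, clade)
    sub <- mat[, clade, drop = FALSE]
    rownames(mat)[rowSums(sub >= 1) == length(clade)]
}

#' Clade-specific gains: families universal in the clade, absent outside
#'
#' Families present in every clade genome and absent (count 0) from
#' every outgroup genome.
#'
#' @inheritParams cladeCore
#' @param outgroup outgroup genome ids; default the complement of the
#'   clade.
#' @return Character vector of family ids.
#' @export
cladeSpecificGains <- function(mat, clade, outgroup = NULL) {
    outgroup <- .checkClade(mat, clade, outgroup)
    if (!length(outgroup)) stop("outgroup must be non-empty")
    core <- cladeCore(mat, clade)
    absentOut <- rownames(mat)[
        rowSums(mat[, outgroup, drop = FALSE] >= 1) == 0]
    intersect(core, absentOut)
}

#' Clade-absent common genes: families missing from the clade that are
#' common outside it
#'
#' Families absent from every clade genome but present in at least
#' \code{commonFraction} of the outgroup genomes.
#'
#' @inheritParams cladeSpecificGains
#' @param commonFraction minimum fraction of outgroup genomes a family
#'   must be present in to count as "common".
#' @return Character vector of family ids.
#' @export
cladeAbsentCommon <- function(mat, clade, outgroup = NULL,
                              commonFraction = 0.667) {
    outgroup <- .checkClade(mat, clade, outgroup)
    if (!length(outgroup)) stop("outgroup must be non-empty")
    absentIn <- rowSums(mat[, clade, drop = FALSE] >= 1) == 0
    commonOut <- rowMeans(mat[, outgroup, drop = FALSE] >= 1) >=
        commonFraction
    rownames(mat)[absentIn & commonOut]
}

#' Ortholog coverage of one genome against a reference genome set
#'
#' Of all the genome's proteins (cluster members plus singletons), how
#' many sit in a cluster that also contains at least one genome from the
#' reference set.
#'
#' @param cs a \code{\linkS4class{ClusterSet}}.
#' @param genome the genome to assess.
#' @param referenceGenomes genomes an ortholog may come from (e.g. all
#'   genomes outside a focal clade).
#' @return A list with \code{n_with_ortholog} and \code{n_total}.
#' @export
orthologCoverage <- function(cs, genome, referenceGenomes) {
    gm <- cs@genomeMap
    if (!genome %in% gm) stop("unknown genome: ", genome)
    own <- names(gm)[gm == genome]
    nTotal <- length(own)
    nWith <- 0L
    for (id in names(cs@clusters)) {
        mem <- cs@clusters[[id]]
        gset <- unname(gm[mem])
        if (any(gset %in% referenceGenomes)) {
            nWith <- nWith + sum(mem %in% own)
        }
    }
    list(n_with_ortholog = nWith, n_total = nTotal)
}

#' Summary of clade signature statistics
#'
#' Runs the clade-level phyletic queries in one call: clade core size,
#' clade-specific gains, clade-absent common genes, and (optionally)
#' expected ancestral content at a node.
#'
#' @inheritParams cladeAbsentCommon
#' @param posteriors optional families x nodes posterior matrix; when
#'   given together with \code{ancestorNode}, the expected gene content
#'   of that ancestor is included.
#' @param ancestorNode node name of the clade ancestor.
#' @return A list of counts and id vectors.
#' @export
cladeSignatures <- function(mat, clade, outgroup = NULL,
                            commonFraction = 0.667, posteriors = NULL,
                            ancestorNode = NULL) {
    core <- cladeCore(mat, clade)
    gains <- cladeSpecificGains(mat, clade, outgroup)
    absent <- cladeAbsentCommon(mat, clade, outgroup, commonFraction)
    out <- list(core = core, gains = gains, absent = absent,
                n_core = length(core), n_gains = length(gains),
                n_absent = length(absent))
    if (!is.null(posteriors) && !is.null(ancestorNode)) {
        acs <- ancestralContentSize(posteriors, ancestorNode)
        out$ancestral_content <- acs$expected
        out$ancestral_content_rounded <- acs$rounded
    }
    out
}
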