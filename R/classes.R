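setOldClass("phylo")

#' GenomeSet: protein sequences grouped by genome
#'
#' Container for the proteomes of a set of genomes: an \code{AAStringSet}
#' of protein sequences (names are protein identifiers, unique across the
#' set) plus a parallel vector assigning each protein to its genome.
#'
#' @slot proteins \code{AAStringSet}; names are protein ids.
#' @slot genome character vector, same length, genome id of each protein.
#' @export
setClass("GenomeSet",
    representation(proteins = "AAStringSet", genome = "character"))

setValidity("GenomeSet", function(object) {
    n <- length(object@proteins)
    ids <- names(object@proteins)
    if (length(object@genome) != n)
        return("genome vector length must match number of proteins")
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        return("protein ids must be unique, non-empty names")
    if (n && any(Biostrings::width(object@proteins) == 0L))
        return("all sequences must be non-empty")
    TRUE
})

#' Construct a GenomeSet
#'
#' @param proteins \code{AAStringSet} named by protein id.
#' @param genome character vector of genome ids, one per protein.
#' @return A \code{GenomeSet}.
#' @export
GenomeSet <- function(proteins, genome) {
    new("GenomeSet", proteins = proteins,
        genome = as.character(genome))
}

#' @describeIn GenomeSet-class number of proteins
#' @param x,object a \code{GenomeSet}
#' @export
setMethod("length", "GenomeSet", function(x) length(x@proteins))

#' Accessors for GenomeSet
#'
#' \code{sequences} returns the protein \code{AAStringSet};
#' \code{proteinIds} the protein identifiers; \code{genomeIds} the genome
#' assignment of each protein (named by protein id); \code{genomeNames}
#' the sorted set of distinct genome ids.
#'
#' @param x a \code{GenomeSet}
#' @return See description.
#' @export
sequences <- function(x) x@proteins

#' @rdname sequences
#' @export
proteinIds <- function(x) names(x@proteins)

#' @rdname sequences
#' @export
genomeIds <- function(x) setNames(x@genome, names(x@proteins))

#' @rdname sequences
#' @export
genomeNames <- function(x) sort(unique(x@genome))

setMethod("show", "GenomeSet", function(object) {
    cat("GenomeSet with", length(object@proteins), "proteins from",
        length(unique(object@genome)), "genomes\n")
})

#' ClusterSet: a partition of proteins into orthologous clusters
#'
#' Holds the clusters (COGs) produced by greedy clustering and refinement:
#' a named list mapping cluster id to member protein ids, the genome of
#' every protein (members and singletons), optional per-cluster alignments,
#' and the singleton proteins that are excluded from clusters but retained
#' for ortholog-coverage accounting.
#'
#' @slot clusters named list; each element a character vector of protein ids.
#' @slot genomeMap named character; protein id to genome id, covering all
#'   cluster members and singletons.
#' @slot alignments named list of \code{AAStringSet} MSAs (or absent).
#' @slot singletons character vector of singleton protein ids.
#' @slot metadata list of bookkeeping (e.g. refinement log).
#' @export
setClass("ClusterSet",
    representation(clusters = "list", genomeMap = "character",
                   alignments = "list", singletons = "character",
                   metadata = "list"))

setValidity("ClusterSet", function(object) {
    ids <- names(object@clusters)
    if (length(object@clusters) && (is.null(ids) || anyDuplicated(ids)))
        return("cluster ids must be unique names")
    memb <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(memb))
        return("each protein may belong to at most one cluster")
    if (length(memb) && !all(memb %in% names(object@genomeMap)))
        return("every member must have a genome in genomeMap")
    if (length(object@singletons) &&
        !all(object@singletons %in% names(object@genomeMap)))
        return("every singleton must have a genome in genomeMap")
    if (any(memb %in% object@singletons))
        return("singletons must not also be cluster members")
    if (any(vapply(object@clusters, length, 1L) == 0L))
        return("clusters must be non-empty")
    aln <- names(object@alignments)
    if (length(object@alignments) && !all(aln %in% ids))
        return("alignments must be named by existing cluster ids")
    TRUE
})

#' Construct a ClusterSet
#'
#' @param clusters named list of character vectors (protein ids).
#' @param genomeMap named character, protein id to genome id.
#' @param singletons character vector of singleton protein ids.
#' @param alignments named list of MSAs (\code{AAStringSet}).
#' @param metadata list.
#' @return A \code{ClusterSet}.
#' @export
ClusterSet <- function(clusters = list(), genomeMap = character(),
                       singletons = character(), alignments = list(),
                       metadata = list()) {
    new("ClusterSet", clusters = clusters, genomeMap = genomeMap,
        alignments = alignments, singletons = as.character(singletons),
        metadata = metadata)
}

#' @describeIn ClusterSet-class number of clusters
#' @param x,object a \code{ClusterSet}
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

#' Accessors for ClusterSet
#'
#' \code{clusterIds} returns the cluster identifiers; \code{clusterMembers} the
#' member protein ids of one cluster; \code{clusterGenomes} the genome of
#' each member; \code{copyCounts} the per-genome copy-number table of one
#' cluster; \code{singletons} the singleton protein ids;
#' \code{clusterAlignment} the stored MSA of a cluster (or NULL).
#'
#' @param x a \code{ClusterSet}
#' @param id a cluster id
#' @return See description.
#' @export
clusterIds <- function(x) names(x@clusters)

#' @rdname clusterIds
#' @export
clusterMembers <- function(x, id) {
    m <- x@clusters[[id]]
    if (is.null(m)) stop("unknown cluster id: ", id)
    m
}

#' @rdname clusterIds
#' @export
clusterGenomes <- function(x, id) {
    m <- clusterMembers(x, id)
    setNames(unname(x@genomeMap[m]), m)
}

#' @rdname clusterIds
#' @export
copyCounts <- function(x, id) table(unname(clusterGenomes(x, id)))

#' @rdname clusterIds
#' @export
singletons <- function(x) x@singletons

#' @rdname clusterIds
#' @export
clusterAlignment <- function(x, id) x@alignments[[id]]

setMethod("show", "ClusterSet", function(object) {
    sz <- vapply(object@clusters, length, 1L)
    cat("ClusterSet with", length(object@clusters), "clusters (",
        sum(sz), "proteins ) and", length(object@singletons),
        "singletons\n")
    if (length(sz))
        cat("  cluster sizes:", paste(range(sz), collapse = "-"), "\n")
})

#' Build the phyletic (copy-count) matrix of a ClusterSet
#'
#' Rows are clusters, columns genomes, entries the number of member
#' proteins of that genome in that cluster.
#'
#' @param x a \code{ClusterSet}
#' @param genomes optional character vector fixing the column set/order;
#'   defaults to all genomes seen in the genome map, sorted.
#' @return Integer matrix with cluster ids as rownames.
#' @export
phyleticMatrix <- function(x, genomes = NULL) {
    if (is.null(genomes)) genomes <- sort(unique(unname(x@genomeMap)))
    mat <- matrix(0L, nrow = length(x@clusters), ncol = length(genomes),
                  dimnames = list(names(x@clusters), genomes))
    for (id in names(x@clusters)) {
        tab <- table(unname(x@genomeMap[x@clusters[[id]]]))
        mat[id, names(tab)] <- as.integer(tab)
    }
    mat
}

#' SimulationTruth: recorded ground truth of a simulated gene history
#'
#' @slot tree the species tree (\code{phylo}, rooted, with node labels).
#' @slot states integer matrix, families x tree nodes (named with tip and
#'   node labels): latent presence (0/1) of each family at each node.
#' @slot counts integer matrix, families x genomes: leaf copy counts
#'   (presence plus terminal-branch duplications).
#' @slot events data.frame with columns \code{child} (node label at the
#'   child end of the edge), \code{family}, \code{type}
#'   (gain/loss/duplication).
#' @slot familyMembership named character, protein id to family id (filled
#'   by \code{\link{simulateSequences}}).
#' @slot nDropped number of all-absent families that were dropped.
#' @export
setClass("SimulationTruth",
    representation(tree = "phylo", states = "matrix", counts = "matrix",
                   events = "data.frame", familyMembership = "character",
                   nDropped = "integer"))

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth:", nrow(object@counts), "families on",
        ncol(object@counts), "genomes;", nrow(object@events),
        "events;", object@nDropped, "all-absent families dropped\n")
})

#' Accessors for SimulationTruth
#'
#' @param x a \code{SimulationTruth}
#' @return \code{trueMatrix}: the families x genomes copy-count matrix;
#'   \code{trueEvents}: the event table; \code{speciesTree}: the tree;
#'   \code{familyMembership}: protein id to family id map;
#'   \code{nodeStates}: the families x nodes latent presence matrix.
#' @export
trueMatrix <- function(x) x@counts

#' @rdname trueMatrix
#' @export
trueEvents <- function(x) x@events

#' @rdname trueMatrix
#' @export
speciesTree <- function(x) x@tree

#' @rdname trueMatrix
#' @export
familyMembership <- function(x) x@familyMembership

#' @rdname trueMatrix
#' @export
nodeStates <- function(x) x@states

#' GainLossModel: two-state gene gain/loss rate model
#'
#' Continuous-time two-state Markov model of gene presence on a tree:
#' absent-to-present at \code{gainRate}, present-to-absent at
#' \code{lossRate} (per unit branch length), with a root presence prior.
#'
#' @slot gainRate non-negative gain rate.
#' @slot lossRate non-negative loss rate.
#' @slot rootPrior probability of presence at the root.
#' @slot logLik log-likelihood at the fitted rates (NA if not fitted).
#' @slot ascertainment logical; whether the likelihood was conditioned on
#'   families being observed in at least one genome.
#' @export
setClass("GainLossModel",
    representation(gainRate = "numeric", lossRate = "numeric",
                   rootPrior = "numeric", logLik = "numeric",
                   ascertainment = "logical"))

setValidity("GainLossModel", function(object) {
    g <- object@gainRate; l <- object@lossRate
    if (length(g) != 1L || length(l) != 1L || !is.finite(g) ||
        !is.finite(l) || g < 0 || l < 0)
        return("rates must be single finite non-negative numbers")
    p <- object@rootPrior
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
        return("rootPrior must be a probability")
    TRUE
})

#' Construct a GainLossModel
#'
#' @param gainRate,lossRate non-negative rates per unit branch length.
#' @param rootPrior root presence probability; default the stationary
#'   probability \code{gainRate / (gainRate + lossRate)}.
#' @param logLik optional fitted log-likelihood.
#' @param ascertainment logical flag recorded with the model.
#' @return A \code{GainLossModel}.
#' @export
GainLossModel <- function(gainRate, lossRate,
                          rootPrior = if (gainRate + lossRate > 0)
                              gainRate / (gainRate + lossRate) else 0.5,
                          logLik = NA_real_, ascertainment = TRUE) {
    new("GainLossModel", gainRate = gainRate, lossRate = lossRate,
        rootPrior = rootPrior, logLik = as.numeric(logLik),
        ascertainment = ascertainment)
}

setMethod("show", "GainLossModel", function(object) {
    cat(sprintf(
        "GainLossModel: gain = %.4g, loss = %.4g, root prior = %.4g\n",
        object@gainRate, object@lossRate, object@rootPrior))
    if (is.finite(object@logLik))
        cat(sprintf("  logLik = %.4f (ascertainment %s)\n", object@logLik,
                    if (object@ascertainment) "on" else "off"))
})

#' Accessors for GainLossModel
#'
#' @param x a \code{GainLossModel}
#' @return \code{gainRate}, \code{lossRate}, \code{rootPrior} return the
#'   corresponding scalar parameters.
#' @export
gainRate <- function(x) x@gainRate

#' @rdname gainRate
#' @export
lossRate <- function(x) x@lossRate

#' @rdname gainRate
#' @export
rootPrior <- function(x) x@rootPrior

#' Supermatrix: concatenated marker alignment with partition map
#'
#' @slot alignment \code{AAStringSet}, one row per genome, equal widths.
#' @slot partitions data.frame with columns \code{cluster_id},
#'   \code{start}, \code{end} (0-based half-open column intervals).
#' @export
setClass("Supermatrix",
    representation(alignment = "AAStringSet", partitions = "data.frame"))

setValidity("Supermatrix", function(object) {
    w <- Biostrings::width(object@alignment)
    if (length(w) && length(unique(w)) != 1L)
        return("all rows must have equal length")
    p <- object@partitions
    if (nrow(p)) {
        if (!all(c("cluster_id", "start", "end") %in% names(p)))
            return("partitions needs cluster_id, start, end")
        if (any(p$end < p$start)) return("empty or negative partition")
        tot <- sum(p$end - p$start)
        if (length(w) && tot != w[1L])
            return("partitions must cover all columns")
    }
    TRUE
})

setMethod("show", "Supermatrix", function(object) {
    w <- Biostrings::width(object@alignment)
    cat("Supermatrix:", length(object@alignment), "genomes x",
        if (length(w)) w[1L] else 0L, "sites in",
        nrow(object@partitions), "partitions\n")
})

#' Accessors for Supermatrix
#'
#' @param x a \code{Supermatrix}
#' @return \code{superAlignment}: the concatenated \code{AAStringSet};
#'   \code{partitions}: the partition table (0-based half-open intervals).
#' @export
superAlignment <- function(x) x@alignment

#' @rdname superAlignment
#' @export
partitions <- function(x) x@partitions
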