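## header comment lines stamped into text outputs
.headerLines <- function(seed = NULL, configHash = NULL) {
    ver <- tryCatch(as.character(utils::packageVersion("phyloCOG")),
                    error = function(e) "0.0.0")
    h <- sprintf("# phyloCOG %s", ver)
    if (!is.null(seed))
        h <- c(h, sprintf("# seed=%s config=%s", seed,
                          if (is.null(configHash)) "NA" else configHash))
    h
}

## write a data.frame as TSV with optional "#" header comments
.writeTSV <- function(df, path, header = NULL) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a GenomeSet as per-genome FASTA files
#'
#' One file \code{<genome>.faa} per genome, sequence lines wrapped at 60
#' characters, headers \code{<genome>|<protein-id>}.
#'
#' @param gs a \code{\linkS4class{GenomeSet}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeGenomeSet <- function(gs, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gmap <- genomeIds(gs)
    paths <- character(0)
    for (g in genomeNames(gs)) {
        sub <- gs@proteins[names(gmap)[gmap == g]]
        names(sub) <- paste0(g, "|", names(sub))
        p <- file.path(dir, paste0(g, ".faa"))
        Biostrings::writeXStringSet(sub, p, width = 60L)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read proteomes from FASTA files into a GenomeSet
#'
#' Headers must be \code{<genome>|<protein-id>}; all files are pooled.
#'
#' @param paths FASTA file paths, or a single directory containing
#'   \code{.faa}/\code{.fasta}/\code{.fa} files.
#' @return A \code{\linkS4class{GenomeSet}}.
#' @export
readGenomeSet <- function(paths) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.(faa|fasta|fa)$",
                            full.names = TRUE)
    paths <- paths[file.exists(paths)]
    if (!length(paths)) stop("no FASTA files found")
    sets <- lapply(sort(paths), Biostrings::readAAStringSet)
    all <- do.call(c, sets)
    hdr <- sub("\\s.*$", "", names(all))
    parts <- strsplit(hdr, "|", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
        stop("malformed FASTA header (expected '<genome>|<protein-id>'): ",
             hdr[bad[1L]])
    genome <- vapply(parts, `[[`, "", 1L)
    pid <- vapply(parts, function(p) paste(p[-1L], collapse = "|"), "")
    names(all) <- pid
    GenomeSet(all, genome)
}

#' Write a phyletic copy-count matrix as TSV
#'
#' Tab-separated, header row of genome ids, first column \code{family}.
#'
#' @param mat integer matrix, families x genomes.
#' @param path output file.
#' @param header optional "#" comment lines written above the table.
#' @return Invisibly, \code{path}.
#' @export
writePhyleticMatrix <- function(mat, path, header = NULL) {
    df <- data.frame(family = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(df, path, header)
}

#' Read a phyletic matrix from TSV
#'
#' Expects the format of \code{\link{writePhyleticMatrix}}; "#" comment
#' lines are skipped.  Negative or non-integer counts are rejected with
#' the offending line number.
#'
#' @param path TSV file.
#' @return Integer matrix, families x genomes.
#' @export
readPhyleticMatrix <- function(path) {
    lines <- readLines(path)
    isComment <- startsWith(lines, "#")
    body <- which(!isComment)
    if (length(body) < 2L) stop("no data rows in ", path)
    hdr <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
    if (hdr[1L] != "family")
        stop("first column must be 'family' (line ", body[1L], ")")
    genomes <- hdr[-1L]
    n <- length(body) - 1L
    mat <- matrix(0L, n, length(genomes),
                  dimnames = list(NULL, genomes))
    fams <- character(n)
    for (i in seq_len(n)) {
        ln <- body[i + 1L]
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) != length(hdr))
            stop("wrong number of fields at line ", ln)
        vals <- suppressWarnings(as.numeric(f[-1L]))
        if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals)))
            stop("invalid count (negative or non-integer) at line ", ln)
        fams[i] <- f[1L]
        mat[i, ] <- as.integer(vals)
    }
    rownames(mat) <- fams
    mat
}

#' Write / read Newick trees
#'
#' Thin wrappers over ape preserving branch lengths and internal node
#' labels.
#'
#' @param tree a \code{phylo}.
#' @param path file path.
#' @return \code{readSpeciesTree} returns a \code{phylo}.
#' @export
writeSpeciesTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' @rdname writeSpeciesTree
#' @export
readSpeciesTree <- function(path) {
    tr <- ape::read.tree(path)
    if (is.null(tr)) stop("could not parse Newick in ", path)
    tr
}

#' Write cluster membership as TSV
#'
#' Columns \code{cluster_id}, \code{protein_id}, \code{genome_id};
#' singletons are listed with cluster_id \code{"-"}.
#'
#' @param cs a \code{\linkS4class{ClusterSet}}.
#' @param path output file.
#' @param header optional comment lines.
#' @return Invisibly, \code{path}.
#' @export
writeClusterTable <- function(cs, path, header = NULL) {
    rows <- lapply(names(cs@clusters), function(id) {
        m <- cs@clusters[[id]]
        data.frame(cluster_id = id, protein_id = m,
                   genome_id = unname(cs@genomeMap[m]),
                   stringsAsFactors = FALSE)
    })
    if (length(cs@singletons))
        rows <- c(rows, list(data.frame(
            cluster_id = "-", protein_id = cs@singletons,
            genome_id = unname(cs@genomeMap[cs@singletons]),
            stringsAsFactors = FALSE)))
    df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cluster_id = character(0), protein_id = character(0),
                   genome_id = character(0))
    .writeTSV(df, path, header)
}

#' Read cluster membership written by writeClusterTable
#'
#' @param path TSV file.
#' @param sequences optional \code{AAStringSet} to attach.
#' @return A \code{\linkS4class{ClusterSet}}.
#' @export
readClusterTable <- function(path, sequences = NULL) {
    df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    singles <- df$protein_id[df$cluster_id == "-"]
    df2 <- df[df$cluster_id != "-", , drop = FALSE]
    clusters <- split(df2$protein_id, df2$cluster_id)
    gmap <- setNames(df$genome_id, df$protein_id)
    cs <- ClusterSet(clusters = clusters[sort(names(clusters))],
                     genomeMap = gmap, singletons = sort(singles))
    if (!is.null(sequences)) cs <- attachSequences(cs, sequences)
    cs
}

#' Write a supermatrix as FASTA and relaxed PHYLIP
#'
#' @param sm a \code{\linkS4class{Supermatrix}}.
#' @param fastaPath FASTA output (wrap 60); NULL to skip.
#' @param phylipPath relaxed PHYLIP output; NULL to skip.
#' @return Invisibly, the written paths.
#' @export
writeSupermatrix <- function(sm, fastaPath = NULL, phylipPath = NULL) {
    paths <- character(0)
    if (!is.null(fastaPath)) {
        Biostrings::writeXStringSet(sm@alignment, fastaPath, width = 60L)
        paths <- c(paths, fastaPath)
    }
    if (!is.null(phylipPath)) {
        aln <- sm@alignment
        w <- if (length(aln)) Biostrings::width(aln)[1L] else 0L
        con <- file(phylipPath, "wt")
        writeLines(sprintf(" %d %d", length(aln), w), con)
        writeLines(paste(format(names(aln),
                                width = max(nchar(names(aln))) + 2L),
                         as.character(aln)), con)
        close(con)
        paths <- c(paths, phylipPath)
    }
    invisible(paths)
}

#' Write a RAxML-style partition file
#'
#' One line per cluster: \code{PROT, <cluster_id> = <start>-<end>} with
#' 1-based inclusive coordinates (internally intervals are 0-based
#' half-open).
#'
#' @param sm a \code{\linkS4class{Supermatrix}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writePartitions <- function(sm, path) {
    p <- sm@partitions
    writeLines(sprintf("PROT, %s = %d-%d", p$cluster_id, p$start + 1L,
                       p$end), path)
    invisible(path)
}

#' Write gain/loss outputs as TSV
#'
#' \code{writeEventCalls} writes the event table;
#' \code{writePosteriors} the families x nodes posterior matrix;
#' \code{writeAncestralContent} the per-node expected content;
#' \code{writeModelJSON} the fitted model.
#'
#' @param events data.frame from \code{\link{callEvents}}.
#' @param path output file.
#' @param header optional comment lines.
#' @return Invisibly, \code{path}.
#' @export
writeEventCalls <- function(events, path, header = NULL) {
    .writeTSV(events, path, header)
}

#' @rdname writeEventCalls
#' @param posteriors families x nodes matrix.
#' @export
writePosteriors <- function(posteriors, path, header = NULL) {
    df <- data.frame(family = rownames(posteriors),
                     round(posteriors, 6L), check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(df, path, header)
}

#' @rdname writeEventCalls
#' @export
writeAncestralContent <- function(posteriors, path, header = NULL) {
    s <- colSums(posteriors)
    df <- data.frame(node = names(s), expected_content = round(s, 4L),
                     rounded = as.integer(round(s)),
                     stringsAsFactors = FALSE)
    .writeTSV(df, path, header)
}

#' @rdname writeEventCalls
#' @param model a \code{\linkS4class{GainLossModel}}.
#' @export
writeModelJSON <- function(model, path) {
    jsonlite::write_json(list(gain_rate = model@gainRate,
                              loss_rate = model@lossRate,
                              root_prior = model@rootPrior,
                              log_likelihood = model@logLik,
                              ascertainment = model@ascertainment),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
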