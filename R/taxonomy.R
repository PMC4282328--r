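#' Parse a lineage-annotated FASTA header
#'
#' Training FASTA headers carry an identifier followed by a
#' semicolon-delimited lineage, most inclusive taxon first, e.g.
#' \code{">s1 Metazoa;Arthropoda;Insecta;Diptera;Culicidae;Aedes"}.
#' Names are mapped onto \code{ranks} positionally; placeholder names
#' (\code{undef_*}) pass through unchanged. A lineage may stop above the
#' last configured rank (family-trained sets stop at family) but may not
#' exceed it.
#'
#' @param header the description line, with or without the leading ">".
#' @param ranks ordered rank names; see [defaultRanks()].
#' @return list with \code{id} and \code{lineage}, a named character
#'   vector over \code{ranks} (NA beyond the lineage's end).
#' @export
#' @examples
#' parseLineageHeader(">s1 Metazoa;Arthropoda;Insecta;Diptera;Culicidae;Aedes")
parseLineageHeader <- function(header, ranks = defaultRanks()) {
    h <- sub("^>", "", trimws(header))
    m <- regexpr("\\s+", h)
    if (m == -1L)
        stop("header '", h, "' has no lineage")
    id <- substr(h, 1L, m - 1L)
    rest <- trimws(substr(h, m + attr(m, "match.length"), nchar(h)))
    names <- trimws(strsplit(rest, ";", fixed = TRUE)[[1L]])
    names <- names[nzchar(names)]
    if (length(names) == 0L)
        stop("header '", h, "' has no lineage")
    if (length(names) > length(ranks))
        stop("header '", h, "' has ", length(names),
             " lineage names but only ", length(ranks),
             " ranks are configured")
    lin <- setNames(rep(NA_character_, length(ranks)), ranks)
    lin[seq_along(names)] <- names
    list(id = id, lineage = lin)
}

## Depth-first, lexicographic taxid assignment under an artificial root.
.assignTaxids <- function(lineages) {
    ranks <- names(lineages)
    rows <- list(data.frame(taxid = 0L, name = .ROOT_NAME,
                            parent = .ROOT_PARENT, depth = 0L,
                            rank = .ROOT_RANK, stringsAsFactors = FALSE))
    counter <- new.env(parent = emptyenv())
    counter$id <- 0L
    recurse <- function(parentId, depth, sub) {
        if (depth > length(ranks)) return(invisible())
        col <- sub[[ranks[depth]]]
        keep <- !is.na(col)
        if (!any(keep)) return(invisible())
        sub <- sub[keep, , drop = FALSE]
        col <- col[keep]
        for (nm in sort(unique(col))) {
            counter$id <- counter$id + 1L
            id <- counter$id
            rows[[length(rows) + 1L]] <<- data.frame(
                taxid = id, name = nm, parent = parentId,
                depth = depth, rank = ranks[depth],
                stringsAsFactors = FALSE)
            recurse(id, depth + 1L, sub[col == nm, , drop = FALSE])
        }
    }
    recurse(0L, 1L, lineages)
    do.call(rbind, rows)
}

#' Build a taxonomy tree from lineages
#'
#' Assembles the tree spanned by a set of lineages, assigning
#' deterministic integer taxids: root = 0, then depth-first in
#' lexicographic name order. The same lineages in any order always yield
#' an identical tree, which keeps written training files diffable.
#'
#' @param lineages data.frame of rank columns (kingdom outermost), one
#'   row per record; NA marks ranks beyond a lineage's end.
#' @return A [TaxonomyTree-class] object.
#' @export
#' @examples
#' lin <- data.frame(kingdom = "Metazoa", phylum = "Arthropoda",
#'                   class = "Insecta", order = "Diptera",
#'                   family = "Culicidae", genus = c("Aedes", "Culex"))
#' buildTaxonomy(lin)
buildTaxonomy <- function(lineages) {
    if (is.null(nrow(lineages)) || nrow(lineages) == 0L)
        stop("empty training set")
    roots <- unique(lineages[[1L]])
    roots <- roots[!is.na(roots)]
    if (length(roots) == 0L) stop("empty training set")
    if (length(roots) > 1L)
        stop("lineages have different roots: ",
             paste(roots, collapse = ", "))
    new("TaxonomyTree", nodes = .assignTaxids(lineages))
}

## Walk a lineage down the tree; error if a node is absent.
.lineageTaxid <- function(tree, lineage) {
    nd <- tree@nodes
    parent <- 0L
    id <- 0L
    for (nm in lineage[!is.na(lineage)]) {
        hit <- which(nd$name == nm & nd$parent == parent)
        if (length(hit) != 1L)
            stop("lineage names taxon '", nm,
                 "' absent from the taxonomy tree")
        id <- nd$taxid[hit]
        parent <- id
    }
    id
}

## Lineage (named by rank) of a node, walking parents up to the root.
.taxidLineage <- function(tree, taxid) {
    nd <- tree@nodes
    out <- character(0)
    rk <- character(0)
    while (taxid != 0L) {
        i <- match(taxid, nd$taxid)
        out <- c(nd$name[i], out)
        rk <- c(nd$rank[i], rk)
        taxid <- nd$parent[i]
    }
    setNames(out, rk)
}

#' Construct a training set directly
#'
#' Assembles a [TrainingSet-class] from identifiers, sequences and
#' lineages, building the taxonomy tree. Sequences are uppercased and U
#' mapped to T on the way in. Most users will prefer
#' [buildTrainingSet()], which also applies curation filters.
#'
#' @param ids record identifiers.
#' @param sequences character vector or \code{DNAStringSet}.
#' @param lineages data.frame of rank columns, one row per sequence.
#' @param trainedRank rank the set is trained to.
#' @return A [TrainingSet-class] object.
#' @export
newTrainingSet <- function(ids, sequences, lineages, trainedRank = "genus") {
    seqs <- .asDNA(sequences)
    names(seqs) <- ids
    keepCols <- seq_len(match(trainedRank, names(lineages)))
    lineages <- lineages[, keepCols, drop = FALSE]
    rownames(lineages) <- NULL
    new("TrainingSet", sequences = seqs, lineages = lineages,
        tree = buildTaxonomy(lineages), trainedRank = trainedRank)
}

.asDNA <- function(x) {
    if (is(x, "DNAStringSet")) x <- as.character(x)
    x <- chartr("u", "t", toupper(x))
    x <- chartr("U", "T", x)
    Biostrings::DNAStringSet(x)
}

#' Write and read the two-file training format
#'
#' The classifier trains from two files: a FASTA of reference sequences
#' whose headers carry semicolon-delimited lineages, and a taxonomy text
#' file with one node per line, \code{taxid*name*parentTaxid*depth*rank},
#' root first (\code{0*Root*-1*0*rootrank}). \code{writeTrainingFiles}
#' and \code{readTrainingFiles} round-trip a [TrainingSet-class] exactly:
#' reading what was written and writing again is byte-identical.
#'
#' @param ts a \code{TrainingSet}.
#' @param fastaPath,taxonomyPath file paths.
#' @param trainedRank on read: rank the set is trained to; default the
#'   deepest rank present in the taxonomy file.
#' @param ranks ordered rank names used to interpret FASTA lineages.
#' @return \code{writeTrainingFiles} invisibly returns the paths;
#'   \code{readTrainingFiles} returns a \code{TrainingSet}.
#' @export
#' @examples
#' lin <- data.frame(kingdom = "Metazoa", phylum = "Arthropoda",
#'                   class = "Insecta", order = "Diptera",
#'                   family = "Culicidae", genus = c("Aedes", "Culex"))
#' ts <- newTrainingSet(c("a", "b"),
#'                      c(strrep("ACGT", 150), strrep("TTGA", 150)), lin)
#' fa <- tempfile(fileext = ".fasta"); tx <- tempfile(fileext = ".tax")
#' writeTrainingFiles(ts, fa, tx)
#' ts2 <- readTrainingFiles(fa, tx)
writeTrainingFiles <- function(ts, fastaPath, taxonomyPath) {
    stopifnot(is(ts, "TrainingSet"))
    lin <- ts@lineages
    heads <- vapply(seq_len(nrow(lin)), function(i) {
        v <- unlist(lin[i, ], use.names = FALSE)
        paste(v[!is.na(v)], collapse = ";")
    }, character(1))
    seqs <- ts@sequences
    names(seqs) <- paste(names(ts@sequences), heads)
    Biostrings::writeXStringSet(seqs, fastaPath, width = 20000L)
    nd <- ts@tree@nodes
    lines <- sprintf("%d*%s*%d*%d*%s", nd$taxid, nd$name, nd$parent,
                     nd$depth, nd$rank)
    writeLines(lines, taxonomyPath)
    invisible(c(fasta = fastaPath, taxonomy = taxonomyPath))
}

#' @rdname writeTrainingFiles
#' @export
readTrainingFiles <- function(fastaPath, taxonomyPath, trainedRank = NULL,
                              ranks = defaultRanks()) {
    lines <- readLines(taxonomyPath)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "*", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
        stop("taxonomy line ", bad[1L], " has ", lengths(parts)[bad[1L]],
             " fields; expected 5 (taxid*name*parent*depth*rank)")
    nd <- data.frame(taxid = as.integer(vapply(parts, `[`, "", 1L)),
                     name = vapply(parts, `[`, "", 2L),
                     parent = as.integer(vapply(parts, `[`, "", 3L)),
                     depth = as.integer(vapply(parts, `[`, "", 4L)),
                     rank = vapply(parts, `[`, "", 5L),
                     stringsAsFactors = FALSE)
    tree <- new("TaxonomyTree", nodes = nd)
    if (is.null(trainedRank)) {
        deepest <- nd$rank[which.max(nd$depth)]
        trainedRank <- deepest
    }
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    parsed <- lapply(names(seqs), parseLineageHeader, ranks = ranks)
    lineages <- do.call(rbind, lapply(parsed, function(p)
        as.data.frame(as.list(p$lineage), stringsAsFactors = FALSE)))
    ## every lineage must resolve to a node of the tree
    for (i in seq_len(nrow(lineages)))
        .lineageTaxid(tree, unlist(lineages[i, ], use.names = FALSE))
    seqs <- .asDNA(seqs)
    names(seqs) <- vapply(parsed, `[[`, "", "id")
    keepCols <- seq_len(match(trainedRank, names(lineages)))
    new("TrainingSet", sequences = seqs,
        lineages = lineages[, keepCols, drop = FALSE], tree = tree,
        trainedRank = trainedRank)
}
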