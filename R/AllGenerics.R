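#' Accessors for package classes
#'
#' Accessor generics: \code{taxNodes} returns a taxonomy's node table;
#' \code{refSequences}, \code{refLineages} and \code{taxonomyTree} expose
#' a training set's components; \code{trainedRank} returns the rank a
#' training set or model is trained to; \code{assignedTaxon} and
#' \code{bootstrapSupport} read one rank (or all ranks) of an assignment.
#'
#' @param x the object.
#' @param rank a rank name, or \code{NULL} for all ranks.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxNodes", function(x) standardGeneric("taxNodes"))

#' @rdname accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname accessors
#' @export
setGeneric("refLineages", function(x) standardGeneric("refLineages"))

#' @rdname accessors
#' @export
setGeneric("taxonomyTree", function(x) standardGeneric("taxonomyTree"))

#' @rdname accessors
#' @export
setGeneric("trainedRank", function(x) standardGeneric("trainedRank"))

#' @rdname accessors
#' @export
setGeneric("assignedTaxon",
    function(x, rank = NULL) standardGeneric("assignedTaxon"))

#' @rdname accessors
#' @export
setGeneric("bootstrapSupport",
    function(x, rank = NULL) standardGeneric("bootstrapSupport"))

#' @rdname accessors
#' @export
setMethod("taxNodes", "TaxonomyTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("refSequences", "TrainingSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("refLineages", "TrainingSet", function(x) x@lineages)

#' @rdname accessors
#' @export
setMethod("taxonomyTree", "TrainingSet", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("trainedRank", "TrainingSet", function(x) x@trainedRank)

#' @rdname accessors
#' @export
setMethod("trainedRank", "KmerModel", function(x) x@trainedRank)

#' @rdname accessors
#' @export
setMethod("trainedRank", "FilterPolicy", function(x) x@trainedRank)

#' @rdname accessors
#' @export
setMethod("assignedTaxon", "Assignment", function(x, rank = NULL) {
    if (is.null(rank)) x@taxa else x@taxa[[rank]]
})

#' @rdname accessors
#' @export
setMethod("bootstrapSupport", "Assignment", function(x, rank = NULL) {
    if (is.null(rank)) x@support else x@support[[rank]]
})

#' @describeIn TrainingSet-class number of reference sequences.
#' @param x a \code{TrainingSet}.
#' @export
setMethod("length", "TrainingSet", function(x) length(x@sequences))

setMethod("show", "TaxonomyTree", function(object) {
    nd <- object@nodes
    cat("TaxonomyTree with", nrow(nd), "nodes\n")
    tab <- table(nd$rank[nd$rank != .ROOT_RANK])
    for (r in names(tab)) cat(" ", r, ": ", tab[[r]], "\n", sep = "")
})

setMethod("show", "TrainingSet", function(object) {
    cat("TrainingSet:", length(object), "sequences, trained to the",
        object@trainedRank, "rank\n")
    cat("  taxa at trained rank:",
        length(unique(object@lineages[[object@trainedRank]])), "\n")
    w <- Biostrings::width(object@sequences)
    cat("  sequence length: ", min(w), "-", max(w), " nt\n", sep = "")
})

setMethod("show", "KmerModel", function(object) {
    cat("KmerModel: k=", object@k, ", ", length(object@genera), " ",
        object@trainedRank, " taxa, N=", object@N, " sequences, ",
        sum(object@wordCount > 0L), " distinct words\n", sep = "")
})

setMethod("show", "Assignment", function(object) {
    cat("Assignment for query '", object@queryId, "' (",
        object@orientation, " orientation",
        if (object@tie) ", tie" else "", ")\n", sep = "")
    for (r in rev(names(object@taxa)))
        cat(sprintf("  %-8s %s (%d)\n", r, object@taxa[[r]],
                    object@support[[r]]))
})

setMethod("show", "COISimulation", function(object) {
    cat("COISimulation:", nrow(object@speciesLineages), "species (",
        sum(object@speciesLineages$novel), "novel, withheld ),",
        length(object@reference), "reference sequences\n")
})

setMethod("show", "LabeledQuerySet", function(object) {
    cat("LabeledQuerySet:", length(object@queries), "queries,",
        sum(object@truth$novel), "from novel taxa\n")
})

#' @describeIn LabeledQuerySet-class number of queries.
#' @param x a \code{LabeledQuerySet}.
#' @export
setMethod("length", "LabeledQuerySet", function(x) length(x@queries))
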