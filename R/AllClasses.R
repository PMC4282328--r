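#' @import methods
#' @importFrom stats setNames
NULL

#' Ordered taxonomic ranks used for training and assignment
#'
#' The classifier is trained to the genus (or family) rank; species is never
#' a trained rank, so the default rank list runs kingdom through genus.
#' Lineages in FASTA headers are mapped onto this list positionally.
#'
#' @return Character vector of rank names, most inclusive first.
#' @export
#' @examples
#' defaultRanks()
defaultRanks <- function() {
    c("kingdom", "phylum", "class", "order", "family", "genus")
}

## Artificial root node conventions of the two-file training format.
.ROOT_NAME <- "Root"
.ROOT_RANK <- "rootrank"
.ROOT_PARENT <- -1L

#' TaxonomyTree: the rank taxonomy behind a training set
#'
#' A rooted tree of taxa. Each node carries an integer taxid, a name, its
#' parent's taxid, its depth (root = 0) and a rank label. The root is an
#' artificial node (\code{"Root"}, rank \code{"rootrank"}, parent sentinel
#' \code{-1}); kingdom nodes sit at depth 1. Taxids are assigned
#' deterministically (root = 0, then depth-first in lexicographic name
#' order) so that identical inputs always produce identical trees.
#'
#' @slot nodes data.frame with columns \code{taxid}, \code{name},
#'   \code{parent}, \code{depth}, \code{rank}, root first, ordered by taxid.
#' @export
setClass("TaxonomyTree", slots = c(nodes = "data.frame"))

setValidity("TaxonomyTree", function(object) {
    nd <- object@nodes
    need <- c("taxid", "name", "parent", "depth", "rank")
    if (!all(need %in% names(nd)))
        return(paste("nodes must have columns", paste(need, collapse = ", ")))
    if (nrow(nd) < 1L) return("tree has no nodes")
    if (anyDuplicated(nd$taxid)) return("duplicate taxids")
    root <- nd$parent == .ROOT_PARENT
    if (sum(root) != 1L) return("tree must have exactly one root")
    if (nd$depth[root] != 0L) return("root depth must be 0")
    nonroot <- nd[!root, , drop = FALSE]
    if (nrow(nonroot)) {
        pidx <- match(nonroot$parent, nd$taxid)
        if (anyNA(pidx)) return("node with parent absent from tree")
        if (!all(nonroot$depth == nd$depth[pidx] + 1L))
            return("depth must equal parent depth + 1")
        if (anyDuplicated(nonroot[, c("name", "parent")]))
            return("(name, parent) pairs must be unique within a parent")
    }
    TRUE
})

#' TrainingSet: curated reference sequences with lineages
#'
#' The classifier's reference database: identified barcode sequences, one
#' lineage per sequence (columns are ranks, kingdom outward-in to the
#' trained rank), and the taxonomy tree spanned by those lineages.
#' Duplicate sequences for the same taxon are permitted (they represent
#' within-species variation).
#'
#' @slot sequences \code{DNAStringSet}; names are record identifiers.
#' @slot lineages data.frame, one row per sequence, one column per rank.
#' @slot tree \code{TaxonomyTree} spanning every lineage.
#' @slot trainedRank character(1); \code{"genus"} or \code{"family"}.
#' @export
setClass("TrainingSet",
    slots = c(sequences = "DNAStringSet", lineages = "data.frame",
              tree = "TaxonomyTree", trainedRank = "character"))

setValidity("TrainingSet", function(object) {
    n <- length(object@sequences)
    if (n == 0L) return("empty training set")
    if (nrow(object@lineages) != n)
        return("lineages must have one row per sequence")
    tr <- object@trainedRank
    if (length(tr) != 1L || !tr %in% names(object@lineages))
        return("trainedRank must name a lineage column")
    if (anyNA(object@lineages[[tr]]))
        return("every record must be named at the trained rank")
    if (any(Biostrings::width(object@sequences) == 0L))
        return("sequences must be non-empty")
    TRUE
})

#' ClassifierParams: tuning parameters of the naive Bayesian classifier
#'
#' @slot k word (k-mer) size; default 8 as used for COI barcodes.
#' @slot nBootstrap bootstrap trials per query (default 100).
#' @slot bootstrapFraction fraction of the query's words drawn (with
#'   replacement) per trial; default 1/8.
#' @slot seed integer seed applied at the start of each classification
#'   call, or \code{NA} to draw from the current RNG stream.
#' @slot checkReverseComplement score both orientations and keep the
#'   better one (default \code{TRUE}).
#' @export
setClass("ClassifierParams",
    slots = c(k = "integer", nBootstrap = "integer",
              bootstrapFraction = "numeric", seed = "integer",
              checkReverseComplement = "logical"),
    prototype = list(k = 8L, nBootstrap = 100L, bootstrapFraction = 1 / 8,
                     seed = NA_integer_, checkReverseComplement = TRUE))

setValidity("ClassifierParams", function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (object@k > 12L) return("k above 12 is not supported (4^k table)")
    if (object@nBootstrap < 1L) return("nBootstrap must be >= 1")
    f <- object@bootstrapFraction
    if (!(f > 0 && f <= 1)) return("bootstrapFraction must be in (0, 1]")
    TRUE
})

#' @rdname ClassifierParams-class
#' @param k,nBootstrap,bootstrapFraction,seed,checkReverseComplement see slots.
#' @return A \code{ClassifierParams} object.
#' @export
#' @examples
#' ClassifierParams(k = 8, seed = 1)
ClassifierParams <- function(k = 8, nBootstrap = 100, bootstrapFraction = 1 / 8,
                             seed = NA, checkReverseComplement = TRUE) {
    new("ClassifierParams", k = as.integer(k),
        nBootstrap = as.integer(nBootstrap),
        bootstrapFraction = bootstrapFraction, seed = as.integer(seed),
        checkReverseComplement = isTRUE(checkReverseComplement))
}

#' KmerModel: trained word statistics of the classifier
#'
#' Per-word and per-genus presence counts supporting the log-posterior
#' score. A word is counted once per sequence that contains it
#' (presence/absence, not occurrences), so \code{m(w, G) <= M(G)} always
#' holds. Counts are stored densely over all 4^k words; words never seen
#' in training have count 0 and still receive a positive prior.
#'
#' @slot k word size.
#' @slot genera sorted taxon names at the trained rank.
#' @slot M integer; training sequences per genus (same order as genera).
#' @slot N integer(1); total training sequences.
#' @slot wordCount integer(4^k); sequences containing each word.
#' @slot genusWordCount integer matrix (genera x 4^k); sequences of each
#'   genus containing each word.
#' @slot lineages data.frame, one row per genus: its full lineage.
#' @slot trainedRank character(1).
#' @export
setClass("KmerModel",
    slots = c(k = "integer", genera = "character", M = "integer",
              N = "integer", wordCount = "integer",
              genusWordCount = "matrix", lineages = "data.frame",
              trainedRank = "character"))

setValidity("KmerModel", function(object) {
    nG <- length(object@genera)
    if (nG == 0L) return("model has no taxa at the trained rank")
    if (length(object@M) != nG) return("M must align with genera")
    if (any(object@M < 1L)) return("every genus must have >= 1 sequence")
    if (sum(object@M) != object@N) return("sum(M) must equal N")
    if (length(object@wordCount) != 4L^object@k)
        return("wordCount must have length 4^k")
    dm <- dim(object@genusWordCount)
    if (!identical(dm, c(nG, length(object@wordCount))))
        return("genusWordCount must be genera x 4^k")
    if (nrow(object@lineages) != nG)
        return("lineages must have one row per genus")
    if (is.unsorted(object@genera)) return("genera must be sorted")
    TRUE
})

#' Assignment: one query's taxonomic call with bootstrap support
#'
#' The winning taxon at the trained rank and, for every rank up to
#' kingdom, the taxon on the winner's lineage together with its bootstrap
#' support: the percentage of resampling trials whose winning genus falls
#' under that taxon. Support is an integer count of trials out of 100 (or
#' rescaled to percent for other trial counts) and never decreases toward
#' the root.
#'
#' @slot queryId character(1).
#' @slot taxa named character: taxon per rank, kingdom first.
#' @slot support named integer: bootstrap support per rank, 0--100.
#' @slot orientation \code{"forward"} or \code{"reverse"}.
#' @slot singleton the winning taxon is represented by a single training
#'   sequence.
#' @slot tie the top score was shared; the lexicographically first taxon
#'   was reported.
#' @export
setClass("Assignment",
    slots = c(queryId = "character", taxa = "character",
              support = "integer", orientation = "character",
              singleton = "logical", tie = "logical"))

setValidity("Assignment", function(object) {
    if (!identical(names(object@taxa), names(object@support)))
        return("taxa and support must share rank names")
    s <- object@support
    if (any(s < 0L | s > 100L)) return("support must lie in [0, 100]")
    ## taxa are ordered kingdom -> trained rank, so support must be
    ## non-increasing left to right
    if (is.unsorted(rev(s)))
        return("support must be non-decreasing toward root")
    TRUE
})

#' FilterPolicy: record-level screening rules for reference curation
#'
#' Mirrors the curation applied to mined COI barcodes: drop sequences
#' shorter than 500 nt, containing Ns, or containing other nucleotide
#' ambiguity codes; for genus-trained sets, drop records whose species
#' name marks them insufficiently identified (\code{sp.}, \code{nr.},
#' \code{aff.}, \code{cf.}); drop records missing a name at the trained
#' rank (missing intermediate ranks above it are filled with
#' \code{undef_<parent>} placeholders instead).
#'
#' @slot minLength minimum sequence length in nt (default 500).
#' @slot forbidN reject sequences containing N.
#' @slot forbidAmbiguity reject sequences with non-ACGTN characters.
#' @slot requireFullSpeciesName reject insufficiently identified names.
#' @slot trainedRank \code{"genus"} or \code{"family"}.
#' @slot nameExclusionTerms tokens that mark a name as insufficient.
#' @export
setClass("FilterPolicy",
    slots = c(minLength = "integer", forbidN = "logical",
              forbidAmbiguity = "logical",
              requireFullSpeciesName = "logical", trainedRank = "character",
              nameExclusionTerms = "character"),
    prototype = list(minLength = 500L, forbidN = TRUE, forbidAmbiguity = TRUE,
                     requireFullSpeciesName = TRUE, trainedRank = "genus",
                     nameExclusionTerms = c("sp.", "nr.", "aff.", "cf.")))

setValidity("FilterPolicy", function(object) {
    if (object@minLength < 1L) return("minLength must be >= 1")
    if (!object@trainedRank %in% c("genus", "family"))
        return("trainedRank must be 'genus' or 'family'")
    TRUE
})

#' @rdname FilterPolicy-class
#' @param minLength,forbidN,forbidAmbiguity,requireFullSpeciesName,trainedRank,nameExclusionTerms
#'   see slots. A family-trained policy defaults to permitting
#'   insufficiently identified names, mirroring how family-level sets are
#'   assembled to maximise taxon diversity.
#' @return A \code{FilterPolicy} object.
#' @export
#' @examples
#' FilterPolicy(trainedRank = "family")
FilterPolicy <- function(minLength = 500, forbidN = TRUE,
                         forbidAmbiguity = TRUE,
                         requireFullSpeciesName = (trainedRank == "genus"),
                         trainedRank = "genus",
                         nameExclusionTerms = c("sp.", "nr.", "aff.", "cf.")) {
    new("FilterPolicy", minLength = as.integer(minLength),
        forbidN = isTRUE(forbidN), forbidAmbiguity = isTRUE(forbidAmbiguity),
        requireFullSpeciesName = isTRUE(requireFullSpeciesName),
        trainedRank = trainedRank, nameExclusionTerms = nameExclusionTerms)
}

#' SimParams: study conditions for the sequence simulator
#'
#' Taxonomy shape, sequence length and per-branch divergence rates for the
#' synthetic reference generator. Sequences evolve down the taxonomy by
#' independent per-site substitution (Jukes--Cantor-like, no indels):
#' order, family and genus ancestors each diverge from their parent at
#' \code{interGenusDivergence}, species ancestors at
#' \code{intraGenusDivergence}, and individual sequences at
#' \code{intraSpeciesDivergence}.
#'
#' @slot orders,familiesPerOrder,generaPerFamily,speciesPerGenus,seqsPerSpecies
#'   taxonomy shape counts.
#' @slot seqLength sequence length in nt (default 650, full-length COI
#'   barcode scale).
#' @slot interGenusDivergence per-site substitution probability on
#'   supra-species branches (default 0.12).
#' @slot intraGenusDivergence species-ancestor divergence (default 0.02).
#' @slot intraSpeciesDivergence within-species divergence (default 0.005).
#' @slot novelTaxonFraction proportion of query taxa drawn from simulated
#'   taxa withheld from the reference.
#' @slot seed integer seed.
#' @export
setClass("SimParams",
    slots = c(orders = "integer", familiesPerOrder = "integer",
              generaPerFamily = "integer", speciesPerGenus = "integer",
              seqsPerSpecies = "integer", seqLength = "integer",
              interGenusDivergence = "numeric",
              intraGenusDivergence = "numeric",
              intraSpeciesDivergence = "numeric",
              novelTaxonFraction = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    cnt <- c(object@orders, object@familiesPerOrder, object@generaPerFamily,
             object@speciesPerGenus, object@seqsPerSpecies, object@seqLength)
    if (any(cnt < 1L)) return("counts and seqLength must be >= 1")
    dv <- c(object@interGenusDivergence, object@intraGenusDivergence,
            object@intraSpeciesDivergence)
    if (any(dv < 0 | dv >= 1)) return("divergence rates must be in [0, 1)")
    f <- object@novelTaxonFraction
    if (f < 0 || f > 1) return("novelTaxonFraction must be in [0, 1]")
    TRUE
})

#' @rdname SimParams-class
#' @param orders,familiesPerOrder,generaPerFamily,speciesPerGenus,seqsPerSpecies,seqLength,interGenusDivergence,intraGenusDivergence,intraSpeciesDivergence,novelTaxonFraction,seed
#'   see slots.
#' @return A \code{SimParams} object.
#' @export
#' @examples
#' SimParams(seed = 42)
SimParams <- function(orders = 5, familiesPerOrder = 2, generaPerFamily = 3,
                      speciesPerGenus = 3, seqsPerSpecies = 2,
                      seqLength = 650, interGenusDivergence = 0.12,
                      intraGenusDivergence = 0.02,
                      intraSpeciesDivergence = 0.005,
                      novelTaxonFraction = 0, seed = 1) {
    new("SimParams", orders = as.integer(orders),
        familiesPerOrder = as.integer(familiesPerOrder),
        generaPerFamily = as.integer(generaPerFamily),
        speciesPerGenus = as.integer(speciesPerGenus),
        seqsPerSpecies = as.integer(seqsPerSpecies),
        seqLength = as.integer(seqLength),
        interGenusDivergence = interGenusDivergence,
        intraGenusDivergence = intraGenusDivergence,
        intraSpeciesDivergence = intraSpeciesDivergence,
        novelTaxonFraction = novelTaxonFraction, seed = as.integer(seed))
}

#' COISimulation: a simulated reference world
#'
#' Holds the simulated taxonomy with its species ancestor sequences
#' (including novel taxa withheld from the reference) and the
#' \code{TrainingSet} built from the non-novel taxa. Novel taxa exist so
#' query sets can emulate taxa absent from the reference database.
#'
#' @slot params the \code{SimParams} used.
#' @slot reference the \code{TrainingSet} of non-novel taxa.
#' @slot speciesAncestors \code{DNAStringSet} of species ancestor
#'   sequences for every simulated species, novel or not.
#' @slot speciesLineages data.frame: rank columns, \code{species} label,
#'   and a logical \code{novel} column, one row per species ancestor.
#' @export
setClass("COISimulation",
    slots = c(params = "SimParams", reference = "TrainingSet",
              speciesAncestors = "DNAStringSet",
              speciesLineages = "data.frame"))

#' LabeledQuerySet: simulated queries with known truth
#'
#' @slot queries \code{DNAStringSet}.
#' @slot truth data.frame: \code{queryId}, rank columns with the true
#'   lineage, and a logical \code{novel} flag (the query's true taxon at
#'   the trained rank is absent from the paired reference).
#' @export
setClass("LabeledQuerySet",
    slots = c(queries = "DNAStringSet", truth = "data.frame"))

setValidity("LabeledQuerySet", function(object) {
    if (length(object@queries) != nrow(object@truth))
        return("one truth row per query required")
    if (!"novel" %in% names(object@truth))
        return("truth must carry a 'novel' flag")
    TRUE
})
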