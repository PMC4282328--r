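#' Screen one candidate record against a curation policy
#'
#' Applies the record-level filters used to curate mined COI reference
#' sequences, in a fixed order so that the single reported rejection
#' reason is deterministic: sequence length, missing data (N), other
#' nucleotide ambiguity codes, insufficiently identified name, then
#' lineage completeness at the trained rank. Name screening compares
#' whitespace-delimited tokens of the species name against the exclusion
#' terms (so a genus called "Crispa" is not rejected by "sp.").
#'
#' @param sequence nucleotide string.
#' @param name the organism name as annotated (e.g. "Aedes aegypti" or
#'   "Aedes sp. BOLD-1"); may be NA when name screening is off.
#' @param lineage named character over ranks; NA = missing rank.
#' @param policy a [FilterPolicy-class].
#' @return \code{"keep"} or one of the reason codes \code{"too_short"},
#'   \code{"has_N"}, \code{"has_ambiguity"}, \code{"insufficient_name"},
#'   \code{"missing_rank"}.
#' @export
#' @examples
#' pol <- FilterPolicy()
#' screenRecord(strrep("A", 499), "Aedes aegypti",
#'              c(kingdom = "Metazoa", genus = "Aedes"), pol)
screenRecord <- function(sequence, name, lineage, policy = FilterPolicy()) {
    seq <- toupper(sequence)
    if (nchar(seq) < policy@minLength) return("too_short")
    if (policy@forbidN && grepl("N", seq, fixed = TRUE)) return("has_N")
    if (policy@forbidAmbiguity && grepl("[^ACGTN]", seq))
        return("has_ambiguity")
    if (policy@requireFullSpeciesName && !is.na(name)) {
        tokens <- strsplit(trimws(name), "\\s+")[[1L]]
        if (any(tokens %in% policy@nameExclusionTerms))
            return("insufficient_name")
    }
    if (!enforceRankCompleteness(lineage, policy@trainedRank)$keep)
        return("missing_rank")
    "keep"
}

#' Lineage completeness at the trained rank
#'
#' A record is discarded when its lineage lacks a named taxon at the
#' trained rank (genus for genus-trained sets, family for family-trained
#' sets); an \code{undef_*} placeholder at the trained rank counts as
#' missing. Missing ranks \emph{above} the trained rank are not grounds
#' for rejection: they are filled with an explicit placeholder named
#' \code{undef_<nearest named ancestor>} (e.g. a record lacking an order
#' classification is placed in \code{undef_Insecta}).
#'
#' @param lineage named character over ranks, NA = missing.
#' @param trainedRank \code{"genus"} or \code{"family"}.
#' @return list with \code{keep} (logical) and \code{lineage}, the input
#'   with placeholders filled (unchanged when rejected).
#' @export
#' @examples
#' lin <- c(kingdom = "Metazoa", phylum = "Arthropoda", class = "Insecta",
#'          order = NA, family = "FamX", genus = "GenY")
#' enforceRankCompleteness(lin, "genus")
enforceRankCompleteness <- function(lineage, trainedRank = "genus") {
    ti <- match(trainedRank, names(lineage))
    if (is.na(ti)) stop("trained rank '", trainedRank, "' not in lineage")
    tv <- lineage[[ti]]
    if (is.na(tv) || startsWith(tv, "undef_"))
        return(list(keep = FALSE, lineage = lineage))
    out <- lineage
    for (i in seq_len(ti - 1L)) {
        if (is.na(out[[i]])) {
            named <- out[seq_len(i - 1L)]
            named <- named[!is.na(named) & !startsWith(named, "undef_")]
            if (length(named) == 0L)
                return(list(keep = FALSE, lineage = lineage))
            out[[i]] <- paste0("undef_", named[length(named)])
        }
    }
    list(keep = TRUE, lineage = out)
}

#' Build a curated training set from candidate records
#'
#' Screens every candidate with [screenRecord()] and assembles the kept
#' records into a [TrainingSet-class]. Duplicate sequences for the same
#' taxon are retained: they improve the representation of within-species
#' variation. The accompanying filter report accounts for every
#' candidate (kept + rejected = input count).
#'
#' @param candidates data.frame with columns \code{id}, \code{name},
#'   \code{sequence}, and one column per rank (NA = missing).
#' @param policy a [FilterPolicy-class].
#' @param ranks ordered rank names expected among the columns.
#' @return list with \code{trainingSet} and \code{report}; the report is
#'   a list with \code{kept} and a named integer \code{rejected} over the
#'   reason codes.
#' @export
buildTrainingSet <- function(candidates, policy = FilterPolicy(),
                             ranks = defaultRanks()) {
    if (is.null(nrow(candidates)) || nrow(candidates) == 0L)
        stop("empty training set")
    reasons <- c("too_short", "has_N", "has_ambiguity",
                 "insufficient_name", "missing_rank")
    rejected <- setNames(integer(length(reasons)), reasons)
    keepIdx <- integer(0)
    keptLin <- list()
    rankCols <- ranks[ranks %in% names(candidates)]
    for (i in seq_len(nrow(candidates))) {
        lin <- setNames(as.character(unlist(candidates[i, rankCols])),
                        rankCols)
        verdict <- screenRecord(candidates$sequence[i],
                                candidates$name[i], lin, policy)
        if (verdict == "keep") {
            keepIdx <- c(keepIdx, i)
            keptLin[[length(keptLin) + 1L]] <-
                enforceRankCompleteness(lin, policy@trainedRank)$lineage
        } else {
            rejected[[verdict]] <- rejected[[verdict]] + 1L
        }
    }
    if (length(keepIdx) == 0L) stop("empty training set")
    lineages <- as.data.frame(do.call(rbind, keptLin),
                              stringsAsFactors = FALSE)
    ts <- newTrainingSet(candidates$id[keepIdx],
                         candidates$sequence[keepIdx], lineages,
                         trainedRank = policy@trainedRank)
    list(trainingSet = ts,
         report = list(kept = length(keepIdx), rejected = rejected))
}

#' Proportion of taxa represented by a single sequence
#'
#' Singleton taxa cannot be recovered during leave-one-out
#' cross-validation (removing their only sequence removes the taxon), so
#' several summaries exclude them; this census reports how prevalent they
#' are at a given rank.
#'
#' @param ts a [TrainingSet-class].
#' @param rank rank at which to count taxa; default the trained rank.
#' @return Proportion in \code{[0, 1]} of taxa at \code{rank} with
#'   exactly one sequence.
#' @export
singletonCensus <- function(ts, rank = trainedRank(ts)) {
    tab <- table(ts@lineages[[rank]])
    as.numeric(mean(tab == 1L))
}
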