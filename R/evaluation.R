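## Evaluation outcome tables are plain data.frames with, per rank r:
## truth_r, taxon_r, support_r, correct_r; plus queryId, singletonQuery.

.outcomeRow <- function(assignment, truth, singletonQuery) {
    row <- .assignmentRow(assignment)
    for (r in names(assignment@taxa)) {
        row[[paste0("truth_", r)]] <- truth[[r]]
        row[[paste0("correct_", r)]] <-
            !is.na(truth[[r]]) && assignment@taxa[[r]] == truth[[r]]
    }
    row$singletonQuery <- singletonQuery
    row
}

.outcomeRanks <- function(outcomes) {
    sub("^correct_", "", grep("^correct_", names(outcomes), value = TRUE))
}

#' Leave-one-out cross-validation of a training set
#'
#' Classifies every training sequence with itself removed from the
#' reference: the held-out sequence's word counts are subtracted from the
#' model for its own classification and restored afterwards (a taxon
#' emptied by the removal is excluded from the candidates for that
#' query). This simulates assignments against a potentially incomplete
#' reference database. Optionally each query is a single contiguous
#' fragment of the stated length sampled at a uniformly random start,
#' emulating the short reads of high-throughput platforms.
#'
#' @param ts a [TrainingSet-class].
#' @param params a [ClassifierParams-class].
#' @param fragmentLength query fragment length in nt (e.g. 50, 100, 200,
#'   400), or \code{NULL} for full-length queries. Sequences shorter than
#'   the fragment are skipped and reported in the \code{"skipped"}
#'   attribute.
#' @param seed seed applied once for the whole run.
#' @return Outcome data.frame, one row per tested sequence: truth,
#'   assigned taxon and support per rank, per-rank correctness flags, and
#'   \code{singletonQuery} (the query's true taxon at the trained rank
#'   had exactly one sequence before removal).
#' @export
loocv <- function(ts, params = ClassifierParams(), fragmentLength = NULL,
                  seed = NULL) {
    model <- trainClassifier(ts, params)
    if (!is.null(seed)) set.seed(seed)
    perQuery <- params
    perQuery@seed <- NA_integer_
    tr <- ts@trainedRank
    gsize <- table(ts@lineages[[tr]])
    seqs <- as.character(ts@sequences)
    ids <- names(ts@sequences)
    rows <- list()
    skipped <- character(0)
    for (i in seq_along(seqs)) {
        full <- seqs[i]
        if (!is.null(fragmentLength)) {
            if (fragmentLength > nchar(full)) {
                skipped <- c(skipped, ids[i])
                next
            }
            query <- sampleFragment(full, fragmentLength)
        } else {
            query <- full
        }
        truth <- setNames(as.character(unlist(ts@lineages[i, ])),
                          names(ts@lineages))
        gname <- truth[[tr]]
        holdout <- list(genusIndex = match(gname, model@genera),
                        codes = unique(.wordCodes(full, model@k)$codes))
        a <- .classifyInternal(model, query, perQuery, id = ids[i],
                               holdout = holdout)
        rows[[length(rows) + 1L]] <-
            .outcomeRow(a, truth, unname(gsize[gname]) == 1L)
    }
    out <- if (length(rows)) do.call(rbind, rows) else data.frame()
    attr(out, "skipped") <- skipped
    out
}

#' Self-classification against the complete reference
#'
#' Classifies every training sequence against the untouched model,
#' simulating assignments when the reference database is known to be
#' complete (it contains an exact match to each query). Accuracy here
#' bounds LOOCV accuracy from above and localizes problematic taxonomic
#' coverage.
#'
#' @inheritParams loocv
#' @return Outcome data.frame as in [loocv()].
#' @export
completeReferenceTest <- function(ts, params = ClassifierParams(),
                                  seed = NULL) {
    model <- trainClassifier(ts, params)
    if (!is.null(seed)) set.seed(seed)
    perQuery <- params
    perQuery@seed <- NA_integer_
    tr <- ts@trainedRank
    gsize <- table(ts@lineages[[tr]])
    seqs <- as.character(ts@sequences)
    ids <- names(ts@sequences)
    rows <- lapply(seq_along(seqs), function(i) {
        truth <- setNames(as.character(unlist(ts@lineages[i, ])),
                          names(ts@lineages))
        a <- .classifyInternal(model, seqs[i], perQuery, id = ids[i])
        .outcomeRow(a, truth, unname(gsize[truth[[tr]]]) == 1L)
    })
    do.call(rbind, rows)
}

#' Classify a labeled query set into an outcome table
#'
#' Convenience wrapper pairing a model's assignments for a
#' [LabeledQuerySet-class] with the known truths, producing the same
#' outcome table as [loocv()] (singleton flags refer to the query's true
#' taxon having a single reference sequence; novel taxa are flagged in a
#' \code{novel} column).
#'
#' @param model a [KmerModel-class].
#' @param qs a [LabeledQuerySet-class].
#' @param ts the paired [TrainingSet-class] (for singleton flags).
#' @param params a [ClassifierParams-class].
#' @return Outcome data.frame with an extra \code{novel} column.
#' @export
evaluateQueries <- function(model, qs, ts, params = ClassifierParams()) {
    perQuery <- params
    if (!is.na(params@seed)) set.seed(params@seed)
    perQuery@seed <- NA_integer_
    tr <- model@trainedRank
    gsize <- table(ts@lineages[[tr]])
    seqs <- as.character(qs@queries)
    rows <- lapply(seq_along(seqs), function(i) {
        truth <- qs@truth[i, ]
        tlin <- setNames(as.character(unlist(
            truth[names(model@lineages)])), names(model@lineages))
        a <- .classifyInternal(model, seqs[i], perQuery,
                               id = truth$queryId)
        g <- tlin[[tr]]
        singleton <- !is.na(g) && !is.na(match(g, names(gsize))) &&
            unname(gsize[g]) == 1L
        row <- .outcomeRow(a, tlin, singleton)
        row$novel <- truth$novel
        row
    })
    do.call(rbind, rows)
}

#' Per-rank accuracy among retained assignments
#'
#' Accuracy is the number of correct queries over the number of tested
#' queries, times 100, at each rank. A query is retained when its
#' support at the rank meets the cut-off. Singleton queries are excluded
#' by default (their LOOCV assignment cannot be correct at the trained
#' rank, so they are not summarized).
#'
#' @param outcomes outcome data.frame from [loocv()] and friends.
#' @param cutoff minimum bootstrap support for retention (default 0).
#' @param includeSingletons keep singleton queries (default FALSE).
#' @return Named numeric: percent correct among retained per rank
#'   (NA when nothing is retained).
#' @export
accuracyByRank <- function(outcomes, cutoff = 0, includeSingletons = FALSE) {
    if (!includeSingletons)
        outcomes <- outcomes[!outcomes$singletonQuery, , drop = FALSE]
    ranks <- .outcomeRanks(outcomes)
    vapply(ranks, function(r) {
        sup <- outcomes[[paste0("support_", r)]]
        ok <- outcomes[[paste0("correct_", r)]]
        ret <- sup >= cutoff
        if (!any(ret)) return(NA_real_)
        100 * sum(ok[ret]) / sum(ret)
    }, numeric(1))
}

#' Type I / type II error rates under a support cut-off
#'
#' Per rank, over all queries (singletons included by default): type I
#' error is the percentage misclassified with support at or above the
#' cut-off (confidently wrong); type II error is the percentage
#' correctly classified with support below the cut-off (right but
#' discarded). Together with the correct-retained and wrong-withheld
#' percentages they partition every query, so the four sum to 100.
#'
#' @param outcomes outcome data.frame.
#' @param cutoff support cut-off (default 90).
#' @param includeSingletons default TRUE.
#' @return data.frame with one row per rank: \code{typeI}, \code{typeII},
#'   \code{correctRetained}, \code{wrongWithheld} (percent), plus the
#'   cut-off used.
#' @export
errorRates <- function(outcomes, cutoff = 90, includeSingletons = TRUE) {
    if (!includeSingletons)
        outcomes <- outcomes[!outcomes$singletonQuery, , drop = FALSE]
    ranks <- .outcomeRanks(outcomes)
    n <- nrow(outcomes)
    rows <- lapply(ranks, function(r) {
        sup <- outcomes[[paste0("support_", r)]]
        ok <- outcomes[[paste0("correct_", r)]]
        ret <- sup >= cutoff
        data.frame(rank = r,
                   typeI = 100 * sum(!ok & ret) / n,
                   typeII = 100 * sum(ok & !ret) / n,
                   correctRetained = 100 * sum(ok & ret) / n,
                   wrongWithheld = 100 * sum(!ok & !ret) / n,
                   cutoff = cutoff, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Bootstrap support cut-offs achieving a target accuracy
#'
#' For each rank and query-length class, finds the smallest cut-off on a
#' grid (default 0, 5, ..., 100) at which at least the target percentage
#' of retained queries is correctly classified, with at least one query
#' retained; NA when no grid value qualifies. Singletons are not
#' summarized. Longer queries and more inclusive ranks generally admit
#' lower cut-offs while retaining more assignments.
#'
#' @param outcomesByLength named list of outcome data.frames, one per
#'   query-length class (e.g. \code{"50"}, \code{"100"}, \code{"full"}).
#' @param target required percent correct among retained (default 99).
#' @param grid candidate cut-offs.
#' @return data.frame: ranks as rows, length classes as columns; entries
#'   are cut-offs or NA.
#' @export
selectCutoffs <- function(outcomesByLength, target = 99,
                          grid = seq(0, 100, by = 5)) {
    stopifnot(length(outcomesByLength) >= 1L)
    ranks <- .outcomeRanks(outcomesByLength[[1L]])
    res <- matrix(NA_integer_, nrow = length(ranks),
                  ncol = length(outcomesByLength),
                  dimnames = list(ranks, names(outcomesByLength)))
    for (lc in names(outcomesByLength)) {
        out <- outcomesByLength[[lc]]
        out <- out[!out$singletonQuery, , drop = FALSE]
        for (r in ranks) {
            sup <- out[[paste0("support_", r)]]
            ok <- out[[paste0("correct_", r)]]
            lastRetained <- Inf
            for (cut in grid) {
                ret <- sup >= cut
                nRet <- sum(ret)
                stopifnot(nRet <= lastRetained)  # monotone retention
                lastRetained <- nRet
                if (nRet >= 1L && 100 * sum(ok[ret]) / nRet >= target) {
                    res[r, lc] <- as.integer(cut)
                    break
                }
            }
        }
    }
    as.data.frame(res)
}

#' Match / nonmatch / not-classified partition at a rank
#'
#' Compares classifier assignments with independent (e.g.
#' morphology-based) truths at one rank under a support cut-off. A query
#' below the cut-off is "not classified"; otherwise it is a "match" when
#' the assigned and true taxa agree and a "nonmatch" when they do not.
#' When a query's taxon is absent from the reference, raising the
#' cut-off converts nonmatches into not-classified instead of errors.
#'
#' @param outcomes outcome data.frame.
#' @param rank rank at which to compare.
#' @param cutoff support cut-off.
#' @return Named integer vector: \code{match}, \code{nonmatch},
#'   \code{not_classified} (they sum to the number of queries).
#' @export
matchTable <- function(outcomes, rank, cutoff = 0) {
    sup <- outcomes[[paste0("support_", rank)]]
    assigned <- outcomes[[paste0("taxon_", rank)]]
    truth <- outcomes[[paste0("truth_", rank)]]
    nc <- sup < cutoff
    match_ <- !nc & !is.na(truth) & assigned == truth
    nonmatch <- !nc & !match_
    c(match = sum(match_), nonmatch = sum(nonmatch),
      not_classified = sum(nc))
}

#' Misclassification rates per taxonomic group
#'
#' Groups queries by their true taxon at a grouping rank (default order)
#' and reports, per group, the number of queries and the percentage
#' misclassified among assignments retained at the cut-off. Raising the
#' cut-off can only shrink the retained set, so no group's misclassified
#' count increases. Groups poorly represented in the reference tend to
#' show the highest rates.
#'
#' @param outcomes outcome data.frame.
#' @param groupRank rank used to group queries (default "order").
#' @param rank rank at which correctness is judged (default the grouping
#'   rank).
#' @param cutoff support cut-off (0 = no cut-off).
#' @return data.frame: \code{group}, \code{n}, \code{misclassified},
#'   \code{pctMisclassified}.
#' @export
misclassificationByGroup <- function(outcomes, groupRank = "order",
                                     rank = groupRank, cutoff = 0) {
    grp <- outcomes[[paste0("truth_", groupRank)]]
    sup <- outcomes[[paste0("support_", rank)]]
    ok <- outcomes[[paste0("correct_", rank)]]
    wrongRetained <- !ok & sup >= cutoff
    rows <- lapply(sort(unique(grp)), function(g) {
        sel <- grp == g
        data.frame(group = g, n = sum(sel),
                   misclassified = sum(wrongRetained[sel]),
                   pctMisclassified = 100 * sum(wrongRetained[sel]) /
                       sum(sel), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Histogram of bootstrap support values
#'
#' Pools support values at one rank into bins of the given width
#' (default 10 percentage points) and reports the proportion of queries
#' in each bin. The terminal bin is closed so that support 100 falls in
#' [90, 100]. Longer queries shift mass toward high-support bins.
#'
#' @param outcomes outcome data.frame (or any data.frame with a
#'   \code{support_<rank>} column).
#' @param rank rank whose supports are binned.
#' @param binWidth bin width in percentage points (must divide 100).
#' @return Named numeric vector of proportions, summing to 1.
#' @export
supportHistogram <- function(outcomes, rank, binWidth = 10) {
    sup <- outcomes[[paste0("support_", rank)]]
    if (is.null(sup) || length(sup) == 0L) stop("no support values")
    stopifnot(100 %% binWidth == 0)
    breaks <- seq(0, 100, by = binWidth)
    bins <- cut(sup, breaks = breaks, right = FALSE,
                include.lowest = TRUE)
    ## right-open bins, except the last which includes 100
    bins[sup == 100] <- levels(bins)[length(levels(bins))]
    prop <- as.numeric(table(bins)) / length(sup)
    setNames(prop, levels(bins))
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Coverage of described taxa by a reference training set
#'
#' Compares, per insect order, the number of described extant families
#' and genera against the number represented in a training set, as a
#' rounded percentage. Orders without a described-count estimate
#' (NA, printed as "?") are excluded from described totals and from the
#' averages, but their represented counts still enter the represented
#' totals. The \code{Total} row is the ratio of column sums; the
#' \code{Average} row is the mean of the per-order values.
#'
#' @param described data.frame: \code{order}, \code{families},
#'   \code{genera} (NA = no estimate). A described count of 0 is an
#'   error (the ratio is undefined; encode it as NA).
#' @param trainingSet optional [TrainingSet-class] from which represented
#'   counts per order are tallied.
#' @param represented optional data.frame \code{order}, \code{families},
#'   \code{genera} giving represented counts directly (used when
#'   \code{trainingSet} is NULL).
#' @return data.frame with per-order rows plus \code{Total} and
#'   \code{Average} rows; columns \code{order}, \code{describedFamilies},
#'   \code{representedFamilies}, \code{pctFamilies},
#'   \code{describedGenera}, \code{representedGenera}, \code{pctGenera}.
#' @export
coverageSummary <- function(described, trainingSet = NULL,
                            represented = NULL) {
    stopifnot(all(c("order", "families", "genera") %in% names(described)))
    if (any(!is.na(described$families) & described$families == 0) ||
        any(!is.na(described$genera) & described$genera == 0))
        stop("no described estimate: a described count of 0 is undefined; ",
             "encode unknown estimates as NA")
    if (!is.null(trainingSet)) {
        lin <- refLineages(trainingSet)
        stopifnot(all(c("order", "family") %in% names(lin)))
        repFam <- vapply(described$order, function(o)
            length(unique(lin$family[lin$order == o])), integer(1))
        repGen <- if ("genus" %in% names(lin))
            vapply(described$order, function(o)
                length(unique(lin$genus[lin$order == o])), integer(1))
        else rep(NA_integer_, nrow(described))
    } else {
        stopifnot(!is.null(represented))
        i <- match(described$order, represented$order)
        repFam <- represented$families[i]
        repGen <- represented$genera[i]
    }
    pf <- ifelse(is.na(described$families), NA_real_,
                 .roundHalfUp(100 * repFam / described$families))
    pg <- ifelse(is.na(described$genera), NA_real_,
                 .roundHalfUp(100 * repGen / described$genera))
    per <- data.frame(order = described$order,
                      describedFamilies = described$families,
                      representedFamilies = repFam, pctFamilies = pf,
                      describedGenera = described$genera,
                      representedGenera = repGen, pctGenera = pg,
                      stringsAsFactors = FALSE)
    total <- data.frame(order = "Total",
        describedFamilies = sum(per$describedFamilies, na.rm = TRUE),
        representedFamilies = sum(per$representedFamilies),
        pctFamilies = .roundHalfUp(100 * sum(per$representedFamilies) /
            sum(per$describedFamilies, na.rm = TRUE)),
        describedGenera = sum(per$describedGenera, na.rm = TRUE),
        representedGenera = sum(per$representedGenera),
        pctGenera = .roundHalfUp(100 * sum(per$representedGenera) /
            sum(per$describedGenera, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    average <- data.frame(order = "Average",
        describedFamilies = .roundHalfUp(mean(per$describedFamilies,
                                              na.rm = TRUE)),
        representedFamilies = .roundHalfUp(mean(per$representedFamilies)),
        pctFamilies = .roundHalfUp(mean(per$pctFamilies, na.rm = TRUE)),
        describedGenera = .roundHalfUp(mean(per$describedGenera,
                                            na.rm = TRUE)),
        representedGenera = .roundHalfUp(mean(per$representedGenera)),
        pctGenera = .roundHalfUp(mean(per$pctGenera, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    rbind(per, total, average)
}
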