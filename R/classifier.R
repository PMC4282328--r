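## Integer encoding of k-mers: A,C,G,T -> 0..3, base-4 positional code.
## Any other character gives NA, which propagates to every window
## overlapping it; those windows are dropped (and counted).

.baseCodes <- function(x) {
    v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    match(v, c("A", "C", "G", "T")) - 1L
}

.wordCodes <- function(x, k) {
    v <- .baseCodes(x)
    L <- length(v)
    if (L < k) stop("query too short: ", L, " nt < k = ", k)
    nw <- L - k + 1L
    idx <- outer(seq_len(nw), 0L:(k - 1L), `+`)
    mat <- matrix(v[idx], nrow = nw)
    code <- as.integer(mat %*% 4^((k - 1L):0L))
    keep <- !is.na(code)
    list(codes = code[keep], dropped = sum(!keep), total = nw)
}

.decodeWords <- function(codes, k) {
    bases <- c("A", "C", "G", "T")
    out <- character(length(codes))
    for (i in seq_along(codes)) {
        c0 <- codes[i]
        w <- character(k)
        for (j in k:1) {
            w[j] <- bases[c0 %% 4L + 1L]
            c0 <- c0 %/% 4L
        }
        out[i] <- paste(w, collapse = "")
    }
    out
}

#' Break a sequence into overlapping k-mer words
#'
#' A sequence of length L yields all L - k + 1 overlapping words of
#' length k. Windows containing characters outside A/C/G/T (Ns,
#' ambiguity codes) are dropped and counted.
#'
#' @param sequence nucleotide string.
#' @param k word size (default 8).
#' @return list with \code{multiset} (every window, in order),
#'   \code{set} (deduplicated words) and \code{dropped} (windows lost to
#'   non-ACGT characters).
#' @export
#' @examples
#' extractWords("ACGTACGTA", k = 8)
extractWords <- function(sequence, k = 8) {
    k <- as.integer(k)
    wc <- .wordCodes(sequence, k)
    multiset <- .decodeWords(wc$codes, k)
    list(multiset = multiset, set = unique(multiset), dropped = wc$dropped)
}

#' Train the naive Bayesian k-mer classifier
#'
#' Counts, for every word of length k, the number of training sequences
#' containing it overall (n(w)) and within each taxon at the trained
#' rank (m(w, G)). Containment is per sequence -- a word occurring five
#' times in one sequence counts once -- which guarantees
#' m(w, G) <= M(G). Training is deterministic: permuting the records
#' yields an identical model.
#'
#' @param ts a [TrainingSet-class].
#' @param params a [ClassifierParams-class]; only \code{k} is used here.
#' @return A [KmerModel-class].
#' @export
trainClassifier <- function(ts, params = ClassifierParams()) {
    stopifnot(is(ts, "TrainingSet"))
    k <- params@k
    tr <- ts@trainedRank
    genera <- sort(unique(ts@lineages[[tr]]))
    nG <- length(genera)
    nWords <- 4L^k
    n <- integer(nWords)
    m <- matrix(0L, nrow = nG, ncol = nWords)
    M <- integer(nG)
    linRows <- integer(nG)
    seqs <- as.character(ts@sequences)
    gidx <- match(ts@lineages[[tr]], genera)
    for (i in seq_along(seqs)) {
        if (nchar(seqs[i]) < k) {
            warning("record '", names(ts@sequences)[i],
                    "' shorter than k = ", k, "; excluded from training")
            next
        }
        u <- unique(.wordCodes(seqs[i], k)$codes) + 1L
        g <- gidx[i]
        n[u] <- n[u] + 1L
        m[g, u] <- m[g, u] + 1L
        M[g] <- M[g] + 1L
        if (linRows[g] == 0L) linRows[g] <- i
    }
    if (any(M == 0L)) stop("a trained taxon has no usable sequence")
    lineages <- ts@lineages[linRows, , drop = FALSE]
    rownames(lineages) <- NULL
    new("KmerModel", k = k, genera = genera, M = M, N = sum(M),
        wordCount = n, genusWordCount = m, lineages = lineages,
        trainedRank = tr)
}

## Log-probability submatrix for a set of word codes (0-based, unique).
## holdout = list(genusIndex, codes) removes one sequence's counts, the
## decrement form of leave-one-out; a genus emptied by the removal is
## dropped from the candidate rows.
.scoreSubmatrix <- function(model, codes, holdout = NULL) {
    cols <- codes + 1L
    msub <- model@genusWordCount[, cols, drop = FALSE]
    nsub <- model@wordCount[cols]
    M <- model@M
    N <- model@N
    keep <- seq_along(model@genera)
    if (!is.null(holdout)) {
        present <- codes %in% holdout$codes
        gi <- holdout$genusIndex
        nsub[present] <- nsub[present] - 1L
        msub[gi, present] <- msub[gi, present] - 1L
        M[gi] <- M[gi] - 1L
        N <- N - 1L
        if (M[gi] == 0L) keep <- keep[-gi]
        msub <- msub[keep, , drop = FALSE]
        M <- M[keep]
    }
    if (length(keep) == 0L) stop("no candidate taxa remain in the model")
    prior <- (nsub + 0.5) / (N + 1)
    logP <- log(msub + matrix(prior, nrow = nrow(msub), ncol = length(prior),
                              byrow = TRUE)) - log(M + 1)
    list(logP = logP, keep = keep, M = M)
}

#' Per-genus log posterior score of a word set
#'
#' The score of genus G for a query with deduplicated word set W is
#' sum over w in W of log P(w | G), with
#' P(w | G) = (m(w, G) + Pi(w)) / (M(G) + 1) and word prior
#' Pi(w) = (n(w) + 0.5) / (N + 1). The prior is strictly positive, so
#' the score is finite even for words never seen in training.
#'
#' @param model a [KmerModel-class].
#' @param words character vector of words (treated as a set; words with
#'   non-ACGT characters are dropped).
#' @param genus taxon name at the trained rank.
#' @return The log score (0 for an empty word set).
#' @export
genusLogScore <- function(model, words, genus) {
    gi <- match(genus, model@genera)
    if (is.na(gi)) stop("unknown genus '", genus, "'")
    words <- unique(words)
    if (length(words) == 0L) return(0)
    stopifnot(all(nchar(words) == model@k))
    codes <- vapply(words, function(w) {
        v <- .baseCodes(w)
        if (anyNA(v)) NA_integer_
        else as.integer(sum(v * 4^((model@k - 1L):0L)))
    }, integer(1), USE.NAMES = FALSE)
    codes <- codes[!is.na(codes)]
    if (length(codes) == 0L) return(0)
    sub <- .scoreSubmatrix(model, codes)
    sum(sub$logP[gi, ])
}

.reverseComplement <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Deepest lineage-prefix agreement of every genus with genus `win`,
## counted in ranks (1 = agrees at kingdom only; ncol = same genus).
.agreeDepth <- function(lineages, win) {
    linM <- as.matrix(lineages)
    nR <- ncol(linM)
    agree <- matrix(linM == matrix(linM[win, ], nrow = nrow(linM),
                                   ncol = nR, byrow = TRUE),
                    nrow = nrow(linM))
    ## depth of the first disagreement minus one; placeholders compare by
    ## full path prefix, so equal names under different parents differ
    cum <- t(apply(agree, 1L, cumprod))
    if (nR == 1L) cum <- matrix(agree[, 1L], ncol = 1L)
    rowSums(cum)
}

#' Classify a query sequence
#'
#' Scores every taxon at the trained rank by the naive Bayes log
#' posterior of the query's deduplicated word set, optionally for both
#' orientations (the better-scoring orientation is kept), and reports the
#' argmax taxon with its full lineage. Ties at the top score are broken
#' lexicographically and flagged. Bootstrap confidence is then estimated
#' over \code{nBootstrap} trials: each trial draws
#' \code{ceiling(words * bootstrapFraction)} words with replacement from
#' the chosen orientation's word multiset and recomputes the argmax; the
#' support of a taxon at any rank is the percentage of trials whose
#' winning genus lies beneath it, so support never decreases toward the
#' root.
#'
#' @param model a [KmerModel-class].
#' @param sequence query nucleotide string (>= k nt).
#' @param params a [ClassifierParams-class]. When \code{seed} is set the
#'   call is reproducible and the caller's RNG state is left untouched.
#' @param id query identifier for the result.
#' @return An [Assignment-class].
#' @export
classifySeq <- function(model, sequence, params = ClassifierParams(),
                        id = "query") {
    .classifyInternal(model, sequence, params, id, holdout = NULL)
}

.classifyInternal <- function(model, sequence, params, id, holdout = NULL) {
    stopifnot(is(model, "KmerModel"))
    if (!is.na(params@seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old))
            assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(params@seed)
    }
    k <- model@k
    fwd <- .wordCodes(sequence, k)$codes
    orientations <- list(forward = fwd)
    if (params@checkReverseComplement)
        orientations$reverse <- .wordCodes(.reverseComplement(sequence),
                                           k)$codes
    best <- NULL
    for (o in names(orientations)) {
        u <- unique(orientations[[o]])
        sub <- .scoreSubmatrix(model, u, holdout)
        sc <- rowSums(sub$logP)
        if (is.null(best) || max(sc) > best$top) {
            best <- list(orientation = o, scores = sc, sub = sub,
                         unique = u, multiset = orientations[[o]],
                         top = max(sc))
        }
    }
    keep <- best$sub$keep
    genera <- model@genera[keep]
    winLocal <- which.max(best$scores)
    tie <- sum(best$scores == best$scores[winLocal]) > 1L
    lineages <- model@lineages[keep, , drop = FALSE]
    ## bootstrap over the chosen orientation's word multiset
    nB <- params@nBootstrap
    mult <- best$multiset
    nDraw <- as.integer(ceiling(length(mult) * params@bootstrapFraction))
    winners <- integer(nB)
    if (nDraw == 0L || length(mult) == 0L) {
        winners[] <- winLocal
    } else {
        map <- match(mult, best$unique)
        logP <- best$sub$logP
        for (t in seq_len(nB)) {
            drawn <- map[sample.int(length(mult), nDraw, replace = TRUE)]
            winners[t] <- which.max(.rowSumsFast(logP, drawn))
        }
    }
    depth <- .agreeDepth(lineages, winLocal)
    nR <- ncol(lineages)
    cnt <- vapply(seq_len(nR), function(d) sum(depth[winners] >= d),
                  integer(1))
    support <- as.integer(round(100 * cnt / nB))
    taxa <- setNames(as.character(unlist(lineages[winLocal, ])),
                     names(lineages))
    new("Assignment", queryId = id, taxa = taxa,
        support = setNames(support, names(lineages)),
        orientation = best$orientation,
        singleton = best$sub$M[winLocal] == 1L, tie = tie)
}

.rowSumsFast <- function(logP, cols) {
    .rowSums(logP[, cols, drop = FALSE], nrow(logP), length(cols))
}

#' Classify many queries into a result table
#'
#' @param model a [KmerModel-class].
#' @param queries \code{DNAStringSet} or named character vector.
#' @param params a [ClassifierParams-class]. \code{seed}, when set,
#'   seeds the whole batch once (queries then consume one RNG stream).
#' @return data.frame with \code{queryId}, per-rank \code{taxon_<rank>}
#'   and \code{support_<rank>} columns, \code{orientation},
#'   \code{singleton} and \code{tie}.
#' @export
classifySequences <- function(model, queries, params = ClassifierParams()) {
    if (is(queries, "DNAStringSet")) queries <- as.character(queries)
    ids <- names(queries)
    if (is.null(ids)) ids <- paste0("query", seq_along(queries))
    if (!is.na(params@seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old))
            assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(params@seed)
    }
    perQuery <- params
    perQuery@seed <- NA_integer_
    rows <- lapply(seq_along(queries), function(i)
        .assignmentRow(classifySeq(model, queries[[i]], perQuery,
                                   id = ids[i])))
    do.call(rbind, rows)
}

.assignmentRow <- function(a) {
    out <- data.frame(queryId = a@queryId, stringsAsFactors = FALSE)
    for (r in names(a@taxa)) {
        out[[paste0("taxon_", r)]] <- a@taxa[[r]]
        out[[paste0("support_", r)]] <- a@support[[r]]
    }
    out$orientation <- a@orientation
    out$singleton <- a@singleton
    out$tie <- a@tie
    out
}

#' Summarize an assignment to a rank under a support cut-off
#'
#' Reports the assignment's taxon at \code{rank} when its bootstrap
#' support meets the cut-off, otherwise \code{"unclassified"}. A cut-off
#' of 0 never withholds an assignment. Summarizing to more inclusive
#' ranks trades taxonomic resolution for accuracy, since support grows
#' toward the root.
#'
#' @param assignment an [Assignment-class].
#' @param rank rank name.
#' @param cutoff minimum support percentage in \code{[0, 100]}.
#' @return The taxon name or \code{"unclassified"}.
#' @export
summarizeToRank <- function(assignment, rank, cutoff = 0) {
    sup <- bootstrapSupport(assignment, rank)
    if (is.null(sup) || is.na(sup)) stop("rank '", rank,
                                         "' not in assignment")
    if (sup >= cutoff) assignedTaxon(assignment, rank) else "unclassified"
}
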