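## Shared fixtures and independent oracles. The oracles deliberately use
## naive string operations (substring k-mer sets, plain-arithmetic
## probability products, full model retrains) so they share no code with
## the implementation they check.

fullLineage <- function(genus, family = "FamA", order = "Ord1",
                        class = "Insecta", phylum = "Arthropoda",
                        kingdom = "Metazoa") {
    data.frame(kingdom = kingdom, phylum = phylum, class = class,
               order = order, family = family, genus = genus,
               stringsAsFactors = FALSE)
}

## The two-genus toy model with disjoint sequences used across tests:
## genus A = ACGTACGTA, genus B = TTTTTTTTT.
disjointPair <- function() {
    lin <- rbind(fullLineage("GenA"), fullLineage("GenB"))
    newTrainingSet(c("a1", "b1"), c("ACGTACGTA", "TTTTTTTTT"), lin)
}

## Substring-based k-mer set (independent of the bit-coded extractor).
kmerSetNaive <- function(s, k) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- vapply(seq_len(L - k + 1L), function(i) substr(s, i, i + k - 1L),
                character(1))
    unique(w[grepl("^[ACGT]+$", w)])
}

## Plain-arithmetic posterior enumeration: products of
## (m + (n + 0.5)/(N + 1)) / (M + 1) over the query's word set, no logs.
bruteForceArgmax <- function(ts, query, k) {
    recs <- as.character(refSequences(ts))
    gen <- refLineages(ts)[[trainedRank(ts)]]
    sets <- lapply(recs, kmerSetNaive, k = k)
    W <- kmerSetNaive(query, k)
    N <- length(recs)
    genera <- sort(unique(gen))
    scores <- vapply(genera, function(g) {
        sel <- gen == g
        M <- sum(sel)
        prod(vapply(W, function(w) {
            n <- sum(vapply(sets, function(s) w %in% s, logical(1)))
            m <- sum(vapply(sets[sel], function(s) w %in% s, logical(1)))
            (m + (n + 0.5) / (N + 1)) / (M + 1)
        }, numeric(1)))
    }, numeric(1))
    genera[which.max(scores)]
}

## A random toy training set for oracle comparisons: few genera, short
## sequences, small k.
randomToyTrainingSet <- function(maxGenera = 4, maxSeqsPerGenus = 3,
                                 seqLen = c(10, 30)) {
    nG <- sample.int(maxGenera, 1L)
    ids <- character(0); seqs <- character(0); lins <- list()
    for (g in seq_len(nG)) {
        nS <- sample.int(maxSeqsPerGenus, 1L)
        for (s in seq_len(nS)) {
            L <- sample(seqLen[1]:seqLen[2], 1L)
            ids <- c(ids, sprintf("g%ds%d", g, s))
            seqs <- c(seqs, paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = ""))
            lins[[length(lins) + 1L]] <- fullLineage(
                sprintf("Gen%02d", g),
                family = sprintf("Fam%02d", (g - 1L) %/% 2L + 1L))
        }
    }
    newTrainingSet(ids, seqs, do.call(rbind, lins))
}

randomSequence <- function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

## Full-retrain leave-one-out oracle: rebuilds the model from scratch for
## every held-out sequence. Consumes the RNG in the same order as
## loocv() so seeded runs are comparable outcome for outcome.
naiveLoocvOracle <- function(ts, params, seed) {
    set.seed(seed)
    perQuery <- params
    perQuery@seed <- NA_integer_
    lin <- refLineages(ts)
    ids <- names(refSequences(ts))
    seqs <- as.character(refSequences(ts))
    tr <- trainedRank(ts)
    rows <- list()
    for (i in seq_along(seqs)) {
        sub <- newTrainingSet(ids[-i], seqs[-i],
                              lin[-i, , drop = FALSE], trainedRank = tr)
        model <- trainClassifier(sub, params)
        a <- classifySeq(model, seqs[i], perQuery, id = ids[i])
        rows[[i]] <- barcodeNBC:::.assignmentRow(a)
    }
    do.call(rbind, rows)
}

## Columns on which decrement-based LOOCV and the retrain oracle must
## agree exactly.
assignmentColumns <- function(df) {
    df[, grep("^(queryId$|taxon_|support_|orientation)", names(df)),
       drop = FALSE]
}

## Synthetic outcome table with known per-rank flags, for the
## error-partition and cut-off machinery.
syntheticOutcomes <- function(correct, support, singleton = NULL,
                              rank = "genus") {
    n <- length(correct)
    if (is.null(singleton)) singleton <- rep(FALSE, n)
    df <- data.frame(queryId = sprintf("q%d", seq_len(n)),
                     stringsAsFactors = FALSE)
    df[[paste0("taxon_", rank)]] <- ifelse(correct, "Right", "Wrong")
    df[[paste0("support_", rank)]] <- as.integer(support)
    df[[paste0("truth_", rank)]] <- "Right"
    df[[paste0("correct_", rank)]] <- correct
    df$singletonQuery <- singleton
    df
}
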