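## Sequences are simulated as integer base codes 0..3 and evolved by
## independent per-site substitution: each site mutates with the branch's
## rate, to one of the three other bases uniformly (Jukes-Cantor-like, no
## indels; barcode curation excludes gaps and ambiguity anyway).

.mutate <- function(v, rate) {
    if (rate <= 0) return(v)
    hit <- which(stats::runif(length(v)) < rate)
    if (length(hit))
        v[hit] <- (v[hit] + sample.int(3L, length(hit),
                                       replace = TRUE)) %% 4L
    v
}

.codesToString <- function(v) {
    paste(c("A", "C", "G", "T")[v + 1L], collapse = "")
}

#' Simulate a reference training set with controlled divergence
#'
#' Draws a root ancestor sequence uniformly over A/C/G/T and evolves it
#' down a balanced taxonomy (orders / families / genera / species):
#' supra-species ancestors diverge from their parent at
#' \code{interGenusDivergence} per site, species ancestors at
#' \code{intraGenusDivergence}, and reference sequences at
#' \code{intraSpeciesDivergence}. Alongside the reference taxa, a pool
#' of \emph{novel} taxa is simulated and withheld from the training set:
#' one extra genus per family plus one whole extra order. Queries drawn
#' from the novel pool emulate taxa absent from the reference database.
#' The run is reproducible bit-for-bit under the seed.
#'
#' @param params a [SimParams-class].
#' @return A [COISimulation-class] holding the reference
#'   [TrainingSet-class] (trained to genus) and every species ancestor,
#'   novel taxa included.
#' @export
#' @examples
#' sim <- simulateReference(SimParams(orders = 2, seed = 7))
#' sim
simulateReference <- function(params = SimParams()) {
    stopifnot(is(params, "SimParams"))
    set.seed(params@seed)
    L <- params@seqLength
    root <- sample.int(4L, L, replace = TRUE) - 1L
    rHi <- params@interGenusDivergence
    spRows <- list()
    spSeqs <- list()
    novelOrders <- 1L
    for (o in seq_len(params@orders + novelOrders)) {
        novelOrder <- o > params@orders
        oName <- if (novelOrder)
            sprintf("NovOrder%02d", o - params@orders)
        else sprintf("Order%02d", o)
        oSeq <- .mutate(root, rHi)
        nFam <- if (novelOrder) 1L else params@familiesPerOrder
        for (f in seq_len(nFam)) {
            fName <- sprintf("%s_Fam%02d", oName, f)
            fSeq <- .mutate(oSeq, rHi)
            ## one extra withheld genus per reference family
            nGen <- params@generaPerFamily + if (novelOrder) 0L else 1L
            for (g in seq_len(nGen)) {
                novelGenus <- novelOrder || g > params@generaPerFamily
                gName <- if (novelOrder || !novelGenus)
                    sprintf("%s_Gen%02d", fName, g)
                else sprintf("%s_NovGen%02d", fName,
                             g - params@generaPerFamily)
                gSeq <- .mutate(fSeq, rHi)
                for (s in seq_len(params@speciesPerGenus)) {
                    sName <- sprintf("%s sp%02d", gName, s)
                    sSeq <- .mutate(gSeq, params@intraGenusDivergence)
                    spRows[[length(spRows) + 1L]] <- data.frame(
                        kingdom = "Metazoa", phylum = "Arthropoda",
                        class = "Insecta", order = oName, family = fName,
                        genus = gName, species = sName,
                        novel = novelGenus, stringsAsFactors = FALSE)
                    spSeqs[[length(spSeqs) + 1L]] <- sSeq
                }
            }
        }
    }
    spLin <- do.call(rbind, spRows)
    anc <- Biostrings::DNAStringSet(vapply(spSeqs, .codesToString, ""))
    names(anc) <- spLin$species
    ## reference sequences: leaves of the non-novel species
    refIdx <- which(!spLin$novel)
    ids <- character(0)
    seqs <- character(0)
    linIdx <- integer(0)
    for (i in refIdx) {
        for (r in seq_len(params@seqsPerSpecies)) {
            ids <- c(ids, sprintf("%s_seq%02d", gsub(" ", "_",
                     spLin$species[i]), r))
            seqs <- c(seqs, .codesToString(
                .mutate(spSeqs[[i]], params@intraSpeciesDivergence)))
            linIdx <- c(linIdx, i)
        }
    }
    ts <- newTrainingSet(ids, seqs,
                         spLin[linIdx, defaultRanks(), drop = FALSE],
                         trainedRank = "genus")
    new("COISimulation", params = params, reference = ts,
        speciesAncestors = anc, speciesLineages = spLin)
}

#' Draw labeled queries from a simulated reference world
#'
#' Generates query sequences as \emph{new} draws from species ancestors
#' (mutated at the within-species rate), never verbatim copies of
#' training sequences. A fraction of query taxa
#' (\code{novelTaxonFraction}, from the simulation's parameters unless
#' overridden) is drawn from the withheld novel pool, so their true taxa
#' are absent from the paired reference. Fragment lengths are applied
#' with the same uniform-start sampler used by fragment LOOCV.
#'
#' @param sim a [COISimulation-class].
#' @param nQueries number of queries (default: one per reference
#'   species).
#' @param novelFraction proportion of queries drawn from novel taxa;
#'   default the simulation's \code{novelTaxonFraction}.
#' @param fragmentLength optional fragment length in nt.
#' @param seed optional seed for this draw.
#' @return A [LabeledQuerySet-class].
#' @export
makeQueries <- function(sim, nQueries = NULL, novelFraction = NULL,
                        fragmentLength = NULL, seed = NULL) {
    stopifnot(is(sim, "COISimulation"))
    if (!is.null(seed)) set.seed(seed)
    if (is.null(novelFraction))
        novelFraction <- sim@params@novelTaxonFraction
    lin <- sim@speciesLineages
    refSp <- which(!lin$novel)
    novSp <- which(lin$novel)
    if (is.null(nQueries)) nQueries <- length(refSp)
    nNov <- round(novelFraction * nQueries)
    pick <- function(pool, n) {
        if (n == 0L) return(integer(0))
        if (length(pool) >= n) sample(pool, n)
        else sample(pool, n, replace = TRUE)
    }
    idx <- c(pick(novSp, nNov), pick(refSp, nQueries - nNov))
    rate <- sim@params@intraSpeciesDivergence
    seqs <- character(length(idx))
    for (j in seq_along(idx)) {
        v <- .mutate(.baseCodes(as.character(
            sim@speciesAncestors[[idx[j]]])), rate)
        s <- .codesToString(v)
        if (!is.null(fragmentLength))
            s <- sampleFragment(s, fragmentLength)
        seqs[j] <- s
    }
    truth <- lin[idx, , drop = FALSE]
    truth$queryId <- sprintf("q%04d", seq_along(idx))
    rownames(truth) <- NULL
    qs <- Biostrings::DNAStringSet(seqs)
    names(qs) <- truth$queryId
    new("LabeledQuerySet", queries = qs, truth = truth)
}

#' Sample a contiguous fragment of a sequence
#'
#' Draws a single window of the requested length whose start is uniform
#' over all feasible positions, emulating the random placement of short
#' sequencing reads along a full-length barcode.
#'
#' @param sequence nucleotide string of length L.
#' @param length fragment length (error if greater than L).
#' @return The fragment.
#' @export
#' @examples
#' set.seed(1); sampleFragment(strrep("ACGT", 40), 50)
sampleFragment <- function(sequence, length) {
    L <- nchar(sequence)
    if (length > L)
        stop("fragment length ", length, " exceeds sequence length ", L)
    start <- sample.int(L - length + 1L, 1L)
    substr(sequence, start, start + length - 1L)
}
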