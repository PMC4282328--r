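genusLin <- function() c(kingdom = "Metazoa", phylum = "Arthropoda",
                         class = "Insecta", order = "Diptera",
                         family = "Culicidae", genus = "Aedes")

test_that("record screening applies the curation rules in fixed order", {
    pol <- FilterPolicy()
    lin <- genusLin()
    expect_identical(screenRecord(strrep("A", 499), "Aedes aegypti",
                                  lin, pol), "too_short")
    expect_identical(screenRecord(paste0(strrep("A", 300), "N",
                                         strrep("C", 299)),
                                  "Aedes aegypti", lin, pol), "has_N")
    expect_identical(screenRecord(paste0(strrep("A", 300), "R",
                                         strrep("C", 299)),
                                  "Aedes aegypti", lin, pol),
                     "has_ambiguity")
    expect_identical(screenRecord(strrep("ACGT", 150),
                                  "Aedes sp. BOLD-1", lin, pol),
                     "insufficient_name")
    ## a family-trained policy permits insufficiently identified names
    famPol <- FilterPolicy(trainedRank = "family")
    expect_identical(screenRecord(strrep("ACGT", 150),
                                  "Aedes sp. BOLD-1", lin, famPol),
                     "keep")
    expect_identical(screenRecord(strrep("ACGT", 150), "Aedes aegypti",
                                  lin, pol), "keep")
    ## precedence: a short sequence with an N reports too_short
    expect_identical(screenRecord(paste0("N", strrep("A", 100)),
                                  "Aedes aegypti", lin, pol), "too_short")
    ## token matching does not reject substrings ("Crispa" vs "sp.")
    expect_identical(screenRecord(strrep("ACGT", 150), "Crispa crispa",
                                  lin, pol), "keep")
})

test_that("rank completeness rejects at the trained rank, fills above it", {
    lin <- genusLin()
    noGenus <- replace(lin, "genus", NA)
    expect_false(enforceRankCompleteness(noGenus, "genus")$keep)
    ## an undef_* placeholder at the trained rank counts as missing
    undefG <- replace(lin, "genus", "undef_Culicidae")
    expect_false(enforceRankCompleteness(undefG, "genus")$keep)
    ## missing order is filled with a placeholder named after the parent
    noOrder <- replace(lin, "order", NA)
    res <- enforceRankCompleteness(noOrder, "genus")
    expect_true(res$keep)
    expect_identical(unname(res$lineage["order"]), "undef_Insecta")
    ## complete lineage untouched
    res2 <- enforceRankCompleteness(lin, "genus")
    expect_true(res2$keep)
    expect_identical(res2$lineage, lin)
    ## family-trained: missing genus is fine, missing family is not
    expect_false(enforceRankCompleteness(replace(lin, "family", NA),
                                         "family")$keep)
    expect_true(enforceRankCompleteness(noGenus, "family")$keep)
})

mixedCandidates <- function() {
    lin <- genusLin()
    base <- data.frame(id = sprintf("c%d", 1:5),
                       name = c("Aedes aegypti", "Aedes aegypti",
                                "Aedes aegypti", "Aedes sp. BOLD-1",
                                "Culex pipiens"),
                       sequence = c(strrep("A", 499),
                                    paste0(strrep("A", 300), "N",
                                           strrep("C", 299)),
                                    paste0(strrep("A", 300), "R",
                                           strrep("C", 299)),
                                    strrep("ACGT", 150),
                                    strrep("ACGA", 150)),
                       stringsAsFactors = FALSE)
    for (r in names(lin)) base[[r]] <- unname(lin[r])
    base$genus[5] <- "Culex"
    base
}

test_that("training sets keep exactly the screened records", {
    cand <- mixedCandidates()
    res <- buildTrainingSet(cand, FilterPolicy(trainedRank = "family"))
    expect_identical(res$report$kept, 2L)
    expect_identical(res$report$kept + sum(res$report$rejected),
                     nrow(cand))
    expect_identical(names(refSequences(res$trainingSet)),
                     c("c4", "c5"))
    ## family-trained lineages stop at family
    expect_identical(names(refLineages(res$trainingSet)),
                     c("kingdom", "phylum", "class", "order", "family"))

    ## duplicates for the same species are retained
    dup <- cand[c(5, 5), ]
    dup$id <- c("d1", "d2")
    res2 <- buildTrainingSet(dup, FilterPolicy())
    expect_identical(res2$report$kept, 2L)
    expect_identical(length(res2$trainingSet), 2L)

    expect_error(buildTrainingSet(cand[0, ], FilterPolicy()),
                 "empty training set")
    ## all rejected is also an empty training set
    expect_error(buildTrainingSet(cand[1:3, ], FilterPolicy()),
                 "empty training set")
})

test_that("filter accounting, order stability and monotonicity hold", {
    set.seed(99)
    lin <- genusLin()
    randomCandidates <- function(n) {
        df <- data.frame(id = sprintf("r%d", seq_len(n)),
                         name = sample(c("Aedes aegypti", "Aedes sp.",
                                         "Culex cf. pipiens"),
                                       n, replace = TRUE),
                         sequence = vapply(seq_len(n), function(i)
                             paste(sample(c("A", "C", "G", "T", "N", "R"),
                                          sample(c(480, 520), 1),
                                          replace = TRUE,
                                          prob = c(.24, .24, .24, .24,
                                                   .02, .02)),
                                   collapse = ""), ""),
                         stringsAsFactors = FALSE)
        for (r in names(lin)) df[[r]] <- unname(lin[r])
        df$genus[sample.int(n, ceiling(n / 5))] <- NA
        df
    }
    for (rep in 1:5) {
        cand <- randomCandidates(40)
        pol <- FilterPolicy(minLength = 500)
        res <- tryCatch(buildTrainingSet(cand, pol),
                        error = function(e) NULL)
        kept <- if (is.null(res)) 0L else res$report$kept
        rej <- if (is.null(res)) 40L else sum(res$report$rejected)
        expect_identical(kept + rej, 40L)

        if (!is.null(res)) {
            ## permuting candidates permutes the kept records identically
            perm <- sample.int(nrow(cand))
            res2 <- buildTrainingSet(cand[perm, ], pol)
            expect_setequal(names(refSequences(res2$trainingSet)),
                            names(refSequences(res$trainingSet)))
            ## tightening min length never increases the kept count
            res3 <- tryCatch(
                buildTrainingSet(cand, FilterPolicy(minLength = 510)),
                error = function(e) list(report = list(kept = 0L)))
            expect_lte(res3$report$kept, res$report$kept)
        }
    }
})

test_that("singleton census counts taxa represented once", {
    lin <- rbind(fullLineage("G1"), fullLineage("G2"), fullLineage("G3"),
                 fullLineage("G3"))
    set.seed(5)
    ts <- newTrainingSet(sprintf("s%d", 1:4),
                         vapply(1:4, function(i) randomSequence(40), ""),
                         lin)
    expect_equal(singletonCensus(ts, "genus"), 2 / 3)
    expect_equal(singletonCensus(ts, "family"), 0)

    lin2 <- rbind(fullLineage("G1"), fullLineage("G2"))
    ts2 <- newTrainingSet(c("a", "b"),
                          c(randomSequence(40), randomSequence(40)), lin2)
    expect_equal(singletonCensus(ts2, "genus"), 1)
})
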