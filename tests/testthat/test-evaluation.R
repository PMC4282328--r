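test_that("leave-one-out handles twins and singleton taxa as expected", {
    ## every genus has two identical sequences: the left-out query still
    ## has an exact twin, so genus accuracy is 100%
    sim <- simulateReference(SimParams(orders = 2, familiesPerOrder = 2,
        generaPerFamily = 2, speciesPerGenus = 1, seqsPerSpecies = 2,
        seqLength = 400, interGenusDivergence = 0.12,
        intraGenusDivergence = 0, intraSpeciesDivergence = 0, seed = 8))
    out <- loocv(sim@reference, ClassifierParams(), seed = 9)
    expect_equal(accuracyByRank(out, includeSingletons = TRUE)[["genus"]],
                 100)

    ## every genus a singleton: its taxon vanishes with its only
    ## sequence, so genus-rank correctness is 0%
    sim1 <- simulateReference(SimParams(orders = 2, familiesPerOrder = 2,
        generaPerFamily = 2, speciesPerGenus = 1, seqsPerSpecies = 1,
        seqLength = 400, seed = 10))
    out1 <- loocv(sim1@reference, ClassifierParams(), seed = 11)
    expect_true(all(out1$singletonQuery))
    expect_false(any(out1$correct_genus))

    ## fragment longer than the sequence: query skipped and reported
    out2 <- loocv(sim1@reference, ClassifierParams(),
                  fragmentLength = 500, seed = 12)
    expect_identical(nrow(out2), 0L)
    expect_identical(length(attr(out2, "skipped")),
                     length(sim1@reference))
})

test_that("decrement-based LOOCV equals a full retrain per query", {
    set.seed(2024)
    params <- ClassifierParams(k = 4, nBootstrap = 20,
                               checkReverseComplement = FALSE)
    for (i in 1:3) {
        ts <- randomToyTrainingSet(maxGenera = 3, maxSeqsPerGenus = 3,
                                   seqLen = c(15, 30))
        seed <- sample.int(1000, 1)
        fast <- loocv(ts, params, seed = seed)
        slow <- naiveLoocvOracle(ts, params, seed = seed)
        expect_identical(assignmentColumns(fast),
                         assignmentColumns(slow))
    }
})

test_that("complete-reference accuracy bounds LOOCV accuracy", {
    sim <- simulateReference(SimParams(orders = 2, seed = 13))
    loo <- loocv(sim@reference, ClassifierParams(), seed = 14)
    comp <- completeReferenceTest(sim@reference, ClassifierParams(),
                                  seed = 15)
    accL <- accuracyByRank(loo, includeSingletons = TRUE)
    accC <- accuracyByRank(comp, includeSingletons = TRUE)
    for (r in names(accL)) expect_gte(accC[[r]], accL[[r]])
})

test_that("accuracy is percent correct among retained queries", {
    out <- syntheticOutcomes(correct = c(rep(TRUE, 8), rep(FALSE, 2)),
                             support = rep(100, 10))
    expect_equal(accuracyByRank(out, cutoff = 0)[["genus"]], 80)
    out2 <- syntheticOutcomes(correct = rep(TRUE, 5),
                              support = c(95, 95, 95, 10, 10))
    expect_equal(accuracyByRank(out2, cutoff = 90)[["genus"]], 100)
    ## singleton exclusion changes the ratio
    out3 <- syntheticOutcomes(correct = c(TRUE, TRUE, FALSE, FALSE),
                              support = rep(100, 4),
                              singleton = c(FALSE, FALSE, TRUE, TRUE))
    expect_equal(accuracyByRank(out3)[["genus"]], 100)
    expect_equal(accuracyByRank(out3,
                                includeSingletons = TRUE)[["genus"]], 50)
    ## nothing retained -> NA
    expect_true(is.na(accuracyByRank(out2, cutoff = 96)[["genus"]]))
})

test_that("type I and II error rates follow their formulas", {
    allGood <- syntheticOutcomes(rep(TRUE, 10), rep(100, 10))
    er <- errorRates(allGood, cutoff = 90)
    expect_equal(er$typeI, 0)
    expect_equal(er$typeII, 0)

    lowSup <- syntheticOutcomes(rep(TRUE, 10), rep(50, 10))
    expect_equal(errorRates(lowSup, cutoff = 90)$typeII, 100)

    ## 10 queries: 1 wrong@95, 2 correct@50, 7 correct@95
    mixed <- syntheticOutcomes(c(FALSE, TRUE, TRUE, rep(TRUE, 7)),
                               c(95, 50, 50, rep(95, 7)))
    er2 <- errorRates(mixed, cutoff = 90)
    expect_equal(er2$typeI, 10)
    expect_equal(er2$typeII, 20)
    expect_equal(er2$correctRetained, 70)
    expect_equal(er2$wrongWithheld, 0)
})

test_that("error partition sums to 100% for random outcome sets", {
    set.seed(321)
    for (i in 1:50) {
        n <- sample(5:60, 1)
        out <- syntheticOutcomes(sample(c(TRUE, FALSE), n, TRUE),
                                 sample(0:100, n, TRUE))
        cutoff <- sample(0:100, 1)
        er <- errorRates(out, cutoff = cutoff)
        expect_equal(er$typeI + er$typeII + er$correctRetained +
                     er$wrongWithheld, 100)
    }
})

test_that("cut-off selection finds the smallest qualifying grid value", {
    ## already >= 99% correct with no cut-off
    good <- syntheticOutcomes(rep(TRUE, 200), rep(100, 200))
    sel <- selectCutoffs(list(full = good))
    expect_identical(sel["genus", "full"], 0L)

    ## no cut-off reaches 99%: wrong calls carry full support
    bad <- syntheticOutcomes(c(rep(TRUE, 5), rep(FALSE, 5)),
                             rep(100, 10))
    expect_true(is.na(selectCutoffs(list(f50 = bad))["genus", "f50"]))

    ## 98% at cut-off 0 but perfect among support-100 queries: the
    ## smallest grid value excluding the wrong call wins
    part <- syntheticOutcomes(c(FALSE, rep(TRUE, 49)),
                              c(50, rep(100, 49)))
    expect_identical(selectCutoffs(list(full = part))["genus", "full"],
                     55L)
})

test_that("match tables partition queries at a rank", {
    ## truths absent from the reference: everything is a nonmatch at
    ## cut-off 0, and raising the cut-off converts them to not_classified
    out <- syntheticOutcomes(rep(FALSE, 8), rep(60, 8))
    m0 <- matchTable(out, "genus", cutoff = 0)
    expect_identical(unname(m0), c(0L, 8L, 0L))
    m1 <- matchTable(out, "genus", cutoff = 70)
    expect_identical(unname(m1["not_classified"]), 8L)
    expect_identical(unname(m1["match"]), 0L)

    allIn <- syntheticOutcomes(rep(TRUE, 5), rep(100, 5))
    expect_identical(unname(matchTable(allIn, "genus", 0)["match"]), 5L)
    expect_identical(sum(matchTable(out, "genus", 50)), 8L)
})

test_that("per-group misclassification shrinks as the cut-off rises", {
    out <- rbind(syntheticOutcomes(c(TRUE, TRUE, FALSE, FALSE),
                                   c(100, 100, 95, 40)),
                 syntheticOutcomes(rep(TRUE, 3), rep(100, 3)))
    out$truth_order <- c(rep("OrdA", 4), rep("OrdB", 3))
    g0 <- misclassificationByGroup(out, "order", rank = "genus",
                                   cutoff = 0)
    expect_equal(g0$pctMisclassified[g0$group == "OrdA"], 50)
    expect_equal(g0$pctMisclassified[g0$group == "OrdB"], 0)
    g90 <- misclassificationByGroup(out, "order", rank = "genus",
                                    cutoff = 90)
    expect_equal(g90$misclassified[g90$group == "OrdA"], 1)
    expect_true(all(g90$misclassified <= g0$misclassified))
})

test_that("support histograms bin proportions over [0, 100]", {
    top <- syntheticOutcomes(rep(TRUE, 6), rep(100, 6))
    h <- supportHistogram(top, "genus")
    expect_equal(unname(h[length(h)]), 1)
    expect_equal(sum(h), 1)

    set.seed(4)
    unif <- syntheticOutcomes(rep(TRUE, 500), sample(0:99, 500, TRUE))
    h2 <- supportHistogram(unif, "genus")
    expect_equal(sum(h2), 1)
    expect_identical(length(h2), 10L)
    expect_true(all(abs(h2 - 0.1) < 0.06))

    expect_error(supportHistogram(top[0, ], "genus"), "no support")
})

test_that("coverage summaries reproduce the described-taxa census", {
    described <- describedTaxa("described")
    represented <- describedTaxa("represented")
    cov <- coverageSummary(described, represented = represented)

    arch <- cov[cov$order == "Archaeognatha", ]
    expect_identical(arch$pctGenera, 14)
    expect_identical(arch$pctFamilies, 100)

    ## every per-order percentage from the printed census
    printedFam <- c(100, 71, 67, 36, 50, 55, 50, 100, 77, 60, 84, 57,
                    100, 56, 100, 100, 42, 48, 69, 47, 69, 5, 100, 19,
                    50, 33, 71, 100)
    printedGen <- c(14, 10, 7, 3, 8, 11, 19, 20, NA, 9, 22, 13, 50, 22,
                    15, NA, 9, 6, 14, 20, 16, 1, 22, 2, NA, 6, 34, 3)
    per <- cov[seq_len(nrow(described)), ]
    expect_equal(per$pctFamilies, printedFam)
    expect_equal(per$pctGenera, printedGen)

    tot <- cov[cov$order == "Total", ]
    expect_identical(tot$pctFamilies, 61)
    expect_identical(tot$pctGenera, 12)
    avg <- cov[cov$order == "Average", ]
    expect_identical(avg$pctFamilies, 65)
    expect_identical(avg$pctGenera, 14)

    bad <- described
    bad$genera[1] <- 0L
    expect_error(coverageSummary(bad, represented = represented),
                 "no described estimate")
})

test_that("coverage counts can be tallied from a training set", {
    lin <- rbind(fullLineage("G1", family = "F1", order = "O1"),
                 fullLineage("G2", family = "F1", order = "O1"),
                 fullLineage("G3", family = "F2", order = "O2"))
    set.seed(6)
    ts <- newTrainingSet(sprintf("s%d", 1:3),
                         vapply(1:3, function(i) randomSequence(40), ""),
                         lin)
    described <- data.frame(order = c("O1", "O2"),
                            families = c(4L, 2L), genera = c(10L, 6L),
                            stringsAsFactors = FALSE)
    cov <- coverageSummary(described, trainingSet = ts)
    expect_equal(cov$representedGenera[1:2], c(2, 1))
    expect_identical(cov$pctFamilies[1:2], c(25, 50))
    expect_identical(cov$pctGenera[1:2], c(20, 17))
})
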