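makeFakeResult <- function(elim, best, idxMap) {
    new("RFEResult", eliminationOrder = elim,
        featureIndex = idxMap[elim],
        djAtRemoval = rep(NA_real_, length(elim)),
        accuracyCurve = data.frame(size = length(elim):1,
                                   TP = 0L, TN = 0L, M = 1L, accuracy = 0),
        bestSubset = best, bestAccuracy = 1, ratioTag = "1:1")
}

test_that("vote tally counts best-subset membership exactly", {
    idx <- c(a = 1L, b = 2L, c = 3L, d = 4L)
    elim <- c("d", "c", "b", "a")
    same <- replicate(5, makeFakeResult(elim, c("b", "a"), idx),
                      simplify = FALSE)
    tally <- tallyVotes(same)
    expect_identical(attr(tally, "totalPartitions"), 5L)
    expect_identical(tally$count[match(c("a", "b"), tally$feature)],
                     c(5L, 5L))
    expect_identical(tally$count[match(c("c", "d"), tally$feature)],
                     c(0L, 0L))

    mixed <- list(makeFakeResult(elim, c("b", "a"), idx),
                  makeFakeResult(elim, c("c", "b", "a"), idx),
                  makeFakeResult(elim, "a", idx))
    t2 <- tallyVotes(mixed)
    # double-counting identity: total votes == total best-subset sizes
    expect_identical(sum(t2$count),
                     sum(vapply(mixed, function(r) length(r@bestSubset), 1L)))
    # ranked by count desc, ties by ascending panel index
    expect_identical(t2$feature, c("a", "b", "c", "d"))
})

test_that("majority rule reproduces the published 12-feature selection", {
    ref <- referenceConsensusRanking()
    counts <- setNames(ref$count, ref$feature)
    got <- majorityFeatures(counts, threshold = 0.5, R = 300)
    expect_length(got, 12)
    expect_identical(got[1:2], c("MAO", "PHOS"))
    expect_true("TB" %in% got)              # count 150 is exactly 50%: kept
    expect_identical(majorityFeatures(counts, threshold = 1, R = 300), "MAO")
})

test_that("raising the majority threshold never lengthens the selection", {
    set.seed(5)
    counts <- setNames(sample(0:100, 30), paste0("f", 1:30))
    lens <- vapply(seq(0.05, 1, by = 0.05), function(th)
        length(majorityFeatures(counts, threshold = th, R = 100)), 1L)
    expect_true(all(diff(lens) <= 0))
    expect_error(majorityFeatures(counts, threshold = 0, R = 100),
                 "threshold")
    expect_error(majorityFeatures(counts, threshold = 0.5), "required")
})

test_that("combination curves average held-out accuracy per nested prefix", {
    co <- makeToyCohort(nSubjects = 50, shifts = c(8, 0, 0), seed = 61)
    plan <- makePartitions(co, ratios = c(1, 2), totalCount = 6, seed = 7)
    curve <- comboAccuracyCurve(c("f1", "f2", "f3"), plan, co)
    expect_identical(nrow(curve), 3L)
    expect_identical(curve$members, c("1", "1+2", "1+2+3"))
    expect_true(all(curve$meanAccuracy >= 0 & curve$meanAccuracy <= 100))
    # an 8-SD shift is perfectly separable: every prefix containing f1 is 100%
    expect_equal(curve$meanAccuracy[1], 100)
    expect_equal(panelMeanAccuracy("f1", plan, co), 100)
    # curve values equal the mean of per-partition accuracies, in percent
    X <- cohortMatrix(co); y <- cohortLabels(co)
    byHand <- mean(vapply(plan@partitions, function(p) {
        m <- trainSVM(X[p$train, c("f1", "f2"), drop = FALSE], y[p$train])
        evaluateAccuracy(m, X[p$test, c("f1", "f2"), drop = FALSE],
                         y[p$test])$P
    }, numeric(1)))
    expect_equal(curve$meanAccuracy[2], 100 * byHand, tolerance = 1e-12)
})

test_that("the final subset is the smallest best prefix", {
    curve <- data.frame(size = 1:3, added = c("x", "y", "z"),
                        members = c("1", "1+2", "1+2+3"),
                        meanAccuracy = c(80, 90, 90))
    expect_identical(selectFinalSubset(curve), c("x", "y"))
    curve$meanAccuracy <- c(80, 90, 95)
    expect_identical(selectFinalSubset(curve), c("x", "y", "z"))
    ref <- referenceConsensusRanking()
    refCurve <- data.frame(size = seq_len(nrow(ref)), added = ref$feature,
                           members = "", meanAccuracy = ref$mean_accuracy)
    expect_identical(selectFinalSubset(refCurve),
                     c("MAO", "PHOS", "CK-MB", "Ca", "LDH", "FRUC", "K",
                       "Na", "ALB"))
})
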