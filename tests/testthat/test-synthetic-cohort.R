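test_that("reference spec carries the published parameters and null defaults", {
    spec <- loadReferenceSpec()
    m <- spec@measures
    expect_identical(nrow(m), 41L)
    expect_identical(sort(m$index), 1:41)

    mao <- m[m$name == "MAO", ]
    expect_equal(c(mao$preMean, mao$preSd, mao$postMean, mao$postSd),
                 c(0.85, 0.21, 0.36, 0.18))
    phos <- m[m$name == "PHOS", ]
    expect_equal(c(phos$preMean, phos$postMean), c(1.17, 1.39))
    # consensus-summary values take precedence over the screen values
    expect_equal(m$postSd[m$name == "LDH"], 28)
    expect_equal(m$preMean[m$name == "Na"], 144.49)

    hdl <- m[m$name == "HDL", ]
    expect_identical(hdl$provenance, "null_default")
    expect_equal(hdl$preMean, hdl$postMean)
    nulls <- m[m$provenance == "null_default", ]
    expect_identical(nrow(nulls), 12L)
    expect_equal(nulls$preMean, nulls$postMean)
    expect_equal(nulls$preSd, nulls$postSd)
})

test_that("spec overrides are applied and unknown analytes rejected", {
    o <- data.frame(name = "MAO", postMean = 0.5)
    spec <- loadReferenceSpec(overrides = o)
    expect_equal(spec@measures$postMean[spec@measures$name == "MAO"], 0.5)
    expect_equal(spec@measures$postSd[spec@measures$name == "MAO"], 0.18)
    expect_error(loadReferenceSpec(overrides = data.frame(name = "XYZ",
                                                          postMean = 1)),
                 "XYZ")
    expect_error(loadReferenceSpec(overrides = data.frame(index = 99,
                                                          postMean = 1)),
                 "99")
})

test_that("generated cohorts are balanced, labeled and reproducible", {
    spec <- loadReferenceSpec()
    co <- generateCohort(spec, nSubjects = 170, seed = 11)
    expect_identical(ncol(co), 340L)
    expect_identical(sum(cohortLabels(co) == 1L), 170L)
    expect_identical(sum(cohortLabels(co) == -1L), 170L)
    expect_true(all(cohortLabels(co)[cohortPhase(co) == "pre"] == 1L))

    co2 <- generateCohort(spec, nSubjects = 170, seed = 11)
    expect_identical(SummarizedExperiment::assay(co),
                     SummarizedExperiment::assay(co2))
    co3 <- generateCohort(spec, nSubjects = 170, seed = 12)
    expect_false(identical(SummarizedExperiment::assay(co),
                           SummarizedExperiment::assay(co3)))
})

test_that("generator recovers the per-analyte moments at large n", {
    n <- 10000
    co <- generateCohort(loadReferenceSpec(), nSubjects = n, seed = 5)
    X <- cohortMatrix(co)
    m <- loadReferenceSpec()@measures
    for (ph in c("pre", "post")) {
        sub <- X[cohortPhase(co) == ph, , drop = FALSE]
        mu <- if (ph == "pre") m$preMean else m$postMean
        sig <- if (ph == "pre") m$preSd else m$postSd
        seMean <- sig / sqrt(n)
        seSd <- sig / sqrt(2 * (n - 1))
        expect_true(all(abs(colMeans(sub) - mu) < 5 * seMean))
        expect_true(all(abs(apply(sub, 2, sd) - sig) < 5 * seSd))
    }
})

test_that("within-subject correlation follows rho", {
    n <- 3000
    spec <- loadReferenceSpec()
    for (rho in c(0, 0.8)) {
        co <- generateCohort(spec, nSubjects = n, rho = rho, seed = 21)
        X <- cohortMatrix(co)
        pre <- X[cohortPhase(co) == "pre", ]
        post <- X[cohortPhase(co) == "post", ]
        r <- vapply(seq_len(ncol(X)), function(j) cor(pre[, j], post[, j]),
                    numeric(1))
        expect_true(all(abs(r - rho) < 5 / sqrt(n)))
    }
})

test_that("an analyte correlation matrix propagates to the draws", {
    R <- diag(41)
    R[1, 2] <- R[2, 1] <- 0.9
    spec <- loadReferenceSpec(corMatrix = R)
    co <- generateCohort(spec, nSubjects = 4000, seed = 3)
    pre <- cohortMatrix(co)[cohortPhase(co) == "pre", ]
    expect_gt(cor(pre[, 1], pre[, 2]), 0.8)
    expect_lt(abs(cor(pre[, 1], pre[, 3])), 0.1)
})

test_that("cohort CSV round-trips and drops incomplete rows with a count", {
    co <- generateCohort(loadReferenceSpec(), nSubjects = 2, seed = 8)
    path <- withr::local_tempfile(fileext = ".csv")
    writeCohort(co, path)
    back <- suppressMessages(readCohort(path))
    expect_equal(cohortMatrix(back), cohortMatrix(co), tolerance = 1e-12)
    expect_identical(cohortLabels(back), cohortLabels(co))
    expect_identical(S4Vectors::metadata(back)$dropped, 0L)

    # poke one missing value into a 4-row file -> 3 rows kept, 1 dropped
    tab <- read.csv(path, check.names = FALSE)
    tab$MAO[2] <- NA
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    expect_message(back2 <- readCohort(path), "dropped 1")
    expect_identical(ncol(back2), 3L)
    expect_identical(S4Vectors::metadata(back2)$dropped, 1L)
})

test_that("complete-case filter keeps 170 pairs from a 200-subject file", {
    co <- generateCohort(loadReferenceSpec(), nSubjects = 200, seed = 13)
    path <- withr::local_tempfile(fileext = ".csv")
    writeCohort(co, path)
    tab <- read.csv(path, check.names = FALSE)
    incomplete <- sprintf("S%04d", 1:30)       # both rows lose a value
    tab$GLU[tab$subject_id %in% incomplete] <- NA
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    back <- suppressMessages(readCohort(path))
    expect_identical(S4Vectors::metadata(back)$dropped, 60L)
    pairs <- intersect(cohortSubjects(back)[cohortPhase(back) == "pre"],
                       cohortSubjects(back)[cohortPhase(back) == "post"])
    expect_identical(length(pairs), 170L)
})

test_that("malformed cohort files are rejected with row/column context", {
    co <- generateCohort(loadReferenceSpec(), nSubjects = 2, seed = 8)
    path <- withr::local_tempfile(fileext = ".csv")
    writeCohort(co, path)
    tab <- read.csv(path, check.names = FALSE)

    bad <- tab; names(bad)[3] <- "NOT_AN_ANALYTE"
    f1 <- withr::local_tempfile(fileext = ".csv")
    write.csv(bad, f1, row.names = FALSE, quote = FALSE)
    expect_error(readCohort(f1), "malformed header")

    bad <- tab; bad$phase[2] <- "during"
    write.csv(bad, f1, row.names = FALSE, quote = FALSE)
    expect_error(readCohort(f1), "phase token 'during' in row 2")

    bad <- tab; bad$ALB <- as.character(bad$ALB); bad$ALB[3] <- "oops"
    write.csv(bad, f1, row.names = FALSE, quote = FALSE)
    expect_error(readCohort(f1), "row 3, column ALB")
})
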