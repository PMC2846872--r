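#' Run the full consensus-selection pipeline
#'
#' End-to-end orchestration: simulate (or accept) a paired cohort, draw
#' resampled train/test partitions across the seven mixing ratios, run
#' recursive feature elimination on every partition, tally the
#' per-partition best subsets by majority-rule voting, evaluate the nested
#' combination-accuracy curve over the majority features, pick the
#' smallest best prefix as the final consensus panel, run the paired
#' t-test screen, and compute the top-k overlap between the two rankings.
#' All randomness derives from `seed` (cohort draw) and `seed + 1`
#' (partition draw); two runs with identical settings produce identical
#' results.
#'
#' @param spec a [CohortSpec-class] (default: the reference
#'   specification); ignored when `cohort` is supplied.
#' @param cohort optional pre-built [BloodCohort-class] (e.g. from
#'   [readCohort()]); skips simulation.
#' @param repeats number of partitions R. The packaged quick default is
#'   50; pass 300 for the full published scale.
#' @param ratios train:test mixing ratios.
#' @param stratified stratify partitions by label.
#' @param config a [KernelConfig-class].
#' @param threshold majority-vote fraction in (0, 1].
#' @param alpha significance level of the t-test screen.
#' @param overlapK prefix length for the ranking overlap (default: the
#'   size of the final consensus subset).
#' @param seed master RNG seed.
#' @param verbose print per-stage progress.
#' @return a [ConsensusRun-class].
#' @examples
#' \donttest{
#' run <- runPipeline(repeats = 10, seed = 1,
#'                    spec = loadReferenceSpec(nSubjects = 60))
#' consensusSubset(run)
#' }
#' @export
runPipeline <- function(spec = loadReferenceSpec(), cohort = NULL,
                        repeats = 50L,
                        ratios = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                        stratified = TRUE, config = kernelConfig(),
                        threshold = 0.5, alpha = 0.05, overlapK = NULL,
                        seed = 1L, verbose = interactive()) {
    say <- function(...) if (verbose) message(...)
    if (is.null(cohort)) {
        say("simulating cohort: ", spec@nSubjects, " paired subjects")
        cohort <- generateCohort(spec, seed = seed)
    }
    conflicts <- checkNoConflicts(cohort)
    if (nrow(conflicts))
        warning(nrow(conflicts), " conflicting-label duplicate pair(s) in cohort")
    say("drawing ", repeats, " partitions over ", length(ratios), " ratios")
    plan <- makePartitions(cohort, ratios = ratios, totalCount = repeats,
                           seed = seed + 1L, stratified = stratified)
    say("running RFE on ", repeats, " partitions")
    rfeResults <- vector("list", repeats)
    for (i in seq_len(repeats)) {
        rfeResults[[i]] <- tryCatch(
            rfeRun(plan@partitions[[i]], cohort, config),
            error = function(e)
                stop("RFE stage failed on partition ", i, ": ",
                     conditionMessage(e), call. = FALSE))
        if (i %% 10L == 0L) say("  partition ", i, "/", repeats)
    }
    tally <- tallyVotes(rfeResults)
    majority <- majorityFeatures(tally, threshold = threshold)
    if (!length(majority))
        stop("no feature reached the ", threshold, " vote threshold")
    say("majority features (", length(majority), "): ",
        paste(majority, collapse = ", "))
    curve <- comboAccuracyCurve(majority, plan, cohort, config)
    finalSubset <- selectFinalSubset(curve)
    say("consensus subset (", length(finalSubset), "): ",
        paste(finalSubset, collapse = ", "))
    screen <- screenFeatures(cohort, alpha = alpha)
    k <- as.integer(overlapK %||% length(finalSubset))
    rfeRanking <- tally$feature
    overlap <- topkOverlap(rfeRanking, screen$feature, k)
    manifest <- list(
        nSubjects = ncol(cohort) %/% 2L, rho = spec@rho, seed = seed,
        repeats = repeats, ratios = ratios, stratified = stratified,
        kernel = config@kernel, gamma = config@gamma, cost = config@cost,
        standardize = config@standardize, threshold = threshold,
        alpha = alpha, overlapK = k,
        packageVersion = as.character(utils::packageVersion("consensusRFE")),
        rVersion = paste(R.version$major, R.version$minor, sep = "."))
    new("ConsensusRun", cohort = cohort, plan = plan,
        rfeResults = rfeResults, voteTally = tally, majority = majority,
        comboCurve = curve, finalSubset = finalSubset, screen = screen,
        overlap = overlap, manifest = manifest)
}

#' ConsensusRun accessors
#'
#' @param run a [ConsensusRun-class].
#' @return `consensusSubset()`: character vector of the final panel;
#'   `voteTally()`: the vote table; `comboCurve()`: the nested
#'   combination-accuracy table (percent).
#' @export
consensusSubset <- function(run) run@finalSubset

#' @rdname consensusSubset
#' @export
voteTally <- function(run) run@voteTally

#' @rdname consensusSubset
#' @export
comboCurve <- function(run) run@comboCurve

#' @describeIn runPipeline summary display
#' @param object a [ConsensusRun-class]
#' @export
setMethod("show", "ConsensusRun", function(object) {
    cat("ConsensusRun:", length(object@rfeResults), "partitions,",
        ncol(object@cohort), "samples\n")
    cat("  majority features:", paste(object@majority, collapse = ", "), "\n")
    best <- max(object@comboCurve$meanAccuracy)
    cat(sprintf("  consensus subset (%d, mean accuracy %.2f%%): %s\n",
                length(object@finalSubset), best,
                paste(object@finalSubset, collapse = ", ")))
    cat("  top-", object@manifest$overlapK, " overlap with t-test screen: ",
        object@overlap, "\n", sep = "")
})

#' Write the run's report bundle
#'
#' Writes plain-text reports to `dir`: the vote/combination table
#' (`vote_table.tsv`), per-partition elimination rankings
#' (`rfe_rankings.tsv`, rank 1 = last-surviving feature), per-partition
#' accuracy curves (`accuracy_curves.tsv`), the t-test screen
#' (`ttest_screen.tsv`), a consensus summary with the cohort's empirical
#' pre/post moments for the final panel (`consensus_summary.tsv`), and a
#' JSON manifest (`manifest.json`) holding every setting plus the final
#' subset and overlap, sufficient to regenerate the run.
#'
#' @param run a [ConsensusRun-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReports <- function(run, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(d, f)
        write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
    tally <- run@voteTally
    curve <- run@comboCurve
    vt <- merge(curve, tally, by.x = "added", by.y = "feature", sort = FALSE)
    vt <- data.frame(rank = vt$size, index = vt$index, feature = vt$added,
                     count = vt$count,
                     pct = round(100 * vt$fraction, 2),
                     members = vt$members,
                     meanAccuracy = round(vt$meanAccuracy, 2))
    tsv(vt, "vote_table.tsv")
    rank <- do.call(rbind, lapply(seq_along(run@rfeResults), function(i) {
        r <- run@rfeResults[[i]]
        n <- length(r@eliminationOrder)
        data.frame(partition = i, ratio = r@ratioTag, rank = n:1,
                   index = r@featureIndex, feature = r@eliminationOrder,
                   dj = r@djAtRemoval,
                   inBest = r@eliminationOrder %in% r@bestSubset)
    }))
    tsv(rank, "rfe_rankings.tsv")
    acc <- do.call(rbind, lapply(seq_along(run@rfeResults), function(i)
        cbind(partition = i, run@rfeResults[[i]]@accuracyCurve)))
    tsv(acc, "accuracy_curves.tsv")
    tsv(run@screen, "ttest_screen.tsv")
    X <- cohortMatrix(run@cohort)
    phase <- cohortPhase(run@cohort)
    fs <- run@finalSubset
    summ <- data.frame(
        feature = fs,
        units = rowData(run@cohort)$units[match(fs, rownames(run@cohort))],
        preMean = colMeans(X[phase == "pre", fs, drop = FALSE]),
        preSd = apply(X[phase == "pre", fs, drop = FALSE], 2, sd),
        postMean = colMeans(X[phase == "post", fs, drop = FALSE]),
        postSd = apply(X[phase == "post", fs, drop = FALSE], 2, sd))
    tsv(summ, "consensus_summary.tsv")
    manifest <- c(run@manifest,
                  list(finalSubset = run@finalSubset,
                       overlap = run@overlap,
                       majority = run@majority))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
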