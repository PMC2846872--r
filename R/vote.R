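#' Tally best-subset membership across partitions
#'
#' Counts, for every panel feature, how many per-partition best subsets
#' contain it. The returned table is ranked by count (descending), with
#' ties broken by ascending panel index. The partition count R is stored
#' in `attr(, "totalPartitions")`.
#'
#' @param results list of [RFEResult-class] objects.
#' @return data.frame with columns `index`, `feature`, `count`,
#'   `fraction`.
#' @export
tallyVotes <- function(results) {
    if (!length(results))
        stop("results must be non-empty")
    idxMap <- results[[1]]@featureIndex
    feats <- names(sort(idxMap))
    counts <- vapply(feats, function(f)
        sum(vapply(results, function(r) f %in% r@bestSubset, NA)), 0L)
    R <- length(results)
    idx <- as.integer(idxMap[feats])
    ord <- order(-counts, idx)
    out <- data.frame(index = idx[ord], feature = feats[ord],
                      count = as.integer(counts[ord]),
                      fraction = as.numeric(counts[ord]) / R,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "totalPartitions") <- R
    out
}

#' Majority-rule feature selection
#'
#' Features present in at least `threshold * R` best subsets ("at least"
#' is inclusive: with threshold 0.5 and R = 300 a count of exactly 150
#' qualifies), returned in count-rank order.
#'
#' @param tally a data.frame from [tallyVotes()], or a numeric vector of
#'   counts (named, or ordered by panel index) together with `R`.
#' @param threshold vote fraction in (0, 1].
#' @param R total partition count; taken from the tally's attribute when
#'   omitted.
#' @return character vector of feature names (or names/indices of the
#'   count vector), ranked by count descending.
#' @examples
#' counts <- c(MAO = 300, PHOS = 286, GLU = 168, TB = 150, UN = 12)
#' majorityFeatures(counts, threshold = 0.5, R = 300)
#' @export
majorityFeatures <- function(tally, threshold = 0.5, R = NULL) {
    if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    if (is.data.frame(tally)) {
        R <- R %||% attr(tally, "totalPartitions")
        counts <- tally$count
        labels <- tally$feature
        idx <- tally$index
    } else {
        counts <- as.numeric(tally)
        labels <- names(tally) %||% as.character(seq_along(tally))
        idx <- seq_along(tally)
    }
    if (is.null(R))
        stop("R (total partition count) is required")
    keep <- counts >= threshold * R
    ord <- order(-counts[keep], idx[keep])
    labels[keep][ord]
}

#' Nested feature-combination accuracy curve
#'
#' For each prefix of the count-ranked feature list, retrains one SVM per
#' partition restricted to the prefix's features and averages the held-out
#' accuracy over all partitions. This is the nested-combination table used
#' to choose the final consensus panel: only the nested prefixes in vote
#' order are examined, not all subsets.
#'
#' @param features character vector of features in vote-rank order.
#' @param plan a [PartitionPlan-class].
#' @param cohort a [BloodCohort-class].
#' @param config a [KernelConfig-class].
#' @return data.frame with columns `size`, `added` (the feature entering
#'   at that size), `members` (cumulative "+"-joined panel indices) and
#'   `meanAccuracy` (percent).
#' @seealso [selectFinalSubset()], [panelMeanAccuracy()]
#' @export
comboAccuracyCurve <- function(features, plan, cohort,
                               config = kernelConfig()) {
    if (!length(features))
        stop("features must be non-empty")
    idxMap <- rowData(cohort)$index
    names(idxMap) <- rownames(cohort)
    out <- data.frame(size = seq_along(features), added = features,
                      members = NA_character_,
                      meanAccuracy = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(features)) {
        pf <- features[seq_len(k)]
        out$members[k] <- paste(idxMap[pf], collapse = "+")
        out$meanAccuracy[k] <- tryCatch(
            panelMeanAccuracy(pf, plan, cohort, config),
            error = function(e)
                stop("combination '", out$members[k], "' failed: ",
                     conditionMessage(e), call. = FALSE))
    }
    out
}

#' Mean held-out accuracy of a fixed feature panel
#'
#' Trains one SVM per partition on exactly the given features and returns
#' the mean test-set accuracy across partitions, in percent.
#'
#' @inheritParams comboAccuracyCurve
#' @return numeric scalar (percent).
#' @export
panelMeanAccuracy <- function(features, plan, cohort,
                              config = kernelConfig()) {
    X <- cohortMatrix(cohort)
    y <- cohortLabels(cohort)
    accs <- vapply(plan@partitions, function(p) {
        m <- trainSVM(X[p$train, features, drop = FALSE], y[p$train], config)
        evaluateAccuracy(m, X[p$test, features, drop = FALSE], y[p$test])$P
    }, numeric(1))
    100 * mean(accs)
}

#' Smallest best prefix of a combination-accuracy curve
#'
#' Returns the features of the smallest prefix attaining the maximal mean
#' accuracy (within 1e-9 to absorb floating-point ties).
#'
#' @param curve data.frame from [comboAccuracyCurve()].
#' @return character vector of feature names.
#' @export
selectFinalSubset <- function(curve) {
    if (!nrow(curve))
        stop("curve must be non-empty")
    best <- max(curve$meanAccuracy)
    k <- min(curve$size[curve$meanAccuracy >= best - 1e-9])
    curve$added[seq_len(k)]
}
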