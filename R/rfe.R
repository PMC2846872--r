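#' Recursive feature elimination on one partition
#'
#' Starting from the full active set, repeatedly: train the kernel SVM on
#' the partition's training rows, record held-out accuracy on the test
#' rows, score every active feature with [djScores()], and remove the
#' single lowest-scoring feature (ties broken by removing the higher panel
#' index first), until one feature remains. The best subset is the active
#' set attaining the maximal held-out accuracy, taking the smallest such
#' set on ties. Selecting on test-set accuracy mirrors the consensus
#' procedure this package implements; the optimism bias of that choice is
#' inherited deliberately and documented, not corrected.
#'
#' When the configuration leaves `gamma` automatic, it is resolved once on
#' the starting active set (1 / (p0 * mean training variance), i.e. 1/41
#' for the standardized full panel) and held fixed while features are
#' removed: the kernel geometry does not change under the elimination, so
#' DJ scores stay comparable across iterations. Re-widening the kernel as
#' features drop out systematically inflates the apparent contribution of
#' noise features at small active-set sizes.
#'
#' @param partition one element of a [PartitionPlan-class] (list with
#'   `train`, `test`, `ratio`), or any list with those fields.
#' @param cohort a [BloodCohort-class].
#' @param config a [KernelConfig-class].
#' @param features optional character vector restricting the starting
#'   active set (default: the full panel).
#' @return an [RFEResult-class].
#' @examples
#' co <- generateCohort(loadReferenceSpec(), nSubjects = 30, seed = 2)
#' plan <- makePartitions(co, ratios = 1, totalCount = 1, seed = 3)
#' res <- rfeRun(plan@partitions[[1]], co, features = c("MAO", "PHOS", "TB"))
#' res@bestSubset
#' @export
rfeRun <- function(partition, cohort, config = kernelConfig(),
                   features = NULL) {
    X <- cohortMatrix(cohort)
    y <- cohortLabels(cohort)
    active <- features %||% colnames(X)
    if (!all(active %in% colnames(X)))
        stop("unknown features: ",
             paste(setdiff(active, colnames(X)), collapse = ", "))
    panelIdx <- rowData(cohort)$index
    names(panelIdx) <- rownames(cohort)
    tr <- partition$train
    te <- partition$test
    nStart <- length(active)
    if (is.na(config@gamma) && config@kernel == "rbf") {
        x0 <- X[tr, active, drop = FALSE]
        st <- standardizeStats(x0, config@standardize)
        xs0 <- sweep(sweep(x0, 2L, st$center, "-"), 2L, st$scale, "/")
        config@gamma <- resolveGamma(config, xs0)
    }
    elim <- character(nStart)
    djRec <- rep(NA_real_, nStart)
    curve <- data.frame(size = integer(nStart), TP = integer(nStart),
                        TN = integer(nStart), M = integer(nStart),
                        accuracy = numeric(nStart))
    step <- 0L
    while (length(active) >= 1L) {
        model <- tryCatch(
            trainSVM(X[tr, active, drop = FALSE], y[tr], config),
            error = function(e)
                stop("training failed at active-set size ", length(active),
                     ": ", conditionMessage(e), call. = FALSE))
        rep <- evaluateAccuracy(model, X[te, active, drop = FALSE], y[te])
        step <- step + 1L
        curve[step, ] <- list(length(active), rep$TP, rep$TN, rep$M, rep$P)
        if (length(active) == 1L) {
            elim[step] <- active
            break
        }
        dj <- djScores(model)
        ord <- order(dj, -panelIdx[active])  # lowest DJ; ties: higher index out first
        worst <- active[ord[1L]]
        elim[step] <- worst
        djRec[step] <- dj[ord[1L]]
        active <- setdiff(active, worst)
    }
    maxAcc <- max(curve$accuracy)
    bestSize <- min(curve$size[curve$accuracy >= maxAcc - 1e-12])
    new("RFEResult",
        eliminationOrder = elim,
        featureIndex = vapply(elim, function(f) as.integer(panelIdx[f]), 1L),
        djAtRemoval = djRec,
        accuracyCurve = curve,
        bestSubset = tail(elim, bestSize),
        bestAccuracy = maxAcc,
        ratioTag = partition$ratio %||% NA_character_)
}

#' @describeIn rfeRun compact display of an RFE result
#' @param object an [RFEResult-class]
#' @export
setMethod("show", "RFEResult", function(object) {
    n <- length(object@eliminationOrder)
    cat(sprintf("RFEResult (%s): %d features, best accuracy %.4f with %d-feature subset\n",
                object@ratioTag, n, object@bestAccuracy,
                length(object@bestSubset)))
    cat("  best subset:", paste(rev(object@bestSubset), collapse = ", "), "\n")
})
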