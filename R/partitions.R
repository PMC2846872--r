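#' Draw resampled train/test partitions
#'
#' Allocates `totalCount` random holdout partitions as evenly as possible
#' across the requested train:test ratios (any remainder goes to the
#' smallest ratios), then assigns cohort rows to train or test uniformly at
#' random within each partition. With `stratified = TRUE` (default) the
#' draw is done within each label class so the training +1/-1 proportion
#' matches the cohort to within one sample. With `bySubject = TRUE` whole
#' subjects (both phases) are assigned to the same side, guarding against
#' within-subject leakage; the achieved ratio is then the closest subject
#' boundary to the target.
#'
#' @param cohort a [BloodCohort-class].
#' @param ratios numeric train:test ratios; default the seven ratios
#'   1:1 .. 4:1 used in the consensus analysis.
#' @param totalCount total number of partitions (default 300).
#' @param seed RNG seed; the plan is deterministic given it.
#' @param stratified logical, stratify the draw by label.
#' @param bySubject logical, split at subject level.
#' @return a [PartitionPlan-class].
#' @examples
#' co <- generateCohort(loadReferenceSpec(), nSubjects = 20, seed = 1)
#' plan <- makePartitions(co, totalCount = 14, seed = 1)
#' table(vapply(plan@partitions, `[[`, "", "ratio"))
#' @export
makePartitions <- function(cohort, ratios = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                           totalCount = 300L, seed = 1L, stratified = TRUE,
                           bySubject = FALSE) {
    y <- cohortLabels(cohort)
    M <- length(y)
    if (length(unique(y)) < 2L)
        stop("cohort must contain both labels")
    totalCount <- as.integer(totalCount)
    if (totalCount < length(ratios))
        stop("totalCount must be at least the number of ratios")
    k <- length(ratios)
    counts <- rep(totalCount %/% k, k)
    rem <- totalCount - sum(counts)
    if (rem > 0L)   # remainder to the smallest ratios
        counts[order(ratios)[seq_len(rem)]] <- counts[order(ratios)[seq_len(rem)]] + 1L
    subj <- cohortSubjects(cohort)
    parts <- withSeed(seed, {
        out <- vector("list", totalCount)
        pos <- 0L
        for (i in seq_len(k)) {
            r <- ratios[i]
            nTrain <- as.integer(round(M * r / (r + 1)))
            if (nTrain < 1L || nTrain >= M)
                stop("ratio ", r, ":1 produces an empty train or test set")
            tag <- sprintf("%g:1", r)
            for (j in seq_len(counts[i])) {
                tr <- drawTrain(y, subj, nTrain, stratified, bySubject)
                pos <- pos + 1L
                out[[pos]] <- list(train = tr,
                                   test = setdiff(seq_len(M), tr),
                                   ratio = tag)
            }
        }
        out
    })
    new("PartitionPlan", partitions = parts, seed = as.integer(seed),
        nRows = M, ratios = as.numeric(ratios), stratified = stratified)
}

drawTrain <- function(y, subj, nTrain, stratified, bySubject) {
    M <- length(y)
    if (bySubject) {
        us <- sample(unique(subj))
        sizes <- cumsum(as.integer(table(subj)[us]))
        kSub <- which.min(abs(sizes - nTrain))
        return(sort(which(subj %in% us[seq_len(kSub)])))
    }
    if (!stratified)
        return(sort(sample.int(M, nTrain)))
    pos <- which(y == 1L)
    neg <- which(y == -1L)
    nPos <- as.integer(round(nTrain * length(pos) / M))
    nPos <- min(max(nPos, 1L), length(pos), nTrain - 1L)
    nNeg <- nTrain - nPos
    if (nNeg > length(neg))
        stop("stratified draw infeasible for this class balance")
    sort(c(sample(pos, nPos), sample(neg, nNeg)))
}

#' Report label conflicts among identical sample vectors
#'
#' Finds pairs of samples whose full analyte vectors are exactly equal but
#' whose labels differ — such pairs are unresolvable noise for any
#' classifier. A freshly simulated continuous cohort reports no conflicts.
#'
#' @param cohort a [BloodCohort-class].
#' @return data.frame with columns `row_a`, `row_b` (sample indices), one
#'   row per conflicting cross-label pair; zero rows on clean data.
#' @export
checkNoConflicts <- function(cohort) {
    X <- cohortMatrix(cohort)
    y <- cohortLabels(cohort)
    key <- apply(X, 1L, paste, collapse = "\r")
    out <- data.frame(row_a = integer(0), row_b = integer(0))
    for (idx in split(seq_along(key), key)) {
        if (length(idx) < 2L) next
        a <- idx[y[idx] == 1L]
        b <- idx[y[idx] == -1L]
        if (length(a) && length(b))
            out <- rbind(out, expand.grid(row_a = a, row_b = b))
    }
    rownames(out) <- NULL
    out
}
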