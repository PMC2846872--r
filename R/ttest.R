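#' Paired t-test on matched measurements
#'
#' Tests zero mean within-subject difference d = pre - post:
#' t = mean(d) / (sd(d) / sqrt(n)) with n - 1 degrees of freedom and a
#' two-sided p-value. Delegates to [stats::t.test()].
#'
#' @param pre,post equal-length paired numeric vectors (n >= 2).
#' @return list with elements `t`, `df`, `p`.
#' @examples
#' pairedTTest(c(1, 2, 3, 4, 5), c(0, 2, 2, 4, 4))
#' @export
pairedTTest <- function(pre, post) {
    if (length(pre) != length(post))
        stop("pre and post must have equal length")
    if (length(pre) < 2L)
        stop("need at least 2 pairs")
    d <- pre - post
    if (var(d) == 0)
        stop("zero difference variance: paired t statistic undefined")
    ht <- t.test(pre, post, paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Paired t-test screen over the whole panel
#'
#' Matches each subject's pre and post samples by `subject_id`, runs the
#' paired t-test on every analyte, and returns the screen ranked by
#' ascending p-value (ties broken by panel index). No multiple-testing
#' correction is applied by default, matching the univariate baseline this
#' package compares against; `correction = "bonferroni"` is available.
#'
#' @param cohort a [BloodCohort-class] containing matched pairs.
#' @param alpha significance level for the `significant` flag (p < alpha).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return data.frame with columns `index`, `feature`, `preMean`, `preSd`,
#'   `postMean`, `postSd`, `t`, `df`, `p`, `significant`, ordered by
#'   ascending p.
#' @export
screenFeatures <- function(cohort, alpha = 0.05,
                           correction = c("none", "bonferroni")) {
    correction <- match.arg(correction)
    subj <- cohortSubjects(cohort)
    phase <- cohortPhase(cohort)
    paired <- intersect(subj[phase == "pre"], subj[phase == "post"])
    if (!length(paired))
        stop("no complete subject pairs in cohort")
    X <- cohortMatrix(cohort)
    preRows <- match(paste0(paired, ".pre"), paste0(subj, ".", phase))
    postRows <- match(paste0(paired, ".post"), paste0(subj, ".", phase))
    idx <- rowData(cohort)$index
    res <- lapply(seq_len(ncol(X)), function(j) {
        pre <- X[preRows, j]
        post <- X[postRows, j]
        tt <- pairedTTest(pre, post)
        data.frame(index = idx[j], feature = colnames(X)[j],
                   preMean = mean(pre), preSd = sd(pre),
                   postMean = mean(post), postSd = sd(post),
                   t = tt$t, df = tt$df, p = tt$p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (correction == "bonferroni")
        out$p <- p.adjust(out$p, "bonferroni")
    out <- out[order(out$p, out$index), , drop = FALSE]
    out$significant <- out$p < alpha
    rownames(out) <- NULL
    out
}

#' Top-k overlap between two rankings
#'
#' Size of the intersection of the first k entries of two ranked feature
#' lists.
#'
#' @param rankingA,rankingB character vectors, best first.
#' @param k prefix length, at most the length of both rankings.
#' @return integer in 0..k.
#' @examples
#' topkOverlap(c("MAO", "PHOS", "LDH"), c("MAO", "ALP", "PHOS"), 2)
#' @export
topkOverlap <- function(rankingA, rankingB, k) {
    k <- as.integer(k)
    if (k > length(rankingA) || k > length(rankingB))
        stop("k exceeds a ranking's length")
    length(intersect(rankingA[seq_len(k)], rankingB[seq_len(k)]))
}
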