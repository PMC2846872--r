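#' @title S4 classes
#' @name consensusRFE-classes
#' @keywords internal
NULL

#' Cohort simulation specification
#'
#' Per-analyte Gaussian pre/post parameters plus cohort-level settings that
#' drive [generateCohort()]. One row of `measures` per panel analyte, with
#' columns `index`, `name`, `units`, `preMean`, `preSd`, `postMean`,
#' `postSd`, `provenance`. Provenance is one of `"consensus"` (values from
#' the published consensus-panel summary), `"screen"` (values from the
#' published univariate screen) or `"null_default"` (analytes the original
#' study reported no shift for; synthetic reference-range parameters with
#' pre == post).
#'
#' @slot measures data.frame of per-analyte parameters (see above).
#' @slot nSubjects integer, number of paired subjects to simulate.
#' @slot rho numeric in [0, 1), within-subject pre/post correlation.
#' @slot seed integer, default RNG seed for [generateCohort()].
#' @slot corMatrix optional analyte-analyte correlation matrix for the
#'   latent Gaussians (NULL = analytes independent).
#'
#' @seealso [loadReferenceSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
    representation(measures = "data.frame", nSubjects = "integer",
                   rho = "numeric", seed = "integer", corMatrix = "ANY"))

setValidity("CohortSpec", function(object) {
    m <- object@measures
    need <- c("index", "name", "units", "preMean", "preSd", "postMean",
              "postSd", "provenance")
    if (!all(need %in% colnames(m)))
        return(paste("measures must have columns:", paste(need, collapse = ", ")))
    if (nrow(m) != 41L)
        return("measures must describe exactly 41 analytes")
    if (!identical(sort(as.integer(m$index)), 1:41))
        return("analyte indices must be exactly 1..41, each used once")
    if (anyDuplicated(m$name))
        return("analyte names must be unique")
    if (any(!is.finite(m$preSd)) || any(!is.finite(m$postSd)) ||
        any(m$preSd <= 0) || any(m$postSd <= 0))
        return("all SDs must be strictly positive")
    nul <- m$provenance == "null_default"
    if (any(nul & (m$preMean != m$postMean | m$preSd != m$postSd)))
        return("null_default analytes must have identical pre and post parameters")
    if (length(object@rho) != 1L || object@rho < 0 || object@rho >= 1)
        return("rho must lie in [0, 1)")
    if (object@nSubjects < 2L)
        return("nSubjects must be >= 2")
    if (!is.null(object@corMatrix)) {
        R <- object@corMatrix
        if (!is.matrix(R) || nrow(R) != 41L || ncol(R) != 41L ||
            !isSymmetric(unname(R)))
            return("corMatrix must be a symmetric 41 x 41 matrix")
    }
    TRUE
})

#' Paired blood-chemistry cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"chemistry"`, analytes x samples) with column metadata `subject_id`,
#' `phase` (`"pre"`/`"post"`) and `label` (+1 for pre, -1 for post), and
#' row metadata `index` and `units` for the analyte panel.
#'
#' @seealso [generateCohort()], [readCohort()], [cohortMatrix()]
#' @export
setClass("BloodCohort", contains = "SummarizedExperiment")

setValidity("BloodCohort", function(object) {
    cd <- colData(object)
    need <- c("subject_id", "phase", "label")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain:", paste(need, collapse = ", ")))
    if (!all(cd$phase %in% c("pre", "post")))
        return("phase must be 'pre' or 'post'")
    lab <- ifelse(cd$phase == "pre", 1L, -1L)
    if (!all(cd$label == lab))
        return("label must be +1 for pre-phase samples and -1 for post")
    if (anyDuplicated(paste(cd$subject_id, cd$phase)))
        return("at most one sample per subject and phase")
    if (length(SummarizedExperiment::assays(object)) < 1L ||
        anyNA(assay(object)))
        return("assay must be present with no missing values")
    TRUE
})

#' Kernel SVM configuration
#'
#' @slot gamma RBF width; `NA_real_` means auto: 1 / (p * mean per-feature
#'   training variance), i.e. 1/p after standardization.
#' @slot cost soft-margin penalty C > 0.
#' @slot standardize logical; z-score features by training statistics.
#' @slot kernel `"rbf"` or `"linear"`.
#' @seealso [kernelConfig()]
#' @export
setClass("KernelConfig",
    representation(gamma = "numeric", cost = "numeric",
                   standardize = "logical", kernel = "character"))

setValidity("KernelConfig", function(object) {
    if (!object@kernel %in% c("rbf", "linear"))
        return("kernel must be 'rbf' or 'linear'")
    if (length(object@cost) != 1L || !is.finite(object@cost) || object@cost <= 0)
        return("cost must be a finite positive scalar")
    if (length(object@gamma) != 1L ||
        (!is.na(object@gamma) && (!is.finite(object@gamma) || object@gamma <= 0)))
        return("gamma must be NA (auto) or a finite positive scalar")
    TRUE
})

#' Fitted soft-margin kernel SVM (dual solution)
#'
#' Stores the dual optimum of the soft-margin problem: per-support-vector
#' multipliers alpha (0 <= alpha_i <= C), their labels, the bias b, and the
#' standardized support vectors, so that the decision value for x is
#' sum_i alpha_i y_i K(sv_i, x) + b.
#'
#' @slot coefs numeric, alpha_i * y_i per support vector.
#' @slot alpha numeric, alpha_i per support vector.
#' @slot svLabels numeric, y_i in {-1, +1} per support vector.
#' @slot bias numeric scalar b.
#' @slot SV matrix of standardized support vectors (rows).
#' @slot supportIndices integer indices into the training rows.
#' @slot featureNames character, active feature set.
#' @slot gamma,cost resolved kernel parameters.
#' @slot kernel `"rbf"` or `"linear"`.
#' @slot standardize logical.
#' @slot center,scale per-feature training statistics applied before the
#'   kernel (identity transform when standardize is FALSE).
#' @slot nTrain integer, training-set size.
#' @seealso [trainSVM()], [djScores()]
#' @export
setClass("TrainedSVM",
    representation(coefs = "numeric", alpha = "numeric", svLabels = "numeric",
                   bias = "numeric", SV = "matrix", supportIndices = "integer",
                   featureNames = "character", gamma = "numeric",
                   cost = "numeric", kernel = "character",
                   standardize = "logical", center = "numeric",
                   scale = "numeric", nTrain = "integer"))

setValidity("TrainedSVM", function(object) {
    n <- length(object@coefs)
    if (length(object@alpha) != n || length(object@svLabels) != n ||
        nrow(object@SV) != n)
        return("coefs, alpha, svLabels and SV rows must agree in length")
    if (any(object@alpha < -1e-8) || any(object@alpha > object@cost + 1e-6))
        return("multipliers must satisfy 0 <= alpha <= C")
    if (abs(sum(object@coefs)) > 1e-4 * max(1, object@cost))
        return("equality constraint sum(alpha * y) = 0 violated")
    TRUE
})

#' Result of one recursive-feature-elimination run
#'
#' @slot eliminationOrder character; features from first removed to last
#'   surviving (a permutation of the starting active set).
#' @slot featureIndex named integer; panel index of each feature.
#' @slot djAtRemoval numeric; DJ score of each removed feature at the time
#'   of its removal (NA for the last survivor).
#' @slot accuracyCurve data.frame with columns `size`, `TP`, `TN`, `M`,
#'   `accuracy`: held-out accuracy at each active-set size.
#' @slot bestSubset character; smallest active set attaining the maximal
#'   held-out accuracy.
#' @slot bestAccuracy numeric in [0, 1].
#' @slot ratioTag character; train:test ratio tag of the partition used.
#' @seealso [rfeRun()], [tallyVotes()]
#' @export
setClass("RFEResult",
    representation(eliminationOrder = "character", featureIndex = "integer",
                   djAtRemoval = "numeric", accuracyCurve = "data.frame",
                   bestSubset = "character", bestAccuracy = "numeric",
                   ratioTag = "character"))

setValidity("RFEResult", function(object) {
    if (anyDuplicated(object@eliminationOrder))
        return("eliminationOrder must not repeat features")
    if (!all(object@bestSubset %in% object@eliminationOrder))
        return("bestSubset must be drawn from the eliminated features")
    k <- length(object@bestSubset)
    if (k > 0 && !setequal(object@bestSubset,
                           tail(object@eliminationOrder, k)))
        return("bestSubset must be a prefix-complement of eliminationOrder")
    TRUE
})

#' Plan of resampled train/test partitions
#'
#' @slot partitions list; each element has `train` and `test` (disjoint row
#'   indices covering the cohort) and `ratio` (a tag such as `"1.5:1"`).
#' @slot seed integer used to draw the plan.
#' @slot nRows integer, cohort size the plan indexes into.
#' @slot ratios numeric train:test ratios used.
#' @slot stratified logical.
#' @seealso [makePartitions()]
#' @export
setClass("PartitionPlan",
    representation(partitions = "list", seed = "integer", nRows = "integer",
                   ratios = "numeric", stratified = "logical"))

setValidity("PartitionPlan", function(object) {
    for (p in object@partitions) {
        if (length(intersect(p$train, p$test)) > 0L)
            return("train and test must be disjoint")
        if (!setequal(c(p$train, p$test), seq_len(object@nRows)))
            return("train and test must cover all cohort rows")
    }
    TRUE
})

#' Full consensus-selection run
#'
#' Container returned by [runPipeline()]: the simulated (or loaded) cohort,
#' the partition plan, all per-partition RFE results, the vote tally, the
#' nested combination-accuracy curve, the final consensus subset, the
#' paired t-test screen and the top-k overlap between the two rankings,
#' plus a manifest of every setting needed to reproduce the run.
#'
#' @seealso [runPipeline()], [writeReports()]
#' @export
setClass("ConsensusRun",
    representation(cohort = "BloodCohort", plan = "PartitionPlan",
                   rfeResults = "list", voteTally = "data.frame",
                   majority = "character", comboCurve = "data.frame",
                   finalSubset = "character", screen = "data.frame",
                   overlap = "integer", manifest = "list"))
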