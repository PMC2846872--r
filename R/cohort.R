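#' Construct a BloodCohort
#'
#' @param values numeric matrix, analytes (rows) x samples (columns);
#'   rownames are analyte names.
#' @param subjectId character vector, one per sample.
#' @param phase character vector of `"pre"`/`"post"`, one per sample.
#' @param panel optional data.frame with `index`, `name`, `units` giving
#'   row metadata (defaults to positional indices).
#' @return a validated [BloodCohort-class].
#' @export
BloodCohort <- function(values, subjectId, phase, panel = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("values must have analyte rownames")
    if (is.null(panel)) {
        panel <- data.frame(index = seq_len(nrow(values)),
                            name = rownames(values), units = NA_character_)
    }
    pos <- match(rownames(values), panel$name)
    if (anyNA(pos))
        stop("analytes missing from panel: ",
             paste(rownames(values)[is.na(pos)], collapse = ", "))
    rd <- DataFrame(index = as.integer(panel$index[pos]),
                    units = panel$units[pos], row.names = rownames(values))
    cd <- DataFrame(subject_id = as.character(subjectId),
                    phase = as.character(phase),
                    label = ifelse(phase == "pre", 1L, -1L),
                    row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(chemistry = values),
                               rowData = rd, colData = cd)
    new("BloodCohort", se)
}

#' Cohort accessors
#'
#' `cohortMatrix()` returns the samples x analytes numeric matrix used by
#' the classifiers; `cohortLabels()` the +1/-1 phase labels;
#' `cohortSubjects()` and `cohortPhase()` the per-sample metadata.
#'
#' @param x a [BloodCohort-class].
#' @return matrix or vector, samples in cohort column order.
#' @export
cohortMatrix <- function(x) t(assay(x, "chemistry"))

#' @rdname cohortMatrix
#' @export
cohortLabels <- function(x) as.integer(colData(x)$label)

#' @rdname cohortMatrix
#' @export
cohortSubjects <- function(x) as.character(colData(x)$subject_id)

#' @rdname cohortMatrix
#' @export
cohortPhase <- function(x) as.character(colData(x)$phase)

#' Simulate a paired cohort from a specification
#'
#' Draws `nSubjects` paired samples. For analyte i with parameters
#' (mu_pre, sigma_pre, mu_post, sigma_post) and within-subject correlation
#' rho, each subject's pair is bivariate normal:
#' pre = mu_pre + sigma_pre * Z1 and
#' post = mu_post + sigma_post * (rho * Z1 + sqrt(1 - rho^2) * Z2) with
#' independent standard normal Z1, Z2. Analytes are independent unless the
#' spec carries a correlation matrix, in which case the latent Z draws are
#' correlated accordingly. Values are not truncated at zero: for every
#' parameterised analyte the mean is several SDs above zero, so negative
#' draws are vanishingly rare and truncation would bias the moments.
#'
#' @param spec a [CohortSpec-class].
#' @param nSubjects,rho,seed optional overrides of the spec's settings.
#' @return a [BloodCohort-class] with `2 * nSubjects` samples (all pre,
#'   then all post), labels +1/-1, bit-identical for identical inputs.
#' @examples
#' co <- generateCohort(loadReferenceSpec(), nSubjects = 20, seed = 7)
#' table(cohortLabels(co))
#' @export
generateCohort <- function(spec, nSubjects = spec@nSubjects,
                           rho = spec@rho, seed = spec@seed) {
    validObject(spec)
    n <- as.integer(nSubjects)
    if (n < 2L) stop("nSubjects must be >= 2")
    m <- spec@measures
    p <- nrow(m)
    withSeed(seed, {
        Z1 <- matrix(rnorm(n * p), n, p)
        Z2 <- matrix(rnorm(n * p), n, p)
        if (!is.null(spec@corMatrix)) {
            L <- chol(spec@corMatrix)
            Z1 <- Z1 %*% L
            Z2 <- Z2 %*% L
        }
        pre  <- sweep(sweep(Z1, 2L, m$preSd, "*"), 2L, m$preMean, "+")
        Zp   <- rho * Z1 + sqrt(1 - rho^2) * Z2
        post <- sweep(sweep(Zp, 2L, m$postSd, "*"), 2L, m$postMean, "+")
    })
    ids <- sprintf("S%04d", seq_len(n))
    values <- t(rbind(pre, post))          # analytes x samples
    rownames(values) <- m$name
    colnames(values) <- c(paste0("pre_", ids), paste0("post_", ids))
    BloodCohort(values, subjectId = c(ids, ids),
                phase = rep(c("pre", "post"), each = n),
                panel = m[, c("index", "name", "units")])
}

#' Read and write cohort CSV files
#'
#' The on-disk format is one sample per row: `subject_id`, `phase`
#' (`pre`/`post`), then one column per panel analyte in panel order.
#' On read, rows with any missing analyte value are dropped (mirroring the
#' original study's complete-case filter); the drop count is reported with
#' a message and stored in `metadata(cohort)$dropped`.
#'
#' @param cohort a [BloodCohort-class].
#' @param path file path.
#' @param panel data.frame with `index`, `name`, `units`; the expected
#'   analyte columns (default the 41-analyte reference panel).
#' @return `readCohort()` returns a [BloodCohort-class]; `writeCohort()`
#'   returns `path` invisibly.
#' @export
writeCohort <- function(cohort, path) {
    df <- data.frame(subject_id = cohortSubjects(cohort),
                     phase = cohortPhase(cohort),
                     cohortMatrix(cohort), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, panel = analytePanel()) {
    raw <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 3L || !identical(colnames(raw)[1:2],
                                     c("subject_id", "phase")))
        stop("malformed header: expected 'subject_id', 'phase', then analyte columns")
    anames <- colnames(raw)[-(1:2)]
    if (!identical(anames, panel$name))
        stop("malformed header: analyte columns must be, in order: ",
             paste(panel$name, collapse = ", "))
    badPhase <- which(!raw$phase %in% c("pre", "post"))
    if (length(badPhase))
        stop("unknown phase token '", raw$phase[badPhase[1]],
             "' in row ", badPhase[1])
    vals <- matrix(NA_real_, nrow(raw), length(anames),
                   dimnames = list(NULL, anames))
    for (j in seq_along(anames)) {
        cell <- trimws(raw[[j + 2L]])
        miss <- is.na(cell) | !nzchar(cell) | cell %in% c("NA", "NaN")
        num <- suppressWarnings(as.numeric(cell))
        badCell <- which(is.na(num) & !miss)
        if (length(badCell))
            stop("non-numeric value '", cell[badCell[1]], "' in row ",
                 badCell[1], ", column ", anames[j])
        vals[, j] <- num
    }
    keep <- !apply(vals, 1L, anyNA)
    dropped <- sum(!keep)
    if (dropped > 0L)
        message("readCohort: dropped ", dropped,
                " row(s) with missing analyte values")
    vals <- vals[keep, , drop = FALSE]
    mat <- t(vals)
    colnames(mat) <- paste0(raw$phase[keep], "_", raw$subject_id[keep])
    co <- BloodCohort(mat, subjectId = raw$subject_id[keep],
                      phase = raw$phase[keep], panel = panel)
    S4Vectors::metadata(co)$dropped <- dropped
    co
}

#' @describeIn BloodCohort compact display
#' @param object a `BloodCohort`
#' @export
setMethod("show", "BloodCohort", function(object) {
    cd <- colData(object)
    cat("BloodCohort:", nrow(object), "analytes x", ncol(object), "samples (",
        sum(cd$phase == "pre"), "pre /", sum(cd$phase == "post"), "post )\n")
    callNextMethod()
})
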