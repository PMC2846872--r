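# Small cohorts and independent oracles used across the suite.

# Paired two-class Gaussian toy cohort with a chosen per-feature mean shift
# (in SD units); feature names f1..fp unless given.
makeToyCohort <- function(nSubjects = 30, shifts = c(3, 0, 0), sds = NULL,
                          names = NULL, seed = 99, rho = 0.5) {
    p <- length(shifts)
    sds <- sds %||% rep(1, p)
    names <- names %||% paste0("f", seq_len(p))
    withr_seed <- function(code) { # local, keep global stream untouched
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed); code
    }
    withr_seed({
        z1 <- matrix(rnorm(nSubjects * p), nSubjects, p)
        z2 <- matrix(rnorm(nSubjects * p), nSubjects, p)
        pre <- sweep(z1, 2, sds, "*")
        post <- sweep(rho * z1 + sqrt(1 - rho^2) * z2, 2, sds, "*")
        post <- sweep(post, 2, shifts * sds, "+")
    })
    vals <- t(rbind(pre, post))
    rownames(vals) <- names
    colnames(vals) <- paste0(rep(c("pre_", "post_"), each = nSubjects),
                             rep(sprintf("S%03d", seq_len(nSubjects)), 2))
    BloodCohort(vals,
                subjectId = rep(sprintf("S%03d", seq_len(nSubjects)), 2),
                phase = rep(c("pre", "post"), each = nSubjects))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference spec in which every analyte is null except `target`, which is
# shifted down by `shift` pre-SDs after the exposure.
singleSignalSpec <- function(target = "MAO", shift = 5, ...) {
    m <- loadReferenceSpec()@measures
    o <- data.frame(name = m$name, postMean = m$preMean, postSd = m$preSd)
    i <- match(target, m$name)
    o$postMean[i] <- m$preMean[i] - shift * m$preSd[i]
    loadReferenceSpec(overrides = o, ...)
}

# Independent oracle: DJ by full kernel recomputation on data with the
# feature deleted (uses stats::dist, not the package's kernel code).
djOracle <- function(model) {
    sv <- model@SV
    coefs <- model@coefs
    kmat <- function(m) {
        if (model@kernel == "rbf")
            exp(-model@gamma * as.matrix(dist(m))^2)
        else m %*% t(m)
    }
    q <- drop(t(coefs) %*% kmat(sv) %*% coefs)
    out <- vapply(seq_len(ncol(sv)), function(j) {
        Kj <- kmat(sv[, -j, drop = FALSE])
        0.5 * abs(q - drop(t(coefs) %*% Kj %*% coefs))
    }, numeric(1))
    names(out) <- model@featureNames
    out
}

# Independent oracle: textbook paired t statistic and two-sided p.
pairedTOracle <- function(pre, post) {
    d <- pre - post
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Random SVM fit for property tests.
randomFit <- function(seed, n = 12, p = 4, kernel = "rbf",
                      standardize = FALSE) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rep(c(-1, 1), length.out = n)
    trainSVM(x, y, kernelConfig(gamma = if (kernel == "rbf") 0.7 else NA,
                                cost = 2, standardize = standardize,
                                kernel = kernel))
}
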