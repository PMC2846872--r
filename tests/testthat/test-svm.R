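test_that("RBF kernel matches its closed form and is PSD", {
    x <- matrix(rnorm(10), 5, 2)
    expect_equal(diag(rbfKernel(x, x, gamma = 0.3)), rep(1, 5))
    expect_equal(rbfKernel(rbind(c(0, 0)), rbind(c(1, 1)), gamma = 0.5)[1, 1],
                 exp(-1))
    for (s in 1:5) {
        set.seed(s)
        X <- matrix(rnorm(8 * 3), 8, 3)
        K <- rbfKernel(X, gamma = runif(1, 0.1, 2))
        expect_equal(K, t(K))
        expect_true(all(K > 0 & K <= 1 + 1e-12))
        expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)
    }
    expect_error(rbfKernel(x, x, gamma = 0), "gamma")
    expect_error(rbfKernel(x, matrix(0, 2, 3), gamma = 1), "dimension")
})

test_that("separable and XOR patterns are fit to training accuracy 1", {
    x <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
    colnames(x) <- c("a", "b")
    y <- c(-1, -1, 1, 1)
    fit <- trainSVM(x, y, kernelConfig(cost = 10))
    expect_identical(predict(fit, x), as.integer(y))

    xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    colnames(xor) <- c("a", "b")
    yx <- c(1, 1, -1, -1)
    fx <- trainSVM(xor, yx, kernelConfig(gamma = 1, cost = 10,
                                         standardize = FALSE))
    expect_identical(predict(fx, xor), as.integer(yx))
})

test_that("dual constraints hold on every fit", {
    for (s in 1:8) {
        fit <- randomFit(s, n = 16, p = 3,
                         kernel = if (s %% 2) "rbf" else "linear")
        expect_lt(abs(sum(fit@coefs)), 1e-6)           # sum alpha_i y_i = 0
        expect_true(all(fit@alpha >= -1e-10))
        expect_true(all(fit@alpha <= fit@cost + 1e-8)) # 0 <= alpha <= C
        expect_equal(fit@coefs, fit@alpha * fit@svLabels)
    }
})

test_that("degenerate inputs are rejected", {
    x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(trainSVM(x, rep(1, 5), kernelConfig()), "one class")
    expect_error(trainSVM(x, c(1, 1, 0, -1, -1), kernelConfig()),
                 "-1 or \\+1")
    fit <- trainSVM(x, c(1, 1, 1, -1, -1), kernelConfig())
    expect_error(predict(fit, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("accuracy reports are internally consistent", {
    co <- makeToyCohort(nSubjects = 40, shifts = c(2.5, 0, 0))
    X <- cohortMatrix(co)
    y <- cohortLabels(co)
    tr <- seq(1, 80, by = 2)          # both phases in the training half
    te <- setdiff(seq_len(80), tr)
    fit <- trainSVM(X[tr, ], y[tr], kernelConfig())
    rep <- evaluateAccuracy(fit, X[te, ], y[te])
    expect_identical(rep$M, length(te))
    expect_equal(rep$P, (rep$TP + rep$TN) / rep$M)
    expect_true(rep$P >= 0 && rep$P <= 1)
    # complementary predictions on a balanced test set give 1 - P
    pred <- predict(fit, X[te, ])
    flipped <- -pred
    Pf <- (sum(flipped == 1 & y[te] == 1) + sum(flipped == -1 & y[te] == -1)) /
        length(te)
    expect_equal(Pf, 1 - rep$P)
})

test_that("decision function agrees with an independent SVM implementation", {
    set.seed(42)
    x <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- ifelse(x[, 1] + 0.3 * rnorm(60) > 0, 1, -1)
    fit <- trainSVM(x, y, kernelConfig(gamma = 0.5, cost = 1,
                                       standardize = FALSE))
    kfit <- kernlab::ksvm(x, factor(y), type = "C-svc", C = 1,
                          kernel = "rbfdot", kpar = list(sigma = 0.5),
                          scaled = FALSE)
    xt <- matrix(rnorm(40 * 3), 40, 3)
    mine <- predict(fit, xt)
    theirs <- as.integer(as.character(kernlab::predict(kfit, xt)))
    expect_gte(mean(mine == theirs), 0.95)
})

test_that("auto gamma is 1/p on standardized features", {
    set.seed(3)
    x <- matrix(rnorm(50 * 4, sd = 9), 50, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- rep(c(1, -1), 25)
    fit <- trainSVM(x, y, kernelConfig())
    expect_equal(fit@gamma, 1 / (4 * mean(apply(scale(x), 2, var))),
                 tolerance = 1e-10)
})
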