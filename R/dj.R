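#' Feature-elimination scores (dual-objective change)
#'
#' For each active feature i, scores the effect of deleting it from the
#' kernel with the multipliers held fixed at the trained solution:
#' DJ(i) = 1/2 * | alpha' H alpha - alpha' H(-i) alpha |, where H has
#' entries y_h y_k K(x_h, x_k) and H(-i) is H recomputed without feature i.
#' The quadratic forms are taken over the support vectors only (all other
#' multipliers are zero). For the RBF kernel, H(-i) is obtained by the
#' exact multiplicative downdate
#' K(-i)_hk = K_hk * exp(gamma * (x_hi - x_ki)^2),
#' which avoids recomputing the kernel from scratch for every candidate
#' feature; for the linear kernel, K(-i) = K - x_i x_i'. The absolute
#' value is taken because a nonlinear kernel's objective can move in
#' either direction. A feature that is constant across the support
#' vectors scores exactly 0.
#'
#' @param model a [TrainedSVM-class].
#' @return named numeric vector of DJ scores (>= 0), one per active
#'   feature.
#' @seealso [rfeRun()]
#' @export
djScores <- function(model) {
    sv <- model@SV
    coefs <- model@coefs    # alpha_i * y_i, so coefs' K coefs = alpha' H alpha
    K <- kernelMatrix(sv, sv, model@gamma, model@kernel)
    qFull <- drop(crossprod(coefs, K %*% coefs))
    p <- ncol(sv)
    dj <- numeric(p)
    for (j in seq_len(p)) {
        d <- outer(sv[, j], sv[, j], "-")
        Kj <- if (model@kernel == "rbf")
            K * exp(model@gamma * d * d)
        else
            K - tcrossprod(sv[, j])
        dj[j] <- 0.5 * abs(qFull - drop(crossprod(coefs, Kj %*% coefs)))
    }
    names(dj) <- model@featureNames
    dj
}
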