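# column-wise log-sum-exp of a matrix, guarded against all--Inf columns
.colLogSumExp <- function(m) {
    cm <- apply(m, 2, max)
    out <- cm
    ok <- is.finite(cm)
    if (any(ok)) {
        sw <- sweep(m[, ok, drop = FALSE], 2, cm[ok])
        out[ok] <- cm[ok] + log(colSums(exp(sw)))
    }
    out
}

.checkBlocks <- function(blocks) {
    stopifnot(is(blocks, "BlockSequence"))
    validObject(blocks)
    blocks
}

#' Block emission exponent
#'
#' The log weight \eqn{E_w(j)} a whole block contributes when its hidden
#' state is \eqn{j}: the product of the \eqn{n_w} Gaussian emission
#' densities (collected through the sufficient statistics
#' \eqn{\Sigma_{1,w}, \Sigma_{2,w}}) and the \eqn{n_w - 1} self-transitions,
#' \deqn{E_w(j) = \frac{2\mu_j \Sigma_{1,w} - \Sigma_{2,w}}{2\sigma_j^2}
#'   + (n_w - 1)\log A_{jj}
#'   - n_w\left(\log\sigma_j + \frac{\mu_j^2}{2\sigma_j^2}
#'   + \tfrac12\log 2\pi\right).}
#' When \eqn{A_{jj} = 0} a block with \eqn{n_w > 1} is unreachable under
#' state \eqn{j} and the exponent is \eqn{-\infty}; with \eqn{n_w = 1} the
#' self-transition term is exactly 0.
#'
#' @param blocks a [BlockSequence-class].
#' @param state 1-based state index.
#' @param model an [HMMModel-class].
#' @return numeric vector of \eqn{E_w(j)} over blocks `w`.
#' @export
blockExponent <- function(blocks, state, model) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    stopifnot(state >= 1, state <= nStates(model))
    .blockExponentMatrix(model, blocks)[, state]
}

# W x N matrix of E_w(j)
.blockExponentMatrix <- function(model, blocks) {
    n <- blocks@end - blocks@start
    s1 <- blocks@s1
    s2 <- blocks@s2
    mu <- model@means
    v <- model@variances
    ajj <- diag(model@trans)
    W <- length(n)
    N <- length(mu)
    E <- matrix(0, W, N)
    for (j in seq_len(N)) {
        selfTerm <- ifelse(n == 1, 0, (n - 1) * .safeLog(ajj[j]))
        E[, j] <- (2 * mu[j] * s1 - s2) / (2 * v[j]) + selfTerm -
            n * (0.5 * log(v[j]) + mu[j]^2 / (2 * v[j]) + 0.5 * log(2 * pi))
    }
    E
}

#' Compressed forward algorithm
#'
#' The forward recursion over blocks instead of observations:
#' \eqn{\log\alpha_w(j) = \mathrm{LSE}_i(\log\alpha_{w-1}(i) + \log A_{ij})
#' + E_w(j)}, with \eqn{\alpha_1(i) = \pi_i e^{E_1(i)}}. The value
#' approximates the uncompressed forward variable at the end of each block,
#' under the weak path assumption that the chain does not switch state
#' inside a block; the total is the compressed approximation of
#' \eqn{\log p(y\mid\lambda)}. With singleton blocks (`W = T`) it is exact.
#'
#' @param model an [HMMModel-class].
#' @param blocks a [BlockSequence-class].
#' @return a list with `logAlpha` (\eqn{W \times N}) and `logLikelihood`.
#' @export
compressedForward <- function(model, blocks) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    E <- .blockExponentMatrix(model, blocks)
    logA <- .safeLog(model@trans)
    W <- nrow(E)
    N <- ncol(E)
    la <- matrix(-Inf, W, N)
    la[1, ] <- .safeLog(model@init) + E[1, ]
    if (W > 1) {
        for (w in 2:W) {
            la[w, ] <- .colLogSumExp(la[w - 1, ] + logA) + E[w, ]
        }
    }
    ll <- .colLogSumExp(matrix(la[W, ], ncol = 1))
    list(logAlpha = la, logLikelihood = as.numeric(ll))
}

#' Compressed backward algorithm
#'
#' Mirror of [compressedForward()]:
#' \eqn{\log\beta_w(i) = \mathrm{LSE}_j(\log A_{ij} + E_{w+1}(j) +
#' \log\beta_{w+1}(j))} with \eqn{\beta_W(i) = 1}, so that
#' \eqn{\sum_i \alpha_w(i)\beta_w(i)} equals the compressed likelihood at
#' every block.
#'
#' @inheritParams compressedForward
#' @return a list with `logBeta` (\eqn{W \times N}).
#' @export
compressedBackward <- function(model, blocks) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    E <- .blockExponentMatrix(model, blocks)
    logA <- .safeLog(model@trans)
    W <- nrow(E)
    N <- ncol(E)
    lb <- matrix(0, W, N)
    if (W > 1) {
        for (w in (W - 1):1) {
            # row i: LSE_j of logA[i,j] + E[w+1,j] + lb[w+1,j]
            m <- t(logA) + (E[w + 1, ] + lb[w + 1, ])
            lb[w, ] <- .colLogSumExp(m)
        }
    }
    list(logBeta = lb)
}

#' Compressed Viterbi decoding
#'
#' Max-product analogue of the compressed forward recursion:
#' \eqn{\log\delta_w(j) = \max_i(\log\delta_{w-1}(i) + \log A_{ij}) +
#' E_w(j)} with per-block backpointers. The decoded path has length `T` and
#' is constant within every block; ties are broken toward the smallest
#' state index.
#'
#' @inheritParams compressedForward
#' @return a list with `logBest`, `path` (0-based, length `T`),
#'   `blockPath` (0-based, length `W`), `logDelta` and `psi`.
#' @export
compressedViterbi <- function(model, blocks) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    E <- .blockExponentMatrix(model, blocks)
    logA <- .safeLog(model@trans)
    W <- nrow(E)
    N <- ncol(E)
    ld <- matrix(-Inf, W, N)
    psi <- matrix(0L, W, N)
    ld[1, ] <- .safeLog(model@init) + E[1, ]
    if (W > 1) {
        for (w in 2:W) {
            m <- ld[w - 1, ] + logA # m[i, j]
            arg <- apply(m, 2, which.max)
            ld[w, ] <- m[cbind(arg, seq_len(N))] + E[w, ]
            psi[w, ] <- arg - 1L
        }
    }
    best <- which.max(ld[W, ])
    blockPath <- integer(W)
    blockPath[W] <- best - 1L
    if (W > 1) {
        for (w in (W - 1):1) {
            blockPath[w] <- psi[w + 1, blockPath[w + 1] + 1L]
        }
    }
    path <- rep(blockPath, blocks@end - blocks@start)
    list(
        logBest = ld[W, best], path = as.integer(path),
        blockPath = blockPath, logDelta = ld, psi = psi
    )
}

#' Compressed posterior statistics
#'
#' Block-level analogues of the \eqn{\xi} and \eqn{\gamma} posteriors. The
#' block-summed \eqn{\xi_w(i,j)} has four cases: within-block self
#' transitions contribute \eqn{(n_w - 1)\,\alpha_w(i)\beta_w(i)/p}; the
#' single between-block transition contributes
#' \eqn{\alpha_w(i) A_{ij} e^{E_{w+1}(j)} \beta_{w+1}(j)/p} (absent for the
#' last block, where cross terms are exactly 0). Because \eqn{\gamma_t(i)}
#' is constant inside a block, \eqn{\gamma_w(i) =
#' \alpha_w(i)\beta_w(i)/p(y|\lambda)} represents every position of block
#' `w`. Products mixing \eqn{e^{E}} terms are evaluated after subtracting
#' the maximum exponent, so nothing overflows.
#'
#' @inheritParams compressedForward
#' @param fwd result of [compressedForward()].
#' @param bwd result of [compressedBackward()].
#' @return a list with `xi` (\eqn{W \times N \times N}) and `gamma`
#'   (\eqn{W \times N}).
#' @export
compressedPosteriors <- function(model, blocks,
                                 fwd = compressedForward(model, blocks),
                                 bwd = compressedBackward(model, blocks)) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    N <- nStates(model)
    W <- nBlocks(blocks)
    if (!identical(dim(fwd$logAlpha), c(W, N)) ||
        !identical(dim(bwd$logBeta), c(W, N))) {
        stop("trellis dimensions do not match the model and blocks")
    }
    la <- fwd$logAlpha
    lb <- bwd$logBeta
    ll <- fwd$logLikelihood
    E <- .blockExponentMatrix(model, blocks)
    logA <- .safeLog(model@trans)
    n <- blocks@end - blocks@start

    gamma <- exp(la + lb - ll)
    xi <- array(0, c(W, N, N))
    for (w in seq_len(W)) {
        diagTerm <- (n[w] - 1) * gamma[w, ]
        m <- matrix(0, N, N)
        if (w < W) {
            # m[i, j] = alpha_w(i) A_ij e^{E_{w+1}(j)} beta_{w+1}(j) / p
            m <- exp(
                outer(la[w, ], E[w + 1, ] + lb[w + 1, ], "+") + logA - ll
            )
            m[logA == -Inf] <- 0
        }
        diag(m) <- diag(m) + diagTerm
        xi[w, , ] <- m
    }
    list(xi = xi, gamma = gamma)
}

#' Compressed Baum-Welch reestimation step
#'
#' M-step from block posteriors: \eqn{\bar\pi_i = \gamma_1(i)};
#' \eqn{\bar A_{ij} = \sum_w \xi_w(i,j) / (\sum_w n_w\gamma_w(i) -
#' \gamma_W(i))};
#' \eqn{\bar\mu_j = \sum_w \gamma_w(j)\Sigma_{1,w} / \sum_w \gamma_w(j)
#' n_w}; and
#' \eqn{\bar\sigma_j^2 = \sum_w \gamma_w(j)[\Sigma_{2,w} -
#' 2\bar\mu_j\Sigma_{1,w} + n_w\bar\mu_j^2] / \sum_w \gamma_w(j) n_w},
#' floored at 1e-8. Topology zeros are preserved; zero-mass states keep
#' their previous parameters with a warning.
#'
#' @inheritParams compressedForward
#' @param post result of [compressedPosteriors()].
#' @return an updated, valid [HMMModel-class].
#' @export
compressedReestimate <- function(model, blocks, post) {
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    N <- nStates(model)
    W <- nBlocks(blocks)
    gamma <- post$gamma
    xi <- post$xi
    if (!identical(dim(gamma), c(W, N))) {
        stop("posterior dimensions do not match the blocks")
    }
    n <- blocks@end - blocks@start

    newInit <- gamma[1, ] / sum(gamma[1, ])

    newTrans <- model@trans
    xiSum <- apply(xi, c(2, 3), sum)
    denomA <- colSums(n * gamma) - gamma[W, ]
    for (i in seq_len(N)) {
        if (denomA[i] > 0) {
            newTrans[i, ] <- xiSum[i, ] / denomA[i]
        } else {
            warning(sprintf(
                "state %d has zero posterior transition mass; keeping its previous transition row",
                i
            ))
        }
    }
    newTrans <- newTrans / rowSums(newTrans)

    newMeans <- model@means
    newVars <- model@variances
    wTot <- colSums(n * gamma)
    for (j in seq_len(N)) {
        if (wTot[j] > 0) {
            newMeans[j] <- sum(gamma[, j] * blocks@s1) / wTot[j]
            newVars[j] <- max(
                sum(gamma[, j] * (blocks@s2 - 2 * newMeans[j] * blocks@s1 +
                    n * newMeans[j]^2)) / wTot[j],
                .VARIANCE_FLOOR
            )
        } else {
            warning(sprintf(
                "state %d has zero posterior mass; keeping its previous emission parameters",
                j
            ))
        }
    }

    HMMModel(newTrans, newMeans, newVars, newInit)
}

#' Compressed Baum-Welch training
#'
#' EM over the block-constrained model: the sequence is compressed once,
#' the blocks stay fixed across iterations, and each iteration runs the
#' compressed forward/backward/posterior/reestimation cycle. The block
#' exponents \eqn{E_w(j)} are recomputed each iteration from the current
#' parameters (they contain \eqn{\log A_{jj}}). The compressed
#' log-likelihood is non-decreasing per iteration.
#'
#' @inheritParams compressedForward
#' @param tol numeric convergence threshold on the log-likelihood
#'   improvement (default 1e-3).
#' @param maxIter iteration cap (default 100).
#' @return a list with `model`, `logLik` (per-iteration compressed
#'   log-likelihood) and `iterations`.
#' @export
compressedBaumWelch <- function(model, blocks, tol = 1e-3, maxIter = 100) {
    stopifnot(tol > 0, maxIter >= 1)
    model <- .checkModel(model)
    blocks <- .checkBlocks(blocks)
    ll <- numeric(0)
    for (it in seq_len(maxIter)) {
        fwd <- compressedForward(model, blocks)
        ll <- c(ll, fwd$logLikelihood)
        if (it > 1 && ll[it] - ll[it - 1] < tol) {
            return(list(model = model, logLik = ll, iterations = it))
        }
        bwd <- compressedBackward(model, blocks)
        post <- compressedPosteriors(model, blocks, fwd, bwd)
        model <- compressedReestimate(model, blocks, post)
    }
    list(model = model, logLik = ll, iterations = maxIter)
}
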