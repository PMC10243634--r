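#' @useDynLib waveHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm kmeans sd
NULL

.checkObservations <- function(y) {
    if (!is.numeric(y) || length(y) < 1) {
        stop("observations must be a non-empty numeric vector")
    }
    if (any(!is.finite(y))) {
        stop("observations must be finite")
    }
    as.numeric(y)
}

.checkModel <- function(model) {
    stopifnot(is(model, "HMMModel"))
    validObject(model)
    model
}

#' Log density of a univariate Gaussian emission
#'
#' The per-state emission log-likelihood
#' \eqn{\log L_j(t) = \log N(y_t \mid \mu_j, \sigma_j^2)}.
#'
#' @param y numeric, observed value(s).
#' @param mean numeric, emission mean.
#' @param variance numeric, emission variance (> 0).
#' @return numeric log density, vectorised over `y`.
#' @examples
#' logEmission(0, 0, 1) # -log(sqrt(2*pi))
#' @export
logEmission <- function(y, mean, variance) {
    if (any(!is.finite(variance)) || any(variance <= 0)) {
        stop("'variance' must be strictly positive")
    }
    -(y - mean)^2 / (2 * variance) - 0.5 * log(2 * pi * variance)
}

# T x N matrix of log L_j(t); the single emission evaluation shared by the
# forward, backward and Viterbi recursions.
.logEmisMatrix <- function(model, y) {
    mu <- model@means
    v <- model@variances
    T <- length(y)
    N <- length(mu)
    out <- matrix(0, T, N)
    for (j in seq_len(N)) out[, j] <- logEmission(y, mu[j], v[j])
    out
}

# log of probabilities with exact zeros mapped to -Inf and no warning
.safeLog <- function(p) {
    out <- rep(-Inf, length(p))
    pos <- p > 0
    out[pos] <- log(p[pos])
    if (is.matrix(p)) dim(out) <- dim(p)
    out
}

#' Forward algorithm (log space)
#'
#' Computes the forward trellis \eqn{\log \alpha_t(i)} and the total
#' log-likelihood \eqn{\log p(y \mid \lambda)} for a Gaussian-emission HMM,
#' entirely in the log domain via log-sum-exp.
#'
#' @param model an [HMMModel-class].
#' @param obs numeric observation vector.
#' @return a list with elements `logAlpha` (\eqn{T \times N} matrix) and
#'   `logLikelihood`.
#' @examples
#' m <- HMMModel(matrix(1), means = 0, variances = 1, init = 1)
#' hmmForward(m, c(0, 0))$logLikelihood # 2 * dnorm(0, log = TRUE)
#' @export
hmmForward <- function(model, obs) {
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    r <- .cpp_forward(
        .safeLog(model@init), .safeLog(model@trans),
        .logEmisMatrix(model, y)
    )
    list(logAlpha = r$log_alpha, logLikelihood = r$log_likelihood)
}

#' Backward algorithm (log space)
#'
#' Computes \eqn{\log \beta_t(j)}, the log probability of the observation
#' suffix \eqn{y_{t+1..T}} given state \eqn{j} at \eqn{t};
#' \eqn{\beta_T(j) = 1}.
#'
#' @inheritParams hmmForward
#' @return a list with element `logBeta` (\eqn{T \times N} matrix).
#' @export
hmmBackward <- function(model, obs) {
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    lb <- .cpp_backward(.safeLog(model@trans), .logEmisMatrix(model, y))
    list(logBeta = lb)
}

#' Viterbi decoding
#'
#' Finds the most likely state path by dynamic programming over
#' \eqn{\log \delta_t(j)} with backpointers \eqn{\psi_t(j)}. Ties in the
#' argmax are broken toward the smallest state index, so decoded paths are
#' reproducible.
#'
#' @inheritParams hmmForward
#' @return a list with `logBest` (the joint log probability of the best
#'   path and the observations), `path` (0-based state indices, length T),
#'   `logDelta` and `psi` (0-based backpointers).
#' @export
hmmViterbi <- function(model, obs) {
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    r <- .cpp_viterbi(
        .safeLog(model@init), .safeLog(model@trans),
        .logEmisMatrix(model, y)
    )
    list(
        logBest = r$log_best, path = as.integer(r$path),
        logDelta = r$log_delta, psi = r$psi
    )
}

#' Pairwise and marginal state posteriors
#'
#' Computes \eqn{\xi_t(i,j) = P(q_t = i, q_{t+1} = j \mid y, \lambda)} for
#' \eqn{t < T} and \eqn{\gamma_t(i) = P(q_t = i \mid y, \lambda)} for all
#' \eqn{t}, from forward and backward trellises. \eqn{\gamma} at the final
#' position is \eqn{\alpha_T \beta_T / p(y|\lambda)}, consistent with
#' \eqn{\gamma_t(i) = \sum_j \xi_t(i,j)} at earlier positions.
#'
#' @inheritParams hmmForward
#' @param fwd result of [hmmForward()] for the same model and data.
#' @param bwd result of [hmmBackward()] for the same model and data.
#' @return a list with `xi` (\eqn{(T-1) \times N \times N} array) and
#'   `gamma` (\eqn{T \times N} matrix).
#' @export
posteriorStats <- function(model, obs, fwd = hmmForward(model, obs),
                           bwd = hmmBackward(model, obs)) {
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    N <- nStates(model)
    if (!identical(dim(fwd$logAlpha), c(length(y), N)) ||
        !identical(dim(bwd$logBeta), c(length(y), N))) {
        stop("trellis dimensions do not match the model and observations")
    }
    r <- .cpp_xi_gamma(
        .safeLog(model@trans), .logEmisMatrix(model, y),
        fwd$logAlpha, bwd$logBeta, fwd$logLikelihood
    )
    list(xi = r$xi, gamma = r$gamma)
}

.VARIANCE_FLOOR <- 1e-8

#' One Baum-Welch reestimation step (M-step)
#'
#' Updates \eqn{\pi}, \eqn{A}, and the per-state Gaussian means and
#' variances from posterior statistics:
#' \eqn{\bar\pi_i = \gamma_1(i)},
#' \eqn{\bar A_{ij} = \sum_{t<T} \xi_t(i,j) / \sum_{t<T} \gamma_t(i)},
#' \eqn{\bar\mu_j = \sum_t \gamma_t(j) y_t / \sum_t \gamma_t(j)}, and the
#' \eqn{\gamma}-weighted variance about \eqn{\bar\mu_j}, floored at 1e-8 to
#' prevent collapse on degenerate clusters. Transitions that are exactly
#' zero in the input model (topology constraints) remain exactly zero. A
#' state with no posterior mass keeps its previous parameters, with a
#' warning.
#'
#' @inheritParams hmmForward
#' @param stats result of [posteriorStats()].
#' @return an updated, valid [HMMModel-class].
#' @export
reestimate <- function(model, obs, stats) {
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    N <- nStates(model)
    T <- length(y)
    gamma <- stats$gamma
    if (!identical(dim(gamma), c(T, N))) {
        stop("posterior dimensions do not match the model and observations")
    }

    newInit <- gamma[1, ]
    newInit <- newInit / sum(newInit)

    newTrans <- model@trans
    if (T > 1) {
        xiSum <- matrix(colSums(matrix(stats$xi, nrow = T - 1)), N, N)
        gammaSum <- colSums(gamma[-T, , drop = FALSE])
        for (i in seq_len(N)) {
            if (gammaSum[i] > 0) {
                newTrans[i, ] <- xiSum[i, ] / gammaSum[i]
            } else {
                warning(sprintf(
                    "state %d has zero posterior transition mass; keeping its previous transition row",
                    i
                ))
            }
        }
        # renormalise away accumulated rounding; support zeros are preserved
        newTrans <- newTrans / rowSums(newTrans)
    }

    newMeans <- model@means
    newVars <- model@variances
    wTot <- colSums(gamma)
    for (j in seq_len(N)) {
        if (wTot[j] > 0) {
            newMeans[j] <- sum(gamma[, j] * y) / wTot[j]
            newVars[j] <- max(
                sum(gamma[, j] * (y - newMeans[j])^2) / wTot[j],
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

#' Baum-Welch training (exact, uncompressed)
#'
#' Iterates forward, backward, posterior and reestimation steps until the
#' log-likelihood improvement falls below `tol` or `maxIter` iterations are
#' reached. The per-iteration log-likelihood is non-decreasing (EM
#' guarantee, up to numerical slack).
#'
#' @inheritParams hmmForward
#' @param tol numeric, stop when the log-likelihood improves by less than
#'   this (default 1e-3).
#' @param maxIter integer, iteration cap (default 100).
#' @return a list with `model` (the trained [HMMModel-class]), `logLik`
#'   (numeric vector of the log-likelihood at each iteration, evaluated at
#'   the iterate's starting parameters), and `iterations`.
#' @export
baumWelch <- function(model, obs, tol = 1e-3, maxIter = 100) {
    stopifnot(tol > 0, maxIter >= 1)
    model <- .checkModel(model)
    y <- .checkObservations(obs)
    ll <- numeric(0)
    for (it in seq_len(maxIter)) {
        fwd <- hmmForward(model, y)
        ll <- c(ll, fwd$logLikelihood)
        if (it > 1 && ll[it] - ll[it - 1] < tol) {
            return(list(model = model, logLik = ll, iterations = it))
        }
        bwd <- hmmBackward(model, y)
        stats <- posteriorStats(model, y, fwd, bwd)
        model <- reestimate(model, y, stats)
    }
    list(model = model, logLik = ll, iterations = maxIter)
}
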