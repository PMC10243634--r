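#' @import methods
NULL

#' Gaussian-emission hidden Markov model
#'
#' An S4 container for a hidden Markov model \eqn{\lambda = (N, A, \theta, \pi)}
#' with a single univariate Gaussian emission density per state: an
#' \eqn{N \times N} row-stochastic transition matrix \eqn{A}, per-state means
#' \eqn{\mu_j} and variances \eqn{\sigma_j^2}, and an initial state
#' distribution \eqn{\pi}. State indices are 0-based in all decoded output.
#'
#' @slot trans numeric matrix, row-stochastic transition probabilities.
#' @slot means numeric vector of per-state emission means.
#' @slot variances numeric vector of strictly positive emission variances.
#' @slot init numeric vector, initial state distribution.
#'
#' @seealso [HMMModel()] for construction, [hmmForward()], [hmmViterbi()],
#'   [baumWelch()] for the classical algorithms.
#' @exportClass HMMModel
setClass("HMMModel",
    representation(
        trans = "matrix",
        means = "numeric",
        variances = "numeric",
        init = "numeric"
    )
)

setValidity("HMMModel", function(object) {
    msg <- character()
    A <- object@trans
    n <- nrow(A)
    if (!is.numeric(A) || ncol(A) != n) {
        return("'trans' must be a square numeric matrix")
    }
    if (length(object@means) != n) {
        msg <- c(msg, "length of 'means' must equal the number of states")
    }
    if (length(object@variances) != n) {
        msg <- c(msg, "length of 'variances' must equal the number of states")
    }
    if (length(object@init) != n) {
        msg <- c(msg, "length of 'init' must equal the number of states")
    }
    if (any(!is.finite(A)) || any(A < 0) || any(A > 1)) {
        msg <- c(msg, "transition probabilities must lie in [0, 1]")
    } else {
        bad <- which(abs(rowSums(A) - 1) > 1e-12)
        if (length(bad)) {
            msg <- c(msg, sprintf(
                "transition matrix row %s does not sum to 1",
                paste(bad, collapse = ", ")
            ))
        }
    }
    p <- object@init
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
        msg <- c(msg, "initial probabilities must lie in [0, 1]")
    } else if (abs(sum(p) - 1) > 1e-12) {
        msg <- c(msg, "initial distribution does not sum to 1")
    }
    if (any(!is.finite(object@variances)) || any(object@variances <= 0)) {
        msg <- c(msg, "variances must be strictly positive")
    }
    if (any(!is.finite(object@means))) {
        msg <- c(msg, "means must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Gaussian-emission HMM
#'
#' @param trans numeric \eqn{N \times N} row-stochastic transition matrix.
#' @param means numeric vector of \eqn{N} emission means.
#' @param variances numeric vector of \eqn{N} positive emission variances.
#' @param init numeric vector of \eqn{N} initial state probabilities
#'   (default uniform).
#'
#' @return A validated [HMMModel-class] object.
#' @examples
#' m <- HMMModel(
#'     trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'     means = c(0, 3), variances = c(1, 1)
#' )
#' nStates(m)
#' @export
HMMModel <- function(trans, means, variances,
                     init = rep(1 / length(means), length(means))) {
    trans <- as.matrix(trans)
    storage.mode(trans) <- "double"
    new("HMMModel",
        trans = trans, means = as.numeric(means),
        variances = as.numeric(variances), init = as.numeric(init)
    )
}

#' Block partition of an observation sequence
#'
#' Contiguous, non-overlapping blocks covering positions \eqn{[0, T)} of an
#' observation sequence, each summarised by its length \eqn{n_w} and the
#' sufficient statistics \eqn{\Sigma_{1,w} = \sum_t y_t} and
#' \eqn{\Sigma_{2,w} = \sum_t y_t^2}. Under the weak path assumption the
#' hidden state is constant within a block, so these statistics are all the
#' compressed algorithms need. Positions are 0-based, blocks half-open
#' `[start, end)`.
#'
#' @slot start integer-valued start positions (0-based, inclusive).
#' @slot end integer-valued end positions (0-based, exclusive).
#' @slot s1 per-block sums of the observations.
#' @slot s2 per-block sums of squared observations.
#' @slot T total sequence length.
#'
#' @seealso [buildBlocks()], [compressSequence()], [compressedForward()]
#' @exportClass BlockSequence
setClass("BlockSequence",
    representation(
        start = "numeric",
        end = "numeric",
        s1 = "numeric",
        s2 = "numeric",
        T = "numeric"
    )
)

setValidity("BlockSequence", function(object) {
    msg <- character()
    W <- length(object@start)
    if (W < 1) msg <- c(msg, "a BlockSequence must contain at least one block")
    if (length(object@end) != W || length(object@s1) != W ||
        length(object@s2) != W) {
        return("slots 'start', 'end', 's1', 's2' must have equal length")
    }
    n <- object@end - object@start
    if (any(n < 1)) msg <- c(msg, "every block must have length >= 1")
    if (W >= 1 && object@start[1] != 0) {
        msg <- c(msg, "the first block must start at 0")
    }
    if (W > 1 && any(object@start[-1] != object@end[-W])) {
        msg <- c(msg, "blocks must be contiguous and non-overlapping")
    }
    if (W >= 1 && object@end[W] != object@T) {
        msg <- c(msg, "blocks must cover [0, T)")
    }
    # Cauchy-Schwarz: n * s2 >= s1^2 (tiny slack for accumulated rounding)
    if (any(object@s2 - object@s1^2 / n < -1e-8 * pmax(1, abs(object@s2)))) {
        msg <- c(msg, "block statistics violate s2 >= s1^2/n")
    }
    if (length(msg)) msg else TRUE
})

#' Haar wavelet decomposition (lifting scheme)
#'
#' Result of the orthonormal Haar analysis of a length-\eqn{T} sequence,
#' stored level by level. Each level holds the detail coefficients produced
#' at that scale together with the 0-based centre of each coefficient's
#' support (the position where the corresponding Haar wavelet changes sign);
#' odd-length levels carry their last element up unchanged, so arbitrary
#' \eqn{T} is handled without padding. The total number of coefficients
#' (details plus the final smooth) equals \eqn{T}.
#'
#' @slot details list of numeric vectors, detail coefficients per level
#'   (finest first).
#' @slot centers list of numeric vectors, support centre of each detail.
#' @slot spanStarts,spanEnds lists of numeric vectors, the 0-based
#'   half-open support `[start, end)` of each detail coefficient.
#' @slot carried logical vector, whether the level had an odd carry.
#' @slot smooth numeric, the final approximation coefficient.
#' @slot T original sequence length.
#'
#' @seealso [haarLift()], [haarInverse()], [detectBreakpoints()]
#' @exportClass HaarDecomposition
setClass("HaarDecomposition",
    representation(
        details = "list",
        centers = "list",
        spanStarts = "list",
        spanEnds = "list",
        carried = "logical",
        smooth = "numeric",
        T = "numeric"
    )
)

setValidity("HaarDecomposition", function(object) {
    msg <- character()
    ncoef <- sum(lengths(object@details)) + length(object@smooth)
    if (ncoef != object@T) {
        msg <- c(msg, "total coefficient count must equal T")
    }
    for (slot in c("centers", "spanStarts", "spanEnds")) {
        v <- slot(object, slot)
        if (length(v) != length(object@details) ||
            any(lengths(v) != lengths(object@details))) {
            msg <- c(msg, sprintf("'%s' must parallel 'details'", slot))
        }
    }
    if (length(object@carried) != length(object@details)) {
        msg <- c(msg, "'carried' must have one entry per level")
    }
    if (length(msg)) msg else TRUE
})
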