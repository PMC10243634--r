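# Replay the level structure (element support sizes and carries) that
# haarLift produces for a length-T input; used by the inverse so nothing
# beyond the coefficients needs storing.
.haarLevelPlan <- function(T) {
    sizes <- rep(1, T)
    plan <- list()
    lev <- 0L
    while (length(sizes) > 1) {
        lev <- lev + 1L
        n <- length(sizes)
        npair <- n %/% 2L
        odd <- n %% 2L == 1L
        ia <- seq(1L, 2L * npair, by = 2L)
        ib <- ia + 1L
        plan[[lev]] <- list(na = sizes[ia], nb = sizes[ib], odd = odd)
        merged <- sizes[ia] + sizes[ib]
        sizes <- if (odd) c(merged, sizes[n]) else merged
    }
    plan
}

#' Haar wavelet analysis via the lifting scheme
#'
#' Orthonormal Haar decomposition of a numeric sequence, computed level by
#' level in \eqn{O(T)}: each pair of equal-support elements \eqn{(a, b)}
#' becomes a smooth \eqn{(a+b)/\sqrt 2} and a detail \eqn{(a-b)/\sqrt 2}.
#' Odd-length levels carry their last element to the next level unchanged,
#' so any length is handled without padding (and hence without phantom
#' jumps at the padded tail). When a carried element is eventually paired
#' with a smooth of larger support, the support-weighted (unbalanced Haar)
#' form of the same rule is used,
#' \deqn{d = (\bar a - \bar b)\sqrt{n_a n_b / (n_a + n_b)},}
#' with \eqn{\bar a, \bar b} the element means and \eqn{n_a, n_b} their
#' supports — identical to \eqn{(a-b)/\sqrt 2} when \eqn{n_a = n_b}. This
#' keeps the transform orthonormal for every length, so each detail has
#' variance \eqn{\sigma^2} under i.i.d. noise, details are invariant to
#' adding a constant, and constant sequences have all-zero details. For
#' each detail coefficient the 0-based centre of its support — the position
#' where the corresponding wavelet changes sign — is recorded; that is the
#' candidate block boundary the coefficient votes for.
#'
#' @param obs numeric observation vector (length >= 1).
#' @return a [HaarDecomposition-class].
#' @examples
#' h <- haarLift(c(2, 0))
#' h@details[[1]] # sqrt(2)
#' @export
haarLift <- function(obs) {
    y <- .checkObservations(obs)
    T <- length(y)
    vals <- y # element value = sum over support / sqrt(support)
    sizes <- rep(1, T)
    starts <- seq_len(T) - 1
    details <- list()
    centers <- list()
    spanStarts <- list()
    spanEnds <- list()
    carried <- logical(0)
    lev <- 0L
    while (length(vals) > 1) {
        lev <- lev + 1L
        n <- length(vals)
        npair <- n %/% 2L
        odd <- n %% 2L == 1L
        ia <- seq(1L, 2L * npair, by = 2L)
        ib <- ia + 1L
        na <- sizes[ia]
        nb <- sizes[ib]
        ns <- na + nb
        meanA <- vals[ia] / sqrt(na)
        meanB <- vals[ib] / sqrt(nb)
        details[[lev]] <- (meanA - meanB) * sqrt(na * nb / ns)
        centers[[lev]] <- starts[ib]
        spanStarts[[lev]] <- starts[ia]
        spanEnds[[lev]] <- starts[ib] + nb
        carried[lev] <- odd
        smooth <- (sqrt(na) * vals[ia] + sqrt(nb) * vals[ib]) / sqrt(ns)
        if (odd) {
            vals <- c(smooth, vals[n])
            sizes <- c(ns, sizes[n])
            starts <- c(starts[ia], starts[n])
        } else {
            vals <- smooth
            sizes <- ns
            starts <- starts[ia]
        }
    }
    new("HaarDecomposition",
        details = details, centers = centers, spanStarts = spanStarts,
        spanEnds = spanEnds, carried = carried, smooth = vals, T = T
    )
}

#' Inverse Haar transform
#'
#' Exact inverse of [haarLift()]. Applied to thresholded coefficients it
#' returns the wavelet shrinkage (regression) estimate \eqn{\hat f}.
#'
#' @param coeffs a [HaarDecomposition-class].
#' @return numeric vector of length `T`.
#' @export
haarInverse <- function(coeffs) {
    stopifnot(is(coeffs, "HaarDecomposition"))
    validObject(coeffs)
    plan <- .haarLevelPlan(coeffs@T)
    if (length(plan) != length(coeffs@details)) {
        stop("coefficient levels do not match the recorded length T")
    }
    vals <- coeffs@smooth
    for (lev in rev(seq_along(coeffs@details))) {
        d <- coeffs@details[[lev]]
        k <- length(d)
        p <- plan[[lev]]
        expect <- k + as.integer(coeffs@carried[lev])
        if (length(vals) != expect || length(p$na) != k) {
            stop(sprintf(
                "level %d size mismatch: expected %d values, have %d",
                lev, expect, length(vals)
            ))
        }
        na <- p$na
        nb <- p$nb
        ns <- na + nb
        s <- vals[seq_len(k)]
        meanS <- s / sqrt(ns)
        diff <- d / sqrt(na * nb / ns)
        meanA <- meanS + nb * diff / ns
        meanB <- meanS - na * diff / ns
        out <- numeric(2L * k)
        out[seq(1L, 2L * k, by = 2L)] <- meanA * sqrt(na)
        out[seq(2L, 2L * k, by = 2L)] <- meanB * sqrt(nb)
        if (coeffs@carried[lev]) out <- c(out, vals[k + 1L])
        vals <- out
    }
    vals
}

#' Estimate the noise standard deviation from finest-detail coefficients
#'
#' Under the orthonormal convention each finest-level detail away from a
#' jump is \eqn{N(0, \sigma^2)}, so the median absolute finest detail
#' divided by 0.6745 is a jump-robust estimate of the noise SD.
#'
#' @param coeffs a [HaarDecomposition-class] of a sequence with `T >= 2`.
#' @return non-negative numeric estimate \eqn{\hat\sigma}.
#' @export
estimateNoiseSd <- function(coeffs) {
    stopifnot(is(coeffs, "HaarDecomposition"))
    if (length(coeffs@details) < 1) {
        stop("noise estimation needs T >= 2 (no detail coefficients)")
    }
    median(abs(coeffs@details[[1]])) / 0.6745
}

#' Universal shrinkage threshold
#'
#' \eqn{\lambda_u = \sqrt{2 \ln T}\,\sigma}: detail coefficients below this
#' in absolute value are attributed to Gaussian noise.
#'
#' @param T integer sequence length (>= 1).
#' @param sigma non-negative noise standard deviation.
#' @return the threshold \eqn{\lambda_u}.
#' @examples
#' universalThreshold(100000, 1) # 4.79853
#' @export
universalThreshold <- function(T, sigma) {
    if (length(T) != 1 || !is.finite(T) || T < 1) {
        stop("'T' must be a single integer >= 1")
    }
    if (sigma < 0) stop("'sigma' must be non-negative")
    sqrt(2 * log(T)) * sigma
}

#' Hard-threshold detail coefficients
#'
#' Zeroes every detail coefficient with absolute value at or below the
#' threshold; [haarInverse()] of the result is the shrinkage estimate.
#'
#' @param coeffs a [HaarDecomposition-class].
#' @param threshold non-negative cutoff.
#' @return a [HaarDecomposition-class] with thresholded details.
#' @export
thresholdCoefficients <- function(coeffs, threshold) {
    stopifnot(is(coeffs, "HaarDecomposition"), threshold >= 0)
    coeffs@details <- lapply(
        coeffs@details,
        function(d) ifelse(abs(d) > threshold, d, 0)
    )
    coeffs
}

#' Detect candidate block boundaries
#'
#' Every detail coefficient whose absolute value exceeds the threshold
#' marks a discontinuity of the shrinkage reconstruction \eqn{\hat f}.
#' \eqn{\hat f} can change value exactly where some retained wavelet does:
#' at its support centre (the sign change) and at its support edges. All
#' those positions are emitted as candidate boundaries \eqn{b \in (0, T)}
#' ("a block ends at `b`, exclusive"), deduplicated and sorted. Emitting
#' the edges as well as the centres yields a superset of the possible
#' boundaries, which costs a little compression but places a boundary at
#' (or next to) every discontinuity the reconstruction can express.
#'
#' @inheritParams thresholdCoefficients
#' @return sorted numeric vector of boundary positions (possibly empty).
#' @export
detectBreakpoints <- function(coeffs, threshold) {
    stopifnot(is(coeffs, "HaarDecomposition"), threshold >= 0)
    hits <- unlist(Map(
        function(d, ctr, s, e) {
            keep <- abs(d) > threshold
            c(ctr[keep], s[keep], e[keep])
        },
        coeffs@details, coeffs@centers, coeffs@spanStarts, coeffs@spanEnds
    ), use.names = FALSE)
    hits <- hits[hits > 0 & hits < coeffs@T]
    sort(unique(hits))
}

#' Re-localize detected boundaries to maximum-likelihood changepoints
#'
#' A detail coefficient above the threshold indicates a jump somewhere in
#' its support, but its centre pins the jump only to the dyadic grid of
#' that scale. This step re-places each retained coefficient's centre at
#' the maximum-CUSUM split of the observations within the coefficient's
#' own support (the maximum-likelihood changepoint under Gaussian noise),
#' clipped to the gap between neighbouring candidates so boundaries cannot
#' cross. Support edges are kept as-is: they delimit where neighbouring
#' wavelets take over. The search window is the detection scale itself, so
#' no tuning parameter is introduced.
#'
#' @param obs numeric observation vector the coefficients came from.
#' @inheritParams thresholdCoefficients
#' @return sorted numeric vector of boundary positions.
#' @export
localizeBreakpoints <- function(obs, coeffs, threshold) {
    y <- .checkObservations(obs)
    stopifnot(is(coeffs, "HaarDecomposition"), threshold >= 0)
    if (length(y) != coeffs@T) {
        stop("observations do not match the decomposition length")
    }
    cand <- detectBreakpoints(coeffs, threshold)
    if (!length(cand)) {
        return(cand)
    }
    cs <- c(0, cumsum(y))
    bestSplit <- function(p, q) {
        n <- q - p
        j <- seq_len(n - 1)
        left <- cs[p + 1 + j] - cs[p + 1]
        tot <- cs[q + 1] - cs[p + 1]
        stat <- abs(left / j - (tot - left) / (n - j)) *
            sqrt(j * (n - j) / n)
        p + which.max(stat)
    }
    ctrs <- do.call(rbind, Map(
        function(d, ctr, s, e) {
            keep <- abs(d) > threshold
            if (!any(keep)) return(NULL)
            cbind(ctr[keep], s[keep], e[keep])
        },
        coeffs@details, coeffs@centers, coeffs@spanStarts, coeffs@spanEnds
    ))
    out <- cand
    for (r in seq_len(NROW(ctrs))) {
        b <- ctrs[r, 1]
        i <- match(b, cand)
        if (is.na(i)) next # centre coincided with another coefficient's edge
        lo <- if (i > 1) cand[i - 1] else 0
        hi <- if (i < length(cand)) cand[i + 1] else length(y)
        p <- max(ctrs[r, 2], lo)
        q <- min(ctrs[r, 3], hi)
        if (q - p >= 2) out[i] <- bestSplit(p, q)
    }
    sort(unique(out))
}

#' Build a block partition with sufficient statistics
#'
#' Splits `[0, T)` at the given boundaries and computes each block's length
#' \eqn{n_w} and sufficient statistics \eqn{\Sigma_{1,w}, \Sigma_{2,w}} in
#' one pass over the data.
#'
#' @param obs numeric observation vector.
#' @param breakpoints sorted unique positions strictly inside `(0, T)`.
#' @return a [BlockSequence-class].
#' @examples
#' b <- buildBlocks(c(1, 1, 5, 5), 2)
#' blockSums(b) # 2, 10
#' @export
buildBlocks <- function(obs, breakpoints = numeric(0)) {
    y <- .checkObservations(obs)
    T <- length(y)
    bp <- as.numeric(breakpoints)
    if (length(bp)) {
        if (is.unsorted(bp, strictly = TRUE)) {
            stop("breakpoints must be sorted and unique")
        }
        if (any(bp <= 0 | bp >= T | bp != floor(bp))) {
            stop("breakpoints must be integers strictly inside (0, T)")
        }
    }
    edges <- c(0, bp, T)
    cs1 <- c(0, cumsum(y))
    cs2 <- c(0, cumsum(y^2))
    W <- length(edges) - 1L
    new("BlockSequence",
        start = edges[-(W + 1L)], end = edges[-1L],
        s1 = diff(cs1[edges + 1L]), s2 = diff(cs2[edges + 1L]),
        T = T
    )
}

#' Compress a sequence into blocks of sufficient statistics
#'
#' The full compression pipeline: Haar analysis, noise-SD estimation (when
#' `sigma` is not supplied), universal thresholding, boundary detection
#' with maximum-likelihood re-localization (see [localizeBreakpoints()])
#' and block construction. For heteroscedastic models the smallest emission SD
#' can be passed as `sigma` (at the cost of under-compression in
#' high-variance regions).
#'
#' @param obs numeric observation vector.
#' @param sigma optional known noise SD; estimated from the finest detail
#'   coefficients when `NULL`.
#' @param thresholdOverride optional explicit threshold replacing the
#'   universal threshold (e.g. 0 to force singleton blocks).
#' @param verbose logical; log the compression ratio `T/W`.
#' @return a [BlockSequence-class]; the threshold used, the noise SD and
#'   the compression ratio are attached as attributes `"threshold"`,
#'   `"sigma"` and `"ratio"`.
#' @export
compressSequence <- function(obs, sigma = NULL, thresholdOverride = NULL,
                             verbose = FALSE) {
    y <- .checkObservations(obs)
    T <- length(y)
    h <- haarLift(y)
    if (is.null(thresholdOverride)) {
        if (is.null(sigma)) {
            sigma <- if (T >= 2) estimateNoiseSd(h) else 0
        }
        lambda <- universalThreshold(T, sigma)
    } else {
        lambda <- thresholdOverride
        if (is.null(sigma)) sigma <- NA_real_
    }
    bp <- if (T > 1) localizeBreakpoints(y, h, lambda) else numeric(0)
    blocks <- buildBlocks(y, bp)
    attr(blocks, "threshold") <- lambda
    attr(blocks, "sigma") <- sigma
    attr(blocks, "ratio") <- T / nBlocks(blocks)
    if (verbose) {
        message(sprintf(
            "compressed T = %d into W = %d blocks (ratio %.2f, threshold %.4g)",
            T, nBlocks(blocks), T / nBlocks(blocks), lambda
        ))
    }
    blocks
}
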