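#' @rdname HMMModel
#' @param object,x an object.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname HMMModel
#' @export
setGeneric("transitionMatrix",
    function(object) standardGeneric("transitionMatrix"))

#' @rdname HMMModel
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))

#' @rdname HMMModel
#' @export
setGeneric("stateVariances",
    function(object) standardGeneric("stateVariances"))

#' @rdname HMMModel
#' @export
setGeneric("initialDistribution",
    function(object) standardGeneric("initialDistribution"))

#' Accessors for block partitions
#'
#' Block counts, coordinates, lengths, sufficient statistics and the
#' compression ratio `T/W` of a [BlockSequence-class].
#'
#' @param object a [BlockSequence-class].
#' @name blockAccessors
#' @rdname blockAccessors
#' @export
setGeneric("nBlocks", function(object) standardGeneric("nBlocks"))

#' @rdname blockAccessors
#' @export
setGeneric("blockStarts", function(object) standardGeneric("blockStarts"))

#' @rdname blockAccessors
#' @export
setGeneric("blockEnds", function(object) standardGeneric("blockEnds"))

#' @rdname blockAccessors
#' @export
setGeneric("blockLengths", function(object) standardGeneric("blockLengths"))

#' @rdname blockAccessors
#' @export
setGeneric("blockSums", function(object) standardGeneric("blockSums"))

#' @rdname blockAccessors
#' @export
setGeneric("blockSumSquares",
    function(object) standardGeneric("blockSumSquares"))

#' @rdname blockAccessors
#' @export
setGeneric("seqLength", function(object) standardGeneric("seqLength"))

#' @rdname blockAccessors
#' @export
setGeneric("compressionRatio",
    function(object) standardGeneric("compressionRatio"))

setMethod("nStates", "HMMModel", function(object) nrow(object@trans))
setMethod("transitionMatrix", "HMMModel", function(object) object@trans)
setMethod("stateMeans", "HMMModel", function(object) object@means)
setMethod("stateVariances", "HMMModel", function(object) object@variances)
setMethod("initialDistribution", "HMMModel", function(object) object@init)

setMethod("show", "HMMModel", function(object) {
    N <- nStates(object)
    cat(sprintf("HMMModel with %d state%s (Gaussian emissions)\n",
        N, if (N == 1) "" else "s"))
    cat("  means:    ", paste(signif(object@means, 5), collapse = " "), "\n")
    cat("  variances:", paste(signif(object@variances, 5), collapse = " "),
        "\n")
    cat("  init:     ", paste(signif(object@init, 5), collapse = " "), "\n")
    cat("  transition matrix:\n")
    A <- signif(object@trans, 5)
    dimnames(A) <- list(
        paste0("  S", seq_len(N)), paste0("S", seq_len(N))
    )
    print(A)
    invisible(object)
})

setMethod("nBlocks", "BlockSequence", function(object) length(object@start))
setMethod("blockStarts", "BlockSequence", function(object) object@start)
setMethod("blockEnds", "BlockSequence", function(object) object@end)
setMethod("blockLengths", "BlockSequence",
    function(object) object@end - object@start)
setMethod("blockSums", "BlockSequence", function(object) object@s1)
setMethod("blockSumSquares", "BlockSequence", function(object) object@s2)
setMethod("seqLength", "BlockSequence", function(object) object@T)
setMethod("compressionRatio", "BlockSequence",
    function(object) object@T / length(object@start))

setMethod("show", "BlockSequence", function(object) {
    W <- nBlocks(object)
    cat(sprintf(
        "BlockSequence: %d block%s over T = %d (compression ratio %.2f)\n",
        W, if (W == 1) "" else "s", as.integer(object@T),
        compressionRatio(object)
    ))
    k <- min(W, 5L)
    df <- data.frame(
        start = object@start[seq_len(k)], end = object@end[seq_len(k)],
        n = (object@end - object@start)[seq_len(k)],
        s1 = signif(object@s1[seq_len(k)], 6),
        s2 = signif(object@s2[seq_len(k)], 6)
    )
    print(df, row.names = FALSE)
    if (W > k) cat(sprintf("  ... and %d more block(s)\n", W - k))
    invisible(object)
})

setMethod("show", "HaarDecomposition", function(object) {
    cat(sprintf(
        "HaarDecomposition of a length-%d sequence: %d level%s, %d detail coefficients\n",
        as.integer(object@T), length(object@details),
        if (length(object@details) == 1) "" else "s",
        sum(lengths(object@details))
    ))
    invisible(object)
})

#' Convert a block partition to a data.frame
#'
#' @param x a [BlockSequence-class].
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return a data.frame with columns `start`, `end`, `n`, `s1`, `s2`.
#' @export
as.data.frame.BlockSequence <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    data.frame(
        start = x@start, end = x@end, n = x@end - x@start,
        s1 = x@s1, s2 = x@s2
    )
}
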