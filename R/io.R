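#' Read an observation sequence
#'
#' Text mode expects one decimal value per line (blank lines ignored);
#' binary mode expects contiguous little-endian IEEE-754 doubles,
#' regardless of the host's byte order.
#'
#' @param path input file path.
#' @param binary logical, read raw doubles instead of text.
#' @return numeric observation vector.
#' @export
readObservations <- function(path, binary = FALSE) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (binary) {
        nbytes <- file.size(path)
        if (nbytes %% 8 != 0) {
            stop(sprintf(
                "truncated binary observation file '%s': %d trailing byte(s) after offset %d",
                path, nbytes %% 8, 8 * (nbytes %/% 8)
            ))
        }
        con <- file(path, "rb")
        on.exit(close(con))
        y <- readBin(con, "double",
            n = nbytes %/% 8, size = 8,
            endian = "little"
        )
    } else {
        lines <- readLines(path)
        lines <- trimws(lines)
        lines <- lines[nzchar(lines)]
        y <- suppressWarnings(as.numeric(lines))
        if (anyNA(y)) {
            bad <- which(is.na(y))[1]
            stop(sprintf(
                "unparseable value '%s' at data line %d of '%s'",
                lines[bad], bad, path
            ))
        }
    }
    .checkObservations(y)
}

#' Write an observation sequence
#'
#' @param obs numeric observation vector.
#' @param path output file path.
#' @param binary logical, write little-endian raw doubles instead of text.
#' @return invisibly, `path`.
#' @export
writeObservations <- function(obs, path, binary = FALSE) {
    y <- .checkObservations(obs)
    if (binary) {
        con <- file(path, "wb")
        on.exit(close(con))
        writeBin(y, con, size = 8, endian = "little")
    } else {
        writeLines(format(y, digits = 17, trim = TRUE, scientific = FALSE),
            con = path)
    }
    invisible(path)
}

#' Read an HMM model from JSON
#'
#' The schema has keys `n_states`, `transitions` (row-major), `means`,
#' `variances` and `initial`; all model invariants are validated on read
#' and violations are reported by field.
#'
#' @param path JSON file path.
#' @return an [HMMModel-class].
#' @export
readModel <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    x <- jsonlite::fromJSON(path)
    need <- c("n_states", "transitions", "means", "variances", "initial")
    missing <- setdiff(need, names(x))
    if (length(missing)) {
        stop(sprintf(
            "model file '%s' lacks field(s): %s",
            path, paste(missing, collapse = ", ")
        ))
    }
    N <- as.integer(x$n_states)
    if (length(x$transitions) != N * N) {
        stop("'transitions' must contain n_states^2 row-major entries")
    }
    A <- matrix(as.numeric(x$transitions), N, N, byrow = TRUE)
    bad <- which(abs(rowSums(A) - 1) > 1e-12)
    if (length(bad)) {
        stop(sprintf(
            "'transitions' row %s does not sum to 1",
            paste(bad, collapse = ", ")
        ))
    }
    tryCatch(
        HMMModel(A, x$means, x$variances, x$initial),
        error = function(e) {
            stop(sprintf("invalid model in '%s': %s", path,
                conditionMessage(e)))
        }
    )
}

#' Write an HMM model to JSON
#'
#' Full-precision round trip of [readModel()]'s schema.
#'
#' @param model an [HMMModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeModel <- function(model, path) {
    model <- .checkModel(model)
    jsonlite::write_json(
        list(
            n_states = nStates(model),
            transitions = as.numeric(t(model@trans)),
            means = model@means,
            variances = model@variances,
            initial = model@init
        ),
        path,
        auto_unbox = TRUE, digits = I(17)
    )
    invisible(path)
}

#' Export a block partition as tab-separated text
#'
#' BED-like table with 0-based half-open coordinates and the per-block
#' sufficient statistics: columns `start`, `end`, `n`, `s1`, `s2`.
#'
#' @param blocks a [BlockSequence-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeBlocks <- function(blocks, path) {
    blocks <- .checkBlocks(blocks)
    df <- as.data.frame(blocks)
    utils::write.table(
        format(df, digits = 17, trim = TRUE, scientific = FALSE),
        file = path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    invisible(path)
}
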