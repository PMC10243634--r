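.TOPOLOGIES <- c("fully_connected", "left_to_right", "circular")

# Topology support matrix (logical N x N): which transitions are allowed.
.topologySupport <- function(kind, N) {
    kind <- match.arg(kind, .TOPOLOGIES)
    S <- switch(kind,
        fully_connected = matrix(TRUE, N, N),
        left_to_right = outer(seq_len(N), seq_len(N), `<=`),
        circular = {
            S <- diag(N) > 0
            S[cbind(seq_len(N), c(seq_len(N - 1) + 1L, 1L))] <- TRUE
            S
        }
    )
    S
}

# Transition matrix for a topology: self-transition 1 - 10N/T, remaining
# mass split uniformly over the allowed out-neighbours. A left-to-right
# final state has no successors and is made absorbing.
.topologyTransitions <- function(kind, N, T) {
    kind <- match.arg(kind, .TOPOLOGIES)
    if (T <= 10 * N) stop("'T' must exceed 10 * N")
    pSelf <- 1 - 10 * N / T
    S <- .topologySupport(kind, N)
    A <- matrix(0, N, N)
    for (i in seq_len(N)) {
        out <- which(S[i, ] & seq_len(N) != i)
        if (length(out) == 0) {
            if (kind == "left_to_right" && i == N) {
                A[i, i] <- 1 # absorbing final state
            } else {
                stop(sprintf("state %d has no allowed out-transitions", i))
            }
        } else {
            A[i, i] <- pSelf
            A[i, out] <- (1 - pSelf) / length(out)
        }
    }
    A
}

#' Build a simulation-study HMM by topology and state separation
#'
#' Constructs a Gaussian-emission HMM following the benchmark design:
#' self-transition probability \eqn{1 - 10N/T} (so a length-`T` sequence
#' sees on average \eqn{10N} state switches), the remaining mass split
#' uniformly over the out-neighbours the topology allows, unit emission
#' variances, and evenly spaced means starting at the standard Gaussian.
#' Adjacent means are spaced so the state separation
#' \eqn{\eta = |\mu_a - \mu_b| / (3(\sigma_a + \sigma_b))} equals `eta`,
#' i.e. \eqn{\Delta\mu = 6\eta} at unit SDs. The initial distribution is
#' uniform. A left-to-right final state is absorbing.
#'
#' @param topology one of `"fully_connected"`, `"left_to_right"`,
#'   `"circular"`.
#' @param N number of states (>= 2).
#' @param T target sequence length; must exceed `10 * N`.
#' @param eta state separation in `(0, 1]` (0.1 = hard, 1.0 = easy).
#' @return an [HMMModel-class].
#' @examples
#' m <- buildModel("fully_connected", N = 2, T = 100000, eta = 0.5)
#' transitionMatrix(m)[1, 1] # 0.9998
#' @export
buildModel <- function(topology = .TOPOLOGIES, N, T, eta) {
    topology <- match.arg(topology)
    stopifnot(N >= 2, eta > 0)
    A <- .topologyTransitions(topology, N, T)
    HMMModel(
        trans = A,
        means = 6 * eta * (seq_len(N) - 1),
        variances = rep(1, N),
        init = rep(1 / N, N)
    )
}

#' Sample a state path and observation sequence from an HMM
#'
#' Markov-chain sampling of the hidden path followed by Gaussian emission
#' per state; fully deterministic given `seed`.
#'
#' @param model an [HMMModel-class].
#' @param T sequence length.
#' @param seed integer seed.
#' @return a list with `states` (0-based, length `T`) and `obs`.
#' @export
sampleSequence <- function(model, T, seed) {
    model <- .checkModel(model)
    stopifnot(T >= 1)
    set.seed(seed)
    path <- .cpp_sample_path(
        cumsum(model@init),
        t(apply(model@trans, 1, cumsum)),
        as.integer(T)
    )
    obs <- rnorm(T,
        mean = model@means[path + 1L],
        sd = sqrt(model@variances[path + 1L])
    )
    list(states = as.integer(path), obs = obs)
}

#' K-means initial parameter estimate
#'
#' Clusters the observations into `N` groups and uses the sorted cluster
#' centres as initial means (sorting gives label stability) and the
#' within-cluster variances (floored) as initial variances. Transitions are
#' initialised to the topology-uniform matrix with self-transition
#' \eqn{1 - 10N/T}; the initial distribution is uniform. An empty cluster
#' triggers an internal re-seed, up to 5 times.
#'
#' @param obs numeric observation vector.
#' @param N number of states.
#' @param T sequence length used for the self-transition rule (defaults to
#'   `length(obs)`).
#' @param seed integer seed for the k-means starts.
#' @param topology transition topology for the initial matrix.
#' @return an [HMMModel-class].
#' @export
kmeansInit <- function(obs, N, T = length(obs), seed = 1,
                       topology = .TOPOLOGIES) {
    y <- .checkObservations(obs)
    topology <- match.arg(topology)
    stopifnot(N >= 1, length(unique(y)) >= N)
    km <- NULL
    for (try in 0:4) {
        set.seed(seed + 1000003L * try)
        km <- tryCatch(
            # convergence warnings are immaterial for an initializer: any
            # clustering near the modes is a usable starting point
            suppressWarnings(kmeans(y, centers = N, nstart = 3,
                iter.max = 50)),
            error = function(e) NULL
        )
        if (!is.null(km) && all(km$size > 0)) break
        km <- NULL
    }
    if (is.null(km)) stop("k-means failed to produce non-empty clusters")
    ord <- order(km$centers)
    means <- as.numeric(km$centers[ord])
    vars <- pmax(km$withinss[ord] / km$size[ord], .VARIANCE_FLOOR)
    A <- if (N >= 2) {
        .topologyTransitions(topology, N, max(T, 10 * N + 1))
    } else {
        matrix(1, 1, 1)
    }
    HMMModel(A, means, vars, rep(1 / N, N))
}

#' Run the accuracy and convergence benchmark
#'
#' For each replicate: build the model for the requested topology and
#' separation, sample a length-`T` sequence, compress it, evaluate and
#' decode in both exact and compressed modes, and (optionally) train both
#' ways from a shared k-means initialisation, keeping the restart with the
#' best final log-likelihood. Replicate `r` uses seed `seed + r - 1`, so
#' any single replicate can be re-run in isolation.
#'
#' @param topology,N,T,eta model construction, as [buildModel()].
#' @param nTests number of replicates.
#' @param nTrainRestarts training restarts per replicate (0 skips
#'   training).
#' @param seed base integer seed.
#' @param tol,maxIter Baum-Welch settings.
#' @return a data.frame with one row per replicate: exact and compressed
#'   log-likelihoods, their relative difference
#'   \eqn{|\Delta\ell| / |\ell|}, Viterbi path agreement, compression
#'   ratio, and (when training) iteration counts and best trained
#'   log-likelihoods for both trainers.
#' @export
runExperiment <- function(topology = .TOPOLOGIES, N = 2, T = 20000,
                          eta = 0.5, nTests = 10, nTrainRestarts = 0,
                          seed = 1, tol = 1e-3, maxIter = 100) {
    topology <- match.arg(topology)
    rows <- vector("list", nTests)
    if (nTests == 0) {
        return(data.frame(
            replicate = integer(0), seed = integer(0),
            logLikExact = numeric(0), logLikCompressed = numeric(0),
            relError = numeric(0), pathAgreement = numeric(0),
            compressionRatio = numeric(0),
            iterExact = integer(0), iterCompressed = integer(0),
            trainLogLikExact = numeric(0),
            trainLogLikCompressed = numeric(0)
        ))
    }
    model <- buildModel(topology, N, T, eta)
    for (r in seq_len(nTests)) {
        repSeed <- seed + r - 1L
        sim <- sampleSequence(model, T, repSeed)
        blocks <- compressSequence(sim$obs)
        fwd <- hmmForward(model, sim$obs)
        cfwd <- compressedForward(model, blocks)
        vit <- hmmViterbi(model, sim$obs)
        cvit <- compressedViterbi(model, blocks)

        iterE <- iterC <- NA_integer_
        bestE <- bestC <- NA_real_
        if (nTrainRestarts > 0) {
            for (s in seq_len(nTrainRestarts)) {
                init <- kmeansInit(sim$obs, N,
                    T = T,
                    seed = repSeed + 7919L * s, topology = topology
                )
                bwE <- baumWelch(init, sim$obs, tol, maxIter)
                bwC <- compressedBaumWelch(init, blocks, tol, maxIter)
                llE <- bwE$logLik[length(bwE$logLik)]
                llC <- bwC$logLik[length(bwC$logLik)]
                if (is.na(bestE) || llE > bestE) {
                    bestE <- llE
                    iterE <- bwE$iterations
                }
                if (is.na(bestC) || llC > bestC) {
                    bestC <- llC
                    iterC <- bwC$iterations
                }
            }
        }
        rows[[r]] <- data.frame(
            replicate = r, seed = repSeed,
            logLikExact = fwd$logLikelihood,
            logLikCompressed = cfwd$logLikelihood,
            relError = abs(cfwd$logLikelihood - fwd$logLikelihood) /
                abs(fwd$logLikelihood),
            pathAgreement = mean(vit$path == cvit$path),
            compressionRatio = attr(blocks, "ratio"),
            iterExact = iterE, iterCompressed = iterC,
            trainLogLikExact = bestE, trainLogLikCompressed = bestC
        )
    }
    do.call(rbind, rows)
}
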