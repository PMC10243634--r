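# Brute-force oracles: exhaustive path enumeration, independent of the
# package's dynamic programming code paths. Only usable at tiny N and T.

# all N^T state paths as rows of a matrix (1-based states)
allPaths <- function(N, T) {
    as.matrix(expand.grid(rep(list(seq_len(N)), T)))
}

pathLogProb <- function(model, y, q) {
    A <- transitionMatrix(model)
    mu <- stateMeans(model)
    v <- stateVariances(model)
    lp <- log(initialDistribution(model)[q[1]]) +
        dnorm(y[1], mu[q[1]], sqrt(v[q[1]]), log = TRUE)
    for (t in seq_along(y)[-1]) {
        lp <- lp + log(A[q[t - 1], q[t]]) +
            dnorm(y[t], mu[q[t]], sqrt(v[q[t]]), log = TRUE)
    }
    lp
}

bfLogLik <- function(model, y) {
    paths <- allPaths(nStates(model), length(y))
    lps <- apply(paths, 1, function(q) pathLogProb(model, y, q))
    m <- max(lps)
    m + log(sum(exp(lps - m)))
}

bfViterbi <- function(model, y) {
    paths <- allPaths(nStates(model), length(y))
    lps <- apply(paths, 1, function(q) pathLogProb(model, y, q))
    best <- which.max(lps)
    list(logBest = lps[best], path = as.integer(paths[best, ] - 1L))
}

bfXiGamma <- function(model, y) {
    N <- nStates(model)
    T <- length(y)
    paths <- allPaths(N, T)
    w <- apply(paths, 1, function(q) pathLogProb(model, y, q))
    w <- exp(w - max(w))
    w <- w / sum(w)
    gamma <- matrix(0, T, N)
    for (t in seq_len(T)) {
        for (i in seq_len(N)) gamma[t, i] <- sum(w[paths[, t] == i])
    }
    xi <- array(0, c(max(T - 1, 0), N, N))
    for (t in seq_len(T - 1)) {
        for (i in seq_len(N)) {
            for (j in seq_len(N)) {
                xi[t, i, j] <- sum(w[paths[, t] == i & paths[, t + 1] == j])
            }
        }
    }
    list(xi = xi, gamma = gamma)
}

# ---- block-constant (constrained) path enumeration --------------------

# log weight of one block-constant assignment q (length W, 1-based),
# computed from raw observations, not from sufficient statistics
blockAssignmentLogProb <- function(model, y, blocks, q) {
    A <- transitionMatrix(model)
    mu <- stateMeans(model)
    v <- stateVariances(model)
    st <- blockStarts(blocks)
    en <- blockEnds(blocks)
    W <- nBlocks(blocks)
    lp <- log(initialDistribution(model)[q[1]])
    for (w in seq_len(W)) {
        j <- q[w]
        n <- en[w] - st[w]
        if (w > 1) lp <- lp + log(A[q[w - 1], j])
        if (n > 1) lp <- lp + (n - 1) * log(A[j, j])
        yw <- y[(st[w] + 1):en[w]]
        lp <- lp + sum(dnorm(yw, mu[j], sqrt(v[j]), log = TRUE))
    }
    lp
}

bfBlockLogLik <- function(model, y, blocks) {
    asg <- allPaths(nStates(model), nBlocks(blocks))
    lps <- apply(asg, 1, function(q) {
        blockAssignmentLogProb(model, y, blocks, q)
    })
    m <- max(lps)
    m + log(sum(exp(lps - m)))
}

bfBlockViterbi <- function(model, y, blocks) {
    asg <- allPaths(nStates(model), nBlocks(blocks))
    lps <- apply(asg, 1, function(q) {
        blockAssignmentLogProb(model, y, blocks, q)
    })
    best <- which.max(lps)
    list(
        logBest = lps[best],
        path = as.integer(rep(asg[best, ] - 1L, blockLengths(blocks)))
    )
}

# block posteriors: gamma_w(i) and the block-summed xi_w(i,j) (within-block
# self transitions plus the single between-block transition)
bfBlockPosteriors <- function(model, y, blocks) {
    N <- nStates(model)
    W <- nBlocks(blocks)
    n <- blockLengths(blocks)
    asg <- allPaths(N, W)
    lps <- apply(asg, 1, function(q) {
        blockAssignmentLogProb(model, y, blocks, q)
    })
    w <- exp(lps - max(lps))
    w <- w / sum(w)
    gamma <- matrix(0, W, N)
    for (b in seq_len(W)) {
        for (i in seq_len(N)) gamma[b, i] <- sum(w[asg[, b] == i])
    }
    xi <- array(0, c(W, N, N))
    for (b in seq_len(W)) {
        for (i in seq_len(N)) {
            xi[b, i, i] <- (n[b] - 1) * gamma[b, i]
            if (b < W) {
                for (j in seq_len(N)) {
                    xi[b, i, j] <- xi[b, i, j] +
                        sum(w[asg[, b] == i & asg[, b + 1] == j])
                }
            }
        }
    }
    list(xi = xi, gamma = gamma)
}

# ---- shared fixtures --------------------------------------------------

# the well-separated two-state chain used across oracle tests
twoStateModel <- function() {
    HMMModel(
        trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
        means = c(0, 3), variances = c(1, 1), init = c(0.5, 0.5)
    )
}

randomModel <- function(N, seed) {
    set.seed(seed)
    A <- matrix(rexp(N * N), N, N)
    A <- A / rowSums(A)
    p <- rexp(N)
    HMMModel(A,
        means = rnorm(N, sd = 2),
        variances = runif(N, 0.3, 2), init = p / sum(p)
    )
}

# smallest error between estimated and true means over all relabelings
bestMeanError <- function(est, truth) {
    perms <- allPaths(length(truth), length(truth))
    perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
        drop = FALSE
    ]
    min(apply(perms, 1, function(p) max(abs(est[p] - truth))))
}
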