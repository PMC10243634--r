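# a small seeded 3-block instance shared by the constrained-oracle tests
threeBlockFixture <- function(seed = 21) {
    model <- twoStateModel()
    set.seed(seed)
    y <- c(rnorm(3, 0), rnorm(2, 3), rnorm(3, 0))
    blocks <- buildBlocks(y, c(3, 5))
    list(model = model, y = y, blocks = blocks)
}

test_that("block exponent reduces to the emission density for singletons", {
    m <- twoStateModel()
    b <- buildBlocks(0)
    expect_equal(blockExponent(b, 1, m), logEmission(0, 0, 1))
    expect_equal(blockExponent(b, 1, m), -0.918939, tolerance = 1e-6)

    # two observations at the state mean: log A_jj - log(2 pi)
    b2 <- buildBlocks(c(3, 3), numeric(0))
    expect_equal(blockExponent(b2, 2, m), log(0.9) - log(2 * pi))
})

test_that("block exponent equals the explicit per-observation identity", {
    # block (1.4, 1.5, 1.6) has n = 3, s1 = 4.5, s2 = 6.77
    yw <- c(1.4, 1.5, 1.6)
    A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
    m <- HMMModel(A, means = c(1.5, 0), variances = c(1, 1))
    b <- buildBlocks(yw)
    expect_equal(blockSums(b), 4.5)
    expect_equal(blockSumSquares(b), sum(yw^2))
    expect_equal(
        blockExponent(b, 1, m),
        2 * log(0.99) + sum(dnorm(yw, 1.5, 1, log = TRUE)),
        tolerance = 1e-12
    )
    # arithmetic form, evaluated independently
    expect_equal(
        blockExponent(b, 1, m),
        (2 * 1.5 * 4.5 - sum(yw^2)) / 2 +
            2 * log(0.99) - 3 * (0 + 1.5^2 / 2 + 0.5 * log(2 * pi)),
        tolerance = 1e-12
    )
})

test_that("zero self-transition makes multi-observation blocks unreachable", {
    A <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
    m <- HMMModel(A, means = c(0, 3), variances = c(1, 1))
    b2 <- buildBlocks(c(0, 0))
    expect_identical(blockExponent(b2, 1, m), -Inf)
    # but a singleton block carries no self-transition term
    b1 <- buildBlocks(0)
    expect_equal(blockExponent(b1, 1, m), logEmission(0, 0, 1))
})

test_that("compressed forward/backward/Viterbi equal uncompressed on singleton blocks", {
    for (seed in 1:3) {
        mod <- randomModel(3, seed + 80)
        set.seed(800 + seed)
        y <- sampleSequence(mod, 40, 800 + seed)$obs
        blocks <- buildBlocks(y, seq_len(39))

        fwd <- hmmForward(mod, y)
        cfwd <- compressedForward(mod, blocks)
        expect_equal(cfwd$logLikelihood, fwd$logLikelihood,
            tolerance = 1e-9)
        expect_equal(cfwd$logAlpha, fwd$logAlpha, tolerance = 1e-9)

        bwd <- hmmBackward(mod, y)
        cbwd <- compressedBackward(mod, blocks)
        expect_equal(cbwd$logBeta, bwd$logBeta, tolerance = 1e-9)

        vit <- hmmViterbi(mod, y)
        cvit <- compressedViterbi(mod, blocks)
        expect_equal(cvit$logBest, vit$logBest, tolerance = 1e-9)
        expect_identical(cvit$path, vit$path)
    }
})

test_that("singleton-block posteriors and one EM step equal the uncompressed ones", {
    mod <- randomModel(3, 91)
    set.seed(910)
    y <- sampleSequence(mod, 30, 910)$obs
    blocks <- buildBlocks(y, seq_len(29))

    st <- posteriorStats(mod, y)
    cp <- compressedPosteriors(mod, blocks)
    expect_equal(cp$gamma, st$gamma, tolerance = 1e-9)
    # xi: per-position slices coincide (the (n_w - 1) term vanishes), and
    # the last block's xi is exactly 0
    for (t in 1:29) {
        expect_equal(cp$xi[t, , ], st$xi[t, , ], tolerance = 1e-9)
    }
    expect_equal(cp$xi[30, , ], matrix(0, 3, 3))

    newU <- reestimate(mod, y, st)
    newC <- compressedReestimate(mod, blocks, cp)
    expect_equal(transitionMatrix(newC), transitionMatrix(newU),
        tolerance = 1e-9)
    expect_equal(stateMeans(newC), stateMeans(newU), tolerance = 1e-9)
    expect_equal(stateVariances(newC), stateVariances(newU),
        tolerance = 1e-9)
    expect_equal(initialDistribution(newC), initialDistribution(newU),
        tolerance = 1e-9)

    # iterate-for-iterate identical training trajectories
    bwU <- baumWelch(mod, y, tol = 1e-4, maxIter = 8)
    bwC <- compressedBaumWelch(mod, blocks, tol = 1e-4, maxIter = 8)
    expect_equal(bwC$logLik, bwU$logLik, tolerance = 1e-8)
})

test_that("compressed forward matches constrained-path enumeration", {
    fx <- threeBlockFixture()
    cfwd <- compressedForward(fx$model, fx$blocks)
    expect_equal(
        cfwd$logLikelihood, bfBlockLogLik(fx$model, fx$y, fx$blocks),
        tolerance = 1e-10
    )
    # W = 1: the likelihood is the best single-state mixture
    y1 <- fx$y
    b1 <- buildBlocks(y1)
    E1 <- sapply(1:2, function(j) blockExponent(b1, j, fx$model))
    expect_equal(
        compressedForward(fx$model, b1)$logLikelihood,
        log(sum(exp(log(c(0.5, 0.5)) + E1))),
        tolerance = 1e-10
    )
    # additional seeded instances, N = 3, W up to 5
    for (seed in 1:4) {
        mod <- randomModel(3, seed + 120)
        set.seed(1200 + seed)
        y <- rnorm(11)
        blocks <- buildBlocks(y, c(2, 5, 7, 9))
        expect_equal(
            compressedForward(mod, blocks)$logLikelihood,
            bfBlockLogLik(mod, y, blocks),
            tolerance = 1e-10
        )
    }
})

test_that("compressed backward is consistent with the compressed forward", {
    fx <- threeBlockFixture()
    cfwd <- compressedForward(fx$model, fx$blocks)
    cbwd <- compressedBackward(fx$model, fx$blocks)
    expect_equal(cbwd$logBeta[3, ], c(0, 0))
    comb <- cfwd$logAlpha + cbwd$logBeta
    for (w in 1:3) {
        expect_equal(
            log(sum(exp(comb[w, ]))), cfwd$logLikelihood,
            tolerance = 1e-9
        )
    }
})

test_that("compressed Viterbi matches constrained enumeration and is block-constant", {
    fx <- threeBlockFixture()
    cvit <- compressedViterbi(fx$model, fx$blocks)
    bf <- bfBlockViterbi(fx$model, fx$y, fx$blocks)
    expect_equal(cvit$logBest, bf$logBest, tolerance = 1e-10)
    expect_identical(cvit$path, bf$path)
    expect_equal(length(cvit$path), 8L)
    # constant within blocks
    for (w in seq_len(nBlocks(fx$blocks))) {
        idx <- (blockStarts(fx$blocks)[w] + 1):blockEnds(fx$blocks)[w]
        expect_equal(length(unique(cvit$path[idx])), 1L)
    }

    # W = 1 with overwhelming evidence for state 2
    m <- twoStateModel()
    b <- buildBlocks(rep(3, 6))
    v1 <- compressedViterbi(m, b)
    expect_identical(v1$path, rep(1L, 6))
})

test_that("compressed posteriors match constrained enumeration and sum rules", {
    fx <- threeBlockFixture()
    cp <- compressedPosteriors(fx$model, fx$blocks)
    bf <- bfBlockPosteriors(fx$model, fx$y, fx$blocks)
    expect_equal(cp$gamma, bf$gamma, tolerance = 1e-10)
    expect_equal(cp$xi, bf$xi, tolerance = 1e-10)

    n <- blockLengths(fx$blocks)
    W <- nBlocks(fx$blocks)
    for (w in seq_len(W)) {
        expect_equal(sum(cp$gamma[w, ]), 1, tolerance = 1e-8)
        rs <- rowSums(cp$xi[w, , ])
        if (w < W) {
            expect_equal(rs, n[w] * cp$gamma[w, ], tolerance = 1e-8)
        } else {
            expect_equal(rs, (n[w] - 1) * cp$gamma[w, ], tolerance = 1e-8)
        }
    }
    # cross-state xi at the last block is exactly zero
    offDiag <- cp$xi[W, , ][!diag(2)]
    expect_identical(offDiag, c(0, 0))
})

test_that("compressed reestimation matches the constrained posterior oracle", {
    fx <- threeBlockFixture()
    cp <- compressedPosteriors(fx$model, fx$blocks)
    new <- compressedReestimate(fx$model, fx$blocks, cp)

    bf <- bfBlockPosteriors(fx$model, fx$y, fx$blocks)
    n <- blockLengths(fx$blocks)
    s1 <- blockSums(fx$blocks)
    s2 <- blockSumSquares(fx$blocks)
    denomA <- colSums(n * bf$gamma) - bf$gamma[3, ]
    aBar <- t(sapply(1:2, function(i) {
        colSums(bf$xi[, i, , drop = FALSE][, 1, ]) / denomA[i]
    }))
    muBar <- sapply(1:2, function(j) {
        sum(bf$gamma[, j] * s1) / sum(bf$gamma[, j] * n)
    })
    varBar <- sapply(1:2, function(j) {
        sum(bf$gamma[, j] * (s2 - 2 * muBar[j] * s1 + n * muBar[j]^2)) /
            sum(bf$gamma[, j] * n)
    })
    expect_equal(initialDistribution(new), bf$gamma[1, ], tolerance = 1e-9)
    expect_equal(transitionMatrix(new), aBar, tolerance = 1e-9)
    expect_equal(stateMeans(new), muBar, tolerance = 1e-9)
    expect_equal(stateVariances(new), varBar, tolerance = 1e-9)

    # W = 1, N = 1: biased sample moments of the single block
    m1 <- HMMModel(matrix(1), 0, 1, 1)
    set.seed(31)
    y <- rnorm(20, 2, 1.3)
    b1 <- buildBlocks(y)
    cp1 <- compressedPosteriors(m1, b1)
    new1 <- compressedReestimate(m1, b1, cp1)
    expect_equal(stateMeans(new1), mean(y))
    expect_equal(stateVariances(new1), mean((y - mean(y))^2))
})

test_that("compressed Baum-Welch is monotone and converges fast on W = 1", {
    m <- twoStateModel()
    b1 <- buildBlocks(rnorm(30))
    fit1 <- compressedBaumWelch(m, b1, tol = 1e-3, maxIter = 100)
    expect_lte(fit1$iterations, 3)

    for (seed in 1:6) {
        mod <- randomModel(2 + seed %% 2, seed + 140)
        set.seed(1400 + seed)
        y <- sampleSequence(mod, 200, 1400 + seed)$obs
        blocks <- compressSequence(y, thresholdOverride = 1.5)
        fit <- compressedBaumWelch(mod, blocks, tol = 1e-4, maxIter = 20)
        expect_true(all(diff(fit$logLik) >= -1e-8))
        expect_true(validObject(fit$model))
    }
})
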