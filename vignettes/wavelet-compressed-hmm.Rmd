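---
title: "Wavelet-compressed inference for Gaussian hidden Markov models"
author: "waveHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-compressed inference for Gaussian hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveHMM)
```

## The model and the problem

waveHMM works with hidden Markov models $\lambda = (N, A, \theta, \pi)$
whose $N$ hidden states each emit a univariate Gaussian observation,
$y_t \mid q_t = j \sim N(\mu_j, \sigma_j^2)$, with row-stochastic
transition matrix $A$ and initial distribution $\pi$. The three classical
inference tasks are all $O(N^2 T)$ in the sequence length $T$:

* **evaluation** — the forward recursion for
  $\log p(y \mid \lambda)$;
* **decoding** — the Viterbi recursion for the most likely state path;
* **training** — Baum-Welch (EM), which runs a forward and a backward
  pass per iteration.

For many genome-scale signals — depth of coverage, array intensities and
other inputs to copy-number segmentation — the data are approximately
piecewise constant with homoscedastic Gaussian noise, equivalently
generated by an HMM with dominant self-transitions. Long stretches then
carry essentially no information about *where* switches happen, yet the
classical recursions still visit every observation.

## Compression into blocks of sufficient statistics

The package's core idea is to partition $[0, T)$ once into $W \ll T$
contiguous *blocks* within which the hidden state is assumed constant
(the *weak path assumption*). Because the Gaussian is an exponential
family, each block $w$ is fully summarised by its length $n_w$ and the
sufficient statistics $\Sigma_{1,w} = \sum y_t$ and
$\Sigma_{2,w} = \sum y_t^2$. A whole block contributes, for state $j$,
a single log weight

$$E_w(j) = \frac{2\mu_j\Sigma_{1,w} - \Sigma_{2,w}}{2\sigma_j^2}
  + (n_w - 1)\log A_{jj}
  - n_w\Big(\log\sigma_j + \frac{\mu_j^2}{2\sigma_j^2}
  + \tfrac12\log 2\pi\Big),$$

the product of $n_w$ emission densities and $n_w - 1$ self-transitions.
The forward, backward and Viterbi recursions then run over blocks
($O(N^2 W)$), and Baum-Welch reestimates all parameters from
block-level posteriors $\gamma_w$ and block-summed $\xi_w$. With
singleton blocks ($W = T$) every compressed quantity is algebraically
identical to its exact counterpart — the package's central correctness
test. Restricting paths to be block-constant is an approximation of the
likelihood; its size is quantified below.

## How blocks are found

1. **Haar analysis.** `haarLift()` computes an orthonormal Haar
   decomposition in $O(T)$ with the lifting scheme: equal-support pairs
   $(a, b)$ map to $(a+b)/\sqrt2$ and $(a-b)/\sqrt2$; odd-length levels
   carry their last element up unchanged, so any $T$ is handled without
   padding. When a carried element is finally paired with a smooth of
   larger support, the support-weighted (unbalanced-Haar) form of the
   same rule is used. That keeps the transform orthonormal for every
   $T$: each detail coefficient has variance $\sigma^2$ under i.i.d.
   noise, details ignore constant shifts, and constant inputs have
   all-zero details. (The naive "carry unchanged with the plain pair
   rule" breaks all three at carry levels, which is why the weighted
   form is used.)
2. **Noise estimate.** Away from jumps, finest details are
   $N(0, \sigma^2)$, so
   $\hat\sigma = \mathrm{median}(|d_{\mathrm{finest}}|)/0.6745$
   is jump-robust. A known (or smallest per-state) SD can be supplied
   instead, which is the appropriate choice under heteroscedastic
   emissions at the cost of under-compression in high-variance regions.
3. **Universal threshold.** Coefficients with
   $|d| \le \lambda_u = \sqrt{2\ln T}\,\hat\sigma$ are attributed to
   noise. Under pure noise the expected number of survivors vanishes as
   $T$ grows, so noise alone yields $W \approx 1$.
4. **Boundary candidates and localization.** A retained coefficient
   witnesses a discontinuity of the shrinkage reconstruction
   $\hat f$. $\hat f$ can change value at the coefficient's support
   centre (the sign change) and support edges, so all three positions
   are candidates. Centres only pin a jump to the dyadic grid of the
   detection scale, which is why `localizeBreakpoints()` then re-places
   each centre at the maximum-CUSUM split of the data within that
   coefficient's own support (the ML changepoint under Gaussian noise),
   clipped to the gap between neighbouring candidates. The search
   window is the detection scale itself — there is no tuning knob.
   Designs we evaluated and rejected: centres alone (dyadic placement
   costs roughly $(\Delta\mu)^2/2$ per misassigned observation, which
   dominated the likelihood error); snapping within unbounded
   neighbour gaps (two nearby true switches can collapse onto the
   stronger one); replacing candidates by one ML split per coefficient
   (a coarse coefficient spanning several switches keeps only one);
   fixed-size snap windows (an arbitrary dial).
5. **Blocks.** `buildBlocks()` cuts $[0, T)$ at the boundaries and
   accumulates $n_w, \Sigma_{1,w}, \Sigma_{2,w}$ in one pass.

Compression happens once per sequence; the blocks stay fixed across all
Baum-Welch iterations (the homoscedastic, static-threshold setting).
The block exponents $E_w(j)$ *are* recomputed every iteration, because
they contain the current $\log A_{jj}$.

## Numerical choices

* All probabilities live in log space; sums use log-sum-exp. The
  per-observation recursions are in C++ (Rcpp) because they are the
  $O(N^2 T)$ inner loop; the per-block recursions stay in R.
* Viterbi ties break toward the smallest state index, so decoded paths
  are reproducible; paths and positions are 0-based, blocks half-open
  `[start, end)`.
* Reestimated variances are floored at `1e-8` to prevent collapse on
  degenerate clusters; a state with zero posterior mass keeps its
  previous parameters and warns (a generalized-EM step, so likelihood
  monotonicity is preserved).
* Transitions that are exactly zero (topology constraints) stay exactly
  zero through reestimation; $A_{jj} = 0$ makes blocks with $n_w > 1$
  unreachable for state $j$ via a $-\infty$ exponent rather than an
  error. The variance parameter is per-state throughout, consistent
  with the per-state reestimation formulas.
* $\gamma$ at the final position (which pairwise posteriors do not
  cover) is $\alpha_T \beta_T / p(y \mid \lambda)$; the compressed
  $\bar\pi_i = \gamma_1(i)$ uses block 1's representative value, an
  approximation when $n_1 > 1$.
* Baum-Welch stops when the log-likelihood improves by less than `tol`
  (default `1e-3`) or after `maxIter` (default 100) iterations; the
  reported iteration count includes the final evaluating iteration.

## The synthetic-data generator

`buildModel()` reproduces the benchmark design used throughout the
package's tests: self-transition probability $1 - 10N/T$, so a
length-$T$ sequence sees on average $10N$ switches regardless of $T$;
the remaining mass split uniformly over the out-neighbours allowed by
the topology (fully connected, left-to-right with an absorbing final
state, or circular); unit variances; means spaced $6\eta$ apart so that
the state separation
$\eta = |\mu_a - \mu_b| / (3(\sigma_a + \sigma_b))$ takes the requested
value, from 0.1 (hard) to 1.0 (easy); uniform $\pi$. `sampleSequence()`
is deterministic given a seed, and `runExperiment()` derives replicate
seeds as `seed + replicate - 1` so any replicate can be rerun alone.

The generator emulates exactly the regime the method targets:
piecewise-constant-plus-Gaussian data from dominant self-transition
HMMs. Real segmentation signals additionally show heteroscedastic and
heavy-tailed noise, position-dependent bias (GC content, mappability)
and autocorrelated noise; none of these are emulated, so green tests
here demonstrate correctness of the algorithms and calibration under
the stated model, not robustness to those artefacts.

## What the benchmarks measure, and at what sizes

The test suite and `scripts/acceptance.R` run a scaled-down version of
the full study: $T = 20000$ with 3 seeds per grid cell
($N \in \{2,3,5,10\}$, $\eta \in \{0.1, \dots, 1.0\}$) for the
evaluation-accuracy grid, and 5 seeds at $N = 10$, $\eta = 0.1$ for the
convergence comparison; the full-scale profile ($T = 10^5$, 100 tests
per model, $N$ up to 20) is reachable through the same functions but is
not a sensible default for routine runs. Two cautions when comparing
with full-scale figures: the expected switch count is $10N$ by
construction, independent of $T$, so any per-switch approximation cost
is about five times larger *relative to* $|\log p|$ at $T = 20000$ than
at $T = 10^5$; and a maximum over seeds is a harsher summary than a
mean over 100 tests. The boundary-localization step exists because the
dyadic-only placement failed exactly this scaled-down bar.

Wall-clock speedups are hardware-dependent and are reported by
`runExperiment()` for information only; no test asserts them.

## Limitations

* Single univariate Gaussian emissions; no mixtures, no multivariate or
  discrete emissions, single training sequence.
* One static threshold per sequence (homoscedastic case); no
  re-thresholding during training and no dynamic breakpoint structure
  queried at arbitrary thresholds.
* The compressed likelihood is an approximation with no one-sided
  guarantee; it is accurate when the data are compressible and the
  universal threshold can see the jumps, and degrades gracefully (more
  blocks, less speedup) when they are not.

## A minimal session

```{r example}
model <- buildModel("fully_connected", N = 2, T = 20000, eta = 1.0)
sim <- sampleSequence(model, T = 20000, seed = 1)
blocks <- compressSequence(sim$obs)
blocks

exact <- hmmForward(model, sim$obs)$logLikelihood
fast <- compressedForward(model, blocks)$logLikelihood
c(exact = exact, compressed = fast,
  relative = abs(fast - exact) / abs(exact))

path <- compressedViterbi(model, blocks)$path
mean(path == sim$states)
```
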