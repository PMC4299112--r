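---
title: "Analog compressed sensing for surface EMG: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog compressed sensing for surface EMG: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgcs)
```

## The measurement model

Surface EMG telemetry spends most of its power budget on sampling and
transmission. Compressed sensing moves the compression in front of the
analog-to-digital converter: instead of acquiring all $N$ Nyquist-rate
samples of a window $D \in \mathbb{R}^N$, the front end takes $M \ll N$
random linear measurements

$$ C = \Phi D, \qquad \Phi \in \mathbb{R}^{M \times N}, $$

and the receiver recovers $D$ by exploiting sparsity. In hardware the
product $\Phi D$ is realised by a chipping multiplier (a $\pm 1$
pseudo-random sequence at the input rate) followed by an
integrate-and-dump stage; `simulate_random_demodulator()` reproduces this
stream processing exactly and also returns the equivalent structured matrix,
so the streaming and algebraic views can be cross-checked to machine
precision.

Three matrix families are provided by `make_matrix()`. Bernoulli
($\pm 1/\sqrt{M}$, exactly unit columns) and Gaussian
($\mathcal{N}(0, 1/M)$) are the standard unstructured choices. The binary
Toeplitz family draws a $\pm 1$ first row and column, completes the
$N \times N$ matrix along its diagonals, and keeps $M$ randomly selected
rows scaled by $1/\sqrt{M}$; its $\pm 1$ alphabet matches what a chipping
front end can implement, which is why it is the reference operator
throughout the package.

Suitability of a draw is judged two ways. The *mutual coherence*
$\mu(\Phi, \Psi) = \sqrt{N}\max_{i,j} |\langle \phi_i, \psi_j \rangle|$
(rows and columns unit-normalised) must sit near its lower bound 1 for a
well-matched pair. The restricted isometry constant is NP-hard to compute,
so `rip_surrogate()` probes it: it samples random $K$-column submatrices of
the column-normalised operator and records the worst deviation of the
squared extreme singular values from 1. A draw passes at
$\hat\delta < 0.5$. The probe is deliberately conservative: at the
package's main operating point ($M = 250$, $N = 1024$, $K = 11$) it
reports $\hat\delta \approx 0.53$ while $\ell_1$ recovery is in fact exact
in essentially every trial — a reminder that worst-case submatrix
statistics and average-case recovery are different questions.
`make_verified_matrix()` redraws a failing matrix up to five times with
derived seeds before giving up.

The classical sufficient-measurement rule is also checked:
$M \ge \beta K \log(N/M)$ with natural logarithm and $\beta = 2$ by
default. At the main operating point the bound is
$2 \cdot 11 \cdot \log(1024/250) \approx 31$, comfortably below $M = 250$.

## Sparsity control: dynamic thresholding

Raw sEMG is only approximately sparse. `dynamic_threshold()` enforces a
target sparsity in two steps:

1. the slowly varying DC level is estimated by a centered sliding average
   over `window_w` samples (default 8, sensible range 5–10; edges are
   truncated) and subtracted;
2. entries of the DC-removed signal with magnitude below
   `threshold_fraction` (default 0.10) times its peak-to-peak amplitude are
   set exactly to zero.

The sparsity level is reported as $SP = (N - K)/N$ where $K$ counts the
survivors; $K = 11$ of $N = 1024$ gives the headline operating point
$SP = 98.9\%$. Raising the fraction can only zero more entries, so $SP$ is
monotone in it — the transmitter flow `compress()` exploits this, raising
the fraction in steps of 0.01 (up to a cap of 0.40) until $SP$ reaches its
target of 0.98, and failing loudly with the achieved $SP$ if the cap is
hit first. Both the 10% default and the more aggressive 30% setting seen
in practice are plain configuration values. For inputs that are already
exactly sparse (the synthetic test vectors), `compress(..., config = NULL)`
skips thresholding entirely; thresholding an exactly sparse vector would
re-distribute energy through the DC estimate and destroy exact sparsity.

## The synthetic data

`generate_semg()` builds motor-unit action-potential (MUAP) trains: each
motor unit convolves a biphasic template (first derivative of a Gaussian)
with a renewal firing train (gamma inter-spike intervals, CV 0.2), units
are summed, Gaussian noise is added at 5% of signal RMS, and the window is
normalised to unit peak. The class parameters are package constants chosen
once on clinical grounds: neuropathic muscle recruits *fewer, larger,
longer* units firing slowly (5 units, 15 ms, 8 Hz), myopathic muscle
*many, smaller, shorter* units firing densely (30 units, 4 ms, 22 Hz),
with healthy in between (18 units, 8 ms, 14 Hz). Each segment carries its
onset log so firing density is auditable. This generator emulates
class-separable morphology and spectra — enough for the routing and
classification checks — but not electrode placement, skin impedance,
motion artifacts, amplifier nonlinearity or inter-subject variability, so
green tests here say nothing about those effects on real recordings.

`generate_ksparse()` produces the exactly sparse unit-norm test vectors
used by the recovery benchmarks: exactly $K$ nonzeros in the time domain,
in an orthonormal real Fourier basis, or confined to
$\lceil K/h \rceil$ blocks of a non-overlapping partition. Magnitudes are
drawn in $[0.3, 1]$ before normalisation so no coefficient is vanishingly
small relative to the rest. `generate_block_ar()` adds intra-block AR(1)
correlation for the Bayesian recovery experiments.

## Reconstruction

### The convex routes

Time-sparse segments are recovered by basis pursuit,
$\min \lVert D\rVert_1$ s.t. $\lVert C - \Phi D\rVert_2 \le \varepsilon$,
and frequency-sparse segments by the combined program
$\min \lVert D\rVert_1 + \lambda \lVert F D\rVert_1$ under the same
constraint, where $F$ is the orthonormal real Fourier transform
(`fourier_basis()`; using the real cosine/sine embedding keeps all solver
arithmetic real). Additional $(\Psi_i, \lambda_i)$ penalties turn the same
machinery into the general multi-transform program.

No convex-programming library is used: the programs are solved by an ADMM
operator-splitting scheme written for this package. Splitting variables
attach to the identity block, each orthonormal transform block and the
measurement operator; the $x$-update is one ridge-type solve handled via
the Woodbury identity with a single cached $M \times M$ Cholesky factor,
so an iteration costs a few matrix–vector products. The measurement block
is the Euclidean projection onto the $\varepsilon$-ball, which covers both
the noiseless ($\varepsilon = 0$) and denoising cases uniformly.
Numerical choices, all visible in `solver_config()`:

* the problem is solved on the unit scale $\lVert C\rVert_2 = 1$ (the
  $\ell_1$ minimiser scales linearly), with $\varepsilon$ defaulting to
  $10^{-6}\lVert C\rVert_2$;
* penalty parameter $\rho$ starts at 1 and is adapted by residual
  balancing (factor 2 when primal and dual residuals diverge by 10×);
* iteration stops when scaled primal and dual residuals fall below
  `tol` (default $10^{-8}$) or at `max_iter` (default 5000);
* for the pure $\ell_1$ objective a dual certificate is evaluated every 25
  iterations over a small ladder of support thresholds: if the
  support-restricted least-squares solution is feasible and admits a dual
  vector $y$ with $\Phi_S^\top y = \mathrm{sign}(x_S)$ and
  $|\phi_j^\top y| \le 1$ off support, it is optimal and iteration stops.
  In the exact-recovery regime this fires within the first few dozen
  iterations and returns the solution to machine precision;
* otherwise a safeguarded least-squares polish runs at the end, kept only
  when it is feasible and does not increase the objective — the standard
  debiasing step, made safe against failed recovery;
* zero measurements short-circuit to the zero solution, which is the
  unique minimiser;
* tie-breaking everywhere (OMP atom choice, row selection, k-NN votes)
  goes to the lowest index/label, so all paths are deterministic.

$\lambda$ defaults to 1 and is genuinely open: it trades time-domain
against frequency-domain sparsity and the right value depends on which
domain carries the signal. The frequency-penalty benchmark in the test
suite uses $\lambda = 10$ to make the contrast sharp.

### Block sparse Bayesian learning

Segments that are sparse in neither point domain but concentrate in a few
*blocks* are recovered by an EM implementation of block sparse Bayesian
learning. The signal is partitioned into $g = N/h$ non-overlapping blocks
(default $h = 16$); block $i$ has prior
$\mathcal{N}(0, \gamma_i B(r))$ with $B(r)$ the Toeplitz AR(1) correlation
matrix $r^{|i-j|}$ *shared across blocks* — one correlation hyperparameter
instead of $g$ of them, which is better conditioned at small $M$ and is
the package's deliberate choice. The E-step computes the Gaussian
posterior mean and block covariances through one $M \times M$ factorisation
per iteration; the M-step updates
$\gamma_i = \mathrm{tr}(B^{-1}\langle d_i d_i^\top\rangle)/h$, re-estimates
$r$ from the lag-1/lag-0 ratio of the $\gamma$-weighted average block
moment (clipped to $|r| \le 0.99$), and updates the noise variance by the
usual EM residual rule (floored at $10^{-12}$).

Three numerical details matter in practice. Convergence is declared when
the largest *per-block* relative change of $\gamma$ falls below `tol`
($10^{-5}$): a max-normalised criterion stops while empty blocks are still
decaying geometrically and leaves them unpruned. Blocks with
$\gamma_i < 10^{-8} \max_j \gamma_j$ are pruned exactly to zero, which is
what makes "support identification" a crisp statement. And $r$ is
estimated only from blocks carrying at least 1% of the maximum
$\gamma$ — near-pruned blocks contribute pure noise to the lag statistics
and demonstrably bias $r$ toward zero. A Cholesky failure on the
$M \times M$ system adds jitter of $10^{-10}$ times the diagonal scale and
records the fact in the result.

With $h = 1$ the same code is an ordinary sparse Bayesian learner, which
the tests use as a consistency check against $\ell_1$ recovery.

### Routing

`reconstruct()` routes by signal class: healthy and myopathy segments are
sparse in the time domain after thresholding and go to $\ell_1$;
neuropathy segments — dominated by a few large, long, slowly repeating
MUAPs — are better summarised by a few frequency components and go to the
combined $\ell_1$-$\ell_1$ program; block-sparse hints go to BSBL. An
explicit route always overrides the rule, and a segment with neither hint
nor label is an error rather than a guess.

## Sensing-dictionary selection

`select_sensing_dictionary()` asks whether a dictionary *learned from
training data* beats the structured reference as a sensing operator. The
training signals are thresholded, a square dictionary is initialised (from
the training columns when at least $N$ signals are available, otherwise
from a seeded noisy DCT basis), and OMP sparse coding alternates with
K-SVD rank-1 atom updates for `sweeps` iterations (default 10, OMP cap
$\lceil 0.05N \rceil$ atoms, tolerance $10^{-6}$). One safeguard departs
from textbook K-SVD: a signal's previous code is kept whenever greedy
re-coding would *increase* its residual, which makes the recorded error
history provably non-increasing rather than just empirically so. $M$ rows
are then selected (uniform at random, or by leverage scores), and the
candidate's coherence against the sparsity basis is compared with a fresh
binary Toeplitz draw of the same size; the lower-coherence candidate is
nominated, with ties — and degenerate candidates containing a zero
measurement row — going to the Toeplitz reference as the simpler operator.
In the experiments here the learned candidate rarely wins: a dictionary
fitted to sparse training signals concentrates energy and makes a poor
*incoherent* sampler, which is itself a useful negative result.

## Metrics and the Monte-Carlo harness

For an original $D$ and reconstruction $\hat D$:

* $\mathrm{PRD} = 100\sqrt{\sum (D - \hat D)^2 / \sum D^2}$;
* $\mathrm{SNR} = 20\log_{10}(\lVert D\rVert / \lVert D - \hat D\rVert)$,
  capped at 300 dB for exact reconstructions, and tied to PRD by
  $\mathrm{SNR} = -20\log_{10}(\mathrm{PRD}/100)$;
* accuracy $= \max(0, 100(1 - \lVert D - \hat D\rVert/\lVert D\rVert))$;
* Monte-Carlo RMSE $= \frac{1}{L}\sum_l \lVert D_l - \hat D_l\rVert /
  \lVert \hat D_l\rVert$ over $L$ repetitions (default 50), the
  denominator being the norm of the estimate;
* $\mathrm{CF} = (D_b - C_b)/D_b \times 100$ on bit budgets, and
  sensitivity/specificity with the standard denominators
  ($\mathrm{SEN} = TP/(TP+FN)$). PRD and SEN also expose a
  `paper_literal` flag computing the bare squared-error ratio and the
  $TP/(TP+TN)$ reading respectively, for comparison against sources that
  print those forms.

`run_sweep()` drives generate → compress → reconstruct → score over a grid
of $(M, K)$ cells, $L$ repetitions each, with all seeds derived from one
base seed; identical specifications reproduce the table byte for byte. It
reports both the sub-sampling ratio $\mathrm{SSR} = M/N$ and the
sampling-rate reduction $\mathrm{SRD} = 1 - M/N$ (the fraction of
Nyquist-rate samples *removed*), never a bare "CR", because compression
nomenclature is ambiguous between the two reciprocals. Mechanically, error
falls as SSR grows and accuracy falls as SRD grows; the directional tests
assert exactly those two monotonicities. Power consumption and wall-clock
timing are explicitly out of scope — the measurement-count ratio is the
only power proxy reported.

k-NN classification (`knn_classify()`) is a light check that compression
artifacts do not destroy class structure: four standard features per
segment (RMS, mean absolute value, zero crossings, spectral-centroid mean
frequency), standardised by the training statistics, Euclidean metric,
$k = 5$, deterministic lowest-label tie-break.

## Problem sizes used by the checks

The package's own acceptance checks run at the full operating point
$N = 1024$, $K = 11$, $M \in \{102, 250, 256\}$ with 20–50 Monte-Carlo
trials per figure — small enough to run comfortably on one CPU because the
dual certificate terminates the exact-recovery solves within a few dozen
iterations. Component benchmarks (BSBL, the frequency-penalty contrast,
the directional sweeps) use $N$ of 64–256, sizes at which brute-force
oracles (exhaustive support search, restricted least squares) are exact
and cheap. Each figure states its own $L$; none is averaged over fewer
than 10 trials.

## Known limitations

* The generator's realism stops at class-separable morphology; no claim is
  made about electrode, skin or hardware effects (the analog chain is
  simulated only as ideal chipping + integration, with no quantizer in the
  default path).
* ADMM tail convergence without the certificate is slow, as first-order
  splitting methods are; non-certified solves report `converged` against a
  $10^{-8}$ scaled-residual criterion, not machine precision. The
  certificate only applies to the pure $\ell_1$ objective.
* The BSBL block grid is fixed and must divide $N$; misaligned block
  boundaries degrade gracefully but are not re-estimated.
* A single $r$ is shared across blocks by design; signals whose blocks
  have genuinely different internal correlation are summarised, not
  modelled.
* WFDB support covers the common single- and multi-channel format-16
  records only, enough to ingest public sEMG recordings, not the full
  format zoo.
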