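---
title: "Compressed-sensing reconstruction of non-uniformly sampled NMR signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-sensing reconstruction of non-uniformly sampled NMR signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuscs)
```

## The problem

Multidimensional NMR experiments sample the indirect time dimension on a
Nyquist grid of $n$ points. Non-uniform sampling (NUS) acquires only
$m < n$ of them, shortening the measurement, and leaves an underdetermined
linear system: with $\boldsymbol F$ an inverse Fourier matrix,
$\tilde{\boldsymbol F}\boldsymbol x = \tilde{\boldsymbol y}$ has more
spectral unknowns than measured points. Compressed sensing closes the gap
with a sparsity assumption, solving

$$\arg\min_{\boldsymbol x \in \mathbb C^n}
  \|\tilde{\boldsymbol F}\boldsymbol x - \tilde{\boldsymbol y}\|_{\ell_2}
  + \lambda \|\boldsymbol x\|_{\ell_p}, \qquad 0 < p \le 1,$$

or the equivalent constrained form with a residual bound $\epsilon$. This
package implements the classic algorithm family used for this problem in
biomolecular NMR — CLEAN (matching pursuit), orthogonal matching pursuit
(OMP), iterative soft thresholding (IST-D and IST-S), iteratively
reweighted least squares (IRLS), and low-rank Hankel reconstruction —
together with the sampling diagnostics that predict when they succeed, and
scripted "pitfall" experiments that show how each fails when its control
parameter is misset. Everything runs on synthetic Lorentzian signals
produced by the package's own generator, so every statement here is
reproducible from code.

## Signal model and conventions

`synth_fid()` builds the standard model: a sum of decaying complex
exponentials plus circular complex Gaussian noise,
$y_t = \sum_k a_k e^{i\phi_k} e^{2\pi i f_k t/n} e^{-R_k t} + \eta_t$.
Frequencies are in cycles per full grid (bin units) and may be off-grid —
the realistic case, since a Lorentzian line is only approximately sparse.
On-grid frequencies give strictly sparse spectra and are used where a test
needs exact support recovery.

The DFT convention is fixed package-wide and unitary: both directions carry
$1/\sqrt n$, and spectrum bin $k$ pairs with $e^{+2\pi i k t/n}$. Unitarity
makes residual norms directly comparable between time and frequency domain
and puts coherence values on the dimensionless $[0,1]$ scale. All indices
are zero-based and half-open, including schedule files.

`virtual_echo()` symmetrizes the zero-filled signal with its conjugated
time reversal so the spectrum becomes purely real, which sharpens the
sparsity assumption (the dispersive imaginary part has long tails). The
discrete construction needs one choice the continuous picture does not fix:
the $t=0$ sample would be counted by both the signal and its mirror, so it
is halved before mirroring. This keeps the spectrum real to machine
precision and the integral unchanged.

```{r virtual-echo}
y <- synth_fid(peak_list(frequency = 7.3, amplitude = 1, decay = 0.1), 32)
sv <- fft_spectrum(virtual_echo(y))$values
max(abs(Im(sv))) / max(abs(Re(sv)))
```

## Sampling diagnostics

The Fourier transform of the schedule's indicator — the point spread
function, `psf()` — describes the artifacts that undersampling convolves
into the spectrum. Its largest off-center magnitude equals the coherence
$\mu$ of the restricted Fourier matrix (columns normalized to unit
$\ell_2$ norm; the normalization is implied rather than stated in most
presentations, but without it full sampling would not have $\mu = 0$).
The $s$-column coherence $\mu_s$ bounds the worst overlap of $s$ artifact
patterns, and

$$\mu_s + \mu_{s-1} < 1$$

guarantees that OMP recovers every $s$-sparse spectrum exactly in at most
$s$ iterations. For a uniform-grid schedule the column inner products
depend only on the index difference mod $n$, so $\mu_s$ is simply the sum
of the $s$ largest off-zero PSF magnitudes; the test suite checks this
against both the explicit-matrix evaluation and exhaustive subset
enumeration.

```{r diagnostics}
sched <- uniform_schedule(n = 64, m = 32, seed = 1)
coherence_report(sched, s_max = 4)
```

## The solvers and their tunable parameters

All solvers start from the zero-filled data $\tilde{\boldsymbol y}_0$ and
return a `nus_recon` holding the spectrum, the FID, the support, and a
residual trace.

**CLEAN / OMP** (`clean()`, `omp()`). Greedy: find the largest bin of the
artifact spectrum, add it to the solution, subtract its artifact pattern
from the residual. OMP refits all found bins by least squares each
iteration; CLEAN never revisits a height. Parameters: the residual stopping
norm `epsilon` (ideally the $\ell_2$ norm of the noise,
$\sigma\sqrt{2m}$ for per-component noise sd $\sigma$ — the CLI exposes
this heuristic as `--noise-sigma`) and the iteration cap, which for OMP is
also the maximal support size. Ties in the maximum search go to the lowest
bin index, and the CLEAN gain defaults to 1 (the textbook step); fractional
gains give the classic cautious variant. Greedy point-wise reconstructions
split Lorentzians into neighboring sticks; `apodize_output()` damps this by
exponential weighting.

**IST-D / IST-S** (`ist_d()`, `ist_s()`). Soft thresholding of whole
spectra instead of single bins; the complex soft-threshold operator
shrinks magnitudes and keeps phases (the proximal operator of the
$\ell_1$ norm, which is what ties IST to the $p=1$ problem). The
`threshold` is *relative to the current iteration's maximum magnitude* —
the dimensionless $0\text{–}1$ values practitioners quote; whether such
thresholds should instead be relative to the initial global maximum is a
genuine ambiguity, and the per-iteration reading was chosen and is used
consistently. IST-D accumulates thresholded artifact spectra and balances
sparsity against data agreement through `epsilon`; IST-S restores the
measured time-domain points after every iteration and reconstructs only
the omitted ones, so its threshold must fall between iterations (geometric
factor, default 0.98 — a simplified decreasing-$\lambda$ schedule in the
Bregman spirit). With `final_replacement` the IST-S output matches the
measured points to machine precision; without it the post-threshold
spectrum converges to the same limit as IST-D, which the acceptance
checks verify numerically at $10^{-3}$ relative.

**IRLS** (`irls()`, `tikhonov()`, `reweighted_solve()`). The $\ell_p$
problem is approximated by weighted $\ell_2$ solves with weights
$d_i = \max(|x_i|, \varepsilon)^{p-2}$; the floor $\varepsilon$ is clamped
inside the power, which is exactly where the weights would otherwise blow
up at zero coordinates. The first solve uses unit weights — it *is* the
Tikhonov solution — and subsequent weights come from the previous iterate;
this convention both matches standard IRLS practice and makes the
one-iteration reduction to `tikhonov()` exact. The adaptive
`eps_rule = "k"` option ties $\varepsilon$ to the $i_0$-th largest
spectral magnitude with $i_0 = \mathrm{round}(m / (4\log(n/m)))$ (natural
logarithm; the base is not fixed by the formula's usual statement, and the
natural log is documented here as the package's reading). With
$\delta > 0$ the exponent $p$ anneals downward each iteration (floored at
0.05 for numerical stability of the power), steering toward the $\ell_0$
problem after about $1/\delta$ iterations. The $m \times m$ system
$\tilde{\boldsymbol F} W^{-2} \tilde{\boldsymbol F}^H + \lambda I$ is the
restriction of a circulant matrix, so it is assembled from one inverse FFT
of $w^{-2}$ rather than from an explicit matrix; cost grows as $m^2$ to
$m^3$, which is why IRLS suits small grids best. A divergence guard stops
the run (flagged non-converged) when the residual rises five consecutive
iterations *and* exceeds 10% of the data norm — the residual drifts up
slightly during reweighting and annealing by design, so a bare
rising-residual rule would abort healthy runs.

**Low-rank Hankel** (`lowrank_reconstruct()`, `svt()`). Sparsity counted
as the number of exponential components: the Hankel lift of a noiseless
$K$-component FID has rank exactly $K$, so the reconstruction minimizes
$\|\boldsymbol R\boldsymbol x\|_* + \alpha\|\tilde{\boldsymbol y} -
\boldsymbol U\boldsymbol x\|_2^2$ over the time-domain signal — the output
is a completed FID, and a single broad fast-decaying line (many nonzero
bins) is still "sparse" here. The augmented-Lagrangian solver alternates
a singular-value soft-thresholding step
$Z \leftarrow \mathrm{svt}(R x + D/2\beta,\ 1/2\beta)$, an entrywise exact
$x$-solve (both $U^\top U$ and the anti-diagonal multiplicities
$\mathrm{diag}(R^\top R)$ are diagonal), and dual ascent
$D \leftarrow D + \tau(Rx - Z)$ with $\tau = \beta$ by default. The update
constants follow the standard scaled form of the augmented Lagrangian;
since presentations of this scheme differ in where the $2\beta$ factors
sit, correctness is anchored not to those constants but to a proximal
oracle test: `svt()` is verified against brute-force minimization of
$\tau\|Z\|_* + \tfrac12\|Z - M\|_F^2$. Defaults: near-square lift
$Q = \lfloor n/2\rfloor + 1$ (best-conditioned; $Q$ must exceed the
expected peak count), $\alpha = 1000$, $\beta = 1$, 500 iterations,
relative-change tolerance $10^{-8}$ — calibrated once so that noiseless
2-exponential signals at 50% sampling are completed to about $10^{-3}$
relative error at the missing points. The SVD sign convention (largest
entry of each left singular vector made real-positive) makes traces
reproducible.

## What the experiments show

`residual_curve()` draws seeded uniform schedules per sampling level,
reconstructs, and records the residue — defined here, since the quantity
is conventionally plotted without units, as the $\ell_2$ distance between
the reconstruction and the full-data reference spectrum (the data-domain
residual is recorded alongside). On strictly sparse fixtures the curve
falls monotonically and the level at which it collapses tracks
$K\log(n/K)$ (`required_m()`): more peaks shift it right, doubling the
grid at fixed $K$ barely moves it. That contrast is the practical point —
quoting sampling as a *percentage* of $n$ has no basis in the theory and
becomes misleading for large grids. The acceptance checks run this
protocol at $n = 512$ and $1024$ with 20 schedules per level and 16 levels
(sizes chosen so the whole study stays desk-scale), requiring a Spearman
correlation $\le -0.9$ and a less-than-50% growth of the required $m$ when
$n$ doubles.

The scripted pitfalls mirror the missetting behaviors, each as a seeded
scenario with frozen parameters:

* **IST threshold triptych** (two peaks 10:1, $n=256$, $m=64$, noise sd
  0.002 of the large amplitude, $\epsilon$ set to the noise norm): at
  threshold 0.25 the accumulated spectrum keeps sampling artifacts — its
  off-peak floor is $\ge 5\times$ the floor at the optimal 0.9 — while at
  0.998 the iteration budget is spent re-finding the dominant peak and the
  small peak reaches $\le 50\%$ of its optimal-threshold height. The noise
  is deliberately small so the optimal-threshold floor reflects residual
  artifacts rather than the noise itself.
* **IRLS with $\lambda$ too high** shrinks everything toward zero; the
  small peak drops below 10% of truth.
* **Low-rank with $\alpha$ too low** (0.7 on a unit-amplitude problem)
  converges to a rank-1 lift: two peaks 4 bins apart merge into one broad
  line with a single local maximum.
* **Extrapolation**: completing the second half of a truncated FID
  (IST-D, threshold 0.95, on a $2\times$ zero-filled grid so the
  mirror-image echo has somewhere to go) keeps a 5:1 small peak within
  20%; truncating to $n/32$ with an over-sparse threshold 0.999 yields an
  essentially undamped tail — the decay-rate fit of the extrapolated part
  is below 20% of truth, the time-domain signature of an artificially
  narrowed peak. Without the zero-filled grid the echo grows into the
  reconstruction window, which is shown by the same function with
  `zf_factor = 1`.

`l_curve()` automates the $\lambda$ choice from the misfit-vs-penalty
curve in log–log coordinates using three-point finite-difference
curvature. One refinement proved necessary: the global curvature maximum
sits on the late "cliff" where peaks collapse, past the corner, so the
selector takes the *first* local extremum of negative curvature scanning
$\lambda$ upward — the bend adjacent to the data-agreement branch — and
falls back to the global maximum (tie-break to larger $\lambda$) when no
local extremum exists. A flat curve returns the grid midpoint with a
`degenerate` flag. `cross_validate()` holds out a seeded fraction
(customarily 25%) of the *scheduled* points and scores candidate
configurations by their misfit on the held-out measurements; the held-out
data are spent on validation, which is the method's price.
`readd_residual()` adds the transform of the final zero-filled residual
back to the spectrum, restoring exact data agreement and revealing peaks a
stopped solver missed.

## What the generator does and does not emulate

The synthetic generator covers the features these algorithms are sensitive
to: multiple Lorentzian components with arbitrary amplitude ratios, phases
and decay rates, off-grid frequencies (approximate sparsity), thermal
noise, and uniform-density NUS. It does not emulate spectrometer
artifacts (baseline distortions, phase errors, $t_1$ noise), hypercomplex
multidimensional acquisition, solvent signals, or non-uniform sampling
densities (weighted and decaying-density schedules are deliberately out of
scope). Passing tests therefore demonstrate algorithmic correctness and
the qualitative parameter behaviors on clean model signals — not
performance claims on any particular experimental spectrum.

## Numerical choices and limitations

* Degenerate inputs: empty schedules are rejected; a zero measurement
  vector returns a zero reconstruction with `converged = TRUE` and zero
  iterations (greedy) or the zero FID (low-rank).
* OMP solves its support system by normal equations; a numerically
  singular Gram matrix gets a $10^{-12}$ ridge and the result is flagged
  `degenerate_support`.
* Soft thresholding at a bin of exactly zero magnitude returns zero (the
  phase is undefined there and irrelevant).
* Residual traces use the $\ell_2$ norm throughout; IST-S reports the
  spectral change per iteration instead, since its measured-point residual
  is identically zero by construction.
* Problem sizes in tests and the acceptance study ($n \le 1024$, 20
  schedules per level, 20-seed recovery studies) were chosen as the
  smallest sizes at which the asymptotic statements are cleanly visible.
* The coherence guarantee is sufficient, not necessary: OMP often succeeds
  far beyond it, and nothing is claimed for failing schedules.
* IRLS stores an $m\times m$ dense system; very large $m$ calls for an
  iterative solver, which is out of scope here, as are multidimensional
  (block-Hankel) lifts and FISTA-style acceleration of IST.
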