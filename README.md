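# nuscs — compressed-sensing reconstruction of non-uniformly sampled NMR signals

Multidimensional NMR spectra take long to acquire because the indirect time
dimension must be sampled on a full Nyquist grid of *n* points. Non-uniform
sampling (NUS) measures only *m* < *n* of them and reconstructs the rest,
which turns spectral analysis into an underdetermined inverse problem: with
**F** an inverse Fourier matrix and the measured vector ỹ,

    F̃ x = ỹ,   |x| = n > m = |ỹ|,

solvable only under a sparsity assumption on the spectrum **x**,

    argmin_x ‖F̃x − ỹ‖₂ + λ‖x‖_p,   0 < p ≤ 1.

`nuscs` implements the standard compressed-sensing algorithm family used in
biomolecular NMR for this problem, for spectroscopists and methods
developers who want transparent, testable reference implementations rather
than black boxes:

* **Greedy:** CLEAN (matching pursuit) and orthogonal matching pursuit
  (`clean()`, `omp()`), with the coherence-based exact-recovery guarantee
  μ_s + μ_{s−1} < 1 (`omp_guarantee()`).
* **Thresholding:** iterative soft thresholding in both variants —
  IST-D (sparsity/data balance) and IST-S (measured points kept exact)
  (`ist_d()`, `ist_s()`).
* **Reweighting:** Tikhonov, weighted least squares, and the δ-annealed
  IRLS for ℓp minimization (`tikhonov()`, `reweighted_solve()`, `irls()`).
* **Low-rank:** Hankel-lift nuclear-norm reconstruction by an
  augmented-Lagrangian scheme with singular value thresholding
  (`lowrank_reconstruct()`, `svt()`), whose output is a completed FID.
* **Diagnostics:** point spread function, coherence μ and s-column
  coherence μ_s of a sampling schedule (`psf()`, `coherence()`,
  `s_coherence()`, `coherence_report()`).
* **Pitfall experiments:** residual-vs-sampling-level curves, parameter
  missetting scenarios, FID extrapolation, L-curve and cross-validation
  parameter selection, residual re-addition (`residual_curve()`,
  `extrapolate()`, `l_curve()`, `cross_validate()`, `readd_residual()`).

All inputs are synthetic Lorentzian signals from the package's own seeded
generator (`synth_fid()`), or user-supplied complex vectors in a plain
two-column text format plus "nuslist"-style schedule files.

## Worked example

```r
library(nuscs)

# ground truth: three Lorentzians, one deliberately off-grid (97.5)
model <- peak_list(frequency = c(40, 97.5, 180),
                   amplitude  = c(1, 0.6, 0.25),
                   decay      = c(0.01, 0.02, 0.01))
y     <- synth_fid(model, n = 256, noise_sigma = 0.01, seed = 42)

# sample 64 of 256 points uniformly and inspect the schedule first
sched <- uniform_schedule(n = 256, m = 64, seed = 7)
coherence_report(sched, s_max = 3)
#> <coherence_report> mu = 0.2557, OMP guarantee holds up to s = 2

# reconstruct with IST-D, stopping at the noise norm sigma*sqrt(2m)
nus <- restrict_fid(y, sched)
rec <- ist_d(nus, ist_config("D", threshold = 0.9,
                             epsilon = 0.01 * sqrt(2 * 64), n_iter = 2000))
rec
#> <nus_recon> method = ist-d, n = 256, |support| = 140, iters = 202, converged = TRUE
#>   final residual l2 = 1.117e-01
```

The schedule report says the sampling is benign (coherence 0.26; any
2-sparse spectrum would be recovered exactly by OMP). IST-D converges in
202 iterations to the noise floor. Comparing peak heights against the
noiseless full-data spectrum:

```r
truth <- fft_spectrum(synth_fid(model, 256))$values
for (b in c(40, 98, 180))
  cat(sprintf("peak near bin %d: recovered %.2f, truth %.2f\n", b,
      max(Mod(rec$spectrum$values[(b-2):(b+2)+1])),
      max(Mod(truth[(b-2):(b+2)+1]))))
#> peak near bin 40: recovered 5.64, truth 5.82
#> peak near bin 98: recovered 1.13, truth 1.67
#> peak near bin 180: recovered 1.28, truth 1.50
```

The on-grid dominant peak is recovered to 3%. The off-grid peak at 97.5
loses about a third of its height: its energy spreads over neighboring
bins, so it is only approximately sparse — exactly the regime where
threshold missetting starts to bite (see the vignette's pitfall section).

## Command line

A thin `nus-cs` script (installed from `exec/`) drives every module:

```sh
nus-cs simulate --peaks peaks.yaml --n 256 --noise-sigma 0.01 --seed 42 --out fid.txt
nus-cs sample   --n 256 --m 64 --seed 7 --out sched.txt
nus-cs diagnose --schedule sched.txt --n 256 --out report.json
nus-cs restrict --fid fid.txt --schedule sched.txt --out y0.txt
nus-cs reconstruct --fid y0.txt --schedule sched.txt --method ist-d \
       --threshold 0.9 --noise-sigma 0.01 --out rec
```

`reconstruct` writes `rec_spectrum.txt`, `rec_fid.txt` and a JSON run
manifest (config, seeds, input digests, version) sufficient to replay the
run. Exit codes: 0 ok, 2 usage, 3 data error, 4 numerical failure.

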