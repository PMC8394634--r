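# pdemct

Iterative CT reconstruction by minimizing an extended family of
power-divergence measures.

## What this is

Tomographic image reconstruction estimates a nonnegative density image
`x` from measured line integrals (a sinogram) `y ≈ A x`, where `A` is the
sparse projection operator of the acquisition geometry. The workhorse
iterative algorithm, MLEM (maximum-likelihood expectation-maximization),
is the multiplicative scheme that minimizes the generalized
Kullback–Leibler divergence between `y` and `A x`.

`pdemct` implements **PDEM**, a two-parameter generalization. The
objective is the extended power divergence

    Φ_{γ,α}(p, q) = Σ_i ∫_{p_i}^{q_i} (s^γ − p_i^γ) / s^{γα} ds ,   γ > 0, α ≥ 0,

a family that contains the KL divergence (γ, α) = (1, 1), half the squared
L2 distance (1, 0), the reverse KL divergence (1, 2), Neyman's χ² (2, 1)
and the generalized Hellinger distances (γ, 1). Setting
V(x) = Φ_{γ,α}(y, Ax) and writing

    ξ = Aᵀ[y^γ (Ax)^{−γα}],   ζ = Aᵀ[(Ax)^{γ(1−α)}],   f = ξ / ζ  (elementwise),

the continuous-time system dx_j/dt = x_j log f_j(x) has V as a Lyapunov
function (dV/dt = −(ξ−ζ)ᵀ diag(x) (log ξ − log ζ) ≤ 0), and its
multiplicative-Euler discretization with step `h` is the PDEM iteration

    z_j ← z_j · f_j(z)^h .

At (γ, α, h) = (1, 1, 1) this is exactly classical MLEM. Suitable
(γ, α) — small γ, α slightly above 1 — make the reconstruction markedly
more robust to measurement noise than MLEM at late iterations.

The package provides, for users running simulation studies of such
algorithms:

* a deterministic Siddon-style parallel-beam projector (sparse `A`,
  forward/backprojection) with documented conventions;
* the divergence family in closed form plus a quadrature oracle;
* PDEM/MLEM reconstruction with per-iteration metric logging, the
  continuous-time analog (Adams integration in log-space), and an FBP
  baseline (Shepp–Logan filter);
* the modified Shepp–Logan phantom, consistent sinogram simulation, and
  white Gaussian noise at a prescribed SNR (dB, power convention);
* image metrics: unnormalized L2 evaluation `E(z) = ||e − z||₂`, SSIM
  (reference settings), line profiles;
* config-driven experiment and (γ, α)-sweep drivers.

## Worked example

A noisy benchmark study at full scale — 128×128 modified Shepp–Logan
phantom, 180 views × 184 bins, 30 dB SNR, 200 iterations, comparing MLEM
with PDEM at the checkpointed parameter choices:

```r
library(pdemct)
cfg <- ct_experiment_config(seed = 11)   # 128 px, 180x184, 30 dB defaults
res <- run_ct_experiment(cfg)
subset(res$summary, N == 200)
```

```
           label gamma alpha   N        E      SSIM
3           MLEM   1.0   1.0 200 3.320833 0.7824164
6  PDEM(0.8,1.2)   0.8   1.2 200 3.318789 0.7978597
9  PDEM(0.5,1.2)   0.5   1.2 200 3.458428 0.8347225
12 PDEM(0.3,1.2)   0.3   1.2 200 4.197687 0.8609431
```

`E` is the Euclidean distance between reconstruction and ground truth
(lower is better; unnormalized, so its scale is tied to the 16,384-pixel
grid) and `SSIM` the structural similarity against the phantom (higher is
better). At 200 iterations the small-γ PDEM variants trade a slightly
larger pixelwise error for visibly better structural quality
(SSIM 0.861 vs 0.782 for MLEM): the multiplicative update with γ < 1
amplifies the measurement noise far less. On noise-free data every member
decreases `E` monotonically, and `res$traces[[label]]$metrics` holds the
full per-iteration `n, V, E, SSIM` log for each algorithm.

## Command-line use

A thin CLI over the same functions lives at `inst/cli/pdemct.R`
(`simulate`, `reconstruct`, `experiment` subcommands; CSV/YAML/PNG
artifacts). See the header of that file for usage lines.

## Further reading

The methods vignette (`vignettes/pdem-reconstruction.Rmd`) documents the
divergence family and its closed-form branches, the Lyapunov argument, the
projector and noise conventions, numerical guards, and known limitations.
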