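---
title: "Power-divergence minimization for iterative CT reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-divergence minimization for iterative CT reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdemct)
```

## The reconstruction problem

Parallel-beam computed tomography measures line integrals of an unknown
nonnegative density image. Discretized, the measurement model is

$$ y = A x + \delta, $$

where $y \in \mathbb{R}_+^I$ is the sinogram ($I$ rays), $A \in
\mathbb{R}_+^{I \times J}$ is the sparse system matrix whose entry $A_{ij}$
is the intersection length of ray $i$ with pixel $j$, $x \in \mathbb{R}_+^J$
is the image, and $\delta$ is measurement noise. When a nonnegative image
$e$ satisfies $y = Ae$ exactly the system is *consistent*; noise makes it
inconsistent, and iterative reconstruction then amounts to minimizing a
data-fit objective over nonnegative images.

The classical maximum-likelihood expectation-maximization (MLEM) algorithm
minimizes the generalized Kullback–Leibler divergence between $y$ and $Ax$
by a multiplicative update. This package implements a two-parameter
superfamily of that scheme.

## The extended power-divergence family

For nonnegative $p$ and positive $q$, and parameters $\gamma > 0$,
$\alpha \ge 0$,

$$ \Phi_{\gamma,\alpha}(p, q) \;=\; \sum_i \int_{p_i}^{q_i}
   \frac{s^{\gamma} - p_i^{\gamma}}{s^{\gamma\alpha}} \, ds . $$

Each term is nonnegative and vanishes iff $p_i = q_i$, because the
integrand changes sign exactly at $s = p_i$. Members include

* $(\gamma,\alpha) = (1,1)$: generalized KL divergence (the MLEM objective),
* $(1,0)$: half squared $L_2$ distance,
* $(1,2)$: reverse KL divergence,
* $(2,1)$: Neyman $\chi^2$ distance,
* $(\gamma,1)$: the classical one-parameter power-divergence family
  (generalized Hellinger distances).

`epdm_divergence()` evaluates the integral analytically. With
$a = 1 + \gamma(1-\alpha)$ and $b = 1 - \gamma\alpha$ the generic
antiderivative gives per-element terms

$$ \frac{q^{a} - p^{a}}{a} - p^{\gamma}\,\frac{q^{b} - p^{b}}{b}, $$

with logarithmic limits replacing the second factor when $\gamma\alpha = 1$
($b = 0$) and the first when $\gamma\alpha = 1 + \gamma$ ($a = 0$). The
printed closed forms one sometimes sees for the three branches are easy to
typeset incorrectly; this implementation derives all branches directly from
the integral, and `epdm_divergence_quadrature()` (adaptive quadrature of the
raw integrand) is kept in the package purely as an independent oracle — the
test suite checks closed form against quadrature to $10^{-8}$ relative
error across the parameter grid, including the two branch points.

Branch routing uses $|\gamma\alpha - 1| < 10^{-12}$ and
$|\gamma\alpha - (1+\gamma)| < 10^{-12}$: nearer to the poles than that,
the $1/b$ and $1/a$ factors of the generic form lose all precision to
cancellation, while outside it they are accurate; continuity across the
switch is part of the test suite. Terms with $p_i = 0$ are finite iff
$a > 0$ (i.e. $\gamma(1-\alpha) > -1$), in which case they equal $q^a/a$;
otherwise the divergence is reported as `Inf` rather than raising, which is
the mathematically faithful answer.

## The continuous-time system and the PDEM iteration

The tomographic objective is $V(x) = \Phi_{\gamma,\alpha}(y, Ax)$
(`epdm_objective()`). Define

$$ \xi = A^{\top}\!\left[ y^{\gamma} (Ax)^{-\gamma\alpha} \right], \qquad
   \zeta = A^{\top}\!\left[ (Ax)^{\gamma(1-\alpha)} \right], \qquad
   f_j = \xi_j / \zeta_j , $$

(all powers elementwise; `pdem_factors()`). The continuous-time system

$$ \frac{dx_j}{dt} = x_j \log f_j(x) $$

has the consistent solution $e$ as an equilibrium, and $V$ is a Lyapunov
function for it:

$$ \frac{dV}{dt} = -(\xi - \zeta)^{\top} \operatorname{diag}(x)
   (\log \xi - \log \zeta) \;\le\; 0, $$

since each summand pairs a difference with the same-signed difference of
logarithms (`pdem_dV_dt()`). Discretizing the flow with the multiplicative
Euler method and step size $h$ yields the PDEM iteration

$$ z_j^{(n+1)} = z_j^{(n)} \, f_j\!\left(z^{(n)}\right)^{h}, $$

which maps positive images to positive images for every $\gamma > 0$,
$\alpha \ge 0$, $h > 0$. At $(\gamma, \alpha, h) = (1, 1, 1)$ the factor
reduces to $[A^{\top}(y/Az)] / [A^{\top}\mathbf{1}]$ — classical MLEM,
which the tests verify against an independently coded MLEM step to
$10^{-12}$ per iteration. The package enforces $h > 0$ (the Lyapunov
argument concerns the continuous flow; for the discrete map the decrease of
$V$ with $h = 1$ is verified empirically across the parameter grid, and no
convergence claim is made for $h \neq 1$, although the parameter is
exposed).

`integrate_pdem_ode()` integrates the flow with the adaptive-step,
variable-order Adams method (`deSolve::ode(method = "adams")`, relative
tolerance $10^{-6}$, absolute $10^{-9}$). The state is propagated as
$u = \log x$, turning the system into $\dot u_j = \log f_j(e^{u})$; this
preserves positivity exactly, with no step-rejection heuristics, and suits
the non-stiff character of the flow (a stiff-switching solver would attempt
dense Jacobians of dimension $J$).

## Projector conventions

`build_system_matrix()` traces one ray per detector bin through its centre
and stores exact ray/pixel intersection lengths (Siddon-style traversal,
implemented in C++). Conventions, fixed and relied upon throughout:

* the image is an `image_size`² square of unit pixels centred on the
  rotation isocenter; matrix row 1 is the top of the image; pixel vectors
  are column-major;
* view angles are equally spaced on $[0°, 180°)$ (half-open);
* the detector axis at angle $\theta$ is $u = (\cos\theta, \sin\theta)$,
  rays run along $(-\sin\theta, \cos\theta)$; rays are indexed view-major;
* detector bins are centred symmetrically with spacing
  `image_size * sqrt(2) / n_bins` by default, so the array spans the image
  diagonal — the smallest array that sees every pixel at every angle. For
  the 128-px study geometry (180 views × 184 bins, $I = 33{,}120$,
  $J = 16{,}384$) this gives a spacing of ≈ 0.984 pixel;
* a ray lying exactly on a pixel boundary is attributed by the half-open
  cell rule (`floor()` of the grid coordinate).

Rays that miss the image square produce all-zero rows. They are retained
(sinograms stay rectangular) but flagged in `valid_rays` and excluded from
divergence sums and update factors, which avoids $0/0$ terms.

### Zero measurements and degenerate support

Measured projections may contain exact zeros (rays that cross the image
square but miss the object, or negative noisy values clipped at zero).
These rays contribute exactly $0$ to $\xi$ — structurally, not via
`0 * big` arithmetic — and their divergence term $\int_0^{q} s^{\gamma -
\gamma\alpha}\,ds$ is finite for the parameter ranges the update uses.
Under the iteration they correctly drive the pixels they exclusively see
toward zero; once such a ray's own projection underflows, it is a
*consistent* zero-against-zero limit. The implementation therefore floors
the projection of zero-measurement rays at $\varepsilon = 10^{-12}$ before
exponentiation (relevant when $\alpha > 1$, where $(Ax)^{\gamma(1-\alpha)}$
grows as the projection decays) and reserves the degenerate-support error
for the genuine contradiction: a vanishing projection on a ray with
*positive* measurement. Silent flooring is never applied in that case, so
projector bugs cannot be masked. Powers are formed in log space when
$\gamma\alpha > 3$ to avoid overflow.

## The phantom simulator

`shepp_logan_phantom()` rasterizes the standard 10-ellipse Shepp–Logan
parameter table with the widely used high-contrast ("modified") additive
densities, keeping all pixel values in $[0,1]$. Pixel centres decide
ellipse membership (no anti-aliasing); negative density sums are clipped at
zero. The rasterization is resolution-consistent (the mean pixel value
moves by less than 1% from 128 to 256 px, checked in the tests).

`add_projection_noise()` adds i.i.d. zero-mean Gaussian noise with

$$ \sigma^2 = \overline{y^2} \big/ 10^{\mathrm{SNR}/10}, $$

the SNR taken as a power ratio over all sinogram entries (the convention of
MATLAB's `awgn(..., 'measured')`), then clips negatives to zero so that
$y^\gamma$ stays real for fractional $\gamma$. Users who prefer a small
positive floor instead of clipping can substitute one before
reconstruction. Noise is driven by an explicit seed and leaves the global
RNG untouched.

What the generator emulates: the geometry, scale, and additive-Gaussian
noise of a bench-top simulation study. What it does not: Poisson counting
statistics, scatter, beam hardening, detector point-spread, fan/cone-beam
geometry — conclusions from passing tests carry to real scanner data only
insofar as the Gaussian, parallel-beam idealization does.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | — | divergence exponent, $>0$; smaller values weight low-count rays more gently and empirically improve noise robustness at late iterations |
| `alpha` | 1 | second exponent, $\ge 0$; $>1$ empirically accelerates early convergence |
| `h` | 1 | multiplicative-Euler step size; 1 reproduces the plain update |
| `z0` | `mean(y) / mean(rowSums(A))` over valid rays | constant initial image whose forward projection has the scale of the data; any positive constant or full image may be supplied |
| `snr_db` | 30 (noisy study) | sinogram-power SNR of the additive Gaussian noise |
| SSIM window | Gaussian 11×11, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, `data_range = 1` | the reference settings of the original SSIM formulation; local statistics are weighted (population) moments and the map is averaged over fully interior windows |

`l2_error()` is deliberately unnormalized, $E(z) = \lVert e - z
\rVert_2$ — no $1/J$ — so its magnitude grows with the pixel count; the
packaged 128 × 128 studies report it on that scale.

## The packaged experiments

`run_ct_experiment()` reproduces the numerical-phantom protocol: modified
Shepp–Logan at 128 px, 180 × 184 rays, $h = 1$, 200 iterations from the
scaled flat start, checkpoints at 50/100/200, optionally 30 dB noise with
one master seed (noise is the only stochastic element; everything else is
deterministic, and metric logs are byte-identical across reruns).
`run_parameter_sweep()` maps $\log_{10} E(z^{(N)})$ over a
$(\gamma, \alpha)$ grid, reusing one system matrix and one noise
realization across the grid, recording per-cell failures without aborting,
and marking the MLEM point $(1,1)$.

Problem sizes in the shipped test suite were chosen to keep a full run on a
single CPU comfortable: oracle and identity checks on short vectors;
MLEM-equivalence on a 32 × 32 problem; Lyapunov/monotonicity and the two
structural sweeps on a 64 × 64, 90 × 92-ray geometry (sweep grids
$\gamma \in \{0.1, \dots, 1.5\}$ step 0.1, $\alpha \in \{0, \dots, 1.4\}$
step 0.2, 200 iterations); the noise-free and noisy benchmark studies at
the full 128-px scale with five noise seeds.

## Known limitations

* The high-contrast density table is the canonical published one; studies
  that used a privately modified table will reproduce only approximately.
* The SNR convention (power over all sinogram entries) and the constant
  initial value are stated choices; alternatives shift absolute $E$/SSIM
  levels, particularly the iteration at which semiconvergence sets in on
  noisy data.
* No convergence guarantee is offered for $h \ne 1$; ordered-subsets
  acceleration, penalized variants, and non-Gaussian noise models are out
  of scope.
* The FBP baseline (Shepp–Logan-windowed ramp filter, adjoint
  backprojection) is provided for comparison, not as a tuned transform
  method; with an exact line-integral projector its relative $L_2$ error on
  the noise-free 128-px phantom is about 0.20.
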