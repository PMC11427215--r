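---
title: "Absolute optical tomography with photon-packet Monte Carlo and stochastic Gauss-Newton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute optical tomography with photon-packet Monte Carlo and stochastic Gauss-Newton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optical tomography reconstructs the absorption coefficient $\mu_a(r)$ and
scattering coefficient $\mu_s(r)$ of a tissue-like medium from light
measurements on its boundary.  In small or low-scattering domains (the
*transport regime*) the diffusion approximation is invalid and light must
be modelled by the radiative transfer equation.  `otmc` takes the
stochastic route: the forward model is a frequency-domain *photon-packet
Monte Carlo* simulation, and the inverse problem is solved as a maximum a
posteriori (MAP) estimate with a Gauss-Newton method that is aware of --
and adapts to -- the Monte Carlo noise in its own forward solutions.

The package implements, end to end, in a 2D circular domain (radius 4 mm,
16 sources and 16 detectors of width 0.5 mm interleaved on the boundary,
100 MHz intensity modulation):

1. structured triangular meshing of the disk and piecewise-constant
   optical fields (three reference phantoms);
2. the Monte Carlo transport solver with complex packet weights
   $w(s) = w_0\exp(-\int\mu_a\,ds')\exp(-i\omega s/c)$, Henyey-Greenstein
   scattering (2D branch), cosine-law boundary sources, and the boundary
   exitance estimator $Y_b = W_b/(P A_b)$;
3. Jacobians of the exitance assembled from the same photon paths:
   direct differentiation for absorption,
   $\partial Y_b/\partial\mu_{a,k} = -\tfrac{1}{PA_b}\sum l_k w$, and
   perturbation Monte Carlo for scattering,
   $\partial Y_b/\partial\mu_{s,k} = \tfrac{1}{PA_b}\sum(n_s/\mu_{s,k}-l_k)w$;
4. the MAP objective
   $u(x) = \tfrac12\|L_e(y_{meas}-y(x))\|^2 + \tfrac12\|L_x(x-\eta_x)\|^2$
   with a per-component relative (1%) Gaussian noise model and an
   Ornstein-Uhlenbeck prior
   $\Gamma_x(i,j) = \sigma_x^2\exp(-\|r_i-r_j\|/\tau)$, $\tau = 0.5$ mm;
5. the stochastic Gauss-Newton (SGN) iteration in scaled variables
   $\tilde\mu = \mu/\eta_\mu$, and its adaptive variant (ASGN) that runs an
   $L$-sample direction ensemble per iteration, applies the norm test
   $V^2 = \widehat E\|\bar\delta-\delta^{(\ell)}\|^2/\|\bar\delta\|^2 \le
   \gamma^2$, and increases the photon budget by the factor $V^2/\gamma^2$
   whenever the test fails.

## A worked example

```{r}
library(otmc)

# simulate measurements on a fine mesh, reconstruct on a coarser one
res <- run_experiment("desk", phantom = "circles", seed = 1)
res$history          # per-iteration u(x), P_i, V^2, cumulative packets
res$metrics          # final and initial-guess relative errors (percent)
```

The `desk` preset is a reduced-scale study that runs in minutes; the
`paper` preset uses the full-scale reference settings (fine meshes,
$10^{10}$ data packets, $L = 10$) and is long-running.

## Model assumptions

* 2D circular domain, matched refractive index ($n = 1$): no Fresnel
  reflection, packets exit at first boundary contact.
* Piecewise-constant coefficients on triangles; the anisotropy $g$ is
  global (default 0.9).
* The speed of light is spatially constant, so the packet phase can be
  accumulated as $-\omega s_{tot}/c$ from the total path length; this is
  algebraically identical to per-element accumulation.
* The noise model is per-component relative: each amplitude *and* phase
  component receives independent zero-mean Gaussian noise with standard
  deviation 1% of its magnitude.  The alternative reading (absolute phase
  noise of 0.01 rad) is available via `add_noise(phase_absolute = TRUE)`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 4 mm | domain radius |
| `frequency` | 100 MHz | intensity-modulation frequency |
| `g` | 0.9 | scattering anisotropy (mean cosine) |
| `width` | 0.5 mm | source/detector arc width |
| `tau` | 0.5 mm | prior correlation length (the inclusion radius) |
| `sigma_mua`, `sigma_mus` | contrast/3 | prior stds (see `phantom_settings`) |
| `termination_threshold` | 1e-6 | relative packet weight below which a packet is dismissed |
| `positivity_floor` | 1e-6 /mm | lower bound applied to the iterate after each update |
| `L`, `gamma`, `P_init`, `P_cap` | 10, 1, 1000, 1e9 | ASGN ensemble size, norm-test threshold, initial and maximal per-source budget |
| `step_length` | 1 | Gauss-Newton step parameter |

Prior means equal the phantom backgrounds, and the coefficient scaling
uses those means, putting absorption and scattering on a common O(1)
scale -- without it the joint norm test would be dominated by whichever
block has the larger raw magnitude.

## Numerical choices

* **Termination.** Packets are killed when their relative weight falls
  below $10^{-6}$, without Russian roulette.  The induced bias is orders
  of magnitude below the 1% measurement noise; setting the threshold to 0
  disables termination, which makes total boundary weight conservation
  exact (this is asserted in the tests to $10^{-13}$ relative).
* **Ray traversal.** Segment-by-segment marching across triangle edges
  using edge-normal intersection tests, with a relative nudge of
  $10^{-12}$ of the domain diameter past each crossed edge to avoid
  re-intersection; a packet landing exactly on a vertex is carried past it
  by the same nudge along its direction of travel.
* **RNG.** One root seed; each (source, packet) pair gets its own
  counter-based substream (splitmix64-seeded xoshiro256+).  Reruns with a
  perturbed medium therefore reuse identical random numbers, which is what
  makes finite-difference validation of the stochastic Jacobians possible
  (common random numbers), and simulations bit-reproducible.
* **Henyey-Greenstein sampling** uses the exact inverse CDF of the 2D
  density, $\theta = 2\arctan\big(\tfrac{1-g}{1+g}\tan(\pi(u-\tfrac12))\big)$.
* **Linear algebra.** The Gauss-Newton system is solved densely
  (Cholesky-based `solve`), and the solution is verified to satisfy the
  normal equations to $10^{-8}$ relative residual, with one step of
  iterative refinement if needed.  The OU prior factorizations use dense
  Cholesky per coefficient block.
* **Degenerate inputs.** Meshes that cannot cover the disk within 1% of
  its area are rejected; `target_edge_length >= radius` is an error; rays
  that fail to advance raise a geometric-degeneracy error rather than
  silently looping.
* **Ensemble averaging.** The ASGN reference direction is solved from the
  sample-averaged forward solution and Jacobian (not the average of the
  per-sample directions -- the solve is nonlinear in $J$).  When all
  samples are bit-identical (a noise-free surrogate model) the average is
  taken to be that sample exactly, so the norm test returns $V^2 = 0$ in
  the deterministic limit.

## Design decisions that were genuinely open

* **Dead channels at small budgets.**  With $P_1 = 1000$ packets and
  forward-peaked scattering ($g = 0.9$), detectors adjacent to the source
  often receive *no* packets; their sampled exitance is exactly zero and
  the amplitude/phase chain rule is undefined.  The reference ASGN
  configuration starts precisely in this regime, so the solver-facing
  forward map treats such channels as uninformative for that sample:
  amplitude 0, zero Jacobian rows.  The strict alternative -- abort and
  ask for more packets -- is available (`dead_channels = "error"`) and
  remains the contract of the lower-level `assemble_jacobian`.
* **Budget growth timing.** When the norm test fails, the increased
  photon count takes effect at the *next* iteration; the current step is
  not recomputed.  This matches a one-budget-per-iteration accounting of
  cumulative packet usage.
* **Packet accounting.** The primary cumulative count includes the
  ensemble multiplicity ($L P_i$ per iteration per source); the
  single-sample count ($P_i$) is logged alongside, since published totals
  can be read either way.
* **Positivity.** The Monte Carlo model is undefined for negative
  coefficients, so after each update the unscaled coefficients are floored
  at $10^{-6}$ mm$^{-1}$ (configurable, can be disabled).
* **Inclusion geometry.** Inclusion positions are not uniquely fixed by
  the reference figures; the defaults (rings of alternating absorbing and
  scattering disks, a concentric low-scattering annulus) are configurable
  in `make_phantom()`.
* **Noise model of reduced-scale synthetic data.**  Simulated data carry
  two noise sources: the added 1% relative Gaussian noise and the Monte
  Carlo sampling error of the data simulation itself.  At $10^{10}$
  packets the latter is negligible, but at the reduced $10^6$-packet
  budget it reaches 0.5-1.5% per channel -- comparable to the modelled
  noise -- and a weighting matrix built from the 1% term alone makes every
  solver overfit the data's own sampling noise.  `simulate_dataset()`
  therefore attaches $\sigma^2 = (0.01|y|)^2 + SE_{MC}^2$ by default
  (`mc_error_model = FALSE` restores the bare 1% model), with the
  per-channel $SE_{MC}$ estimated from the tallied second moments of the
  packet weights.
* **Serialization** uses plain structured text (mesh node/element lists,
  measurement tables, YAML configs) so every artifact is diffable and
  re-validated on read.

## What the synthetic data does and does not emulate

The generator reproduces the reference study conditions: distinct
data-simulation and reconstruction meshes (edge-length ratio about 0.7;
an inverse-crime guard refuses identical meshes), cosine-law sources,
1% relative noise, and the three phantoms with prior settings tied to
their contrasts.  It does *not* emulate real measurement systems:
source/detector coupling coefficients, calibration drift, refractive-index
mismatch, detector dark counts, or 3D effects are all absent.  Passing
tests therefore demonstrate correctness of the transport model, the
path-based Jacobians and the adaptive inversion loop under the stated
noise model -- not robustness to experimental systematics.

## Problem sizes used in the tests

The test suite and the acceptance script run a reduced-scale version of
the reconstruction study chosen so the whole pipeline exercises in
minutes on one core: data simulated at $10^6$ packets per source on a
mesh of about 1200 elements, reconstruction on about 600 elements, ASGN
with $L = 5$, $\gamma = 1$, $P_1 = 1000$, 10 iterations, and a $10^6$
per-source packet cap.  At this scale the Monte Carlo noise of the
*data itself* (0.5-1.5% per channel at $10^6$ packets, against the
reference study's effectively noiseless $10^{10}$) is comparable to the
1% modelled noise, and the reconstruction errors are correspondingly
larger than the full-scale reference values; the convergence ordering
between methods and budgets is preserved, which is what the reduced-scale
assertions check.

A genuine limitation of the reduced scale deserves emphasis: on a
~600-element reconstruction mesh the prior correlation length
$\tau = 0.5$ mm is barely larger than the element spacing (~0.45 mm), so
the Ornstein-Uhlenbeck prior couples neighboring elements only weakly
(correlation $\approx 0.4$ against $\approx 0.7$ at full scale).  The
per-element posterior spread for absorption then remains close to the
prior spread, and the Euclidean relative error of even a
noise-floor-converged MAP estimate stays at about the level of the
homogeneous initial guess -- we verified this with an inverse-crime
reconstruction at sixteen-fold the usual budgets.  Scattering, being more
strongly informed by the data, does drop below the initial-guess error in
that limit.  Full-scale runs (the `paper` preset) do not share this
artifact.

## Known limitations

* 2D only; no diffusion-approximation fallback for highly scattering
  media (the highly scattering phantom runs, but needs large budgets).
* No adjoint/gradient-only mode: the full Jacobian is assembled densely.
* Derivatives with respect to $g$ or the refractive index are not
  provided.
* Variance reduction is limited to packet weighting; no splitting or
  roulette.
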