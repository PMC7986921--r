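---
title: "Worst-case local SAR without phase monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case local SAR without phase monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigsar)
```

## The problem

Parallel-transmit (pTx) MRI drives an array of $N_c$ independent RF channels.
The radiofrequency safety limit that binds in practice is the peak
10g-averaged local specific absorption rate, pSAR$_{10g}$ (IEC 60601-2-33).
For each voxel $j$ the local SAR is a Hermitian quadratic form in the complex
channel drive $\mathbf{s}$,

$$\mathrm{SAR}_j = \mathbf{s}^\dagger Q_j \mathbf{s},
  \qquad Q_j = \frac{\sigma_j}{2\rho_j}
  \left(\tilde E_x^\dagger \tilde E_x + \tilde E_y^\dagger \tilde E_y +
        \tilde E_z^\dagger \tilde E_z\right),$$

where $\tilde E_x, \tilde E_y, \tilde E_z$ are the rows of per-channel field
components for unit excitation, $\sigma$ is the conductivity and $\rho$ the
mass density. Because $Q_j$ is a sum of three rank-1 terms it has rank at most
3 and is positive semidefinite, whatever the channel count.

Transmit chains monitor per-channel *amplitudes* reliably; *phases* at the
coil are sensitive to cable lengths, loading and calibration, and a phase
error can silently push the true pSAR above the predicted one. The safe
quantity to supervise when phases are unknown or untrusted is therefore the
**worst case over all phase settings at the known amplitudes**:

$$\mathrm{SAR}_j^{\mathrm{wc}}(\mathbf{s}_{\mathrm{amp}}) =
  \max_{\phi_1,\dots,\phi_{N_c}} \;
  \sum_n s_n^2 Q_{nn} + \sum_{n<m} 2 s_n |Q_{nm}| s_m
  \cos(-\phi_n + \theta_{nm} + \phi_m),$$

with $\theta_{nm} = \arg Q_{nm}$. This package computes that maximum exactly
per voxel, its peak over the body, and the classical estimators it should be
compared against.

## The fixed-point maximizer

Holding all phases but $\phi_\ell$ fixed, the SAR is a single sinusoid in
$\phi_\ell$:

$$\mathrm{SAR}(\phi_\ell) = c + X_\ell \cos\phi_\ell + Y_\ell \sin\phi_\ell,
  \qquad X_\ell + i Y_\ell = Z_\ell =
  \sum_{m \ne \ell} s_\ell |Q_{\ell m}| s_m\, e^{i(\theta_{\ell m} + \phi_m)},$$

so the exact coordinate maximizer is $\phi_\ell = \operatorname{atan2}(Y_\ell,
X_\ell) = \arg Z_\ell$. (We derived $X_\ell$ and $Y_\ell$ directly from the
stationarity condition $\partial\,\mathrm{SAR}/\partial\phi_\ell = 0$ together
with the second-order condition; the sign of the lower-index cosine sum in
$X_\ell$ matters — with the wrong sign the update returns the coordinate
*minimizer*, which a 2-channel hand computation exposes immediately.)
`maximize_phases()` iterates this update over all channels until the SAR
change falls below `epsilon` (default `1e-6` W/kg) *and* below `epsilon_rel`
relatively; `worst_case_psar()` peaks the per-matrix results over the body.
The per-matrix problems are independent, so results do not depend on the
order in which matrices are visited.

Numerically the update is carried out in complex form, $u_\ell \leftarrow
Z_\ell / |Z_\ell|$ with $u_\ell = e^{i\phi_\ell}$, which is algebraically the
same atan2 update without transcendental calls; the compiled kernel in
`src/` exists because the Monte-Carlo comparisons run millions of per-matrix
maximizations.

### Sweep order

Two sweep schemes are provided. `gauss_seidel` (the default) uses
already-updated phases within a sweep; every step is then an exact
block-coordinate ascent, so the SAR history is monotone non-decreasing and
the iteration cannot cycle. `jacobi` updates all channels from the previous
iterate. For two symmetric coupled channels the Jacobi map sends the cosine
argument $d \mapsto -d$: the SAR is constant along the 2-cycle, a
change-based stopping rule fires, and the returned value is wrong (SAR 2
instead of 3 on the worked 2-channel example). `maximize_phases()` therefore
verifies stationarity (gradient sup-norm) whenever a Jacobi run stops, and
repairs a non-stationary stop with coordinate sweeps; both schemes then reach
the same fixed-point value, which the tests assert.

### Starting points and global convergence

For $N_c = 2$ every local maximum of the cosine form is a periodic copy of
the global one. For $N_c > 2$ that is no longer a theorem: on isotropic
random rank-3 ensembles the all-zero start converges to a genuinely
sub-global stationary point (negative-semidefinite Hessian) in roughly 1% of
instances, with relative gaps up to a few percent. Because the method's whole
point is to *never* underestimate, the iteration is run from a small
deterministic set of starts — the configured initial phases plus the phase
vector of every eigenvector with a non-negligible eigenvalue (at most three,
by the rank bound) — and the best fixed point is kept. The
dominant-eigenvector start is exactly the lower-bound construction below and
sits in the global basin whenever one eigenvalue dominates; the remaining
starts cover the other rank directions. Against a 720-point exhaustive grid
oracle this start set produced no misses over hundreds of random instances.
The escape from an (unstable) stationary point that is not a maximum — only
reachable from contrived symmetric starts — perturbs phases by $10^{-3}$ rad
using a seeded generator and resumes, recorded in the fit diagnostics.

### Stopping rule and accuracy

The stopping rule compares successive sweeps: stop at sweep $k \ge 2$ when
$|\mathrm{SAR}_k - \mathrm{SAR}_{k-1}| \le \varepsilon$ and the relative
change is below `epsilon_rel`. Since near a maximum the SAR change scales
like the squared gradient, a solution stationary to $10^{-8}$ requires
iterating essentially to the floating-point fixed point
(`epsilon_rel = 0`); the default `1e-6` is ample for safety supervision,
where SAR values are order 0.1–10 W/kg.

## Comparator estimators

* **Total-power (TP) bound**: $\max_j \lambda_{\max}(Q_j)\, P_{\mathrm{tot}}$
  — the Rayleigh bound over *all* drives of the given total power. Exact only
  when the amplitude profile matches the dominant eigenvector moduli;
  otherwise conservative, often grossly so.
* **Eigenvector-phase lower bound (LB)**: evaluate the cosine form at the
  phases $\psi$ of the dominant eigenvector. For rank-1 $Q$ these phases
  cancel every entry phase ($-\psi_n + \theta_{nm} + \psi_m = 0$) and the
  bound is exact; in general it can only fall short of the worst case.
* **Magnitude-sum upper bound (UB)**: $\sum_{n,m} s_n |Q_{nm}| s_m$, i.e.
  every cosine at 1 — feasible exactly in the rank-1 case, conservative
  otherwise. LB and UB need no iteration; they are also used internally to
  prune the per-drive peak search (a matrix whose UB is below the best exact
  value so far cannot host the peak).
* **Reference-phases (RP) estimate**: $\min_k \zeta_k \max_j
  \mathbf{w}_k^\dagger Q_j \mathbf{w}_k$, where $\mathbf{w}_k$ carries the
  drive amplitudes with fixed reference phases $P_k$, capped at the TP bound
  for the same total power. The defaults are the zero-phase set and a
  circularly-polarized ramp $2\pi n/N_c$; suitable references depend on the
  array, so both are replaceable.

The correction factors $\zeta_k$ are calibrated against the exact maximizer:
$\zeta_k = \max_{\mathbf{s}} \mathrm{pSAR}_{\mathrm{wc}}(\mathbf{s}) /
\max_j \mathbf{w}_k^\dagger Q_j \mathbf{w}_k$ over amplitude sets drawn
uniformly on the power simplex, followed by Nelder–Mead ascents of the ratio
from the highest sampled points (log-power coordinates keep the iterate on
the simplex). The local ascent matters: sampling alone left the estimate
below the exact worst case on a few percent of held-out drives; with
refinement the audit over $10^4$ held-out drives shows zero violations. The
ratio is invariant to total power, so calibrating at 1 W suffices.

## 10g averaging

The safety limit applies to SAR averaged over a region containing 10 g of
tissue. `average_10g()` grows an odd-sided cube symmetrically around each
voxel until the enclosed tissue mass reaches the target (10 g default),
clipping at the grid boundary; entries are averaged mass-weighted over body
voxels, with air contributing neither mass nor SAR. Averaged matrices are
convex combinations of PSD matrices, hence PSD. A voxel whose fully clipped
cube never reaches the target mass is excluded with a warning. This integer
cube rule is deliberately simpler than fractional-shell surface-corrected
averaging (IEC 62704-1 style): interpolating partial voxel shells changes
absolute averaged values slightly but leaves the maximization machinery —
the package's subject — untouched. On 5 mm isotropic voxels at
1000 kg/m³ the cube side is 5 voxels (15.6 g), the smallest odd cube over
10 g.

## VOP compression

To run estimators at interactive speed, `compress_vops()` reduces the
matrix set with a guaranteed allowance: matrix $Q_j$ may be represented by a
VOP $V$ if $V + \delta\bar\lambda I - Q_j \succeq 0$, where $\bar\lambda$ is
the largest eigenvalue over the whole set and $\delta$ defaults to 5%. PSD
dominance gives, for every drive,
$\max_j \mathbf{s}^\dagger Q_j \mathbf{s} \le \max_V \mathbf{s}^\dagger V
\mathbf{s} + \delta\bar\lambda \|\mathbf{s}\|^2$, i.e. never an
underestimate and at most $\delta\bar\lambda P_{\mathrm{tot}}$ of excess.
The pass is greedy in descending $\lambda_{\max}$ order with first-fit
dominance and index tie-breaks — reproducible, but making no claim of
minimal VOP counts; published counts from other compression algorithms are
not comparable. $\delta$ is applied to the global maximum eigenvalue, the
conservative reading; a per-matrix allowance would be tighter but is a
different contract.

## Synthetic data: what it emulates and what it does not

No field data ships with the package; everything is generated:

* `generate_phantom_fields()` builds analytic surrogate fields for an
  $N_c$-element array on a cylindrical former around a homogeneous lossy
  phantom (defaults: 12³ voxels at 5 mm, $\sigma = 0.5$ S/m, $\rho = 1000$
  kg/m³, 8 channels). Magnitudes decay exponentially from each element
  (decay length 40 mm), phases advance with distance (wavelength 120 mm,
  roughly tissue at 7 T), and a `dominant_z` parameter sets the fraction of
  field power in the z component (0.9 for dipole-like elements, which are
  strongly z-polarized; 0.4 for loop-like). These fields are **not**
  Maxwell solutions; they exist to produce Q ensembles with the right
  *structure*: rank ≤ 3 everywhere, near-rank-1 close to elements, mixed
  components at depth. Passing tests on them validates the algebra and the
  algorithms, not any specific scanner's absolute W/kg values.
* `random_q_ensemble()` draws $\sum_{i\le r} v_i v_i^\dagger$ with complex
  Gaussian $v_i$ (rank ≤ r ≤ 3 by construction) — the stress ensemble:
  isotropic instances are *harder* for the maximizer than field-derived ones.
* `random_drives()` samples per-channel powers uniformly on the simplex
  (amplitudes are square roots) and phases uniformly on $(-\pi,\pi]$; the
  published validation protocol says only "random drive vectors normalized
  to 1 W", so the simplex-uniform choice is ours and the sampler is
  replaceable. Quantities that depend on the drive distribution (mean
  overestimation percentages) are therefore qualitative, not reproductions.
* `brute_force_max()` is the independent oracle: exhaustive grid over all
  phases but the first (global phase invariance pins $\phi_1 = 0$) with
  optional BFGS polish; cost $G^{N_c-1}$, refused above 5 channels, with
  `random_restart_max()` as the cross-check beyond the grid's reach.

## Problem sizes and tolerances

The shipped validation runs at desk scale, chosen so the full suite and the
acceptance script each finish comfortably on a single CPU: 100 matrices per
channel count against the 720-point oracle at `1e-3` relative; $10^4$ random
drives against 200 matrices for the no-underestimation and ordering audits
(`1e-9` relative slack for ties); 500 matrices for the VOP audit; the
phantom pipeline at 12³ voxels. Convergence is summarized on the
phantom-derived 10g set: the median run reaches a $10^{-12}$ relative
residual within 10 sweeps. The claimed $10^{-3}$ relative accuracy after a
*single* sweep is reproduced only where one eigenvalue strongly dominates
(it is exact for rank-1 matrices); under this generator's conditions
(`dominant_z = 0.9`) the ensemble median after one sweep is about $10^{-2}$,
and the corresponding acceptance assertion is expected to fail — we kept the
stated threshold rather than tuning the generator toward it.

## Known limitations

* The worst case is over phases only; amplitude uncertainty is out of scope
  (the TP bound covers the all-unknown case).
* Cube averaging ignores fractional shells; absolute 10g values differ from
  IEC 62704-1-conformant implementations by a discretization-dependent
  amount.
* RP correction factors are calibrated on a sampled amplitude family with
  local refinement — conservative on everything audited, but without a
  global optimality certificate over the entire simplex.
* The greedy VOP pass optimizes nothing but the dominance guarantee; counts
  are larger than cluster-based compressors would give.
* Phantom fields are analytic surrogates; no anatomy, no tissue
  heterogeneity, no FDTD.
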