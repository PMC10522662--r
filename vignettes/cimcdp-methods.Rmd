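---
title: "Hybrid Ising-machine solvers for L0-regularised compressed sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Ising-machine solvers for L0-regularised compressed sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Compressed sensing reconstructs a sparse source signal $x \in \mathbb{R}^N$
from $M < N$ linear measurements $y = A(\xi \circ x) + w$, where
$\xi \in \{0,1\}^N$ is the true support, $a = \|\xi\|_0/N$ the sparseness
and $\alpha = M/N$ the compression ratio. The L1 relaxation (LASSO) is
convex but shrinks the recovered values; the L0-regularised form

$$(\hat R, \hat\sigma) = \arg\min_{\sigma \in \{0,1\}^N}\arg\min_{R \in \mathbb{R}^N}
  \tfrac12\|y - A(\sigma \circ R)\|_2^2 + \lambda\|\sigma\|_0$$

recovers unshrunk values and tolerates higher sparseness, at the price of a
combinatorial search over supports. Written elementwise, the inner
objective is a quadratic unconstrained binary optimisation (QUBO)
Hamiltonian in $\sigma$,

$$\mathscr{H} = \sum_{r<r'}\sum_k A^k_r A^k_{r'} R_r R_{r'}\sigma_r\sigma_{r'}
  - \sum_r\sum_k y^k A^k_r R_r \sigma_r + \lambda\sum_r \sigma_r,$$

which is the natural workload for an Ising machine. `cimcdp` simulates a
quantum–classical hybrid: a coherent Ising machine (CIM) — a network of
degenerate optical parametric oscillator (DOPO) pulses, one per signal
entry — optimises the support $\sigma$, while a classical digital
processor (CDP) solves the restricted least-squares problem for $R$ at
frozen $\sigma$; the two alternate. The injection threshold $\eta$ of the
machine maps onto the penalty through the Maxwell rule
$\lambda = \eta^2/2$.

## Machine models

Three stochastic-differential-equation models of the CIM are integrated by
Euler–Maruyama (`run_cim()`), all with vacuum initial conditions
($c = s = \mu = 0$, $V = 1/2$, $n = m = 0$, $e = 1$):

**Open-loop Wigner** (`wigner_ol`) integrates in-phase and quadrature
amplitudes $(c_r, s_r)$ with pump schedule $p(t) = 1.5(t/5)^2$ over 5
photon lifetimes ($\Delta t = 0.1$, 50 steps). The injection
$\tilde K(|h_r| - \eta)$ drives pulses whose local field exceeds the
threshold positive; the support is the Heaviside binarisation of the
final $c_r$ (with $H(0) = 0$).

**CAC Wigner** (`cac_wigner`) integrates mean amplitudes $\mu_r$ and
variances $V_r$ of the in-phase quadrature, with chaotic amplitude control
(CAC): an error gain $e_r$ obeying
$\dot e_r = -\beta(g^2\tilde\mu_r^2 - \tau)e_r$ multiplies the injection,
forcing every pulse's squared measured amplitude toward the target $\tau$
and destabilising intermediate (locally optimal) configurations. The
measured amplitude $\tilde\mu_r = \mu_r + \sqrt{1/4j}\,W_R$ reuses the
same Gaussian realisation as the drift noise, as a homodyne record does.
The Zeeman (matched-filter) term is scaled by $\sqrt{\tau/g^2}$ so that
it balances the interaction term when amplitudes sit at
$\pm\sqrt{\tau/g^2}$.

**Positive-P** (`positive_p`) replaces $(\mu_r, V_r)$ with
$(\mu_r, n_r, m_r)$ — mean plus two quantum-fluctuation variances — and
needs no truncation of the underlying phase-space expansion. At
$g^2 = 10^{-7}$ its supports agree with the CAC-Wigner supports on
essentially every entry (a property the test suite asserts at the 90%
level on matched seeds).

CAC models integrate 20 lifetimes ($\Delta t = 0.02$, 1000 steps) under
the sigmoidal pump $p(t) = (p_{thr} - d) + 2d/(1 + e^{-(t-4)/2})$.

## Discretisation choices

* The white-noise increment over a step is $\sqrt{\Delta t}\,w_r$ with
  $w_r \sim N(0,1)$ drawn once per pulse per step; the measured amplitude
  uses the same draw with the white-noise scaling,
  $\tilde\mu_r = \mu_r + \sqrt{1/(4j\Delta t)}\,w_r$. The continuous-time
  scaling of the measurement record is not uniquely determined by the
  model statement; the shared-draw convention is the package's choice and
  is documented here once.
* The error equation is multiplicative, so it is integrated by its exact
  exponential step $e_r \leftarrow e_r\exp[-\beta(g^2\tilde\mu_r^2 -
  \tau)\Delta t]$, which preserves $e_r > 0$ for any step size; a plain
  Euler step only does so for small increments.
* The $r' \neq r$ exclusion in every local field is computed as a full
  Gram matrix–vector product minus the diagonal correction, O(NM) instead
  of O(N²M).
* The pump-schedule clock restarts at every CIM call: each alternating
  iteration integrates a fresh trajectory over the stated number of
  lifetimes.
* Divergence (any non-finite state entry) aborts the run with the step
  index.

## Parameters

| parameter | default | meaning |
|---|---|---|
| $g^2$ | $10^{-7}$ | saturation parameter; photon-number scale $\tau/g^2$ and quantum-noise size |
| $j$ | 1 | out-coupling rate for homodyne measurement (not stated numerically; unit rate on the photon-lifetime scale) |
| $\tilde K$ | 0.25 | open-loop feedback strength |
| $K$ | 0.1 (random instances), 0.01 (MRI preset) | CAC feedback strength |
| $\beta$ | 1 | error-feedback rate per lifetime |
| $\tau$ | 1 (0.21 / 0.15 for the noisy grid runs) | CAC target squared amplitude |
| $\Delta t$, steps | 0.02 × 1000 (CAC), 0.1 × 50 (open-loop) | integration grid |
| $\eta_{init} \to \eta_{end}$, velo | experiment-specific | threshold schedule $\eta_i = \max[\eta_{init}(1 - i/velo), \eta_{end}]$ |
| $\gamma$ | $10^{-4}$ | L2 smoothness weight of the MRI objective |

$K$ and $\beta$ for the random-instance experiments are not fixed by the
problem statement; they were set by a rough search on the
amplitude-stabilisation behaviour itself — the time-averaged
$g^2\tilde\mu^2$ over the second half of a run should sit near $\tau$,
which is the defining feature of the amplitude-control loop. With
$\beta = 0.2$ the error gain grows too slowly for off-support pulses to
reach the target within 20 lifetimes (second-half averages near $0.15$);
$\beta = 1$, $K = 0.1$ yields averages within a few percent of $\tau$.
The support quality is insensitive to $K$ over 0.1–2, so this calibration
does not trade recovery accuracy against stabilisation.

## The alternating loop

`run_hybrid()` iterates: threshold $\eta_i$ from the schedule; one CIM
trajectory at the current signal estimate; a CDP solve on the returned
support (`solve_jacobi()` with $\Delta t_c = 0.1$, 100 sweeps for dense
Gaussian instances; `solve_cgd()` for operator problems). Two design
points deserve explanation because the loop's data flow is not fully
determined by its defining equations:

* **The signal estimate passed to the CIM is dense.** The restricted
  least-squares system $R_r\sum_k (A^k_r)^2 = \sigma_r\mathbb{H}_r$ only
  determines $R$ on the support; off-support entries are arbitrary and
  masked on output. If they are communicated to the CIM as zeros, the CAC
  injection $je_r(R_r h_r - \frac{\eta^2}{2}\sqrt{\tau/g^2})$ is strictly
  negative wherever $R_r = 0$: a dropped entry can never re-enter, the
  empty support is absorbing, and the decreasing threshold schedule has
  nothing to act on. The package therefore fills off-support entries with
  the residual matched-filter value $\mathbb{H}_r / \sum_k (A^k_r)^2$ —
  the value the entry would take if added to the support. This puts the
  CAC entry criterion $R_r h_r > \frac{\eta^2}{2}\sqrt{\tau/g^2}$ on the
  same field scale as the open-loop criterion $|h_r| > \eta$ (an entry
  re-enters when its residual correlation exceeds $\approx \eta/\sqrt2$),
  and it makes dropped entries recoverable as $\eta$ anneals down. With
  the masked alternative the hybrid locks into small supports and the CAC
  variant performs strictly worse than open-loop, contrary to every
  benchmark comparison; with the dense rule it is consistently better.
* **The default initial estimate is the matched filter $A^Ty$**, for the
  same reason: a zero start is a fixed point of the CAC loop. For the
  MRI pipeline the LASSO solution is used instead, computed once per
  problem.

Per-iteration threshold, support size, Hamiltonian (at
$\lambda = \eta_i^2/2$) and, when ground truth is attached, direction
cosine and RMSE are recorded; `tidy()`, `glance()` and `autoplot()`
expose them.

## Baselines

*Simulated annealing* (`sa_metropolis()`): single-flip Metropolis on
$\sigma$ against the same Hamiltonian at fixed $R$, one uniformly random
proposed flip per Monte-Carlo step, energy changes maintained
incrementally in O(N). Zero-temperature (greedy, ties accepted with
probability ½) and exponential-cooling (geometric, 0.02 → 0.00002)
schedules. The initial support is uniform random — a neutral choice the
problem statement leaves open.

*LASSO* (`lasso_fista()`): accelerated proximal gradient with
objective-restart. It is written in operator form because the MRI
problem only exists as an implicit Gram operator at $128^2$ unknowns; on
dense instances it is cross-checked against an independent coordinate
descent implementation (glmnet) in the test suite.

## Random instances and the MRI pipeline

`generate_random_cs()` draws $A^k_r \sim N(0, 1/M)$ (unit expected column
norm), $x_r \sim N(0,1)$, exactly $\mathrm{round}(aN)$ support entries,
and Gaussian observation noise of standard deviation $\nu$.

The MRI pipeline works in the orthogonal 2-D Haar wavelet domain: with
$\Psi$ the full-depth separable Haar transform ($H \otimes H$), $F$ the
unitary 2-D DFT and $S$ a uniform random k-space sampling mask, the
observation matrix is $A = SF\Psi^T$ and the QUBO data are

$$h^z = \mathrm{Re}(\Psi F^H S^T y), \qquad
  \tilde J = \Psi F^H\!\left(S^TS + \gamma(|\Lambda_v|^2 +
  |\Lambda_h|^2)\right)\!F\Psi^T,$$

where the periodic second-difference smoothness operators are diagonal in
Fourier space with symbols $\Lambda$. $\tilde J$ is applied via fast
transforms and never materialised; because $F\Psi^T = G \otimes G$ with
$G$ the (tiny) product of the 1-D DFT and Haar matrices, its exact
diagonal is the $O(\mathrm{side}^3)$ quadratic form
$P^T D P$ with $P = |G|^2$ — verified against a dense materialisation at
side 8 in the tests. As printed, the Zeeman expression has the sampling
and synthesis operators in data order ($SF\Psi^Ty$), which does not
typecheck for a length-$M$ data vector; the package uses the adjoint form
$\mathrm{Re}(A^H y)$, the gradient of the data-fidelity term.

`generate_phantom()` replaces proprietary anatomical data: overlapping
random ellipses and rectangles plus a scale-decaying texture synthesised
directly in the Haar domain (coefficient s.d. halving per finer level,
the ~1/f wavelet statistics of natural images), so that no coefficient
is exactly zero and the subsequent hard threshold meets the target
sparseness exactly; the image is affinely rescaled to $[0,1]$, which
touches only the DC coefficient. The phantom reproduces the *structure*
that matters to the solvers — large piecewise-smooth coefficients plus a
smoothly decaying tail at a controlled sparseness — but not anatomical
textures, coil sensitivities or complex-valued magnitudes of real
scanner data, so MRI results here support qualitative solver
comparisons, not clinical error levels.

Two further pipeline choices: the reconstruction mask always samples the
k-space origin (`include_dc = TRUE` in `mri_problem()`) — the image mean
lives entirely in that one coefficient and is unrecoverable by any
sparsity prior when unobserved, collapsing every solver's RMSE equally —
and the threshold schedules in `mri_demo()` are per solver: constant for
the open-loop model, but annealed from $4\eta_{end}$ down to
$\eta_{end}$ over the first six iterations for the CAC models, whose
softer entry criterion ($R_r h_r$ rather than $|h_r|$) otherwise
over-admits entries from the warm-start support that a constant
threshold never prunes. Thresholds are tuned per model, as the schedule
endpoints are whenever the solvers are compared; each solver is scored
at its best grid point.

## Numerical tolerances and problem sizes

Conjugate gradients stop at relative residual $10^{-10}$ (cap 10,000
iterations) by default; the MRI pipeline uses $10^{-8}$ with a cap of
2,000, which leaves the reconstruction error orders of magnitude below
the undersampling error. FISTA stops on a relative objective change of
$10^{-8}$. The test suite exercises the full study conditions where they
are cheap (support estimation at $N = 500$, $\alpha = a = 0.6$, 50
instances; 64 × 64 phantom reconstructions over threshold grids at the
published iteration counts, 10 seeds) and reduced sizes elsewhere
($N = 200$ with 51 alternating iterations for the recovery-regime checks;
$N = 12$ against exhaustive enumeration), chosen so the whole suite runs
on one CPU in minutes while keeping every comparison statistically
meaningful.

## Known limitations

* No density-matrix or master-equation simulation; the SDE models are
  approximations whose fidelity degrades at large $g^2$.
* No physical-hardware timing model: comparisons are per-trajectory or
  per-Monte-Carlo-step, never wall-clock-matched to an optical machine.
* Uniform random k-space sampling only; no variable-density or
  non-Cartesian patterns, no 3-D volumes, no coil combination.
* The exponential-cooling annealer interprets the printed increasing
  exponential as the described *cooling* from 0.02 to 0.00002 (geometric
  decay); the time constant is implied by the endpoints and step count.
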