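---
title: "Strand-specific PCR moments, probe fluorescence and detection limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific PCR moments, probe fluorescence and detection limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcruq)
```

# The stochastic amplification model

PCR is treated as a two-type branching process on the pair
$\mathbf{U}_i = (X_i, Y_i)$ of forward- and reverse-strand counts. Per
cycle, each template strand independently yields one copy of its
complement with a direction-specific probability:

$$X_i = X_{i-1} + \mathrm{Bin}(Y_{i-1};\, \bar p R), \qquad
  Y_i = Y_{i-1} + \mathrm{Bin}(X_{i-1};\, \bar p / R).$$

Both draws within a cycle condition on the previous cycle's counts (a
synchronous update), and all Bernoulli trials are independent. The
parameterisation by the geometric-mean efficiency $\bar p$ and the ratio
parameter $R$ is chosen so that the single-type textbook model is the
special case $R = 1$, where the process can be summed to
$N_i = N_{i-1} + \mathrm{Bin}(N_{i-1}; p)$.

Key assumptions worth keeping in mind:

* efficiencies are constant across cycles — there is no plateau phase, so
  the model is meaningful for the background and exponential regimes, not
  for late-cycle saturation;
* strands are never destroyed, and at most one copy per template per
  cycle is made;
* wells are independent and identically distributed;
* no within-cycle kinetics: melting/annealing/elongation are not
  time-resolved.

## Moments

The expectation matrix $A = \begin{pmatrix}1 & \bar p R\\ \bar p/R &
1\end{pmatrix}$ has eigenvalues $\lambda_1 = 1 + \bar p$ and
$\lambda_2 = 1 - \bar p$. `spectralDecomposition()` uses the explicit
eigenvectors (columns of $X = \tfrac{1}{\sqrt 2}\begin{pmatrix}R & R\\ 1 &
-1\end{pmatrix}$ and rows of $Z = X^{-1}$) rather than a numeric
eigensolver, so signs and scaling are deterministic and all four vectors
are unit-norm exactly when $R = 1$. Expected counts follow
$\mathbb E[\mathbf U_i] = A^i\,\mathbb E[\mathbf U_0]$ evaluated in the
eigenbasis; the weighted sum $X_i + R Y_i$ grows as $\lambda_1^i$ while
the weighted difference decays as $\lambda_2^i$, which is why the
forward/reverse ratio relaxes from its input value to the critical value
$R$ within a few cycles (the lag phase).

The covariance matrix satisfies the one-cycle recursion
$\mathrm{Var}[\mathbf U_i] = A\,\mathrm{Var}[\mathbf U_{i-1}]\,A^\top +
\sum_\ell \lambda_\ell^{i-1} K_\ell$, whose closed-form solution (a
double sum over eigenpairs with coefficients $\nu_{jk}$ and
$\eta^\ell_{jk}$) is what `varianceCounts()` evaluates. The test suite
keeps a deliberately naive implementation of the recursion itself and
checks the two routes agree to $10^{-9}$ relative over randomised
parameters up to 50 cycles.

## Inputs

`InputDistribution` describes the pipetted copy number $I$: dsDNA (case
D, both strands i.i.d. $\sim I$) or single-stranded RNA reverse
transcribed with per-molecule efficiency $r$ (cases RF/RR, binomial
thinning, so $\mathrm{Var}[\mathrm{Bin}(I;r)] = r^2\mathrm{Var}[I] +
r(1-r)\mathbb E[I]$ by the law of total variance). The variance-to-mean
ratio $\chi$ summarises input dispersion: 1 for the conventional Poisson
choice, $>1$ for a negative binomial (parameterised by mean $m$ and
size $m/(\chi - 1)$), 0 for a deterministic input. $\mathbb E[I]$ is
treated as a nonnegative real (a Poisson mean), not constrained to
integers.

# The fluorescence model

For a hydrolysis probe the two fluorescent species (inactive and active
probe) contribute linearly, a Beer's-law analog. With the probe bound to
the reverse strand, one probe is activated per forward strand
synthesised, giving

$$F_{i,w} = b_{i,w} + d_{i,w}\,\Delta X_{i,w}, \qquad
  \Delta X_i = X_i - X_0,$$

with background $b_{i,w} = f^-_{i,w} C$ and increment
$d_{i,w} = (f^+_{i,w} - f^-_{i,w})/(\mathcal V N_A)$. Units: molar
fluorescences $f^\pm$ in fluorescence·L/mol, probe concentration $C$ in
mol/L, volume $\mathcal V$ in litres (`pmolPerL()` and `microliters()`
convert from the usual assay units; typical magnitudes at
$C = 0.125$ pmol/L and $\mathcal V = 20\,\mu$L are $b \approx 1$ and
$d \approx 10^{-6}$). Because $\mathrm{Cov}[X_i, X_0] =
\tfrac{\mathrm{Var}[X_0]}{2}(\lambda_1^i + \lambda_2^i)$ is available in
closed form, the exact mean and variance of $F_{i,w}$ follow directly
from the strand moments. `fluorescenceMoments()` reports a normal band
$\mathbb E[F] \pm \kappa\sqrt{\mathrm{Var}[F]}$, justified by the
$>10^6$ Bernoulli successes needed before fluorescence rises visibly
above background.

Two configuration switches cover chemistry variants: `monitored =
"reverse"` mirrors the probe orientation, and `chemistry = "annealing"`
models probes read during annealing, where the signal at cycle $i$
reflects $X_{i-1}$.

## Calibrating molar fluorescence

With no template, $F = f^- C$ deterministically, so no-template control
plates at $q$ increasing concentrations give a per-(cycle, well)
regression through the origin, $\hat f = \sum_j F_j C_j / \sum_j C_j^2$.
Treating the per-plate ratios $F_j/C_j$ as i.i.d. normal about $f$, the
pointwise dispersion is estimated as $\hat\sigma = \lVert F/C - \hat
f\rVert / \sqrt{q-1}$; this form is used (rather than the raw residual
norm $\lVert F - \hat f C\rVert/\sqrt{q-1}$) because it carries the same
units as $f$, so $\hat\sigma/\hat f$ is the dimensionless coefficient of
variation that `qcSummary()` histograms and flags (default threshold
0.022). With a single plate the fit degenerates to pointwise division
and $\sigma$ is reported missing, not zero — one plate carries no
replication information.

# Limit of detection

Calling a well positive requires the fluorescence to clear its
background by $\kappa$ standard deviations. Because $d$ cancels, the
constraint reduces to $\mathrm{CV}[\Delta X_n]^2 \le 1/\kappa^2$,
well-independent; and since the squared CV converges at rate
$O(\lambda_1^{-i})$ to the asymptote $\alpha\,\mathrm{CV}[I]^2 +
\beta/\mathbb E[I]$, the practical criterion is $\mathbb E[I] \ge
(\chi\alpha + \beta)\kappa^2$. `lodPoint()` evaluates the asymptotic
criterion (as the grid scan does); `feasibilityCheck()` exposes the
finite-$n$ inequality separately — at 35–50 cycles the two differ by far
less than one copy except exactly at the boundary.

Two conventions are fixed deliberately:

* $L$ is the smallest **positive** integer satisfying the bound — an
  expected input of zero copies is never "detectable", so
  $\kappa \to 0$ gives $L = 1$;
* the bound is non-strict: an exactly-integer threshold is itself the
  limit.

# The synthetic-data generator

`generateControlPlates()` emulates the calibration experiment so the
whole chain (generation → fit → parameter derivation → curves) is
testable without instrument data:

* ground truth $f^\pm(i, w) = \text{base} \times (1 + \text{well
  effect}) \times \text{cycle trend}$, with Gaussian per-well effects
  (default SD 3 %) and a fixture-shaped cycle trend for the inactive
  probe (an early maximum near cycle 2–3 followed by a slow exponential
  photobleaching decay) and a slow upward drift for the active probe;
* observed readings $F = f C (1 + \varepsilon)$,
  $\varepsilon \sim N(0, \text{noiseCV}^2)$ — multiplicative noise, so
  $F/C$ is i.i.d. normal across plates at fixed (cycle, well), matching
  the fitting assumption;
* defaults: full 96-well plates over 45 cycles, $q = 4$ active / $q = 3$
  inactive concentrations. The concentration series is an evenly spaced
  bracket of the working concentration 0.125 pmol/L
  (`seq(0.075, 0.15, length.out = q)` pmol/L): the calibration targets
  the molar fluorescence *at* working conditions, and a tight bracket
  keeps the leverage of the origin-regression balanced across plates.
  Base molar fluorescences ($8\times10^{12}$ and
  $2.0044\times10^{13}$ L/mol) are chosen so the derived $b$ and $d$
  land at the typical magnitudes 1 and $10^{-6}$;
* 1 % relative noise as the default instrument repeatability.

What the generator does **not** emulate: drift correlated across wells,
optical crosstalk, plateau-phase chemistry, or any dependence of noise
on cycle. Passing recovery tests therefore demonstrates correctness of
the estimators under the model's own assumptions, not robustness to
instrument artifacts.

`generateAmplificationRuns()` produces sample plates by simulating one
branching-process trajectory per well and applying the fluorescence map,
which is how the analytic curves are cross-validated against Monte
Carlo.

# Numerical choices

* **Direct double-precision evaluation.** All moments are evaluated
  directly; $\lambda_1^{2i} \le 4^{50} \approx 1.3\times10^{30}$ at 50
  cycles fits comfortably. Cycle counts above 500 are refused rather
  than risking overflow ($\lambda_1^{2i}$ can exceed the double range);
  no log-space arithmetic is needed at assay scale.
* **Guarded eigen-denominators.** The closed-form variance divides by
  $\lambda_j\lambda_k - \lambda_\ell$, which is nonzero for
  $\bar p \in (0, 1)$; at the accepted boundary $\bar p = 1$ the
  corresponding noise matrices $K_\ell$ vanish, so zero numerators are
  short-circuited before the (then meaningless) division, and a genuine
  near-zero denominator with nonzero numerator raises an error.
* **Symmetrisation.** After evaluating the closed form, each covariance
  matrix has its off-diagonal pair averaged to remove
  $\sim 10^{-16}$ floating-point asymmetry.
* **One-pass caching.** `momentTrajectory()` computes all cycles
  $0..n$ once and caches them; downstream consumers (fluorescence
  curves, feasibility checks) index into the cache.
* **Boundary probabilities.** Efficiencies may equal 1 exactly (the
  deterministic-doubling limit, useful as a test case); 0 is invalid.
* **Seeding.** `simulatePCR()` derives one sub-seed per stage (input
  draw, reverse transcription, cycling) from the master seed, so a
  rerun of any stage with the same configuration is bit-identical.
* **Convergence checks near machine precision.** Tests of the
  geometric CV$^2$ convergence exclude differences below
  $10^{-10}$ of the asymptote, the floating-point floor of the
  cancellation-heavy CV computation, and allow a 0.1 % tolerance on the
  per-cycle ratio; the clean $1/\lambda_1$ rate is a property of the
  assay-realistic efficiency range $\bar p \ge 0.8$ (at much lower
  efficiencies mixed-sign subdominant terms can transiently nudge a
  single-step ratio above it).

# Problem sizes used by the checks

The test suite validates the simulator against the analytic moments
with $2\times10^5$ replicates over 15 cycles per input case (every
per-cycle mean, variance and cross-covariance within 4 standard
errors), recovers calibration parameters from full 96-well × 45-cycle
plates at 1 % noise, and scans the full $100^3$-point detection-limit
grid; the whole suite runs in under two minutes on one CPU. These sizes
were chosen to make sampling error small relative to the tested
tolerances while keeping the suite quick.

# Known limitations

* No inference: efficiencies $\bar p$, $R$, $r$ and the input moments
  are taken as known, not estimated from amplification data.
* Only the first two moments are provided; tail probabilities rely on
  the normal approximation.
* DNA-binding dyes are out of scope — the stoichiometric map from
  strand synthesis to fluorescence is probe-specific.
* The molar fluorescences $f^\pm$ are data-driven per cycle and well;
  photobleaching is not modelled mechanistically.
* The $\kappa$-sigma rule calibrates no false-positive/negative rates
  beyond the normal-band interpretation.
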