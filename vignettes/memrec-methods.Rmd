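---
title: "Reconstructing stored patterns from synaptic connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stored patterns from synaptic connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memrec)
```

## The problem

A recurrent attractor network stores `P` activity patterns in its synaptic
weights. Given only a measured connectivity matrix — noisy, thresholded,
non-negative, as a connectome reconstruction would provide — can the stored
patterns be recovered? `memrec` implements a Bayesian answer for a
rectified-Hopfield generative model: approximate message passing (AMP) for
low-rank matrix factorisation, together with the scalar state-evolution
theory that predicts exactly when reconstruction is possible.

## Generative model

Patterns are collected in a `P x N` matrix $X^*$ with i.i.d. entries from
one of three priors (all centred):

* **binary** — $x = \pm 1$ equiprobably; second moment $m_2 = 1$;
* **sparse** — $x \in \{-1, 0, +1\}$, non-zero with probability $\rho$;
  $m_2 = \rho$;
* **low_coding** — $x \in \{1-\rho, -\rho\}$, active with probability
  $\rho$ (activity with its mean subtracted); $m_2 = \rho(1-\rho)$. This
  prior is *skewed* for $\rho \neq 1/2$, which matters for hardness (below).

The Hebbian weights are $W = X^{*\top} X^* / \sqrt N$ and the observed
connectivity is
$$J_{ij} = \max(0,\; W_{ij} - \tau + \zeta_{ij}),$$
with threshold $\tau \ge 0$ and symmetric Gaussian noise
$\zeta_{ij} \sim \mathcal N(0, \nu^2)$. The $1/\sqrt N$ scaling places the
model at the spiked-Wigner operating point: the Hebbian signal per entry is
$O(1/\sqrt N)$ against $O(1)$ noise, the regime in which recovery of the
$N$ unknowns per pattern from $O(N^2)$ observations is neither trivial nor
impossible, and the regime in which the message-passing theory below is
exact as $N \to \infty$. (Renderings of the learning rule with a $1/N$
normalisation appear in the literature; only the $1/\sqrt N$ convention
makes the algorithm's signal and noise terms the same order, and the
AMP-matches-state-evolution tests in this package confirm it.) The diagonal
is excluded throughout: self-couplings are not observed and the posterior
involves pairs $j > i$ only. An entry is exactly zero iff
$W_{ij} - \tau + \zeta_{ij} \le 0$.

## Channel and effective noise

Conditioned on the signal $w = W_{ij}$, an observed weight follows a mixed
law: an atom at zero, $P(J = 0\,|\,w) = \Phi((\tau - w)/\nu)$, plus a
Gaussian density $\mathcal N(w - \tau, \nu^2)$ on $J > 0$. Everything the
inference machinery needs from the channel is the *Fisher score*
$$S_{ij} = \partial_w \ln P_{\rm out}(J_{ij}\,|\,w)\big|_{w=0} =
\begin{cases}
(J_{ij} + \tau)/\nu^2, & J_{ij} > 0,\\[2pt]
-\phi(\tau/\nu) / \big(\nu\,\Phi(\tau/\nu)\big), & J_{ij} = 0,
\end{cases}$$
and the *effective noise* $\Delta$, the inverse Fisher information at the
null signal:
$$\frac1\Delta = \frac{\phi(t)^2}{\nu^2\,\Phi(t)} +
  \frac{1 - \Phi(t) + t\,\phi(t)}{\nu^2}, \qquad t = \tau/\nu.$$
This closed form was derived by reducing the defining expectation (atom
contribution plus a truncated-Gaussian integral); the package also
evaluates the definition by numerical quadrature and the test suite pins
their agreement to $10^{-8}$. We kept both routes deliberately: published
renderings of this constant differ by a factor of two in the middle term,
and the quadrature of the defining expectation is the arbiter (it confirms
the form above).

Two consequences are worth noting. First, *channel universality*: two
channels with different $(\tau, \nu)$ but equal $\Delta$ are
indistinguishable to the algorithm. Second, *stochastic resonance*: at
fixed $\tau > 0$, $\Delta(\nu)$ is non-monotone — some noise is required to
push the sub-threshold Hebbian signal through the rectification, so
recovery is possible only in an intermediate window of $\nu$.
`solve_nu_for_delta()` therefore brackets every root on a geometric grid
(400 points on $[10^{-4}, 10^3]$) rather than assuming monotonicity.

## Message passing

`run_amp()` iterates, per neuron $i$,
$$b_i = \frac{1}{\sqrt N} \sum_k S_{ki}\,\hat x_k -
\Big(\frac1N \sum_k S^2_{ki}\,\sigma_k\Big)\hat x^{t-1}_i,
\qquad
A_i = \frac1N \sum_k S^2_{ki}\,\hat x_k \hat x_k^\top,$$
followed by the prior's posterior-mean threshold
$\hat x_i = f(A_i, b_i)$, $\sigma_i = \partial_b f$. The second term of
$b_i$ (the Onsager memory term) cancels the feedback of neuron $i$'s own
previous estimate through the network; the test suite includes a regression
test showing that removing it breaks the agreement with state evolution.
The field scalings ($b \propto 1/\sqrt N$, $A \propto 1/N$) are fixed by
requiring both signal and Onsager terms to be $O(1)$; the
AMP-versus-state-evolution agreement across noise levels is the
end-to-end check of this convention.

Initialisation follows the generative logic: a fresh draw from the prior
(an uninformed start whose overlap with the truth is the chance level
$O(1/\sqrt N)$), or the ground truth itself ("informed", used to probe
hard phases). Convergence is declared when the mean squared update
$\frac1N\sum_i \|\hat x_i^{t} - \hat x_i^{t-1}\|^2$ falls below `tol`
(default $10^{-8}$; default cap 200 iterations). Damping
$\hat x \leftarrow (1-\eta)\hat x_{\rm new} + \eta\hat x_{\rm old}$ is
available but off by default; $\eta = 0.5$ is the documented fallback if
the iteration oscillates.

**Mirror basin of skewed priors.** The likelihood depends on the patterns
only through $X^\top X$ and is therefore invariant under a global sign
flip. For the sign-symmetric priors this is harmless (alignment absorbs
it), but for the skewed low-coding prior the flipped configuration is a
*different* state: a metastable fixed point in which the roles of active
and inactive neurons are swapped. An uninformed start lands in it in
roughly half of all runs, at any noise level below critical, producing an
aligned error near 2 instead of the state-evolution value. The correct
branch is identifiable without ground truth: the mirrored state fits the
data much worse, because the quadratic form
$\mathrm{tr}(\hat X^\top S \hat X)$ grows with the squared overlap and the
prior suppresses the overlap in the mirrored basin. For skewed priors
`run_amp()` therefore always performs a second run started from the
mirrored estimate and keeps the better-fitting state
(`mirror_restart` in the result records when the restart won). Composition
statistics (activity fraction, empirical skewness) cannot play this role —
the mirrored state relabels which neurons are active and looks
prior-consistent marginally.

**Exact versus mean-field threshold.** The exact $f$ sums over the
$|\mathcal X|^P$ support vectors of the prior (log-sum-exp throughout,
since $b$ grows like $m/\Delta$ and overflows naive exponentials at low
noise). This is capped at $P \le 20$ for two-point priors and $P \le 12$
for the three-point sparse prior — beyond that, enumeration would take
longer than the rest of the algorithm combined, and the mean-field mode is
the intended tool. The mean-field threshold factorises the tilted
posterior over the $P$ pattern slots, keeping the diagonal of $A_i$ in the
exponent and treating the off-diagonal curvature by linearisation around
the current means: slot $j$ of neuron $i$ sees the corrected field
$b_{ij} - \sum_{k \ne j} A_i[j,k]\, \hat x_{ik}$. This cross-term is what
makes the slots *compete* for distinct patterns — dropping it entirely
decouples the slots into $P$ independent rank-one solvers which then
collide on the same patterns. The corrected fields are evaluated
slot-sequentially (each slot sees the freshest values of the others),
which in our experiments is what keeps the update stable without damping;
the fully synchronous variant oscillates at larger $P$. For $P = 1$ the
two modes coincide exactly, and the suite asserts it.

## State evolution

In the large-$N$ limit the overlap
$M^t = \frac1N \sum_i \hat x^t_i x^{*\top}_i$ concentrates, and for
uncorrelated patterns stays proportional to the identity, $M^t = m^t I_P$:
recovering $P$ patterns is the same scalar problem $P$ times. The scalar
recursion implemented by `se_step()` is
$$m^{t+1} = E_{x_0, z}\Big[f\big(\tfrac m\Delta,\; \tfrac m\Delta x_0 +
\sqrt{\tfrac m\Delta}\,z\big)\, x_0\Big],$$
with the $x_0$-expectation summed exactly over the prior support and the
$z$-expectation by Gauss–Hermite quadrature (201 nodes; the integrand is
analytic against a Gaussian weight, so this is converged to machine
precision — doubling the node count changes results by less than
$10^{-9}$, and a Monte-Carlo cross-check agrees within standard errors).
We implement this generic form once for all three priors and use the
prior-specific closed-form recursions only as test oracles: the published
specialised forms for the skewed prior are ambiguous in places, while the
generic recursion plus the linearisation checks below pin the behaviour
unambiguously.

Normalised reconstruction error and overlap are related by
${\rm mse} = (m_2 - m)/m_2$ at the Bayes fixed point, where the estimate's
self-overlap equals its overlap with the truth.

Linearising around the trivial fixed point $m = 0$ gives
$m^{t+1} = (\langle x^2\rangle^2 / \Delta)\, m^t$, hence the critical noise
$$\Delta_c = \langle x^2\rangle^2 = \begin{cases}
1 & \text{binary},\\ \rho^2 & \text{sparse},\\
\rho^2(1-\rho)^2 & \text{low coding}.\end{cases}$$
Above $\Delta_c$ the random-initialisation branch collapses to $m = 0$
(normalised mse 1); below it, recovery is possible. `iterate_se()` runs
both branches: `random` starts at $m^0 = 10^{-6}$ (the idealisation of the
chance overlap) and `informed` at $m^0 = m_2(1 - 10^{-6})$ — the informed
start generalises the binary convention to priors with $m_2 \ne 1$.
Fixed-point iteration uses `tol = 1e-10` and up to 5000 iterations;
convergence slows critically near $\Delta_c$, which the generous cap
absorbs.

**Hard phase.** Where the two branches converge to different fixed points,
reconstruction is information-theoretically possible but message passing
(and, conjecturally, any polynomial-time algorithm) fails from an
uninformed start. A sufficient criterion for such a first-order transition
is a skewed prior, $\langle x^3\rangle^2 > 2\langle x^2\rangle^3$. For the
low-coding prior the moments give $(1-2\rho)^2 > 2\rho(1-\rho)$, i.e.
$6\rho^2 - 6\rho + 1 > 0$: the criterion holds for coding levels *below*
$\rho_c = 1/2 - 1/\sqrt{12} \approx 0.2113$ (taking $\rho < 1/2$). The
direction matters and is easy to get wrong in prose: sparser coding is
*harder*, consistent with the empirically observed branch separation at
small $\rho$ for both the sparse and low-coding priors, and
`hard_phase_criterion()` evaluates the inequality from the exact moments
rather than trusting any printed reduction. The criterion is sufficient,
not necessary — the symmetric sparse prior has $\langle x^3\rangle = 0$
yet still shows a branch gap at $\rho = 0.05$.

## Finite-size behaviour near the critical noise

Away from the critical noise, a single N = 5000 run lands within a few
hundredths (normalised) of the state-evolution fixed point. At
$\Delta/\Delta_c \approx 0.9$ the picture changes qualitatively: the
iteration often fails to converge (persistent oscillation at any
iteration budget we tried), single-run errors scatter by $\pm 0.1$ to
$\pm 0.2$, and the median error sits systematically about $0.1$ above the
state-evolution prediction at N = 5000, shrinking to about $0.05$ at
N = 10000. This is the expected critical finite-size rounding of the
transition (the natural scale $N^{-1/3}$ is $\approx 0.06$ at N = 5000);
a Gaussian-channel control shows the same scatter, ruling out a
channel-specific artifact. Comparisons of the algorithm against its
asymptotic theory near threshold should therefore be read with this
rounding in mind — at these sizes the theory line is the centre of a wide,
slightly shifted distribution, not a point prediction.

## Implementation notes

The iteration is memory-bound on the N x N score matrix, so the
performance-critical loops are compiled (RcppArmadillo): a fused
single-pattern kernel streams the symmetric upper triangle of S once per
iteration while accumulating the field, curvature and Onsager sums
simultaneously, and the multi-pattern mean-field kernel evaluates the
slot-sequential sweep in blocks (`block_size` slots per refresh of the
cross-term; block size trades nothing measurable for BLAS-level speed and
defaults to 1 in `run_amp()`, 8 in the capacity experiments). Pure-R
reference implementations of the same updates remain available
(`backend = "R"`) and the suite pins the two against each other to
machine precision. Instance generation draws the symmetric noise once on
the upper triangle through R's RNG inside a compiled one-pass kernel, so
instances are bit-reproducible per seed.

## Spectral baselines

`pca_reconstruct()` implements the non-parametric alternative: the top-$P$
eigenvectors of either the connectivity $J$ or the score matrix $S$ (the
latter arises by linearising AMP around $\hat x = 0$ and is slightly
better near threshold), each rescaled to squared norm $N$. Because the
rectified channel has a positive mean weight, $J$ contains an $O(N)$
rank-one component along the all-ones vector that is pure channel offset;
the grand off-diagonal mean is subtracted by default (`center = TRUE`)
before the eigendecomposition — without this, the leading eigenvector of
$J$ is simply the uniform vector at any noise level. $S$ is centred by
construction (the score has zero mean under the null channel), so
centering there is a no-op in expectation. At high noise the leading
eigenvector is an uninformative bulk vector, and with the norm-$N$ scaling
the raw error tends to $2$ (binary), $1 + \rho$ (sparse) and
$1 + \rho(1-\rho)$ (low coding) — PCA keeps confidently predicting where
the Bayesian estimate correctly shrinks to zero. For $P > 1$ the leading
subspace is returned without attempting to undo the rotational
degeneracy.

## Experiments

`mse_vs_delta()` sweeps effective-noise levels (absolute or as fractions
of $\Delta_c$), derives $\nu$ by inverting $\Delta(\tau, \nu)$ at the
configured threshold, and tabulates AMP (both initialisations), both PCA
baselines, and both state-evolution branches in tidy long format; SE rows
are deterministic and bit-identical to standalone `iterate_se()` calls.

`pcrit_scan()` measures reconstruction capacity: at
$\Delta = 0.2\,\Delta_c$ (the configured default), it runs `n_runs`
mean-field reconstructions per pattern count $P$ and calls a run
successful when the aligned per-pattern error is below
`success_fraction` $\times\, m_2$ — 20% of the trivial (all-zero
estimate) error by default, so the binary threshold is 0.2. $P_{\rm crit}$
is the largest $P$ at which at least half the runs succeed. Per-run errors
near the transition are strongly bimodal (either the single-pattern
state-evolution level or chance), which makes the majority criterion
stable against the exact threshold choice. The scan steps by 1 from
`p_min` (located by coarse doubling when not given) and stops after five
consecutive majority failures; a cell stops early once the majority
outcome is decided, which does not change the decision for any seed.
Instance seeds and initialisation seeds are derived from the base seed
with distinct offsets — with a shared stream, the "random" initialisation
would silently reproduce the planted patterns.

`pcrit_scaling()` repeats the scan over a list of network sizes and fits
$P_{\rm crit} \sim N^\gamma$ by least squares in log–log coordinates. The
exponent is sensitive to the noise level (run-to-run fluctuations grow
near $\Delta_c$); the default problem sizes cap $N$ at a few thousand,
where a full scan is hours of compute — the suite exercises the machinery
on an exact synthetic power law and small networks, and the full-scale
exponent measurement is left to dedicated long runs.

## Alignment conventions

The posterior is invariant under pattern permutations, and under
per-pattern sign flips for the sign-symmetric priors (binary, sparse);
for the skewed low-coding prior a flipped pattern is distinguishable, so
signs are fixed to $+1$. `align_patterns()` greedily matches estimate
columns to truth rows by maximum absolute overlap (ties broken at the
lowest index; exhaustive search over signed permutations confirms the
greedy matching in the tests for $P \le 3$). Reported errors are aligned
by default: above threshold the estimate collapses to zero and alignment
is immaterial (mse $\to m_2$ per pattern, i.e. 1 normalised, not 2),
while below threshold a sign convention is required to compare against
the overlap-based state-evolution prediction at all.

## Problem sizes used in the shipped checks

The package's own validation uses sizes chosen to keep the full suite in
the minutes range while leaving the finite-size gaps to state evolution
well inside the asserted tolerances: AMP-versus-SE agreement at
$N = 5000$ (binary, sparse, low-coding; $\Delta/\Delta_c$ from 0.3 to
1.2), the above-threshold collapse at $N = 5000$, high-noise PCA constants
at $N = 5000$, and the binary capacity experiment at $N = 1000$ with 20
runs per pattern count. The capacity-scaling exponents
($\gamma \approx 0.5$–$0.7$ depending on the prior) require scans over
several network sizes with tens of runs each; the shipped tests validate
the fitting machinery exactly and exercise a reduced scan, reporting the
full measurement as a long-run experiment rather than a unit test.

## Known limitations

* Patterns are assumed uncorrelated and the pattern count known; rank
  mismatch and hyper-parameter learning (e.g. by expectation maximisation)
  are out of scope.
* The mean-field mode's capacity ceiling depends on the linearised
  treatment of the cross-pattern curvature; the exact mode is the
  reference wherever enumeration is feasible.
* The generator produces symmetric noise and excitatory-only weights by
  construction; asymmetric connectivity, inhibitory plasticity and
  non-Gaussian weight noise are not modelled.
* Synthetic instances are the only data path exercised: real connectomes
  bring correlated noise, heterogeneous thresholds and unknown priors,
  none of which the passing tests speak to.
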