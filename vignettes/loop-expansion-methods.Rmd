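---
title: "Predicting spike-train cumulants beyond linear response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spike-train cumulants beyond linear response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkesloops)
```

## The model

`hawkesloops` works with networks of conditionally Poisson spiking
neurons — nonlinear multivariate Hawkes processes, equivalently point-process
GLMs read generatively. Neuron $i$ emits spikes with conditional intensity

$$r_i(t) = \phi_i\Big(\sum_j W_{ij}\,(g * \tfrac{dN_j}{dt})(t) + \lambda_i\Big),$$

where $W_{ij}$ (mV) is the synaptic weight from $j$ onto $i$, $\lambda_i$
(mV) a baseline drive, and every interaction shares the causal alpha kernel
$g(t) = (t/\tau^2)e^{-t/\tau}$, normalized to unit integral so that weights
carry the full interaction magnitude. Given the filtered input, spike counts
in disjoint bins are independent Poisson. The transfer function $\phi$ may be
threshold-linear $\alpha\lfloor x\rfloor_+$, a rectified power law
$\alpha\lfloor x\rfloor_+^p$, or exponential $\alpha e^x$; internal units are
fixed to ms, mV and ms$^{-1}$ (gains $\alpha$ in ms$^{-1}$mV$^{-p}$).

Linearizing around the stationary state gives the classical
mean-field/linear-response description: the rates solve
$\bar r = \phi(W\bar r + \lambda)$ (the kernel integrates to one, so the
stationary convolution drops out), and fluctuations propagate through

$$\Delta(\omega) = \big(I - \mathrm{diag}(\phi^{(1)})\,W\,g(\omega)\big)^{-1},
\qquad g(\omega) = \frac{1}{(1 + i\omega\tau)^2}.$$

At this *tree level* the integrated pairwise covariance is
$C(0) = \Delta(0)\,\mathrm{diag}(\bar r)\,\Delta(0)^T$ and the integrated
third cumulant is assembled from $\Delta(0)$, the zero-frequency loop kernel
$F(0) = W\Delta(0)$ and the branching gains $\phi^{(1)}$. Linear stability is
measured by the spectral radius of $\Psi = \mathrm{diag}(\phi^{(1)})W$;
because $|g(\omega)| \le g(0) = 1$ monotonically, the frequency-dependent
radius peaks at $\omega = 0$ and that single number is the stability measure.

## One-loop corrections

When $\phi$ has curvature at the operating point, cumulants of different
orders couple: pairwise-correlated input drives extra mean rate, triplet
correlations reshape pairwise covariances, and fluctuations shift the
stability boundary. The package implements the first (one-loop) corrections
of this hierarchy. All of them are built from one reusable object, the loop
kernel $F(\omega) = g(\omega)\,W\,\Delta(\omega)$ and its integrated square

$$P_{jk} = \frac{1}{2\pi}\int |F_{jk}(\omega)|^2\, d\omega ,$$

computed by quadrature on the shared frequency grid:

* **rates** — $r_1 = \Delta(0)\,v$ with
  $v_j = \tfrac12\phi_j^{(2)}\sum_k P_{jk}\bar r_k$ (`one_loop_rate()`);
* **integrated covariance** — the five-diagram correction evaluated at zero
  total frequency (`one_loop_two_point()`); writing
  $Q = \mathrm{diag}(\phi^{(2)}/2)P$, it is
  $\Delta_0[\mathrm{diag}(Q\bar r)]\Delta_0^T + S + S^T$ with
  $S = \Delta_0\,[Q\,\mathrm{diag}(\bar r) +
  Q\,\mathrm{diag}(\phi^{(1)})F(0)\,\mathrm{diag}(\bar r)]\,\Delta_0^T$;
* **stability** — the proper-vertex correction
  $\Gamma_1(\omega)_{jm} = \tfrac12\phi_j^{(2)}
  \sum_k (F_{jk}\!\star\!F_{jk})(\omega)\,\phi_k^{(1)}W_{km}\,g(\omega)$,
  where $\star$ is the frequency self-convolution (the transform of
  $F(t)^2$), computed by zero-padded FFT along the grid (`gamma1()`). The
  corrected measure is the maximum over a frequency scan of
  $\rho(\Psi g(\omega) + \Gamma_1(\omega))$ (`corrected_stability()`), and
  $\Delta_1 = \bar\Delta\,\Gamma_1\,\bar\Delta$ recovers the one-loop
  propagator correction.

Every correction vanishes identically when $\phi^{(2)} = 0$ at the operating
point, so threshold-linear networks reduce exactly to linear-response
theory; this is asserted in the tests.

A useful scaling consequence, verified numerically in the tests: since $F$
carries one factor of $W$, the one-loop rate correction scales as the
*square* of a global weight scale in the weak-coupling limit.

## Numerical choices

**Frequency grid.** Symmetric about 0 with default cutoff
$\omega_{\max} = 20/\tau$ and $2^{12}+1$ points. At the cutoff
$|g| \approx 2.5\times10^{-3}$, and the loop integrands decay at least like
$|g|^2$; a tail-mass guard errors out when more than 1% of a loop integral
sits in the top decade of the band, suggesting a larger cutoff. Doubling
both cutoff and resolution changes $C(0)$ and $P$ by under 0.5% in the
regression tests. Only the $\omega \ge 0$ half is computed and stored
(conjugate symmetry); large-network sweeps use $2^9{+}1$–$2^{10}{+}1$ point
grids, which keeps a full sweep point to tens of seconds at $N = 240$.

**Propagator at the boundary.** `propagator()` refuses operating points with
tree radius $\ge 1$ rather than returning a numerically exploding inverse;
`solve_mean_field()` reports non-convergence (including overflow, read as
the absence of a stable branch) through a flag instead of an error. For the
exponential transfer the stationary equation can have several solutions; the
solver reports the branch reached by damped Picard iteration (damping 0.5)
from the uncoupled start $r = \phi(\lambda)$, which is the low-rate branch.

**Rectification edge.** Derivatives of the threshold kinds at exactly
$x = 0$ use the left limit (zero), so neurons with non-positive mean-field
input are silent and drop out of the propagator; the rectified-quadratic
$\phi^{(2)}$ jumps from 0 to $2\alpha$ at threshold.

**Simulator.** Fixed-step (default $dt = 0.1$ ms) conditionally Poisson
stepping: counts are Poisson with mean $r_i dt$ where $r_i$ uses input from
spikes strictly before the step (Ito convention). The alpha kernel is
realized *exactly* as a cascade of two first-order exponential stages
(their convolution is $g$), propagated with exact per-step decay; inputs are
maintained as $O(N)$ state updates plus sparse per-spike column additions,
so cost is linear in network size per step. The per-neuron impulse response
of this state space reproduces `filter_kernel()` to $O(dt)$ (tested).
Divergence is declared at the first step any rate exceeds the cap
(default $10^3$ ms$^{-1}$); statistics are then taken over the
pre-divergence window. Halving $dt$ moves weak-coupling rate estimates by
well under 2%.

**Estimators.** Rates are counts over the usable window with disjoint-block
standard errors (20 blocks). The integrated population autocovariance sums
the lag-windowed autocovariance of the binned summed train (Bartlett
truncation at `max_lag`, default 500 ms $= 50\tau$), the zero-lag bin
carrying the point-process variance; a long-window count-variance estimator
is kept as a cross-check. Error bars are the package's addition — the
reference observables are plotted without them.

## Network ensembles

`make_er_ei_network()` builds Erdős–Rényi E-I networks with the standard
study conditions as defaults: $N_E = 200$, $N_I = 40$, $p_{EE} = 0.2$,
other blocks 0.5, weight ratios $(1, -4, 0.4, -4)$ relative to $W_{EE}$ —
under which the mean net inhibitory input weight is twice the net excitatory
one — with $\tau = 10$ ms, gain $\alpha = 0.1$, baseline 0.1 mV. Autapses
are excluded (standard for these models and immaterial at these densities).
Weight sweeps scale all four weights proportionally through $W_{EE}$.

`make_heavytail_network()` replaces the E-E block: in/out degrees are drawn
from a truncated power law ($p(d) \propto d^{\gamma_1}$ up to $L_1$,
$d^{\gamma_2}$ up to $L_2$, branches matched continuously; with the default
$L_1 = 0$ the rising branch is empty and the support is $\{1,\dots,L_2\}$,
the only normalizable reading), coupled by a Gaussian copula with latent
correlation $\rho$ (defaults $\gamma_1 = 0.8$, $\gamma_2 = -1.5$,
$\rho = 0.8$). Edge probabilities are proportional to
$\text{in}_i \cdot \text{out}_j$, normalized so the expected E-E edge count
matches the Erdős–Rényi density, and clipped at 1 with a recorded count —
at the default cutoffs the hub pairs clip heavily, which is inherent to the
product-likelihood recipe at this density. E-E weights are i.i.d. lognormal
with equal location and scale $\mu = \sigma$; since $\sigma \ge 0$, the
attainable mean weights under this convention are $\ge 1$ mV
(`lognorm_location_for_mean()` inverts the mean on that domain), and the
generator records the realized mean rather than trusting any nominal
location-to-mean conversion. Discretization ties attenuate the degree
Spearman correlation slightly below the continuous-margin copula value
$(6/\pi)\mathrm{asin}(\rho/2)$; the tests compare against the exact tied
value computed by quadrature over the latent Gaussian.

## What the sweeps show — and what the generator does not emulate

`run_sweep()` reproduces the standard experiment: scale weights, compute
tree-level and one-loop predictions while the tree radius is below 1,
simulate, estimate, and tabulate. On the threshold-linear design the tree
theory tracks simulation up to near the instability. On the
threshold-quadratic design the one-loop rates and population variances are
markedly closer to simulation at strong weights, the corrected stability
measure crosses 1 well before the tree-level radius does, and simulations
diverge at weights where mean-field theory is still stable — divergence near
the corrected boundary is a stochastic escape event, so individual runs at
intermediate weights may or may not diverge within a finite window. On the
heavy-tailed design the corrected boundary moves to even smaller weights;
in that ensemble's attainable weight range (means $\ge 1$ mV) the
hub-dominated simulations diverge throughout, so only its stability and
divergence orderings are checked against simulation.

The generator emulates stationary, homogeneous-parameter networks with a
single shared synaptic filter and no conduction delays, refractoriness,
spatial structure, or plasticity. Passing tests therefore validate the
cumulant machinery and its numerics — not the adequacy of this model family
for any particular recorded dataset.

## Validation strategy

Every loop formula is checked against an independent time-domain route: the
linearized network is a $2N$-state linear system (two cascade stages per
neuron with rate feedback), so the propagator and loop kernels are exact
matrix-exponential kernels, and the corrections become direct Riemann
quadratures — no frequency grids or FFTs shared with the implementation.
For the single-unit case a fully literal nested-lattice quadrature (Toeplitz
operator matrices over a time grid) additionally validates the stationary
factorization itself. Closed-form limits (linear Hawkes rate
$\lambda/(1-\epsilon)$, integrated autocovariance $\bar r/(1-\epsilon)^2$,
Poisson degeneracy at zero coupling) and simulation agreement at weak
coupling complete the chain. Test problem sizes — toys of $N \le 3$ for
oracle equivalence, the 240-neuron design at 20–100 s of simulated time for
network benchmarks — were chosen so the whole suite runs comfortably on one
CPU.

## Known limitations

Two-loop and higher corrections, lag-resolved third cumulants and
third-cumulant tensors beyond $N = 20$, heterogeneous per-synapse filters,
conduction delays, and non-stationary (time-dependent) mean-field
trajectories are out of scope. Near the corrected stability boundary the
expansion itself degrades — all loop orders grow together — so quantitative
agreement there should not be expected from any truncation.
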