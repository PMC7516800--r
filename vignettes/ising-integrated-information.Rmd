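---
title: "Integrated information as an order parameter of the generalized Ising model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information as an order parameter of the generalized Ising model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingphi)
```

## The model

The generalized Ising model places binary spins $s_i = \pm 1$ on the nodes
of an arbitrary weighted graph and couples them through

$$H(s) = -\sum_{i<j} J_{ij}\, s_i s_j, \qquad k_B = 1,$$

with each unordered pair counted once. In the neuroscience setting the
couplings $J_{ij}$ stand in for structural connectivity (e.g. tractography
fiber counts between regions), restricted here to *ferromagnetic*
(non-negative) weights: only excitatory interactions. The package generates
ensembles of small, fully connected random networks — the `n(n-1)/2` distinct
weights drawn independently from Uniform(0, 1), mirrored, diagonal zero, and
the matrix rescaled so the strongest weight is exactly 1 — as a combinatoric
stand-in for small excitatory network motifs.

The double sum in the energy is sometimes written over ordered pairs; we
count each pair once. With max-normalized Uniform(0, 1) weights on five
nodes this puts the mean-field critical temperature near
$\sum_j J_{ij} \approx 2$, which is why the default temperature grid
(200 log-spaced points on $[0.1, 4]$) brackets the transition. Counting
pairs twice would simply rescale all temperatures by 2 and push the
transition off this grid.

## Dynamics: two update schemes with different jobs

Metropolis dynamics accept a proposed single-spin flip with probability
$1$ if $\Delta E \le 0$ and $e^{-\Delta E/T}$ otherwise. The package
implements two update schemes, and deliberately uses them for different
purposes:

* **Sequential** (`update_mode = "sequential"`): one uniformly chosen site
  is offered a flip at a time. One *iteration* of `simulate_ising()` is one
  time step = $N$ such attempts (the standard Monte-Carlo step-per-site
  convention), with observables recorded once per time step. This chain
  satisfies detailed balance for the Boltzmann distribution, so all
  thermodynamic claims (energy, magnetization, susceptibility, specific
  heat, critical temperatures) are made on sequential traces. The test
  suite validates them against exact enumeration of the canonical ensemble
  (`enumerate_canonical()`), which is feasible because the systems are
  tiny.

* **Synchronous** (`update_mode = "synchronous"`): all spins attempt a flip
  simultaneously, each against the *current* state. Because the per-node
  updates are conditionally independent given the current state, this —
  and only this — scheme induces a well-defined *state-by-node* transition
  probability matrix (`build_tpm()`): a $2^n \times n$ table of
  $P(\text{node } i \text{ up at } t\!+\!1 \mid \text{state } s \text{ at } t)$,
  which is exactly the input format the integrated-information machinery
  requires.

The two schemes are *not* interchangeable. Synchronous Metropolis does not
sample the Gibbs measure; its magnetic susceptibility peaks at a very
different temperature than the canonical one. More drastically, the
synchronous chain of a weighted complete graph is **never ergodic**: for
the max-cut bipartition of the nodes, every spin's cross-group coupling
exceeds its within-group coupling (that is what makes the cut maximal), so
in the state that sets one side up and the other down every $\Delta E_i$ is
negative, every spin flips with probability one at *any* temperature, and
the state and its global complement form a deterministic 2-cycle.
`stationary_distribution()` therefore checks strong connectivity and
aperiodicity of the kernel's support graph and refuses chains without a
unique stationary law; Phi averages over synchronous dynamics use visited
states of a trace (or, for ergodic non-Metropolis kernels, exact stationary
weights).

State bookkeeping is little-endian throughout: node 1 is the least
significant bit, spin $+1$ is bit 1, so a length-$n$ configuration has a
code in $0..2^n-1$ shared by the simulator, the TPMs and the Phi engine.

## Integrated information

For a given state-by-node TPM and system state, `big_phi()` computes the
IIT 3.0 integrated conceptual information $\Phi$:

1. For every nonempty mechanism, cause and effect repertoires over every
   purview are built from the TPM (maximum-entropy prior over unobserved
   elements; effect repertoires factorize over purview nodes).
2. A mechanism's irreducibility $\varphi$ in each direction is the
   earth-mover distance (Hamming ground metric, solved exactly as a
   transportation problem) between the whole repertoire and the closest
   partitioned repertoire, minimized over mechanism/purview bipartitions
   and maximized over purviews. A concept exists when
   $\min(\varphi_{\text{cause}}, \varphi_{\text{effect}})$ exceeds the
   $10^{-6}$ precision threshold.
3. The system-level $\Phi$ is the generalized earth-mover distance between
   the cause–effect structure of the intact system and that of the system
   under the worst-case unidirectional cut (severed inputs replaced by
   maximum-entropy noise), minimized over all $2^n - 2$ cuts; concepts
   carry mass $\varphi$ and surplus mass is exchanged with the null
   concept.

Numerical conventions that matter for reproducibility:

* $\varphi$ values are compared at precision $10^{-6}$; purview ties
  within that band resolve to the larger purview, then the smaller
  bitmask. These rules are deterministic and implemented identically in
  the C++ engine and in the independent Python reference implementation
  (`tools/iit3_reference.py`) used to freeze the test-suite oracle values.
* Effect repertoires and their partitions are product distributions, for
  which the Hamming EMD equals the sum of per-node marginal differences;
  the engine uses that closed form while the reference implementation
  solves the full transportation program — the test suite confirms the two
  routes agree to $10^{-6}$ on sixty frozen cases (fifty 3-node, ten
  4-node) and the repertoires themselves to $10^{-10}$.
* The engine's purview/partition searches carry exact pruning bounds
  (Kantorovich lower bounds on the EMD; upper bounds from the
  unconstrained partition); candidates are skipped only when they provably
  cannot alter the result.
* $\Phi$ is cached per distinct state: at $n = 5$ a whole temperature
  sweep costs at most 32 evaluations per temperature regardless of trace
  length, and the exact spin-flip symmetry of field-free Ising kernels
  ($\Phi(s) = \Phi(\bar s)$, verified as a property test) halves that
  again. `big_phi()` is guarded to $n \le 5$: the partition search grows
  super-exponentially and five nodes is where exhaustive IIT 3.0 remains
  practical.

## Criticality analysis

`sweep_network()` runs, per temperature: a seeded sequential trace for the
thermodynamic observables; optionally the synchronous TPM and per-visited-
state $\Phi$, summarized like any other observable,

$$\langle O \rangle = \frac{1}{N_t}\sum_t O_t,\qquad
  \chi_O = \langle O^2\rangle - \langle O\rangle^2,\qquad
  \chi = \chi_M / T,\qquad C_v = \chi_E / T^2,$$

all with population (1/N) variances. Across networks,
$\sigma_J^2(O)$ is the population variance of the per-network time means.
`find_peak()` locates susceptibility maxima after a centered 5-point moving
average (raw curves from a few thousand iterations are noisy; the window
shrinks at grid edges, ties resolve to the lowest temperature, and a raw
mode is available). `summarize_ensemble()` reports the consensus critical
temperature as the peak of the ensemble-*mean* curve — matching how such
ensembles are usually presented — alongside the per-network peaks.

Default protocol parameters: 500 thermalization and 2000 recorded time
steps, 200 log-spaced temperatures on $[0.1, 4]$, with every (network,
temperature) work unit carrying a seed derived from one master seed, so
units are independently reproducible and order-independent.

## What the tests do and do not show

The synthetic generator implements the exact recipe above — i.i.d.
Uniform(0, 1) weights, full connectivity, max-normalization — so the test
suite validates the *method* end to end:
simulator against exact enumeration, TPMs against one-step Monte-Carlo
frequencies, $\Phi$ against an independent implementation, and the peak
coincidence of $\chi$ and $\chi_\Phi$ on a scaled-down ensemble (ten
4-node networks, 25 temperatures). It does not tell you anything about
real tractography matrices, whose weights are neither i.i.d. nor
fully connected; `read_connectivity()` accepts such matrices but their
phase behavior is the user's question, not a tested property.

Scaled-down problem sizes used by the tests and the acceptance script
(chosen to keep exhaustive-$\Phi$ work practical while leaving the
statistics decisive): the critical-temperature check uses 20–60 five-node
networks at 50 temperatures with the 500 + 2000 protocol; exact enumeration
shows the ensemble-mean susceptibility peak for this family sits at the
grid point $T \approx 1.75$, and that with fewer than roughly 40 networks
the finite-ensemble peak occasionally lands one grid point away — hence 60
networks in the acceptance script. The $\Phi$-susceptibility coincidence
check uses ten 4-node networks at 25 temperatures with per-state caching.

## Known limitations

* $\Phi$ beyond $n = 5$ is out of reach by design (no approximate
  surrogates are provided).
* The stationary-weighted $\Phi$ average applies only to ergodic
  synchronous kernels, which excludes Metropolis-derived kernels (see
  above); visit-frequency weighting is the default for exactly this
  reason.
* Autocorrelation-corrected error bars are not computed; ensemble spread
  is reported as the plain standard deviation across networks.
* The dense TPM representation stops at $n = 12$; that bound exists for
  the Markov-chain utilities, not for $\Phi$.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
J <- generate_random_network(5, seed = 42)
temps <- temperature_grid(50, 0.1, 4)
sweep <- sweep_network(J, temps, n_thermalization = 500,
                       n_iterations = 2000, seed = 7)
find_peak(temps, sweep$chi)$T_peak     # this network's critical temperature

tpm <- build_tpm(J, temperature = 1.8)
tr <- simulate_ising(J, 1.8, update_mode = "synchronous", seed = 7)
phi_over_trace(tr, tpm)$phi_mean       # time-averaged integrated information
```
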