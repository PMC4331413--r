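---
title: "Markov chain models of gap junction voltage gating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov chain models of gap junction voltage gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjgate)
```

## The model

A gap junction (GJ) channel couples the cytoplasms of two adjacent cells. It
is formed by two hemichannels in series, each a hexamer of connexin proteins.
Junctional conductance measured under sustained transjunctional voltage
\(V_j\) decays with \(|V_j|\) — voltage gating. `gjgate` models this by
attributing a *subgate* to every connexin: each subgate switches stochastically
between an open state \(o\), a closed state \(c\), and (optionally) a
deep-closed state \(d\), and the channel's state is the tally of subgate
states in each hemichannel.

Because the six subgates of a hemichannel are exchangeable, the full
\(2^{12} = 4096\)-state description of 12 individual two-state subgates lumps
exactly onto counts: the left and right hemichannels become birth–death
automata over the number of closed subgates (7 states each), and the channel
is their composition — 49 global states arranged in 7 blocks of 7. The
three-state variants enumerate tuples \((n_o, n_c)\) with \(n_o + n_c \le 6\):
28 states when only one hemichannel gates, \(28^2 = 784\) when both do.
`lump_full_subgate_model()` verifies the lumping numerically in the
constant-rate regime, where the closed-count marginal is
\(\mathrm{Binomial}(6, \lambda_{oc}/(\lambda_{oc}+\lambda_{co}))\).

### Kronecker composition

For independent automata with generators \(Q^{(i)}\), the joint generator is
the Kronecker (tensor) sum \(\bigoplus_i Q^{(i)}\) and the stationary law is
the Kronecker product of the local laws. GJ gating breaks independence —
every transition shifts the voltage division between the hemichannels and
therefore every rate — so the package composes generators with a
*generalized* Kronecker sum (`assemble_functional_generator()`): each local
transition contributes an off-diagonal entry whose rate is evaluated at the
*global* state. With constant rates this reduces exactly to the ordinary
Kronecker sum, which the tests assert entrywise.

The first (left) automaton is the slow index, so the 49-state generator is
block tridiagonal with \(7\times 7\) blocks whose sub- and super-diagonal
blocks are diagonal matrices, and has bandwidth \(m = k_1 + k_2 + 1 = 15\)
for every positive parameter set. The 28-state model is block tridiagonal
with block sizes 7, 6, ..., 1 (grouped by \(n_o\), \(n_c\) ascending within a
block); under this ordering its measured bandwidth is 13. The 784-state model
is a 28-block layered structure whose diagonal blocks repeat the 28-state
pattern shifted by the left automaton's diagonal rates; its measured bandwidth
is 337. The package always records the *measured* bandwidth on the generator
object rather than asserting a nominal one.

### Voltage-dependent rates

Subgate kinetics follow a Boltzmann law. With
\(k = \exp\!\big(A\,P\,(V - V_0)\big)\),

\[
p_{oc} = \frac{K\,k}{1+k}, \qquad p_{co} = \frac{K}{1+k},
\qquad \lambda_{oc} = p_{oc}/\tau, \quad \lambda_{co} = p_{co}/\tau .
\]

* `A` (1/mV) — voltage sensitivity; larger values steepen the gating curve.
* `P` (±1) — gating polarity: which voltage sign drives closure.
* `V0` (mV) — half-activation voltage, where \(p_{oc} = p_{co} = K/2\).
* `K` — kinetic constant. It scales both directions equally, so it cancels in
  the equilibrium ratio \(p_{oc}/p_{co} = k\): the steady state is invariant
  to `K` (and to `τ`), which the tests verify through the full solver chain.
* `tau` — the time step converting transition probabilities to CTMC rates.
* `Ro`, `Rc` (mV) — rectification constants of the open/closed subgate
  conductances \(g_o = 2\,e^{PV/R_o}\), \(g_c = 0.25\,e^{PV/R_c}\); `Inf`
  disables rectification.

The defaults (`A = 0.04`, `K = 0.01`, `V0 = 25`, `Ro = Rc = 100`, `tau = 1`)
are a synthetic reference set chosen so that generator entries land in the
0.001–0.01 magnitude band typical of these models; they are not fitted to any
recording.

**Deep-closed transitions.** The published two-state rate law does not pin
down the \(c \leftrightarrow d\) kinetics. We reuse the same Boltzmann form
with an independent parameter set `deep = list(A, P, K, V0)`, mapping the
"forward" branch to \(c \to d\) and the complement to \(d \to c\); nested
Boltzmann gates are the standard construction for multi-state connexin
models. The deep state's conductance defaults to the closed-state value
(`g_deep_policy = "closed"`) and can be set to a constant residual instead.
Both choices are open design territory, which is why they are explicit,
documented parameters.

**Voltage division.** The two hemichannels divide \(V_j\) in series:
\(V_\mathrm{left} = V_j\,g_r/(g_l + g_r)\) with both conductances evaluated
at the voltages being solved for. Because of rectification the circuit is
nonlinear; `solve_voltage_division()` runs a damped fixed-point iteration
(damping 0.5, cap 100). A state counts as settled when the relative change of
both voltages between consecutive iterations *and* the relative series-current
imbalance \(|V_l g_l - V_r g_r| / \max(|V_l g_l|, |V_r g_r|)\) drop below
0.1%. The second criterion guarantees that the returned split conserves
current at the same tolerance the voltage criterion uses; a bisection
root-finder on the current-balance residual is the test oracle. The right
hemichannel is docked antiparallel to the left one and by default senses the
voltage across it with opposite sign (`right_orientation = -1`); this makes
the homotypic \(g_j\)–\(V_j\) curve an even function of \(V_j\), which the
tests check to 1e-10.

The junctional conductance is the probability-weighted series conductance
over global states,
\(g_j = \sum_i \pi_i\, g_{l,i} g_{r,i} / (g_{l,i} + g_{r,i})\),
with each term evaluated at that state's voltage split (cached on the
generator object).

## Steady-state solvers

All four solvers solve \(\pi Q = 0\), \(\sum_i \pi_i = 1\):

* **`dense_ge`** — base-R LU on the transposed system with the last balance
  equation replaced by the normalization row. The reference oracle.
* **`banded_ge`** — hand-written banded LU with partial pivoting. The
  normalization is imposed by *grounding*: the last state's probability is
  fixed to 1, the leading principal banded subsystem (nonsingular for an
  irreducible chain) is solved, and the result renormalized. Replacing an
  equation with the all-ones row would destroy the band, so grounding is the
  structure-preserving choice.
* **`block_recursive`** — a Thomas-like direct method for block-tridiagonal
  generators with *equal* block sizes and diagonal off-blocks (the 49-state
  model). It forward-substitutes through the block lower-triangular
  remainder, solves a single block-sized singular system for the last
  probability segment, and back-substitutes. On varying block sizes it raises
  an unsupported-structure error, mirroring its domain of applicability. Its
  agreement with dense GE is below 1e-12 at the default parameters.
* **`block_gauss_seidel`** — iterative sweeps over the block partition; each
  inner system against a diagonal block is solved by the Thomas algorithm
  when the block is tridiagonal and by banded LU for the 784-state model's
  28×28 diagonal blocks. The iterate is renormalized after every sweep and
  iteration stops when consecutive iterates differ by less than `epsilon` in
  every entry (`convergence_check()`), starting from the uniform vector
  unless a warm start is supplied.

**Stopping rule vs. solution error.** The entrywise-difference criterion
controls the *step size*, not the distance to the fixed point. Block
Gauss-Seidel on these models contracts at a rate of roughly 0.4–0.7 per
sweep (about 2–3 extra sweeps per decade of `epsilon`, visible in the
iteration ladders the tests assert), so the converged iterate sits within a
small multiple of `epsilon` of the true steady state — not orders of
magnitude inside it. Cross-method comparisons at `epsilon = 1e-6` therefore
agree to about 1e-6, and users who need 1e-8 agreement should run at
`epsilon = 1e-8` or tighter. The iterative-vs-direct comparisons in the unit
tests use `epsilon = 1e-10` against a 1e-8 agreement bound for exactly this
reason.

The residual \(\max_i |(\pi Q)_i|\) is logged per sweep. It decays
monotonically after a short initial transient; from the uniform start on the
784-state model it can rise for a sweep or two before the decay sets in.

`group_inverse()` computes \(Q^\# = (Q - e\pi)^{-1} + e\pi\) and backs the
steady-state perturbation bound
\(\lVert\Delta\pi\rVert_1 / \lVert\pi\rVert_1 \le
\lVert Q^\#\rVert_\infty \lVert\Delta Q\rVert_\infty\),
which the tests exercise on 100 random generator perturbations. This bound is
what makes warm starting effective: a small voltage step perturbs the
generator entries slightly, so the previous steady state is an excellent
initial vector.

## The voltage sweep

`run_sweep()` walks a voltage grid, rebuilding the generator and re-solving at
each point. With `warm_start = TRUE` ("Method II") the previous solution
seeds the next solve whenever the voltage increment is at most 1 mV; larger
jumps fall back to the uniform start ("Method I" uses it always). On the
default 0–100 mV grid at 0.1 mV steps and `epsilon = 1e-6`, warm starting
cuts total outer iterations by roughly half without changing the solutions
(the tests compare warm and cold probability vectors at tight tolerance).
Results are returned as a tibble and export losslessly to CSV/JSON via
`write_results()`.

## Synthetic fixtures

`generate_fixture_params()` draws reproducible parameter sets: `A` in
0.01–0.1 /mV, `V0` in 10–60 mV, `K` in 0.002–0.02 with `tau = 1`, mild
rectification (`Ro`, `Rc` in 100–500 mV), and an independent deep-gate set of
the same form. These ranges keep the seed-averaged generator entry magnitudes
inside 1e-4–1e-1 (the individual Boltzmann branches still decay exponentially
at extreme voltages, so a *pointwise* bound on every rate is not attainable —
nor physiologically meaningful). The generator emulates the *structure* of
fitted connexin parameter sets, not any particular isoform: passing tests
show the numerics are right across this family, not that a specific
connexin's gating curve is reproduced. Fitting to experimental recordings is
out of scope.

## Operation-count ledgers

`standard_ge_ops()`, `banded_ge_ops()`, `recursive_ops()` and
`bgs_sweep_ops()` tabulate exact integer operation counts — never wall-clock
times — for comparing the methods:

* standard GE: \((4n^3 + 9n^2 - 13n)/6\); 81 928 at \(n = 49\), 15 750 at
  \(n = 28\);
* banded GE: \(n(m+1)^2/4\); 3 136 at \(n = 49, m = 15\);
* block recursive at block size 7: 3 514 total across its six operation
  kinds;
* block Gauss-Seidel per outer sweep: 854 for the 49-state model, 10 220 for
  the 784-state model, and the fixed constant 196 for the 28-state model
  (stored as a constant: the equal-block tally scheme does not transfer to
  varying block sizes).

`efficiency_threshold()` turns these into break-even sweep counts: block
Gauss-Seidel beats standard GE below 96 sweeps on the 49-state model and
below 80 on the 28-state model, beats the recursive method at 4 or fewer
sweeps, and the recursive method is at least 23-fold cheaper than standard
GE. All of this is exact integer arithmetic, reproduced by
`scripts/acceptance.R`.

## Numerical choices and limitations

* Problem sizes are small by design (49–784 states); dense generators with
  block metadata are the right storage, and descriptor-only (shuffle-algorithm)
  products or synchronizing events are deliberately not implemented.
* The test and acceptance workloads use 10 seeded parameter sets × 6 voltages
  for cross-solver checks and the full 1001-point grid for the warm-start
  comparison; these sizes make every check deterministic and quick while
  still covering the parameter family.
* Banded LU uses partial pivoting (upper fill \(k_1 + k_2\)); the block
  recursive method, like its tridiagonal ancestor, does not pivot and relies
  on the small, well-scaled entries of these generators — the dense-GE
  cross-check in the tests is the guard.
* Degenerate inputs: `A = 0` gives the constant-rate regime (used by the
  lumping check); `Ro = Rc = Inf` disables rectification; `Vj = 0` splits as
  zero exactly. Reducible generators are rejected with an explicit error.
* Heterotypic channels are expressed by giving the two hemichannels different
  parameter sets; different connexin *isoform* models beyond that, plaque-level
  multi-channel behaviour, dwell-time statistics and time-course simulation
  are out of scope.
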