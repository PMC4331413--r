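# gjgate

Continuous-time Markov chain (CTMC) models of transjunctional voltage gating
of gap junction (GJ) channels, built compositionally with Kronecker (tensor)
algebra, solved with four interchangeable steady-state methods, and compared
with exact operation-count ledgers.

## The problem

A gap junction channel directly couples the cytoplasms of two adjacent cells.
It is formed by two hemichannels in series, each a hexamer of connexin
proteins, and its junctional conductance g_j decays under sustained
transjunctional voltage V_j of either polarity. `gjgate` models this by
attributing a voltage-sensitive *subgate* to each of the 12 connexins. Because
the six subgates of a hemichannel are exchangeable, the naive 2^12 = 4096
state space lumps exactly onto subgate *counts*: each hemichannel becomes a
7-state birth–death automaton over its number of closed subgates, and the
channel is their composition.

The global infinitesimal generator is assembled as a generalized Kronecker
sum. For hemichannel generators Q^(l), Q^(r),

    Q = Q^(l) ⊕_g Q^(r) = Q^(l) ⊗_g I + I ⊗_g Q^(r),

where ⊕_g marks that every transition rate is *functional* — it depends on the
global state through the series voltage division between the hemichannels.
Subgate kinetics follow a Boltzmann law: with k = exp(A·P·(V − V0)),

    p_oc = K·k/(1+k),   p_co = K/(1+k),   λ = p/τ,

and the open/closed subgate conductances rectify as g_o = 2·exp(P·V/Ro),
g_c = 0.25·exp(P·V/Rc). Three model variants are provided: 12 two-state
subgates (49 states, 7×7 blocks, bandwidth 15), 6 three-state subgates with
a deep-closed state (28 states, blocks 7…1), and 12 three-state subgates
(784 states, 28 blocks of 28).

The steady state π (πQ = 0, Σπ = 1) is computed by four solvers that exploit
this block structure to different degrees — dense Gaussian elimination,
banded Gaussian elimination, a block recursive direct method, and
warm-startable block Gauss-Seidel — and `g_j = Σ_i π_i·g_l,i·g_r,i/(g_l,i+g_r,i)`
gives the steady-state g_j–V_j gating curve. Exact operation counts
(`complexity_ledger()`) say when each method wins.

Audience: modelers of connexin/ion-channel gating and anyone who needs fast
repeated steady-state solves of small structured CTMCs (e.g. inside a
parameter-fitting loop).

## Worked example

```r
library(gjgate)

p <- gating_params(A = 0.04, P = 1, K = 0.01, V0 = 25, Ro = 100, Rc = 100)
gen <- build_generator("two_state_12", p, vj = 40)
gen
#> Gap-junction CTMC generator 'two_state_12' at Vj = 40 mV
#>   49 states, 7 blocks, bandwidth m = 15 (k1 = 7, k2 = 7)

res <- solve_steady_state(gen, "block_gauss_seidel", solver_options(epsilon = 1e-6))
res
#> Steady state (block_gauss_seidel): n = 49, outer iterations = 22,
#>   residual = 7.021e-09, converged = TRUE
junction_conductance(res$pi, gen)
#> [1] 4.211229
```

The 49-state generator always has bandwidth 15; block Gauss-Seidel needs 22
outer sweeps at tolerance 1e-6 here, and the channel's conductance at 40 mV
is ~94% of its 0 mV value (4.21 vs 4.48). A full gating curve:

```r
sw <- run_sweep(sweep_config("two_state_12", p, v_start = 0, v_end = 100,
                             v_step = 10, epsilon = 1e-8))
tidy(sw)
#> # A tibble: 11 × 6
#>    vj_mv    gj gj_normalized outer_iterations residual converged
#>  1     0  4.48         1                   26 7.48e-11 TRUE
#>  5    40  4.21         0.939               29 7.02e-11 TRUE
#> 11   100  3.19         0.712               28 8.12e-11 TRUE
autoplot(sw)          # normalized g_j–V_j curve, even in V_j
```

`gj_normalized` falls from 1 to 0.71 over 0–100 mV: the symmetric decay of
junctional conductance under voltage. With `warm_start = TRUE` (the default),
each solve on a fine grid is seeded with the previous voltage's solution,
roughly halving total outer iterations on a 0.1 mV grid.

Operation counts, exact integers independent of hardware:

```r
complexity_ledger("two_state_12")
#>   method                  n    ops  kind               note
#> 1 standard_ge            49  81928  direct total
#> 2 banded_ge              49   3136  direct total       bandwidth m = 15
#> 3 block_recursive        49   3514  direct total       block size 7
#> 4 block_gauss_seidel     49    854  per outer sweep
#> 5 bgs_vs_standard_ge     49     96  break-even sweeps
#> 6 bgs_vs_block_recursive 49      4  break-even sweeps
```

So block Gauss-Seidel beats standard Gaussian elimination whenever it
converges in fewer than 96 sweeps, and the block recursive method is
81928/3514 ≈ 23-fold cheaper than standard elimination.

A thin command-line front end is included:

```sh
Rscript inst/cli/gjgate.R sweep --model two12 --v-start 0 --v-end 100 \
    --v-step 0.1 --method bgs --epsilon 1e-6 --warm-start --out sweep.csv
Rscript inst/cli/gjgate.R complexity --model two12
```

## Documentation

The methods vignette (`vignettes/gap-junction-gating.Rmd`) documents the
model assumptions, every tunable parameter with units and defaults, the
solver stopping rules and their accuracy implications, the design choices
behind the deep-closed state and the voltage-division convention, and known
limitations. Shipped parameter files are synthetic reference sets, not fits
to experimental recordings.
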