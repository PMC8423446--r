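# fluctlearn

Simulation and analysis toolkit for regulatory circuits that **learn the
fluctuation statistics of their environment** — the variance, correlations
and dominant direction of a stochastically fluctuating demand — and use that
information to tune their own responsiveness.

## The science

A cell's production rates **P**(t) should track external demands **D**(t)
that fluctuate too fast to follow exactly; fitness is the negated mean
squared mismatch, the *performance* −⟨Σᵢ(Pᵢ−Dᵢ)²⟩. The demand follows an
Ornstein–Uhlenbeck process,

    D(t+Δt) = D(t) − M (D(t) − D̄) Δt + √(2ΓΔt) η,

whose stationary covariance Γ·M⁻¹ defines the *fluctuation structure*: Γ
sets the magnitude, the eigenvectors of M the preferred direction. The
structure itself changes across *epochs* — too fast for evolution to track,
slow enough for physiology to learn.

The package implements:

* **SEPI**, simple end-product inhibition (x = P/D, P = a, τₐ·ȧ = 1 − x):
  a baseline that adapts to any static demand but has fixed responsiveness;
* the **learning architecture** — SEPI plus an excess of regulators
  (Nₐ > Nₓ), self-activation and a rectifying nonlinearity:

      xᵢ = Pᵢ/Dᵢ,   Pᵢ = Σμ σμᵢ aμ,
      τₐ ȧμ = aμ · max{d, Σᵢ σμᵢ (1 − xᵢ)} − κ aμ,

  whose opposing regulator pairs rectify fluctuations: the pair difference
  encodes the demand mean, the pair sum grows with the fluctuation
  magnitude and sets the responsiveness ℛ = τₐ⁻¹ Σμ aμ σμσμᵀ. In two
  dimensions the dominant eigenvector of ℛ is the circuit's **learned
  angle**, which recovers the input's dominant fluctuation direction;
* two **biochemical implementations** (an allosteric enzyme pair and a
  bifunctional-enzyme homeostasis circuit) showing the mechanism survives
  realistic Hill-function kinetics;
* the **optimality ceiling**: the linear-quadratic tracking optimum for
  known (M, Γ) under a Control Input Power budget (CIP = ⟨‖Ṗ‖²⟩), solved
  via an algebraic Riccati equation, for matched-effort comparisons —
  including misspecified ceilings that assume the demand components are
  independent;
* **analysis and sweep drivers** (performance/CIP reports, finite-difference
  responsiveness, learning-threshold detection, Γ/anisotropy/ablation
  sweeps) and a config-driven command line entry point
  (`inst/cli/fluctlearn.R`).

## Worked example

One metabolite, an activator/repressor pair, three epochs of rising
fluctuation strength:

```r
library(fluctlearn)

sched   <- variance_schedule(c(0.02, 0.06, 0.18), duration = 2000, dt = 1e-3)
demand  <- simulate_demand(sched, seed = 1)
circuit <- simulate_learning(demand, regulator_geometry(2, 1),
                             discard = 0.3, record_every = 64L)
sepi    <- simulate_sepi(demand, discard = 0.3, record_every = 64L)

data.frame(epoch = 1:3, gamma = c(0.02, 0.06, 0.18),
           a_diff = circuit$mean_a[, 1] - circuit$mean_a[, 2],
           a_sum  = circuit$mean_a[, 1] + circuit$mean_a[, 2],
           performance      = circuit$epoch_stats$performance,
           sepi_performance = sepi$epoch_stats$performance)
#>   epoch gamma a_diff a_sum performance sepi_performance
#> 1     1  0.02  0.992  19.2    -0.01080          -0.0187
#> 2     2  0.06  0.999 161.4    -0.00697          -0.0595
#> 3     3  0.18  1.008 649.6    -0.00568          -0.2256
```

Reading the numbers: the pair difference `a_diff` stays pinned at the mean
demand (≈ 1) in every epoch, while the pair sum `a_sum` — the stored
responsiveness — grows thirty-fold as Γ rises ninefold. Consequently the
learning circuit's performance stays essentially flat, while SEPI's
mismatch grows in proportion to Γ (−0.019 → −0.23).

In two dimensions the circuit learns the *direction* of fluctuations and
approaches the matched-effort optimum:

```r
env  <- ou_params(dbar = c(1, 1), M = anisotropy_matrix(pi / 4),
                  gamma = 0.05, dt = 1e-3)
dem2  <- simulate_demand(env, seed = 2, duration = 3000)
circ2 <- simulate_learning(dem2, regulator_geometry(5, 2),
                           discard = 0.5, record_every = 64L)
R <- responsiveness_analytic(circ2$mean_a[1, ], circ2$geometry, circ2$params)
learned_angle(R) * 180 / pi        # input direction was 45 degrees
#> [1] 39.4
ceiling_at_cip(env, circ2$epoch_stats$cip)  # best possible at the same CIP
#> [1] -0.0103
circ2$epoch_stats$performance
#> [1] -0.0123
```

The learned angle lands within six degrees of the true 45° input, and the
circuit reaches ~84% of the full-knowledge ceiling at its own Control Input
Power.

## Command line

```sh
Rscript inst/cli/fluctlearn.R variance-epochs --seed 1 --out out/
Rscript inst/cli/fluctlearn.R gamma-sweep --config my.yaml --quick
```

Protocols: `variance-epochs`, `angle-epochs`, `gamma-sweep`,
`anisotropy-sweep`, `ablation-grid`, `biochem`, `ceiling`. Each run writes
CSV outputs, a JSON report and a manifest from which it is regenerable.
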