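# seivdyn

Analysis toolkit for an SEIV (susceptible–exposed–infectious–vaccinated)
compartmental model of childhood diseases with partial permanent
immunity, waning vaccination and disease-caused death.  It is aimed at
infectious-disease modellers who want the full threshold/bifurcation
workup of this model family as tested, reusable code: reproduction
numbers, equilibria, local and global stability, backward-bifurcation
diagnostics, Hopf detection, and stiff simulation.

## The model

$$
\begin{aligned}
\dot S &= (1-p)A + \omega V + \tau I - \mu S - \beta S I(1+\alpha I),\\
\dot V &= pA - (\omega+\mu)V,\\
\dot E &= \beta S I(1+\alpha I) - (\mu+\sigma)E,\\
\dot I &= \sigma E - (\mu+\tau+\epsilon)I,
\end{aligned}
$$

where `A` is recruitment, `p` the vaccinated fraction of recruits,
`omega` the waning rate, `mu` natural mortality, `beta` transmission,
`alpha` the incidence nonlinearity, `sigma` the latency progression
rate, `tau` the treatment/return rate (treated individuals become
susceptible again — partial permanent immunity), and `epsilon` the
disease-caused death rate.  The basic reproduction number, from the
next-generation matrix at the disease-free equilibrium, is

$$
R_0 = \frac{\sigma\beta A[\mu(1-p)+\omega]}
           {\mu(\mu+\omega)(\mu+\sigma)(\mu+\tau+\epsilon)} .
$$

Two auxiliary thresholds `R0*` and `R1*` and the critical nonlinearity
`alpha0` decide the endemic-equilibrium count and whether the
bifurcation at `R0 = 1` is forward or backward; a Routh–Hurwitz margin
`h(tau) = c1*c2 - c3` detects Hopf bifurcations in the treatment rate.
The methods vignette (`vignettes/seiv-dynamics.Rmd`) derives and
documents all of it, including two sign errata in commonly printed
formulas and a set of reported example values that the model's own
equations contradict.

## Worked example

```r
library(seivdyn)

prm <- example2_params(tau = 20)   # endemic regime
seiv_thresholds(prm)
#> SEIV threshold set
#>   M         = 137.38   (sigma*tau*(mu+omega) = 63.84)
#>   R0        = 48.1293
#>   R0*       = -234.932
#>   R1*       = 267.652
#>   alpha0    = 2.78055e-05
#>   beta*     = 1.03887e-06

endemic_equilibria(prm)
#> SEIV equilibria  [case: one-endemic | branch: R1*>1 ]
#>   P0: S = 4.14286e+07, V = 8.57143e+06
#>   P*1: S = 731552, V = 8.57143e+06, E = 33330.1, I = 35329  (residual 2.3e-10)

eq <- endemic_equilibria(prm)
endemic_stability(eq$endemic[[1]], prm)$verdict
#> [1] "unstable"

hopf_scan(prm, 1, 100, n_grid = 32)
#> Hopf scan over tau in [1, 100] (32 grid points, 0 skipped)
#>   no sign change of c1*c2 - c3
```

`R0 = 48.13 > 1`, so the disease invades and a unique endemic state
exists (`R1* > 1` branch).  At `tau = 20` that state is locally
unstable — the Jacobian carries the complex pair `0.717 ± 4.807i` — and
simulation (`seiv_simulate()` + `asymptotics()`) shows a sustained
large-amplitude limit cycle rather than convergence.  The Hopf scan
finds no critical `tau` on `[1, 100]` for this regime;
`discrepancy_report()` tabulates how these recomputed values differ
from previously reported ones.

A vaccine-dominated counterpart:

```r
ts <- seiv_thresholds(example1_params())
round(ts$M, 4);  signif(ts$R0, 5)
#> [1] 168.8254
#> [1] 0.00031987
dfe_global_condition(example1_params())
#> Disease-free global condition: R0(1 + alpha*A/mu) = 0.00111953
#>   globally stable: TRUE | branch: R1*>1
```

Here `R0 << 1` and the Lyapunov quantity is below 1, so the
disease-free equilibrium `(50001, 450000, 0, 0)` is globally stable:
epidemics die out for any starting state.

A thin CLI over the same functions ships in `inst/exec/seiv`
(`seiv thresholds --config cfg.json`, `seiv hopf-scan --config cfg.json
--tau-min 1 --tau-max 100`, ...), with JSON configs (`scenario_config()`,
`write_config()`) and CSV/JSON outputs.

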