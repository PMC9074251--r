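# nrtlle

Liquid–liquid equilibrium (LLE) modelling for solvent-extraction recovery
of dilute fermentation products, built around the Non-Random Two-Liquid
(NRTL) activity-coefficient model. The motivating application is the
recovery of butyric acid from fermentation broth with a high-boiling
ester solvent (octyl acetate): the broth holds only a few percent of acid
in water, so the acid is pulled into a small organic stream by a
countercurrent extractor before any distillation happens, and the whole
design rests on a reliable LLE model regressed from tie-line data.

The package provides, as composable functions plus a small CLI:

* **Thermodynamics** — multicomponent NRTL activity coefficients
  (`activity_coefficients()`), the reduced Gibbs free energy of mixing
  $\Delta G_{mix}/RT = \sum_k \sum_i l_i^k (\ln x_i^k + \ln \gamma_i^k)$
  (`gibbs_mixing_reduced()`), and a tangent-plane stability test
  (`stability_test()`).
* **Flash and diagrams** — an isothermal two-liquid-phase flash solving
  $x_i^I = z_i/\{1 + (K_i-1)L^{II}\}$, $x_i^{II} = K_i x_i^I$,
  $K_i = \gamma_i^I/\gamma_i^{II}$ (`lle_flash()`), and binodal/tie-line
  tracing for ternary diagrams (`binodal_curve()`).
* **Parameter estimation** — a *non-iterative* tie-line-constrained
  K-value regression (`estimate_nrtl()`): the feed is pinned on each
  measured tie-line by collinearity, the organic fraction comes from the
  Euclidean lever rule, and the K-values are evaluated one-shot at the
  measured compositions, so no flash iteration runs inside the objective.
  Accepted fits must pass a Gibbs-energy feasibility check on every
  tie-line.
* **Extractor simulation** — a steady-state countercurrent multistage
  equilibrium cascade (`simulate_extractor()`) with recovery,
  distribution-coefficient/selectivity and lever-rule mixing-point
  helpers.
* **Economics** — annualized unit recovery cost
  $(I/t_{payout} + U)/(\dot m\, h_{yr})$ from a cost table
  (`unit_recovery_cost()`, `cost_totals()`).
* **Synthetic data** — seeded demixing systems and noisy tie-line
  datasets (`make_demixing_system()`, `generate_tielines()`) so the whole
  pipeline is testable without external data.

## Worked example

Generate six noisy tie-lines from a known broth-like system, refit the
NRTL parameters with the non-iterative K-value method, and use the fitted
model to design an extraction:

```r
library(nrtlle)

sys <- make_demixing_system("ternary_broth_like", seed = 1)
dat <- generate_tielines(sys, n = 6, noise_sd = 0.003, seed = 7)

fit <- estimate_nrtl(dat, n_starts = 16, seed = 42)
print(fit)
#> NRTL fit: RMS composition deviation 0.002195 over 6 tie-lines
#>   multistart: 16 starts (seed 42), all Gibbs-feasible: TRUE

bc <- binodal_curve(dat$T, fit$params, n_lines = 6)
binodal_rms(bc, dat$truth)
#> [1] 0.00367
```

The fit reproduces the tie-lines to about the injected noise level
(0.003), and the binodal predicted by the refitted parameters matches the
generating truth to 0.0037 RMS mole fraction — parameter values
themselves are not compared, because NRTL parameters are correlated and
only the predicted phase behaviour is identifiable.

```r
feed <- stream(c(water = 97, solute = 3, ester = 0), "feed")
solv <- stream(c(water = 0, solute = 0, ester = 10), "solvent")
res <- simulate_extractor(feed, solv, 16, 298.15, fit$params, tol = 1e-11)
print(res)
#> Countercurrent cascade: 16 stages (converged, 18 sweeps)
#>   extract:   12.86 kmol/h
#>   raffinate: 97.14 kmol/h
#>   balance residual: 1.03e-15
recovery(feed, res$extract, "solute")
#> [1] 0.9875...  (attr "percent": 99)
```

Sixteen stages and a 10:97 solvent-to-feed molar ratio recover 99 % of
the solute into an organic stream an eighth the size of the feed.
Finally, the packaged cost table (extraction plus a three-column
distillation train; totals 1.032 M\$ investment, 0.273 M\$/yr utilities)
gives the annualized recovery cost at a 265 kg/h product rate:

```r
ct <- read_cost_file(system.file("extdata", "recovery_costs.yaml", package = "nrtlle"))
unit_recovery_cost(ct, 265)
#> [1] 0.2261321  (attr "cents": 0.23)   # $0.23 per kg recovered
```

## Command line

A thin CLI over the same functions lives at `inst/cli/nrtlle-cli.R`
(after installation: `system.file("cli", "nrtlle-cli.R", package =
"nrtlle")`), with subcommands `synth`, `fit`, `flash`, `binodal`,
`extract`, `cost`, each taking `--config <yaml>`, `--seed`, `--out` and
`--log-level`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","nrtlle-cli.R",package="nrtlle"))')" \
    synth --config synth.yaml --seed 4 --out run1
```

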