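# tavrcea

Cost-effectiveness modelling of transcatheter versus surgical aortic valve
replacement (TAVR vs SAVR) for intermediate-surgical-risk aortic-stenosis
patients, from the Chinese healthcare payer perspective.

The package is for health economists and HTA analysts who want the published
evaluation as a tested, rerunnable pipeline rather than a spreadsheet: every
input is a declarative parameter (JSON/YAML with a flat CSV audit export),
every stage is an exported function, and every published figure or table has
a corresponding computation.

## The model

A 30-day **decision tree** assigns each arm's cohort its periprocedural
complications (death, disabling/non-disabling stroke, new AF, MI, major
vascular complication, bleeding, AKI, pacemaker) at published marginal
incidences, accrues their one-time costs and one-month disutilities, and
hands a five-state distribution to a **Markov cohort model** — no event,
post-AF, post-disabling stroke, post-non-disabling stroke, death — run for
59 monthly cycles with time-banded transition probabilities (months 2–12,
13–24, 25–60). Costs are discounted at 3.7 %/year (monthly compounded);
utilities are time-banded per arm.

The comparison reports

$$\mathrm{ICER} = \frac{C_\mathrm{TAVR}-C_\mathrm{SAVR}}
                       {E_\mathrm{TAVR}-E_\mathrm{SAVR}}
  \quad\text{[USD/QALY]},\qquad
  \mathrm{NMB}(\lambda)=\lambda\,\Delta E-\Delta C,$$

judged against willingness-to-pay thresholds of 1× and 3× Chinese per-capita
GDP (12,500 / 37,500 USD/QALY). Around the deterministic base case the
package provides one-way (tornado) sensitivity over all published ranges, a
10,000-draw probabilistic sensitivity analysis (beta-distributed
probabilities, gamma-distributed costs, method of moments), cost-
effectiveness acceptability curves, device-price scenario analysis, and a
solver for the device price at which TAVR breaks even. Modelling conventions
and their calibration are documented in the methods vignette
(`vignettes/model-methods.Rmd`).

## Worked example

```r
library(tavrcea)

params <- default_params()     # the full published input set
run_base_case(params)
#> Base case over 60 months:
#>   SAVR:    36130 USD  2.727 QALY
#>   TAVR:    55433 USD  2.835 QALY
#> <ce_result> TAVR vs SAVR: dCost 19304 USD, dQALY 0.1089 (trade_off)
#>   ICER 177321 USD/QALY; NMB -15221 at WTP 37,500; not cost-effective
```

TAVR buys 0.109 extra QALYs over five years but costs ~19,300 USD more —
about 177,000 USD per QALY, far above the 37,500 USD/QALY threshold, so TAVR
is not cost-effective at the current imported-device price. The lever is the
device price:

```r
threshold_device_price(params, wtp = 37500)
#> [1] 29802.72

run_scenarios(params)[, c("scenario", "device_cost", "summary_cost", "icer")]
#>     scenario device_cost summary_cost   icer
#> 1  base_case       15580        36130     NA
#> 2  base_case       45526        55433 177321
#> 3 scenario_1       33846        44126  73455
#> 4 scenario_2       17268        28078 -73966
#> 5 scenario_3       26794        37299  10745
#> 6 scenario_4       29766        40177  37173
```

At the domestic-device price (33,846 USD) TAVR is still not cost-effective;
at the Canadian price (17,268 USD) it dominates SAVR (cheaper *and* more
effective, hence the negative ratio); the break-even device price at the
3×-GDP threshold computes to ≈ 29,800 USD — roughly 65 % of the current
price. Uncertainty:

```r
psa  <- run_psa(params, n_draws = 10000, seed = 1)
ceac(psa, wtp_grid = c(37500, 100000, 170000))
#>      wtp probability
#> 1  37500      0.0265
#> 2 100000      0.1124
#> 3 170000      0.4176

head(one_way_sensitivity(params), 3)   # tornado: device price dominates
```

A command-line wrapper covers the same surface
(`Rscript inst/cli/tavrcea.R all --out results/`), writing CSV reports plus
a manifest that makes every artifact reproducible from its seed.

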