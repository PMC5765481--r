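# dlwtee

Classical and Bayesian estimation of total energy expenditure (TEE) from
doubly labelled water (DLW) experiments.

The DLW method is the reference technique for measuring free-living energy
expenditure: a subject drinks water labelled with both ²H and ¹⁸O, and the
two enrichments are followed in body water for about two weeks. Both labels
leave with water, but ¹⁸O also leaves as CO₂, so the difference between the
two first-order elimination fluxes measures CO₂ production,

    rCO2 = (kO·NO − kH·NH − 27.3(f2−f1)) / (2f3 + 1.1(f2−f1))   (natural spaces, Coward)
    rCO2 = (kO·NO − kH·NH) / (2f3 + 2.1(f2−f1))                  (normalized spaces, Schoeller)

with pool sizes `N` (mol), rate constants `k` (day⁻¹) and fractionation
factors `f1–f3 = 0.941, 0.991, 1.037`. TEE follows from the modified Weir
equation, `TEE = 22.4·(15.48/RQ + 5.55)·rCO2` — 532 kJ per mol CO₂ at
RQ = 0.85.

A long-standing practical controversy is how to handle the dilution-space
ratio `S = NH/NO` (physiologically ≈ 1.03–1.04): use the fitted spaces as
they are, or normalize them to a fixed ratio (1.03 Schoeller, 1.034 IAEA)?
The choice shifts individual TEE estimates by several percent. `dlwtee`
implements both classical routes and a third: a Bayesian model in which the
kinetics are re-parameterized by four physiological quantities — CO₂
production `rCO2`, space ratio `S`, water turnover `R_W` and body-fat
fraction `F` — with an informative prior `S ~ N(1.035, 0.01)` and vague
priors elsewhere, estimated per subject or hierarchically (per sex stratum)
by Metropolis-within-Gibbs MCMC. The hierarchical model shrinks extreme
subjects toward the population, compressing the TEE distribution.

The package is aimed at energy-metabolism and nutrition-survey researchers
who have per-subject dose records and enrichment time series (‰ vs VSMOW)
and want TEE with honest uncertainty. A synthetic-cohort generator with
known ground truth makes every estimator testable without study data.

## Worked example

```r
library(dlwtee)

# a synthetic cohort emulating a survey population (known ground truth)
design <- cohort_design(n_women = 6, n_men = 6, seed = 2026)
sim    <- simulate_cohort(design)
subj   <- sim$subjects[[1]]

classical_tee(subj, method = "exponential", normalize = "none")
#> Subject S01 (exponential fit, normalize=none): TEE = 9627 kJ/day, rCO2 = 18.09 mol/day, S = 1.0336
classical_tee(subj, method = "exponential", normalize = "schoeller")
#> Subject S01 (exponential fit, normalize=schoeller): TEE = 9874 kJ/day, rCO2 = 18.55 mol/day, S = 1.0336

post <- sample_independent(subj, config = mcmc_config(iterations = 20000,
                                                      burnin = 4000, seed = 1))
summary(post)
#>   parameter      mean        sd    median       cv      q2.5     q97.5  rhat    ess
#> 1      rco2   18.2957 5.563e-01   18.2909 0.030406   17.2101 1.939e+01 1.001 1080.3
#> 2         S    1.0341 5.323e-03    1.0341 0.005148    1.0236 1.044e+00 1.000 2426.9
#> 3       R_W  138.4946 1.005e+00  138.4945 0.007255  136.5350 1.405e+02 1.001  993.7
#> 4         F    0.3617 1.857e-03    0.3617 0.005135    0.3581 3.653e-01 1.000 2527.7
#> 5       TEE 9738.1514 2.961e+02 9735.5554 0.030406 9160.3077 1.032e+04 1.001 1080.3
```

The subject's generating truth was `rCO2 = 17.87` mol/day,
`TEE = 9512` kJ/day, `S = 1.0321`: the natural-space classical estimate
(9627 kJ/day), the normalized one (9874 — higher, because the natural
ratio is above the 1.03 target), and the Bayesian posterior median
(9736 kJ/day, CV 3.0%) bracket it. `run_four_arm_analysis()` runs all
four analysis arms (natural, normalized, independent Bayesian,
hierarchical Bayesian) across a cohort and reports per-sex
median (range) tables and Bland–Altman agreement statistics between arms;
`bland_altman()` is also exported directly.

A thin command-line front end covering simulation, classical fits,
Bayesian fits and method comparison is installed at
`system.file("cli", "dlw", package = "dlwtee")`:

```sh
dlw simulate      --out data/ --seed 1
dlw fit-classical --measurements data/measurements.csv --subjects data/subjects.csv \
                  --normalize schoeller --out normalized.csv
dlw fit-bayes     --measurements data/measurements.csv --subjects data/subjects.csv \
                  --mode hierarchical --seed 1 --out bayes.csv
dlw compare       --a natural.csv --b normalized.csv --out ba.json
```

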