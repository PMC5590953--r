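# gmrfish

Bayesian hierarchical spatio-temporal modelling of fish abundance from
research trawl surveys, with diagnostics for the spatial erosion of stock
structure.

Collapses of heavily fished stocks have repeatedly been preceded by a
pattern that aggregate indices miss: densities in core areas stay high
while the occupied area contracts (hyperstability under local
overfishing). `gmrfish` targets exactly that failure mode. It fits a
latent Gaussian field model to per-set trawl counts and summarises the
stock's spatial structure with three parameters — **connectivity** ρ (the
spatial correlation range), **spatial variance** σ (contrast between
high- and low-density areas) and **persistence** a (year-to-year coupling
of the spatial pattern) — then tracks per-year (ρ_t, σ_t) trajectories
and classifies year-to-year movements as erosion, recovery, fluctuation
or stable. A simultaneous jump to larger ρ and smaller σ (the field
flattening) is the erosion signature.

## The model

Counts y(s,t) per trawl set at location s in year t:

    y(s,t) ~ NB(mu(s,t), n),   Var = mu (1 + mu/n),   phi = log n
    log mu(s,t) = beta0 + xi(s,t) + sum_j f_j{c_j(s,t)}

with smoothed covariate effects f_j (piecewise linear, random-walk-2
penalty) and a spatio-temporal random effect

    xi(s,t) = a xi(s,t-1) + omega(s,t),   |a| < 1

whose innovations have Matern (nu = 1) spatial covariance
C(h) = (kappa h) K_1(kappa h), with range rho = sqrt(8)/kappa — the
distance at which correlation drops to about 0.1 (exactly 0.1397). The
field is represented as a Gauss-Markov random field via the SPDE
finite-element discretisation on a triangulated domain (precision
Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)), so everything runs on
sparse Cholesky factorizations. Penalized-complexity priors shrink toward
the structureless base model (rho = Inf, sigma = 0), calibrated by
P(rho < 0.5) = 0.5 and P(sigma > 0.75) = 0.5 by default. Inference is a
nested Laplace approximation: Newton on the latent field inside,
empirical-Bayes optimization plus a small weighted grid over the
hyperparameters outside. Model comparison uses DIC, W-fold
cross-validated CPO/LPML and RMSEE.

Everything — mesher, FEM assembly, precision algebra, Laplace engine,
assessment, diagnostics, survey simulator — is implemented in this
package on top of `Matrix`.

## Worked example

Simulate a six-year survey (120 sets/year on a unit-square domain, true
rho = 0.3, sigma = 1.5, a = 0.6, phi = 1, intercept 2) and refit it:

```r
library(gmrfish)
sc <- scenario_config(n_years = 6, sets_per_year = 120, rho = 0.3,
                      sigma = 1.5, a = 0.6, phi = 1, intercept = 2,
                      seed = 42, domain = cbind(c(0,1,1,0), c(0,0,1,1)),
                      covariate_effects = list(), mesh_max_edge = 0.08)
survey <- simulate_survey(sc)
spec <- model_spec(spatial = "ar1", family = "negative_binomial")
fit <- fit_abundance_model(spec, survey,
                           mesh_args = list(max_edge = 0.15, cutoff = 0.05))
fit
#> gmrfish fit: ar1 spatial structure, negative_binomial family
#>   rho = 0.375  sigma = 1.56  a = 0.5288  phi = 0.8227
#>   n_obs = 720, log posterior at mode = -2210.544
d <- dic(fit)
sprintf("DIC = %.2f (p_D = %.1f), RMSEE = %.2f", d$dic, d$p_d, rmsee(fit))
#> "DIC = 4147.96 (p_D = 251.8), RMSEE = 23.48"
```

The hyperparameter mode lands near the generating values (rho 0.38 vs
0.3, sigma 1.56 vs 1.5, a 0.53 vs 0.6); `p_D` of roughly 250 reflects the
effective size of the latent field the 720 observations support, and
RMSEE is on the count scale of the simulated survey.

Now an engineered collapse — aggregations of constant peak density whose
extent crashes mid-window — followed by per-year fits and the classifier:

```r
sc <- scenario_config(n_years = 6, sets_per_year = 200, seed = 2,
                      collapse_window = c(2, 6), covariate_effects = list())
survey <- simulate_collapse(sc)
traj <- annual_parameter_series(model_spec(spatial = "constant"), survey,
                                mesh_args = list(max_edge = 0.4, cutoff = 0.13))
erosion_classify(traj)
#>   from   to dlog_rho dlog_sigma       label
#> 1 2001 2002  -0.0268     0.0364 fluctuation
#> 2 2002 2003  -0.1754    -0.0757 fluctuation
#> 3 2003 2004   1.7068    -1.1413     erosion
#> 4 2004 2005  -0.0382     0.2362      stable
#> 5 2005 2006  -1.1141    -0.2033      stable
```

The crash year is flagged as erosion: ρ_t jumps from 0.72 to 3.94 degrees
while σ_t falls from 1.54 to 0.49 — the fitted field flattens exactly
when the aggregations drop below the survey's resolution, even though the
true peak density never changed. `core_range_mask()` renders the same
story as 75th-percentile core-range maps with patch areas, maxima and
separations (in units of ρ), and `relative_exploitation()` joins landings
shares to survey-abundance shares per sub-zone.

A command-line wrapper covering the whole pipeline
(`simulate | fit | assess | annual | diagnose | predict`) is installed at
`inst/cli/gmrfish.R`:

```sh
Rscript inst/cli/gmrfish.R simulate --out run1 --seed 3
Rscript inst/cli/gmrfish.R fit --data run1/survey.csv --out run1
Rscript inst/cli/gmrfish.R assess --data run1/survey.csv --out run1 --folds 5
```

See `vignettes/spatial-stock-structure.Rmd` for the model, priors,
numerical choices, the design of the synthetic generator and the known
limitations.

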