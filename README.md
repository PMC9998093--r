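# isodesmix

Self-consistent SAXS refinement of oligomer distributions and
conformational ensembles for linearly self-associating proteins.

## The problem

A protein that polymerises into linear filaments produces SAXS data that
average over *which* oligomers are in solution and over *what each
oligomer looks like*. `isodesmix` fits both at once against a
concentration series of SAXS experiments:

- the **species distribution** from the isodesmic model — a single
  association constant $K_A$ for every subunit-addition step, free
  protomer $c_1 = (2c_{tot}K_A + 1 - \sqrt{4c_{tot}K_A + 1})/(2c_{tot}K_A^2)$,
  geometric ladder $c_i = c_1 (K_A c_1)^{i-1}$, volume fractions
  $\phi_i = i c_i / \sum i c_i$ — or dimer–n-mer alternatives for model
  comparison;
- the **conformational weights** of each oligomer by Bayesian/maximum-
  entropy (BME) reweighting, minimising
  $L(w) = \frac{m}{2}\chi_r^2(w) - \theta S_{rel}(w)$ against a
  per-species curve deconvoluted from the mixture signal,
  $\langle I\rangle_{i,extr} = (I_{exp} - \langle I\rangle_{mix,rest})/\phi_i$.

The outer loop iterates scale/background fitting, a Metropolis
simulated-annealing fit of the global $K_A$, and per-species BME
reweighting with a decaying confidence parameter $\theta$ that freezes
per species once the fraction of effective frames drops below a cut-off.
Around the core sit a splice-based builder for long helical oligomer
ensembles with clash rejection, a Debye-formula forward model
(I(0) normalised to subunit count), filament geometry analytics
($R_g$, end-to-end scaling $R = R_0 N^\nu$, domain distances),
degenerate-motif spacing analysis for disordered substrates, a CG-MALS
average-molecular-weight fit, and a synthetic-data generator so that the
entire pipeline is testable offline.

## Worked example

```r
library(isodesmix)

# synthetic study conditions: 5-40 uM monomer series, KD_true = 1.6 uM,
# 1% noise; scaled to 8 species / 20 conformers for a quick run
sim <- simulate_series(synthetic_spec(), kd_true = 1.6,
                       n_conformers = 20, nmax = 8,
                       q = seq(0.01, 0.4, length.out = 20), seed = 101)
fit <- refine_saxs(sim$series, sim$ensembles,
                   outer = outer_schedule(n_iterations = 50),
                   ka_start = 1, seed = 11)
glance(fit)
#> # A tibble: 1 x 9
#>      kd    ka chi2r_global_initial chi2r_global n_experiments n_species
#>   <dbl> <dbl>                <dbl>        <dbl>         <int>     <int>
#> 1  1.59 0.630                 3.77        0.673             6         8
#> # i 3 more variables: n_iterations <int>, n_frozen <int>, min_phi_eff <dbl>
```

The fitted dissociation constant `kd` (µM, protomer units) recovers the
generative 1.6 µM; `chi2r_global` is the mean reduced chi-square across
the series after refinement (values near 1 mean the model fits within
the noise), and `min_phi_eff` says how much of the prior ensembles the
reweighting retained (1 = untouched). `tidy(fit)` returns per-conformer
weights per experiment with their signal-share average; `autoplot(fit)`
plots the chi-square trajectory. `kd_error_scan()` turns the fit into an
uncertainty interval (all KD within 10% of the minimum chi-square), and
`leave_one_out()` reproduces the four-cell held-out validation used to
choose the reweighting cut-off. See the vignette
(`vignettes/self-consistent-saxs-refinement.Rmd`) for the model details.

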