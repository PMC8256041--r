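# tcrmech

Quantitative analysis of T cell receptor (TCR) mechanosensing, for
structural immunologists and single-molecule biophysicists. The package
implements the two bespoke computations that decide whether a TCR behaves as
a mechanosensor:

1. **Interdomain contact occupancy on MD trajectories.** Hydrogen bonds are
   detected as donor-hydrogen/acceptor pairs within 2.4 Å; nonpolar contacts
   as atom pairs with |partial charge| < 0.3 *e* within 3.0 Å, aggregated
   per residue pair. Occupancy — the fraction of frames in which a contact
   is present — is computed in overlapping time windows (ten 36.4-ns
   windows with 50% overlap over a 100–300 ns interval by default), and
   interfaces are summarised as the mean ± SD (over windows) of the number
   of contacts with occupancy strictly greater than 80%, with Welch t-tests
   between constructs. Shrake–Rupley solvent-accessible and buried surface
   areas quantify interface size.

2. **Optical-trap force spectroscopy of single TCR–ligand bonds.** Traces of
   bead–trap separation are segmented into loading ramp, force-clamp dwell
   and rupture (the bead's snap-back to the trap center at 0 nm);
   conformational transitions appear as smaller steps toward the trap
   center during the dwell. Bond events are binned into force–lifetime
   curves (mean ± SEM), and lifetimes are fit by maximum likelihood to a
   dual-pathway Bell model

   k(F) = k_c · exp(−F·x_c / k_BT) + k_s · exp(+F·x_s / k_BT),   τ(F) = 1/k(F)

   whose interior lifetime maximum at
   F\* = k_BT · ln(k_c·x_c / (k_s·x_s)) / (x_c + x_s) distinguishes a
   *catch bond* (lifetime grows with force up to F\*) from a *slip bond*
   (monotone decay), via a likelihood-ratio test against the slip-only
   nested model. The *sensitivity index* — the ratio of mean bond lifetime
   for the specific versus the nonspecific ligand at matched force — scores
   ligand discrimination.

Because cluster-scale MD runs and wet-lab trap data are not portable,
`tcrmech` ships first-class synthetic-data generators with known ground
truth: trajectories with planted per-frame contact probabilities (iid or
two-state Markov), and trap traces drawn from dual-pathway kinetics with
loading ramp, optional transition steps and Gaussian bead noise. Every
analysis stage is validated against these generators.

## Worked example

Simulate a force-clamp experiment in the "chimera-like" regime (a catch
bond engineered to peak at 5 s near 15 pN), run the full trace-analysis
pipeline, and fit the bond model:

```r
library(tcrmech)

make_windows(100, 300, count = 10)
#> # A tibble: 10 × 3
#>   window start   end
#>    <int> <dbl> <dbl>
#> 1      1  100   136.
#> 2      2  118.  155.
#> 3      3  136.  173.
#> # ℹ 7 more rows

p <- demo_params("chimera", noise_sd = 2)
sim <- simulate_experiment(c(7.5, 12.5, 15, 17.5, 22.5), 30, p, seed = 42)
events <- analyze_traces(sim$traces)
fit <- fit_bond_model(dplyr::filter(events, !censored))
fit
#> <dual_pathway_fit> catch bond (n = 150)
#>   k_c = 7.452 1/s, x_c = 1.134 nm, k_s = 0.0003931 1/s, x_s = 1.329 nm
#>   peak force 16.19 pN, peak lifetime 6.28 s
#>   LRT vs slip-only: stat 59.6, p = 1.17e-13
```

The fit correctly classifies the bond as a catch bond with its lifetime
peak (6.3 s near 16 pN here, at n = 150 events) close to the generator's
true peak of 5 s at 15 pN; `tidy(fit)` and `glance(fit)` return the
parameters and the one-row summary as tibbles, and
`autoplot(lifetime_curve(events), fit = fit)` draws the force–lifetime
curve with SEM error bars and the fitted model.

The contact pipeline is driven the same way — see `?run_contact_pipeline`
for a config-file interface that reads a trajectory plus charge table,
resolves named domains (e.g. a Vγ domain as chain G residues 1–119),
and writes occupancy tables, per-interface summaries and pairwise Welch
comparisons with full provenance headers.

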