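# gbspopgen

Population-genomic analysis of genotyping-by-sequencing (GBS) SNP data
sampled along an urbanization gradient — for plant and landscape
geneticists who have a filtered-or-raw VCF, sampling coordinates, and two
questions:

1. **Does urbanization structure genetic variation?** Diversity (π,
   Watterson's θ, windowed Tajima's D, F_IS), differentiation (pairwise
   Hudson F_ST, hierarchical AMOVA, PERMANOVA, PERMDISP) and spatial
   structure (PCA, Mantel correlograms, Moran-eigenvector-map regression)
   between urban and rural habitats.
2. **What happened to effective population size (N_e)?** A folded
   site-frequency-spectrum (SFS) reconstruction of piecewise-constant N_e
   by composite likelihood with SNP bootstrap, followed by segmented
   regression of ln(N_e) on time to delimit periods of constant
   exponential growth or decline.

The core model of the second question: under exponential change at rate
*r* per year, `N_e(t) = N_e(0) * (1+r)^t`, so ln N_e against
years-before-sampling *t* is piecewise linear with slope `b = ln(1+r)` per
period. `fit_piecewise()` estimates the change points by Muggeo-style
iterative linearization and converts each segment's slope to a growth rate
with its 95% CI via `r = -(e^b - 1)` (sign reverted because the trajectory
runs backward in time).

Everything is testable without real data: a built-in coalescent simulator
(piecewise-constant N_e, two-deme island models with calibrated expected
F_ST = 1/(1+M), GTA-style sampling landscapes, missingness and sib
planting) generates VCF + metadata + truth sidecars, byte-reproducibly
from a seed.

## Worked example

Simulate a 100-fold decline (ancestral N_e = 25,000 dropping to 250 at
500 generations ago), rebuild the folded SFS, reconstruct the trajectory
and run the breakpoint analysis:

```r
library(gbspopgen)

scn  <- simulation_scenario("decline", n_individuals = 50,
                            n_loci = 12000, mu = 2e-7)
sim  <- simulate_coalescent(scn, seed = 1)
sfs  <- build_folded_sfs(sim$geno, n_chrom = 80)
traj <- infer_ne_trajectory(sfs, demography_config(mu = 2e-7,
                                                   n_bootstrap = 50,
                                                   seed = 1))
print(traj)
#> ne_trajectory: 14 epochs, 2 free sizes, 50 bootstrap replicates (0 non-converged)
#>     t_years  ne_median      ne_lo      ne_hi
#>     0.00000   237.5034   157.0209   307.0355
#>    56.45228   237.5034   157.0209   307.0355
#>    98.53844   237.5034   157.0209   307.0355
#>   172.00056   237.5034   157.0209   307.0355
#>   300.22995   239.7053   161.3084   322.4964
#>   524.05658   257.8460   204.7014 20963.6417
#>   914.74985 20001.5429   224.3066 28310.4562
#>  1596.71172 24765.4520 17458.5392 54620.5141
#>   ...
```

The recent median (~238) against the ancient median (~25,000) recovers
the two-orders-of-magnitude decline, with the transition placed near
1,000 years ≈ 500 generations at the two-year generation time. Feeding
the trajectory to the breakpoint model:

```r
bp <- fit_piecewise(subsample_years(traj), k_breakpoints = 8)
summary(bp)
```

reports per-period slopes `b` with 95% CIs and the derived rates `r`; a
period with `r` significantly below zero is a supported decline. On this
run the fitted single dominant period carries
`r = -3.5e-4 [-3.95e-4, -3.07e-4]` per year — a CI that excludes zero
with the declining sign.

The whole pipeline — filtering presets, habitat classification under both
schemes, all diversity/differentiation/spatial analyses, demography and
breakpoints, with every artifact written as TSV/JSON — runs from one call:

```r
cfg <- pipeline_config(scenario = "decline", out_dir = "run1", seed = 1)
run_pipeline(cfg)
```

or from the shell via `inst/scripts/gbspopgen-cli.R`
(`simulate`, `filter`, `run-all` subcommands, YAML config). Reruns with
the same configuration are byte-identical.

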