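# kappa2sim

Monte-Carlo estimation of the FRET orientation factor κ² for
membrane-embedded fluorophores.

## What problem this solves

Quantitative FRET analyses need the orientation factor

    κ² = (û_D · û_A − 3 (r̂ · û_D)(r̂ · û_A))²,   0 ≤ κ² ≤ 4,

which couples the donor and acceptor transition dipoles û_D, û_A to the
unit separation vector r̂.  Since the Förster radius scales as (κ²)^(1/6),
the ubiquitous shortcut ⟨κ²⟩ = 2/3 (the dynamic isotropic limit) can bias
recovered distances and acceptor densities — especially in lipid
bilayers, where probes sit at preferred depths and tilts.

`kappa2sim` is aimed at membrane biophysicists who know (from linear
dichroism, polarized microscopy or MD simulation) each probe's most
probable tilt θ_max relative to the membrane normal and the spread σ of
its cosθ distribution.  From those inputs it computes, in the dynamic
regime:

- the distribution and mean of κ² for donors and acceptors in parallel
  planes (one leaflet, both leaflets, or a 3D slab);
- the distance-weighted average ⟨κ²⟩ = Σκ²ᵢRᵢ⁻⁶ / ΣRᵢ⁻⁶, the natural
  average when each donor sees many acceptors, because the transfer rate
  to acceptor i scales as κ²ᵢ/Rᵢ⁶;
- closed-form references for validation: the isotropic κ² density, and
  the Knoester–van Himbergen curve ⟨κ²⟩ = 2/3 − (2/3)S + S² with
  S = P₂(cosθ) for identically oriented planar dipoles;
- the planar donor decay law (lower incomplete-gamma kinetics) and
  universal FRET-efficiency curves E(σ_c) for given α = R̄₀/R_e and
  β = (3/2)⟨κ²⟩.

A catalogue of common membrane probe pairs (t-PnA, DPH, NBD,
carbocyanine, Rhodamine B, BODIPY) is bundled with literature depths and
orientation parameters.

## Worked example

```r
library(kappa2sim)

# identical in-plane dipoles (theta = 90 deg, no spread), coplanar:
res <- simulate_unweighted(angular_spec(90, 0), angular_spec(90, 0),
                           geometry_config(n = 1e6, h = 0), seed = 1)
res
#> <kappa2_result> mode = unweighted, 1e+06 pairs
#>   mean kappa^2 (unweighted): 1.2530
#>   max sampled kappa^2: 4.0000

knoester_mean(90)   # closed-form value for this configuration
#> [1] 1.25
```

The simulated mean 1.2530 agrees with the analytic 1.25 to within the
Monte-Carlo error (the spread of κ² here gives a standard error of about
0.0015 at 10⁶ pairs).

For a bilayer with acceptors in both leaflets (planes at 0 and 2 nm,
exclusion 0.8 nm), the R⁻⁶-weighted average is dominated by the closest
pairs, so single runs are noisy and the protocol repeats over seeds:

```r
g <- geometry_config(n = 1e6, h1 = 0, h2 = 2, re1 = 0.8, re2 = 0.8)
repeat_runs(simulate_weighted, angular_spec(90, 0), angular_spec(90, 0),
            g, n_repeats = 10, base_seed = 1)
#> <repeat_summary> 10 runs: <kappa^2> = 1.2534 (sd 0.0588)
```

The grand mean sits slightly below the single-plane value 1.25 pulled by
the far leaflet — here within its standard error of it.  Finally, the
effect on the observable:

```r
efficiency_curve(0.5, 1.25, c(1, 3, 5))
#>   sigma_c efficiency
#> 1       1 0.05478054
#> 2       3 0.14824834
#> 3       5 0.22501048
```

`sigma_c = πR̄₀²c` is the expected number of acceptors within a Förster
radius; at α = 0.5 these efficiencies are more than three times those
obtained with ⟨κ²⟩ = 0.30, which is why the orientation factor matters
when R̄₀ is comparable to the contact distance.

## Command line

A thin CLI wraps the same functions (installed under
`inst/exec/kappa2sim`, or call `kappa2sim_cli()` directly):

```sh
kappa2sim run --mode weighted --theta-d 90 --theta-a 90 \
  --h1 0 --h2 2 --re1 0.8 --re2 0.8 --n 1000000 --repeats 10 \
  --seed 1 --out results/
kappa2sim analytic --curve knoester --out knoester.csv
kappa2sim efficiency --alpha 0.5 --kappa2 1.25 --sigma-max 5 --out eff.csv
kappa2sim preset list
kappa2sim preset run rhodamineB_homo --seed 1
```

YAML config files mirroring the flags are accepted via `--config`.

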