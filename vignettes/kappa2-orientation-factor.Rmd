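---
title: "Estimating the FRET orientation factor for membrane probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the FRET orientation factor for membrane probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappa2sim)
```

## The problem

The rate of Förster resonance energy transfer between a donor and an
acceptor fluorophore depends on the relative orientation of their
transition dipoles through the orientation factor

$$\kappa^2 = \left(\hat u_D \cdot \hat u_A
  - 3\,(\hat r \cdot \hat u_D)(\hat r \cdot \hat u_A)\right)^2
  \in [0, 4],$$

where $\hat r$ is the unit vector joining the two fluorophores.  Because
the Förster radius scales as $(\kappa^2)^{1/6}$, analyses almost always
substitute the dynamic isotropic average $\langle\kappa^2\rangle = 2/3$ —
a good assumption in fluid solvents, but questionable in lipid bilayers,
where probes sit at preferred depths and tilt angles and reorient within
restricted ranges.

`kappa2sim` estimates the full distribution and average of $\kappa^2$ for
membrane-embedded probes in the *dynamic* regime (reorientation fast
relative to the donor lifetime), by Monte-Carlo sampling of positions and
orientations.  The inputs are quantities that linear dichroism, polarized
microscopy or molecular-dynamics studies actually provide: the most
probable tilt $\theta_{max}$ of each dipole relative to the membrane
normal, and the spread $\sigma$ of its $\cos\theta$ distribution.

## Orientation model

Each dipole's tilt cosine is drawn from
$\mathcal N(\cos\theta_{max}, \sigma)$ truncated to $[-1, 1]$, with the
azimuth uniform on $[0, 2\pi)$.  Truncation is by rejection: out-of-range
draws are redrawn (never clipped), so the sampled law is the exact
truncated normal.  Redrawing only the offending fluorophore is
statistically identical to redrawing the pair, because the two draws are
independent; the per-fluorophore variant is implemented.  A guard caps the
rejection loop at $10^6$ passes and raises an error rather than silently
truncating; with any admissible $(\theta_{max}, \sigma)$ the acceptance
probability per pass is far too high for the cap to be reachable.

Normal deviates come from the Box–Muller transform by default, for strict
replication of the reference algorithm; `method = "inversion"` selects R's
own generator.  The two are distributionally identical, as the test suite
verifies by a Kolmogorov–Smirnov comparison.

Two limiting behaviours anchor the model:

* $\sigma \to 0$ gives fixed tilts; $\sigma \gg 1$ makes $\cos\theta$
  nearly uniform, i.e. the isotropic tilt density $\sin\theta/2$.
* The truncated Gaussian at $\sigma = 3$ (used in the original
  illustration of the isotropic limit) is *not exactly* uniform: its
  density varies by $e^{1/18} \approx 5.7\%$ across $[-1, 1]$.  In a
  coplanar run this residual alignment raises the mean to
  $\langle\kappa^2\rangle \approx 0.6715$, about $0.005$ above $2/3$ — a
  real property of the $\sigma = 3$ protocol, reproduced independently by
  two implementations during development.  Cross-checks against the exact
  isotropic density therefore use $\sigma = 30$, where the bias is
  $\sim 10^{-4}$ and a $\chi^2$ goodness-of-fit comparison passes at the
  99% level.

## Monte-Carlo engines

All engines place donors uniformly on an $l \times l$ square at $z = 0$
and acceptors on a parallel plane (or slab), with **no** periodic
boundaries: finite-size edge effects are part of the physics studied (the
dependence of parallel-plane results on $l$).  Defaults are
$l = 100$ nm, $N = 10^6$ pairs and 100 histogram bins on $[0, 4]$.

* `simulate_unweighted()` — one acceptor plane at distance $h$; arithmetic
  mean and histogram of $\kappa^2$, plus tilt histograms of both species.
* `simulate_unweighted_slab()` — acceptor $z$ uniform on
  $[0, z_{max}]$, emulating a three-dimensional acceptor distribution.
* `simulate_weighted()` — one or two acceptor planes ($h_1$, $h_2$; the
  two bilayer leaflets at equal acceptor density) with per-plane exclusion
  distances.  Because the transfer rate to acceptor $i$ scales as
  $\kappa_i^2/R_i^6$, the physically meaningful average is
  $$\langle\kappa^2\rangle =
    \frac{\sum_i \kappa_i^2 R_i^{-6}}{\sum_i R_i^{-6}},$$
  pooled over both planes.  Pairs closer than the exclusion distance
  $R_e$ (3D separation) have their *positions* redrawn, orientations
  kept, as in the reference procedure; since positions and orientations
  are independent this choice does not affect the sampled law.

The RNG draw order within a run is fixed (donor $x, y$; acceptor $x, y$;
slab $z$ if any; donor $\cos\theta$, $\phi$; acceptor $\cos\theta$,
$\phi$), so a run is bit-reproducible for a given seed and engine.
Computation is chunked at $10^6$ pairs so memory stays flat for large
$N$.

### Variance of the weighted average

The $R^{-6}$ weights are extremely skewed: for a coplanar plane with
$R_e = 0.8$ nm and $l = 100$ nm, the effective sample size
$(\sum w)^2 / \sum w^2$ of a $10^6$-pair run is only a few hundred, so
individual weighted runs scatter by several hundredths around the true
mean.  This is why the weighted protocols are always repeated over
independent seeds (`repeat_runs()`, ten repeats by default) and why
comparisons in the test suite allow for three standard errors of the
grand mean in addition to any reported spread.  The unweighted estimator
has no such amplification and converges at the usual $N^{-1/2}$ rate.

## Analytic references

Two closed forms validate the engines:

* the isotropic $\kappa^2$ density (`isotropic_pdf()`), with
  $\int_0^4 p = 1$ and mean $2/3$, continuous (with a square-root cusp)
  at $\kappa^2 = 1$ and an integrable singularity at $0$;
* the Knoester–van Himbergen average for identically oriented coplanar
  dipoles (`knoester_mean()`),
  $\langle\kappa^2\rangle = 2/3 - (2/3)S + S^2$ with
  $S = P_2(\cos\theta)$, which ranges from $5/9$ (at
  $\theta = 41.81^\circ$ and its supplement) to $1.25$ (at $90^\circ$)
  and crosses $2/3$ at four tilts, including the magic angle
  $\theta_m = \arccos(1/\sqrt3) = 54.74^\circ$.

`knoester_mean()` is restricted to fixed tilts ($\sigma = 0$), where
$\langle\cos^2\theta\rangle = \cos^2\theta$; its validity under
$\cos\theta$-Gaussian heterogeneity is not asserted.  At the magic angle
the simulated distribution vanishes above $25/9 = 2.778$; the test of
this support cutoff evaluates the tilt at $\arccos(1/\sqrt3)$ exactly
rather than at the two-decimal rounding $54.74^\circ$, whose support edge
sits a few $10^{-4}$ above $25/9$.

## From $\langle\kappa^2\rangle$ to observables

For a uniform plane of acceptors (surface density $c$) no closer than
$R_e$ to the donor, the donor survival function in reduced time
$\zeta = t/\tau_0$ is

$$i_{DA}(\zeta) = e^{-\zeta}\exp\left\{-\beta^{1/3}\sigma_c\left(
  \gamma\!\left[\tfrac23, \beta\alpha^6\zeta\right]\zeta^{1/3}
  - \frac{1 - e^{-\beta\alpha^6\zeta}}{\beta^{1/3}\alpha^2}
  \right)\right\}$$

with $\alpha = \bar R_0/R_e$, $\beta = \tfrac32\langle\kappa^2\rangle$,
$\sigma_c = \pi \bar R_0^2 c$, and $\gamma$ the **lower, unnormalized**
incomplete gamma function ($\gamma(s,x) = \Gamma(s)\,P(s,x)$, computed
via `pgamma`).  That convention is the only one for which the
$R_e \to 0$ limit recovers the classical planar decay
$\exp(-\sigma_c \beta^{1/3}\Gamma(2/3)\zeta^{1/3})$, which the tests
verify at $\alpha = 10^6$ against the closed-form limit.  The efficiency
is $E = 1 - \int_0^\infty i_{DA}(\zeta)\,d\zeta$, evaluated by adaptive
quadrature (absolute tolerance $10^{-8}$) and cross-checked against a
fixed-grid Simpson rule on randomly drawn parameter sets.
`efficiency_curve()` produces the universal $E(\sigma_c)$ curves for
fixed $\alpha$ and $\langle\kappa^2\rangle$; at $\alpha = 0.5$ the curve
for $\langle\kappa^2\rangle = 1.25$ exceeds three times the
$\langle\kappa^2\rangle = 0.30$ curve throughout $\sigma_c \le 5$.

## Probe-pair catalogue

`preset_catalogue()` bundles literature-derived transverse locations and
orientation parameters for t-PnA, DPH, NBD, a carbocyanine, Rhodamine B
and BODIPY, combined into nine donor/acceptor presets.  Geometry follows
from the locations: same-leaflet plane at $h_1 = |z_D - z_A|$ and
opposite-leaflet plane at $h_2 = z_D + z_A$, with $R_e = 0.8$ nm on both.
Where a source table prints a fluorophore's parameters only once, the
same values are used wherever that fluorophore appears; the NBD/NBD
homo-transfer entry uses identical donor and acceptor specifications.
The gel-phase t-PnA entry changes only the donor orientation
($5^\circ$, $0.03$), keeping fluid-phase locations and the DPH acceptor
parameters — the minimal substitution the source describes.

```{r preset, eval = FALSE}
run_preset("rhodamineB_homo", n = 1e6, n_repeats = 10, base_seed = 1)
#> <repeat_summary> 10 runs: <kappa^2> = 1.0817 (sd 0.0724)
```

## Problem sizes and reproducibility

The bundled tests and the acceptance script use the original study's run
conditions directly: $10^6$ pairs per plane (and $10^7$ for the
near-isotropic illustration), ten seeded repeats for every weighted
protocol, $l = 100$ nm, $R_e = 0.8$ nm.  These runs complete in minutes
on a single core because every engine is vectorized and chunked.  All
randomness flows through R's seeded stream; every reported number is
reproducible from its seed.

## What the generators do and do not emulate

The synthetic configurations capture uniform lateral placement, fixed
transverse planes, independent truncated-Gaussian tilts and uniform
azimuths.  They deliberately omit: lateral pair correlations (domains,
clustering), probe wobble dynamics and time-correlated reorientation,
distance–orientation coupling through linkers, and any static or
intermediate averaging regime — the computed averages apply to the
dynamic limit only.  Agreement of the test suite therefore demonstrates
correctness of the sampling and averaging machinery under these stated
assumptions, not the realism of the assumptions for any particular
membrane system.

## Known limitations

* The weighted average's heavy-tailed weights make single runs noisy
  (see above); always use repeats and quote the spread.
* For $\sigma \gtrsim 1$ the truncated-Gaussian tilt model is only an
  approximate route to isotropy; exact isotropic sampling is emulated by
  large $\sigma$ rather than provided as a separate code path.
* The ideal-dipole $\kappa^2$ expression is used throughout; near-field
  corrections at sub-nanometre separations are out of scope (the
  exclusion distance keeps the weighted engines away from that regime).
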