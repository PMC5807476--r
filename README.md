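# stripcount

Counting enzymes immobilized on gold-nanoparticle-coated electrodes by
anodic stripping coulometry and fluorimetry.

## The problem

Enzymatic electrochemical biosensors are built by electrodepositing gold
nanoparticles (AuNPs) onto a glassy carbon disc and adsorbing
fluorophore-labeled enzyme (typically glucose oxidase) onto them.  To
optimize such sensors — ideally toward a fast, monolayer enzyme coating —
you need, *per individual electrode*: the mean AuNP size, the particle
count, the total gold surface area, the electrode coverage, and the number
of enzymes actually bound.  `stripcount` computes all of these from two
integrated voltammetric charges plus one fluorescence reading, for analysts
characterizing AuNP biosensor electrodes.

## The model

With $Q$ the anodic stripping charge (gold dissolution, peak ≈ +1.3 V vs
NHE) and $Q_{ox}$ the gold-oxide reduction charge (peak ≈ +1.1 V):

$$S = Q_{ox}/k_{ox}, \qquad
Q = n_{eff}\, e\, \frac{\tfrac{x}{3}\pi r^{3}\rho_{Au}}{M_{Au}}\, N_A\, N,
\qquad S = x\pi r^{2} N$$

so that

$$r = \frac{3\,M_{Au}}{n_{eff}\, e\, \rho_{Au}\, N_A}\cdot\frac{Q}{S},
\qquad N = \frac{S}{x\pi r^{2}},$$

with $k_{ox}$ = 489 µC/cm² (configurable: 400/450/543 also ship),
$n_{eff}$ = 1.9 electrons per gold atom, and $x$ = 2 for hemispherical
particles.  Fluorescence intensity of the enzymes released by stripping,
inverse-predicted through a linear calibration curve, gives the molar
concentration in the 200-µL stripping droplet, hence the absolute count
$n = cVN_A$, enzymes per particle $n/N$, and per-enzyme footprint
$S(\mathrm{nm}^2)/n$.

A forward simulator generates voltammograms and fluorescence tables from a
known ground truth, so the entire pipeline is testable by parameter
recovery — no instrument data needed.

## Worked example

Simulate one realistic electrode (17 ± 7 nm particles, 1.9×10¹⁰ of them)
and analyze it:

```r
library(stripcount)
gt  <- ground_truth(d_mean = 17, d_sd = 7, n_np = 1.9e10, seed = 1)
sim <- simulate_voltammograms(gt)
q_ox <- integrate_charge(sim$oxide,     oxide_window())
q_st <- integrate_charge(sim$stripping, stripping_window())
(np <- estimate_np(q_st$q, q_ox$q))
#> Nanoparticle estimate (per electrode):
#>   mean diameter : 22 nm
#>   particle count: 1.33e+10 (13 x 1e9)
#>   total NP area : 0.101 cm2 (10 x 1e-2)
#>   coverage      : 71.6 % of a 3 mm disc
#>   charges       : Q_strip = 0.000668 C, Q_ox = 4.95e-05 C

flu   <- simulate_fluorescence(gt, truth = sim$truth)
curve <- fit_calibration(flu$standards)
conc  <- concentration_from_intensity(curve, flu$sample$intensity)$conc
per_np_and_footprint(enzyme_count(conc, gt$volume), np, conc = conc)
#> Enzyme report:
#>   count      : 5e+10 enzymes (4.15e-10 mol/L in 200 uL)
#>   per NP     : 3.77 enzymes/NP
#>   footprint  : 202 nm2/enzyme
```

The recovered diameter (22 nm) exceeds the planted mean (17 nm) because the
charge ratio estimates the charge-weighted mean ⟨r³⟩/⟨r²⟩ of a polydisperse
population — a real property of the method, quantified in the methods
vignette.  The footprint (202 nm²) is the per-enzyme share of the total
gold surface.

Geometry helpers reproduce the standard packing arithmetic: a 14-nm
hemisphere offers `hemisphere_area(14)` ≈ 308 nm², onto which
`enzyme_packing(308, 21, "round")` = 15 GOx fit short-side-on, or
`enzyme_packing(308, 67, "floor")` = 4 long-side-on.

## Command line

```sh
Rscript -e 'stripcount::stripcount_cli()' simulate --config gt.json --outdir sim --seed 11
Rscript -e 'stripcount::stripcount_cli()' analyze  --config sim/run_config.json --outdir reports
Rscript -e 'stripcount::stripcount_cli()' recover  --config gt.json --outdir rec
```

`analyze` writes `per_electrode.csv`, `cohort_summary.csv` (unweighted
mean ± SD per metric per group, failed electrodes listed, never silently
dropped) and a `run_manifest.json` echoing every analysis setting.

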