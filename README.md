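# rlmsim

Simulation and quantification for dual-scintillator radioluminescence
microscopy (RLM) of single cells.

## The problem

RLM images the decay of single radioactive molecules in live cells: a
CdWO₄ scintillator against the cells converts each β⁺ particle from
[¹⁸F]FDG into an optical flash, captured by a low-light microscope
(20×/0.75 NA, effective magnification 3.6×) on an EMCCD. Counting flashes
over ~10,000 frames quantifies per-cell tracer content, but acquisitions
take 15–30 minutes — painful for a 110-minute-half-life tracer. Sandwiching
the cells between **two** scintillators captures both emission hemispheres
and doubles the sensitivity:

- expected counts from a cell with N₀ tracer molecules:
  `D = S·Y·N₀·(1 − exp(−ln2·t/τ½))`, with sensitivity `S`, positron yield
  `Y = 0.97`, half-life `τ½ ≈ 110 min`;
- dual/single sensitivity ratio from two acquisitions Δt apart:
  `S_double/S_single = D_double·exp(ln2·Δt/τ½)/D_single`
  (decay correction 1.14 for Δt = 21 min);
- depth of field `d = n·λ/NA² + n·b·e/(M·NA) ≈ 24.5 µm`, enough to keep
  both slab surfaces (10 µm apart) in focus simultaneously.

The package provides, for synthetic data: a desk-scale Monte Carlo of ¹⁸F
positron transport and backscatter in one or two slabs; a defocus-broadened
Gaussian PSF + EMCCD noise renderer; flash reconstruction (background
model, 5σ thresholding, component clustering, peak-windowed centroids)
into decay-event images; and the study's statistics — ROI counting with
background correction, dual-vs-single regression, decay-corrected
sensitivity ratios with Poisson-ratio confidence intervals, 2-D Gaussian
FWHM fits, line profiles, and efflux difference images. A synthetic
experiment generator emulates heterogeneous uptake (3–4× spread),
first-order efflux into a peri-cellular annulus, and the
single-then-dual acquisition protocol with its 21-minute delay.

## Worked example

```r
library(rlmsim)

depth_of_field(optical_system(), camera_model())
#> [1] 24.54815
decay_correction_factor(21, 110)
#> [1] 1.141483

# factor-of-two Monte Carlo: 1 Bq source, 20,000 decays, both geometries
src <- source_model(activity_bq = 1)
rd  <- run_decay_batch(src, scintillator_stack(), 20000, seed = 5,
                       keep_deposits = FALSE)
rs  <- run_decay_batch(src, scintillator_stack(gap_top = NULL), 20000,
                       seed = 5, keep_deposits = FALSE)
sensitivity_ratio(rd$tally[["any"]], rs$tally[["bottom"]], delta_t_min = 0)
#> S_double/S_single = 1.992 (95% CI 1.943-2.042), decay correction 1.000
```

The first two numbers are the microscope's depth of field in µm — large
enough to keep both scintillator surfaces in focus, which is what makes
the sandwich feasible — and the multiplicative decay correction applied
to the later dual acquisition.
The ratio near 2 is the headline sensitivity doubling: the same emission
sample detected in the dual vs the single geometry.

A full synthetic experiment (a few minutes):

```r
res <- run_pipeline(rlm_scenario("scaled"), seed = 1)
res$report$slope               # dual-vs-single per-cell regression slope
res$report$sensitivity_ratio   # decay-corrected ratio of ROI totals
res$report$mean_single         # mean background-corrected counts/cell
```

`rlm_scenario("scaled", efflux = TRUE)` adds tracer efflux between the
acquisitions: the regression slope falls below 2 and the difference image
(`efflux_difference_image()`) turns negative at cells and positive in the
surrounding annuli.

A thin command-line front end with `simulate`, `reconstruct`, `quantify`,
`compare`, `run` and `dof` subcommands is installed at
`system.file("cli", "rlm.R", package = "rlmsim")`.

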