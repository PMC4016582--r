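# sizecontrol

Does a bacterium divide because it has lived long enough, or because it has
grown large enough? `sizecontrol` is an R package for settling that question
quantitatively from single-cell tracking data. It implements the two
competing hypotheses as structured-population models — a **timer** (Age
Model), where the instantaneous division rate depends on cell age, and a
**sizer** (Size Model), where it depends on cell size — estimates the
division rate nonparametrically from the data, reconstructs the stable
age–size distribution each hypothesis implies, and measures which
reconstruction matches the observed population. It is aimed at
quantitative microbiologists and modellers working with time-lapse data of
growing bacterial lineages (agar-pad microcolonies where the full
genealogical tree is tracked, or mother-machine microfluidics where one
daughter per division is followed).

## The models

The density $n(t,a,x)$ of cells of age $a$ (min) and size $x$ (µm length)
evolves under growth $v(x)$ and a division hazard $B$:

$$\big(\partial_t + \partial_a\big) n + \partial_x\big(v(x)\,n\big)
  = -B(a,x)\,n, \qquad
  n(t,0,x) = 4\int_0^\infty B(a,2x)\,n(t,a,2x)\,da ,$$

with $B = B_a(a)$ for the timer and $B = B_s(x)$ for the sizer restriction
(renewal factors 4 → 2 for mother-machine, one-daughter observation). After
transients $n(t,\cdot) \approx e^{\lambda t} N(\cdot)$: the package
computes the Malthus coefficient $\lambda$ and stable distribution $N$ by a
conservative upwind finite-volume scheme with renormalized forward
iteration. Division rates are estimated without parametric assumptions:
$\hat B_a = \hat f/\hat S$ from the division-age density and survival, and
$\hat B_s = v\,\hat\psi/\hat\pi$ from the division-size density and the
at-risk fraction. Goodness of fit is the normalized integrated squared
error between the empirical age–size distribution (kernel estimate of
every cell at every time step) and the model reconstruction,
$D = \sqrt{\smash{\int (f-g)^2 / \int f^2}} \times 100\%$.

The package also ships an exact stochastic lineage simulator (the
Monte-Carlo counterpart of the PDEs, with growth-rate and septum-position
noise and a measurement-error layer), single-cell growth analysis
(linear vs exponential fits, increment curves, detection of the
exponential size range), noise-extended Size Models (growth-rate
variability, noisy septum positioning), and robustness scans.

## Worked example

Simulate a mother-machine experiment under size control (150 channels,
40 generations, 1-min frames, 8% growth-rate CV, 4% septum CV), then ask
which control law explains the data:

```r
library(sizecontrol)

cfg <- simConfig("sizer", topology = "sparse_tree", nChannels = 150L,
                 generations = 40L, acquisitionDt = 1, seed = 4L)
tracks <- simulateMotherMachine(cfg)
report <- evaluateModels(tracks, generationWindow = c(10L, 40L))
report
#> FitReport (timer vs sizer)
#>   cycles: 4500; mean growth rate 0.0274/min
#>   D(Age Model)  = 108.40%
#>   D(Size Model) =  13.21%
#>   corr(division age, birth size) = -0.696 (perm. p = 0.0005)
#>   preferred model: sizer
```

The sizer reconstruction sits ~13% from the empirical age–size
distribution while the timer reconstruction misses it entirely (~108%), and
the strongly negative correlation between division age and birth size —
impossible under a timer, which draws lifetimes independently of birth
size — independently confirms size control. The phenotypic noise put into
the generator is recovered from the extracted cycles:

```r
noiseSummary(extractCycles(tracks, generationWindow = c(10L, 40L)))
#> NoiseSummary (4491 cycles)
#>   growth rate: mean 0.0274/min, CV 0.0788 (Shapiro W 0.999)
#>   septum ratio: CV 0.0407 (Shapiro W 1)
```

Other entry points: `solveStable()` (stable distributions and Malthus
coefficients), `estimateAgeRate()` / `estimateSizeRate()` (hazards),
`solveGrowthVariability()` / `solveSeptumNoise()` (noise-extended Size
Models), `robustnessScan()` (distance-versus-noise curves),
`readTracks()` / `writeTracks()` (CSV dialects). The vignette
`vignettes/sizer-timer-models.Rmd` documents the models, the numerics and
the design choices.

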