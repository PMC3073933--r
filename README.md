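# dispersim

Frame-wise spatial-homogeneity testing for tracked microorganisms in
band-loaded microfluidic chemotaxis assays, plus the synthetic data to
validate it.

In these assays a channel holds three side-by-side fluid sections; the
central band can carry an attracting or repelling chemical, and a
population of ~200 motile organisms (e.g. *Paramecium*) is video-tracked,
yielding a planar point pattern per frame.  `dispersim` makes the informal
question "is the population uniformly distributed?" quantitative: each
coordinate marginal of each frame is tested against the homogeneous
Poisson null with the quadrat-count **index of dispersion**

&nbsp;&nbsp;&nbsp;&nbsp; *I* = (*k* − 1) *S*² / *N̄*,

where *N̄* and *S*² are the sample mean and (unbiased) sample variance of
the counts in *k* equal cells.  Under the null *I* ~ χ²(*k* − 1)
approximately, so homogeneity is rejected at level α when *I* falls above
the 1 − α/2 quantile (**clustered**) or below the α/2 quantile
(**regular**).  The test is swept over a range of *k* (default 5–25), run
on both the cross axis (across the bands, where chemotaxis acts) and the
long axis (along the channel, a built-in control), and complemented by an
area-normalised **chemotactic index** — the in-band/out-of-band density
ratio, 1 under uniformity.

The package also ships generators for homogeneous and (thinned)
inhomogeneous Poisson point fields and an agent-based drift–diffusion
simulator (the agent-level analogue of the Keller–Segel model: drift
χ ∂c/∂x plus diffusion D, reflecting walls) with presets for the three
canonical experiments: `control`, `attractant`, `repellent`.

## Worked example

A small simulated control run (organisms released in the middle third, no
chemical) ships with the package:

```r
library(dispersim)
library(dplyr)

path <- system.file("extdata", "demo_control_positions.csv", package = "dispersim")
series <- read_positions(path)
report <- analyze_frames(series, k_range = 5:12)
filter(tidy(report), k == 10)
#>    time axis      k statistic lower upper verdict        n chemotactic_index
#> 1     0 cross    10      85.6  2.70  19.0 clustered     50            Inf
#> 2     0 long     10      10.8  2.70  19.0 consistent    50             NA
#> 3    10 cross    10      52.8  2.70  19.0 clustered     50              7.09
#> 4    10 long     10      10    2.70  19.0 consistent    50             NA
#> 5    20 cross    10      26    2.70  19.0 clustered     50              3.56
#> 6    20 long     10       8.8  2.70  19.0 consistent    50             NA
#> 7    30 cross    10      12    2.70  19.0 consistent    50              2.17
#> 8    30 long     10       5.2  2.70  19.0 consistent    50             NA
```

Read it like the assay's time-course figures: at *t* = 0 the cross-axis
statistic (85.6) sits far above the χ²₉ upper bound (19.0) — the release
in the middle third is heavily clustered — and decays over 30 s into the
acceptance band (12, `consistent`) as the organisms disperse, while the
long axis stays `consistent` throughout (no spurious structure along the
channel).  The chemotactic index tells the same story as a density ratio
falling from ∞ (everyone in the band) toward 1.

Simulate-and-analyse in one call, then plot:

```r
res <- run_scenario("attractant", out_dir = "out", seed = 1)
autoplot(res$report_table, k = 10)     # index vs time with rejection band
plot_frames(read_positions(res$positions), band = c(1/3, 2/3))
```

A thin CLI wraps the same functions
(`inst/cli/dispersim.R simulate|analyze|report`); a single YAML key-value
file (see `read_config()`) configures bounds, k-range, alpha, and any
simulator field.

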