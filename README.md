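# kspaceSplice

Splicing MRI k-space data acquired at several receiver gains into one
k-space with a higher image signal-to-noise ratio.

## The problem

In MRI, each phase-encoding line of k-space is one echo, and echo
amplitude varies enormously across lines: central lines (low spatial
frequencies) carry the bulk of the signal energy, outer lines are orders
of magnitude weaker. A receiver with a single fixed receiving gain (RG)
must be set so the central lines do not saturate the ADC — which leaves
the outer lines spanning only a few quantizer steps, so their SNR is
limited by quantization noise rather than by thermal noise.

The remedy implemented here: scan the object three times at gains
τ, τ−6 and τ−12 dB, then splice one k-space from the three —

* **region 1** (outer lines, e.g. m = 1–36 and 185–220 of 220) from the
  **highest** gain τ, where the weak echoes best fill the ADC range;
* **region 2** (intermediate, m = 37–72 and 149–184) from τ−6 dB;
* **region 3** (central, m = 73–148) from the **lowest** gain τ−12 dB,
  the only one whose central echoes do not overflow.

Because real receiver gains differ from their nominal dB values, the
amplitude ratio between acquisitions is *estimated from the data*: for
each group of four lines, the middle N (default 120) magnitude samples
of the group's representative line give per-sample ratios
αᵢ = δ_A,i / δ_B,i whose mean is the group's gain-difference factor β.
Averaged over line groups this yields avg[ΔG1] (τ vs τ−6) and, chained
per group, avg[ΔG1·ΔG2] (τ vs τ−12); a 6 dB step corresponds to
10^(6/20) ≈ 2, a 12 dB step to ≈ 4. Regions 2 and 3 are multiplied by
these factors (normalizing everything *up* to the τ amplitude scale),
phase differences are screened over the noise-robust central window
(circular mean of γᵢⱼ = ε_A,ij − ε_B,ij; compensation defaults to zero
when the offset is below 2°), and the spliced k-space is reconstructed
by centered inverse FFT. Image quality is quantified as
**SNR = SI / SD** — mean intensity of the brightest region of interest
over the averaged standard deviation of four corner background
rectangles — and reported as the percent boost against the lowest-gain
reconstruction with paired ROI/corner bounds.

Because no public scanner data exist for this protocol, the package
includes a first-class simulator of the study: a homogeneous spherical
phantom on a 220 × 440 scan matrix, acquired through a receiver model
with pre-/post-gain complex Gaussian noise and a uniform mid-rise ADC
quantizer with clipping, three scans at 6 dB gain steps with
independent noise.

## Worked example

```r
library(kspaceSplice)
res <- runPipeline()   # simulate -> splice -> reconstruct -> SNR
res$splice
#> SpliceResult
#>   spliced gain label: 12 dB
#>   avg[dG1] = 1.98104  avg[dG1*dG2] = 3.88294
#>   phase offsets (deg): region2 = 0 , region3 = 0
res$boostPct
#> [1] 41.95594
```

The estimated gain factors sit close to their nominal values 2 and 4
(they are estimated from noisy, quantized data, not assumed), the
central phase offsets fall below the 2° threshold so no phase
compensation is applied, and the spliced reconstruction improves SNR
over the lowest-gain reconstruction by ~42% under the default simulator
settings, where outer-line quantization noise dominates the lowest-gain
background. A hardware receiver adds channel noise that quantization
improvements cannot touch, so measured boosts on real scanners are
smaller.

The same pipeline is scriptable from a shell via
`inst/scripts/ksplice.R` (subcommands `simulate`, `splice`, `evaluate`,
`full`; YAML configuration mirroring `defaultConfig()`).

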