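# ogtrace

Infer optimal growth temperatures (OGT) of extant and ancestral prokaryotes
from the temperature dependence of GDP binding by translation elongation
factors (EF-1A in archaea and eukaryotes, EF-Tu in bacteria).

## The problem

The temperature at which an elongation factor binds GDP most strongly
closely tracks the optimal growth temperature of the organism it comes
from. That makes EF-1A a molecular thermometer: express the protein —
extant or resurrected from an ancestral sequence reconstruction — measure
its Mant-GDP binding fluorescence across a temperature grid, locate the
binding optimum, and read off a proxy for the organism's OGT. Mapping
those optima onto a phylogeny traces how growth temperature evolved across
a clade, including at ancestral nodes for which no organism can be
cultured.

`ogtrace` implements the full analysis for this kind of study:

* **Peak model.** Replicate fluorescence-versus-temperature profiles are
  fit by least squares to a skewed Gaussian-like bell curve,

  $$F'(t) = F_0 + (F^* - F_0)\, e^{-\left((t - t^*)/s(t)\right)^2},
  \qquad
  s(t) = s_L + \frac{s_R - s_L}{1 + e^{-(t - t^*)/w}},$$

  with baseline $F_0$, peak intensity $F^*$, peak temperature $t^*$, and
  a width that switches logistically from $s_L$ below the peak to $s_R$
  above it over $w = 5$ °C. The five free parameters
  ($F_0, F^*, t^*, s_L, s_R$) are fit to all replicate datapoints
  (typically 3 replicates × 11 temperatures = 33 residuals) by
  multi-start Nelder–Mead; `w` is held fixed.
* **Bootstrap CI.** At each temperature the replicates are resampled with
  replacement, each of 1000 bootstrap datasets is refit, and the 90%
  confidence interval of $t^*$ is the 5th–95th percentile of the
  bootstrap distribution.
* **Thermal stability.** ThermoFluor melt profiles locate the unfolding
  transition at the grid temperature of maximal mean dye fluorescence;
  the protein's stable range runs from the lowest assayed temperature to
  one grid step below the transition, and binding fits are restricted to
  it.
* **OGT and lifestyle.** The binding optimum is taken as the OGT proxy
  (an optional linear calibration is available), classified as mesophile
  (< 45 °C), moderate thermophile (45–80 °C) or hyperthermophile
  (≥ 80 °C), and checked against a calibration table of organisms with
  known OGT via the Pearson correlation.
* **Ancestral consensus.** Ancestral sequences reconstructed by several
  ASR engines are merged into a consensus by majority vote with
  posterior-probability tie-breaks, with per-site and mean posterior
  probabilities and a disagreement report.
* **Tree annotation.** OGT estimates are painted onto a rooted newick
  phylogeny and summarised as an evolutionary-trajectory table of
  parent-to-child OGT changes.
* **Synthetic data.** Seeded generators produce every input the pipeline
  consumes — binding profiles, melt curves, ASR sets, whole trait trees —
  with known ground truth, so every stage is testable end to end.

## Worked example

Simulate an ancestral-protein assay (true binding optimum 52.9 °C, melt
transition at 80 °C, 2% assay noise), then run the analysis exactly as it
would run on measured data:

```r
library(ogtrace)

melt <- simulate_thermofluor("AncEF", melt_t = 80, seed = 42)
sr <- stable_range(melt)
sr
#> Thermal stability of 'AncEF': stable 0-70 degC (transition at 80 degC, grid step 10)

sim  <- simulate_binding_profile("AncEF",
          true_params = list(F0 = 100, F_star = 1000, t_star = 52.9,
                             s_L = 8, s_R = 12, w = 5),
          noise_frac = 0.02, seed = 42)
prof <- restrict_to_stable(sim$profile, sr)

fit <- fit_peak(prof)
fit
#> Skewed peak fit for 'AncEF'
#>   Peak temperature t* = 53.05 degC
#>   F0 = 115.1, F* = 1002 a.u.; s_L = 7.488, s_R = 11.42 degC (w = 5)
#>   SSE = 1.108e+04 over 24 datapoints in [0, 70] degC; converged: TRUE

boot <- bootstrap_peak_ci(prof, n_boot = 1000, seed = 42)
boot
#> Bootstrap peak temperature for 'AncEF'
#>   t* = 53.046 degC, 90% CI: 52.472-53.504 degC
#>   1000 bootstrap datasets (0 failed fits dropped), seed 42

infer_ogt("AncEF", boot)
#> OGT estimate for 'AncEF': 53 degC (CI 52.5-53.5), moderate_thermophile

pearson_r(calibration_table("methods"))
#> Pearson correlation OGT vs binding optimum: r = 0.8894 (n = 4)
```

The fitted optimum (53.0 °C, CI 52.5–53.5) recovers the generating
52.9 °C to within the assay noise, and the protein classifies as a
moderate thermophile. `run_pipeline(run_config(...))` chains all of these
stages — stability → restriction → fit → bootstrap → OGT → tree
annotation — over a batch of proteins with per-protein failure isolation
and a JSON run manifest; `plot()` on the annotated tree draws the
temperature-coloured phylogeny.

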