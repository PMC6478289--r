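# larvagrowth

Growth-trajectory analysis of sexual size dimorphism (SSD) in larval
insects.

In species where females are the larger sex and both sexes have the same
number of larval instars, the dimorphism must come from growing *longer*,
growing *faster*, or from other features of the non-linear larval growth
curve (e.g. pre-pupal mass loss). Telling "longer" from "faster" requires a
growth-rate index that does not itself depend on body size — otherwise the
already-larger sex is mislabelled as the faster one. This package provides
that analysis for longitudinal last-instar mass records, for researchers in
insect life-history and ontogeny:

* a **stochastic trajectory simulator** calibrated to a published rearing
  design (109 broods, 12 + 3 larvae per brood on two host plants, ~1600
  larvae) with brood-, individual- and day-level variation, gut-fill
  inflation on day 1, growth taper around the mass peak, wandering-stage
  mass loss, and stream-based reproducibility;
* **trajectory IO** in documented wide/long TSV/CSV dialects with strict
  validation and lossless round trips;
* **growth-curve descriptors** (maximal mass, time to peak, mass-loss
  ratios, daily increments) with per-sex mean ± SE summaries;
* the three **differential growth-rate indices** over the free-growth
  window (days 2–5): absolute `m_d − m_(d−1)`, relative
  `log10(m_d / m_(d−1))`, and allometric `m_d^(1/3) − m_(d−1)^(1/3)` —
  the last is constant on a cubic growth curve
  `m(t) = (m_0^(1/3) + g t)^3` and therefore size-independent, plus
  integral (whole-phase) rates for comparison;
* **mixed ANOVAs**: descriptor models with a random brood intercept, and
  repeated-measures models of the daily rates (fixed sex, day, host,
  sex:day, sex:host; random brood and individual) with denominator degrees
  of freedom derived from the number of larvae, not measurements, to avoid
  pseudoreplication;
* an **SSD decomposition** under the cubic model: how much dimorphism a
  rate difference produces versus an extra day of growth.

## Worked example

The `analysis/` directory is a numbered pipeline over the package. Running
it end to end:

```sh
Rscript analysis/01_simulate.R     # simulate the default design
Rscript analysis/02_features.R    # descriptors + per-sex summaries
Rscript analysis/03_rates.R       # differential growth rates
Rscript analysis/04_inference.R   # regressions + mixed ANOVAs
Rscript analysis/05_decompose.R   # SSD decomposition
```

prints (seed 20190423):

```
Simulated 1635 larvae in 109 broods (seed 20190423)
Sex split: 818 F / 817 M; hosts: 1308 / 327

Simulated SSD in initial_mass  1.154 (SDI 0.15)
Simulated SSD in maximal_mass  1.212 (SDI 0.21)
Simulated SSD in pupal_mass    1.157 (SDI 0.16)
Published sex-mean ratios:  initial 1.15, maximal 1.22, pupal 1.16

Mean allometric rate: F 0.280, M 0.273 mg^(1/3)/day (generative 0.279 / 0.270)
Daily fold gain (geometric): F 1.231, M 1.235

allometric sex      F(1,1631) =   4.77, p = 0.02903
allometric sex:day  F(1,4901) =   2.61, p = 0.1065
relative   sex      F(1,1631) =   2.49, p = 0.1149
relative   sex:day  F(1,4901) =   3.56, p = 0.05938
pupal mass sex effect: F(1,1632) = 267.1, p = 1e-55, R2 = 0.14

Rate-difference contribution over 5 days: 1.032-fold
One extra growth day at the male rate:    1.201-fold
```

Reading: females end ~16% heavier as pupae and ~21% heavier at the larval
peak. The allometric (size-independent) rate is slightly but detectably
higher in females, while the relative rate shows no sex difference — the
female rate advantage is cancelled by the relative index's negative size
dependence. A flat sex:day interaction confirms the window is free growth.
The decomposition puts numbers on the conclusion: the 0.009 mg^(1/3)/day
rate difference yields only a 1.03-fold mass gap after five days, whereas a
single extra growth day yields 1.20-fold — growth *duration*, not growth
*rate*, is the dominant source of the dimorphism. (Each pipeline run is one
stochastic study; p-values vary between seeds.)

The same machinery works on real data via
`read_trajectories("your_file.tsv")`; see `?read_trajectories` for the
column layout.

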