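# zebratox

Analysis pipeline for high-throughput developmental-toxicity screens in
embryonic zebrafish. Each 96-well plate carries one chemical at seven nominal
concentrations (0, 0.01, 0.1, 1, 10, 50, 100 µM; one row of n = 12 embryos
per concentration; 0 µM is the in-plate vehicle control). The package takes
the screen's four data domains from plate tables to integrated chemical
prioritization:

* **Morphology** — binary endpoint incidence, the consolidated "Any Effect"
  endpoint, lowest effect level (one-sided exact binomial, p < 0.05),
  family-wise Fisher activity flags, and benchmark-concentration modeling:
  a binomial log-logistic fit
  `p(c) = p0 + (1 − p0)·c^h / (c^h + EC50^h)` whose added-risk BMC solves
  `p(BMC) − p0 = BMR` in closed form
  `BMC = EC50·(q/(1−q))^(1/h)`, `q = BMR/(1−p0)` (BMR = 0.10, a BMD10).
* **EPR** (embryonic photomotor response, 24 hpf) — background/excitatory/
  refractory interval means and a compound hit rule: two-sample
  Kolmogorov–Smirnov on per-embryo interval means at the Bonferroni-corrected
  p < 0.007 (0.05/7 concentration groups) *and* a ≥ 50 % relative peak
  difference of the mean movement trace.
* **LPR** (larval photomotor response, 120 hpf) — 6-s binned swim distances,
  dead/malformed exclusion, per-larva AUC over the analysis light/dark
  cycle; active iff KS p < 0.01 and the signed relative AUC change is
  ≥ +1.0 (hyper) or ≤ −0.3 (hypo).
* **RNA-seq** — median-of-ratios normalization against a pooled global
  control, an engine-agnostic NB Wald differential-expression summary (or
  ingestion of external per-gene tables), DEGs at raw p ≤ 0.05 with no
  fold-change cutoff, UpSet-style overlap counts, PCA, hypergeometric
  gene-set enrichment with BH adjustment, and pathway-hierarchy rollups.
* **Integration** — ToxPi-style profiles: per-domain slices min–max scaled
  across the chemical set (inactive endpoints scale to 0), equal-weight
  scores in [0, 1], ranking, Venn classification by active domains, and Ward
  hierarchical clustering (Lance–Williams on squared Euclidean distances,
  deterministic tie-breaking) of the profiles.

A synthetic-data generator (`simulate_screen()` and friends) emulates the
whole design with known ground truth, so every stage is testable end to end
without any external data. See the methods vignette
(`vignettes/zebrafish-screen-methods.Rmd`) for the models, assumptions, and
the design decisions behind every threshold.

## Worked example

Simulate a three-chemical screen (two active, one null) and run it through
morphology, behavior, and ToxPi integration:

```r
library(zebratox)
library(dplyr)

scr <- simulate_screen(c("PCB-A", "PCB-B", "PCB-C"), seed = 42,
                       active = c(1, 1, 0))

morphology_hits(scr$morphology, scr$plates,
                endpoints = c("MORT", "ANY_EFFECT")) %>%
  select(chemical_id, endpoint_id, lel, bmc, ec50, h)
#> # A tibble: 6 × 6
#>   chemical_id endpoint_id   lel     bmc        ec50      h
#>   <chr>       <chr>       <dbl>   <dbl>       <dbl>  <dbl>
#> 1 PCB-A       MORT         0.1   0.0274       0.175  1.18
#> 2 PCB-A       ANY_EFFECT   0.01  0.641        0.667 44.9
#> 3 PCB-B       MORT        10     1.69         6.53   1.63
#> 4 PCB-B       ANY_EFFECT   1     0.0706       0.254  1.55
#> 5 PCB-C       MORT        NA    NA      1000000.     4.81
#> 6 PCB-C       ANY_EFFECT  50    23.2    1000000.     0.196
```

Each row is one chemical × endpoint: `lel` is the lowest concentration (µM)
whose incidence significantly exceeds the control, `bmc` the concentration
producing a 10-percentage-point added risk over background, `ec50`/`h` the
fitted curve. The null chemical PCB-C shows what noise does to a screen: no
mortality signal (the flat fit demands no finite potency, so no BMC is
reported), but its Any Effect background still produces a chance LEL at
50 µM — the LEL definition carries no multiplicity correction, which is why
downstream calls rest on the BMC and the family-wise Fisher flags.

```r
epr_hits(scr$epr_frames, scr$plates) %>% filter(active)
#> # A tibble: 3 × 10
#>   chemical_id concentration_uM interval       D   p_value peak_ratio n_treated
#> 1 PCB-A                     50 excitatory     1 0.000671       0.745         6
#> 2 PCB-B                      1 excitatory     1 0.0000207      0.633        12
#> 3 PCB-B                     10 excitatory     1 0.0001         0.753         9
```

Both active chemicals disrupt the excitatory (post-pulse) interval; `D` is
the KS statistic on per-embryo interval means and `peak_ratio` the relative
peak difference of the mean trace (both criteria must pass).

```r
sv <- bind_rows(
  morphology_hits(scr$morphology, scr$plates, endpoints = "ANY_EFFECT") %>%
    transmute(chemical_id, slice = "morphology", value = potency_transform(bmc)),
  epr_bmc(scr$epr_frames, scr$plates) %>%
    transmute(chemical_id, slice = "EPR", value = potency_transform(bmc)),
  lpr_bmc(scr$lpr_bins, scr$plates) %>%
    transmute(chemical_id, slice = "LPR", value = potency_transform(bmc)))
toxpi_profiles(sv)$profiles
#> # A tibble: 3 × 6
#>   chemical_id   EPR   LPR morphology score  rank
#> 1 PCB-B       1         0      1     0.667     1
#> 2 PCB-A       0.629     0      0.619 0.416     2
#> 3 PCB-C       0         0      0     0         3
```

Slices are −log10(BMC) min–max scaled across the chemical set (no BMC → 0),
and the score is their equal-weight mean: the two active chemicals rank
above the null. `ward_cluster(toxpi_matrix(...))` clusters the profiles;
`autoplot()` methods draw dose–response curves, ToxPi bars, PCA, and
behavior traces.

A command-line workbench wrapping these functions ships at
`inst/exec/zebratox` (subcommands `simulate`, `morph`, `epr`, `lpr`,
`rnaseq`, `toxpi`).

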