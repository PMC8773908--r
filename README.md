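# circfish

Design, simulation and quantification for circular RNA single-molecule
FISH.

## The problem

Exonic circular RNAs (circRNAs) share their whole sequence with the linear
transcript they derive from; only the back-splice junction is unique to
the circle, and one junction cannot hold enough fluorophores for
single-molecule imaging. Dual-probe smFISH solves this without touching
the junction. Two probe sets tile the transcript:

* **PC** (probe circular) tiles the circularised exon(s) and binds **both**
  isoforms;
* **PL** (probe linear) tiles linear-only exons and binds **only** the
  full-length linear transcript.

Every bound probe set produces one diffraction-limited spot. After 3D spot
detection in both channels, each spot is classified by the **250 nm
counterpart rule**:

| observation                          | interpretation            |
|--------------------------------------|---------------------------|
| PL and PC spots within 250 nm (3D)   | full-length linear RNA    |
| PC spot with no PL counterpart       | circular RNA              |
| PL spot with no PC counterpart       | linear fragment           |

so that `linear + circular = #PC spots` and `linear + fragment = #PL
spots`. Per-cell counts, nuclear/cytoplasmic fractions, 95% confidence
intervals (1.96·SEM over ≥100 cells) and pooled-variance Student's
t-tests between conditions complete the analysis. The package is for
anyone building or validating such a pipeline: it implements every
computational stage and a synthetic-scene generator with exact ground
truth, including RNase R digestion (exponential survival `2^(-t/t½)`,
linear RNA digested, circles resistant) and class-selective shRNA
knockdown scenarios.

The core design rules it encodes: probes are 18–20 nt with GC in
[35%, 55%] and 2 nt between binding sites, tiled greedily left to right;
a target of length `L` holds at most `floor((L + g)/(l + g))` probes, and
the recommended minimum of 15 probes needs
`15·20 + 14·2 = 328 nt` of target.

## Worked example

Design discriminating probes for a ZNF609-like transcript whose first
exon (875 nt) circularises:

```r
library(circfish)
tm <- transcript_model(
  gene_id = "ZNF609",
  spliced_sequence = withr::with_seed(609,
    paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = "")),
  exons = tibble::tibble(start = c(0, 875, 1800, 2900),
                         end   = c(875, 1800, 2900, 4000)),
  circ_exon_indices = 1
)
probes <- design_probes(tm)
dplyr::count(probes, set_label, fluor)
#> # A tibble: 2 × 3
#>   set_label fluor        n
#>   <chr>     <chr>    <int>
#> 1 PC        Cy5         34
#> 2 PL        TexasRed   126
```

34 GC-filtered probes fit the 875-nt circularised exon — the scale of a
real panel for this circRNA. Then simulate an in-situ RNase R time course
(100 cells, 30 linear / 10 circular / 3 fragments per cell, half-lives
1 h linear and 48 h circular) and summarise it:

```r
cfg <- scenario_config(n_cells = 100, rng_seed = 11)
counts <- simulate_rnase_r_experiment(cfg, t_hours = c(0, 4), seed = 101)
summarize_conditions(counts)
#> # A tibble: 6 × 6
#>   condition class    n_cells mean_per_cell    sd ci95_halfwidth
#> 1 0h        circular     100         10.2  3.29          0.645
#> 2 0h        fragment     100          3.3  1.62          0.317
#> 3 0h        linear       100         30.9  5.43          1.06
#> 4 4h        circular     100          9.61 3.23          0.633
#> 5 4h        fragment     100          0.27 0.489         0.0959
#> 6 4h        linear       100          2.12 1.42          0.278
#> comparisons:
#>   class    condition_a condition_b t_statistic    df   p_value stars
#> 1 linear   0h          4h                51.3    198 2.82e-116 ***
#> 2 circular 0h          4h                 1.19   198 2.35e-  1 ns
#> 3 fragment 0h          4h                17.9    198 2.42e- 43 ***
```

Four hours of digestion wipe out the linear RNA (30.9 → 2.12 per cell,
`***`) while the circular count is statistically unchanged (`ns`) — the
specificity control that distinguishes a genuine circRNA signal. The
localisation summary on the untreated arm recovers the configured
compartment biology (linear ~75% cytoplasmic, circular ~50/50):

```r
localization_fractions(dplyr::filter(counts, condition == "0h"))
#>   condition class    n_cells nuclear_fraction ci95_halfwidth cytoplasmic_fraction
#> 1 0h        linear       100            0.256         0.0168                0.744
#> 2 0h        circular     100            0.493         0.0332                0.507
#> 3 0h        fragment      98            0.302         0.0589                0.698
```

For image-level work, `simulate_scene()` renders two-channel + DAPI
z-stacks with Poisson/read noise, `run_pipeline()` executes
detect → classify → segment → quantify on a TIFF and writes all
intermediate CSVs, a summary JSON and a log, and `autoplot()` /
`plot_localization()` visualise the results. The methods vignette
(`vignettes/circfish-methods.Rmd`) documents the models, defaults and
numerical choices.

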