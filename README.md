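# paleocore

Multiproxy sediment-core analysis for reconstructing lake eutrophication and
food-web change: ²¹⁰Pb geochronology, hyperspectral chloropigment indexing,
pigment and zooplankton-subfossil quantification, stratigraphically
constrained zonation, and a permutation-based intervention analysis — with a
synthetic-core generator that plants known effect structure so the whole
chain can be validated by parameter recovery.

## Who it is for

Paleolimnologists and ecologists working with depth-indexed core data:
²¹⁰Pb/¹³⁷Cs activities with errors, per-depth reflectance spectra, HPLC
pigment concentrations, bulk geochemistry (TC%, TN%, δ¹³C, δ¹⁵N), and
subfossil body-part counts with marker-spore tallies. All interchange is
plain CSV with validated schemas.

## What it computes

* **Geochronology** — supported ²¹⁰Pb from the profile tail; the CFCS model
  (error-weighted regression of ln unsupported activity on cumulative dry
  mass, rate r = −λ/slope) and the CRS model (ages
  t(z) = λ⁻¹ ln A(0)/A(z) from the residual inventory, with Monte-Carlo
  95% bands); tie-point transfer of a chronology to an undated core.
* **RABD₆₅₅₋₆₈₀** — the continuum-normalized chlorophyll absorption-band
  depth of reflectance spectra, a total-chloropigment proxy, with moving
  average and depth binning.
* **Pigments & geochemistry** — organic-carbon normalization, fluxes, the
  chlorophyll preservation index Chl a / (Chl a + derivatives), atomic
  TC:TN, and Suess-effect correction of δ¹³C against a pluggable
  atmospheric curve.
* **Subfossils** — minimum numbers of individuals from multiplicity-adjusted
  body-part counts, concentrations per screened volume from Lycopodium
  marker-spore recovery, and influxes from local years-per-cm.
* **Zonation** — CONISS (adjacent-only agglomerative clustering minimizing
  incremental within-cluster sum of squares) with broken-stick selection of
  the number of significant zones.
* **Intervention analysis** — the pre/post mean difference per proxy with a
  seeded permutation null, exact enumeration on short series, and batch
  application across a proxy matrix.

## Worked example

```r
library(paleocore)

core <- generate_core(synthetic_config(seed = 42))
core
#> Synthetic multiproxy core
#>   37 samples, 37 cm, surface 2018 CE, seed 42
#>   planted: intervention 1920 CE (fold 5), collapse 1957 CE (decline 75%)

supp <- estimate_supported(core$activity, tail_n = 5)
prof <- unsupported_activity(core$activity, supp, exclude_tail_n = 5)
fit_cfcs(prof, collection_year = 2018)
#> 210Pb age-depth model (CFCS), collection year 2018
#>   mass accumulation rate: 0.06123 g/cm^2/yr
#>   37 depths, 0.5 to 36.5 cm; ages 2016 to 1839 CE

ria_test(rev(subset(core$pigments, pigment == "diatoxanthin")$conc),
         split_index = 16, n_perm = 999, seed = 1)
#> Randomized intervention analysis (sampled, 999 permutations)
#>   mean pre 25.71, post 124.9; delta 99.15 (+385.6%)
#>   p = 0.001 (add_one)
```

The recovered mass accumulation rate (0.0612 g cm⁻² yr⁻¹) is within 3% of
the planted 0.063 (= 0.21 cm/yr × 0.3 g/cm³) despite 5% activity noise;
the diatoxanthin series, split at the 1920 layer, shows the planted
concentration increase (mean post/pre ≈ 4.9) at the smallest p the add-one
correction allows with 999 permutations.

The whole chain — simulate (or ingest CSVs), date, index, normalize, count,
zone, test — runs as one call and writes per-stage CSVs plus a YAML
manifest:

```r
res <- run_pipeline(pipeline_config(output_dir = "out", n_perm = 999,
                                    seed = 1,
                                    cladoceran_changepoint_year = 1957))
res
#> paleocore pipeline result
#>   age model: CFCS; intervention depth 20.32 cm
#>   zones: 2; significant pigments (p<=0.05): 15/15
```

A thin command-line front end with `simulate`, `date`, `tchl`, `pigments`,
`subfossils`, `zones`, `ria`, and `run` subcommands lives at
`inst/scripts/paleocore.R`.

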