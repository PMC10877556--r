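# tetrasem

Climate shapes global species richness both directly and through the
make-up of local communities.  `tetrasem` implements an assemblage-level
analysis for tetrapods (amphibians, birds, mammals, squamates) that asks
how contemporary climate and climate *instability* — the change in
temperature and precipitation since the Last Glacial Maximum — drive
species richness directly and indirectly via three community-wide traits:
log median body mass, body-size variance, and a trophic-structure index.
It is written for macroecologists who want the full pipeline — from range
polygons to standardized effect decompositions — as tested, seedable code.

## The model

Per taxon group, a piecewise structural equation model (pSEM) over
grid-cell assemblages:

```
climate  ──────────────┐
   │  │                ▼
   │  ├──► body_size ──────────► richness
   │  ├──► size_variance ──────►    ▲  ▲
   │  └──► trophic_structure ──►    │  │
instability ───────────────────────-┘  │
   └──► (each trait) ──────────────────┘
```

* `climate` and `instability` are **composite variables**: regression
  weighted sums of (temperature, precipitation) and of the two LGM
  anomalies, z-scored to unit variance.
* Each endogenous node is one OLS submodel; trait errors covary freely.
* Global structure is tested by directed separation: every non-adjacent
  pair yields an independence claim, and Fisher's
  `C = -2 Σ ln p_i ~ χ²(2k)` summarises them.
* Effects on richness are decomposed as **direct** (β of the edge),
  **indirect** (sum over mediated paths of the product of standardized
  coefficients), and **total = direct + indirect**, exactly.
* Spatial autocorrelation is absorbed with distance-based Moran's
  eigenvector maps (dbMEM: minimum-spanning-tree truncation,
  `w = 1 − (d/4t)²`), selected per submodel by minimising residual
  Moran's I (MIR) with a seeded permutation stop rule.

Community traits follow the field's conventions: trophic weights 2
(primary consumer, >90% plant diet), 2.5 (omnivore), 3 (secondary
consumer, >90% animal diet); body size is log10 of the median mass in
grams; cells with fewer than 3 species are excluded; species are present
in a cell iff a range polygon contains the cell centroid.

A synthetic-data module generates all inputs — spatially autocorrelated
two-era climate fields, disc ranges placed along the temperature field,
log-normal masses, mixture diets, and a grid-level structural table with
known standardized coefficients — so every stage is validated by parameter
recovery rather than by eyeballing maps.

## Worked example

```r
library(tetrasem)

cfg <- synthetic_config(seed = 1)                 # known true paths
g   <- generate_grid_sem_data(cfg, n = 2000)      # per-cell model table
fit <- fit_psem(default_path_model(), g$data)     # four OLS + d-sep + effects
print(fit)
```

```
Piecewise SEM fit
  submodels: body_size, size_variance, trophic_structure, richness
  R-squared: body_size=0.12, size_variance=0.19, trophic_structure=0.09, richness=0.40
  d-separation: saturated model (no testable claims)
  standardized effects on richness
         predictor     direct    indirect       total
           climate  0.4190246  0.11112244  0.53014705
       instability  0.1689765 -0.09980412  0.06917241
         body_size -0.2436971  0.00000000 -0.24369714
     size_variance  0.2492454  0.00000000  0.24924540
 trophic_structure -0.1394863  0.00000000 -0.13948631
```

The generating coefficients were 0.40 (climate→richness), 0.20
(instability→richness), −0.25, 0.25, −0.15 for the three traits; every
estimate lands within 0.031 of truth here.  The positive indirect climate
effect (0.111) is the sum of the three mediated path products, and each
total is exactly direct + indirect.  The theoretical model is saturated
once correlated trait errors are excluded from the basis set, so Fisher's
C has no claims to test on this DAG; sparser DAGs report C, df and a
global p.

The numbered scripts under `analysis/` run the full narrative: simulate
the study system (`01`), build per-group assemblages from ranges, traits
and climate (`02`), fit composites + dbMEM + pSEM with a report under
`results/sem/` (`03`), and run the recovery/calibration studies (`04`).

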