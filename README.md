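# cytostd

Flow cytometry produces one row of measurements per cell ("event"):
scatter signals plus fluorescence intensities from antibody-conjugated
markers. The measurements themselves travel well — every instrument
writes the FCS file format — but the *analysis* traditionally does not:
gate boundaries, per-cell classification results and the relationships
between raw, preprocessed and derived files are usually locked inside
vendor-specific formats. `cytostd` is an R implementation of the family
of open standards that make the whole analysis exchangeable:

| Layer | What it captures | In this package |
|---|---|---|
| **FCS 3.1** | raw list-mode event data + metadata keywords | `read_fcs()`, `write_fcs()` (2.0/3.0/3.1 readable, 3.1 written) |
| **Gating-ML** | exact, reproducible gate definitions | `read_gatingml()`, `write_gatingml()`, `evaluate_gate()`, `evaluate_all()` |
| **CLR** | per-event, possibly fuzzy class-membership probabilities (CSV) | `read_clr()`, `write_clr()`, `hard_assignment()` |
| **ACS** | ZIP container bundling all of the above with an XML table of contents, relations and checksums | `acs_pack()`, `acs_unpack()`, `acs_validate()`, `acs_relation_graph()` |

Supporting layers: the five standard display-scale transformations
(`transform_scale()`: linear, log, inverse hyperbolic sine, logicle,
hyperlog — logicle being the inverse of the biexponential
`B(y) = a e^{by} − c e^{−dy} − f`), and spillover compensation with the
FCS 3.1 `$SPILLOVER` convention: with events as row vectors,
`observed = true · S` where `S[i,j]` is the fraction of fluorochrome
*i*'s signal seen by detector *j*, so compensation right-multiplies by
`S⁻¹` (`compensate()`, `parse_spillover_keyword()`).

A seeded synthetic-data module (`simulate_sample()`) generates
PBMC-like 10-parameter samples (scatter; CD123, CD11c, MHC-II, CD14;
IL-6, IL-12, TNF-α, IFN-α) as a Gaussian mixture of monocytes, myeloid
and plasmacytoid dendritic cells, B cells, debris and two "novel"
populations, with spillover applied and ground-truth labels retained.
On top of it, `build_example_acs()` reproduces a complete analytical
workflow — preprocessing (live gate, compensation, channel subsetting),
manual-style gating, Gaussian-mixture clustering, Hungarian cluster
matching, precision/recall/F comparison — and bundles everything into
one ACS container.

## Worked example

```r
library(cytostd)

res <- build_example_acs(seed = 42, path = "example.acs")
res$comparisons[[1]]
#> <comparison_result>
#>  population precision recall f_measure
#>   monocytes         1      1         1
#>         mDC         1      1         1
#>         pDC         1      1         1
#>     B cells         1      1         1
#>   mean F-measure: 1.0000
print(res$container)
#> <acs_container> v1.0: 8 member(s), 8 ToC entries, 6 relation(s)
#>   fcs/sample1.fcs [application/vnd.isac.fcs] - raw data
#>   fcs/sample1_preprocessed.fcs [application/vnd.isac.fcs] - preprocessed data
#>   gating/sample1_gates.xml [application/xml+gating-ml] - manual gating description
#>   clr/sample1_clusters.csv [text/csv+clr] - automated classification results
#>   ... (same four for sample2)
```

The default synthetic populations are deliberately well separated
(≥ 8 latent standard deviations between neighbouring populations on at
least one marker), so near-perfect agreement between the gates and the
mixture-model clusters is the expected outcome; the comparison
machinery, not the difficulty of the data, is what is being exercised.

The per-population table compares the manually gated populations with
the matched mixture-model clusters: precision is the fraction of a
cluster's events that really belong to the population, recall the
fraction of the population the cluster recovers, and
`F = 2PR/(P + R)`. The container holds 2 raw FCS + 2 preprocessed FCS +
2 Gating-ML + 2 CLR files plus `TOC.xml`; `acs_validate()` returns zero
findings and `verify_example_acs()` replays the shipped gates against
the shipped data. Rebuilding with the same seed yields byte-identical
archives, and the `.acs` file opens in any ZIP tool.

A command-line interface wraps the same functions
(`inst/cli/cytostd`): `cytostd fcs info`, `cytostd gate apply`,
`cytostd clr validate`, `cytostd acs pack|unpack|validate|graph`,
`cytostd synth`, `cytostd example build|verify`.

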