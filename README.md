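# stemnet

Signed co-expression network screening for **secondary cell wall (SCW)
regulators** in developing grass stem internodes.

## What it does, and for whom

Stem biomass in sorghum and other bioenergy grasses is mostly cell wall:
cellulose, hemicelluloses (xylans) and lignin laid down as the secondary
wall once internode cells stop elongating. The MYB and NAC transcription
factor families contain the master switches of this program, but moving
from *Arabidopsis* homology to working candidates in a grass requires
expression evidence. `stemnet` is for plant genomicists who have (or want
to simulate) a gene × sample RNA-seq count matrix over internode
development and want a reproducible path from counts to a ranked table of
MYB/NAC candidates with co-expression evidence.

The pipeline: low-expression filtering (> 3 reads in ≥ 20 samples) →
TMM/log2-CPM normalization → batch (year/block) estimation and removal →
signed weighted co-expression network → module detection and
strong-correlation refinement → hub ranking by intramodular connectivity
→ GO / custom cell-wall-list over-representation → two-layer top-15
bait subnetworks around every MYB/NAC gene → enrichment-category
classification — plus Van Soest fiber-fraction summaries
(hemicellulose = NDF − ADF, cellulose = ADF − ADL, lignin = ADL) to tie
module expression peaks to wall deposition.

At its core is the soft-thresholded signed-hybrid adjacency

```
a_ij = r_ij^beta  (r_ij > 0, beta = 12),   a_ij = 0 otherwise
```

so an adjacency cutoff of 0.1 corresponds to a gene–gene correlation of
about 0.82, and the topological overlap

```
TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)
```

whose complement drives average-linkage module detection. A
negative-binomial synthetic-data generator with planted modules, planted
hubs, planted annotations and a 191-sample three-year internode design
makes every stage testable end to end without any download.

## Worked example

```r
library(stemnet)
res <- run_pipeline(list(seed = 1, simulate = TRUE,
                         output_dir = "stemnet_output"))
res$cw_modules
#>      module n_genes n_retained    cw_list_p n_cw_go_terms cw_related
#> 1 turquoise      60         60 1.000000e+00             0      FALSE
#> 2      blue      60         60 1.000000e+00             0      FALSE
#> 3     brown      60         60 1.704665e-81            28       TRUE
#> 4    yellow      60         60 1.704665e-81            28       TRUE
#> 5     green      60         60 1.000000e+00             0      FALSE
```

Five modules are detected in the default simulation; two (`brown`,
`yellow` — the planted late-peaking SCW programs) pass the dual
criterion: Fisher enrichment in the custom cell-wall gene list *and* at
least one enriched cell-wall GO term.

```r
head(res$evidence, 6)
#>   gene_id tf_family clade module is_hub_top10 is_hub_top10pct subnetwork_size cw_term_count category status
#> 1  G00121       NAC     C  brown         TRUE            TRUE              45            28     high     ok
#> 2  G00122       MYB     4  brown        FALSE           FALSE              45            28     high     ok
#> 3  G00123       NAC     C  brown        FALSE           FALSE              45            28     high     ok
#> 4  G00181       NAC     C yellow         TRUE            TRUE              44            28     high     ok
#> 5  G00182       MYB     4 yellow        FALSE           FALSE              40            28     high     ok
#> 6  G00183       NAC     C yellow        FALSE           FALSE              43            28     high     ok
```

Every bait planted in a cell-wall module screens as `high` (≥ 12
significant CW GO terms in its two-layer subnetwork of ≤ 241 genes), and
the planted hub of each module (`G00121`, `G00181`) carries the
`is_hub_top10` flag — it ranks in the module's top 10 by intramodular
connectivity (kWithin). Baits in non-CW modules classify `none`.

```r
fr <- derive_wall_fractions(res$data$biochem)
compare_stages(fr, res$data$samples, "lignin")
#>     trait stage  n     mean standard_error single_replicate letter_group
#> D1 lignin    D1 32 1.362061      0.2051674            FALSE            c
#> D2 lignin    D2 16 1.609863      0.2030216            FALSE            c
#> D3 lignin    D3 64 3.126831      0.1147223            FALSE            b
#> D4 lignin    D4 16 5.130859      0.2407969            FALSE            a
#> D5 lignin    D5 63 5.636781      0.1298007            FALSE            a
```

Lignin accumulates late (stages sharing a letter are not significantly
different; Welch + Holm at α = 0.05), trailing the polysaccharides —
exactly the planted trajectory.

See `vignettes/stemnet-methods.Rmd` for the model, parameter defaults,
generator assumptions and numerical conventions.

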