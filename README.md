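# attinakaryo

Comparative cytogenetics of the fungus-farming ants (Formicidae:
Myrmicinae: Attini: Attina) in R: karyomorphometry from metaphase
measurements, compilation statistics over published cytogenetic records,
and chromosome-number / genome-size mapping on a time-calibrated phylogeny,
plus simulators for every kind of input the pipeline consumes.

## The science

Ant karyotypes are described by a handful of standard quantities measured
on metaphase chromosomes:

- **TL**, the total length of a chromosome (µm); **L** and **S**, its long-
  and short-arm lengths, with TL = L + S;
- the **arm ratio** r = L/S, which places the centromere and defines the
  morphology classes *metacentric* (m), *submetacentric* (sm),
  *subtelocentric* (st) and *telocentric* (t) — this package assigns
  m for r ≤ 1.5, sm for 1.5 < r ≤ 3, st for 3 < r ≤ 7 and t beyond
  (see the vignette for why these cutpoints);
- the **relative length** RL = TL × 100 / ΣTL, summing to 100 per spread;
- the **karyotype formula** 2K (e.g. `24 m + 4 sm`), the **fundamental
  number** FN = 2·(m + sm + st) + (t + a) counting chromosome arms, and the
  **karyotype length** KL = Σ TL.

Across the subtribe, compiled counts range from n = 4 to n = 27 while 1C
genome sizes cluster tightly around 0.38 pg. Mapping both traits on a
time-calibrated tree shows the same low numbers (n = 10–12) persisting in
many mutually independent clades over tens of millions of years —
karyotype stasis — while high numbers (n > 15) are confined to scattered
lineages that also carry richer C-band heterochromatin. The package's
fission/fusion chain (a continuous-time random walk on n with an optional
hard cap) and Brownian genome-size model let users explore the hypothesis
that a genome-size constraint imposes an upper limit on chromosome number.

## Worked example

```r
library(attinakaryo)

# karyomorphometry: packaged per-chromosome profiles of a new karyotype
kt <- attina_karyomorph_tables()
summarize_karyotype(kt[["Myrmicocrypta sp."]])
#> Karyotype summary (diploid material)
#>   2n = 28, 2K = 24 m + 4 sm, FN = 56, KL = 82.47 um

# the record compilation
s <- summarize_records(attina_records())
s
#> Cytogenetic record summary
#>   records: 61 (59 distinct taxon-karyotype pairs, 10 morphospecies)
#>   haploid number range: 4-27
#>   genome size: 31 taxa, mean 0.38 pg (sd 0.09)

# karyotype stasis on the packaged chronogram
at <- attach_traits(attina_timetree(), make_trait_table(attina_records()))
fixed_number_clades(at, 11)[, c("n_tips", "crown_age", "stem_age")]
#>   n_tips crown_age stem_age
#> 1      5      13.7       16   # all Atta
#> 2      3       4.7       18   # all Amoimyrmex
#> 3      1       0.0       45   # an Apterostigma lineage
#> 4      1       0.0       18   # a Cyphomyrmex lineage
#> 5      1       0.0       20   # a Mycetomoellerius lineage
```

The five n = 11 clades are mutually independent: the haploid number 11 has
been in place since before the Atta/Acromyrmex split yet reappears on
deep Paleoattina branches — the stasis pattern the analysis quantifies.

The full analysis is scripted under `analysis/` (run from the repository
root, in order): `01_karyomorphometry.R`, `02_records.R`,
`03_phylo_stasis.R`, `04_simulation_upper_limit.R`. Each writes its tables
under `results/`.

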