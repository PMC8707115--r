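---
title: "Karyomorphometry and karyotype evolution in fungus-farming ants: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyomorphometry and karyotype evolution in fungus-farming ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attinakaryo)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the analysis runs: measurement,
compilation, phylogenetic mapping, simulation.

## Karyomorphometry

A metaphase spread is a table of per-chromosome arm measurements
(`spread_id`, `chromosome_index`, `long_um`, `short_um`). Orientation is
normalised on construction — the larger measurement is always the long
arm — so the arm ratio r = L/S is at least 1 by definition. From a set of
spreads of one individual (at least 10 in standard practice),
`aggregate_spreads()` produces per-chromosome profiles:

1. within each spread, chromosomes are ranked by total length TL = L + S
   descending, and consecutive ranks are paired as homologues. This
   size-rank pairing is the standard manual convention; no published
   pairing algorithm exists for these data. Ties are broken by long-arm
   length, then input order, making the ranking deterministic.
2. TL, L, S, the relative length RL = TL·100/ΣTL and r are computed per
   spread and then averaged across spreads (sample SD, n − 1; a single
   spread reports SD 0). Averaging ratios per spread, rather than taking
   the ratio of averaged arms, matches how published tables are built:
   their printed mean r is not always the ratio of the printed mean arms.
3. morphology is classified from the mean r per chromosome.
4. profiles are displayed in the conventional order — pairs grouped by
   morphology class (m, sm, st, t), within a class by decreasing size —
   mirroring published karyomorphometric tables.

### Morphology cutpoints

Levan's nomenclature names the classes; the cutpoints in use vary between
authors. The classical scheme places the m/sm bound at r = 1.7, but the
karyomorphometric tables this package reproduces classify chromosomes with
mean r = 1.61 as submetacentric while r up to 1.50 is metacentric. The
package therefore adopts the widely used alternative cutpoints

> m: 1 ≤ r ≤ 1.5 < sm: r ≤ 3.0 < st: r ≤ 7.0 < t: r > 7.0

(each bound belonging to the smaller class), which reproduce every
printed classification in the reference tables, including the r = 1.70
submetacentric boundary case. The bounds are exposed via
`levan_thresholds()` for users who prefer the 1.7 convention. An
acrocentric label `a` is accepted in karyotype formulas (compilations mix
`t` and `a` across sources) and counted as one-armed, but the classifier
never emits it.

### Karyotype summaries

`summarize_karyotype()` derives the chromosome number (2n, or n for
haploid male material), the karyotype formula 2K, the fundamental number
FN = 2·(m + sm + st) + (t + a), and the karyotype length KL = Σ mean TL.
For any formula, 2n ≤ FN ≤ 2·2n, with equality on the right exactly when
no one-armed chromosome is present.

### Heteromorphism screening

`detect_heteromorphism()` flags a homologue pair when the two homologues
fall in different morphology classes in at least 50% of spreads, or when
their mean TLs differ by more than a factor 1.25. Both thresholds are
arguments. The defaults separate a persistent structural polymorphism
(such as a published submetacentric pair-15 case) from per-spread
measurement noise: under the package's default noise model (2% arm error),
class flips at these distances from the cutpoints are rare and never
systematic.

## The record compilation

Records follow a fixed TSV schema (one row per published count; see
`?record_schema`). Conventions worth stating:

- **Counting rules.** "Unidentified" counts *records* whose epithet is a
  morphospecies label (`sp.`, `sp.1`, ...); "taxa with genome size" counts
  *distinct taxon names* carrying a 1C value, so repeated records of one
  taxon count once. These two rules jointly reproduce the published
  compilation's headline numbers (10 morphospecies records, 31 taxa with
  genome sizes). The mean genome size averages record-level values (each
  non-missing cell once, 0.376 → 0.38 pg at 2 dp); deduplicating by taxon
  changes nothing at 2 dp, and the record-level rule is the more
  transparent.
- **Row counts.** The summary reports the raw record count (61) and the
  distinct (taxon, karyotype) count (59). The source literature quotes "58
  chromosome counts" and "13 of 18 genera" without stating its
  deduplication rule; neither number is derivable from the table alone
  (the packaged table spans 12 genera), so the package reports its own
  well-defined counts instead.
- **Validation, not correction.** Compilations mix diploid and haploid
  formula conventions, and a few rows are internally inconsistent
  (a 2n = 54 record whose formula sums to 48; two records of one species
  whose formulas appear swapped). `validate_records()` reports a status
  per record — `diploid_consistent`, `haploid_consistent`,
  `inconsistent`, `no_formula` — and never edits the data. The statuses
  over the packaged table are frozen in a golden file in the test suite.
- **Known data notes.** One *Acromyrmex* record (2n = 36) departs from
  the genus's otherwise uniform n = 19; narrative summaries that state
  "all Acromyrmex are n = 19" gloss over it. One karyomorphometric table
  row prints a TL cell that disagrees with its own L + S by 0.10 µm; the
  package treats the L cell as the misprint since the printed KL sums the
  TL column.
- Heterochromatin positions left blank by a source are *unknown*, not
  negative, and are excluded from band-richness denominators.
  `band_richness_by_threshold()` is deliberately descriptive (group sizes
  and means, no test): the underlying claim in the literature is
  qualitative, and the records are neither independent nor randomly
  sampled.

## Traits on the time-calibrated tree

`attach_traits()` matches reconciled per-taxon traits (haploid number,
genome size) to tree tips by normalised name (case-insensitive,
underscores as spaces); genus-level fallback exists but is off by
default. Reconciliation of multiple records per taxon prefers newly
reported counts, then table order, and flags taxa whose records disagree
on n.

`fixed_number_clades()` returns every *maximal* monophyletic group in
which all trait-bearing tips share a given n and at least one tip bears
it. Tips without traits are neutral — they neither support nor break
uniformity — because the underlying reasoning is over sampled taxa only;
`strict = TRUE` requires full trait coverage. Maximality is computed by a
postorder sweep (a node is uniform iff no descendant trait-tip differs;
maximal iff its parent is not uniform); the test suite verifies this
against a brute-force enumeration over all nodes on random trees.
Polytomies are allowed and a polytomous ancestor is one clade. Crown age
is the node's age (maximum tip-to-node path length on an ultrametric
tree); stem age is the parent's age.

The packaged chronogram is a *synthetic fixture*: its genus-level topology
follows the published phylogeny of the subtribe and its node ages are set
to the approximate crown ages quoted for the stasis clades (~45, ~25,
~24.8, ~19, ~16.8, ~13.7, ~4.7 Myr). It exists so the mapping is runnable
and testable; it is not a reproduced divergence-time estimate, and no
quantitative conclusion in this package depends on a specific age.
Morphospecies records that share one label ("Apterostigma sp." appears
three times with three different counts) cannot be tree tips — tip labels
must be unique — and surface in the match report as unused traits.

## Simulators

All simulators are pure functions of their inputs and an explicit seed.

**Metaphase spreads.** Per spread, a condensation factor c ~ log-normal
(median 1, log-SD `condensation_sd`, default 0.10) scales every
chromosome jointly — condensation varies between metaphases but is shared
within one — and each arm independently picks up multiplicative error
1 + ε, ε ~ N(0, `arm_noise_sd`) (default 0.02, a realistic digitising
error for µm-scale measurements). Defaults represent the measurement
protocol the karyomorphometry module assumes: 10 spreads per individual.
With these defaults, morphology recovery is essentially perfect for
karyotypes whose true r values stay ≥ 0.05 away from the class cutpoints
(the test suite requires ≥ 99/100 replicates). What the generator does
*not* emulate: overlapping or bent chromosomes, rank-swapping between
similar-sized non-homologues, and satellite/secondary constrictions — so
a passing recovery test says nothing about segmentation-stage errors in
real micrographs.

**Chromosome number.** A continuous-time random walk on the haploid
number: fissions (n → n+1) at `fission_rate` and fusions (n → n−1) at
`fusion_rate` events/Myr along each branch, simulated exactly via
exponential waiting times. The walk reflects at `n_min` (default 1) and,
if `n_cap` is set, cannot fission above the cap — a deliberately minimal
embodiment of the verbal model in which fissions and fusions balance and
an upper limit exists. With equal rates the expected tip value equals the
root value (verified by Monte Carlo); fission-only chains are monotone
non-decreasing. The source literature proposes no quantitative rates;
the defaults (0.05/Myr each) are chosen so that a 55-Myr-deep tree
accumulates a handful of events per lineage, matching the observed
within-genus stability, and are not fitted estimates. No likelihood
inference on the chain is provided or implied.

**Genome size.** Brownian motion along branches (SD `gs_sigma`·√length,
default 0.02 pg/√Myr around a root of 0.38 pg — the compilation mean),
floored at a small positive value, with an optional per-fission jump
(`gs_fission_jump`) coupling chromosome-number gain to repetitive-DNA
growth. Tip variance grows linearly with root-to-tip path length
(verified by regression across replicates).

**Record tables.** `make_fixture_tables()` emits a schema-complete
synthetic compilation together with a ledger of every summary statistic
bookkept during generation, so the records module can be tested for exact
recovery without touching the real table.

## Problem sizes and numerical notes

The test suite and analysis scripts run at desk scale: the clade-oracle
comparison uses 100 random trees of 20–25 tips; chain calibration uses
500 replicates on the 51-tip fixture tree; spread recovery uses 100
replicates of 10 spreads. Table-facing output is rounded half-to-even at
2 decimals; all internal computation is at full precision.
Ultrametricity is checked to a relative tolerance of 1e-6 of tree depth.
Degenerate inputs have defined behaviour: a single spread yields SD 0, a
single tip is a valid (degenerate) clade, and an empty group in the
band-richness split is reported as size 0 with NA mean.

## Limitations

- The karyomorphometry module consumes measurement tables, not images;
  chromosome detection and band densitometry are out of scope.
- The record table is a static packaged snapshot of the published
  compilation; there is no live database access.
- The phylogeny is consumed as input. No dating, model selection or
  ancestral-state reconstruction is performed — clade uniformity is a
  descriptive mapping, deliberately matching the qualitative character of
  the claims it implements.
- The fission/fusion and Brownian models are exploration tools; fitting
  them to data (chromEvol-style inference) is explicitly not provided.
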