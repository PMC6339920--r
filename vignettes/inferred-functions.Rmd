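---
title: "Inferring community functional potential from 16S taxonomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community functional potential from 16S taxonomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funmapper)
```

## The problem and the model

Amplicon (16S rRNA gene) sequencing yields taxonomic abundance profiles but
no direct measurement of a community's functional gene content. Because
sequenced prokaryotic genomes carry annotated copy numbers for functional
units — EC enzymes, KEGG Orthologs, COG, Pfam and TIGRfam families — the
functional potential of a community can be *inferred*: each taxon in the
profile is matched to the genomes sharing its lineage, and the community's
unit content is the abundance-weighted combination of those genomes' copy
numbers. funmapper implements this inference chain and the downstream
comparative analytics as a batch library with a thin command-line front end.

The chain has four steps.

**1. Copy-number correction.** Amplicon read fractions over-represent taxa
with many 16S gene copies. With relative abundance $a_{ts}$ for taxon $t$ in
sample $s$ and mean 16S copy number $c_t$ over the genomes matching $t$'s
lineage, the corrected abundance is

$$\tilde a_{ts} = \frac{a_{ts}/c_t}{\sum_{t'} a_{t's}/c_{t'}}.$$

Taxa matching no genome are dropped and their mass is accounted per sample
in a coverage report; a sample losing all its mass is flagged uninferable.

**2. Unit profiles.** Under the *co-metabolism* (CoM) assumption community
members pool the units they encode, so the community abundance of unit $u$
is $U_{us} = \sum_t \tilde a_{ts}\, m_{tu}$, where $m_{tu}$ is the mean copy
number of $u$ across the genomes matched by $t$.

**3. Cross-mapping.** Unit profiles can be translated to another namespace
through a many-to-many cross-map; a source unit's abundance is split equally
across its targets ($1/\mathrm{outdegree}$ each) so mapped mass is conserved,
and unmapped source mass is reported.

**4. Pathway estimation with quorum filtering.** A pathway is reported
present in a sample only when the fraction of its member units with strictly
positive abundance reaches the *pathway exclusion cut-off* (PEC). Profiles
are computed unfiltered (PEC 0) and at the five grid levels 50–90%; the
presence sets are nested across the grid by construction. For a present
pathway the raw abundance is the sum of member-unit abundances with each
unit split equally across all pathways containing it (the *multiplicity
split*; `split = FALSE` gives the plain sum), and per-sample profiles are
renormalized over surviving pathways.

Under the *independent contributions* (ICo) assumption each taxon is an
independent functional entity: its private unit vector is
$\tilde a_{ts} m_{tu}$, the PEC quorum is evaluated on the taxon's own
detected units, and per-taxon pathway abundances are summed into the
community profile. The pre-normalization taxon × pathway × sample values
form the contribution tensor, whose taxon-sums reproduce the un-normalized
ICo profile exactly; the tensor feeds the contributor tables and
co-contribution networks. For a single-taxon community CoM and ICo coincide,
and in general the CoM presence set contains the ICo one, since pooling can
only add detected units.

## Design choices where the method was open

Several details of this tool genre are conventions rather than published
formulas; funmapper fixes them as follows and exposes each behind a
parameter.

* **Taxon–genome aggregation** is the unweighted arithmetic mean of copy
  numbers over every genome matching the query lineage at its deepest named
  rank (and all named ancestor ranks), after normalizing names (lowercase,
  rank prefixes and bracketed qualifiers stripped). The mean is
  order-independent and treats each sequenced genome equally; whether the
  original web back-ends average, sum or pick best hits is not documented
  anywhere we could verify.
* **Shared enzymes** are split across pathways by multiplicity rather than
  double-counted, keeping column totals conserved through the hierarchy
  roll-up (level3 → level2 → level1 sums preserve column sums exactly).
* **Quorum counting** uses strictly positive abundance, not an abundance
  floor — the cut-off is defined on the *proportion of detected
  constituents*. At PEC 0 a pathway with no detected unit is still reported
  absent (its abundance is zero regardless).
* **Lineage dialects.** Greengenes is recognized by `k__`-style prefixes
  (majority vote over rows), SILVA by prefix-free, domain-led,
  ≥5-field semicolon lineages, and RDP is the fallback (plain or name;rank
  alternating). "unclassified"/"uncultured" tokens terminate a lineage so
  they never match genomes spuriously. Counts and proportions are both
  accepted; every sample is renormalized to sum 1, making all relative
  outputs invariant to per-sample scaling.

## Statistics and ordination

Two-class comparisons use the two-sided Wilcoxon rank-sum test, exact when
both groups have ≤ 8 samples and the normal approximation with tie
correction otherwise; multi-class comparisons use Kruskal–Wallis. Raw and
Benjamini–Hochberg-corrected p values are both reported; functions constant
across all samples are skipped and listed. The PEC consensus marks each
function significant or not at every sweep level (absent-at-level counts as
not significant) and scores it by the fraction of the five levels passed.

Ordination uses the Jensen–Shannon divergence with base-2 logarithms (so it
is bounded in [0, 1]) and a $10^{-9}$ pseudocount before renormalization;
the embedded distance is $\sqrt{\mathrm{JSD}}$, which is a metric and in
practice embeds with non-negative eigenvalues. Classical PCoA
(double-centred $-\tfrac12 d^2$, eigendecomposition) reports all
eigenvalues including negative ones, and fixes each axis's sign so its
first nonzero loading is positive.

Co-contribution networks correlate, for every taxa pair and every pathway
both contribute to, the per-sample contribution series by Spearman's rho.
Candidates need rho ≥ 0.6 (positive only — the hypothesis is
*co*-contribution), p values are BH-corrected across all candidate
(pair, function) tests, and an edge survives when at least one of its
functions does at $\alpha = 0.05$. Degree, normalized betweenness and local
clustering coefficients are computed on the resulting simple graph. At
least 4 samples are required; with fewer, rank correlation is meaningless.

## What the synthetic generator emulates

`generate_synthetic_db()` builds a structurally faithful genome–function
map: a consistent nested taxonomy (two domains, a handful of phyla through
genera), 16S copy numbers uniform on 1–15 (the span observed across
sequenced prokaryotes, which exercises the correction non-trivially), unit
copies uniform on 0–`max_copies`, pathways of 3–12 EC members with a full
three-level hierarchy path, and a random EC→KO cross-map.
`generate_synthetic_community()` draws a 2 × 2 Status × Timepoint study
(Control/Treated × Day2/Day42, three samples per cell by default),
log-normal baseline abundances across genera with 0.4-SD sample noise, and
a 4-fold perturbation of a random third of the genera in Treated samples so
differential signal exists by construction.

What this does *not* emulate: real copy-number correlation structure along
the phylogeny, incomplete genome annotation, compositional zero-inflation,
or lineage strings that disagree between reference taxonomies. Passing
tests on synthetic data therefore demonstrate the algebra and the contracts
of the pipeline — conservation, nesting, invariances — not field accuracy
of inference on real communities, which is bounded by the quality of the
genome–function database supplied.

## Numerical and degenerate-input conventions

Column renormalization leaves all-zero columns at zero and flags them.
Conservation identities (tensor sums, roll-ups) are exact to 1e-9 and
tested at that tolerance. Ranking ties in top functions break
lexicographically by function id. Degenerate inputs fail loudly: ragged or
non-numeric tables, metadata naming unknown samples, pathways referencing
unknown units, cross-maps without a source, ordination on identical
samples. Profile, database and KEGG-export serializations round-trip
losslessly; KEGG colour files use a 5-bin diverging palette over the log2
ratio of two class means clipped to ±2, with undetected units in the
neutral mid-bin, and the companion 3D "height" file carries mean unit
abundances (the rendering itself is the KEGG web service's job).

## Problem sizes used in the test-suite and acceptance runs

The invariant suites quantify over 50–100 seeded synthetic communities of
5–10 genomes, 10–16 units and 3–4 pathways with 4–12 samples; the
brute-force equivalence checks use 20 random databases of ≤ 5 genomes and
≤ 3 pathways, where an independent straight-line recomputation matches
every matrix to 1e-9. These sizes fully exercise every code path (multi-rank
lineages, shared units, partial quorums, cross-maps) while keeping the
whole suite in the tens of seconds.

## Worked example

```{r example, eval = FALSE}
bundle <- run_synth(tempfile(), seed = 1)
cfg <- make_run_config(algorithm = "ico", pec = 50, out_dir = tempfile())
run_global_map(bundle$taxa_path, bundle$db_dir, cfg, bundle$metadata_path)
run_isfa(cfg$out_dir, bundle$metadata_path,
         make_run_config(out_dir = tempfile()),
         category = "Status", mode = "batch")
```

## Known limitations

Inference quality is bounded by the genome–function database: taxa absent
from it are dropped (visibly, via the coverage report) rather than
imputed — there is no hidden-state prediction across a phylogeny. Pathway
abundance under the multiplicity split is a modelling convention, not a
measured quantity; comparisons should be made within one convention. The
co-contribution network is correlational: edges are hypotheses about
interaction, sensitive to sample size, as any rank correlation over few
samples must be.
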