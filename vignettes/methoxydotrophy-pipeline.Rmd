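---
title: "Genomics and metagenomics of aerobic methoxydotrophy: methods and design"
author: "methoxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomics and metagenomics of aerobic methoxydotrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methoxr)
```

# The scientific problem

Some *Methylobacterium* lineages grow aerobically on lignin-derived
methoxylated aromatic compounds, using both the methoxy (-OCH~3~) group — a
C~1~ substrate whose demethylation releases formaldehyde — and the aromatic
ring itself (via the protocatechuate branch of the beta-ketoadipate
pathway). `methoxr` implements the computational side of that study as a
reusable, tested pipeline over four marker genes:

| marker | KO | enzyme | substrate it gates |
|---|---|---|---|
| *vanA* | K03862 | vanillate monooxygenase, alpha subunit | vanillate |
| *pcaG* | K00448 | protocatechuate 3,4-dioxygenase, alpha subunit | protocatechuate (PCA) |
| *pobA* | K00481 | *p*-hydroxybenzoate 3-monooxygenase | *p*-hydroxybenzoate (PHBA) |
| *ech*  | K18383 | *trans*-feruloyl-CoA hydratase / vanillin synthase | ferulate |

The pipeline has five analysis stages (each a module of exported functions,
driven by the numbered scripts under `analysis/`): marker presence/absence
profiling with gain/loss reconstruction; tetranucleotide composition
analysis of a candidate catabolic island; likelihood-based phylogenetic
placement of metagenome-derived *vanA* fragments; an ecosystem-level survey;
and numeric helpers for the growth assays. A synthetic-data generator
produces every input class with known ground truth, so the whole pipeline is
testable without external downloads.

# Marker profiling and gain/loss reconstruction

Presence of a marker in a genome is defined as *at least one annotation row
carrying the marker's KO identifier* (`build_presence_matrix()`), with the
matching locus tags kept as provenance. No sequence-similarity search is
re-implemented: the profiling operates on annotation exports, as the
original survey did, and synteny-based rescue of mis-annotated homologs is
out of scope.

Gain/loss histories are reconstructed by Fitch parsimony
(`fitch_gain_loss()`): a bottom-up pass over the rooted tree (score = number
of union operations) followed by top-down refinement. Two conventions make
the reconstruction deterministic: ties at the root and at ambiguous nodes
resolve toward absence (state 0), and the full ambiguity sets are always
reported next to the single chosen labeling. The choice of parsimony over
likelihood reconstruction is deliberate — the question asked of the data
("was the capacity ancestral to one clade, with later horizontal
acquisitions?") needs event placement, not rate estimates, and the test
suite can verify the score against an exhaustive enumeration oracle.

Growth prediction from genotype (`predict_growth()`) uses PHBA &#8592;
*pobA*, PCA &#8592; *pcaG*, vanillate &#8592; *vanA*, and ferulate &#8592;
*ech* AND *vanA*: ferulate catabolism funnels through vanillate, so a genome
with *ech* but no *vanA* is predicted not to grow on ferulate. The 8-strain
by 4-substrate assay grid ships as a fixture (`growth_assay_fixture()`);
one encoding judgment is flagged in its `notes`: the modest vanillate growth
of *M. variabile* is encoded "little-or-none".

# Tetranucleotide genome signature and the island scan

`genome_signature()` counts k-mers (default k = 4) over the sequence *and
its reverse complement* (strand symmetrization) — windows containing N are
skipped — and converts frequencies to relative abundances
$\rho^*_w = f_w / \prod_i f_{w_i}$, the observed word frequency over the
product of its single-nucleotide frequencies. `delta_star()` is the mean
absolute difference between two $\rho^*$ vectors,
$\delta^* = 4^{-k} \sum_w |\rho^*_w(a) - \rho^*_w(b)|$, reported raw with
the conventional &times;1000 value alongside.

Two normalizations are exposed because the methodology leaves the choice
open at k = 4: the default zeroth-order form above (the direct
generalization of the dinucleotide statistic) and a maximal-order Markov
normalization $f_w f_{mid} / (f_{prefix} f_{suffix})$ (`normalization =
"mmax"`). Likewise both the raw and &times;1000 scales are always reported.

`island_scan()` operationalizes "is this region compositionally unusual?"
as an empirical-null percentile: $\delta^*$(region, genome) is ranked
against $\delta^*$ of random same-length windows of the genome. Percentile
&le; 95 is reported as *indistinguishable* — the expected verdict for an
ameliorated island or one acquired from a close relative. Two numerical
choices matter:

* **Null windows never overlap the query region.** Windows that overlap the
  island inherit its signature and would let the region blunt its own test;
  with the exclusion, a structured island separates cleanly (percentile
  &gt; 99) while a same-composition region stays uniform in the null.
* **$\rho^*$ is blind to pure GC shifts by construction.** Dividing by the
  single-nucleotide frequencies removes base composition, so an iid
  sequence at any GC has $\rho^* \approx 1$ everywhere. A planted island
  detectable by `island_scan()` must differ in *word structure*, which the
  generator's order-3 Markov mode provides; GC itself is reported separately
  (`gc_content()`, `sliding_gc()` with the 5-kb genome / 500-bp island
  window conventions, step defaulting to the window size).

# Phylogenetic placement of vanA fragments

The placement engine (`edge_likelihoods()`, `place_fragment()`,
`classify_batch()`) is a minimal re-implementation of the pplacer idea:

1. **Alignment.** The fragment is aligned semi-globally (no end penalties on
   the reference) against the column-wise majority consensus of the
   reference alignment, scored +1/&minus;1/&minus;2; both orientations are
   tried. A score below 0 flags the fragment *unalignable* (classified
   "outside"): with these scores a random sequence drifts to a strongly
   negative expected score, so the floor is a safe discriminator.
2. **Likelihood.** For every edge of the unrooted reference tree the
   fragment is grafted at the edge midpoint by a pendant branch (default
   0.1 expected substitutions/site) and the log-likelihood is computed by
   Felsenstein pruning over the columns where the fragment is non-gap; N is
   missing data. Directional messages on the reference tree are computed
   once per package and cached, so per-edge work is a handful of 4&times;L
   matrix products.
3. **Weights and classification.** Likelihoods become likelihood weight
   ratios $LWR_e = e^{\ell_e - \ell_{max}} / \sum_{e'} e^{\ell_{e'} -
   \ell_{max}}$. The fragment is classified by the most specific labeled
   clade whose induced subtree contains both endpoints of the best edge
   (ties broken toward the lowest edge id), else "outside". For a singleton
   clade the induced subtree is taken to be the leaf plus its parent —
   otherwise a one-leaf clade could never be called.

Models are JC69 (default) and K80 (optional $\kappa$); branch lengths are in
expected substitutions per site and the models are verified against closed
forms and a brute-force enumeration oracle. The full pplacer feature set
(GTR+&Gamma;, pendant/attachment optimization, Bayesian mode) is
deliberately out of scope; the midpoint attachment and fixed pendant keep
the engine analyzable. An optional LWR-mass filter is available when writing
jplace output, but classification always uses the single best edge — how the
original analysis decided a gene "fell within" the genus is not stated, and
best-edge is the stricter, simpler reading.

# The metagenome survey

The survey stage reproduces the published bookkeeping exactly:

* `filter_metagenomes()` keeps metagenomes with **strictly more than** 100
  marker genes (the boundary value is excluded, per the stated ">100" rule).
* `select_candidates()` matches scaffold lineage labels against
  *Methylobacterium* **and** *Methylorubrum*, case-insensitively.
* `conservative_intersect()` keeps only candidates whose placement also
  falls in an in-genus clade — not "outside" and not any clade labeled
  `outgroup*`. This is the conservative dual-classifier rule: a scaffold
  counts only when the database lineage assignment and the placement agree.
* `map_sample_type()` maps raw Ecosystem-Type strings to sample types
  (Phyllosphere/Phylloplane &rarr; Leaf, Rhizosphere/Rhizoplane &rarr; Root,
  &hellip;); the shipped table covers the documented pairs plus obvious
  identities, is user-extensible, and totalizes via "Other" with a warning.
* `summarize_survey()` reports per-clade and per-sample-type counts with
  integer percents rounded **half away from zero** — the convention that
  reproduces 63/17/20 from 114/31/37 of 182 — plus exact raw fractions
  (rounded percents are never forced to sum to 100), and the candidate
  frequency to two decimals (348 of 317,816 &rarr; 0.11%).

Read-recruitment surveys are supported only as tallying of externally
supplied hit tables (`tally_hits()`); the aligner is out of scope, and the
published environmental percentages that depend on external sample metadata
are not recomputed.

# Assay numerics

`substrate_concentration()` converts a target carbon concentration (default
16 mM C) to substrate mM (`target / carbons`, two decimals, half away from
zero — reproducing 2.67 mM glucose and 2.29 mM PHBA).
`collate_growth()` tidies plate-reader long tables into per-well curves and
replicate summaries (max OD mean/range, time to half-max; no growth-model
fitting — the source analysis reports raw curves).
`summarize_formaldehyde()` extracts the peak, the peak time, and the first
return below the detection limit (default 0.01 mM, configurable; the
original limit is unstated), censoring sub-limit values at the limit. The
two qualitative patterns of interest are: transient accumulation peaking
mid-exponential with later return below the limit (non-methylotrophic
lignin degraders) versus no detectable formaldehyde at any time
(*Methylobacterium*).

# The synthetic-data generator

Every input class is generated with ground truth:

* `simulate_tree()` — Yule trees (ape's birth-death sampler, death 0),
  ultrametric, seed-deterministic.
* `evolve_sequences()` — indel-free JC69/K80 simulation from a uniform root;
  verified against the JC69 expected-difference closed form.
* `fragment_genes()` — contiguous substrings with coordinates, optional
  reverse-complementing and a uniform per-base error rate (default 0:
  assembled scaffolds, not raw reads, are emulated).
* `simulate_genome_with_island()` — host and island from independent iid
  (order 0) or 3rd-order Markov chains. In the Markov mode each context's
  G+C probability equals the target GC exactly (only the G-vs-C and A-vs-T
  splits are Beta-perturbed), so island GC is unbiased while tetranucleotide
  structure differs between island and host. The Markov order is capped at
  3, matching the resolution of the tetranucleotide statistic. The island
  lands &ge; 500 bp from either end, with transposase/tRNA marker
  annotations planted at its bounds.
* `simulate_gain_loss()` — a two-state continuous-time Markov chain down
  every branch from an absent root, or a single deterministically planted
  gain for forcing a known event topology.
* `simulate_survey()` — per-metagenome ecosystem strings (drawn from the
  same vocabulary the survey's mapping table ships), marker counts spanning
  the >100 filter boundary, and per-fragment truth. `contamination_rate` is
  the probability a fragment is an outgroup-derived scaffold *mislabeled*
  with an in-genus lineage — the situation the conservative intersection
  must catch; a separate `nongenus_rate` yields truthfully outgroup-labeled
  scaffolds so candidate selection is exercised too.
* `make_reference_package()` — a clade-labeled reference package: a
  depth-scaled ingroup Yule tree joined to a distant outgroup, gap-free
  evolved alignment, clades from recursive splitting of the deepest
  subtrees.

What the generator does *not* emulate: sequencing error profiles and read
pairing (scaffolds are modeled, not reads), indels (so reference alignments
are gap-free; the placement engine itself accepts gapped references),
genome-scale heterogeneity such as rRNA operons or mobile elements beyond
the planted island, and database annotation noise other than the lineage
mislabeling above. Passing tests therefore demonstrate correctness of the
statistics and bookkeeping under controlled conditions — not robustness to
every artifact of real survey data.

# Problem sizes and numerical choices

The shipped tests and drivers use desk-scale versions of the study design:
a 12-leaf/3-clade (+3 outgroup) reference package with 900-bp alignments and
200-600-bp fragments; 20-30-kb host genomes with 2-5-kb islands; empirical
nulls of 100-200 windows; 8-20 metagenomes with 50-300 scaffolds each.
Tolerances: LWRs sum to 1 within 1e-9; the pruning engine matches
brute-force enumeration within 1e-8; unrooted-likelihood invariance to
rooting within 1e-9; $\delta^*$ pseudometric identities within 1e-12.
Degenerate inputs are defined rather than left to chance: all-N sequences
give `NA` GC; a region spanning the whole genome gives $\delta^* = 0$ at
percentile 0; zero confirmed fragments suppress percent computation rather
than divide by zero; a flat growth curve has an undefined time-to-half-max.

# Known limitations

* Presence calls inherit the annotation quality of the input tables; a
  missing KO annotation is indistinguishable from a missing gene.
* The placement engine's fixed pendant length and midpoint attachment bias
  LWRs slightly toward long edges; fine placement *within* a clade is not
  the goal, clade membership is.
* The empirical-null island test is calibrated for a single query region;
  scanning many regions would need multiplicity control.
* Percent rounding (half away from zero) reproduces the published tables but
  can make displayed percents sum to 99 or 101; the raw fractions carry the
  exact information.
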