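---
title: "Detecting and dating a lineage-specific whole-genome duplication"
author: "reedwgd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating a lineage-specific whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reedwgd)
```

## The inference problem

A whole-genome duplication (WGD) doubles every chromosome at a single moment
and then erodes: most duplicate pairs lose one member (fractionation), while
the survivors diverge neutrally at synonymous sites.  Long after the event,
four independent kinds of gene-level evidence still betray it:

1. **Synteny.**  Paralogous copies of a duplicated region stay colinear:
   runs of neighbouring genes appear twice in the genome, and a
   single-copy comparator genome aligns to the duplicated genome at 2:1
   syntenic depth.
2. **Ks ages.**  Synonymous divergence at four-fold degenerate (4D) sites
   accumulates roughly clocklike, so the Ks distribution of colinear
   paralogue pairs peaks at the age of the WGD.  Comparing that peak with
   the Ks peaks of orthologue pairs from bracketing speciations places the
   event on the species tree: a *lineage-specific* WGD satisfies
   *within-taxon peak < paralogue peak < every between-species peak*.
3. **Copy number.**  For each orthologue group, the copy-number ratio
   `R_CN` = (count in the focal species) / (mean count in the comparators)
   is unimodal at 1 in unduplicated lineages but bimodal -- modes at 1
   ("conserved") and ~2 ("duplicated") -- in the WGD lineage.
4. **Retention bias.**  The genes that keep their duplicate are not a
   random sample; dosage-sensitive regulatory genes are preferentially
   retained, which a hypergeometric over-representation test on the
   duplicated set exposes.

Independently of any historical WGD, the *functional* ploidy of the
sequenced genotype is read from short-read allele balance: a disomic
(functionally diploid) genotype puts the nonreference allele frequency of
heterozygous sites at 1/2, while tetrasomic dosage adds modes near 1/4 and
3/4.

`reedwgd` implements each evidence stream as a separate module and chains
them with `run_pipeline()`.  Because the real datasets that motivate this
kind of analysis are genome-scale, the package ships a genome-evolution
simulator that reproduces the statistical structure the inference assumes,
with full ground truth, so that every step is testable end to end.

## The simulator

`simulate_dataset()` evolves an ancestral genome of random sense codons
along an ultrametric species history:

* **Speciation depths** are given per species as the *pairwise* Ks
  divergence expected between that species and the focal lineage; under
  the clock each split sits at half that depth.  A species with depth
  smaller than the WGD age acts as a within-taxon comparator (a
  subspecies that split after the duplication).
* **Substitution model.**  Only 4D third codon positions evolve, by
  per-site Poisson substitution counts under Jukes-Cantor with equal base
  frequencies; all other positions are invariant.  Two consequences are
  deliberate: homologous proteins remain identical, so homology detection
  is never weakened by the synonymous divergence the Ks stage later
  measures, and the downstream Ks estimator can be validated against
  direct site counts.  Richer codon models would add realism the
  inference never reads.
* **The WGD** is an instantaneous doubling of all chromosomes at the
  configured Ks age, immediately followed by per-gene Bernoulli
  fractionation with a per-category retention probability.  Gene
  categories (e.g. `regulatory` / `other`) double as flat GO-like
  annotation terms, so retention-bias enrichment has a known truth.
* **Rearrangements**: inversions of 3-20 contiguous genes and
  whole-segment translocations, equal probability, at a configurable rate
  per 100 genes per terminal branch -- enough to break synteny chains
  without destroying blocks.

Defaults describe the scenario the package is designed around: a WGD at
Ks 0.15 bracketed by a subspecies split at 0.02 and speciations at
0.30-0.60, retention biased 0.8 (regulatory) versus 0.3 (other), one
rearrangement event per 100 genes per branch, and 100 codons per gene
(about 52 comparable 4D sites per pair, comfortably above the default
`min_sites = 30` for a Ks estimate).

What the simulator does *not* emulate -- and hence what passing tests do
not certify about real data -- includes indels and frameshifts (all genes
share one codon length), nonsynonymous divergence, tandem duplication,
gene conversion between paralogues, rate variation among lineages, and
annotation error.  On real genomes the homology and synteny stages face
all of these; the simulator isolates the statistical core of the
inference instead.

```{r}
cfg <- simulation_config(n_ancestral_genes = 120, codon_length = 80,
                         n_chromosomes = 2, seed = 3)
sim <- simulate_dataset(cfg)
sim
```

## Homology and orthologue groups

Homology is scored on translated sequences with BLOSUM62 and affine gaps
(open 10, extend 1, half-bit units), so synonymous change is invisible to
it.  For equal-length sequences the optimal affine-gap global alignment
of indel-free homologues is gapless (any gap costs more than any
substitution gains), and the package computes it directly with vectorised
cross-products; length-mismatched pairs go through the full affine-gap
aligner.  For unrelated sequence pairs the gapless score is a lower
bound, but such pairs sit near the ~6% amino-acid background identity,
far below the default `min_identity = 0.5`, so no call changes.

Orthologue groups are connected components of a graph whose edges are
cross-species reciprocal best hits (RBH, per species pair) plus
within-species hits scoring at least the weakest RBH of the component
either endpoint belongs to -- the rule that lets both WGD copies join the
group anchored by their single-copy orthologues.  This single-linkage
construction is a deliberate desk-scale simplification of graph-clustering
orthology tools; it is exact on the simulator (where scores separate
cleanly) and is flagged here because on real data single linkage can
chain families together.  Score ties in RBH are broken towards the
lexicographically smallest gene id and counted in the `n_ties` attribute.

## Synteny blocks

Anchors (homologous gene pairs with gene-order coordinates) are chained
per chromosome pair by sparse dynamic programming: the highest-scoring
subsequence strictly increasing on the A side and strictly monotone on
the B side, with a penalty of `gap_penalty = 0.1` anchor-score units per
skipped gene and a hard cap of `max_gap = 10` skipped genes per genome
between consecutive anchors.  Both orientations are searched;
non-overlapping blocks are extracted greedily by descending chain score;
blocks with fewer than `min_anchors = 5` colinear pairs are discarded.
Chaining works in gene-order coordinates rather than base pairs, matching
anchor-based synteny practice and the simulator's truth representation.
The chain optimum is verified in the tests against exhaustive enumeration
of all monotone anchor subsets.

Within-genome (self) comparison removes self matches and collapses tandem
arrays (paralogues within `tandem_window = 5` genes on one chromosome) to
their lowest-index representative before chaining, so an array
contributes one anchor.  Syntenic depth counts, for each reference gene,
the *distinct* blocks covering its position -- "represented twice" means
two covering blocks, not two anchors.

## Ks estimation and WGD placement

For a gene pair, comparable 4D sites are third positions whose first two
codon positions are identical in both sequences and define a four-fold
family; with `p` the mismatch fraction over those sites,
`Ks = -(3/4) log(1 - 4p/3)`.  Estimates with `p >= 0.75` are flagged
saturated and excluded; pairs with fewer than `min_sites = 30` comparable
sites are skipped with a log message.  This transparent estimator
replaces likelihood codon machinery on purpose: only the *ordering* of
peaks drives the placement verdict, and the closed form is testable to
machine precision against site counts.

Distribution peaks use a Gaussian kernel density with Silverman's
bandwidth on a 512-point grid over `[0.001, 2.0]` (the range filter
removes identical-gene artifacts and saturated pairs); the peak is the
grid argmax with ties broken towards the smallest Ks, and local maxima
above 10% of the global maximum are reported as modes.  Colinear pairs
(anchors inside blocks) feed the paralogue and orthologue distributions;
RBH pairs feed the within-taxon comparison, where no synteny is needed.
`place_wgd()` returns `lineage_specific` only when the full inequality
chain holds, otherwise it lists every violated inequality.

## Copy-number classification

`classify_groups()` calls a group **conserved** when the focal `R_CN`
lies in `[0.8, 1.25]` *and* the focal count equals the rounded comparator
mean (the copy number is genuinely unchanged, not merely
ratio-compatible), and **duplicated** when `R_CN` lies in `[1.6, 2.5]`
with a focal count of at least 2.  The bands are centred on the
theoretical peaks at 1 and 2; they are configurable, and their
recovery behaviour is what the tests pin down (the duplicated fraction
tracks the configured retention within binomial error).  An optional
`strict_equal` mode requires every comparator count to equal the focal
count for the conserved class.  Groups whose comparators are all zero
have no defined ratio and are excluded with a count.  The
universal-single-copy duplication fraction -- among groups single-copy in
every comparator, the fraction with exactly two focal copies -- serves as
the package's analogue of a duplicated-BUSCO statistic without running an
external completeness tool.

Histograms of `R_CN` (and of allele fractions in the ploidy module) use
bins *centred* on multiples of the bin width.  With edge-aligned bins the
theoretical values 1, 2, 0.5 would sit exactly on bin boundaries and the
modal bin would be a coin flip of floating-point rounding; centring makes
the expected peaks bin centers.

## Enrichment

Annotation transfer follows the bidirectional-coverage rule: a query gene
inherits a reference protein's terms only when the alignment covers at
least 30% of *both* sequences, unioned over hits.  Over-representation is
the upper-tail hypergeometric probability with Benjamini-Hochberg
adjustment applied within each gene-set/background pairing.  Annotations
are flat term-to-gene sets -- no GO-DAG ancestor propagation; real OBO
hierarchies are out of scope.  Enriched terms are clustered by the
literal smaller-set rule: terms sorted by gene-set size, each joining the
first cluster whose representative shares at least 80% of the smaller
set.  (Whether a Jaccard denominator was intended instead is genuinely
open; the smaller-set reading is implemented because it is what the rule
as stated says.)

## Ploidy

`site_spectrum()` filters sites at `min_depth = 10` and `min_nonref = 3`
(the latter removes homozygous sites whose only nonreference reads are
sequencing error), histograms nonreference fractions at bin width 0.05,
and reports modes holding at least 5% of retained sites -- binned mode
detection rather than KDE because it is robust at the few-thousand-site
scale and has no bandwidth to choose.  `classify_ploidy()` calls
*functionally_diploid* for a single mode in [0.40, 0.60] and
*tetraploid_signature* for modes in both [0.15, 0.35] and [0.65, 0.85];
the bands are symmetric around the theoretical dosages 1/2 and 1/4, 3/4.
Fewer than 500 retained sites is always *ambiguous*.  The module takes a
plain per-site count table (`position`, `depth`, `nonref_count`); such a
table is produced from an alignment with, e.g.,
`bcftools mpileup` / `samtools mpileup` by counting non-reference bases
per site.

## A complete run

```{r, message = FALSE}
report <- run_pipeline(list(
  seed = 3,
  simulation = list(n_ancestral_genes = 120, codon_length = 80,
                    n_chromosomes = 2),
  ks = list(min_sites = 20, min_values = 30),
  ploidy = list(genome_length = 1500, mean_depth = 40)
), out_dir = tempfile("wgd_run_"))
summarize_report(report)
```

The report is also written as `report.json` next to the per-stage TSV
artifacts, and is byte-identical across runs with the same configuration
and seed.

## Problem sizes and numerical choices

The validation suite runs on deliberately modest simulations -- 120-300
ancestral genes, 60-100 codons per gene, 2-4 chromosomes, 20 seeded
replicates for the recovery properties -- sizes at which every property
under test (binomial retention error, Ks peak ordering, R_CN bimodality,
enrichment power) is already well inside its asymptotic regime, while a
full run stays in seconds.  Scaling the same configuration up only
tightens the sampling error.

Other numerical conventions, gathered in one place: ties in RBH and in
KDE peaks break towards the lexicographically/numerically smallest
candidate; greedy block extraction orders by chain score; histogram
plateaus report their leftmost bin; `R_CN` rounding uses round-half-up so
a comparator mean of exactly 1.5 rounds to 2; and all randomness flows
from a single integer seed per entry point.

## Known limitations

* Single-linkage orthology and gapless equal-length scoring are exact on
  the simulator but simplifications on real proteomes (see above).
* The Ks estimator ignores multiple-hit structure beyond Jukes-Cantor and
  does not model rate variation; peaks, not absolute ages, are the
  supported readout.
* The conserved/duplicated bands assume comparators without their own
  recent WGDs; a duplicated comparator shifts `R_CN` of every group and
  the classification with it.
* The ploidy caller distinguishes disomic from tetrasomic dosage only;
  higher or mixed ploidies, allele-specific mapping bias, and
  contamination are out of scope.
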