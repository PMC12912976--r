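---
title: "Methods: synteny-based analysis of a paleohexaploid clade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-based analysis of a paleohexaploid clade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosynteny)
```

# The problem

Many plant families descend from an ancient whole-genome triplication: every
region of the pre-polyploid genome is represented three times (the
*homoeologs*, from subgenomes conventionally labelled *a*, *b*, *c*), after
which tens of millions of years of *fractionation* (loss of duplicated gene
copies) and chromosomal rearrangement turned the descendants into mosaics of
the three progenitor genomes. Given chromosome-level gene annotations for a
clade of such descendants plus one diploid outgroup that split off before
the triplication, this package

1. detects collinear **synteny blocks** from gene-order homology anchors and
   measures **syntenic depth** (a 1:3 depth against the outgroup is the
   classic signature of a triplication),
2. clusters **microsynteny** networks across species and profiles their
   copy numbers,
3. counts **fissions and fusions** separating each descendant from the
   outgroup karyotype,
4. reconstructs the triplicated **ancestral genomic blocks** — regions of
   the outgroup genome times three homoeolog slots — and concatenates them
   into a **model ancestral genome** onto which further genomes can be
   mapped,
5. quantifies per-homoeolog **gene retention** in sliding windows, its
   **reciprocity** across homoeologs, and pairwise **Ks** of syntenic
   genes, and
6. identifies **retained triplicated genes (RTGs)** — ancestral genes whose
   three copies survive across the clade — with hotspot, annotation
   over-representation and expression-specificity (tau) analyses.

Everything runs on *gene-rank coordinates*: the only thing taken from the
input GFF3/BED files is the order of genes along chromosomes, because block
sizes, gaps and windows in this literature are counted in genes, not base
pairs. Homology anchors are an input (or simulator truth), not something the
package infers from sequence.

# The simulator defines the study conditions

Real inputs for such a study are dozens of chromosome-level assemblies;
those are far beyond desk scale, so the package carries a genome-evolution
simulator whose *defaults are the study conditions* every test and the
acceptance analysis run under:

* ancestral genome of 8 chromosomes x 500 genes (4,000 ancestral genes, a
  realistic per-genome gene count once triplicated to 12,000);
* a two-step triplication (duplication, then addition of a third subgenome)
  with no divergence modelled between the steps — the literature supports
  the two-step history but provides no rates with which to separate them;
* per-copy retention 0.41 after fractionation, so the expected *combined
  retention* (sum over the three homoeologs) is 123% of the outgroup gene
  count, out of the theoretical 300% ceiling — matching the ~124% regime
  reported for real triplication descendants with per-block retention in
  the ~25–55% range;
* 2% of ancestral genes planted as loss-immune triple-copy genes (RTGs)
  with tissue-partitioned expression;
* 3 fissions, 3 fusions, 3 inversions and 1 translocation per descendant
  lineage, and 2 inversions (nothing else) on the outgroup lineage —
  modelling the structurally conservative sister lineage whose karyotype
  makes a usable reference;
* four descendant species, sharing the triplicated ancestor but
  fractionating and rearranging independently.

## The fractionation model

The published observations the simulator must reproduce are qualitative:
retention is *locally biased* (within a window one homoeolog may be clearly
less fractionated), *globally unbiased* (no subgenome dominance), and
*reciprocal* (a window keeping more of one homoeolog keeps less of the other
two). No quantitative model is published, so the package uses the simplest
mechanism with those properties: for every window of 100 ancestral genes a
Dirichlet weight triple $w \sim \mathrm{Dir}(\alpha,\alpha,\alpha)$ is drawn
and the per-copy survival probabilities are

$$p_s = r + m\,(3 w_s - 1), \qquad m = \min\!\big(r, \tfrac{1-r}{2}\big),$$

with $r$ the configured retention mean. This keeps every $p_s$ in $[0,1]$,
makes the marginal exactly $r$ (so $r = 1$ deletes nothing and the combined
retention ceiling of 300% is attained exactly), and fixes the per-window sum
at $3r$ — which is what produces reciprocity. A naive scaling $p_s = 3 r
w_s$ would have to be clipped at 1 and would break both boundary behaviours.
`bias_concentration` $\alpha$ tunes the strength of local bias
($\alpha = 3$ by default; $\alpha \to \infty$ gives identical, independent
probabilities — the null used to test the reciprocity statistic). Planted
RTGs always survive; the survival probability of the remaining genes is
deflated by $(p_s - f)/(1 - f)$ (with $f$ the RTG fraction) so that the
genome-wide marginal stays $r$ *including* the immune genes — retention
parameters describe the genome as observed, not the mutable subset.

Fractionation is per-gene Bernoulli within windows rather than a run-length
deletion process; this reproduces window-level differentiation with minimal
machinery but does not model deletion-block length spectra, so passing tests
say nothing about run-length statistics of real fractionation.

## Identifiability rules for rearrangements

Breakpoints are sampled uniformly over inter-gene gaps, are never reused
within a lineage (gaps created by fusions and translocations are retired
too), and fission/translocation breakpoints leave at least two genes on each
side. The last rule exists because a single-gene fragment can never form a
collinear chain — no synteny method can see it — so allowing it would make
exact event-count recovery structurally impossible rather than merely hard.
Within these rules the junction-counting estimator below recovers simulated
fission/fusion counts exactly.

# Algorithms and the choices behind them

## Anchor chaining

Within each (query chromosome, target chromosome) pair the package
repeatedly extracts the highest-scoring chain by dynamic programming
(score = anchor count; strictly monotone in both genomes, rank gaps at most
`gap_size` on both sides), removes the chain's anchors plus any remaining
anchor sharing a query gene with it (tandem-duplicate control: a query gene
chained once cannot seed a second overlapping block), and stops when the
best chain falls below `block_size`. Defaults are the field's usual
`block_size = 5`, `gap_size = 5`. Ties are broken by smaller query start
rank, then target start rank, then + orientation, making the decomposition
deterministic. Greedy best-chain-first is not guaranteed to maximise total
chained anchors — simultaneous optimal decomposition under gap constraints
is combinatorial — but on 200 random small instances it matches an
exhaustive-enumeration oracle exactly (see the acceptance tests).
Chained-gene removal is deliberately local to the chromosome pair:
homoeologous copies on *different* target chromosomes each keep their own
chain, which is what lets a triplicated genome show syntenic depth 3 against
the outgroup.

## Fission/fusion counting

The descendant is painted by its blocks against the reference; a *fusion
junction* is an adjacency between painted segments that cannot continue the
same reference chromosome (different source, or reference intervals
discontinuous beyond `junction_tol` = 20 ranks — overlap also counts as
discontinuity, so fusing two homoeologous copies of one chromosome is
detected). Orientation is ignored, making the counts invariant to
inversions. Fissions come from the balance
$S = F + C_d - \mathrm{ploidy} \times C_r$ (floored at 0). Two documented
choices: segments shorter than `min_segment` = 3 genes are dropped first
(fractionation creates spurious micro-segments), and $C_d$ counts every
gene-bearing descendant chromosome including unpainted ones — a descendant
chromosome of a triplication descendant always traces back to the
reference, and excluding small unpainted fission products would bias $S$
downward. Translocation junctions are counted as fusions; that bias is
inherent to junction counting and the estimator is only claimed exact on
fission/fusion histories.

## Ancestral-block reconstruction (levels 1–4)

Level 1 blocks are the ingroup-vs-outgroup chains. Level 2 merges
consecutive level-1 segments whose outgroup counterparts are physically
adjacent (same chromosome, consistent orientation, rank gap within an
`adjacency_tol` of 5 — the literature states the merge rule but not its
tolerance). The outgroup is then partitioned into `n_regions` homoeologous
set regions (default 16 on 8 chromosomes, i.e. the cuts are apportioned
per chromosome — largest mean region first — and placed on the strongest
clusters of level-2 block ends, falling back to midpoints when there is no
boundary signal). "Proximity and complementarity", the published principle
for distributing blocks among the three homoeolog slots, is formalised as a
deterministic greedy interval 3-colouring: blocks straddling a cut are
split there; within a region, blocks are processed by outgroup start rank
and placed in a slot where they overlap nothing (complementarity),
preferring the slot holding the nearest already-assigned block from the
same ingroup chromosome (proximity — neighbouring blocks of one chromosome
almost always descend from the same homoeolog), then the emptiest slot;
unresolvable overlaps go to the minimum-overlap slot and are logged, never
silently absorbed. Level 4 sorts each slot's blocks by median outgroup
anchor rank and flips blocks whose anchors run mostly against the outgroup
direction. Slot labels a/b/c are arbitrary per set — with homoeologs this
homogeneous true subgenome phasing is not attempted, mirroring the random
a/b/c grouping used on real data — so recovery is always evaluated up to
relabelling (adjusted Rand index), never on absolute labels.

Because the region partition is itself an analysis construct (there is no
biological fact of "16 regions"), set-assignment correctness is evaluated
by containment: a gene is correctly assigned when its inferred set's
outgroup region contains the outgroup position of its ancestral gene. Slot
correctness is the within-set ARI against true subgenome labels, weighted
by set size.

## Retention, reciprocity, Ks

Retention is synteny-anchored: a reference gene counts as retained in a
slot only if an anchor of that slot's blocks lands on it (a copy that
transposed away from its block does not count). Windows are 100 genes
sliding by 50 (the window size is published, the step is not; 50 matches
the 50-gene density windows used elsewhere and is exposed in the
configuration, as is a trailing partial window rule: kept when at least
`step` genes remain). Reciprocity is the mean pairwise Pearson correlation
of per-window retention deviations; under the independent-fractionation
null it centres on 0, under the Dirichlet model it is negative.

Ks/Ka use Nei–Gojobori (1986) with Jukes–Cantor correction (the source
literature does not name its estimator; NG86 is the standard simple
choice): synonymous site fractions per codon (mutations to stop codons
count as nonsynonymous, so sites always total 3 per codon), multi-hit
codons averaged over all substitution orderings that avoid stop codons
(all orderings if every one is blocked), and saturation flagged when
$p \ge 3/4$ reaches the correction's domain boundary. The implementation
(memoised codon-pair table) is checked against an independent
pathway-enumeration oracle to $10^{-9}$ and, during development, against
Biopython's NG86 implementation.

## RTG calling and statistics

The copy matrix records, per reference gene, species and slot, whether a
syntenic copy survives. A gene is an RTG when each slot is present in at
least `species_fraction` of species (default 0.8; published results note
threshold sensitivity without fixing a rule, so the threshold is prominent
in the configuration and RTG counts are monotone non-increasing in it).
Hotspots are windows whose RTG count lies strictly above the 95th
percentile of a label-permutation null; with strictly-greater flagging the
test is conservative for small discrete counts, and its calibration is
tested in a regime of ~10 expected counts per window where discreteness is
mild. Over-representation is a two-sided Fisher exact test per label with
Benjamini–Hochberg correction (stricter than the uncorrected "P < 0.05"
convention sometimes used for such scans) on a synteny-conditional
background — genes placeable on the model genome — rather than whole
proteomes. Expression specificity uses
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$ and group contrasts use a two-sided
Mann–Whitney test on per-gene tau.

# Numerical and determinism conventions

Every stochastic stage takes one integer seed; the pipeline seeds a single
shared RNG stream, and rerunning a configuration reproduces every output
byte for byte (the run manifest records an MD5 checksum per artifact, and
manifests of repeated runs are identical). Coordinates are normalised to
0-based half-open on load (BED native, GFF3 shifted); gene-rank ties in
start position are broken by end then gene id. All greedy stages define
total orders for their choices, so results are invariant to input-file row
order.

# Problem sizes used by the tests

The test suite and acceptance analyses run the default 8 x 500-gene clade
for recovery experiments (10 seeds for ancestral-block and RTG recovery, 20
loss-free histories for rearrangement recovery) and a reduced 4 x 150-gene
clade for the end-to-end pipeline determinism checks; these sizes give the
statistics enough resolution (e.g. ~600 pooled window values for the
retention calibration) while keeping a full run in minutes on one core.

# Known limitations

* Anchors are inputs; the package does not compute protein homology, and
  anchor quality bounds everything downstream.
* The fission/fusion estimator is biased by fractionation-induced painting
  gaps and counts translocation junctions as fusions; it is exact only on
  the loss-free histories it is tested on, and those biases are visible in
  the junction tables it emits rather than corrected invisibly.
* Single-gene rearrangement products are invisible to any gene-order
  method; the simulator excludes them by design (see the identifiability
  rules) rather than pretending they could be recovered.
* The simulator does not model sequence evolution, transposable elements,
  tetraploid-stage fractionation between the two triplication steps, or
  gene transposition; conclusions about those processes cannot be drawn
  from its tests.
* Headline counts published for real 20+ genome datasets (cluster counts,
  fission/fusion averages, model-genome gene totals, RTG counts) depend on
  those assemblies and are deliberately not reproduced at desk scale; the
  package validates the *properties* of each method instead.
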