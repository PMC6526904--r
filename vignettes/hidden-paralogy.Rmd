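---
title: "Screening single-copy gene families for hidden paralogy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening single-copy gene families for hidden paralogy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clanshield)
```

## The problem

Phylogenomic pipelines routinely select "single-copy" gene families as
presumed orthologs.  But a gene that is single-copy today need not have been
single-copy throughout its history.  After an ancient duplication -- for
vertebrates, up to two rounds of whole-genome duplication predate most of
the lineages one cares about -- redundant copies decay and are lost.  If
loss happens *early*, before the speciations under study, the survivors are
true deep orthologs.  If loss happens *late*, independently in each
descendant lineage, every extant species still carries exactly one copy,
but different species may carry *different* copies: hidden paralogs.  A gene
tree built from such a family records duplication divergences, not
speciation divergences, and can support a wrong species relationship with
high confidence.  This matters most for sparsely sequenced groups analysed
from transcriptomes, such as the three living amphibian orders (Anura,
Caudata, Gymnophiona), where competing rootings of the group (Batrachia:
frogs + salamanders; Procera: salamanders + caecilians) have each received
strong support from different data sets.

## The clan test

clanshield's central operation is deliberately simple.  Gene trees are
unrooted, so clades are unavailable; the natural unrooted unit is the
*clan*: a subset of leaves forming one side of the bipartition induced by
removing a single edge.  The user asserts a set of *incontestable* clans --
taxon groups whose monophyly is beyond serious doubt, such as mammals -- and
every gene family is required to be *able* to recover each of them:

> for each asserted group, all members present in the family's tree must
> occur together as a clan.

A family violating any incontestable clan has a history incompatible with
pure speciation along the accepted backbone and is flagged as a putative
hidden paralog.  Two vacuous cases pass by convention: a clan with at most
one member present, and a clan whose present members cover the entire leaf
set.  Neither can be violated, so neither is evidence of paralogy
(`is_clan()` returns `TRUE`; `check_family()` reports them as
`"untestable"` and they never trigger removal).  We also treat a clan whose
present members equal the whole leaf set as untestable-pass; an
implementation could instead refuse to score it, and the report table makes
that choice visible per family.

Polytomies are taken at face value: a taxon set is a clan only if it is one
side of an actual edge, and no resolution of soft polytomies is attempted.
When a family carries several leaves of the same taxon, all of them must
fall inside the block.  There is deliberately no tolerance parameter in the
default decision rule: one misplaced leaf violates the clan and removes the
family, because the screen's purpose is enrichment, not classification of
individual leaves.

## Why late loss is dangerous: the exact enumeration

The worst case can be computed exactly.  Take a rooted three-lineage
species tree ((L1,L2),L3) whose speciations are all more recent than R
rounds of duplication, and let every lineage retain exactly one of the
2^R copies, uniformly and independently.  For a pair of lineages, the
divergence of their retained sequences is the speciation time if they kept
the same copy and the (older) duplication time otherwise; the pair with the
most recent divergence forms the cherry of the induced three-leaf gene
tree.  Comparisons use time *ranks* under the strict order
t(SP2) < t(SP1) < t(DUP_R) < ... < t(DUP_1), so ties cannot occur.  The two
same-round duplication nodes of a round share a rank; this never creates an
ambiguous minimum because two pairs achieving the same duplication rank
always lose to a third, more recent pair.

```{r enumeration}
enumerate_retention(2)
```

With two duplication rounds there are 4^3 = 64 retention combinations.
24 (38%) support the true topology, but 20 (31%) support *each* of the two
alternatives -- and of the 24 "correct" families only 4 are genuine
orthologs; the other 20 are paralogs that happen to agree.  The package's
tests verify this enumeration against a brute-force oracle that builds the
full gene tree for every assignment and reads off its cherry, for one to
four rounds.  Enumeration beyond three lineages is intentionally out of
scope: many-taxon behaviour is covered by simulation instead.

## Validating the filter by simulation

The filter should fire on duplication + late loss, and should *not* fire on
incomplete lineage sorting (ILS), the other common source of gene-tree
discordance.  The argument is structural: ILS is local to short internodes,
whereas late loss after an ancient duplication scrambles relationships
across the whole tree, including deep outgroup clans that ILS essentially
never disturbs.  `run_experiment()` quantifies this on a built-in study
design.

**The fixture model.**  `default_species_model()` is a rooted ultrametric
33-taxon species tree in coalescent units: 18 ingroup amphibians (8 Anura,
5 Caudata, 5 Gymnophiona, joined as Batrachia) and 15 outgroups (6 fishes,
5 sauropsids, 4 mammals), the taxon structure of a realistic vertebrate
transcriptome study.  Stems separating the seven incontestable groups are
deep (4--10 coalescent units; the probability that two lineages fail to
coalesce along a stem of length T is e^-T, under 2% for the shallowest
stem), while within-group internodes are short (1--2 units), so simulated
gene trees show the within-group discordance real data have without
breaking deep groups.  Node times are in coalescent units with a per-branch
population scaling theta (default 1), the dimensionless parameterization
for which closed forms exist: the package's tests check the simulator
against the three-taxon mismatch probability (2/3)e^-T.

**Occupancy.**  Each simulated family contains a taxon subset drawn from
`default_occupancy()`: family sizes uniform on 6--32 of the 33 taxa with
taxa sampled uniformly, emulating the size range of informative
transcriptome-derived families (at least six taxa, rarely complete).  An
empirical per-taxon probability mode is also available.

**The two generating models.**  `simulate_msc_tree()` is a standard
multispecies coalescent.  `simulate_duploss_family()` implements the
duplication scenario: 2^rounds copies arise above the species root
(duplication nodes spaced one unit apart), every copy tracks the species
tree, and each sampled taxon retains one copy uniformly at random -- the
late-loss worst case, which at three ingroup taxa reproduces the 24:20:20
enumeration (checked by a chi-square goodness-of-fit test on 10,000
simulated families).  A survival-probability loss mode conditioned on one
survivor per taxon would interpolate between early and late loss; we expose
the worst case only, since the screen is validated against its extreme.  An
optional ILS layer inside each copy is off by default so that the two
experiment arms isolate one mechanism each; with it on, subtree coalescence
can predate the attachment duplication node, and the stem is clamped at
zero length.

**The metric.**  For each replicate we report the fraction of *testable*
(family, clan) evaluations that are violated, averaged over replicates --
untestable clans are excluded from the denominator.

```{r experiment, eval = FALSE}
model <- default_species_model()
clans <- default_clans()
cfg <- list(n_families = 100, n_replicates = 100,
            occupancy = default_occupancy(model))
run_experiment(model, clans, c(cfg, mode = "ils_only"), seed = 1)
run_experiment(model, clans, c(cfg, mode = "dup_late_loss", rounds = 2),
               seed = 1)
```

On this design (100 replicates of 100 families; the problem size keeps the
full experiment under two minutes and Monte-Carlo error on the means below
half a percentage point) the ILS-only violation rate is a fraction of a
percent, while the two-round duplication + late-loss rate exceeds 85%.
What passing these bounds shows is the *separation* -- the filter fires on
its target mechanism and not on ILS -- under this model's parameters.  Real
data add sources of violation the generator does not emulate: gene-tree
estimation error, alignment error, contamination, and lineage-specific rate
variation, all of which can push the no-duplication violation rate above
the pure-ILS floor.  The replicate seeds are derived deterministically from
the root seed (seed + 9973 * replicate), so replicates are reproducible
independently of each other's draw counts.

## Curation helpers around the filter

The package also implements the standard curation steps that surround the
clan screen in practice:

* `prune_species_duplicates()` collapses each maximal same-taxon clan
  (isoform or allele redundancy in transcriptome assemblies) to its longest
  sequence, with lexicographic tie-breaking for determinism, and
  `is_single_copy()` then identifies families ready for clan checking.
  Same-taxon leaves that do *not* form a clan are left alone -- they are
  real multicopy signal.
* `informativeness_filter()` keeps families with at least `min_taxa`
  (default 6) taxa and representation of every required group, the
  criterion for a family to bear on the question at all.
* `saturation_stat()` screens alignments for substitution saturation by
  comparing the sum of NJ branch lengths under the uncorrected p-distance
  with the sum under a multiple-hit-corrected distance.  The correction is
  Kimura's closed-form protein formula d = -ln(1 - p - 0.2 p^2) -- a
  deliberate, documented stand-in for a full ML model distance: the screen
  needs only a monotone, multiple-hit-aware transform, and the closed form
  is exactly testable.  Gaps and `X` are deleted pairwise rather than
  column-wise to preserve signal in patchy transcriptome alignments.  Pairs
  beyond the correction domain (p >= 0.854) are capped at a configurable
  distance (default 5) and counted -- saturation being visible is the
  point.  The historical screen judged outliers by eye; `flag_saturated()`
  replaces that with median + 5 MAD on the ratio plus an absolute cap of 3,
  both exposed as parameters.
* `composition_test()` tests each sequence's residue usage against the
  alignment-wide frequencies by chi-square, with degrees of freedom equal
  to the number of states observed in that sequence minus one -- short,
  gappy sequences use few states, and the reduced df avoids
  anti-conservative p-values.
* `bias_report()` asks whether the filter's kept and removed sets differ
  systematically in average branch length (`avg_branch_length()`: sum of
  all branch lengths over the number of branches) or in composition-test
  failure, via Wilcoxon rank-sum tests.  A non-significant result is the
  desired outcome: the filter should select on history, not on rate or
  composition.

## Numerical and design choices

* **Split keys.**  Clan membership reduces bipartitions to orientation-free
  canonical keys; for up to 52 leaves these are exact double-precision
  bitmasks, beyond that sorted label strings.
* **NJ.**  `nj_tree()` wraps the standard Saitou--Nei implementation, adds
  the closed-form three-taxon solution, and clamps negative branch length
  estimates to zero while recording the clamped deficit.
* **Serialization.**  `write_newick()` emits children sorted by smallest
  descendant label, so equal topologies serialize identically -- fixture
  files are diffable and simulation output is byte-stable under a fixed
  seed.
* **Newick dialect.**  Unquoted labels, optional branch lengths, polytomies
  preserved; internal node labels (usually support values) are ignored with
  a warning since they play no role in clan computation.  Zero-length
  branches are kept as-is: they are distinct edges and their splits count.
* **Enumeration guard.**  `build_copy_tree()` refuses more than 10 rounds;
  the enumeration grid grows as 8^rounds.

## Limitations

The simulators validate the decision rule, not gene-tree inference: input
trees are taken as true.  The duplication model places all rounds on the
root stem (the scenario the screen targets); duplications inside the
ingroup would require reconciliation machinery that is out of scope.  The
support-spectrum tally classifies gene-tree topologies directly and is not
a substitute for site-likelihood topology tests.  And the filter itself is
an enrichment device: late loss can by chance produce families that pass
every clan yet still support a wrong topology, so passing families are
"putative" orthologs, never certified ones.
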