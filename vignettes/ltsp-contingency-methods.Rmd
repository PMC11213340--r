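---
title: "Methods: lineage structure, selection and historical contingency in LTSP clone samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage structure, selection and historical contingency in LTSP clone samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltspevo)
```

This vignette is the package's own account of the models and procedures
it implements: the data it expects, each analysis stage with its
assumptions and tunable parameters, what the synthetic-data generator
does and does not emulate, the numerical choices made where the design
was genuinely open, and the known limitations.

## The data and its assumptions

The unit of observation is a **clone**: a sequenced isolate sampled from
one of several independently evolving populations at a known day since
the start of the experiment. Each clone carries a set of mutation calls
(SNPs, small indels, larger structural events) relative to the common
ancestor. The package consumes this as a tab-separated table, one row
per call per clone (`read_mutation_table()`, with a configurable column
schema because exported call tables vary in dialect), plus a GFF3+FASTA
genome annotation (`read_annotation()`; a GenBank reader is not
provided). Duplicated calls are collapsed with a warning. A clone
manifest retains sequenced clones with zero mutations — they carry
information for frequency denominators and Muller tables.

Two standing assumptions: coordinates are 1-based inclusive throughout,
and a single reference sequence underlies all positions. Mutator clones
— clones carrying any mutation in a configurable mutator-gene list
(default `mutS`, `mutL`, `mutH`, `dnaQ`) — are flagged by
`flag_mutators()` and excluded from all selection and contingency
statistics, because their mutation spectra are dominated by the repair
defect rather than by selection.

## Selection statistics

`count_syn_nonsyn_sites()` computes expected synonymous and
nonsynonymous site counts per gene and genome-wide: each of the three
possible substitutions at each coding position contributes 1/3
site-weight to one class under the standard genetic code. This is a
**uniform substitution model** — no transition/transversion or codon-usage
bias — which is the natural desk-scale choice and the convention the
site-likelihood formulation implies. Three further conventions, made
once:

* the terminal stop codon is excluded from the totals, and substitutions
  *creating* a stop count as nonsynonymous (the Nei–Gojobori-style
  convention);
* start codons are counted like any other codon;
* genes with internal stop codons (pseudogenes, annotation errors) are
  skipped with a warning rather than guessed at.

Site totals per gene always satisfy `n_sites + s_sites = 3 x` (codons
counted), a conservation law the test suite asserts on every generated
gene.

Observed counts are **unique mutation events among non-mutator clones**:
the same mutation key (position:ref>alt) within one population counts
once however many clones inherit it, while the same key in two
populations counts twice (independent origins). Each event is dated by
the earliest sampling day at which any clone carries it; this dating
feeds the per-time-point nonsynonymous fractions
(`nonsyn_fraction_by_timepoint()`) and the per-day convergence
categories. Only SNPs enter dN/dS — indels and structural events have no
synonymous/nonsynonymous dichotomy.

`compute_dnds()` returns `(n_obs/n_sites)/(s_obs/s_sites)`, flagging the
ratio infinite when `s_obs = 0 < n_obs` and undefined when both counts
are zero. `chi_square_neutrality()` is the one-degree-of-freedom
goodness-of-fit of the observed split against the site-count
expectation, computed directly from the 2-cell formula (the test suite
cross-checks it against `chisq.test`).

## Lineage inference

Within each population, a mutation's frequency at a sampling day is the
fraction of that day's sequenced clones carrying it — computed from that
day's clones only, with no smoothing across days. Only mutations whose
frequency reaches **30% at some day** enter phylogeny construction; with
~10 clones per sample this threshold means "seen in at least 3 clones at
once", which suppresses the cloud of clone-private mutations.

Each clone's filtered mutation set, sorted canonically by genomic
position then allele, becomes a symbol string, and distances between
clones are **Levenshtein edit distances** between these strings
(`levenshtein_distance()`, backed by `utils::adist` on a symbol-to-
character mapping; an independent dynamic-programming implementation
serves as the test oracle). The canonical ordering matters: without a
fixed ordering the string distance would be ill-defined on sets. With
it, the distance equals the symmetric-difference size whenever one set
contains the other — exactly the ancestor/descendant case.

`infer_parents()` assigns every clone the candidate (same population,
same or earlier day) minimizing this distance, with ties broken by
earlier day, then larger shared-mutation count, then lexicographic clone
id. The population ancestor (empty mutation set) is always a candidate,
so early clones with no filtered mutations attach to the root. One
guard keeps the graph a forest: a same-day candidate is admissible only
if it precedes the focal clone in the (day, profile size, clone id)
order. This makes parent edges a topological order, so acyclicity and
day-monotonicity hold by construction (and are asserted in tests).

A **lineage** is defined by a founding mutation that (i) reached the
30% threshold at some day and (ii) has carriers at two or more distinct
sampling days. Walking each clone's root path, the first edge acquiring
such a mutation fixes the clone's lineage; among several qualifying
mutations on the same edge (co-founders, common because a founder sweeps
with its hitchhikers) the highest peak frequency names the lineage, with
position then key as deterministic tie-breaks. "Lasts two time points"
is read as members at >= 2 distinct days, not necessarily consecutive;
a candidate whose member set ends up spanning fewer than two days is
removed from the qualifying set and the assignment recomputed, so every
emitted lineage honestly satisfies the rule. Clones acquiring no
qualifying mutation go to their population's **pseudo-lineage** — a
single per-population container that later counts as one independent
unit in the contingency screen.

`muller_table()` tabulates per-day lineage frequencies (member clones
over clones sampled that day); rows sum to 1 including the
pseudo-lineage, and `plot()` on the lineage object renders minimal
stacked-area Muller plots.

## Convergence

`locus_map()` defines the loci: every gene, plus one promoter locus per
gene covering the upstream intergenic gap, assigned strand-aware. A gap
between divergently transcribed genes is split by proximity, the exactly
equidistant position going to the lexicographically smaller gene id
(deterministic, logged in the map); gaps bordered only by 3' ends stay
unassigned. A gene and its promoter are distinct loci — promoter
mutations are regulatory events in their own right.

`convergent_loci()` counts, per locus, the independent units
(populations, or lineages + pseudo-lineages) containing at least one
mutated non-mutator clone; a locus is convergent when mutated in >= 2
units. Because the lineage roster excludes the founder genes' own
convergence trivially dominating the screen, the candidate-pair stage
takes an explicit exclusion list (the RNA-polymerase-core genes on real
data). Both the population-level and lineage-level counts are emitted,
since the two rosters answer slightly different questions.

## The contingency screen

The screen formalizes the intuition that if mutations in locus B are
adaptive only on the background of mutations in locus A, then across
independent lineages B-mutant clones should almost always also be
A-mutant, while A can occur alone. The **units** are the non-mutator
lineages plus pseudo-lineages (mutator lineages are dropped entirely and
mutator clones never contribute to any cell). For each candidate pair —
both members convergent, co-mutated within a single non-mutator clone in
>= 2 units, founder genes excluded — a 2x2 table counts units containing
a clone mutated in both (`a`), in the first only (`b`), in the second
only (`c`), and in neither (`d`); one unit may contribute to several
cells at once, since it can hold clones of several genotypes.

Yule's Q, Y and phi are computed from the raw cells, with undefined
values (zero denominators) flagged as `NA` rather than raised. The
identity `Q = 2Y/(1+Y^2)` and the empirical ordering |phi| <= |Q| on
all-positive tables are asserted over ten thousand random tables in the
test suite.

Significance is a **one-sided large-sample z-test of positive
association** per coefficient: `SE(Q) = ((1-Q^2)/2)sqrt(1/a+1/b+1/c+1/d)`,
the analogous `((1-Y^2)/4)` form for Y, and `z = phi sqrt(n)` for phi.
When any cell is zero the *test statistic* — coefficient and standard
error together — is computed from the +0.5-corrected table, while the
reported coefficients stay on the raw counts (so perfect tables still
print Q = Y = 1). Computing only the SE on corrected cells, with the raw
coefficient, would make the correction vacuous exactly where it is
needed (bc = 0 forces the raw `1-Q^2` factor to zero); the corrected
statistic is the standard resolution and is isolated in one internal
function should a different null ever be preferred. Benjamini–Hochberg
correction is applied per coefficient across all tested pairs.

Cutoffs for Q and Y (defaults 0.8 and 0.5) can instead be selected from
a functional-association pair table: `select_thresholds()` scans the
sorted distinct coefficient values among FDR-significant pairs and
returns the cutoff maximizing the fraction of above-cutoff pairs with a
known functional link, ties to the lowest cutoff. The **reliable set**
holds pairs FDR-significant for phi that exceed both cutoffs.
`functional_enrichment()` compares the reliable set's functional
fraction against `n_rand` draws of equally many distinct random pairs
from the candidate loci, reporting the add-one-smoothed empirical
p-value `(1 + #(null >= observed)) / (n_rand + 1)`.

**Directionality** (`infer_directionality()`): in each unit containing a
double-mutant clone, that clone's ancestor chain is walked rootward; the
first ancestor carrying exactly one member of the pair says which locus
came first there, and a chain jumping from neither to both means the two
were only ever seen together. Calls combine conservatively: a direction
is reported only when every direction-informative unit agrees;
`always_together` when no unit ever separates the pair; `ambiguous`
otherwise.

`rnapc_locus_association()` applies the same machinery to locus vs
**lineage-defining mutation** tables (which founding mutation does a
locus's occurrence track?). Here mutator lineages and clones are
included — the mutator trait itself is the canonical example of a
background-restricted character — and a `merge_groups` argument can fuse
several gene loci into one entity (e.g. the three mismatch-repair genes)
before table building.

## The synthetic-data generator

`simulate_ltsp()` is first-class, tested code, not a fixture. It
emulates the *statistical structure* of an LTSP clone-sampling
experiment:

* five populations sampled at 12 days from day 11 to day 2191, ~10
  clones per population-day, drawn with replacement from current lineage
  frequencies (picking colonies from a large population);
* three lineages per population founded at day 0 by fixed
  nonsynonymous SNPs in two designated founder genes, the same founder
  mutations recurring across populations (convergent lineage
  structure); founding frequencies default to 0.35/0.30/0.25 with the
  remainder unassignable;
* lineage frequency trajectories follow a renormalized geometric random
  walk (log-normal steps, SD 0.25 per sampling interval) — any smooth
  competing-lineage process on the simplex would do, and this one
  guarantees the sum-to-one constraint by construction;
* each lineage maintains a heritable **trunk**: adaptive pool gains
  (20 loci at 4e-4/day), planted contingent-pair gains, and neutral
  background mutations (4e-3 per genome per day) accumulate on it in
  continuous time, and a sampled clone inherits the trunk state at its
  day plus clone-private neutral mutations from a 50-day terminal
  branch;
* one mutator lineage (population 1) multiplies all its rates 20-fold
  and carries a defining mutation in the designated mutator gene;
* pseudo clones carry only independent neutral mutations — transient
  genotypes that never form heritable sublineages;
* planted pairs: locus B's gain hazard is `rate_b (1-s)` before locus A
  is acquired and `rate_b` after, so strength `s` is exactly the
  fraction of B's propensity that requires the A background.
  Contingency is rate suppression, not prohibition, so `s < 1` produces
  mixed patterns. The enabling rate (`rate_a`, default 5e-4/day,
  putting the locus in roughly 60% of lineages by year six — the
  prevalence of the most convergent real loci) and the follow-up rate
  (`rate_b`, default 5e-3/day, follow-up within ~200 days) are separate
  parameters because a contingency that makes a locus adaptive implies
  rapid acquisition once enabled.

The neutral background skips the mutator gene and the planted pair
genes: their mutation processes are the explicit ones above, and on a
~8 kb toy genome uniform background hits would otherwise corrupt the
planted structure (e.g. falsely flagging late clones as mutators at a
~2% per-mutation rate). The toy genome itself (`generate_toy_genome()`)
is 40 genes of 60 codons with 30 bp spacers by default — genes start
ATG, end with a stop, contain no internal stops, and a third sit on the
minus strand so strand-aware code paths are always exercised.

What the generator does **not** emulate: death curves and demography,
within-population spatial structure, sequencing and calling error,
indels and structural variants (all calls are SNPs), mutation-rate
heterogeneity along the genome, and clonal interference *within* a
lineage. Passing tests therefore demonstrate that the pipeline recovers
planted structure from idealized clone samples of realistic size — not
that it is robust to calling artifacts or model misspecification in
real data.

## Numerical choices and degenerate inputs

* Undefined coefficients (zero denominators) are `NA` values carried
  through, never exceptions; degenerate tables get p = 1.
* Ties everywhere break deterministically (documented per function):
  parent choice by day/shared-count/id, lineage naming by peak
  frequency/position/key, promoter splits by lexicographic gene id,
  threshold scans to the lowest maximizing cutoff.
* Empty inputs degrade gracefully: populations with no 30% mutation
  yield only a pseudo-lineage; an empty candidate-pair set returns an
  empty, well-formed screen object; header-only result files are valid.
* The enrichment randomization draws distinct pairs by sampling linear
  indices of the pair lattice without replacement, so a replicate never
  repeats a pair while loci may recur across pairs.

## Validation design and problem sizes

The test suite validates against independent oracles: a hand-rolled
dynamic-programming Levenshtein implementation, full 9-substitution
codon enumeration for site counts, direct evaluation of the printed
Yule formulas, `chisq.test`, a birthday-collision Monte Carlo for
neutral convergence fractions, and the simulator's machine-readable
ground truth. End-to-end recovery uses five replicate experiments of
600 clones each (five populations, 12 days, 10 clones per sample) with
six planted pairs at strength 1.0, high founding frequencies
(0.35/0.32/0.28) and mild drift (SD 0.15): the pipeline recovers all 15
lineages in every replicate, and pooled reliable-pair precision and
recall land near 1.0 and 0.97 with all directed calls matching the
planted direction. Neutral calibration uses ten replicates of a
three-population, selection-free configuration (~2000 classified SNP
events), where dN/dS averages within a few percent of 1. These are the
same computations `scripts/acceptance.R` reruns from scratch; the
vignette states no number that script and the tests do not themselves
compute.

## Known limitations

* **Leaky contingencies are hard to see at this scale.** With ~20
  units, a planted pair at strength 0.9 often fails the phi FDR filter:
  the 10% baseline leak at a realistic follow-up rate fills the
  B-without-A cell with several units, and phi drops below
  significance. The screen's sensitivity is to strong, nearly
  deterministic contingencies; weak ones are systematically missed
  rather than mis-signed.
* **Direct and indirect contingencies are indistinguishable**: if B
  depends on A only through an unobserved C, the pair (A, B) can still
  associate.
* A pair must be co-mutated in >= 2 independent units to be tested at
  all, so one-off contingencies are invisible by design.
* The one-sided z-tests are large-sample approximations on small unit
  counts, mitigated but not fixed by the continuity correction; the
  test machinery is isolated so an exact or permutation null could be
  swapped in.
* Parent assignment trusts the 30% filter: a true parent whose
  distinguishing mutations never reach 30% is invisible, and ties are
  resolved by convention, not evidence.
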