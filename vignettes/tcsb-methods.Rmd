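---
title: "Centrifugal substitution bias and mRNA structure: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrifugal substitution bias and mRNA structure: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical and thermodynamic machinery inside
`tcsb`, the assumptions each stage makes, and the design choices that were
genuinely open. It is the companion to the worked example in the README.

## The scientific question

Closely related mitochondrial lineages can differ not in their proteins
but in how their synonymous sites are used. If synonymous substitutions
accumulate with a *directional* bias — say, consistently replacing weak
A/T (W) nucleotides with strong G/C (S) nucleotides in one lineage and the
reverse in another — and if those substitutions alter the folded mRNA,
that is circumstantial evidence of selection acting through mRNA secondary
structure rather than through the protein. `tcsb` implements a pipeline to
look for exactly this signature in an intraspecific haplotype sample of a
single mitochondrial coding gene (the motivating system is the ~1140-bp
cytochrome *b* gene of cold-adapted teleosts):

1. classify each substitution as synonymous or not, and by W/S direction;
2. orient every substitution *centrifugally* — from the central
   (presumed ancestral) haplotype of a group outward to its peripheral
   derivatives — using a parsimony haplotype network;
3. compare the per-group W→S / S→W direction spectra with an exact test
   (the Test of Centrifugal Substitution Bias, TCSB);
4. localise the bias along the gene with class-partitioned sliding-window
   nucleotide diversity;
5. ask whether the diagnostic substitutions between groups change the
   minimum-free-energy (MFE) fold of the mRNA, and whether haplotypes
   cluster by structure when folds are repeated across an ecologically
   relevant temperature range.

## Orientation: network, centrality, and direction

The haplotype network is a **minimum-spanning network**: every edge that
occurs in at least one minimum spanning tree of the Hamming-distance graph
is retained, so tied alternatives appear as reticulations instead of being
broken arbitrarily. This differs from the median-joining construction that
desktop tools use: no median (inferred ancestral) vectors are added. On
the shallow, star-like genealogies this method assumes — a
high-frequency central haplotype with low-divergence peripherals — the
two constructions coincide, which is why the simpler, fully specified one
was chosen. No statistical-parsimony connection limit is applied:
intraspecific data of this depth are always connectable.

The **central haplotype** of a group is, by default, its highest-frequency
node (`method = "frequency"`), with within-group degree as the
alternative; ties break by frequency then label so the choice is
deterministic. Orientation is a breadth-first search from the central
node: each edge is read from the shallower to the deeper node and each
differing column on it becomes one oriented mutation. An edge joining two
nodes of equal BFS depth cannot be oriented; such edges are dropped with a
warning rather than resolved by any ad-hoc rule, and the affected sites
simply do not contribute to the spectra. On a true star radiating from
the supplied central, orientation recovers the simulator's ancestral /
derived labels exactly (this is a tested invariant, not an aspiration).

**Codon context.** Synonymy of a substitution at a focal column is judged
in the codon formed by the majority base, among the haplotypes carrying
the *from* allele, at the two non-focal positions (ties broken
alphabetically). Real data rarely make this choice matter — segregating
sites in neighbouring codon positions are rare at these divergences — but
a rule has to be fixed, and this one is testable. Translation uses the
vertebrate mitochondrial code (NCBI table 2) by default; the code is
configurable because nothing else in the pipeline depends on it. Columns
containing a gap or `N` in any haplotype are excluded from *all*
statistics: a conservative rule that avoids imputing states.

## The TCSB test

Oriented synonymous mutations are tallied per group into W→S, S→W, W→W
and S→S. The test statistic for a pair of groups is the 2×2 table of
W→S vs S→W counts, compared with a **two-tailed Fisher exact test** using
the sum-of-small-probabilities convention (every table with fixed margins
whose point hypergeometric probability is at most the observed one, with
relative tolerance `1 + 1e-7`). A table with a zero margin returns p = 1.
W→W and S→S transversions are reported but excluded from the table: they
do not change GC content, which is the axis of interest. The small number
of planned pairwise comparisons is reported with raw p-values, without
multiplicity adjustment. Whether the original analyses included the
neutral classes in their tables is not recoverable; restricting to the
two directional classes is the stricter reading and is documented here as
a package decision.

## Sliding-window diversity

Nucleotide diversity is the frequency-weighted mean pairwise difference
per site,
$$\pi = \frac{\sum_{i<j} f_i f_j d_{ij}}{\binom{n}{2} L},$$
with $n = \sum f$ and $L$ the normalising length. The profile slides a
100-bp window by 10 bp (both configurable; these defaults are the
method's canonical settings). Within each window, $\pi$ is also computed
restricted to the columns whose oriented class is W→S, and separately
S→W, each still normalised per window site so the class curves are
commensurable with the total; on gap-free, fully oriented data the four
class curves sum exactly to the total (a tested conservation property).
Sites with undefined orientation count toward the total only. The final
partial window, when the gene length is not reached by a full window, is
computed over its own length and flagged `truncated`. A 1140-bp gene
yields 105 full windows.

An alternative reading of class-partitioned profiles — counting class
mutations per window instead of computing class-restricted $\pi$ — was
considered and rejected: $\pi$ keeps the frequency weighting, so a
high-frequency derived allele contributes more than a singleton, which is
what a selection screen wants.

## The folding model

`tcsb` predicts MFE secondary structures with a Zuker-style dynamic
program over nested structures: stacking on Watson–Crick and GU wobble
pairs, hairpins (minimum three unpaired bases), bulges and internal loops
(capped at 30 unpaired bases), and multiloops with an affine
$a + b\,(\text{branches}) + c\,(\text{unpaired})$ cost. The energy model
is the package's own compact nearest-neighbour table: per-stack
$\Delta H$ built from pair strengths (GC 5.0, AU 2.8, GU 1.6 kcal/mol,
plus a 2.4 kcal/mol cooperativity bonus), $\Delta S = 2.7\,\Delta H$
cal/mol/K, and loop penalties stored as pure entropies with logarithmic
length dependence. Every free energy derives uniformly from
$\Delta G(T) = \Delta H - (T + 273.15)\,\Delta S/1000$, so a temperature
change moves the whole model coherently: stacks weaken and loop penalties
grow as $T$ rises, which is the physics the temperature sweep exploits.

This is deliberately **not** the Turner parameter set. The original
analyses themselves observed that two established folding programs
disagree on these sequences — there is no single ground-truth structure
to match. Correctness here is therefore defined *internally*: the dynamic
program must return exactly the minimum over all nested structures of the
model it was given. That is enforced by a brute-force oracle — an
independent exhaustive enumeration of every admissible pair set, scored
by a separate loop-decomposition evaluator — with exact agreement
required on hundreds of random short sequences. Tie-breaking in the
traceback is lexicographic (pair the smallest position with its smallest
admissible partner), so folding is bit-reproducible.

The headline fold temperature is 3.5 °C — the approximate ambient
temperature of the stenothermal deep-lake fish that motivated the method
— and the sweep runs 1.0 to 4.0 °C in 0.1 °C steps: 31 folds per
haplotype, covering the habitat's thermal range.

## Structure distances, trees, and the consensus

Structures are compared by **base-pair distance** (the size of the
symmetric difference of their pair sets), a true metric that is trivially
auditable; a coarse homeomorphically-reduced shape edit distance is
available as a secondary, qualitative metric. Tree-edit distances on
coarse structure representations were considered but rejected as the
primary metric: they depend on the reduction convention in ways that are
hard to verify independently.

Each temperature's distance matrix is summarised by a
**Fitch–Margoliash** least-squares tree: minimise
$\sum_{i<j} (d_{ij} - p_{ij})^2 / d_{ij}^2$ over topologies and
non-negative branch lengths. Zero distances get a weight far above every
finite $1/d^2$, making them numerically exact constraints. The topology
search is sequential addition in input order followed by one full
nearest-neighbour-interchange pass — a desk-scale heuristic that is exact
on additive matrices (residual zero and the generating topology, a tested
property) and adequate for the few dozen taxa this analysis sees.
Negative WLS branch estimates are clamped to zero.

The 31 trees are combined by strict **majority-rule consensus**:
bipartitions in more than half of the trees, annotated with their
occurrence percentage; no extended-majority completion. These supports
measure *robustness to the folding temperature*, not statistical
confidence — the same caveat the original analysis attached to its
supports, and one this package inherits deliberately.

## The synthetic-data generator

Because the real sequences live in external archives, the package ships a
generator that emulates the *structure* of the study system, with full
ground truth:

* a random in-frame, stop-free CDS (default 1140 bp, a teleost
  cytochrome *b* length) as the ancestral central haplotype;
* derived group centrals connected to it by configured **diagnostic
  substitutions** — by default two forced-synonymous T→C changes with
  four intervening nucleotides for the sister group (the reading frame
  makes a first-position Leu TTA→CTA plus a third-position NNT→NNC the
  only synonymous realisation of that spacing), and four unconstrained
  synonymous changes for the outgroup;
* peripheral haplotypes radiating star-fashion from each group central,
  each carrying `max(1, Poisson(lambda))` private synonymous mutations whose
  W↔S direction is W→S with group-specific probability `beta`;
* optional mutational hotspots (column ranges with elevated sampling
  weight), used to test the window profile's localisation.

Default group settings (three groups; central frequencies 40/30/20;
12/10/15 peripherals; `lambda = 2`; `beta` 0.8/0.55/0.2) reproduce the
qualitative pattern of the motivating system: a strongly W→S-biased
ancestral group, a weakly biased sister group two diagnostic steps away,
and an oppositely biased outgroup.

Every mutated codon is used at most once across a simulation. That buys
three properties at once: no homoplasy (so the network is a tree and
orientation ground truth is unambiguous), every emitted change is exactly
synonymous in its lineage, and the star genealogy is preserved. The cost
is realism: real data contain homoplasy, recurrent sites, and
nonsynonymous polymorphism. Passing tests on this generator therefore
demonstrate correctness of the *machinery* under the model's assumptions,
not robustness of the method to messy genealogies — a limitation shared
with the original analysis, which likewise assumed an unambiguous
genealogy. Saturated hotspots are a visible consequence: a narrow hotspot
contains only a couple of dozen synonymous-admissible codons, so
simulations aimed at hotspot localisation keep the per-lineage mutation
rate low enough that the planted excess is not flattened by exhaustion.

## Numerical choices and degenerate inputs

* Fisher p-values: direct `dhyper` summation, clamped to [0, 1]; the
  implementation is cross-checked in the test suite against full
  log-binomial enumeration for every table with total ≤ 60 and against
  the reference implementation in `stats`.
* Folding traceback tolerance 1e-9 on recomputed energies; DP and oracle
  agree exactly (not approximately) on the enumeration range (≤ 18 nt in
  routine testing, guard at 25 nt).
* FM fits use `lm.wfit`; unidentifiable coefficients (possible only in
  degenerate all-tie cases) are treated as zero-length branches. An
  all-zero distance matrix returns a star tree with a warning.
* Empty groups, groups with zero W↔S mutations, and empty oriented sets
  produce explicit all-zero spectra or p = 1 with warnings, never silent
  NAs.
* Simulation sizes used in the shipped tests and acceptance script are
  desk-scale by design: 200 replicates for power/size studies (50
  haplotypes, 1140 bp each), 10 sequences of 200 nt for the sweep count,
  500 random short sequences for oracle equivalence. These sizes give
  Monte-Carlo error comfortably below the margins being tested.

## Known limitations

* The MSN is not a median-joining network; on deeply reticulate data the
  two can differ, and unorientable tie edges are excluded rather than
  resolved.
* The energy model is compact and internally validated; absolute folding
  energies are not comparable to Turner-parameter programs, and no
  partition-function (ensemble) quantities are computed.
* Consensus supports are temperature-stability values, not bootstrap
  proportions.
* The pipeline does not attempt to reproduce any published p-values or
  figures from the motivating system: the underlying counts and archived
  sequences are not part of the package, and the acceptance checks are
  defined on in-package fixtures and simulations instead.
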