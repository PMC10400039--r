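---
title: "Genic methylation and duplicate gene evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genic methylation and duplicate gene evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`methyldup` implements a comparative-epigenomic workflow for studying how
genic DNA methylation relates to the evolution of duplicate genes
(paralogs) in plant genomes. This vignette describes the models and
procedures in full, the assumptions behind them, the parameters a user
may want to change, and the design choices made where more than one
reasonable convention exists.

## Genic methylation classification

Plant genes fall into three broad genic-methylation states. Gene-body
methylated (gbM) genes carry CG-context methylation only within coding
regions and are typically broadly expressed and conserved. TE-like
methylated (teM) genes carry both CG and non-CG (CHG/CHH) methylation,
resembling transposable elements, and are associated with silencing.
Unmethylated (unM) genes carry essentially no methylation.

The classifier works from per-cytosine calls (allc-style tables: one row
per cytosine with methylated and total read counts plus a binary
methylated-site call). For each gene, calls are summarized over the CDS
intervals of its *primary transcript* -- defined here as the transcript
with the longest total CDS, ties broken by lexicographic transcript id,
since annotation sets differ in whether they mark a canonical isoform.
Sites on both strands are counted regardless of gene strand, the usual
convention in the gene-body-methylation literature.

Per context $c \in \{CG, CHG, CHH, nonCG\}$ (nonCG pools CHG and CHH),
a background rate $b_c$ is estimated as the unweighted mean over genes
of the fraction of methylated sites in that context, excluding genes
with no covered site in the context. Each gene is then tested for
enrichment with a one-tailed binomial test,
$p_c = P(X \ge m_c),\ X \sim \mathrm{Binomial}(n_c, b_c)$,
where $n_c$ is the number of covered sites and $m_c$ the number of
methylated sites. P-values are Benjamini--Hochberg adjusted per context
across the genes with a defined p-value. The decision tree is applied
in this order:

1. **missing** -- no covered CDS cytosine in any context;
2. **teM** -- $q < \alpha$ for CHG, CHH or nonCG with $\ge$ 10 covered
   sites in that context;
3. **gbM** -- $q_{CG} < \alpha$ with $\ge$ 10 CG sites and neither CHG
   nor CHH significant;
4. **unM** -- at most one methylated site across CG+CHG+CHH, or
   weighted methylation (read-sum ratio $\sum mC / \sum C$) at most 2%
   in all three contexts;
5. **unclassified** -- intermediate methylation fitting none of the
   above.

Defaults: $\alpha = 0.05$ on BH-adjusted q-values, minimum 10 sites,
unM ceilings of 1 methylated site and 2% weighted methylation.

Three conventions here were genuinely open and are package decisions:

* **Background scope.** The background is computed per species by
  default. Pooling methylomes across species with different coverage
  depths would let one deeply covered species dominate the rate; a
  pooled background can still be obtained by row-binding the per-gene
  summaries of several species before `compute_background()`.
* **The unM methylated-site ceiling** is interpreted as a ceiling on
  the *total* across contexts (option `unm_rule = "per_context"`
  applies it per context instead). The total reading is the stricter
  and pairs naturally with the "2% in all contexts" alternative.
* **Precedence.** teM is tested before gbM, so a gene enriched for both
  CG and CHG is teM (the gbM rule itself requires non-significant
  CHG/CHH); enrichment takes precedence over the unM absolute criteria,
  which can conflict only under extremely low backgrounds. A context
  with no coverage counts as unmethylated in the 2% rule -- absence of
  evidence is not treated as methylation.

For allc inputs lacking the per-site call column,
`call_site_methylation()` re-calls sites with a one-tailed binomial
test against a per-read error rate (default $\varepsilon$ = 0.005, call
threshold p < 0.01), the standard treatment of incomplete bisulfite
conversion.

## Duplicate-pair classification

Paralog pairs come from all-vs-all protein similarity hits filtered as
in standard paralog-calling practice: self-hits removed, e-value
$< 10^{-5}$, hits restricted to genes of the same orthogroup when a
membership table is available, reciprocal duplicates collapsed to the
smaller e-value. To avoid overcounting, pairs are then retained by
greedy matching on e-value -- hits are visited from the smallest
e-value and a pair is kept only if neither gene is already matched --
so each gene contributes at most one pair. Exact ties resolve to the
lexicographically smaller pair, deterministically.

Collinear (syntenic) blocks are detected by dynamic programming over
gene-rank space: for each chromosome pair, an anchor chain is grown
where consecutive matches advance by 1--`max_gap` ranks on both axes in
a consistent orientation (both increasing, or one increasing and one
decreasing for inverted segments). The best chain is extracted, its
matches removed, and the search repeated; chains with at least
`min_anchors` (default 5) anchors are reported. `max_gap` defaults to
25 genes, the customary chain-gap ceiling of collinearity scanners.

Pairs are typed with the priority **WGD > tandem > proximal >
translocated > dispersed**:

* **WGD** -- the pair is an anchor pair of an intra-species collinear
  block;
* **tandem** -- same chromosome, adjacent ranks (rank difference 1);
* **proximal** -- same chromosome, at most 10 intervening genes;
* **translocated** -- exactly one gene is syntenic (an anchor of any
  block, intra-species or versus a designated outgroup gene set); the
  syntenic gene is the parent, the other the daughter;
* **dispersed** -- anything else.

The priority order mirrors the hierarchy of the standard duplicate
classifiers; in particular a rank-adjacent pair that is also a block
anchor is WGD, not tandem. Translocation ages are expressed as
*epochs*: given an ordered ladder of outgroups (closest first) and
per-outgroup flags saying whether the daughter locus is syntenic versus
that outgroup, the epoch is the smallest ladder index with synteny
(the duplication predates that divergence node), or 0 when the daughter
is syntenic with no outgroup (the youngest class). This ladder is a
deliberate simplification of sequential-exclusion epoch machinery: it
keeps the semantics (older translocations are syntenic with closer
outgroups) while accepting the flags as input rather than re-deriving
them from full outgroup genomes.

For pairs whose two genes both carry an informative label (gbM, teM or
unM), the pair methylation class is the unordered label pair
(`gbM-gbM`, `gbM-unM`, `gbM-teM`, `unM-unM`, `unM-teM`, `teM-teM`);
pairs with a missing or unclassified gene are excluded. For
translocated pairs the parental label is taken as the ancestral state,
so a differing daughter label defines a switch direction (`to-gbM`,
`to-unM`, `to-teM`).

## Orthogroup categories

Orthogroups (from an Orthofinder-style membership table) are
categorized by phylogenetic breadth and copy number. Groups present in
at least `ceiling(0.879 * n_species)` species are *core* (51 of a
58-species panel); the fraction is used rather than the absolute count
so panels of any size reproduce the same cutoff logic. Core groups
whose single-copy fraction is at least 70% are *core:single-copy*
("duplication-resistant" families), the rest *core:multicopy*.
Non-core groups are *cross-family* (at least two plant families),
*family-specific*, or *species/lineage-specific*. The denominator of
the 70% rule is ambiguous in common usage; both modes are implemented,
with species-in-which-the-group-is-present as the default
(`sc_denominator = "all"` switches to the whole panel). Within a
species, genes of a core:single-copy group are *SC-singletons* when the
species retains one copy and *SC-intermediates* when two or more copies
persist -- the still-duplicated members of duplication-resistant
families.

## Sequence evolution: Ka, Ks and Ka/Ks

Nonsynonymous (Ka) and synonymous (Ks) substitution rates are estimated
with the Nei--Gojobori (1986) method on pairwise codon alignments:
synonymous site fractions per codon from the standard genetic code
(changes to stop codons counted nonsynonymous), differences averaged
with equal weights over all minimal mutational pathways between each
codon pair (pathways through stop codons excluded; if every pathway is
blocked, all pathways are used), proportions converted to distances
with the Jukes--Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.
Codons with gaps or ambiguity and observed stop codons are dropped
pairwise; a proportion at or beyond the correction's domain
($p \ge 0.75$) yields an undefined, saturation-flagged distance, and
$\omega = Ka/Ks$ is undefined when Ks is zero or undefined.
$\omega < 1$ indicates purifying, $\omega > 1$ diversifying selection.

NG86 assumes equal rates across the four nucleotides (no
transition/transversion bias) and equal codon usage; it is unweighted
and fully specifiable, which makes it exactly testable against
enumeration. For reruns with a codon-model calculator (e.g. a gamma
or maximum-likelihood method), `read_kaks_table()` imports externally
computed values so downstream summaries are unchanged. No Ks cap is
applied by default when summarizing; saturated pairs are simply
undefined and counted as such.

## Expression specificity

The tissue-specificity index over $n \ge 2$ conditions is
$$\tau = \frac{\sum_i (1 - x_i / \max_j x_j)}{n - 1},$$
0 for uniform expression and 1 for expression confined to one
condition. Genes with no expression in any condition have no defined
$\tau$ and are excluded. $\tau$ is computed on linear normalized values
by default: a log transform requires an arbitrary pseudo-count, so it
is offered as an explicit option (`log2 = TRUE` applies
$\log_2(x+1)$) rather than a silent default. Conditions are taken as
the matrix columns; replicate collapsing, if needed, belongs upstream.
Per duplicate pair, expression divergence is measured by the Pearson
correlation of the two profiles (undefined for zero-variance profiles,
flagged) and by $|\Delta\tau|$.

## Shared statistics

Enrichment of a label (methylation class) in a category (duplication
type, orthogroup category, TE association, PAV) uses the two-sided
Fisher's exact test under the minimum-likelihood convention, with the
sample odds ratio $ad/bc$ reported as-is ($\infty$/0 sentinels for zero
cells, plus a Haldane--Anscombe +0.5 version for plotting) and BH
correction across all tests of a scan. The test universe excludes
missing and unclassified genes by default, since only the three
informative classes are under test. Contrasts of two proportions (e.g.
SC-intermediates versus SC-singletons) use the pooled two-proportion
Z-test without continuity correction; a pooled proportion of exactly 0
or 1 is reported as uninformative rather than significant.

Genomic organization is profiled in 100-kb windows sliding by 50 kb
from position 0 (last window truncated at the chromosome end). A gene
is counted in a window when its midpoint lies inside -- each gene is
counted exactly once per 50-kb phase, avoiding gene-length bias -- and
TEs are counted by overlap and by overlapping base pairs. Class counts
are correlated (Pearson, t-based p, BH) against gene counts, TE counts
and TE base pairs. A gene is TE-associated when any TE overlaps the
gene body extended by 1 kb on both sides, with half-open interval
arithmetic so a TE exactly 1 kb away is not associated. Genes with
average read coverage below 0.2 in at least one accession are called
presence--absence variable (PAV); the threshold is strict, so exactly
0.2 is not PAV.

Population epiallele frequencies are computed per gene over accessions
with an informative label; the frequency of each class is binned as 0%,
<25%, 25--50%, 50--75% and >75%. The printed bin labels overlap at
their boundaries, so the package fixes them as left-closed above zero:
exactly 25% falls in 25--50%, exactly 75% in >75%, and 0% is reserved
for genes never in the class.

## The synthetic-data generator

Every stage is exercised end to end on generated data with known
truth. All draws flow from one seed through named substreams (genome,
hits, methylome, classes, sequences, expression, population,
orthogroups, TEs), so adding an output never perturbs another and a
given seed and configuration reproduce byte-identical files.

**Genome and duplications.** Base genes are laid out with fixed
spacing (defaults: 3 chromosomes of 700 genes, 1.9-kb genes with two
CDS intervals every 3 kb). Planted events follow the reference
conditions: one 10-gene WGD block emitted as a duplicated collinear
segment, and 20 events each of tandem (rank-adjacent copy), proximal
(copy after 2--9 intervening genes), translocated (parent inside a
segment made collinear with a small outgroup gene set; daughter
elsewhere) and dispersed (isolated distant copy) duplication. Planted
hit e-values are far below the retention cutoff; optional spurious
hits are added at a configurable rate with e-values between the
planted ones and the cutoff. Two layout rules protect the ground
truth: single-gene insertions are spaced more than `max_gap` base
genes apart, and tandem/proximal events are grouped in mixed clusters
of at most four separated by more than `max_gap` -- otherwise
regularly spaced single-gene duplicates would themselves chain into
collinear blocks (any 17 or more compactly placed matches must contain
a monotone run of five, so spacing, not randomness, is what guarantees
the planted types are recoverable). Epoch ladders for translocated
pairs are emitted as per-pair outgroup-synteny flags.

**Methylome.** Per gene, site counts per context are Poisson around 30
(CG), 25 (CHG) and 60 (CHH); coverage is Poisson with mean 20;
methylated read counts are binomial with class-specific rates --
gbM 0.85/0.01/0.01, teM 0.90/0.65/0.10, unM 0.005/0.005/0.005 for
CG/CHG/CHH -- and the per-site call applies the error-rate binomial
test. These emission rates realize the class definitions (gbM
methylated in CG only, teM in CG and non-CG, unM unmethylated) with
realistic noise; at these defaults the classifier recovers over 99% of
labels, and the tested contract is 95%.

**Sequences.** Each pair descends from an ancestor drawn uniformly
over sense codons and evolves along two branches under a
continuous-time process where every single-base change has rate 1 if
synonymous and $\omega$ if nonsynonymous (changes into stops
forbidden). Because a codon with $n_s$ synonymous neighbor changes has
$n_s/3$ synonymous sites, Ks accrues at 3 per unit time, so branch
lengths of $K_s/6$ give the target pairwise divergence. Default
targets per pair methylation class plant the expected biology: teM-
containing pairs youngest (Ks 0.20--0.30) and least constrained
($\omega$ 0.5--0.8), gbM-containing pairs oldest and most constrained.

**Expression.** A profile shape with exactly the target $\tau$ (one
dominant condition, others at $1-\tau$ of it) is perturbed by a
Dirichlet draw and scaled lognormally. The concentration (default
3000) was chosen so the mean realized $\tau$ stays within 0.05 of its
target across the whole range -- near-uniform profiles otherwise
inflate $\tau$ because the identity of the maximum condition flips
between draws.

**Population.** Each gene keeps its base class per accession or
switches per class-specific rates (defaults: gbM to unM 5%, unM to gbM
3% and to teM 2%) across 928 accessions with 2% missing data. teM
genes instead retain teM with a per-gene probability drawn from four
strata (0.10, 0.375, 0.625, 0.875), which populates the four nonzero
frequency bins. The target $\tau$ of a teM gene rises with its planted
retention ($\tau = 0.40 + 0.55 \times$ retention): stably silenced
epialleles are modelled as the most narrowly expressed, which is the
population-level association the analysis is designed to detect, so it
is planted explicitly rather than emerging from a deeper model.

**Orthogroups.** A 58-species, 8-family pseudo-panel (so the
51-species core cutoff is exercised literally) with planted counts per
category; categorization recovers the planted categories exactly
because the rules are deterministic.

**What the generator does not emulate.** Real bisulfite data have
non-uniform coverage, strand asymmetries, partially converted reads
and mosaic intermediate methylation; real genomes have nested and
fractionated duplications, tandem arrays larger than two, and
collinearity degraded by rearrangement; expression atlases have
correlated conditions and replicate structure; accessions are related
by population structure rather than independent. Passing recovery
tests therefore demonstrates correctness of the implementations under
the stated statistical model, not robustness to every artifact of real
data.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open everywhere internally; GFF3 and allc
  coordinates are converted on read and reconverted on write, an exact
  bijection.
* A zero background rate gives p = 0 when methylation is observed and
  p = 1 otherwise; p-values are undefined (and excluded from the BH
  family) when a gene has no covered site in the context.
* Weighted methylation is undefined at zero coverage; in the unM rule
  an uncovered context counts as unmethylated.
* Chain extraction resolves overlapping collinear chains greedily by
  anchor count; e-value ties in pair selection resolve
  lexicographically and are logged.
* The Fisher odds ratio uses $\infty$/0 sentinels; an all-zero table
  is an error, not a silent 1.
* Frequency bins above zero are left-closed; exactly 0 is its own bin.
* Test problem sizes: classifier recovery uses 2,001 genes at 20x
  coverage; duplicate recovery uses the default 2,100-gene genome with
  90 planted pairs; the Fisher oracle enumerates all 2x2 tables with
  margins up to 30; the NG86 oracle checks 500 random 30-codon pairs
  and recovery uses 200 pairs of 200 codons per target; calibration
  uses 1,000 simulated enrichment scans of 400 genes.

## Limitations

The NG86 estimator ignores transition/transversion bias and codon
usage, and underestimates $\omega$ slightly at high divergence; for
publication-grade selection inference, import externally computed
values. The collinearity scanner scores blocks by anchor count only
(no e-value-weighted scoring or block merging across chromosomes). The
epoch ladder consumes synteny flags rather than computing them from
outgroup genomes. Enrichment tests treat genes as independent; no
phylogenetic or family-structure correction is applied, matching the
scale of the per-species scans the workflow produces.
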