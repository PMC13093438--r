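---
title: "Models and methods behind phylodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylodisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylodisc re-implements, as a tested and reusable pipeline, the
discordance-analysis core of transcriptome-scale studies of closely related
plant species complexes: which parts of the gene-tree conflict in a clade
are explained by incomplete lineage sorting (ILS), and which demand
reticulation. This vignette documents the models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices a
maintainer would want to know about. It states no empirical result that the
test suite does not itself compute.

## The multispecies coalescent as the null model

The null model throughout is the multispecies coalescent (MSC): gene
lineages entering a species-tree branch with population scaling
$\theta_b$ coalesce at rate $\binom{k}{2}/\theta_b$, and lineages that
reach the root coalesce above it. Branch lengths are in coalescent units
(time / $2N$ generations), tracked with a tree-level `units` attribute so a
substitutions-per-site tree cannot be simulated by accident. For a 3-taxon
internal branch of length $t$ the probability that a gene tree matches the
species tree is $1 - \tfrac{2}{3}e^{-t}$; this closed form is the primary
correctness oracle for the simulator (`simulate_gene_tree()`), along with
the constraint that a pair's coalescence can never predate its species
divergence.

`simulate_network_gene_tree()` adds one reticulation: each sampled hybrid
lineage independently follows the first parent's history with probability
$\gamma$, entering that parent's branch at the attachment age, and is an
ordinary MSC lineage thereafter. Lineages choosing the same parent share a
stem population below the attachment and may coalesce there; lineages
choosing different parents cannot coalesce below the network root. With a
single sampled hybrid individual this is exactly the standard
hybrid-speciation MSC; with several individuals it corresponds to reading
"each lineage chooses independently" literally at the tips, which is the
contract the recovery tests verify. Attachment ages default to the
midpoints of the parental branches (measured on the species tree with the
hybrid leaf removed) and are configurable.

Sequences evolve along simulated gene trees under GTR+$\Gamma$
(`evolve_sequences()`): site-i.i.d. CTMC with the rate matrix normalized to
one expected substitution per unit branch length, discrete-Gamma rate
categories (category means computed analytically from the incomplete-gamma
identity, cross-checked against phangorn), and optional per-tip rate
multipliers used to build lineage-rate null scenarios. Coalescent-unit
trees must be rescaled through an explicit `subst_per_coal` factor; the
default used by the generator is 0.01 substitutions/site per coalescent
unit, a stand-in recorded in every manifest because summary-coalescent
species trees do not carry this conversion.

## Ortholog filtering

The filter battery mirrors a genome-skimming/transcriptome protocol, with
constants taken from that protocol where it prints them:

* occupancy: keep genes present in at least
  $\lfloor 0.70 \times n \rfloor$ samples — the floor is deliberate, since
  the printed pair (32 of 47 at 70%) is only consistent with flooring;
* organellar screening: exact $k$-mer containment ($k = 21$, removal at a
  shared fraction of 0.5, both strands) against organellar references,
  replacing an external BLAST call while preserving the contract of
  sequence-similarity triage; parameters exposed;
* column trimming: columns with **strictly more than** 20% missing symbols
  ({`-`, `N`, `?`}) are removed; a 10-row column with exactly 2 gaps stays;
* length classes: non-disjoint classes of genes at least 1000 and 2000 bp
  after trimming;
* reliability: average bootstrap support (ABS), the mean bootstrap value
  over internal nodes that carry one; gene trees are retained only when ABS
  **strictly exceeds** 60. (One stated example would keep ABS = 100 at a
  threshold of exactly 100, which contradicts the strict rule; the strict
  reading is implemented because it is the one the source protocol prints.)
* long branches: a leaf is flagged when its pendant branch exceeds 5x the
  median pendant branch — a simplified, dependency-free stand-in for a
  statistical long-branch test; flag-only by default, pruning opt-in.

The tool-free gene-tree estimator is neighbor joining on Jukes–Cantor
distances with column-resampling bootstrap; it exists so the pipeline and
its tests run without external inference tools, and the JC+NJ choice is the
simplest consistent estimator for that role. Saturated distances
($p \ge 0.75$) are capped with a warning.

## Concordance and ILS assessment

`map_concordance()` classifies every gene tree at every nontrivial
species-tree bipartition as concordant, conflicting, or uninformative,
after collapsing gene-tree edges with support below `support_collapse`
(default 50, a conventional PhyParts-style cutoff; the source protocol does
not print the value it used, so it is exposed as a parameter). Each
conflicting gene contributes one representative conflicting split — the
incompatible split with the highest support, ties broken lexicographically
— and the modal representative becomes the "top conflict" slice of the
per-node pie. Counts conserve exactly at every node.

Distance-based assessment compares the unweighted Robinson–Foulds
distances of empirical gene trees to the species tree against the same
distances for MSC-simulated gene trees. RF on unrooted topologies is the
deliberate metric choice: the protocol names only the library it used, and
RF is that library's default topology distance. Alongside the histogram the
package reports an overlap coefficient and a two-sample
Kolmogorov–Smirnov test. RF values on a fixed leaf set are small even
integers, so the KS p-value under ties is conservative; the calibration
property tested is therefore one-sided (the rejection rate must not exceed
its binomial bound), not uniformity of the p-value.

Cyto-nuclear attribution (`attribute_conflicts()`) simulates gene trees
under the nuclear MSC model and reports, for every plastid-tree
bipartition absent from the nuclear tree, the raw fraction of simulated
trees displaying it — the most literal reading of "contribution of ILS to
the conflict", with no renormalization to conflicting trees only, because
no renormalization is defined by the source. A configurable threshold
(default 0.05) turns the fraction into an "ILS plausible / implausible"
verdict. Cloud-tree preparation replaces penalized-likelihood time
calibration with proportional depth normalization to unit root height; the
plot is qualitative and the simplification is deliberate.

## The hybridization test

The detector is an outgroup-anchored site-pattern invariants test (the
package's own re-derivation is vendored at
`inst/notes/hils_derivation.txt`). Sites are classified into the 15 set
partitions of the four sampled bases (outgroup written `A`); the two
invariants are $X_1 = n_{ABBA} - n_{ABAB}$ and $X_2 = n_{AABB} - n_{ABAB}$.
Under any treelike history at least one has zero expectation; under
hybridization both are positive. The statistic
$z = X_2 / \mathrm{sd}(\rho X_1 - X_2)$ with plug-in $\rho = X_2/X_1$ is
asymptotically standard normal under H0 and the estimate
$\hat\gamma = X_1/(X_1+X_2)$ tends to 1 as the hybrid approaches P1;
swapping P1 and P2 maps $\hat\gamma \mapsto 1-\hat\gamma$ exactly.
Out-of-range raw estimates are clamped for reporting, retained raw, and
flagged.

**Variance choice (important).** For unlinked sites the multinomial
variance is exact. For concatenated multi-gene data it is not: the ~500
sites of a gene share one genealogy, so the invariants have substantial
between-gene variance that the multinomial formula ignores, and the test
becomes strongly anticonservative (measured family-wise error near 0.75 in
the no-hybridization scenario). When gene partitions are supplied,
`hils_test()` therefore estimates the variances and covariance of the
invariants from their independent per-gene increments (a cluster-robust
estimator, used from 10 blocks up). This is the implementation of the
stated contract — "z asymptotically standard normal under H0" — for the
data this pipeline actually feeds the test; the multinomial path remains
for unpartitioned input and for the null replicates, where sites are
i.i.d. given the fixed simulation tree.

`scan_triples()` tests every candidate hybrid against every unordered pair
of remaining ingroup taxa ($k\binom{k-1}{2}$ tests), averaging pattern
counts over all individual combinations (capped at 10,000 with uniform
subsampling), and applies Bonferroni correction by default — the source
reports corrected significance without naming an alternative. "Node Mode"
(`node_mode()`) pools significant tests whose hybrid descends from a target
MRCA and reports per parent-pair means and SDs of $\hat\gamma$ in the field
convention "mean ± SD".

**Null filter.** Lineage-rate heterogeneity inflates both invariants
jointly (convergent changes toward both parents), producing significant
tests with $\hat\gamma$ near 0.5 and no reticulation.
`null_hypothesis_filter()` re-simulates each significant triple under "no
hybridization" on the empirical substitution-unit species tree — whose
branch lengths carry the real rate heterogeneity — and filters a triple
when more than 5% (configurable) of replicates are significant at the same
corrected level. The null tree must be species-level (one tip per taxon):
a sample-level tree estimated from hybrid-containing data places the
hybrid individuals paraphyletically between the parents and would smuggle
the very reticulation under test into the null, which measurably destroys
the filter's ability to retain true positives. The pipeline builds the
null tree by NJ on one representative sequence per taxon and translates
individual-level assignments through the taxon map.

## What the synthetic generator emulates — and what it does not

`make_scenario()` writes complete, self-describing bundles. The shared
species tree has ~10 ingroup taxa and a distant outgroup, in coalescent
units, ultrametric, with (i) one subclade of six taxa with short internal
branches (0.3–0.6 coalescent units) generating realistic ILS discordance,
and (ii) a hybrid-bearing subclade in which the two parental species
diverged 6 coalescent units ago and the hybrid population formed recently
(attachment age 1.0 on both parental branches, so the two parental
routes are symmetric and $\hat\gamma$ is unbiased). The hybrid taxon is
sampled at the population level (6 individuals), as multi-individual
sampling of focal populations is how such studies are actually designed;
with $B$ genes and $k$ sampled hybrid lineages the per-gene parental-route
choice imposes an irreducible binomial noise floor of
$\sqrt{\gamma(1-\gamma)/(Bk)}$ on pooled $\hat\gamma$, so single-individual
sampling could not meet a ±0.05 recovery tolerance at 100 genes even with
infinite sites. Defaults: 100 genes x 500 sites, GTR rates
(1.2, 3.5, 0.9, 1.1, 4.0, 1.0), base frequencies (0.30, 0.19, 0.21, 0.30),
$\alpha_\Gamma = 1$, per-column missingness drawn from Beta(0.6, 10)
(mean ~6%, occasional columns above the 20% trimming threshold), gene
presence 0.92 per non-core sample, $\theta = 1$ everywhere,
`subst_per_coal` 0.01. Scenario `adonis_like` adds the reticulation with
$\gamma = 0.6$; `no_hybrid` omits it; `rate_artifact` omits it and makes
lineage `spx` evolve 5x faster. Bundles include a synthetic `plastid.nwk`
(a single extra MSC draw standing in for the organellar genealogy) so the
cyto-nuclear stage runs end-to-end; it is labelled synthetic in the
manifest.

What the generator does **not** emulate: within-locus recombination,
indel evolution (missingness is injected, not evolved), selection,
migration beyond the single reticulation, base-composition
non-stationarity, assembly or alignment error. A green test therefore
establishes correctness of the statistical machinery under the stated
model, not robustness to all real-data pathologies — that is what the
null-simulation filter and the long-branch flagging are for, and even they
target specific artifact modes.

## Numerical and reproducibility choices

* All randomness flows from one integer seed through deterministic
  per-item substreams (`seed`, item index, stream id), so adding genes to
  a bundle never perturbs earlier genes; every seed stays below $2^{31}$.
* Missing terminal branch lengths on summary-coalescent species trees
  default to 2.0 coalescent units with a warning.
* Supports are read from internal-node labels; numeric labels lying in
  [0, 1] are rescaled to [0, 100] with a warning. A missing support counts
  as 0 for collapsing, so a threshold above 100 yields a star tree while
  threshold 0 is the identity (the rule is strict `<`).
* Bipartitions are encoded canonically as the sorted block not containing
  the alphabetically first taxon; trivial splits never enter RF or
  concordance accounting; polytomies contribute only the splits they
  display.
* `P(t)` matrices come from the symmetrized eigendecomposition of the GTR
  generator; negative round-off entries are clamped and rows renormalized.
* The invariants test guards degenerate inputs: an exactly zero $X_1$ is
  shifted by one count (mirroring the reference implementation), and a
  non-positive variance combination yields an explicit "undefined" flagged
  result rather than a silent zero.
* Pipeline outputs are plain TSV/Newick/FASTA plus a JSON manifest with
  input checksums and the full config; reruns with the same config are
  byte-identical. Figures (SVG) are pure views of the TSVs.

## Known limitations

Single reticulation per scenario; the network simulator does not nest
reticulations. The NJ fallback is for testing and null-tree construction,
not publication-grade inference. The cluster-robust variance needs a
reasonable number of genes (it engages at 10 blocks); for one short gene
the multinomial test applies, with its unlinked-sites assumption. Node
Mode aggregates leaf-level tests; it does not simulate ancestral hybrid
lineages explicitly. The "contribution of ILS" fraction is reported raw;
alternative normalizations would change the numbers but not the ranking of
nodes.
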