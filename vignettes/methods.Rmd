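---
title: "Methods: network expansion of genetic hits and clinical-outcome enrichment"
author: "proxyNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network expansion of genetic hits and clinical-outcome enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Genes with direct genetic evidence of disease association make better
drug targets, but most successful targets have no such evidence.
Network propagation promises to recover these "missing" targets by
transferring evidence from genetically supported genes ("seeds") to
their interaction partners ("proxies"). `proxyNet` implements a full
evaluation harness for that idea: it defines high-confidence genetic
hits (HCGHs) from colocalization records, expands them into proxy
sets with ten methods ranging from naive guilt-by-association to heat
diffusion and gene-score pathway enrichment, and asks whether proxy
genes are enriched among drug targets that succeeded in the clinic
rather than failed there.

The historical inputs such an analysis needs (large trial databases,
hundreds of GWAS with eQTL colocalization, proprietary interactomes)
are not freely available, so the package ships a synthetic-world
generator that reproduces their statistical structure. All claims the
test suite makes are claims about these synthetic worlds.

# Pipeline stages

## High-confidence genetic hits

A colocalization record carries a GWAS p-value, an eQTL p-value and
the posterior probability `p12` that the GWAS and eQTL signals share
one causal variant. A record survives when the eGene is protein
coding, `gwas_p <= 5e-8`, `eqtl_p <= 1e-4` and `p12 >= 0.8`, all
thresholds inclusive. Filtering happens per tissue record first; per
locus, the surviving eGene with the highest `p12` across tissues wins,
so each disease-associated locus yields one hit or none. `p12` ties
are broken lexicographically by gene identifier, a determinism choice
the data source leaves open. A gene winning several loci is kept once
with its best record. Traits are retained only when they have at least
one hit and at least one drug target with a decisive clinical outcome
for a matched indication.

## Clinical outcomes

Asset-level trial statuses map to three classes: `Launched` means
success; `Discontinued`, `No Development Reported`, `Withdrawn` and
`Suspended` mean failure; anything else is still in progress. Failed
assets whose furthest phase was Phase I–III are clinical failures,
others preclinical. An asset touching exactly one target gene is
*Selective*. Each (gene, indication) pair receives exactly one outcome
by precedence: Selective success, Selective clinical failure,
Non-Selective success, Non-Selective clinical failure, then
preclinical failures (Selective before Non-Selective), else
in-progress. The prose this rule derives from admits one alternative
reading (Non-Selective successes before Selective clinical failures);
we follow the sequential reading and expose `ruleOrder` so the other
is one argument away. Succeeded pairs form the positive set, clinical
failures the negative set; preclinical failures and in-progress pairs
are in neither.

## Proxy expansion methods

Complexes and pathways are treated as cliques for co-membership
expansion; ligand–receptor expansion is strictly first-neighbor (a
seed ligand implicates its receptors, never those receptors' other
ligands); interactome expansion takes first or first-plus-second
neighbors; pathway-topology expansion walks directed pathway edges
both upstream and downstream, once or twice. Whether second-degree
pathway interactors should respect edge direction is not specified by
the method description we follow; we use undirected reachability,
matching the "upstream and downstream" wording at both steps. The
random baseline draws `round(10000/22758 * #coding)` genes so the
sampling fraction of the reference background is preserved at any
universe size. Every proxy set excludes its seeds by construction.

## Heat diffusion

Seed evidence is converted to heat by `-log2(1 - p12)` (a posterior
of 1 is clipped to `1 - 2^-20` to keep heat finite) and diffused with
the insulated random-walk-with-restart operator
`F = beta * (I - (1-beta) W)^{-1}` over the column-normalized
adjacency of the largest connected component. Restart `beta = 0.4` is
the common choice for protein interaction networks and is
configurable; columns of `F` sum to one, so heat is conserved — the
suite checks this to `1e-8` on random topologies. Modules are strongly
connected components of the graph with edge `j -> i` wherever the
exchanged heat `E[i,j] = F[i,j] * h[j]` reaches a threshold `delta`,
subject to a minimum size `kMin = 3`.

Because strong connectivity requires reciprocated heat exchange, a
gene with zero heat can never join a module. Heat therefore comes from
*all* colocalization records of a trait, not only the winning ones:
sub-threshold candidates (decoys, moderately colocalized neighbors)
provide the low-grade heat that lets unseeded genes be pulled into
modules. This mirrors the premise that missing hits are underpowered
rather than absent.

`delta` is selected by permutation: the heat vector is shuffled over
network genes `nPerm` times, each permutation's largest
module-surviving threshold is found by binary search over observed
edge values, and the smallest candidate for which the expected number
of modules per permutation falls below `level = 0.05` is chosen. With
degenerate heat the procedure returns `max(E) + 1` as an explicit
sentinel. The selection is deterministic given its seed.

## Gene scores and pathway enrichment

The sum score of a gene window is `T = sum(z_i^2)` over its variants;
under the null `T` follows a mixture of one-degree chi-squares
weighted by the eigenvalues of the window's LD matrix. The tail is
computed by numerical inversion of the characteristic function
(Imhof's formula, `stats::integrate`, relative tolerance `1e-9`), with
two guards: a single non-zero eigenvalue short-circuits to the exact
scaled chi-square, and any failed or out-of-range inversion falls back
to a Satterthwaite moment-matching approximation. Accuracy is pinned
by Monte-Carlo oracles in the tests rather than assumed.

Genes in the same pathway whose windows (gene body ± 50 kb) overlap
are fused transitively before scoring; the fused block concatenates
variants with block-diagonal LD, since per-gene LD files carry no
cross-gene correlation. The pathway statistic is the Fisher-style sum
of `-ln p` over (fused) members; its reference distribution comes from
size-matched random gene sets drawn from the scored universe, with the
add-one estimator `(1 + #{S* >= S}) / (nPerm + 1)` so an empirical
p-value is never zero. The exact "empirical" statistic of the original
gene-score tool is not documented in our source; any member statistic
is calibrated by this construction, which the null-uniformity tests
verify. Pathways pass at Benjamini–Hochberg adjusted p below 0.05;
proxies are their members with a nominally significant (p < 0.05)
gene score, excluding HLA-flagged genes and seeds.

## Enrichment

For each trait and method, the counted population is the coding genes
with a decisive outcome (success or clinical failure) for an
indication matched to the trait. Seeds are excluded from the
population, not merely from the proxy set: leaving them in the
"not hit" rows would contaminate the comparison with the seeds' own
enrichment, and the planted odds ratio of a synthetic world would not
be recoverable. A gene with several matched indications counts once,
as a success if any of them succeeded. Tables with `a = b = 0` (no
proxy overlaps any outcome-bearing target) are removed; where `a` or
`b` alone is zero, 0.5 is added to every cell (Haldane). The surviving
strata are pooled with the Mantel–Haenszel odds ratio, a
Robins–Breslow–Greenland 95% confidence interval and the CMH
chi-squared statistic (continuity correction off by default), all
computed on the corrected cells.

### A calibration caveat worth knowing

Adding 0.5 to every cell of a corrected stratum is *asymmetric* when
successes are much rarer than failures: in a stratum whose single
outcome-bearing proxy succeeded, the corrected cross-products
overstate the odds ratio far more than the mirror-image stratum
understates it. Pooling many such strata therefore biases the pooled
odds ratio upward for methods with very sparse proxy–outcome overlap
(in our worlds: ligand–receptor pairs and diffusion modules; the
uncorrected Mantel–Haenszel estimator has no such bias). We keep the
corrected-cell pooling because it is the procedure under evaluation,
and we surface the consequence: on null worlds, confidence intervals
of the sparsest methods can systematically exclude 1. Any user reading
small-overlap odds ratios from this framework — including published
ones — should keep this in mind.

# The synthetic world

The generator is the package's definition of the study conditions;
every default is chosen once and documented here.

* **Universe and interactome.** 2000 genes, 95% coding, 1% HLA.
  Preferential attachment (3 edges per node) gives the heavy-tailed
  degree distribution on which the hub-failure result depends;
  Erdős–Rényi is available for contrast experiments.
* **Prior knowledge.** 250 complexes (3–10 members), 250
  ligand–receptor pairs, 80 pathways (10–100 members) with internal
  directed edges. A `structureCoherence` of 0.7 grows that fraction of
  structures from interactome neighborhoods, because real complexes
  and pathways are subgraphs of the interactome; without this
  alignment no pathway-level method has signal to find.
* **Traits.** 100 traits, each with one synthetic indication and a
  planted connected disease module of 14–24 genes, usually (80%)
  planted inside a coherent pathway. 60% of module genes form the
  connected causal core with genome-wide-significant, strongly
  colocalized records (`p12 ~ Beta(18, 2)`); loci average ~22 per
  trait, and 2–4 candidate eGenes per locus exercise the per-locus
  argmax. Non-causal module genes carry sub-threshold evidence (70%
  probability; intermediate `p12 ~ Beta(4, 4)`, non-significant GWAS
  p), and decoy loci draw null values (`p12 ~ Beta(2, 6)`).
* **Trial records.** 80–140 targets per indication enter the record,
  sampled with probability proportional to degree (hub bias) and a
  5x weight for genes near the planted signal — drug programs pursue
  biologically plausible targets, and without this overlap the 2x2
  strata of small proxy sets carry almost no information. Baseline
  success probability is 0.15; the planted odds multiplier (default 3)
  applies through a configurable channel, by default to genes sharing
  a complex with a causal gene whose colocalization records pass the
  hit filters — the prospective seeds — so the multiplier is exactly
  the estimand of seed-based expansion. Half of failures are clinical;
  10% of pairs are still in progress; 80% of assets are Selective, and
  Non-Selective assets take their second target from tested genes of
  the same outcome class, keeping every pair's outcome faithful to its
  own odds draw.
  `degreeFailureExponent` (default 0) scales success odds by
  `(degree/median degree)^-x` to emulate failure accumulation at
  heavily tested hubs.
* **Variant statistics.** 10 variants per gene with AR(1) LD
  (`rho = 0.5`); module genes' variant z-scores are mean-shifted by
  1.5. Windows live on one abstract chromosome with realistic body
  and gap lengths so ±50 kb fusion actually triggers.

What the generator does *not* emulate: physical genotypes and LD
between neighboring genes, the many-to-many fuzzy matching of traits
to indications (one synthetic indication per trait; a map file allows
many-to-many), MeSH ontology structure, dosage of evidence across
tissues, and any correlation between druggability and network
position. Passing tests therefore show that the pipeline's inferential
machinery is correct and calibrated on worlds with the assumed
structure — not that any particular biological network will behave
the same way.

# Problem sizes used by the checks

The statistical acceptance checks run at sizes chosen to make their
claims testable in minutes: null calibration uses 20 replicates of
800-gene, 100-trait worlds; parameter recovery 20 replicates of
2000-gene, 200-trait worlds (planted odds ratio 3); the hub-failure
direction 10 replicates at 100 traits with `degreeFailureExponent = 1`;
module recovery 10 planted 6-cliques in 300-node scale-free graphs;
and the proxy gene-score comparison 10 replicates of 1000-gene,
8-trait worlds. The acceptance script (`scripts/acceptance.R`)
recomputes the headline quantities on a full default world.

# Known limitations

* The Haldane-corrected pooling bias described above is inherent to
  the evaluated procedure, not removable here.
* With one z-vector per gene, gene scores are shared across traits;
  pathway enrichment is consequently trait-independent in the
  synthetic world, and the per-trait element of the gene-score method
  enters only through seed exclusion.
* The permutation threshold rule (`level = 0.05`) effectively requires
  the observed heat configuration to beat nearly every permutation;
  diffusion modules are therefore conservative, and on small worlds
  some traits legitimately yield none.
* Consensus modules across several networks are supported only as the
  union-of-runs reconstruction implied by per-network results; the
  package reports per-network modules as primary output.
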