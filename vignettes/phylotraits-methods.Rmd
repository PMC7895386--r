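---
title: "Methods: ranking gene families by association with a binary trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking gene families by association with a binary trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Some genomic traits — the motivating example is the Calvin–Benson–Bassham
(CBB) CO~2~-fixation cycle, marked by the joint presence of Rubisco and
phosphoribulokinase (Prk) — are repeatedly gained and lost across bacteria
and archaea. Acquiring such a trait reshapes the rest of the genome:
copy numbers of other gene families (enzymes identified by EC number,
protein domains identified by Pfam accession) shift as metabolism adapts.
`phylotraits` ranks gene families by the strength of their association
with a binary trait, contrasting trait-positive genomes against their
closest trait-negative relatives so that the signal reflects adaptation
rather than deep phylogenetic structure.

Three complementary methods probe each feature, and their ranks are merged:

1. **Enrichment** — a Wilcoxon rank-sum test per feature comparing copy
   numbers between the trait groups, Benjamini–Hochberg (BH) adjusted.
2. **Ancestral character estimation (ACE)** — trait history and
   copy-number history are reconstructed on phylogenetic subtrees and
   correlated, asking whether the *emergence* of the trait coincides with
   copy-number change.
3. **Random forest** — a classifier separates the trait groups from copy
   numbers; impurity importance ranks the features it relies on.

A gene-neighbourhood stage measures how far each feature's ORFs lie from
the trait-marker ORFs, distinguishing co-transmitted operon members from
independently selected adaptations.

# Pipeline stages

## Trait calling

Genomes are called trait-positive when every required marker (e.g. both
Rubisco and Prk) has at least one homology hit with full-sequence
E-value < 0.01. Two filters mirror practice with profile-HMM searches:
an optional catalytic-residue filter on a supplied reference alignment
(a Rubisco sequence without the catalytic lysine is a form IV
Rubisco-like protein, not a carboxylase — a gap never satisfies the
filter), and a taxon exclusion list for clades whose inclusion would bias
the contrast (Cyanobacteria in the motivating study). Marker identity is
established upstream by a model-name whitelist; re-annotation of hits is
out of scope, which keeps this stage deterministic.

## Closest-relative pairing

Each trait-positive genome is paired with its closest unused
trait-negative genome by a greedy loop: select the globally minimal
remaining distance, retire that row and column, repeat. The greedy loop
(not optimal bipartite matching) is deliberate — it is the procedure the
ranking is designed around, it guarantees the first pair attains the
global minimum, and each positive receives a distinct negative. Ties are
broken lexicographically by (positive, negative) accession so results are
reproducible; patristic distances are rounded to 1e-8 substitutions/site
before pairing because ultrametric trees produce exact ties that must
survive a newick round trip.

## Enrichment

Only genomes at or above a completeness threshold (default 95%) enter
this stage; completeness errors dilute count differences. Features
defining the trait itself (the marker enzymes/domains) are excluded, as
are features never observed in any retained genome — a feature with no
observations carries no evidence and would only pad the BH pool. p-values
are BH-adjusted jointly across ECs and Pfams. The Wilcoxon test uses the
exact null distribution for tie-free samples of at most 20 observations
and the tie-corrected normal approximation with continuity correction
otherwise; count data are massively tied, so the approximate path
dominates.

## Ancestral character estimation

Trait signal washes out when a tree mixes many independent gains and
losses, so reconstruction happens on *subtrees* of 50–300 taxa (bounds
are parameters; see problem sizes below). Candidate subtrees are scored
against a reference tree by

$$ s = \exp\!\left(-\left(\left|\ln\frac{P_B}{P_A}\right| +
\left|\ln\frac{N_B}{N_A}\right| + \left|\ln\frac{c_{v,B}}{c_{v,A}}\right| +
\left|\ln\frac{h_B}{h_A}\right|\right)\right) \in (0, 1], $$

where $P$ and $N$ are trait-positive/negative leaf counts, $c_v$ the
coefficient of variation of edge lengths, and $h$ the maximum
root-to-tip height; `B` is the candidate and `A` the reference. The
score is 1 only when all four statistics match and is symmetric in the
two trees. Subtrees are selected greedily by descending score, skipping
any candidate sharing nodes with an earlier selection.

Within each subtree:

* **Trait likelihoods** come from a 2-state equal-rates (ER) Mk model.
  The ER model is the conventional default when no asymmetry information
  exists. The transition rate is fitted by maximum likelihood
  (Felsenstein pruning; a 31-point log-spaced grid over $[10^{-8}, 10^3]$
  brackets the optimum, refined by bounded 1-D optimization), and
  marginal ancestral likelihoods are computed by a two-pass (down/up)
  algorithm equivalent to the re-rooting method for this reversible
  model. A subtree whose leaves all share one state short-circuits to
  likelihood 1 for that state — the ML rate sits at the boundary zero.
* **Ancestral copy numbers** are maximum-likelihood Brownian-motion
  estimates. They solve the weighted squared-change problem (edge weight
  = 1/branch length), a sparse linear system whose solution coincides
  with the re-rooted GLS estimate at every node; a single factorization
  handles all features at once, which is what makes per-feature
  reconstruction affordable.
* Per feature, the Spearman correlation `r` between trait likelihood and
  ancestral copy number is computed across internal nodes (asymptotic
  p-value; ancestral estimates are continuous but can tie when a feature
  is constant, so the t-approximation is used throughout), and nodes are
  split at likelihood strictly > 0.5 (ties to negative, following the
  strict reading of the classification rule) for a Wilcoxon comparison
  of ancestral counts.

p-values are BH-adjusted within each subtree, separately per test: each
subtree is its own testing universe, which matches reporting significance
counts per subtree. A feature is significant in a subtree when both
q-values fall below 0.001. Features are then summarized by

$$ \sum |r_w| = \sum_{T_n} |r| \cdot
\frac{\ln(q_{c,n} + q_c)}{\ln q_c} \cdot
\frac{\ln(q_{W,n} + q_W)}{\ln q_W}, $$

with $q_c$, $q_W$ the medians of the two q-value families across all
subtrees and features. Each weight is clamped to $[0, 1]$: the raw
expression turns negative once $q_n + q_{med} > 1$, which would reward
poor q-values, so clamping preserves the intended monotone
down-weighting. The median itself is clamped below 1 so its logarithm
cannot vanish on degenerate inputs. Subtree terms with an undefined
correlation (constant feature) or an undefined Wilcoxon q (all nodes on
one side of 0.5) are omitted from the sum. Features are ranked by the
descending sum; a feature absent from every subtree scores 0.

When the pipeline runs on a single tree, the reference for the
similarity score is a held-out clade: the smaller child clade of the
root, provided it has at least four leaves of each color and
well-defined statistics (otherwise the whole tree serves as reference).
The held-out clade is itself analyzed as subtree 0, mirroring a design
where one domain of life anchors the score and is also reconstructed.

## Random forest

EC and Pfam universes are processed separately end to end, because
impurity importances are only comparable within a feature type. When a
type has more features than `n_keep` (default 600), recursive feature
elimination trims it: an L2-penalized (ridge) logistic regression is fit
on the raw counts and the ten features with the smallest absolute
coefficients are dropped, repeatedly. Ridge rather than an unpenalized
fit keeps the coefficients defined when features outnumber genomes; raw
counts are used without standardization since the coefficients feed only
a rank-based elimination. Then `n_forests` (default 100) forests of
`n_estimators` (default 500) trees are trained, each on a fresh random
¾ of the genomes (simple random sampling, not stratified — the paired
design is balanced by construction) with the remaining ¼ measuring
held-out accuracy. Per forest, impurity importances are normalized to
sum to 1; the mean and coefficient of variation over forests are
reported. Per-repetition seeds derive from the master seed by a counter,
so any single repetition can be reproduced.

## Consensus

Each method contributes a rank: enrichment by ascending q, ACE by
descending weighted-|r| sum, forest by descending importance (within
type). Average ranks resolve ties throughout — the default of the
statistical environment the procedure originates from. A feature missing
from a method (filtered out by RFE, say) receives that method's maximum
rank plus one. The consensus rank is the rank of the sum of the three,
so it is invariant to any monotone transform of a method's scores.

## Proximity

For trait-positive genomes only, and only on contigs carrying at least
one marker ORF, the distance from every feature-bearing ORF to every
marker ORF is the absolute difference of ORF indices. Contigs are
treated as linear even when the molecule is known to be circular — with
many draft genomes in unplaced scaffolds, a uniform convention beats a
mixed one, at the cost of overstating some distances. Distances to *all*
marker copies are recorded (each occurrence is a count in the output),
the marker-to-itself pair on a single ORF is dropped by default, and
summaries are grouped by (feature, marker, strand relation) with
occurrence counts per molecule type.

# The synthetic-data generator

The generator exists so every stage is testable without external
downloads, and its defaults are the package's benchmark conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_genomes` | 200 | leaves of a pure-birth tree |
| `birth_rate` | 1 | speciation rate (sets the time scale) |
| `q01`, `q10` | 0.1, 0.3 | trait gain/loss rates per substitutions/site |
| `n_features` | 300 | gene families, half EC-style, half Pfam-style |
| `frac_linked` | 0.1 | fraction of features with trait-dependent copy number |
| `base_log_mean` | 0 | log expected copies in the neutral state |
| `effect_beta` | 1.5 | log-scale shift while trait-positive (≈ 4.5-fold) |
| `bm_sigma2` | 0.1 | Brownian variance of the latent log-abundance |
| `co_prob` | 0.75 | operon-like co-location probability for linked copies |

Rationale for the values not fixed by the benchmark definition: the
gain/loss rates give a stationary trait prevalence of
$q_{01}/(q_{01}+q_{10}) = 0.25$, so trait-negatives outnumber positives
(the pairing precondition) while a 200-leaf tree still carries several
gains and losses — the regime the subtree analysis is designed for.
`base_log_mean = 0` and `bm_sigma2 = 0.1` yield copy numbers mostly in
the 0–6 range with occasional higher counts, matching the magnitudes
typical of per-genome EC/Pfam counts. The trait effect acts on the log
scale, i.e. multiplicatively on expected copies, consistent with
summarizing enrichment as log~2~ count ratios.

A pure-birth (Yule) tree suffices for method testing; a birth–death
model would add a parameter without changing what the tests probe.
Counts are Poisson draws around the exponentiated latent Brownian value;
trait linkage adds `effect_beta` at nodes whose lineage is currently
trait-positive. Ground truth (true internal states, the linked-feature
list, latent means) always accompanies the data so recovery tests are
self-describing.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: horizontal transfer of feature clusters
independent of the trait, annotation error in the count matrix, genome
incompleteness (simulated completeness is always 100%), correlated
evolution among features, and non-ultrametric rate variation. The
trait-calling stage sees clean simulated hit tables (strong marker hits,
occasional decoys above threshold, partial marker subsets in some
negatives), not real HMM score distributions.

# Numerical choices

* Mk rate search bounded in $[10^{-8}, 10^3]$ on a log grid, then
  refined; likelihood underflow is handled by per-node rescaling with
  accumulated log-scale.
* Zero-length branches are floored at $10^{-9}$ before forming edge
  weights or transition probabilities.
* Patristic distances are rounded to $10^{-8}$ before pairing (exact-tie
  stability across newick serialization).
* Greedy ties: lexicographic by accession (pairing) and ascending node
  number (subtree selection).
* Ancestral nodes with likelihood exactly 0.5 are classed trait-negative.
* The Eq-weight clamps described above.
* Per-repetition forest seeds: `master + repetition`, reduced modulo a
  31-bit prime.

# Problem sizes used by the tests

The shipped tests and the acceptance script run the benchmark at
200 genomes × 300 features with subtree bounds 15–80 (the paired subset
of a 200-leaf tree holds roughly 100 leaves, so the 50–300 bounds
appropriate for trees of thousands of genomes would admit at most one
subtree) and a forest configuration of 25 repetitions × 200 trees with
`n_keep = 150` per type. These sizes keep a full run under a minute
while leaving the recovery margin wide: at least 80% of planted
trait-linked features are expected in the top consensus decile, and
observed captures are typically 83–97%.

# Interface

The package is driven from R: `pipeline_config()` + `run_pipeline()`
orchestrate the stages, and each stage is exported on its own
(`run_enrichment()`, `run_ace()`, `run_forest()`, `consensus_rank()`,
`orf_distances()`, …) for piecemeal use. `scripts/acceptance.R` is the
only shell entry point, reproducing the benchmark quantities.

# Known limitations

* The ER Mk model cannot express asymmetric gain/loss; a trait that is
  almost never lost will have its ancestral likelihoods pulled toward
  0.5 deep in the tree.
* The weighted-|r| summary depends on the q-value *medians*, so adding
  uninformative features shifts every feature's weights slightly.
* Greedy pairing is order-dependent under ties and not globally optimal;
  it reproduces a specific published procedure rather than solving the
  assignment problem.
* Impurity importance is biased toward high-cardinality features; counts
  have small cardinality, which limits but does not remove the bias.
* With unstratified ¾ splits and a balanced design, a training split can
  in principle lack a class; it is resampled and logged.
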