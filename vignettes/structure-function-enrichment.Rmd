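---
title: "Bidirectional structure-function enrichment for antimicrobial peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional structure-function enrichment for antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampenrich)
```

## The question and the model

Antimicrobial peptides (AMPs) carry up to seven annotated activities —
antibacterial (`G`), anti-Gram-positive (`G+`), anti-Gram-negative
(`G-`), antifungal (`F`), antiviral (`V`), antiparasitic (`P`) and
anticancer (`C`) — and fold into a wide range of structures. `ampenrich`
asks whether particular activities and particular structural categories
are *mutually* over-represented: is an activity enriched among the
peptides of a structural category, and is the category in turn enriched
among the peptides with that activity?

Both directions are one-sided hypergeometric tests. For a population of
$N$ peptides of which $M$ carry a property, and a sample of $n$ of which
$m$ carry it,

$$P \;=\; \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

the probability of at least $m$ marked peptides under sampling without
replacement. The two directions differ only in how population and sample
are built:

* **Function in structure** — population: every peptide (each carries at
  least one activity, structural annotation not required); property: the
  activity $f$; sample: the peptides of structural category $s$.
* **Structure in function** — population: the peptides annotated under
  the structural scheme; property: membership in $s$; sample: the
  scheme-annotated peptides with $f$.

Because the hypergeometric tail is symmetric in $(M, n)$, the two
directions give identical raw p-values whenever the two populations
coincide (for example when every peptide is scheme-annotated). Observed
one-direction arrows therefore arise *only* from the population
restriction and from the multiple-testing families, a property the test
suite asserts explicitly.

P-values are adjusted by the Benjamini–Hochberg step-up procedure within
one family per `{scheme, level, direction, threshold}` batch. The exact
family membership is a genuine design choice (the alternative — pooling
directions or schemes — is defensible); batching per direction and
threshold keeps families comparable across the identity sweep, and the
run log records every family size so the choice is auditable. At FDR
level $Q$ (default 0.05) each (structure, activity, threshold) cell gets
an arrow: `<->` when both directions pass, `->` when only the functional
direction does, `<-` when only the structural one does, `.` otherwise.

Two size filters guard the tests: a structural category is only tested
when at least `min_category = 5` *original* (unclustered) peptides
belong to it, and only categories with at least `min_table = 10`
original peptides enter the summary arrow table. Both filters are
evaluated on the original dataset, not on the representative sets,
because a category's evidential basis is its real membership, not what
survives redundancy removal. Only over-representation is tested;
depletion is out of scope.

## Redundancy control: representative sets

AMP collections are highly redundant, so every analysis is repeated on
representative sets built at identity thresholds from 100% down to 40%
in steps of 10. Identity is measured on a global alignment with match
+1, mismatch 0 and linear gap penalty −1 — an identity criterion, not a
similarity one, hence no substitution matrix — and normalised by the
*shorter* sequence length. The consequence, deliberate and worth
remembering, is that a perfect substring scores identity 1.

Clustering is greedy leader clustering: peptides are visited by
decreasing length (ties broken by id), each joins the first
representative within the threshold or founds a new cluster. This is
deterministic and dependency-free; it does not attempt to reproduce any
particular cascaded-clustering tool's output, because the enrichment
layer only needs *a* well-defined representative set per threshold. A
representative keeps its own annotation record; member annotations are
not unioned onto it, since no principled reconciliation rule exists when
members disagree.

## Structural labels

Three labelling schemes feed the same test machinery:

* **CATH** class/architecture and **SCOP** class/fold labels are
  *consumed* from the annotation table, never computed: assigning them
  is the job of the curated hierarchies. Level-1 analyses appear as
  `"*"` rows in the summary table (all architectures/folds of a class).
* **TM fold clusters** are computed from C-alpha traces. The TM-score
  of two traces is
  $\mathrm{TM} = \frac{1}{L_{\text{norm}}}\sum_i \frac{1}{1+(d_i/d_0)^2}$
  over aligned residue pairs, with $L_{\text{norm}} = \min(L_a, L_b)$
  and $d_0 = \max(0.5,\; 1.24\,(L_{\text{norm}}-15)^{1/3} - 1.8)$ Å.
  Normalising by the shorter chain makes the score symmetric — the usual
  target-normalised convention is direction-dependent, unsuitable for
  undirected clustering — and the 0.5 Å clamp on $d_0$ matters because
  most AMPs are shorter than the formula's $L = 15$ pole. Scores at or
  above 0.5 are read as "same fold topology".

The score is maximised heuristically: correspondences are seeded by
gapless threading of the shorter trace at every offset of the longer;
each seed is refined by at most 20 rounds of Kabsch superposition on the
current pairs followed by dynamic-programming realignment with pair
score $1/(1+(d/d_0)^2)$ and gap penalty −0.6, stopping when the pair set
repeats. This is not a full TM-align reimplementation (no secondary
structure seeding, no fragment enhancements); on peptide-sized chains
the simple search recovers self-scores of 1, exact rigid-motion
invariance, and clean separation of planted helix and hairpin families.
Arguments are ordered internally (shorter chain threaded onto longer),
so the score is exactly symmetric in its arguments.

Fold clusters then come from the same greedy leader rule at cutoff 0.5,
renumbered by decreasing size. The linkage rule is our choice — leader
clustering keeps the guarantee that every member scores at least the
cutoff against its leader — and cluster numbers are therefore
arbitrary labels, not comparable to any external numbering.

## The synthetic generator

`generate_amp_dataset()` emulates the *structure* of an annotated AMP
collection: sequence families with tunable within-family identity
(mutation of a random family seed), one structural category per family
per scheme (family-level, because real structural annotation is
family-coherent — this is what makes the clustering-to-enrichment
interaction testable), independent per-activity Bernoulli draws with
configurable prevalences, and optional planted associations:
$P(f \mid s) = \min(1, \lambda \pi_f)$ for a planted (category,
activity, lift) triple. Peptides whose draw comes up empty get the
highest-prevalence activity, enforcing the non-empty-activity
invariant. Toy C-alpha traces (ideal helix: 1.5 Å rise, 100° turn,
2.3 Å radius; hairpin: 3.4 Å-rise antiparallel strands with a 4-residue
turn; extended chain: 3.5 Å spacing — conventional idealisations) give
each family a structure consistent with its TM category.

Defaults were fixed once as a plausible desk-scale collection: 30
families of 10 peptides, lengths 15–60, mutation rate 0.1, and base
prevalences `G` 0.5, `G+` 0.3, `G-` 0.3, `F` 0.2, `V` 0.1, `P` 0.05,
`C` 0.1, reflecting the antibacterial-dominated composition of AMP
databases. The error-control simulations in the test suite use 300
peptides in 6 TM categories with antifungal prevalence 0.1; the planted
power condition fixes the planted category at exactly 40 of 300
peptides via the generator's deterministic `allocation` option, with
lift 5 (so $P(F \mid s) = 0.5$). The RNG is split per family, so
extending a dataset with more families leaves the existing ones
byte-identical.

What the generator does *not* emulate: real AMP residue composition,
hierarchical activity structure (no implication from `G+`/`G-` to `G` —
the three are treated as independent annotations throughout, matching
their treatment as separate rows in the summary table), annotation
noise, or physics-based structures. Passing tests therefore demonstrate
the statistical machinery's calibration and power under known ground
truth, not biological conclusions about real AMP collections.

## Motif summaries

For the peptide set behind an enrichment, `star_align()` builds an
anchor-based multiple alignment (longest sequence as anchor, pairwise
global alignments, anchor-relative gaps merged) and `consensus_motif()`
reports per-column residue frequencies (gaps excluded from the
denominator), information content in bits ($\log_2 20$ minus the column
entropy), and a consensus string: a column shows its modal residue when
that residue reaches `min_freq = 0.5` among covering rows and at least
`min_coverage = 0.5` of rows cover the column. A star alignment is not
a progressive MSA; for the short, family-homogeneous sets that
enrichment produces it is adequate, deterministic and dependency-free.
Outputs are comparable to published motif figures only qualitatively
(conserved cysteines and glycines), never column-for-column.

## Worked example

```{r example}
cfg <- synthetic_config(
  n_families = 30, family_size = 10, seq_length = c(15, 40),
  categories = list(TM = setNames(rep(5, 6), as.character(1:6))),
  allocation = list(TM = setNames(c(4, 6, 5, 5, 5, 5),
                                  as.character(1:6))),
  base_prevalence = c(G = 0.5, Gpos = 0.3, Gneg = 0.3, F = 0.1,
                      V = 0.1, P = 0.05, C = 0.1),
  planted = data.frame(scheme = "TM", category = "1", activity = "F",
                       lift = 5),
  seed = 1)
g <- generate_amp_dataset(cfg)
g$dataset

sw <- representative_sweep(g$dataset, cluster_config(c(1.0, 0.7, 0.4)))
vapply(sw$datasets, n_peptides, integer(1))

en <- enrichment_sweep(g$dataset, sw$datasets, "TM")
subset(en$mutual, key == "1" & activity == "F",
       select = c(threshold, q_fun, q_struct, arrow))

render_arrow_matrix(en$mutual)
```

The planted antifungal association with TM cluster 1 surfaces as `<->`
at the high-identity columns (it fades as the 40% representative set
shrinks the sample); null cells stay `.` at the configured FDR.

## Numerical and interface choices

* The hypergeometric tail is computed in log space (log-gamma binomial
  coefficients, log-sum-exp) — exact rational arithmetic is unnecessary
  at these population sizes. It is cross-checked in the tests against
  exhaustive sample enumeration (complete scan up to $N = 12$) and an
  independent distribution-function route.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` after
  validation; tests verify it against a direct step-up evaluation.
* All sequence and trace indices are 0-based internally where stored in
  result objects (e.g. TM-score `aligned_pairs`), 1-based in
  user-facing tables.
* Alignment, identity and TM-score constants (gap penalties, iteration
  cap, convergence rule) are fixed, logged defaults, overridable via
  `cluster_config()` / `tm_score()` arguments.
* Degenerate inputs: collinear point sets are superposed but flagged;
  reflections in the Kabsch solution are corrected by flipping the
  smallest singular direction; `d0` is clamped at 0.5 Å; empty
  sequences, short traces (< 3 residues) and invalid counts are
  rejected with named errors.
* Simulation sizes in the test suite (200 null and 100 planted
  replicates of 300 peptides; complete hypergeometric scan to
  $N = 12$; 20-trace fold-recovery sets) were chosen as the smallest
  scales at which the calibration, power and recovery properties are
  sharp; they run in a few minutes on one CPU.
* The package is driven from R: `run_pipeline()` orchestrates the full
  sweep and writes TSV artifacts (enrichment rows, arrow matrix, count
  tables, cluster memberships, run log), which is the intended
  command-line-equivalent surface; TSV-first output makes every figure
  of the analysis reproducible from flat files. Outputs are
  deterministic and reruns are byte-identical; an existing non-empty
  output directory is never overwritten without `force = TRUE`.

## Known limitations

* Greedy leader clustering (both sequence and fold) is order-dependent
  by construction; the visiting order (decreasing length, id
  tie-break) is part of the contract, and no attempt is made to match
  the output of cascaded clustering tools.
* The data model holds at most one structural label per scheme per
  peptide; reconciling multiple structures per peptide is left to the
  caller.
* With identity normalised by the shorter length, fragments cluster
  into their parent's family at any threshold — intended for redundancy
  control, but worth knowing when interpreting representative counts.
* The TM-score search is heuristic; it can in principle undershoot the
  optimum on convoluted topologies, though never on the self-score or
  rigid-motion cases, which are exact.
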