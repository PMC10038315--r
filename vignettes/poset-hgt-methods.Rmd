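---
title: "Detecting horizontal gene transfer from partial orders of species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer from partial orders of species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posetHGT)
```

## The model

posetHGT works from one *species-anchored partial order* (poset) per gene
per species. The poset anchored at species $s_i$ orders the other species by
closeness to $s_i$ for a given gene: the strict pair $(a, b)$ asserts that
$a$ is strictly closer to $s_i$ than $b$ is, and $s_i$ itself is the unique
minimum. In practice such orders come from ranking per-gene similarity
scores (e.g. alignment bit scores of the gene in $s_i$ against its
orthologs), which `posets_from_scores()` implements: strictly greater score
means strictly closer, equal scores leave species incomparable. Ties are
expected — coalescence makes equal distances common — so the orders are
genuinely partial, not linear.

A rooted species tree (an *S-tree*: leaves bijectively labelled by the
species, every internal node with two or more children) realises a poset
when closeness agrees with tree structure: $a \le_i b$ requires
$\mathrm{depth}(\mathrm{MRCA}(s_i, b)) \le
\mathrm{depth}(\mathrm{MRCA}(s_i, a))$, with the root at depth 0. This is
the operational form of the path condition that the walk from $s_i$ to $b$
must pass through $\mathrm{MRCA}(s_i, a)$; the two are verified equivalent
in the test suite by an independent path-walking oracle.

## From posets to a gene tree and back

For each gene, `construct_tree()` rebuilds the tree from its poset family
through the *sibling matrix* $A$, where $A(i, j)$ counts the species
strictly above $s_j$ in the $s_i$-anchored poset and the diagonal holds the
sentinel $-1$. For a mutually *consistent* family ($s_j \le_i s_k$ implies
$s_i \le_j s_k$) the matrix is symmetric, and equal maximal entries identify
sibling leaves — larger values mean deeper, more recent siblinghood. The
algorithm repeatedly finds the maximum off-diagonal value, groups the
labels connected by edges carrying it, merges each group's rows and columns
into a parent label, and stops when everything remaining is mutually at
value 0, adopting the remainder under one root. The inverse direction,
`generate_posets()`, walks from each leaf to the root and converts the
successively contributed leaf sets into closeness levels; pairs are emitted
exactly across levels, so equally close species stay incomparable.

```{r roundtrip}
t <- parse_newick("(((s1,s2),s3),(s4,s5));")
fam <- generate_posets(t)
build_matrix(fam)
stree_equal(construct_tree(fam), t)
```

Three numerical/structural choices deserve a note, since the procedure
itself does not fix them:

* **Sibling groups as connected components.** All labels joined by
  max-valued edges in one component are merged under one parent. Clique
  components are the ordinary case; a non-clique (star) component — a hub
  equally close to several groups that are not close to each other — is
  merged whole, which is the only reading consistent with the multifurcating
  worked examples. A notice is logged when this rule fires, because
  overlapping-clique inputs are not covered by any worked example.
* **Round processing order.** Every group found at the current maximum is
  merged before rescanning, and groups are processed by smallest contained
  species label. Order does not affect the result for consistent input
  (components are disjoint), but determinism keeps outputs and tests stable.
* **Merge validation.** When a group's members disagree on their count
  towards an outside label, the posets are mutually inconsistent and
  construction stops with an error rather than guessing. Recovering trees
  from inconsistent or incomplete families is out of scope by design.

## Comparing gene trees: 2-partitions and refinement

Cutting any tree edge splits the species into a *2-partition*. Two
2-partitions contradict when a crossing quadruple exists ($a, b$ together
versus $c, d$ in one, $a, c$ versus $b, d$ in the other) — operationally,
when all four pairwise side intersections are nonempty, which the suite
checks against exhaustive quadruple enumeration up to eight species. Two
trees contradict when any of their 2-partitions do. A tree never contradicts
itself or any of its refinements, and two non-contradictory trees admit a
unique *minimum common refinement*, rebuilt by `min_common_refinement()`
from the union of their partition sets.

Reconstruction from partitions processes non-singleton sides smallest
first, making each side's members siblings and substituting the new parent
throughout. Two conventions are ours: a reserved pseudo-leaf `s0` under the
root keeps root-edge partitions distinguishable before the union (and is
stripped afterwards), and ties among equally small sides are broken
lexicographically — the procedure's result is invariant to this, but a
fixed order makes runs reproducible.

## Inferring transfer candidates

`infer_hgt()` builds one tree per gene, clusters trees sequentially —
each tree joins the first cluster (in creation order) whose representative,
the founding tree, it does not contradict — and declares the largest
cluster the majority topology. Genes outside the majority are transfer
candidates; `witness_transfers()` converts each contradicting partition pair
into the two species pairs united in the candidate tree but separated in
the majority tree, each annotated with both transfer directions, since
nothing in the topology comparison resolves donor from recipient.

```{r hgt}
maj <- parse_newick("((s1,s2),(s3,s4));")
t4  <- parse_newick("((s1,s3),(s2,s4));")
fams <- list(g1 = generate_posets(maj, "g1"),
             g2 = generate_posets(maj, "g2"),
             g3 = generate_posets(maj, "g3"),
             g4 = generate_posets(t4, "g4"))
infer_hgt(fams)
```

Open edges of the scheme, and how the package resolves them:

* A tree can be non-contradictory with representatives of several clusters
  (contradiction is not transitive); it joins the first. `strict = TRUE`
  instead requires non-contradiction with every member.
* A tie for the largest cluster is an explicit no-call (`majority = NA`,
  no candidates) rather than an arbitrary pick: the method's premise is a
  dominant vertical topology, and without one the minority notion is
  undefined.
* Arbitrary input posets are accepted, not only the level-shaped orders
  trees produce; families that admit no tree fail construction and are
  reported as unconstructible rather than silently dropped.

## What the simulator emulates — and what it does not

`make_dataset()` draws one base species tree (uniform recursive splits;
binary by default, since gene histories are fully resolved in expectation),
gives clean genes its poset family, and injects each listed transfer by
*leaf regrafting*: the recipient leaf is detached and reattached as sibling
of the partner. Regrafting is the smallest edit guaranteeing a crossing
quadruple whenever four or more species are present, so it exercises every
detection path; it does not emulate general subtree transfers, duplication,
loss, or incomplete lineage sorting — all of which can also make gene trees
disagree in real data. Passing simulations therefore show that the
machinery recovers exactly the planted topology conflicts, not that real
incongruence is always transfer. `corrupt_posets()` produces the
complementary negative control: dropped or flipped pairs yield families
that construction correctly refuses.

The default study conditions in the tests are 20-gene datasets over 6, 8,
or 10 species with one to three injected transfers, 50 seeded replicates,
and property sweeps over 200 random trees of up to 12 species — sizes at
which every structural claim can also be checked by brute-force oracles.
The construction algorithm is cubic in the species count, so much larger
inputs remain practical.

## Limitations

* Detection is topological only: transfers that do not change the gene-tree
  topology (e.g. between sister species) are invisible.
* Direction of transfer is reported as unresolved alternatives.
* Inconsistent or incomplete poset families are rejected, not repaired.
* All gene trees must share one leaf set; differing leaf sets (gene absence)
  are out of scope.
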