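# posetHGT

Infer horizontal gene transfer (HGT) candidates from partial orders of
species closeness.

## The problem

Genes move vertically from ancestor to descendant — and sometimes
horizontally between lineages. A horizontally transferred gene carries a
history that disagrees with the species phylogeny: its gene tree places the
donor and recipient together where the species tree separates them. posetHGT
detects such genes starting from very weak input: for each gene and each
*focal* species $s_i$, only a partial order ("poset") saying which species
are closer to $s_i$ than which others for that gene. Such orders fall out of
ranking per-gene similarity scores (e.g. BLAST bit scores of the gene in
$s_i$ against its orthologs), with ties left incomparable.

The pipeline, per gene:

1. **Posets → tree.** Build the sibling matrix
   $A(i,j) = |\{s_x : s_j <_i s_x\}|$ (diagonal $-1$). For mutually
   consistent posets $A$ is symmetric, and repeatedly merging the groups of
   labels joined by the maximal entries reconstructs the unique compatible
   rooted tree (`construct_tree()`); `generate_posets()` is the inverse.
2. **Tree ↔ tree comparison.** Each tree edge induces a 2-partition of the
   species; two trees *contradict* when some pair of their 2-partitions
   crosses on four species. Non-contradictory trees admit a minimum common
   refinement, computed from the union of their partition sets
   (`min_common_refinement()`).
3. **Clustering and calling.** Gene trees are clustered by pairwise
   contradiction; the largest cluster is the majority (vertical) topology
   and every gene outside it is an HGT candidate, reported with the witness
   species pairs its tree unites but the majority separates
   (`infer_hgt()`).

Seeded simulators (`random_stree()`, `inject_hgt()`, `make_dataset()`,
`corrupt_posets()`, `posets_from_scores()`) generate complete datasets with
known ground truth, so no external data is needed.

## Worked example

```r
library(posetHGT)

maj <- parse_newick("((s1,s2),(s3,s4));")   # three genes follow this tree
t4  <- parse_newick("((s1,s3),(s2,s4));")   # one gene groups s1 with s3
fams <- list(g1 = generate_posets(maj, "g1"),
             g2 = generate_posets(maj, "g2"),
             g3 = generate_posets(maj, "g3"),
             g4 = generate_posets(t4, "g4"))
infer_hgt(fams)
#> HGT inference report
#>   genes analysed: 4 (plus 0 unconstructible)
#>   clusters: 2
#>   majority cluster: #1 (3 gene(s)); representative ((s1,s2),(s3,s4));
#>   candidate gene g4: possible transfer between s1<->s3 or s2<->s4
```

Gene `g4` is flagged because its tree contradicts the majority topology;
the witness pairs say the transfer happened between `s1` and `s3` or
between `s2` and `s4` (either direction — topology alone cannot resolve
donor and recipient).

The intermediate objects are all exposed:

```r
fam <- generate_posets(parse_newick("(((s1,s2),s3),(s4,s5));"))
build_matrix(fam)
#>    s1 s2 s3 s4 s5
#> s1 -1  3  2  0  0
#> s2  3 -1  2  0  0
#> s3  2  2 -1  0  0
#> s4  0  0  0 -1  3
#> s5  0  0  0  3 -1
```

The maximal value 3 pairs `s1` with `s2` and `s4` with `s5`; after merging,
the maximum drops to 2 (joining the `s1,s2` parent with `s3`), then to 0,
and the root closes the tree.

A command-line interface wrapping the same functions is installed under
`exec/posethgt` (subcommands `gen-posets`, `build-tree`, `check`, `refine`,
`infer-hgt`, `simulate`; poset files are plain TSV, trees are Newick,
reports are JSON).

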