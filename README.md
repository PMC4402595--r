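# nbmpath

Detection of overlapping mutated driver pathways from binary somatic
mutation data, de novo — no prior pathway, interaction-network or
annotation knowledge required.

## The problem

Tumors accumulate many somatic mutations, but only a minority drive
tumorigenesis, and drivers tend to hit *pathways* rather than fixed genes.
Two signals make driver gene sets detectable from mutation data alone:

* **high coverage** — many patients carry at least one mutation in the set;
* **high exclusivity** — few patients carry more than one, because a single
  hit per pathway is usually sufficient.

Given a binary mutation matrix *A* (m patients × n genes), write
Γ(g) for the set of patients in which gene *g* is mutated and
Γ(M) = ∪<sub>g∈M</sub> Γ(g) for a gene set *M*. `nbmpath` scores gene sets
with

* exclusive degree  ED(M) = |Γ(M)| / Σ<sub>g∈M</sub> |Γ(g)|  (= 1 iff the
  per-gene coverages are pairwise disjoint),
* coverage degree  CD(M) = |Γ(M)| / m  (= 1 iff every patient is covered),
* exclusivity-coverage degree  ECD(M) = ED(M) × CD(M) =
  |Γ(M)|² / (m · Σ<sub>g∈M</sub> |Γ(g)|),

and searches for gene sets with high ECD in three steps:

1. **Filter** — drop genes mutated in fewer than 5% of patients
   (likely passengers).
2. **Network** — connect every gene pair whose pairwise ED is ≥ λ
   (default 0.95); the edge weight is that ED.  Genes with no
   near-exclusive partner drop out.
3. **Greedy growth** — repeatedly seed on the free connected gene pair
   with the highest pairwise ECD and grow it by the best single
   add/remove move that strictly increases ECD while keeping ED > λ,
   until locally optimal.  Candidates with fewer than 3 genes or
   coverage degree below δ (default 0.3) are discarded.  Growth may
   absorb genes already claimed by earlier sets, so reported pathways can
   overlap.

Because exhaustively maximizing set weights over all k-gene submatrices is
NP-hard, this network-guided greedy search is what makes the problem
tractable at matrix scale.

The package also ships the implanted-pathway simulator used to benchmark
the method (mutually exclusive driver sets of configurable coverage plus
Bernoulli passenger noise, with ground-truth labels) and a
permutation-based empirical significance estimate for candidates.

## Worked example

Simulate the standard benchmark — 300 patients, 500 genes, five implanted
mutually exclusive 5-gene pathways with coverage degrees
0.95/0.85/0.75/0.65/0.55, passenger probability q = 0.001 — and run the
detector with default parameters:

```r
library(nbmpath)
sim <- simulate_mutations(q = 0.001, seed = 42)
sim$matrix
#> mutation_matrix: 300 patients x 500 genes, 1284 mutation events

res <- run_nbm(sim$matrix)
res
#> nbm_result: 5 driver pathway(s), 0 candidate(s) discarded
#>   1. {G0049, G0074, G0153, G0321, G0485}  ED = 0.9930  CD = 0.9500  ECD = 0.9434
#>   2. {G0122, G0128, G0146, G0228, G0500}  ED = 0.9961  CD = 0.8500  ECD = 0.8467
#>   3. {G0024, G0089, G0303, G0327, G0356}  ED = 0.9956  CD = 0.7500  ECD = 0.7467
#>   4. {G0020, G0110, G0165, G0370, G0410}  ED = 1.0000  CD = 0.6500  ECD = 0.6500
#>   5. {G0283, G0297, G0367, G0387, G0486}  ED = 0.9940  CD = 0.5533  ECD = 0.5500
```

All five reported sets equal the implanted ground truth
(`sim$truth$pathways`); e.g. pathway 1 is exactly
`G0049 G0074 G0153 G0321 G0485`, mutated in 95% of patients with
near-perfect exclusivity (ED = 0.993; the small deficit is passenger
noise).  An empirical significance for the top set:

```r
filtered <- filter_by_frequency(sim$matrix, 0.05)
permutation_pvalue(filtered, res$pathways[[1]], n_permutations = 1000, seed = 7)
#> [1] 0.000999001   # = 1/1001: no permutation matched the observed ECD
```

Real data come in as a headered 0/1 TSV (`read_matrix_tsv()`) or a
two-column patient–gene event list (`read_pair_list()`).

### Command line

The installed `nbm` script (under `exec/`) wires the same pipeline up for
shell use:

```sh
nbm simulate --q 0.001 --seed 42 --out-prefix bench
nbm run --matrix bench_matrix.tsv --out-prefix out      # pathways TSV/JSON,
                                                        # edge list, manifest
nbm score --matrix bench_matrix.tsv --genes G0049,G0074,G0153,G0321,G0485
```

Every run writes a manifest (inputs, resolved parameters, seed, version)
sufficient to reproduce it exactly.

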