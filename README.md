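# pancub — pangenome codon usage bias analysis

`pancub` asks a comparative-genomics question: within a bacterial pangenome,
do **core genes** (present in every strain) and **strain-specific genes**
(unique to one strain) experience different balances of **mutation** and
**selection** on their synonymous codon usage? The package is aimed at
microbial genomics researchers who have per-strain CDS FASTA files (plus,
optionally, ortholog clusters, expression estimates, tRNA gene copy numbers
and an HGT exclusion list) and want the full diagnostic battery as one
reproducible pipeline.

## What it computes

**Stratification.** Gene clusters are binned by presence count into five
sets; with N strains and w = ⌊(N−2)/3⌋ the bins are {1}, [2, 1+w],
[2+w, 1+2w], [2+2w, N−1], {N} — for N = 26 the classic
1 / 2–9 / 10–17 / 18–25 / 26 split. Pan/core rarefaction curves are computed
over seeded strain-order permutations.

**Per-gene codon usage bias** (genes shorter than 100 codons are excluded):

- **RSCU**: RSCU(c) = x_c / mean(x over the synonymous family); 59
  informative codons (61 sense − AUG, UGG).
- **CAI** (Sharp–Li): geometric mean of relative adaptiveness
  w_c = (x_c + 0.5)/(max_F x + 0.5) over a highly expressed reference set
  (default: genes annotated "ribosomal protein").
- **Nc** (Wright): Nc = 2 + 9/F̄₂ + 1/F₃ + 5/F̄₄ + 3/F̄₆ with family
  homozygosity F = (nΣp² − 1)/(n − 1); range [20, 61].
- **Nc′** (Novembre): as Nc with F̂ = (χ² + n − m)/(m(n − 1)), where χ²
  measures deviation from frequencies expected under the gene's own
  positional nucleotide composition.
- **CDC**: 1 − cos θ between observed codon usage and usage expected from
  positional GC and purine contents.
- Nc and Nc′ are rescaled to a [0, 1] bias scale via **(61 − X)/41**.

**Mutation–selection diagnostics per gene set:**

- **ENC-plot**: deviation (expected − estimated)/expected from the
  mutation-only curve Nc\* = 2 + x + 29/(x² + (1−x)²), x = GC3; flagged at a
  0.15 threshold with a 0.05–0.30 sweep.
- **Neutrality plot**: OLS of GC12 on GC3 (slope 1 = pure mutation
  pressure, 0 = complete selective constraint).
- **Correspondence analysis** of the gene × 59 RSCU matrix, with Spearman
  correlations of axis 1 against GC fractions, length, CAI, Nc, Nc′, CDC
  and expression.
- **CUB–expression** Spearman correlation and **tRNA–RSCU cosine
  similarity** (Watson–Crick anticodon mapping; wobble optional).
- One-way ANOVA of each bias measure across the five sets.

A seeded **synthetic pangenome generator** with known presence structure,
GC3 pressure, selection strengths and expression coupling provides ground
truth for every stage.

## Worked example

```r
library(pancub)
pg  <- generate_pangenome(synthetic_config(n_strains = 10,
                                           n_families = 300, seed = 1))
res <- run_pipeline(run_config(out_dir = "reports", seed = 1),
                    pangenome = pg)
res$neutrality[, c("set_label", "slope", "r", "n")]
```

```
          set_label    slope        r   n
1              core -0.00118 -0.00218 950
2     highly_shared  0.03510  0.13249 435
3      lowly_shared  0.10961  0.36769  64
4 moderately_shared  0.07017  0.31969 152
5   strain_specific  0.33102  0.68369  86
```

The neutrality slope falls from 0.33 in strain-specific genes to ~0 in core
genes: mutation pressure dominates the composition of strain-specific genes
while core-gene codon usage is decoupled from it. The ENC-plot agrees —
fractions of genes deviating more than 0.15 below the mutation-only curve:

```r
subset(res$enc$sweep, threshold == 0.15)
```

```
           set_label threshold fraction_deviated   n
3               core      0.15             0.998 950
9      highly_shared      0.15             0.880 435
15      lowly_shared      0.15             0.000  64
21 moderately_shared      0.15             0.237 152
27   strain_specific      0.15             0.000  86
```

and codon usage of core genes is the most aligned with the tRNA pool
(`res$similarity`: cosine 0.54 in strain-specific vs 0.93 in core genes).
Every table is also written to `out_dir` as TSV, with a JSON run manifest.

## Command line

```sh
Rscript inst/scripts/pancub simulate --n_strains 10 --n_families 300 \
    --seed 1 --out_dir sim
Rscript inst/scripts/pancub all --fasta_dir sim/fasta \
    --cluster_table sim/clusters.tsv --expression_table sim/expression.tsv \
    --trna_table sim/trna.tsv --out_dir reports
```

Exit codes: 0 success, 2 validation error, 3 I/O error.

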