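# georif

Regulatory Impact Factor (RIF) scoring for two-condition RNA-seq count
data, with four interchangeable co-expression measures and PCIT network
filtering.

## What it does, and for whom

Given a gene × sample count matrix with two conditions (e.g. tumor vs
normal), lists of candidate regulators (transcription factors, epigenetic
factors, lncRNAs), `georif`:

1. normalizes counts (TMM factors, log2-CPM);
2. calls differentially expressed (DE) genes with a simplified
   negative-binomial exact test (mean–variance law `v = μ + αμ²`,
   conditional-likelihood dispersion estimation, Benjamini–Hochberg FDR);
3. computes regulator × DE-gene association matrices per condition under
   **Pearson**, **Spearman**, the **Fisher information metric**
   (`d(p,q) = arccos Σᵢ√(pᵢqᵢ)` on simplex-embedded profiles) or a
   **Sobolev metric** (`d² = ‖w‖² + ‖Dw‖²`, `w = p − q`, `D` the circular
   finite difference);
4. scores each regulator `j` over DE genes `i` by

   - `PIF_i = (e1_i² − e2_i²)/2` (phenotype impact),
   - `DW_ij = r1_ij − r2_ij` (differential wiring),
   - `RIF1_j = meanᵢ(PIF_i · DW_ij²)`,
   - `RIF2_j = meanᵢ[(e1_i r1_ij)² − (e2_i r2_ij)²]`,

   z-standardizes within metric and selects the union of the top-k by
   |RIF1 z| and |RIF2 z|;
5. builds a significant-regulator network: pooled-sample Pearson
   correlations filtered by the PCIT (partial correlation and information
   theory) trio-tolerance rule plus a direct-correlation threshold
   (default 0.90);
6. summarizes regulator counts per metric/class and their overlaps.

It is aimed at systems-biology analyses that prioritize regulators from
expression contrasts; a synthetic NB data generator with planted DE genes
and planted differential wiring makes every stage testable without
external data.

## Worked example

Generate a wired synthetic dataset (one TF sharing a latent factor with 20
up-regulated targets in the tumor condition only) and run the full
pipeline:

```r
library(georif)
p     <- synth_params(n_genes = 300, n_per_condition = 20, dispersion = 0.1,
                      n_tf = 30, n_ef = 15, n_tf_ef_overlap = 5, n_lncrna = 5)
truth <- synthetic_truth(p, seed = 7, n_de = 60, n_targets = 20, rho = 0.9)
fx    <- generate_wired(p, truth)
write_counts(fx$matrix, "counts.tsv", "condition_map.tsv")
# ... write regulator lists from fx$catalog, then:
cfg <- run_config(counts = "counts.tsv", condition_map = "condition_map.tsv",
                  condition1 = "tumor", out_dir = "out",
                  tf_list = "tf.txt", ef_list = "ef.txt",
                  lncrna_list = "lncrna.txt", dispersion = "common")
res <- run_pipeline(cfg)
head(res$rif_tables$fisher[, c("regulator","classes","rif1_z","rif2_z",
                               "rank1","rank2","selected")], 5)
```

prints (the planted regulator is `gene_00001`):

```
   regulator classes rif1_z rif2_z rank1 rank2 selected
1 gene_00001      TF   4.07 1.7933     1     4     TRUE
2 gene_00004      TF  -1.93 0.0725     2    43     TRUE
3 gene_00016      TF   1.92 2.3008     3     1     TRUE
4 gene_00009      TF   1.66 2.0948     4     3     TRUE
5 gene_00024      TF   1.43 1.3360     5    11     TRUE
```

The planted regulator tops the Fisher RIF1 ranking (z = 4.07, rank 1) and
is selected into the network node set. The run log records every default
taken (`common dispersion alpha = 0.1314`, `FDR cutoff = 0.05`,
`DE genes: 62 of 300`, ...), and `out/` contains the DE table, one RIF
table and one network (edge + node TSVs) per metric, and the
overlap summary — e.g. here 32 unique significant regulators across the
four metrics, 3 of them found by all four.

A thin command-line wrapper is installed at `inst/cli/georif.R`:

```sh
Rscript inst/cli/georif.R synth --preset wired --seed 7 --out data/
Rscript inst/cli/georif.R run --counts data/counts.tsv \
    --condition-map data/condition_map.tsv --condition1 tumor \
    --tf-list data/tf_list.txt --out results/
```

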