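# histonet

Quantitative modeling of gene and exon expression from
histone-modification signal, for computational epigenomics work on the
coupling between chromatin state, transcription and splicing.

Histone marks on *transcribed regions* — not just promoters — track
expression, and because splicing happens co-transcriptionally, marks on
individual exons carry information about exon inclusion. `histonet`
implements the full analysis chain for interrogating that relationship:

1. **Quantification** — extend aligned reads to fragment length, count
   them over exon unions, single exons and promoter windows, and form
   log2 length-normalized densities
   `s = log2(n/L + c)` with pseudocount `c = 0.01`. Internal exons are
   classified constitutive/cassette from an alternative-event table, and
   the exon inclusion value is the log2 ratio of exon to gene density.
2. **Regression** — OLS of expression on the `N` mark signals,
   `e = b + Σ aᵢ hᵢ (+ Σ aᵢⱼ hᵢhⱼ)`, with per-coefficient t-tests,
   Benjamini–Hochberg correction, ten-fold cross-validation (mean
   Pearson r), a shuffled-input control (deranged feature columns at
   prediction time), exhaustive one/two-mark model enumeration, and the
   improvement ratio `(P_singleton − P_interaction)/P_singleton`
   comparing additive and interaction models.
3. **Network** — full-conditional partial correlations
   `P_AB·−AB = −Ω_AB/√(Ω_AA Ω_BB)` among marks, gene expression and
   exon expression; nested networks over pairs sorted by |pcor|, scored
   by Gaussian BIC (`m(ln(2π·RSS/m)+1) + d·ln m`, summed node-wise);
   threshold at the last pair whose BIC drop reaches 20% of the maximum
   drop; significance from a 100-fold no-fixed-point permutation null.
4. **Combinations & redundancy** — median H/L binning of mark pairs
   with rank-sum contrasts, singleton-vs-interaction comparisons over
   network neighborhoods, stepwise BIC along the partial-correlation
   order, and a clustered signal-matrix export.
5. **Cross-cell transfer** — per-variable affine normalization onto a
   reference cell type (regression line forced to `y = x`), model
   transfer, and fold-change-filtered evaluation (≥2/5/10-fold).
6. **Synthetic data** — Gaussian-graphical feature matrices with known
   precision structure, linear (± interaction) exon-expression
   responses with closed-form attainable accuracy, read-level toy
   genomes that invert the quantification stage, and affinely distorted
   second cell types — every stage is validated against exported ground
   truth.

## Worked example

Generate the default synthetic world (10 marks + gene expression from a
Gaussian graphical model; exon expression = gene expression + H3K36me3 +
H4K20me1 + noise, 2,000 exons), score the marks-only model, and infer
the interaction network:

```r
library(histonet)

scenario <- synth_preset("small", seed = 1)
marks <- setdiff(colnames(scenario$data), c("gene_expr", "exon_expr"))
X <- scenario$data[, marks]
y <- scenario$data[, "exon_expr"]

cross_validate(X, y, k = 10, seed = 1)
#> <CVResult 10-fold, mean Pearson r = 0.7926>
shuffle_control(X, y, k = 10, seed = 1)
#> <CVResult 10-fold, mean Pearson r = 0.4858>

pc <- pairwise_partial_correlations(scenario$data)
sel <- select_threshold(bic_trace(scenario$data, pc), fraction = 0.2)
perm <- permutation_null(scenario$data, n_perm = 100, seed = 1,
                         threshold = sel$threshold)
perm
#> <PermutationResult 100 perms, null mean -5.214e-05 sd 0.02223, max |pcor| 0.0809, z = 18.13>

net <- build_network(pc, sel$threshold, exon_col = "exon_expr")
net
#> <NetworkModel 12 nodes, 7 edges, threshold 0.4030>
network_neighbors(net, "exon_expr")
#> [1] "gene_expr" "H3K36me3"  "H4K20me1"
```

The marks predict exon expression well (r = 0.79; the all-variable
ceiling implied by the generator is 0.95), the shuffled-input control
degrades sharply, no permuted dataset produces a partial correlation
anywhere near the selected threshold (max null 0.081 vs threshold
0.403, z = 18.1), and the exon-expression node connects to exactly the
three variables wired into it by the generator — the transcription
effect and the two driver marks — while the other marks attach only to
each other.

## The analysis workflow

`analysis/` holds numbered drivers that run the whole study on
synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # scenarios, second cell type, toy genome
Rscript analysis/02_quantify.R    # read-level round trip
Rscript analysis/03_regress.R     # CV, shuffle control, improvement ratio
Rscript analysis/04_network.R     # pcors, BIC trace, threshold, permutation
Rscript analysis/05_combos.R      # bins, neighborhood interactions, stepwise BIC
Rscript analysis/06_crosscell.R   # affine transfer, fold filters
```

`run_pipeline(default_config(out_dir, seed))` performs the same chain in
one call and writes a `report.json`. Reruns with the same seed are
byte-identical.

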