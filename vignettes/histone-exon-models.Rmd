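---
title: "Methods: modeling exon expression from histone-modification signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling exon expression from histone-modification signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette describes the statistical procedures implemented in
`histonet`, the assumptions behind them, the constants and tunable
parameters, and the design decisions taken where more than one reading of
the procedure was defensible. The package implements a desk-scale,
fully testable version of a classic epigenomic analysis: relating
histone-modification (and RNAPII) ChIP-seq signal on gene bodies and
exons to gene and exon expression, and asking which marks associate with
exon inclusion *directly* once transcription is conditioned away.

## Signal quantification

Aligned reads arrive as BED6 intervals. Each read is extended to 100 bp
in the direction of its strand (`extend_reads()`), approximating the
sequenced fragment. The signal of a chromatin feature on a region is

$$ s = \log_2\!\left(\frac{n}{L} + c\right), $$

where $n$ is the number of extended reads overlapping the region union
by at least one base (each read counted at most once per region, even
when it spans several exons of the union), $L$ the union length in base
pairs, and $c = 0.01$ a pseudocount that keeps empty regions defined.
Gene expression uses RNA-seq reads over the gene's *exon union*; the
transcribed region is operationalized as that union, and multi-isoform
genes are merged into one union per gene id. Exon-level values use the
single exon interval. The exon inclusion value is the difference of the
two log2 densities (a log2 fold change); cassette exons with negative
inclusion are flagged as alternatively spliced. The first and last exon
of every gene are excluded from all analysis sets because initiation and
termination dominate their signal.

Promoter signal counts extended reads in the 4,001-bp window centered on
the strand-aware TSS and logs the raw sum. Because the window width is
identical for all genes, no length normalization is applied; we do add
the same 0.01 pseudocount before the logarithm so genes with empty
windows remain finite — a deliberate, documented extension of the
original promoter recipe, which logs the raw sum without stating how
zero counts were handled.

Two choices here were genuinely open. Whether a read spanning an exon
boundary should count fractionally is not specified anywhere we could
find; we count a read once per region it overlaps, which conserves
counts across disjoint regions and avoids double counting within a
union. And coordinates are held internally in Bioconductor `GRanges`
(1-based, closed), with BED's 0-based half-open convention converted at
parse time; all width and overlap arithmetic goes through `IRanges`, so
the representation cannot introduce off-by-one errors.

## Regression and cross-validation

Expression is regressed on the $N$ feature signals by ordinary least
squares (`fit_linear()`), optionally augmented with all
$\binom{N}{2}$ pairwise products (the interaction model; with $N = 39$
that is 741 product terms). Coefficients carry two-sided t-tests;
multiplicity across the coefficient family is handled by
Benjamini–Hochberg step-up FDR (the "Benjamini method" is read as BH),
and "significant" defaults to adjusted $p < 0.001$. Features are not
standardized before fitting, so coefficients stay on the log2-signal
scale.

Predictive accuracy is the mean, over ten seeded random folds, of the
Pearson correlation between measured and predicted response
(`cross_validate()`); remainder rows are spread one per fold. The
shuffled-input control (`shuffle_control()`) trains with every feature
in its right place and predicts held-out rows after reassigning the
feature columns by a seeded derangement (no column keeps its position).
The literal alternative — deranging the columns *before* refitting — is
a no-op, since OLS is invariant to relabeling its regressors; only
shuffling at prediction time tests whether the model has learned
feature-specific weights. With two features the only derangement is the
swap.

The improvement ratio
$(P_{\text{singleton}} - P_{\text{interaction}})/P_{\text{singleton}}$
compares the cross-validated accuracies of the main-effects and
interaction models; negative values favor the interaction model.
`enumerate_combination_models()` scores every one- and two-feature model
the same way, and `transfer_predict()` applies a trained model to a new
stratum or cell type, reporting the Pearson correlation with its t-test.

## The partial-correlation network

For variables $A$ and $B$ among the marks, gene expression and exon
expression, the full-conditional partial correlation
$P_{AB\cdot -AB}$ is computed from the inverse of the correlation
matrix, $-\Omega_{AB}/\sqrt{\Omega_{AA}\Omega_{BB}}$
(`pairwise_partial_correlations()`). The definition — correlate the
residuals of $A$ and $B$ each regressed on the conditioning set — is
implemented independently as `pcor_residual()` and kept as a
cross-check; the two routes agree to numerical precision, and for three
variables both reduce to the familiar closed form
$(P_{AB} - P_{AC}P_{BC})/\sqrt{(1-P_{AC}^2)(1-P_{BC}^2)}$. A
correlation matrix whose condition number exceeds $10^{10}$ is refused
with the near-collinear columns named.

Edges are selected by a BIC trace. All $V(V-1)/2$ pairs are sorted by
descending $|P_{AB\cdot -AB}|$ (ties broken by pair name for
determinism) and added one at a time to a growing undirected graph. Each
graph is scored as the sum over nodes of the Gaussian OLS BIC of that
node regressed on its current neighbors, intercept-only when isolated,
with

$$ \mathrm{BIC} = m\left(\ln\frac{2\pi\,\mathrm{RSS}}{m} + 1\right) + d\ln m, $$

$d$ counting regressors including the intercept. The trace starts at
the empty graph, so every added pair has a difference
$\mathrm{BIC}_{i-1} - \mathrm{BIC}_i$. How a *network* should map onto
"the linear regression model" scored by BIC is not fully specified by
the procedure we implement; the node-wise sum was chosen because it
degenerates to the ordinary per-model BIC when only one response is
involved and it reprices every edge addition locally. Alternatives (a
single exon-expression regression, or a joint Gaussian likelihood) would
be drop-in replacements for `network_bic()`.

The threshold is the $|$pcor$|$ of the last pair whose BIC difference
still reaches 20% of the maximum difference; all pairs through it become
edges, and earlier small dips do not truncate the scan. Significance is
assessed by a permutation null: each column is independently permuted
with a no-fixed-point permutation (so no value stays with its own exon;
two rows degenerate to a swap), the full pcor matrix is recomputed, all
pair values are pooled over 100 permutations, and the threshold is
located in that pooled null by its z-score. Edge weights (and the
exon-expression association of each node) are reported both raw and
normalized by the absolute value of the largest edge coefficient, so the
strongest edge has weight 1.

## Combinations, redundancy, cross-cell transfer

For a pair of marks, exons are binned LL/HL/LH/HH by strict comparison
with each mark's median (ties at the median count as Low — the original
recipe does not say, and the choice only moves boundary points).
Per-bin response distributions are summarized and contrasted with
two-sided Wilcoxon rank-sum tests; the figures the procedure mirrors
show distributions without naming a test, and the rank-sum test is the
standard nonparametric choice for such contrasts.
`network_combination_tests()` refits every network node with at least
two neighbors on those neighbors, with and without pairwise products,
and reports improvement ratios. `stepwise_bic_by_pcor()` adds marks to
the response regression in descending order of $|$pcor with the
response$|$ and records the BIC path; collinear additions are dropped
with a warning. `cluster_matrix_export()` orders features by
average-linkage hierarchical clustering on $1 - r$ distance (again a
conventional default where the original names neither linkage nor
metric) and sorts rows by ascending response.

For cross-cell-type transfer, each shared variable of the training cell
is mapped onto the reference cell's scale by the OLS line of reference
on source (`fit_affine_normalizer()`), which turns the regression line
into $y = x$; the direction (normalize the training cell toward the
prediction-target cell) follows the original procedure and is
switchable. The model is fit in the normalized training cell and
evaluated on the reference cell — over all matched exons and over the
subsets whose expression differs by at least $\log_2 k$ for
$k \in \{2, 5, 10\}$ (boundary inclusive, symmetric in the two cells).
Whether normalization should use all exons or expressed exons only is
unstated in the original; we fit on all matched exons.

## The synthetic-data generator

Every stage is validated against generated data with exported ground
truth, and the generators are pure functions of their spec and seed.

* `make_ggm_scenario()` draws i.i.d. rows from a multivariate normal
  whose precision matrix has unit diagonal and $-\rho$ at declared
  edges, so declared pairs have full-conditional partial correlation
  exactly $\rho$ and undeclared pairs exactly 0. Non-positive-definite
  requests are refused with the minimal eigenvalue. The default 10-node
  pattern has eight edges with true $|\rho|$ between 0.25 and 0.40 —
  strong enough to separate from a null of scale $1/\sqrt{m}$ at
  $m = 2000$, with the weakest/strongest ratio chosen so the 20% BIC
  rule has a margin on both sides.
* `make_feature_scenario()` adds a `gene_expr` column to the GGM block
  and generates `exon_expr` as intercept + gene expression + two driver
  marks + Gaussian noise, optionally plus one driver-product term. The
  defaults (10 marks, $m = 2000$, coefficients 1.0/0.6/0.5, noise sd
  0.6) give a population $R^2$ whose square root — the attainable CV
  correlation — is exported in closed form, together with the joint
  precision of all columns (the linear response moralizes its parents,
  which the truth matrix makes explicit). A `paper-shape` preset with 39
  marks and 17,713 rows reproduces the real study's dimensions for
  scale tests.
* `make_read_level()` inverts quantification: one three-exon toy gene
  per row, middle exon carrying the row's signals, counts drawn
  Poisson with rate $L \cdot (2^s - c)$, 25-bp reads placed uniformly
  inside exons on random strands. Introns (300 bp) exceed the 100-bp
  extension so no read leaks into a neighboring exon, and flank-exon
  RNA densities are chosen so the exon-union density realizes the
  generating gene expression. Signals are offset by +2 before read
  generation so every region expects well over 50 reads, the regime in
  which the log-density round trip is essentially exact.
* `make_second_cell()` re-expresses every variable through its own
  affine map (seeded slopes 0.7–1.3, intercepts ±0.5) with fresh
  measurement noise (sd 0.1), and shifts a designated fraction of exon
  expressions by at least $\log_2 k$ — magnitudes 1.3–2.2 times the
  cutoff, applied inside the affine map so they survive
  re-normalization and clear the fold filter despite noise.

What the generator does *not* emulate: nucleosome positioning and peak
shape, mappability and GC bias, input-control structure, duplicate
reads, overdispersed counts, and any non-Gaussian tail behaviour of real
log densities. Passing tests therefore demonstrate correctness of the
procedures under the model's own assumptions, not performance on real
ChIP-seq; the headline correlations of the original genome-scale study
(e.g. $r = 0.92$ for the gene-body model) are context, not targets, at
desk scale.

## Numerical choices and problem sizes

Rank-deficient designs are refused with the collinear columns named
rather than silently pivoted (except inside cross-validation folds,
where dropped columns predict as zero). BIC is undefined at RSS = 0 and
errors. Derangements are sampled by seeded rejection from uniform
permutations (expected under three tries). All randomness flows through
explicit integer seeds, and reruns of the pipeline with the same
configuration are byte-identical.

The shipped analyses use desk-scale sizes chosen to make every check
sharp but quick: 2,000 exons for scenario work, 5,000 for coefficient
recovery and additivity checks, 20,000 where an estimate must converge
tightly, 120 toy genes for the read-level round trip, 100 permutations
and 10 CV folds throughout. The `paper-shape` preset is available when
the full 39-mark, 17,713-exon geometry is wanted.

## Known limitations

The network is undirected; nothing here orients edges or claims
causality. The node-wise network BIC is one defensible reading among
several (see above). The permutation z-score summarizes a pooled null
that is approximately but not exactly Gaussian in its extreme tail. The
affine cross-cell map is a single global line per variable and will not
absorb nonlinear batch effects. And the exon classifier trusts the
alternative-event table: an exon involved in any non-cassette event is
excluded rather than modeled.
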