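# teGRN

Transfer-entropy gene regulatory network inference from pseudotime-ordered
single-cell RNA-seq data.

## The problem

Single-cell RNA-seq snapshots ordered along a pseudotime trajectory form,
for every gene, a time series of expression values. Directed regulatory
relationships between genes can then be scored with **transfer entropy
(TE)**: the TE from a putative regulator *Y* to a target *X* is

```
TE(Y -> X) = H(X_{t+1} | X_t) - H(X_{t+1} | X_t, Y_t)
           = sum p(x_{t+1}, x_t, y_t) log2 [ p(x_{t+1}, x_t, y_t) p(x_t)
                                             / ( p(x_{t+1}, x_t) p(x_t, y_t) ) ]
```

i.e. the reduction in uncertainty about the target's next state provided by
the regulator's current state beyond what the target's own state already
provides. It is non-negative and zero under conditional independence.

TE is estimated with a plug-in estimator over discretized expression
series, which requires counting four lag-1 joint events per ordered gene
pair: `(X_{t+1}, X_t, Y_t)`, `(X_{t+1}, X_t)`, `(X_t, Y_t)` and `(X_t)`.
The naive dense count array over all `b^3` bin triples is almost entirely
zeros (on a 14-step toy pair over 5 bins, 112 of 125 cells — 89.6 % — are
empty), which wastes memory and bounds the batch sizes usable for parallel
execution. `teGRN` instead stores **only the unique joint-event patterns
actually observed**, lexicographically sorted, with the four count vectors
position-aligned per pattern, so the TE sum is a single elementwise pass
whose memory is proportional to the number of observed patterns (at most
`l_t - 1` for `l_t` cells). All `n(n-1)` ordered pairs are partitioned into
contiguous batches, executed through a pluggable array-computing backend
(reference CPU backend included) optionally across worker processes, and
assembled into the TE matrix keyed by pair index — so the result is
bit-identical for any worker count or batch size.

Downstream, off-diagonal TE values are z-scored against the global TE
background, converted to one-tailed p-values, Benjamini–Hochberg adjusted,
and thresholded into a directed edge list; candidate hub regulators are
ranked by outdegree.

For whom: anyone with a genes × cells expression matrix plus a pseudotime
ordering (from any trajectory method) who wants a directed GRN and hub
candidates, at the R console or from the shell.

## Worked example

A synthetic 10-gene × 300-cell dataset with one planted regulator (`R01`)
driving four targets (`T01`–`T04`) at coupling 0.8, five unregulated genes
as background:

```r
library(teGRN)

ds   <- generateDataset(seed = 7)       # ExpressionDataset with pseudotime
dset <- preprocessDataset(ds)           # order, discretize (5 bins here)
te   <- computeTEMatrix(dset)           # 90 ordered pairs
te
#> TEMatrix: 10 genes, log base 2
#>   off-diagonal TE: min 0.09263, median 0.1655, max 1.139

el <- edgesFromTE(te, fdrLevel = 0.01)
el
#> EdgeList: 4 edge(s) at BH level 0.01
#>   source target       te        z         padj
#> 1    R01    T03 1.138571 4.580322 9.779596e-05
#> 2    R01    T01 1.135856 4.566889 9.779596e-05
#> 3    R01    T02 1.124112 4.508794 9.779596e-05
#> 4    R01    T04 1.103129 4.404999 1.190075e-04

hubRanking(el)
#>   gene outdegree
#> 1  R01         4
```

The four retained edges are exactly the four planted couplings (TE ≈ 1.1
bits against a background of ≈ 0.17 bits), and the planted regulator is
the sole hub. `writeTEMatrix()`, `writeEdgeList()` (TSV and SIF) and
`writeExpression()` persist all artifacts as delimited text.

The same pipeline runs from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "tegrn.R", package = "teGRN"))') \
    run --expr expr.tsv --pseudotime pt.txt --out-prefix out
```

with subcommands `run`, `preprocess`, `te`, `grn` and `synth`.

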