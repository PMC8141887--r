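# mdanet

Candidate prioritization for miRNA–disease associations by **attributed
network embedding**. Known associations form a bipartite graph; miRNA
sequence similarity (k-mer cosine) and disease semantic similarity (decaying
ancestor overlap on a MeSH-style hierarchy) attach attributes to the nodes.
`mdanet` fuses the two channels into one random walk, accumulates several
walk orders into a proximity matrix, compresses each node's profile with a
stacked auto-encoder, and scores node pairs with a random forest.

For a researcher with a table of verified associations, a FASTA of miRNA
sequences and a disease hierarchy, the package answers: *which unobserved
miRNA–disease pairs should be validated next?*

## The model in brief

With `S` and `Z` the row-normalized structure (adjacency) and attribute
(similarity) matrices, the fused transition matrix and the multi-order
enhanced matrix are

    P = α·S + (1 − α)·Z              (α = 0.85: 85% structure, 15% attributes)
    M = Σ_{l=1..t} β^(l−1) · P^l     (β = 0.94, t = 5)

Rows of `M` are per-node proximity profiles; a stacked auto-encoder
(input → 256 → 64 by default) compresses them to codes, a pair's feature
vector is the concatenation of its two codes, and a random forest (against
balanced, uniformly sampled negatives) produces association scores.
Evaluation is masked k-fold cross-validation: test-fold edges are removed
from the graph before feature construction, so reported metrics contain no
label leakage.

Everything is runnable end-to-end on synthetic data: a planted-partition
generator emulates all three inputs with correlated structure and attribute
signal, so nothing external is needed to build, test, or benchmark.

## Worked example

```r
library(mdanet)

data <- simulate_mda_data(synth_config(n_mirnas = 60, n_diseases = 30,
                                       n_groups = 3, p_in = 0.4,
                                       p_out = 0.02, seed = 11))
fit <- mdanet(data$associations, data$sequences, data$dag, seed = 1)
print(fit)
#> miRNA-disease association model (attributed network embedding)
#>   nodes: 60 miRNAs + 30 diseases; 260 known associations
#>   walk: alpha = 0.85, beta = 0.94, t = 5; code dim 15
#>   classifier: random_forest on 520 balanced pairs

candidate_ranking(fit, "disease-01", top_n = 5)
#> Top 5 candidate miRNA(s) for 'disease-01' (13 known pair(s) excluded)
#>    mirna score
#> 1 mir-37 0.956
#> 2 mir-19 0.922
#> 3 mir-01 0.916
#> 4 mir-55 0.784
#> 5 mir-31 0.748

report <- mdanet_cv(data$associations, data$sequences, data$dag,
                    k = 5, seed = 1)
print(report)
#> 5-fold cross-validation (masked mode)
#>           acc    sen   spec   prec    mcc    auc   aupr
#> fold 1 0.7788 0.7308 0.8269 0.8085 0.5603 0.8656 0.8404
#> fold 2 0.7115 0.6731 0.7500 0.7292 0.4243 0.7367 0.7363
#> fold 3 0.7788 0.7308 0.8269 0.8085 0.5603 0.8216 0.7584
#> fold 4 0.7885 0.8462 0.7308 0.7586 0.5808 0.8454 0.8061
#> fold 5 0.7692 0.6731 0.8654 0.8333 0.5487 0.8667 0.8434
#> mean   0.7654 0.7308 0.8000 0.7876 0.5349 0.8272 0.7969
#> sd     0.0309 0.0707 0.0570 0.0425 0.0629 0.0538 0.0482
```

The top-ranked candidates are the held-back same-group miRNAs the planted
structure implies; the mean AUC of 0.83 sits close to the information
ceiling these synthetic conditions admit (see the methods vignette). All
numbers are deterministic given the seeds.

The fitted object supports `print`, `summary`, `coef`, `predict` (score
arbitrary pairs), `residuals`, and `plot` (auto-encoder loss trace);
`plot(report, which = "roc")` / `"pr"` draws the per-fold curves.

A thin command-line wrapper over the same functions ships in
`inst/cli/mdanet.R` with `simulate`, `similarity`, `cv` and `case-study`
subcommands driven by a YAML config (see `?mdanet_config`).

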