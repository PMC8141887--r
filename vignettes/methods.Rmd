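---
title: "Predicting miRNA-disease associations from an attributed bipartite network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations from an attributed bipartite network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdanet)
```

## The problem

Experimentally verified miRNA-disease associations are sparse and expensive
to obtain, while the space of plausible pairs is enormous. Treating the known
associations as edges of a bipartite graph turns candidate prioritization
into link prediction: score every unobserved (miRNA, disease) pair by how
likely it is to be a true association, so that bench validation can focus on
the top of the list.

Two complementary information sources are available. The *structure* channel
is the association graph itself: miRNAs sharing many disease partners (and
vice versa) tend to be functionally related. The *attribute* channel is
per-node side information: miRNA sequences, and the position of each disease
in a MeSH-style hierarchy. `mdanet` fuses both channels into one random-walk
proximity matrix, compresses it into per-node codes with a stacked
auto-encoder, and classifies node-pair code vectors with a random forest.

## The model

### Attributed network

Nodes are the $m$ miRNAs followed by the $d$ diseases, each side sorted
lexicographically so runs never depend on input order. The structure matrix
$A$ is the $(m+d)\times(m+d)$ symmetric 0/1 adjacency of known associations;
being bipartite, its diagonal blocks are zero. The attribute matrix $Z_0$ is
block diagonal: the miRNA block holds sequence similarity, the disease block
semantic similarity, and there is no direct attribute coupling across node
types.

**Sequence similarity** is the cosine between $k$-mer count vectors
($k = 3$ by default, giving $4^3 = 64$ possible words). It is
alignment-free, deterministic, $O(\text{length})$ per sequence, and bounded
in $[0,1]$ because counts are non-negative. For ~22-nt miRNAs, 3-mers are a
reasonable compromise: $k = 2$ is nearly saturated (every dinucleotide
appears), while $k \ge 5$ makes the 18-20 observed words so sparse that most
pairs share none.

**Disease semantic similarity** follows the decaying-ancestor-contribution
construction standard for DAG-based measures. A disease contributes 1 to
itself; an ancestor $t$ contributes $\Delta^{s}$ where $s$ is the shortest
upward distance and $\Delta \in (0,1)$ is the decay (default 0.5, the
conventional value in this literature). With multiple parents the maximum
over paths is taken, keeping contributions bounded; because $\Delta < 1$,
the maximum over paths is attained on a shortest path, which is how the
implementation computes it (breadth-first search up the parent relation).
Writing $DV(x) = \sum_t D_x(t)$ for the semantic value, similarity is

$$\mathrm{DSS}(x, y) = \frac{\sum_{t \in T_x \cap T_y} \big(D_x(t) + D_y(t)\big)}{DV(x) + DV(y)},$$

symmetric, in $[0,1]$, and equal to 1 exactly when the two ancestor profiles
coincide.

### Fused multi-order proximity

Both channels are row-normalized into transition matrices — $S$ from $A$,
$Z$ from $Z_0$ — and fused as a convex combination

$$P = \alpha S + (1 - \alpha) Z,$$

where $\alpha$ is the structure preference ($\alpha = 1$: walk only on
edges; $\alpha = 0$: walk only on attribute similarity). Rows of $A$ with no
edges are left all-zero rather than being given fabricated uniform
transitions; such a row of $P$ then sums to $1-\alpha$, and the node still
carries signal through the attribute channel (unit diagonal of $Z_0$).

Walk orders $1 \dots t$ are accumulated with geometric damping:

$$M = \sum_{l=1}^{t} \beta^{l-1} P^{l}, \qquad \beta \in (0, 1],$$

computed by updating a running power with one matrix multiplication per
order. The first-order term carries full weight, matching the intuition that
low-order (local) structure is the most informative; $\beta = 1$ degenerates
to an unweighted sum. For a fully stochastic $P$ every row of $M$ sums to
$(1-\beta^t)/(1-\beta)$, a conserved quantity the tests verify to $10^{-9}$.
Because fusion happens *before* powering, orders $\ge 2$ contain
cross-channel terms (structure steps composed with attribute steps), which
is the point of building an attributed walk rather than two separate ones.

Defaults are $\alpha = 0.85$, $\beta = 0.94$, $t = 5$ — the tuned optima
reported for this family of methods; all three are exposed and the package's
ablation interface (`alpha = 1` / `alpha = 0`) reproduces the
structure-only / attribute-only comparisons.

The networks this package targets stay below a few thousand nodes, so $M$ is
kept dense; exactness and simplicity beat sparse machinery at this scale. An
optional `renormalize_m` switch row-normalizes $M$ before encoding; for
stochastic $P$ the row sums are constant, so this is immaterial in the
default configuration and is off by default.

### Stacked auto-encoder

Each node's row of $M$ is a $(m+d)$-dimensional proximity profile; the
auto-encoder compresses it to a low-dimensional code (default architecture
input → 256 → 64, scaled down automatically for small inputs). Training is
the classic greedy recipe: each layer is pretrained to reconstruct the
previous layer's output, then the full encoder-decoder is fine-tuned
end-to-end on mean-squared reconstruction error. Hidden units are logistic
sigmoids; the final reconstruction layer is linear. Per-layer pretraining
uses a sigmoid output when its target is itself a hidden (sigmoid)
representation, so pretrained weights drop into the stacked decoder without
an activation mismatch.

Numerical choices that matter:

* **Input standardization.** Rows of $M$ sum to the geometric series, so
  individual entries are tiny (order $1/(m+d)$). Fed raw, they park every
  sigmoid at its linear midpoint and the trained codes collapse toward a
  constant. The fitting functions therefore standardize the columns of $M$
  (zero-variance columns are set to 0) before encoding. This is an
  embedding-stage preprocessing choice, not part of the proximity
  definition; `enhanced_matrix()` itself is exact.
* **Optimizer.** Deterministic mini-batch gradient descent. The loss is
  normalized per sample (summed over features), the usual auto-encoder
  convention; with per-entry normalization the gradient shrinks with the
  input width and training stalls. Learning rate defaults to $10^{-3}$,
  batch size 32, 50 pretraining epochs per layer and 100 fine-tuning
  epochs. Classical momentum is available (`momentum`, default 0): it
  speeds up deep compression of clean low-rank inputs considerably, but on
  proximity profiles the extra convergence mainly reconstructs
  attribute-channel noise and measurably blurs the group structure of the
  codes, so the default stays plain.
* **Determinism.** Glorot-uniform initialization and every batch order are
  drawn from a single stream seeded by `encoder_spec(seed=)`; identical seed
  and input reproduce the weights bitwise. Training restores the caller's
  random-number state on exit.

No denoising or sparsity penalties are used: the model is a plain stacked
auto-encoder. The architecture is configuration, not substance — none of the
package's checks depend on a particular layer layout.

### Pair classification

The feature vector of a pair is the miRNA code concatenated with the disease
code ($2\times$ code dimension). Negatives are drawn uniformly without
replacement from the non-positive cells of the miRNA × disease grid, as many
as there are positives — the standard balanced protocol when verified
non-associations do not exist. Four classifiers are available with their
library-default settings: random forest (500 trees; the default and the
recommended choice), Gaussian naive Bayes, AdaBoost.M1 over depth-1 decision
stumps (50 rounds), and k-nearest neighbours ($k = 5$ vote fraction). All
expose a score in $[0,1]$.

### Evaluation protocol

`mdanet_cv()` splits positives and negatives independently into $k$
seed-deterministic folds (default 5). Negatives are sampled once per
experiment, before folding. Two leakage regimes are provided:

* **masked** (default): for each fold the adjacency is rebuilt from training
  positives only before the walk and embedding, so no held-out edge can leak
  into feature construction. This is the honest protocol and the one used by
  the package's own checks.
* **paper**: the full adjacency is embedded once and only the classifier is
  fold-aware. Published benchmarks in this area frequently evaluate this
  way (often without saying so); the switch exists so such numbers can be
  reproduced, with the caveat that it scores optimistically.

Metrics per fold: accuracy, sensitivity, specificity, precision and MCC at
threshold 0.5 (classes are balanced by construction, and no alternative
operating point is prescribed); AUC as the midrank statistic (ties credited
0.5), which equals the trapezoidal area under the tie-grouped ROC curve to
machine precision; AUPR as step-wise, non-interpolated precision. The report
stores per-fold values, mean ± sd, the full curve points, and the hash of
the configuration that produced it.

`candidate_ranking()` scores every miRNA not already known for a disease and
returns the top candidates, ties broken lexicographically so top-$n$ lists
are reproducible.

## The synthetic data generator

`simulate_mda_data()` produces the three inputs from a planted-partition
model so the whole pipeline is testable without downloads. miRNAs and
diseases are assigned to `n_groups` groups round-robin; a pair is associated
with probability `p_in` within a group and `p_out` across. Each group has a
random `motif_len`-mer implanted (with per-base mutation) into otherwise
random `seq_len`-nt sequences; the hierarchy is a rooted `dag_branching`-ary
tree in which each group's diseases occupy a private subtree, so same-group
diseases share a deeper ancestor. One master seed is split into
per-component sub-streams (sequences / hierarchy / edges), so changing one
configuration field perturbs only its component.

Defaults — 200 miRNAs, 100 diseases, 5 groups, `p_in` 0.3, `p_out` 0.01,
22-nt sequences with 8-nt motifs at 10% mutation, branching 3, seed 7 —
mimic miRNA length and the sparse association density of curated databases
at desk scale. They are study conditions, chosen once.

What the generator does *not* emulate: the heavy-tailed degree distribution
of real association databases (every planted node has the same expected
degree), literature biases (well-studied diseases accumulate associations),
shared miRNA family/cluster structure beyond one motif per group, and
polyhierarchy (the generated DAG is a tree; the similarity code handles
multiple parents, the generator does not produce them). Passing the
package's checks therefore demonstrates correct mechanics and recoverable
planted signal, not performance on real HMDD-scale data.

### A ceiling worth knowing about

Because generated associations are independent Bernoulli draws given the
group labels, and expected degrees are constant, *no* predictor can beat one
that knows the true groups: for a held-out pair, every same-group pair is
exchangeable. With the default rates, roughly 14-15% of sampled negatives
are same-group while ~86-88% of positives are, which caps the achievable
masked-CV AUC at about

$$\mathrm{AUC}_{\max} = \tfrac12 + \tfrac{w_p - w_n}{2} \approx 0.85{-}0.87,$$

where $w_p$, $w_n$ are the same-group fractions of positives and negatives
in the realized draw. On the default seed the realized within-group rate
falls a little under three binomial standard errors below 0.3 (the
generator's own consistency test computes this margin), which puts the
oracle ceiling near the bottom of that range; masked-CV AUC lands within
about 0.01 of the ceiling. Numbers in this range
should be read as near-optimal for these conditions, not as a shortfall of
the method. The permuted-label control sits at 0.5 as it must, and the
channel ablations preserve the expected ordering (fusion ≥ structure-only ≥
attribute-only).

## Worked example

```{r example, eval = FALSE}
data <- simulate_mda_data(synth_config(n_mirnas = 60, n_diseases = 30,
                                       n_groups = 3, p_in = 0.4,
                                       p_out = 0.02, seed = 11))
fit <- mdanet(data$associations, data$sequences, data$dag, seed = 1)
print(fit)
summary(fit)
candidate_ranking(fit, "disease-01", top_n = 10)

report <- mdanet_cv(data$associations, data$sequences, data$dag,
                    k = 5, seed = 1)
print(report)
plot(report, which = "roc")
```

## Known limitations

* Only sequence and hierarchy attributes are implemented; functional
  similarity and interaction-profile kernels are out of scope.
* The auto-encoder is a plain fully connected stack; graph-convolutional or
  denoising variants are not provided.
* Dense matrices bound practical problem size to a few thousand nodes.
* The walk has no restart component; PageRank-style variants are
  deliberately excluded.
* The package's own evaluations run at desk scale (300-node default
  network); they validate mechanics and relative orderings, not absolute
  performance on full curated databases.
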