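# Attributed network assembly and the fused multi-order proximity ("enhanced")
# matrix. Nodes are indexed miRNAs-first (sorted), then diseases (sorted).
# Structure = bipartite 0/1 adjacency of known associations; attributes =
# block-diagonal similarity matrix (sequence block, semantic block). Both are
# row-normalized into transition matrices, fused as a convex combination
# P = alpha * S + (1 - alpha) * Z, and accumulated over walk orders as
# M = sum_{l = 1..t} beta^(l-1) P^l.

#' Build the bipartite adjacency matrix of known associations
#'
#' @param assoc an `mda_associations` table.
#' @param mirna_ids,disease_ids id universes; every pair in `assoc` must use
#'   ids present here.
#' @return list of class `attributed_network` part: `(m+d) x (m+d)` symmetric
#'   0/1 matrix `A` with nonzero entries only in the miRNA-disease off-diagonal
#'   blocks, plus the `node_index` used. Isolated nodes are listed in
#'   `isolated`.
#' @export
build_adjacency <- function(assoc, mirna_ids, disease_ids) {
  idx <- node_index(mirna_ids, disease_ids)
  i <- match(assoc$mirna, idx$mirnas)
  j <- match(assoc$disease, idx$diseases)
  if (anyNA(i)) stop("unknown miRNA id: ", assoc$mirna[is.na(i)][1L])
  if (anyNA(j)) stop("unknown disease id: ", assoc$disease[is.na(j)][1L])
  n <- idx$m + idx$d
  A <- matrix(0, n, n, dimnames = list(idx$nodes, idx$nodes))
  A[cbind(i, idx$m + j)] <- 1
  A[cbind(idx$m + j, i)] <- 1
  isolated <- idx$nodes[rowSums(A) == 0]
  list(A = A, index = idx, isolated = isolated)
}

#' Assemble an attributed network
#'
#' Combines the association adjacency with the block-diagonal attribute
#' matrix: the miRNA block is the sequence similarity matrix, the disease
#' block the semantic similarity matrix, and the two off-diagonal blocks are
#' zero (attributes do not connect across node types directly).
#'
#' @param assoc an `mda_associations` table.
#' @param mirna_sim,disease_sim similarity matrices with id dimnames covering
#'   all ids used; rows/columns are re-ordered to the canonical node index.
#' @param allow_missing drop associations whose ids carry no attributes
#'   instead of erroring.
#' @return object of class `attributed_network`: list with `A`, `Z0`, `index`,
#'   `isolated`.
#' @export
attributed_network <- function(assoc, mirna_sim, disease_sim,
                               allow_missing = FALSE) {
  mirna_ids <- rownames(mirna_sim)
  disease_ids <- rownames(disease_sim)
  assoc <- check_association_ids(assoc, mirna_ids, disease_ids,
                                 allow_missing = allow_missing)
  adj <- build_adjacency(assoc, mirna_ids, disease_ids)
  idx <- adj$index
  n <- idx$m + idx$d
  Z0 <- matrix(0, n, n, dimnames = list(idx$nodes, idx$nodes))
  Z0[seq_len(idx$m), seq_len(idx$m)] <-
    mirna_sim[idx$mirnas, idx$mirnas]
  Z0[idx$m + seq_len(idx$d), idx$m + seq_len(idx$d)] <-
    disease_sim[idx$diseases, idx$diseases]
  structure(list(A = adj$A, Z0 = Z0, index = idx, isolated = adj$isolated),
            class = "attributed_network")
}

#' @export
print.attributed_network <- function(x, ...) {
  cat("Attributed network:", x$index$m, "miRNAs +", x$index$d, "diseases,",
      sum(x$A) / 2, "associations,", length(x$isolated), "isolated node(s)\n")
  invisible(x)
}

#' Row-normalize a non-negative matrix into a transition matrix
#'
#' Each nonzero row is divided by its sum; all-zero rows are left zero and
#' their indices recorded, so no transitions are fabricated for isolated
#' nodes.
#'
#' @param mat non-negative matrix.
#' @return list of class `transition_matrix` with `values` and `zero_rows`.
#' @export
row_normalize <- function(mat) {
  if (any(mat < 0)) stop("matrix has negative entries")
  rs <- rowSums(mat)
  zero_rows <- which(rs == 0)
  scale <- ifelse(rs == 0, 1, rs)
  structure(list(values = mat / scale, zero_rows = unname(zero_rows)),
            class = "transition_matrix")
}

#' Fuse structure and attribute transition matrices
#'
#' `P = alpha * S + (1 - alpha) * Z`. With `alpha = 1` the walk depends only
#' on the network structure; with `alpha = 0` only on the attributes.
#'
#' @param S,Z `transition_matrix` objects (or plain matrices) of equal shape.
#' @param alpha structure preference weight in [0, 1].
#' @return `transition_matrix` for the fused walk; `zero_rows` lists rows with
#'   no mass in either input.
#' @export
fuse_transition <- function(S, Z, alpha = 0.85) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  Sv <- transition_values(S)
  Zv <- transition_values(Z)
  if (!all(dim(Sv) == dim(Zv))) stop("shape mismatch between S and Z")
  P <- alpha * Sv + (1 - alpha) * Zv
  rs <- rowSums(P)
  structure(list(values = P, zero_rows = unname(which(rs == 0))),
            class = "transition_matrix")
}

transition_values <- function(x) {
  if (inherits(x, "transition_matrix")) x$values else as.matrix(x)
}

#' Multi-order enhanced proximity matrix
#'
#' Accumulates walk orders 1..t of the fused transition matrix with a
#' geometric down-weighting of higher orders:
#' `M = sum_{l = 1..t} beta^(l-1) P^l`, computed by updating a running power
#' with one matrix multiplication per order. The first-order term carries full
#' weight; `beta = 1` reduces to an unweighted sum. For a fully row-stochastic
#' `P`, every row of `M` sums to `(1 - beta^t) / (1 - beta)` (or `t` when
#' `beta = 1`).
#'
#' @param P `transition_matrix` (or plain square matrix).
#' @param beta high-order damping factor in (0, 1].
#' @param t number of walk orders, a positive integer.
#' @param renormalize if `TRUE`, row-normalize M before returning (immaterial
#'   for fully stochastic `P`, where row sums are constant).
#' @return matrix `M` with attributes `beta` and `t` (class `enhanced_matrix`).
#' @export
enhanced_matrix <- function(P, beta = 0.94, t = 5L, renormalize = FALSE) {
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be a positive integer")
  Pv <- transition_values(P)
  power <- Pv
  M <- Pv
  if (t > 1L) {
    for (l in seq(2L, t)) {
      power <- power %*% Pv
      M <- M + beta^(l - 1L) * power
    }
  }
  if (renormalize) M <- row_normalize(M)$values
  structure(M, beta = beta, t = t, class = c("enhanced_matrix", "matrix",
                                             "array"))
}
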