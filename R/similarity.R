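# Attribute features: disease semantic similarity over the hierarchy
# (Wang-style decaying ancestor contributions) and alignment-free miRNA
# sequence similarity (cosine of k-mer count vectors).

#' Semantic profile of a disease in the hierarchy
#'
#' The disease contributes 1 to itself; an ancestor's contribution decays by
#' the factor `delta` per hierarchy step, taking the maximum over all upward
#' paths (so with `delta < 1` the contribution is `delta ^ s` where `s` is the
#' shortest child-to-parent distance). The semantic value `DV` is the sum of
#' all contributions and is always at least 1.
#'
#' @param dag a `disease_dag`.
#' @param d disease id; must be a node of `dag`.
#' @param delta semantic contribution decay factor in (0, 1).
#' @return list of class `semantic_profile` with `disease`, `contributions`
#'   (named numeric over `d` and its ancestors), `semantic_value`, `delta`.
#' @export
semantic_profile <- function(dag, d, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!(delta > 0 && delta < 1)) stop("delta must be in (0, 1)")
  if (!d %in% dag$nodes) stop("unknown disease: ", d)
  # BFS up the parent relation: first visit gives the shortest distance
  dist <- c(0L)
  names(dist) <- d
  frontier <- d
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (node in frontier) {
      for (p in dag$parents[[node]]) {
        if (!p %in% names(dist)) {
          dist[p] <- dist[node] + 1L
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- nxt
  }
  contrib <- delta ^ dist
  structure(list(disease = d, contributions = contrib,
                 semantic_value = sum(contrib), delta = delta),
            class = "semantic_profile")
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat("Semantic profile of '", x$disease, "': ", length(x$contributions),
      " ancestor term(s), DV = ", format(x$semantic_value), "\n", sep = "")
  invisible(x)
}

#' Semantic similarity between two disease profiles
#'
#' The shared-ancestor contributions of both profiles, normalized by the two
#' semantic values: `sum over shared t of (D1(t) + D2(t)) / (DV1 + DV2)`.
#' Symmetric, in [0, 1], and equal to 1 exactly when the two ancestor sets and
#' contributions coincide.
#'
#' @param p1,p2 `semantic_profile` objects built with the same `delta`.
#' @return similarity in [0, 1].
#' @export
disease_semantic_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "semantic_profile"), inherits(p2, "semantic_profile"))
  if (!isTRUE(all.equal(p1$delta, p2$delta))) {
    stop("profiles were built with different delta values")
  }
  shared <- intersect(names(p1$contributions), names(p2$contributions))
  if (length(shared) == 0L) return(0)
  sum(p1$contributions[shared] + p2$contributions[shared]) /
    (p1$semantic_value + p2$semantic_value)
}

#' Pairwise disease semantic similarity matrix
#'
#' @param dag a `disease_dag`.
#' @param ids disease ids (all must be nodes of `dag`); row/column order.
#' @param delta decay factor, see [semantic_profile()].
#' @return symmetric matrix with unit diagonal, dimnames = `ids`.
#' @export
disease_similarity_matrix <- function(dag, ids, delta = 0.5) {
  ids <- as.character(ids)
  profiles <- lapply(ids, function(d) semantic_profile(dag, d, delta))
  n <- length(ids)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        S[i, j] <- S[j, i] <- disease_semantic_similarity(profiles[[i]],
                                                          profiles[[j]])
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

#' miRNA sequence similarity: cosine of k-mer count vectors
#'
#' Each sequence is represented by its vector of overlapping k-mer counts
#' (4^k possible k-mers); similarity is the cosine between count vectors.
#' Deterministic, alignment-free, and in [0, 1] since counts are non-negative.
#'
#' @param seqs named character vector of RNA sequences (alphabet ACGU).
#' @param k k-mer length; every sequence must be at least `k` long.
#' @return symmetric similarity matrix with unit diagonal, dimnames = ids.
#' @export
sequence_similarity_matrix <- function(seqs, k = 3L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  too_short <- nchar(seqs) < k
  if (any(too_short)) {
    stop("sequence '", names(seqs)[too_short][1L], "' is shorter than k = ", k)
  }
  kmer_list <- lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })
  vocab <- sort(unique(unlist(kmer_list, use.names = FALSE)))
  counts <- do.call(rbind, lapply(kmer_list, function(km) {
    tabulate(match(km, vocab), nbins = length(vocab))
  }))
  norms <- sqrt(rowSums(counts^2))
  unit <- counts / norms
  S <- tcrossprod(unit)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(names(seqs), names(seqs))
  S
}

#' Write a similarity matrix as CSV with id header row and column
#' @param S square similarity matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(S, path) {
  write.csv(as.data.frame(S), path, quote = FALSE)
  invisible(path)
}
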