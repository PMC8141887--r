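# Hand-computed micro-examples frozen as expected values: a 3-node chain, a
# diamond (two parents), siblings under one root, and a 3-mer cosine pair.

test_that("semantic profile matches hand recursion on chain and diamond", {
  chain <- disease_dag(child = c("d", "p"), parent = c("p", "r"))
  prof <- semantic_profile(chain, "d", delta = 0.5)
  expect_equal(prof$contributions[c("d", "p", "r")],
               c(d = 1, p = 0.5, r = 0.25), tolerance = 1e-12)
  expect_equal(prof$semantic_value, 1.75, tolerance = 1e-12)

  diamond <- disease_dag(child = c("d", "d", "p1", "p2"),
                         parent = c("p1", "p2", "r", "r"))
  pd <- semantic_profile(diamond, "d", delta = 0.5)
  expect_equal(pd$contributions[["r"]], 0.25, tolerance = 1e-12)
  expect_equal(pd$semantic_value, 2.25, tolerance = 1e-12)

  root_only <- disease_dag(child = "x", parent = "lone")
  pr <- semantic_profile(root_only, "lone", delta = 0.5)
  expect_equal(pr$contributions, c(lone = 1))
  expect_equal(pr$semantic_value, 1)

  expect_error(semantic_profile(chain, "nope", 0.5), "unknown disease")
  expect_error(semantic_profile(chain, "d", delta = 1), "delta")
})

test_that("semantic similarity: self = 1, disjoint = 0, siblings = 1/3", {
  sib <- disease_dag(child = c("d1", "d2", "e1", "e2"),
                     parent = c("r", "r", "s", "s"))
  p1 <- semantic_profile(sib, "d1", 0.5)
  p2 <- semantic_profile(sib, "d2", 0.5)
  e1 <- semantic_profile(sib, "e1", 0.5)
  expect_equal(disease_semantic_similarity(p1, p1), 1, tolerance = 1e-12)
  expect_equal(disease_semantic_similarity(p1, e1), 0)
  expect_equal(disease_semantic_similarity(p1, p2), 1 / 3, tolerance = 1e-12)
  expect_equal(disease_semantic_similarity(p2, p1),
               disease_semantic_similarity(p1, p2))
})

test_that("similarity matrix agrees with the pairwise operation", {
  expect_equal(disease_similarity_matrix(tiny_dag(), "d1"),
               matrix(1, 1, 1, dimnames = list("d1", "d1")))

  dag <- tiny_dag()
  ids <- c("d1", "d2", "d3")
  S <- disease_similarity_matrix(dag, ids, delta = 0.5)
  expect_symmetric_unit_diag(S)
  profs <- lapply(ids, semantic_profile, dag = dag, delta = 0.5)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(S[i, j],
                 disease_semantic_similarity(profs[[i]], profs[[j]]),
                 tolerance = 1e-12)
  }

  sib <- disease_dag(child = c("d1", "d2"), parent = c("r", "r"))
  S2 <- disease_similarity_matrix(sib, c("d1", "d2"), 0.5)
  expect_equal(S2[1, 2], 1 / 3, tolerance = 1e-12)
})

test_that("profile contributions decay along ancestor chains", {
  dag <- tiny_dag()
  for (d in c("d1", "d4")) {
    prof <- semantic_profile(dag, d, delta = 0.7)
    # each step up multiplies by delta < 1
    expect_equal(sort(unname(prof$contributions), decreasing = TRUE),
                 c(1, 0.7, 0.49), tolerance = 1e-12)
  }
})

test_that("profiles equal exhaustive path enumeration on random small DAGs", {
  # independent oracle: contribution of ancestor t = max over all directed
  # paths d -> t of delta^length, found by enumerating every path
  enumerate_paths <- function(parents, from) {
    best <- new.env()
    assign(from, 0L, envir = best)
    recurse <- function(node, len) {
      for (p in parents[[node]]) {
        cur <- get0(p, envir = best, ifnotfound = Inf)
        if (len + 1L < cur) assign(p, len + 1L, envir = best)
        recurse(p, len + 1L)
      }
    }
    recurse(from, 0L)
    out <- mget(ls(best), envir = best)
    vapply(out, identity, 0L)
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    ids <- paste0("n", seq_len(n))
    # random DAG: each node may point to any lower-indexed node (acyclic)
    child <- character(0); parent <- character(0)
    for (i in 2:n) {
      k <- sample(0:min(2, i - 1), 1)
      if (k > 0) {
        for (p in sample(ids[seq_len(i - 1)], k)) {
          child <- c(child, ids[i]); parent <- c(parent, p)
        }
      }
    }
    if (length(child) == 0) next
    dag <- disease_dag(child, parent)
    d <- sample(unique(child), 1)
    delta <- runif(1, 0.3, 0.9)
    prof <- semantic_profile(dag, d, delta)
    oracle_dist <- enumerate_paths(dag$parents, d)
    oracle <- delta ^ oracle_dist[sort(names(oracle_dist))]
    expect_equal(prof$contributions[sort(names(prof$contributions))],
                 oracle, tolerance = 1e-12)
  }
})

test_that("k-mer cosine matches hand-enumerated counts", {
  s <- c(a = "ACGACG", b = "ACGUAC")
  S <- sequence_similarity_matrix(s, k = 3)
  # a: {ACG:2, CGA:1, GAC:1}; b: {ACG:1, CGU:1, GUA:1, UAC:1}
  expect_equal(S["a", "b"], 2 / (sqrt(6) * sqrt(4)), tolerance = 1e-12)

  dup <- c(x = "ACGUACGU", y = "ACGUACGU")
  for (k in c(1, 2, 4)) {
    expect_equal(sequence_similarity_matrix(dup, k)["x", "y"], 1)
  }

  disjoint <- c(x = "AAAAA", y = "CCCCC")
  expect_equal(sequence_similarity_matrix(disjoint, 3)["x", "y"], 0)
})

test_that("sequence similarity is reorder-invariant and validates lengths", {
  s <- tiny_sequences()
  S1 <- sequence_similarity_matrix(s, 3)
  S2 <- sequence_similarity_matrix(rev(s), 3)
  expect_equal(S1, S2[rownames(S1), colnames(S1)])
  expect_symmetric_unit_diag(S1)

  expect_error(sequence_similarity_matrix(c(ok = "ACGU", bad = "AC"), 3),
               "bad")
  expect_error(sequence_similarity_matrix(s, 0), "k must be")
})
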