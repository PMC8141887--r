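test_that("adjacency places associations in the bipartite blocks", {
  adj <- build_adjacency(association_table("m1", "d1"),
                         c("m1", "m2"), c("d1", "d2"))
  expect_equal(sum(adj$A), 2)
  expect_true(isSymmetric(adj$A))
  expect_equal(adj$A["m1", "d1"], 1)
  expect_setequal(adj$isolated, c("m2", "d2"))

  empty <- association_table(character(0), character(0))
  adj0 <- build_adjacency(empty, c("m1", "m2"), c("d1", "d2"))
  expect_equal(sum(adj0$A), 0)
  expect_setequal(adj0$isolated, c("m1", "m2", "d1", "d2"))

  complete <- association_table(rep(c("m1", "m2"), each = 2),
                                rep(c("d1", "d2"), 2))
  adjc <- build_adjacency(complete, c("m1", "m2"), c("d1", "d2"))
  expect_equal(sum(adjc$A), 8)
  expect_equal(unname(rowSums(adjc$A)[c("m1", "m2")]), c(2, 2))
  # miRNA-miRNA and disease-disease blocks stay empty
  expect_equal(sum(adjc$A[1:2, 1:2]), 0)
  expect_equal(sum(adjc$A[3:4, 3:4]), 0)

  expect_error(build_adjacency(association_table("mX", "d1"),
                               c("m1"), c("d1")), "mX")
})

test_that("row normalization preserves zero rows and rejects negatives", {
  T1 <- row_normalize(rbind(c(1, 1, 0), c(0, 0, 0), c(2, 0, 2)))
  expect_equal(T1$values[1, ], c(0.5, 0.5, 0))
  expect_equal(T1$values[2, ], c(0, 0, 0))
  expect_equal(T1$zero_rows, 2L)

  T2 <- row_normalize(matrix(c(2, 0, 2, 4), 1))
  expect_equal(T2$values[1, ], c(0.25, 0, 0.25, 0.5))

  expect_error(row_normalize(matrix(c(1, -1), 1)), "negative")
})

test_that("fusion is the convex combination of structure and attributes", {
  S <- row_normalize(rbind(c(1, 0), c(1, 1)))
  Z <- row_normalize(rbind(c(0, 1), c(1, 0)))
  expect_equal(fuse_transition(S, Z, 1)$values, S$values)
  expect_equal(fuse_transition(S, Z, 0)$values, Z$values)
  P <- fuse_transition(S, Z, 0.85)
  expect_equal(P$values[1, ], c(0.85, 0.15))
  expect_error(fuse_transition(S, row_normalize(diag(3)), 0.5), "shape")
  expect_error(fuse_transition(S, Z, 1.2), "alpha")
})

test_that("enhanced matrix: single order returns P, two orders hand-checked", {
  P <- rbind(c(0, 1), c(1, 0))
  for (beta in c(0.3, 0.94, 1)) {
    expect_equal(unclass(enhanced_matrix(P, beta, 1)), P,
                 ignore_attr = TRUE)
  }
  M2 <- enhanced_matrix(P, beta = 0.5, t = 2)   # P + 0.5 * P^2, P^2 = I
  expect_equal(unclass(M2), rbind(c(0.5, 1), c(1, 0.5)), ignore_attr = TRUE)
  expect_error(enhanced_matrix(P, beta = 0, t = 2), "beta")
  expect_error(enhanced_matrix(P, beta = 0.5, t = 0), "t must be")
})

test_that("iterative accumulation equals the explicit-powers oracle", {
  explicit <- function(P, beta, t) {
    acc <- matrix(0, nrow(P), ncol(P))
    for (l in seq_len(t)) {
      Pl <- Reduce(`%*%`, rep(list(P), l))
      acc <- acc + beta^(l - 1) * Pl
    }
    acc
  }
  set.seed(11)
  P <- random_stochastic(4)
  M <- enhanced_matrix(P, beta = 0.94, t = 5)
  expect_lt(max(abs(unclass(M) - explicit(P, 0.94, 5))), 1e-10)
})

test_that("row sums of M are the geometric series for stochastic P", {
  set.seed(4)
  P <- random_stochastic(6)
  M <- enhanced_matrix(P, beta = 0.94, t = 5)
  expect_equal(unname(rowSums(M)), rep((1 - 0.94^5) / (1 - 0.94), 6),
               tolerance = 1e-9)
  M1 <- enhanced_matrix(P, beta = 1, t = 4)
  expect_equal(unname(rowSums(M1)), rep(4, 6), tolerance = 1e-9)
})

test_that("successive orders differ by exactly the next weighted power", {
  set.seed(12)
  P <- random_stochastic(5)
  for (t in 1:4) {
    Mt <- unclass(enhanced_matrix(P, 0.8, t))
    Mt1 <- unclass(enhanced_matrix(P, 0.8, t + 1))
    Pl <- Reduce(`%*%`, rep(list(P), t + 1))
    expect_lt(max(abs((Mt1 - Mt) - 0.8^t * Pl)), 1e-10)
  }
})

test_that("alpha gates which channel can influence the walk", {
  data <- small_synth()
  mirna_sim <- sequence_similarity_matrix(data$sequences, 3)
  ids <- sort(unique(data$associations$disease))
  disease_sim <- disease_similarity_matrix(data$dag, ids, 0.5)
  net <- attributed_network(data$associations, mirna_sim, disease_sim)

  build_M <- function(A, Z0, alpha) {
    P <- fuse_transition(row_normalize(A), row_normalize(Z0), alpha)
    unclass(enhanced_matrix(P, 0.94, 3))
  }

  # perturb attributes: alpha = 1 must not notice
  Z0p <- net$Z0
  Z0p[1, 2] <- Z0p[2, 1] <- 0.99
  expect_equal(build_M(net$A, net$Z0, 1), build_M(net$A, Z0p, 1))
  expect_false(isTRUE(all.equal(build_M(net$A, net$Z0, 0.5),
                                build_M(net$A, Z0p, 0.5))))

  # perturb edges: alpha = 0 must not notice
  Ap <- net$A
  i <- net$index$m + 1L                 # first disease node
  Ap[1, i] <- Ap[i, 1] <- 1 - Ap[1, i]
  expect_equal(build_M(net$A, net$Z0, 0), build_M(Ap, net$Z0, 0))
  expect_false(isTRUE(all.equal(build_M(net$A, net$Z0, 0.5),
                                build_M(Ap, net$Z0, 0.5))))
})

test_that("structure-only walk alternates sides of the bipartite graph", {
  a <- association_table(c("m1", "m2"), c("d1", "d2"))
  adj <- build_adjacency(a, c("m1", "m2"), c("d1", "d2"))
  S <- row_normalize(adj$A)
  m_side <- 1:2; d_side <- 3:4
  for (l in 1:4) {
    Pl <- Reduce(`%*%`, rep(list(S$values), l))
    from_mirna <- Pl[m_side, , drop = FALSE]
    if (l %% 2 == 1) {
      expect_equal(sum(from_mirna[, m_side]), 0, label = paste("order", l))
    } else {
      expect_equal(sum(from_mirna[, d_side]), 0, label = paste("order", l))
    }
  }
})
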