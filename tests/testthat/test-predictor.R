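test_that("negative sampling avoids positives and is forced when unique", {
  pos <- association_table(c("m1", "m1", "m2"), c("d1", "d2", "d1"))
  neg <- sample_negatives(pos, 1, c("m1", "m2"), c("d1", "d2"), seed = 1)
  expect_equal(neg$mirna, "m2")
  expect_equal(neg$disease, "d2")
  expect_error(sample_negatives(pos, 2, c("m1", "m2"), c("d1", "d2")),
               "only 1")
})

test_that("negative sampling is balanced by default and seed-deterministic", {
  data <- small_synth()
  pos <- data$associations
  mirnas <- data$truth$id[data$truth$type == "mirna"]
  diseases <- data$truth$id[data$truth$type == "disease"]
  n1 <- sample_negatives(pos, mirna_ids = mirnas, disease_ids = diseases,
                         seed = 5)
  expect_equal(nrow(n1), nrow(pos))
  key <- function(a) paste(a$mirna, a$disease)
  expect_length(intersect(key(n1), key(pos)), 0L)
  expect_false(anyDuplicated(key(n1)) > 0)

  n2 <- sample_negatives(pos, mirna_ids = mirnas, disease_ids = diseases,
                         seed = 5)
  expect_identical(n1, n2)
  n3 <- sample_negatives(pos, mirna_ids = mirnas, disease_ids = diseases,
                         seed = 6)
  expect_false(identical(n1, n3))
})

test_that("pair features concatenate miRNA code then disease code", {
  H <- matrix(seq_len(12), 4, 3,
              dimnames = list(c("m1", "m2", "d1", "d2"), NULL))
  pairs <- data.frame(mirna = c("m1", "m2"), disease = c("d2", "d1"))
  ds <- build_pair_features(H, pairs, c(1, 0))
  expect_equal(dim(ds$features), c(2L, 6L))
  expect_equal(unname(ds$features[1, ]), c(H["m1", ], H["d2", ]))

  # swapping the miRNA changes only the first half
  pairs2 <- data.frame(mirna = c("m2", "m2"), disease = c("d2", "d1"))
  ds2 <- build_pair_features(H, pairs2, c(1, 0))
  expect_equal(ds$features[1, 4:6], ds2$features[1, 4:6])
  expect_false(all(ds$features[1, 1:3] == ds2$features[1, 1:3]))

  expect_error(build_pair_features(H, data.frame(mirna = "mX", disease = "d1"),
                                   0), "mX")
})

# feature layout matches build_pair_features() with 2-dim codes, so models
# trained here can score candidate features built from a 2-column embedding
separable_dataset <- function(n = 60, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(labels * 2 + rnorm(n, sd = 0.1), rnorm(n),
             rnorm(n), rnorm(n))
  colnames(x) <- c("m1", "m2", "d1", "d2")
  structure(list(pairs = data.frame(mirna = paste0("m", 1:n),
                                    disease = "d1"),
                 labels = labels, features = x),
            class = "pair_dataset")
}

test_that("all four classifiers train and score in [0, 1]", {
  ds <- separable_dataset()
  for (name in c("random_forest", "naive_bayes", "adaboost", "knn")) {
    clf <- train_classifier(ds, name, seed = 3)
    s <- predict(clf, ds)
    expect_length(s, 60L)
    expect_true(all(s >= 0 & s <= 1), label = name)
    expect_equal(compute_metrics(ds$labels, s)$auc, 1, label = name)
  }
  expect_error(train_classifier(ds, "svm"), "valid names")
  one_class <- ds; one_class$labels <- rep(1L, 60)
  expect_error(train_classifier(one_class, "random_forest"), "both classes")
})

test_that("random forest scoring is seed-deterministic", {
  ds <- separable_dataset()
  s1 <- predict(train_classifier(ds, "random_forest", seed = 7), ds)
  s2 <- predict(train_classifier(ds, "random_forest", seed = 7), ds)
  expect_identical(s1, s2)
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  set.seed(77)
  n <- 2000
  x <- matrix(rnorm(n * 8), n, 8)
  labels <- sample(rep(c(1L, 0L), each = n / 2))
  fold <- sample(rep(1:5, length.out = n))
  colnames(x) <- paste0("f", 1:8)
  aucs <- vapply(1:5, function(f) {
    tr <- fold != f
    ds <- structure(list(pairs = data.frame(mirna = as.character(which(tr)),
                                            disease = "d"),
                         labels = labels[tr], features = x[tr, ]),
                    class = "pair_dataset")
    clf <- train_classifier(ds, "random_forest", seed = f)
    compute_metrics(labels[!tr], predict(clf, x[!tr, ]))$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("candidate ranking excludes known pairs and orders by score", {
  # injected oracle model scoring miRNA i as 1 - i/m: ranking must come out
  # in exactly ascending index order
  registerS3method("predict", "index_oracle",
                   function(object, newdata, ...) {
                     1 - newdata$features[, 1] / object$m
                   }, envir = globalenv())
  m <- 10
  oracle <- structure(list(m = m), class = "index_oracle")
  H <- matrix(0, m + 1, 2,
              dimnames = list(c(sprintf("m%02d", 1:m), "d1"), NULL))
  H[1:m, 1] <- seq_len(m)                # code column 1 encodes the index
  r <- rank_candidates(oracle, H, "d1",
                       association_table("m99", "dX"),
                       mirna_ids = rownames(H)[1:m], top_n = m)
  expect_equal(r$entries$mirna, sprintf("m%02d", 1:m))
  expect_true(all(diff(r$entries$score) <= 0))

  # through the real API with a trained model: all-known edge case
  ds <- separable_dataset()
  clf <- train_classifier(ds, "random_forest", seed = 1)
  Hm <- matrix(rnorm(12), 6, 2,
               dimnames = list(c("m1", "m2", "m3", "m4", "m5", "d1"), NULL))
  all_known <- association_table(paste0("m", 1:5), rep("d1", 5))
  r0 <- rank_candidates(clf, Hm, "d1", all_known,
                        mirna_ids = paste0("m", 1:5))
  expect_equal(nrow(r0$entries), 0L)
  expect_equal(r0$n_excluded, 5L)

  r2 <- rank_candidates(clf, Hm, "d1",
                        association_table("m1", "d1"),
                        mirna_ids = paste0("m", 1:5), top_n = 50)
  expect_equal(nrow(r2$entries), 4L)     # top_n larger than candidate count
  expect_true(all(diff(r2$entries$score) <= 0))
  expect_error(rank_candidates(clf, Hm, "dX", all_known,
                               mirna_ids = paste0("m", 1:5)),
               "unknown disease")
})

test_that("tied candidate scores break ties by miRNA id", {
  ds <- separable_dataset()
  clf0 <- train_classifier(ds, "knn", seed = 1)
  # constant features => every candidate gets an identical score
  Hc <- matrix(1, 5, 2, dimnames = list(c("mB", "mA", "mD", "mC", "dZ"), NULL))
  r <- rank_candidates(clf0, Hc, "dZ",
                       association_table("mA", "dZ"),
                       mirna_ids = c("mB", "mA", "mD", "mC"))
  expect_equal(r$entries$mirna, c("mB", "mC", "mD"))
})
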