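# Pair-level learning: negative sampling, feature construction from node
# codes, and the pluggable classifiers (random forest, naive Bayes, AdaBoost
# over decision stumps, k-nearest neighbours).

#' Sample negative miRNA-disease pairs
#'
#' Draws `n` distinct pairs uniformly without replacement from the Cartesian
#' product of the id universes minus the known positives, matching the common
#' protocol of sampling as many negatives as there are positives.
#'
#' @param positives an `mda_associations` table of known pairs.
#' @param n number of negatives; defaults to `nrow(positives)`.
#' @param mirna_ids,disease_ids the id universes.
#' @param seed integer seed; the draw is seed-deterministic.
#' @return an `mda_associations` table of sampled non-associations.
#' @export
sample_negatives <- function(positives, n = nrow(positives),
                             mirna_ids, disease_ids, seed = 1L) {
  mirna_ids <- sort(unique(mirna_ids))
  disease_ids <- sort(unique(disease_ids))
  m <- length(mirna_ids); d <- length(disease_ids)
  pos_idx <- (match(positives$disease, disease_ids) - 1L) * m +
    match(positives$mirna, mirna_ids)
  if (anyNA(pos_idx)) stop("positive pair uses an id outside the universe")
  free <- setdiff(seq_len(m * d), pos_idx)
  if (n > length(free)) {
    stop("cannot sample ", n, " negatives: only ", length(free),
         " non-positive pairs exist")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- sort(free[sample.int(length(free), n)])
  i <- ((pick - 1L) %% m) + 1L
  j <- ((pick - 1L) %/% m) + 1L
  association_table(mirna_ids[i], disease_ids[j], source_tag = "negatives")
}

#' Concatenate node codes into pair feature vectors
#'
#' The feature vector of a pair is the miRNA code followed by the disease
#' code (2 x code_dim columns).
#'
#' @param H embedding matrix with node ids as row names.
#' @param pairs data.frame with `mirna` and `disease` columns.
#' @param labels 0/1 vector, one per pair.
#' @return list of class `pair_dataset`: `pairs`, `labels`, `features`.
#' @export
build_pair_features <- function(H, pairs, labels) {
  if (nrow(pairs) != length(labels)) stop("pairs/labels length mismatch")
  mi <- match(pairs$mirna, rownames(H))
  di <- match(pairs$disease, rownames(H))
  if (anyNA(mi)) stop("no embedding for miRNA: ", pairs$mirna[is.na(mi)][1L])
  if (anyNA(di)) stop("no embedding for disease: ", pairs$disease[is.na(di)][1L])
  features <- cbind(H[mi, , drop = FALSE], H[di, , drop = FALSE])
  colnames(features) <- c(paste0("m", seq_len(ncol(H))),
                          paste0("d", seq_len(ncol(H))))
  rownames(features) <- NULL
  structure(list(pairs = pairs, labels = as.integer(labels),
                 features = features),
            class = "pair_dataset")
}

#' Train a pair classifier
#'
#' All classifiers are used with their library-default hyperparameters and
#' expose a score in [0, 1] per pair (estimated probability of association):
#' `random_forest` (500 trees), `naive_bayes` (Gaussian), `adaboost`
#' (AdaBoost.M1 over decision stumps, 50 rounds), and `knn` (k = 5 vote
#' fraction; the training set is stored and used at prediction time).
#'
#' @param data a `pair_dataset` containing both classes.
#' @param name one of `"random_forest"`, `"naive_bayes"`, `"adaboost"`,
#'   `"knn"`.
#' @param seed integer seed passed to any stochastic learner.
#' @return object of class `mda_classifier`; score new pairs with
#'   [predict.mda_classifier()].
#' @export
train_classifier <- function(data, name = "random_forest", seed = 1L) {
  stopifnot(inherits(data, "pair_dataset"))
  valid <- c("random_forest", "naive_bayes", "adaboost", "knn")
  if (!name %in% valid) {
    stop("unknown classifier '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  if (length(unique(data$labels)) < 2L) {
    stop("training data must contain both classes")
  }
  x <- data$features
  y <- factor(data$labels, levels = c(0L, 1L))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  model <- switch(name,
    random_forest = randomForest::randomForest(x, y),
    naive_bayes = e1071::naiveBayes(x, y),
    adaboost = adaboost_stumps(x, data$labels),
    knn = list(x = x, y = data$labels, k = 5L))
  structure(list(name = name, model = model, seed = seed),
            class = "mda_classifier")
}

#' Score pairs with a trained classifier
#' @param object an `mda_classifier`.
#' @param newdata a `pair_dataset` or a bare feature matrix.
#' @param ... unused.
#' @return numeric vector of scores in [0, 1].
#' @export
predict.mda_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pair_dataset")) newdata$features else newdata
  switch(object$name,
    random_forest = unname(predict(object$model, x, type = "prob")[, "1"]),
    naive_bayes = unname(predict(object$model, x, type = "raw")[, "1"]),
    adaboost = adaboost_score(object$model, x),
    knn = {
      votes <- class::knn(train = object$model$x, test = x,
                          cl = factor(object$model$y, levels = c(0L, 1L)),
                          k = object$model$k, prob = TRUE)
      p <- attr(votes, "prob")
      ifelse(votes == "1", p, 1 - p)
    })
}

# AdaBoost.M1 with depth-1 rpart stumps; 50 rounds (the common library
# default). Scores are the normalized weighted vote for the positive class.
adaboost_stumps <- function(x, y01, rounds = 50L) {
  df <- as.data.frame(x)
  y <- ifelse(y01 == 1L, 1, -1)
  n <- length(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (r in seq_len(rounds)) {
    fit <- rpart::rpart(yf ~ ., data = cbind(df, yf = factor(y)),
                        weights = w, method = "class", control = ctrl)
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != y])
    if (err <= 0) {                     # perfect stump: cap its weight
      stumps[[r]] <- fit; alphas[r] <- 10
      break
    }
    if (err >= 0.5) break               # no better than chance: stop
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[r]] <- fit; alphas[r] <- alpha
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {           # degenerate: fall back to prior
    return(list(stumps = list(), alphas = numeric(0),
                prior = mean(y01 == 1L)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y01 == 1L))
}

adaboost_score <- function(model, x) {
  if (length(model$stumps) == 0L) return(rep(model$prior, nrow(x)))
  df <- as.data.frame(x)
  votes <- vapply(seq_along(model$stumps), function(r) {
    model$alphas[r] *
      (predict(model$stumps[[r]], df, type = "class") == "1")
  }, numeric(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  rowSums(votes) / sum(model$alphas)
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA in the embedding that is not already positively paired
#' with the disease in the training set, and returns the highest-scoring
#' candidates in descending score order, ties broken by miRNA id ascending.
#'
#' @param model an `mda_classifier`.
#' @param H embedding matrix with node ids as row names.
#' @param disease disease id (must be embedded).
#' @param training_positives an `mda_associations` table whose pairs are
#'   excluded from the candidate set.
#' @param mirna_ids candidate miRNA universe (default: all embedded ids that
#'   look like training miRNAs, i.e. the miRNA side of `training_positives`
#'   plus any extra ids supplied).
#' @param top_n number of candidates to return.
#' @return list of class `ranked_predictions` with `disease`, `entries`
#'   (data.frame mirna/score, scores non-increasing), `n_excluded`.
#' @export
rank_candidates <- function(model, H, disease, training_positives,
                            mirna_ids, top_n = 50L) {
  if (!disease %in% rownames(H)) stop("unknown disease: ", disease)
  mirna_ids <- sort(unique(mirna_ids))
  known <- training_positives$mirna[training_positives$disease == disease]
  candidates <- setdiff(mirna_ids, known)
  n_excluded <- length(mirna_ids) - length(candidates)
  if (length(candidates) == 0L) {
    entries <- data.frame(mirna = character(), score = numeric())
  } else {
    pairs <- data.frame(mirna = candidates,
                        disease = rep(disease, length(candidates)),
                        stringsAsFactors = FALSE)
    ds <- build_pair_features(H, pairs, rep(0L, nrow(pairs)))
    scores <- predict(model, ds)
    ord <- order(-scores, candidates)
    keep <- head(ord, top_n)
    entries <- data.frame(mirna = candidates[keep], score = scores[keep],
                          stringsAsFactors = FALSE)
  }
  structure(list(disease = disease, entries = entries,
                 n_excluded = n_excluded),
            class = "ranked_predictions")
}

#' @export
print.ranked_predictions <- function(x, ...) {
  cat("Top ", nrow(x$entries), " candidate miRNA(s) for '", x$disease,
      "' (", x$n_excluded, " known pair(s) excluded)\n", sep = "")
  print(utils::head(x$entries, 10))
  invisible(x)
}
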