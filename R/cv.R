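# k-fold cross-validated evaluation. Positives and sampled negatives are each
# split into k seed-deterministic folds; each fold in turn is held out for
# testing. In `masked` mode the adjacency is rebuilt from training positives
# only before the walk and embedding, so no test edge leaks into feature
# construction; `paper` mode embeds on the full adjacency (the classifier
# still never sees test pairs).

#' Cross-validate the association pipeline
#'
#' @inheritParams mdanet
#' @param k number of folds (>= 2).
#' @param mode `"masked"` (default; test-fold edges removed from the
#'   adjacency before embedding) or `"paper"` (full adjacency used for
#'   embedding).
#' @param permute_labels if `TRUE`, the positive/negative labels of the pair
#'   set are randomly permuted before folding — a null control whose AUC
#'   should sit near 0.5.
#' @param threshold score threshold for the thresholded metrics.
#' @param seed master seed: drives negative sampling, label permutation, fold
#'   assignment, and per-fold training seeds.
#' @return object of class `mdanet_cv`: `per_fold` (list of `mda_metrics`),
#'   `mean`, `sd`, `fold_assignment`, `k`, `mode`, `config`, `config_hash`.
#' @export
mdanet_cv <- function(associations, sequences, dag, k = 5L, seed = 1L,
                      mode = c("masked", "paper"),
                      alpha = 0.85, beta = 0.94, t = 5L, delta = 0.5,
                      kmer = 3L, encoder = NULL,
                      classifier = "random_forest",
                      permute_labels = FALSE, threshold = 0.5,
                      renormalize_m = FALSE, allow_missing = FALSE) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  config <- list(k = k, seed = as.integer(seed), mode = mode, alpha = alpha,
                 beta = beta, t = as.integer(t), delta = delta,
                 kmer = as.integer(kmer), classifier = classifier,
                 permute_labels = permute_labels, threshold = threshold,
                 renormalize_m = renormalize_m,
                 encoder = if (is.null(encoder)) "default" else
                   unclass(encoder))
  validate_walk_params(alpha, beta, t)

  mirna_sim <- sequence_similarity_matrix(sequences, k = kmer)
  disease_sim <- disease_similarity_matrix(dag, intersect(
    sort(unique(associations$disease)), dag$nodes), delta = delta)
  missing_dag <- setdiff(unique(associations$disease), dag$nodes)
  if (length(missing_dag) > 0L && !allow_missing) {
    stop("disease absent from the hierarchy: ", missing_dag[1L])
  }
  positives <- check_association_ids(associations, rownames(mirna_sim),
                                     rownames(disease_sim),
                                     allow_missing = allow_missing)
  idx <- node_index(rownames(mirna_sim), rownames(disease_sim))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L) # negatives, permute, folds

  negatives <- sample_negatives(positives, nrow(positives),
                                idx$mirnas, idx$diseases, seed = sub[1L])
  pairs <- rbind(data.frame(mirna = positives$mirna,
                            disease = positives$disease),
                 data.frame(mirna = negatives$mirna,
                            disease = negatives$disease))
  labels <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))
  if (permute_labels) {
    set.seed(sub[2L])
    labels <- sample(labels)
  }
  pos_rows <- which(labels == 1L)
  neg_rows <- which(labels == 0L)
  if (length(pos_rows) < k || length(neg_rows) < k) {
    stop("not enough samples per class for ", k, " folds")
  }
  set.seed(sub[3L])
  fold <- integer(length(labels))
  fold[pos_rows] <- sample(rep(seq_len(k), length.out = length(pos_rows)))
  fold[neg_rows] <- sample(rep(seq_len(k), length.out = length(neg_rows)))

  full_net <- if (mode == "paper") {
    attributed_network(association_table(pairs$mirna[pos_rows],
                                         pairs$disease[pos_rows], "cv"),
                       mirna_sim, disease_sim)
  } else NULL

  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold != f
    train_pos <- association_table(pairs$mirna[train & labels == 1L],
                                   pairs$disease[train & labels == 1L], "cv")
    train_neg <- association_table(pairs$mirna[train & labels == 0L],
                                   pairs$disease[train & labels == 0L], "cv")
    # masked: adjacency from training positives only, over the FULL node
    # universe so embeddings exist for every node (held-out nodes may be
    # isolated)
    net <- if (mode == "masked") {
      attributed_network(train_pos, mirna_sim, disease_sim)
    } else full_net
    fit <- fit_core(net, train_pos, alpha, beta, t, encoder, classifier,
                    negatives = train_neg, seed = seed + f,
                    renormalize_m = renormalize_m)
    test_pairs <- pairs[!train, , drop = FALSE]
    scores <- predict(fit, test_pairs)
    per_fold[[f]] <- compute_metrics(labels[!train], scores,
                                     threshold = threshold)
  }

  scalars <- c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr")
  tab <- vapply(per_fold, function(m) unlist(unclass(m)[scalars]),
                numeric(length(scalars)))
  structure(list(per_fold = per_fold,
                 mean = rowMeans(tab),
                 sd = apply(tab, 1L, sd),
                 fold_assignment = fold,
                 k = k, mode = mode, config = config,
                 config_hash = config_hash(config)),
            class = "mdanet_cv")
}

validate_walk_params <- function(alpha, beta, t) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  if (as.integer(t) < 1L) stop("t must be a positive integer")
  invisible(TRUE)
}

#' @export
print.mdanet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s mode)\n", x$k, x$mode))
  scalars <- c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr")
  tab <- t(vapply(x$per_fold, function(m) unlist(unclass(m)[scalars]),
                  numeric(length(scalars))))
  rownames(tab) <- paste("fold", seq_len(x$k))
  tab <- rbind(tab, mean = x$mean[scalars], sd = x$sd[scalars])
  print(round(tab, 4))
  invisible(x)
}

#' Plot cross-validated ROC or precision-recall curves
#' @param x an `mdanet_cv` report.
#' @param which `"roc"` or `"pr"`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mdanet_cv <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(0:1, 0:1, type = "n", xlab = "false positive rate",
         ylab = "true positive rate", main = "Cross-validated ROC", ...)
    abline(0, 1, lty = 3, col = "grey")
    for (f in seq_len(x$k)) {
      p <- x$per_fold[[f]]$roc_points
      lines(p$fpr, p$tpr, col = f)
    }
  } else {
    plot(0:1, 0:1, type = "n", xlab = "recall", ylab = "precision",
         main = "Cross-validated precision-recall", ...)
    for (f in seq_len(x$k)) {
      p <- x$per_fold[[f]]$pr_points
      lines(p$recall, p$precision, col = f)
    }
  }
  legend("bottomright", legend = sprintf("fold %d (AUC %.3f)", seq_len(x$k),
           vapply(x$per_fold, `[[`, 0, "auc")), col = seq_len(x$k),
         lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

# Stable hash of a configuration list (for output provenance).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}
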