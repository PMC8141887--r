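# The fitting surface: mdanet() runs the whole pipeline on one dataset
# (attributes -> attributed network -> enhanced matrix -> auto-encoder codes
# -> balanced pair dataset -> classifier) and returns a classed fit usable
# for scoring and ranking.

#' Fit a miRNA-disease association model
#'
#' Builds the attributed bipartite network from the known associations and
#' the two attribute similarity matrices (k-mer cosine for sequences,
#' decaying ancestor overlap for diseases), fuses the row-normalized
#' structure and attribute transition matrices with weight `alpha`,
#' accumulates walk orders 1..t damped by `beta` into the enhanced proximity
#' matrix, compresses each node's row to a code with a stacked auto-encoder,
#' and trains a classifier on balanced positive/sampled-negative pairs whose
#' features are the concatenated node codes.
#'
#' @param associations an `mda_associations` table of known pairs.
#' @param sequences named character vector of miRNA RNA sequences.
#' @param dag a `disease_dag` covering every disease id.
#' @param alpha structure weight in [0, 1] of the fused walk (default 0.85,
#'   i.e. 85% structure / 15% attributes).
#' @param beta high-order damping in (0, 1] (default 0.94).
#' @param t number of walk orders (default 5).
#' @param delta semantic decay for disease similarity (default 0.5).
#' @param kmer k-mer length for sequence similarity (default 3).
#' @param encoder an [encoder_spec()]; `NULL` for defaults (hidden layers
#'   256 -> 64; on inputs smaller than 256 nodes the hidden widths are scaled
#'   down to fit).
#' @param classifier classifier name, see [train_classifier()].
#' @param negatives optional pre-sampled `mda_associations` of negatives; by
#'   default as many negatives as positives are drawn with `seed`.
#' @param seed master seed for negative sampling and training.
#' @param renormalize_m row-normalize the enhanced matrix before encoding.
#' @param allow_missing drop associations whose ids carry no attributes.
#' @return object of class `mdanet`; see [predict.mdanet()],
#'   [rank_candidates()], [summary.mdanet()].
#' @export
mdanet <- function(associations, sequences, dag,
                   alpha = 0.85, beta = 0.94, t = 5L, delta = 0.5,
                   kmer = 3L, encoder = NULL, classifier = "random_forest",
                   negatives = NULL, seed = 1L, renormalize_m = FALSE,
                   allow_missing = FALSE) {
  mirna_sim <- sequence_similarity_matrix(sequences, k = kmer)
  disease_ids <- sort(unique(associations$disease))
  missing_dag <- setdiff(disease_ids, dag$nodes)
  if (length(missing_dag) > 0L && !allow_missing) {
    stop("disease absent from the hierarchy: ", missing_dag[1L])
  }
  disease_sim <- disease_similarity_matrix(dag,
                                           intersect(disease_ids, dag$nodes),
                                           delta = delta)
  net <- attributed_network(associations, mirna_sim, disease_sim,
                            allow_missing = allow_missing)
  fit_core(net, associations, alpha, beta, t, encoder, classifier,
           negatives, seed, renormalize_m,
           extra = list(delta = delta, kmer = kmer))
}

# Shared by mdanet() and the CV folds (which reuse precomputed attributes).
fit_core <- function(net, train_pos, alpha, beta, t, encoder, classifier,
                     negatives, seed, renormalize_m, extra = list()) {
  idx <- net$index
  S <- row_normalize(net$A)
  Z <- row_normalize(net$Z0)
  P <- fuse_transition(S, Z, alpha = alpha)
  M <- enhanced_matrix(P, beta = beta, t = t, renormalize = renormalize_m)
  # standardize proximity columns before encoding: raw entries are tiny
  # (row sums are bounded by the geometric series) and would saturate the
  # sigmoid units into near-constant codes
  Ms <- scale(unclass(M))
  Ms[, attr(Ms, "scaled:scale") == 0] <- 0
  if (is.null(encoder)) encoder <- default_encoder_spec(ncol(Ms), seed)
  ae <- train_autoencoder(Ms, encoder)
  H <- encode(ae, Ms)
  rownames(H) <- idx$nodes

  train_pos <- train_pos[train_pos$mirna %in% idx$mirnas &
                           train_pos$disease %in% idx$diseases, ]
  if (is.null(negatives)) {
    negatives <- sample_negatives(train_pos, nrow(train_pos),
                                  idx$mirnas, idx$diseases, seed = seed)
  }
  pairs <- rbind(data.frame(mirna = train_pos$mirna,
                            disease = train_pos$disease),
                 data.frame(mirna = negatives$mirna,
                            disease = negatives$disease))
  labels <- rep(c(1L, 0L), c(nrow(train_pos), nrow(negatives)))
  ds <- build_pair_features(H, pairs, labels)
  clf <- train_classifier(ds, name = classifier, seed = seed)

  structure(c(list(network = net, embedding = H, autoencoder = ae,
                   classifier = clf, training = ds,
                   params = c(list(alpha = alpha, beta = beta, t = t,
                                   classifier = classifier, seed = seed,
                                   renormalize_m = renormalize_m), extra)),
              list()),
            class = "mdanet")
}

# Scale the default 256 -> 64 architecture down when the input is small,
# keeping strictly decreasing widths.
default_encoder_spec <- function(input_dim, seed) {
  h1 <- if (input_dim > 256L) 256L else
    max(4L, as.integer(floor(input_dim * 2 / 3)))
  h2 <- min(64L, max(2L, h1 %/% 4L))
  if (h2 >= h1) h2 <- max(2L, h1 - 1L)
  encoder_spec(hidden_dims = c(h1, h2), seed = seed)
}

#' @export
print.mdanet <- function(x, ...) {
  idx <- x$network$index
  cat("miRNA-disease association model (attributed network embedding)\n")
  cat(sprintf("  nodes: %d miRNAs + %d diseases; %d known associations\n",
              idx$m, idx$d, sum(x$network$A) / 2))
  cat(sprintf("  walk: alpha = %.2f, beta = %.2f, t = %d; code dim %d\n",
              x$params$alpha, x$params$beta, x$params$t, ncol(x$embedding)))
  cat(sprintf("  classifier: %s on %d balanced pairs\n",
              x$params$classifier, length(x$training$labels)))
  invisible(x)
}

#' Summary of a fitted association model
#' @param object an `mdanet` fit.
#' @param ... unused.
#' @return list of class `summary.mdanet` with network size, parameters,
#'   reconstruction losses and training-set metrics.
#' @export
summary.mdanet <- function(object, ...) {
  scores <- predict(object$classifier, object$training)
  train_metrics <- compute_metrics(object$training$labels, scores)
  out <- list(index = object$network$index,
              params = object$params,
              isolated = object$network$isolated,
              loss = object$autoencoder$loss,
              train_metrics = train_metrics)
  class(out) <- "summary.mdanet"
  out
}

#' @export
print.summary.mdanet <- function(x, ...) {
  cat(sprintf("Network: %d miRNAs + %d diseases (%d isolated)\n",
              x$index$m, x$index$d, length(x$isolated)))
  cat(sprintf("Walk: alpha %.2f, beta %.2f, t %d | encoder MSE %.3g\n",
              x$params$alpha, x$params$beta, x$params$t,
              x$loss$finetune_mse))
  cat("Training-set (resubstitution) metrics:\n  ")
  print(x$train_metrics)
  invisible(x)
}

#' Coefficients of a fitted association model
#'
#' A link-prediction pipeline has no regression coefficients; the fitted
#' "coefficients" reported are its tuned walk parameters.
#'
#' @param object an `mdanet` fit.
#' @param ... unused.
#' @return named numeric vector with `alpha`, `beta`, `t`, `delta`, `kmer`.
#' @export
coef.mdanet <- function(object, ...) {
  with(object$params,
       c(alpha = alpha, beta = beta, t = as.numeric(t),
         delta = delta, kmer = as.numeric(kmer)))
}

#' Score miRNA-disease pairs with a fitted model
#'
#' @param object an `mdanet` fit.
#' @param pairs data.frame with `mirna` and `disease` columns; default: the
#'   training pairs.
#' @param ... unused.
#' @return numeric vector of association scores in [0, 1].
#' @export
predict.mdanet <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(predict(object$classifier, object$training))
  ds <- build_pair_features(object$embedding, pairs,
                            rep(0L, nrow(pairs)))
  predict(object$classifier, ds)
}

#' Rank candidate miRNAs for a disease with a fitted model
#' @param object an `mdanet` fit.
#' @param disease disease id.
#' @param top_n number of candidates to return.
#' @return a `ranked_predictions` object; see [rank_candidates()].
#' @export
candidate_ranking <- function(object, disease, top_n = 50L) {
  stopifnot(inherits(object, "mdanet"))
  pos <- object$training$pairs[object$training$labels == 1L, , drop = FALSE]
  rank_candidates(object$classifier, object$embedding, disease,
                  association_table(pos$mirna, pos$disease, "training"),
                  mirna_ids = object$network$index$mirnas, top_n = top_n)
}

#' Plot the auto-encoder training loss of a fitted model
#' @param x an `mdanet` fit (or a `stacked_autoencoder`).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mdanet <- function(x, ...) {
  loss <- x$autoencoder$loss
  ft <- loss$finetune
  plot(seq_along(ft), ft, type = "l", xlab = "fine-tuning epoch",
       ylab = "reconstruction MSE",
       main = "Stacked auto-encoder training", ...)
  abline(h = loss$pretrain_mse, lty = 2)
  legend("topright", lty = c(1, 2), bty = "n",
         legend = c("fine-tuning", "after pretraining"))
  invisible(x)
}

#' Residuals of a fitted association model
#'
#' Defined as observed label minus predicted association score on the
#' training pairs.
#'
#' @param object an `mdanet` fit.
#' @param ... unused.
#' @return numeric vector, one residual per training pair.
#' @export
residuals.mdanet <- function(object, ...) {
  object$training$labels - predict(object$classifier, object$training)
}
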