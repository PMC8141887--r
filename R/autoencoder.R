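# Stacked auto-encoder trained with greedy layer-wise pretraining followed by
# end-to-end fine-tuning on mean-squared reconstruction error. Pure matrix
# arithmetic, deterministic given the seed: Glorot-style uniform
# initialization and per-epoch mini-batch order are both drawn from one
# seeded stream.

#' Auto-encoder architecture and training specification
#'
#' @param hidden_dims sizes of the hidden layers, input to code (the input
#'   dimension is taken from the data at fit time); must be strictly
#'   decreasing and end in a code dimension >= 2.
#' @param epochs_pretrain pretraining epochs per layer.
#' @param epochs_finetune end-to-end fine-tuning epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate gradient-descent step size.
#' @param momentum classical momentum coefficient in [0, 1); 0 (default)
#'   is plain mini-batch gradient descent.
#' @param seed integer seed; together with the input it fully determines the
#'   trained weights.
#' @return list of class `encoder_spec`.
#' @export
encoder_spec <- function(hidden_dims = c(256L, 64L), epochs_pretrain = 50L,
                         epochs_finetune = 100L, batch_size = 32L,
                         learning_rate = 1e-3, momentum = 0, seed = 1L) {
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims) < 1L || any(diff(hidden_dims) >= 0L)) {
    stop("hidden_dims must be strictly decreasing")
  }
  if (hidden_dims[length(hidden_dims)] < 2L) stop("code dimension must be >= 2")
  spec <- list(hidden_dims = hidden_dims,
               epochs_pretrain = as.integer(epochs_pretrain),
               epochs_finetune = as.integer(epochs_finetune),
               batch_size = as.integer(batch_size),
               learning_rate = learning_rate,
               momentum = momentum,
               seed = as.integer(seed))
  if (spec$epochs_pretrain < 0L || spec$epochs_finetune < 0L) {
    stop("epoch counts must be non-negative")
  }
  if (spec$batch_size < 1L) stop("batch_size must be >= 1")
  if (spec$learning_rate <= 0) stop("learning_rate must be positive")
  if (spec$momentum < 0 || spec$momentum >= 1) {
    stop("momentum must be in [0, 1)")
  }
  class(spec) <- "encoder_spec"
  spec
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# One-hidden-layer auto-encoder: sigmoid hidden; reconstruction output is
# linear for the raw-input layer and sigmoid when the target is itself a
# hidden (sigmoid) representation, so that pretrained weights drop into the
# stacked decoder unchanged. Returns (W1, b1, W2, b2) and per-epoch MSE.
train_layer_ae <- function(X, hidden, spec, epochs, out_sigmoid = FALSE) {
  n <- nrow(X); d <- ncol(X)
  W1 <- glorot(d, hidden); b1 <- numeric(hidden)
  W2 <- glorot(hidden, d); b2 <- numeric(d)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  lr <- spec$learning_rate; mom <- spec$momentum
  forward <- function(Xin) {
    H <- sigmoid(sweep(Xin %*% W1, 2L, b1, `+`))
    R <- sweep(H %*% W2, 2L, b2, `+`)
    if (out_sigmoid) R <- sigmoid(R)
    list(H = H, R = R)
  }
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    order <- sample.int(n)
    for (start in seq(1L, n, by = spec$batch_size)) {
      rows <- order[start:min(start + spec$batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      fw <- forward(Xb)
      H <- fw$H; R <- fw$R
      E <- R - Xb
      if (out_sigmoid) E <- E * R * (1 - R)
      # loss = mean over samples of squared reconstruction error (summed
      # over features), the usual MSE convention for auto-encoders
      gscale <- 2 / length(rows)
      dH <- E %*% t(W2) * H * (1 - H)
      vW2 <- mom * vW2 - lr * gscale * crossprod(H, E)
      vb2 <- mom * vb2 - lr * gscale * colSums(E)
      vW1 <- mom * vW1 - lr * gscale * crossprod(Xb, dH)
      vb1 <- mom * vb1 - lr * gscale * colSums(dH)
      W2 <- W2 + vW2; b2 <- b2 + vb2
      W1 <- W1 + vW1; b1 <- b1 + vb1
    }
    R <- forward(X)$R
    trace[ep] <- mean((R - X)^2)       # reported per entry, like variance
    if (!is.finite(trace[ep])) {
      stop("non-finite pretraining loss at epoch ", ep)
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace)
}

stack_forward <- function(X, model) {
  enc <- list(X)
  H <- X
  for (layer in model$encoder) {
    H <- sigmoid(sweep(H %*% layer$W, 2L, layer$b, `+`))
    enc[[length(enc) + 1L]] <- H
  }
  dec <- list()
  L <- length(model$decoder)
  for (j in seq_len(L)) {
    layer <- model$decoder[[j]]
    H <- sweep(H %*% layer$W, 2L, layer$b, `+`)
    if (j < L) H <- sigmoid(H)         # linear output on the last layer
    dec[[j]] <- H
  }
  list(enc = enc, dec = dec, output = H)
}

finetune_step <- function(X, model, vel, lr, mom) {
  fw <- stack_forward(X, model)
  nE <- length(model$encoder)
  nD <- length(model$decoder)
  gscale <- 2 / nrow(X)
  delta <- fw$output - X               # linear final layer
  for (j in rev(seq_len(nD))) {
    inp <- if (j == 1L) fw$enc[[nE + 1L]] else fw$dec[[j - 1L]]
    gW <- crossprod(inp, delta)
    gb <- colSums(delta)
    delta <- delta %*% t(model$decoder[[j]]$W)
    if (j > 1L) delta <- delta * inp * (1 - inp)  # through sigmoid
    vel$decoder[[j]]$W <- mom * vel$decoder[[j]]$W - lr * gscale * gW
    vel$decoder[[j]]$b <- mom * vel$decoder[[j]]$b - lr * gscale * gb
    model$decoder[[j]]$W <- model$decoder[[j]]$W + vel$decoder[[j]]$W
    model$decoder[[j]]$b <- model$decoder[[j]]$b + vel$decoder[[j]]$b
  }
  # delta now holds the gradient wrt the code; each encoder output is a
  # sigmoid, so its derivative is applied at the top of the loop
  for (i in rev(seq_len(nE))) {
    out <- fw$enc[[i + 1L]]
    delta <- delta * out * (1 - out)
    inp <- fw$enc[[i]]
    gW <- crossprod(inp, delta)
    gb <- colSums(delta)
    delta <- delta %*% t(model$encoder[[i]]$W)
    vel$encoder[[i]]$W <- mom * vel$encoder[[i]]$W - lr * gscale * gW
    vel$encoder[[i]]$b <- mom * vel$encoder[[i]]$b - lr * gscale * gb
    model$encoder[[i]]$W <- model$encoder[[i]]$W + vel$encoder[[i]]$W
    model$encoder[[i]]$b <- model$encoder[[i]]$b + vel$encoder[[i]]$b
  }
  list(model = model, vel = vel)
}

#' Train a stacked auto-encoder on the rows of a matrix
#'
#' Greedy layer-wise pretraining (each layer learns to reconstruct the
#' previous layer's output) followed by end-to-end fine-tuning of the full
#' encoder-decoder on mean-squared reconstruction error.
#'
#' @param M numeric matrix; one training example per row (here: the enhanced
#'   proximity matrix, one row per network node).
#' @param spec an [encoder_spec()].
#' @return object of class `stacked_autoencoder` with `encoder`, `decoder`
#'   (lists of `W`/`b`), `loss` (`$pretrain` per-layer traces, `$finetune`
#'   trace, `$pretrain_mse`/`$finetune_mse` full-stack reconstruction MSE),
#'   `dims`, `spec`.
#' @export
train_autoencoder <- function(M, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  M <- unclass(M)
  attr(M, "beta") <- NULL; attr(M, "t") <- NULL
  dims <- c(ncol(M), spec$hidden_dims)
  if (any(diff(dims) >= 0L)) {
    stop("hidden_dims must be strictly decreasing from the input dimension (",
         ncol(M), ")")
  }
  if (nrow(M) < dims[length(dims)]) {
    stop("need at least code_dim = ", dims[length(dims)], " rows")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  encoder <- list(); decoder <- list(); pre_traces <- list()
  X <- M
  for (i in seq_along(spec$hidden_dims)) {
    ae <- train_layer_ae(X, spec$hidden_dims[i], spec, spec$epochs_pretrain,
                         out_sigmoid = (i > 1L))
    encoder[[i]] <- list(W = ae$W1, b = ae$b1)
    decoder <- c(list(list(W = ae$W2, b = ae$b2)), decoder)
    pre_traces[[i]] <- ae$trace
    X <- sigmoid(sweep(X %*% ae$W1, 2L, ae$b1, `+`))
  }
  model <- list(encoder = encoder, decoder = decoder, dims = dims, spec = spec)
  pretrain_mse <- mean((stack_forward(M, model)$output - M)^2)

  n <- nrow(M)
  zero_like <- function(layers) lapply(layers, function(l)
    list(W = l$W * 0, b = l$b * 0))
  vel <- list(encoder = zero_like(encoder), decoder = zero_like(decoder))
  ft_trace <- numeric(spec$epochs_finetune)
  for (ep in seq_len(spec$epochs_finetune)) {
    order <- sample.int(n)
    for (start in seq(1L, n, by = spec$batch_size)) {
      rows <- order[start:min(start + spec$batch_size - 1L, n)]
      step <- finetune_step(M[rows, , drop = FALSE], model, vel,
                            spec$learning_rate, spec$momentum)
      model <- step$model; vel <- step$vel
    }
    ft_trace[ep] <- mean((stack_forward(M, model)$output - M)^2)
    if (!is.finite(ft_trace[ep])) stop("non-finite fine-tune loss at epoch ", ep)
  }
  model$loss <- list(pretrain = pre_traces, finetune = ft_trace,
                     pretrain_mse = pretrain_mse,
                     finetune_mse = if (spec$epochs_finetune > 0L)
                       ft_trace[spec$epochs_finetune] else pretrain_mse)
  class(model) <- "stacked_autoencoder"
  model
}

#' @export
print.stacked_autoencoder <- function(x, ...) {
  cat("Stacked auto-encoder", paste(x$dims, collapse = " -> "),
      sprintf("| reconstruction MSE %.3g (pretrain %.3g)\n",
              x$loss$finetune_mse, x$loss$pretrain_mse))
  invisible(x)
}

#' Encode matrix rows into low-dimensional codes
#'
#' Deterministic forward pass through the trained encoder; row `i` of the
#' result is the code of input row `i`.
#'
#' @param model a `stacked_autoencoder`.
#' @param M matrix with `ncol(M)` equal to the model's input dimension.
#' @return numeric matrix `n x code_dim`; row names are carried over.
#' @export
encode <- function(model, M) {
  stopifnot(inherits(model, "stacked_autoencoder"))
  M <- unclass(M)
  if (ncol(M) != model$dims[1L]) {
    stop("input has ", ncol(M), " columns; model expects ", model$dims[1L])
  }
  H <- M
  for (layer in model$encoder) {
    H <- sigmoid(sweep(H %*% layer$W, 2L, layer$b, `+`))
  }
  rownames(H) <- rownames(M)
  H
}

#' Reconstruct matrix rows through the full encoder-decoder
#' @param model a `stacked_autoencoder`.
#' @param M input matrix.
#' @return reconstruction matrix of the same shape.
#' @export
reconstruct <- function(model, M) {
  stopifnot(inherits(model, "stacked_autoencoder"))
  M <- unclass(M)
  if (ncol(M) != model$dims[1L]) {
    stop("input has ", ncol(M), " columns; model expects ", model$dims[1L])
  }
  stack_forward(M, model)$output
}
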