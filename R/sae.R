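# Stacked autoencoder: greedy unsupervised layer-wise pretraining, then
# supervised fine-tuning with an appended 2-unit label layer. Implemented
# with dense base-R matrices and full-batch Adam; at this problem scale
# (hundreds of features, tens of subjects) that is both fast and exactly
# reproducible.

#' Stacked-autoencoder training hyperparameters
#'
#' @param pretrain_epochs Full-batch epochs per autoencoder during greedy
#'   pretraining (default 30).
#' @param finetune_epochs Full-batch epochs of supervised fine-tuning
#'   (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @return List of class `sae_hyper`.
#' @export
sae_hyper <- function(pretrain_epochs = 30L, finetune_epochs = 100L,
                      learning_rate = 1e-3) {
  stopifnot(pretrain_epochs >= 0, finetune_epochs >= 0, learning_rate > 0)
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = as.numeric(learning_rate)),
            class = "sae_hyper")
}

# Glorot-uniform weight matrix (n_out x n_in)
glorot <- function(n_out, n_in) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -r, r), n_out, n_in)
}

# One Adam step over a list of parameter matrices/vectors.
adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

adam_init <- function(params) {
  list(t = 0, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Train a single autoencoder (sigmoid encoder, linear decoder, MSE loss) on
# input h; returns encoder weights and the per-epoch loss trace.
train_autoencoder <- function(h, n_hidden, epochs, lr, seed) {
  n <- nrow(h); d <- ncol(h)
  params <- with_seed(seed, list(W = glorot(n_hidden, d), b = numeric(n_hidden),
                                 V = glorot(d, n_hidden), cvec = numeric(d)))
  st <- adam_init(params)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    z <- h %*% t(params$W) + rep(params$b, each = n)
    act <- sigmoid(z)
    rec <- act %*% t(params$V) + rep(params$cvec, each = n)
    err <- rec - h
    losses[ep] <- mean(err^2)
    if (!is.finite(losses[ep])) {
      stop(sprintf("non-finite pretraining loss in %d-unit autoencoder (lr = %g)",
                   n_hidden, lr))
    }
    drec <- 2 * err / (n * d)
    grads <- list(
      W = t(((drec %*% params$V) * act * (1 - act))) %*% h,
      b = colSums((drec %*% params$V) * act * (1 - act)),
      V = t(drec) %*% act,
      cvec = colSums(drec)
    )
    up <- adam_step(st, params, grads, lr)
    st <- up$state; params <- up$params
  }
  list(W = params$W, b = params$b, losses = losses)
}

#' Greedy layer-wise pretraining of the autoencoder stack
#'
#' Sequentially trains one autoencoder per hidden layer: the first
#' reconstructs the (standardized) input, each subsequent one reconstructs
#' the hidden code of its predecessor. Returns the encoder weights that
#' initialize supervised fine-tuning.
#'
#' @param x Standardized feature matrix (subjects x features).
#' @param layer_sizes Strictly decreasing hidden-layer widths
#'   (default `c(128, 64, 32, 10)`).
#' @param hyper A [sae_hyper()].
#' @param seed Seed for weight initialization (one derived seed per layer).
#' @return List with `W` (list of encoder weight matrices, each
#'   `size(l_{i+1}) x size(l_i)`), `b` (bias list), `layer_sizes` including
#'   the input width, and `pretrain_log`.
#' @export
pretrain_autoencoders <- function(x, layer_sizes = c(128L, 64L, 32L, 10L),
                                  hyper = sae_hyper(), seed = 1L) {
  x <- as.matrix(x)
  sizes <- c(ncol(x), as.integer(layer_sizes))
  if (any(diff(sizes) >= 0)) {
    stop("layer sizes must be strictly decreasing from the input width")
  }
  w <- list(); b <- list(); logs <- list()
  h <- x
  for (i in seq_along(layer_sizes)) {
    ae <- train_autoencoder(h, sizes[i + 1], hyper$pretrain_epochs,
                            hyper$learning_rate, seed = derive_seed(seed, i))
    w[[i]] <- ae$W; b[[i]] <- ae$b; logs[[i]] <- ae$losses
    h <- sigmoid(h %*% t(ae$W) + rep(ae$b, each = nrow(h)))
  }
  list(W = w, b = b, layer_sizes = sizes, pretrain_log = logs)
}

# forward pass through the encoder; returns list of activations per layer
# (a[[1]] = input, a[[length]] = deepest code)
sae_forward <- function(w, b, x) {
  a <- vector("list", length(w) + 1)
  a[[1]] <- x
  for (i in seq_along(w)) {
    a[[i + 1]] <- sigmoid(a[[i]] %*% t(w[[i]]) + rep(b[[i]], each = nrow(x)))
  }
  a
}

#' Supervised fine-tuning with a label layer
#'
#' Stacks the pretrained encoders, appends a 2-unit softmax label layer, and
#' trains the whole network end to end with cross-entropy loss. The label
#' layer is retained on the returned model for feature attribution.
#'
#' @param init Output of [pretrain_autoencoders()].
#' @param x Standardized feature matrix used for pretraining.
#' @param y Binary factor of group labels (first level = positive class).
#' @param hyper A [sae_hyper()].
#' @param seed Seed for label-layer initialization.
#' @return An object of class `sae_model` with weights `W` (list), biases
#'   `b`, label layer `W_label`/`b_label`, `layer_sizes`, `levels`, and
#'   `finetune_log`.
#' @export
fine_tune_supervised <- function(init, x, y, hyper = sae_hyper(), seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  n <- nrow(x)
  yi <- as.integer(y)
  ymat <- matrix(0, n, 2); ymat[cbind(seq_len(n), yi)] <- 1
  w <- init$W; b <- init$b
  lab <- with_seed(seed, list(W = glorot(2, utils::tail(init$layer_sizes, 1)),
                              b = numeric(2)))
  params <- c(w, b, list(lab$W, lab$b))
  st <- adam_init(params)
  nl <- length(w)
  losses <- numeric(hyper$finetune_epochs)
  for (ep in seq_len(hyper$finetune_epochs)) {
    a <- sae_forward(params[seq_len(nl)], params[nl + seq_len(nl)], x)
    zo <- a[[nl + 1]] %*% t(params[[2 * nl + 1]]) + rep(params[[2 * nl + 2]], each = n)
    zo <- zo - apply(zo, 1, max)
    p <- exp(zo) / rowSums(exp(zo))
    losses[ep] <- -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-12)))
    if (!is.finite(losses[ep])) stop("non-finite fine-tuning loss")
    dz <- (p - ymat) / n
    grads <- vector("list", length(params))
    grads[[2 * nl + 1]] <- t(dz) %*% a[[nl + 1]]
    grads[[2 * nl + 2]] <- colSums(dz)
    da <- dz %*% params[[2 * nl + 1]]
    for (i in nl:1) {
      dzi <- da * a[[i + 1]] * (1 - a[[i + 1]])
      grads[[i]] <- t(dzi) %*% a[[i]]
      grads[[nl + i]] <- colSums(dzi)
      if (i > 1) da <- dzi %*% params[[i]]
    }
    up <- adam_step(st, params, grads, hyper$learning_rate)
    st <- up$state; params <- up$params
  }
  structure(
    list(W = params[seq_len(nl)], b = params[nl + seq_len(nl)],
         W_label = params[[2 * nl + 1]], b_label = params[[2 * nl + 2]],
         layer_sizes = init$layer_sizes, levels = levels(y),
         pretrain_log = init$pretrain_log, finetune_log = losses,
         hyper = hyper),
    class = "sae_model"
  )
}

#' Encode features to the deepest hidden representation
#'
#' Deterministic forward pass through the fine-tuned encoder stack to the
#' final hidden layer (the low-dimensional code fed to the SVM).
#'
#' @param model An [fine_tune_supervised()] `sae_model`.
#' @param x Feature matrix with the training column order.
#' @return Matrix of codes, `nrow(x)` x deepest-layer width.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "sae_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$layer_sizes[1]) {
    stop(sprintf("x has %d columns; model expects %d", ncol(x),
                 model$layer_sizes[1]))
  }
  a <- sae_forward(model$W, model$b, x)
  a[[length(a)]]
}

#' Class probabilities from the fine-tuned label layer
#'
#' @param model An `sae_model`.
#' @param x Feature matrix with the training column order.
#' @return Matrix of per-class softmax probabilities (columns = class levels).
#' @export
sae_predict <- function(model, x) {
  z <- encode(model, x)
  zo <- z %*% t(model$W_label) + rep(model$b_label, each = nrow(z))
  zo <- zo - apply(zo, 1, max)
  p <- exp(zo) / rowSums(exp(zo))
  colnames(p) <- model$levels
  p
}
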