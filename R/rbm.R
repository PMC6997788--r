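# Restricted Boltzmann machines: the bipartite energy model
# E(v,h) = -(a'v + b'h + v' omega h), contrastive-divergence (CD-1)
# pretraining of a two-RBM stack, and the RBM-CapsNet built on top of it
# (dense 179 -> 256 -> 128 feature extractor initialized from the pretrained
# weights, then a capsule head fine-tuned end-to-end).

#' RBM-CapsNet hyperparameters
#'
#' Defaults are the tuned settings of the published architecture: two RBMs
#' of 256 and 128 hidden units, 100 CD-1 epochs at learning rate 0.001,
#' 200 fine-tuning epochs with Adam at learning rate 0.005, ReLU activations
#' in the fine-tuned network, batch size 148, 2 routing iterations, primary
#' capsules of dimension 8 (16 capsules from the 128-node layer), and two
#' 2-dimensional output capsules.
#'
#' @param n_rbms Number of stacked RBMs (the assembled network supports 2).
#' @param hidden_sizes Hidden-unit counts of the RBMs, visible-to-deep.
#' @param rbm_epochs CD-1 pretraining epochs per RBM.
#' @param finetune_epochs Maximum end-to-end fine-tuning epochs.
#' @param rbm_lr CD-1 learning rate.
#' @param network_lr Fine-tuning learning rate.
#' @param activation Fine-tuning activation; only \code{"relu"}.
#' @param batch_size Mini-batch size (pretraining and fine-tuning).
#' @param optimizer Fine-tuning optimizer, \code{"adam"} or \code{"sgd"}.
#' @param routing_iterations Dynamic routing passes.
#' @param capsule_dim Dimension of each primary capsule.
#' @param n_classes Number of output capsules.
#' @param digitcaps_dim Dimension of each output capsule.
#' @return A list of class \code{rbm_hyperparams}.
#' @export
rbm_hyperparams <- function(n_rbms = 2L, hidden_sizes = c(256L, 128L),
                            rbm_epochs = 100L, finetune_epochs = 200L,
                            rbm_lr = 0.001, network_lr = 0.005,
                            activation = "relu", batch_size = 148L,
                            optimizer = "adam", routing_iterations = 2L,
                            capsule_dim = 8L, n_classes = 2L,
                            digitcaps_dim = 2L) {
  if (!identical(tolower(activation), "relu"))
    stop("only the rectified linear activation ('relu') is supported")
  optimizer <- match.arg(tolower(optimizer), c("adam", "sgd"))
  stopifnot(n_rbms >= 1, length(hidden_sizes) == n_rbms,
            all(hidden_sizes >= 1), rbm_epochs >= 0, finetune_epochs >= 0,
            rbm_lr >= 0, network_lr >= 0, batch_size >= 1,
            routing_iterations >= 1, capsule_dim >= 1, n_classes >= 2,
            digitcaps_dim >= 1)
  pc <- hidden_sizes[length(hidden_sizes)]
  if (pc %% capsule_dim != 0)
    stop("the deepest hidden size must be a multiple of capsule_dim")
  structure(list(
    n_rbms = as.integer(n_rbms), hidden_sizes = as.integer(hidden_sizes),
    rbm_epochs = as.integer(rbm_epochs),
    finetune_epochs = as.integer(finetune_epochs),
    rbm_lr = rbm_lr, network_lr = network_lr, activation = "relu",
    batch_size = as.integer(batch_size), optimizer = optimizer,
    routing_iterations = as.integer(routing_iterations),
    capsule_dim = as.integer(capsule_dim), n_classes = as.integer(n_classes),
    digitcaps_dim = as.integer(digitcaps_dim)), class = "rbm_hyperparams")
}

#' Initialize one RBM
#'
#' @param n_visible,n_hidden Unit counts.
#' @param seed Optional integer seed; \code{NULL} continues the current RNG
#'   stream.
#' @param sd Standard deviation of the (truncated) normal weight draw.
#' @return A list of class \code{rbm_params} with visible biases \code{a},
#'   hidden biases \code{b}, and weight matrix \code{omega}
#'   (\code{n_visible x n_hidden}).
#' @export
init_rbm <- function(n_visible, n_hidden, seed = NULL, sd = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(a = numeric(n_visible), b = numeric(n_hidden),
                 omega = tnorm_mat(n_visible, n_hidden, sd)),
            class = "rbm_params")
}

#' RBM energy
#'
#' Evaluates \eqn{E(v, h) = -(a^T v + b^T h + v^T \omega h)}.
#'
#' @param v Visible vector.
#' @param h Hidden vector.
#' @param p An \code{\link{init_rbm}} parameter list.
#' @return Scalar energy.
#' @export
rbm_energy <- function(v, h, p) {
  stopifnot(length(v) == length(p$a), length(h) == length(p$b))
  -(sum(p$a * v) + sum(p$b * h) + drop(t(v) %*% p$omega %*% h))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One contrastive-divergence (CD-1) update
#'
#' Hidden probabilities are logistic, hidden states are Bernoulli samples,
#' the visible reconstruction uses mean-field probabilities, and the
#' gradient is the difference of the data and reconstruction statistics
#' \eqn{\langle v h^T \rangle_{data} - \langle v h^T \rangle_{recon}}
#' (batch-averaged), applied with the given learning rate.
#'
#' @param p An \code{rbm_params} list.
#' @param batch Matrix of visible vectors with values in \eqn{[0, 1]}
#'   (min-max-scaled features are treated as Bernoulli probabilities).
#' @param lr Learning rate.
#' @param seed Optional seed for the Bernoulli hidden sampling; \code{NULL}
#'   continues the current RNG stream.
#' @return List with the updated \code{params} and the mean squared
#'   \code{reconstruction_error} of the batch.
#' @export
cd_update <- function(p, batch, lr, seed = NULL) {
  batch <- as.matrix(batch)
  if (any(batch < 0 | batch > 1))
    stop("visible values must lie in [0, 1]")
  stopifnot(ncol(batch) == length(p$a))
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(batch)
  h0p <- sigmoid(batch %*% p$omega + rowrep(p$b, B))
  h0s <- matrix(stats::rbinom(length(h0p), 1L, as.vector(h0p)), nrow = B)
  v1p <- sigmoid(h0s %*% t(p$omega) + rowrep(p$a, B))
  h1p <- sigmoid(v1p %*% p$omega + rowrep(p$b, B))
  gW <- (t(batch) %*% h0p - t(v1p) %*% h1p) / B
  ga <- colMeans(batch) - colMeans(v1p)
  gb <- colMeans(h0p) - colMeans(h1p)
  p$omega <- p$omega + lr * gW
  p$a <- p$a + lr * ga
  p$b <- p$b + lr * gb
  list(params = p, reconstruction_error = mean((batch - v1p)^2))
}

# Hidden mean-field activations of an RBM for a data matrix.
rbm_hidden_probs <- function(p, X) {
  sigmoid(as.matrix(X) %*% p$omega + rowrep(p$b, nrow(X)))
}

#' Greedy layer-wise pretraining of the RBM stack
#'
#' The first RBM is trained by CD-1 on the scaled features; each subsequent
#' RBM is trained on the hidden (mean-field) probabilities of the previous
#' one.
#'
#' @param x Matrix of scaled features (values in \eqn{[0, 1]}).
#' @param hyper An \code{\link{rbm_hyperparams}} object.
#' @param seed Integer seed.
#' @param verbose Print the reconstruction error once per epoch.
#' @return List of \code{rbm_params}, one per RBM, with the per-epoch mean
#'   reconstruction errors attached as attribute \code{"recon_errors"}.
#' @export
pretrain_stack <- function(x, hyper = rbm_hyperparams(), seed = 1L,
                           verbose = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("pretraining data is empty")
  set.seed(seed)
  stack <- vector("list", hyper$n_rbms)
  inp <- x
  for (r in seq_len(hyper$n_rbms)) {
    p <- init_rbm(ncol(inp), hyper$hidden_sizes[r])
    errs <- numeric(hyper$rbm_epochs)
    n <- nrow(inp)
    for (epoch in seq_len(hyper$rbm_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = hyper$batch_size)
      tot <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + hyper$batch_size - 1L, n)]
        up <- cd_update(p, inp[idx, , drop = FALSE], hyper$rbm_lr)
        p <- up$params
        tot <- tot + up$reconstruction_error * length(idx)
      }
      errs[epoch] <- tot / n
      if (verbose)
        message(sprintf("RBM %d epoch %d recon_error %.6f", r, epoch,
                        errs[epoch]))
    }
    attr(p, "recon_errors") <- errs
    stack[[r]] <- p
    inp <- rbm_hidden_probs(p, inp)
  }
  stack
}

#' Assemble an RBM-CapsNet from a pretrained stack
#'
#' The dense feature-extraction layers take their weights and biases from
#' the pretrained RBMs (weight matrix \code{omega} and hidden bias \code{b};
#' visible biases have no feed-forward analogue and are discarded). The
#' routing weights are drawn fresh from a truncated normal (sd 0.01).
#'
#' @param stack List of 2 \code{rbm_params} with compatible shapes
#'   (visible -> first hidden -> PrimaryCaps).
#' @param hyper An \code{\link{rbm_hyperparams}} object.
#' @param seed Integer seed for the routing-weight draw.
#' @return An object of class \code{rbm_capsnet}.
#' @export
init_rbm_capsnet <- function(stack, hyper = rbm_hyperparams(), seed = 1L) {
  if (length(stack) != 2L)
    stop("the assembled network requires a stack of exactly 2 RBMs")
  s1 <- stack[[1L]]; s2 <- stack[[2L]]
  if (ncol(s1$omega) != nrow(s2$omega))
    stop("RBM stack shapes are inconsistent (wrong order?)")
  if (ncol(s1$omega) != hyper$hidden_sizes[1L] ||
      ncol(s2$omega) != hyper$hidden_sizes[2L])
    stop("RBM stack shapes do not match the hyperparameters")
  set.seed(seed)
  n_caps <- hyper$hidden_sizes[2L] %/% hyper$capsule_dim
  params <- list(
    W1 = s1$omega, b1 = s1$b,
    W2 = s2$omega, b2 = s2$b,
    Wij = array(tnorm(n_caps * hyper$n_classes *
                        hyper$digitcaps_dim * hyper$capsule_dim),
                dim = c(n_caps, hyper$n_classes,
                        hyper$digitcaps_dim, hyper$capsule_dim)))
  structure(list(params = params, hyper = hyper,
                 input_len = nrow(s1$omega), seed = as.integer(seed)),
            class = "rbm_capsnet")
}

rbm_forward_full <- function(params, hyper, X) {
  H1 <- dense_forward(X, params$W1, params$b1)
  A1 <- relu(H1)
  H2 <- dense_forward(A1, params$W2, params$b2)
  A2 <- relu(H2)
  u <- encapsule(A2, dim(params$Wij)[1L], hyper$capsule_dim)
  u_hat <- predict_vectors_batch(u, params$Wij)
  fw <- routing_forward(u_hat, hyper$routing_iterations)
  list(lengths = fw$lengths, v = fw$v, routing = fw, u = u,
       H1 = H1, A1 = A1, H2 = H2, A2 = A2)
}

rbm_backward_full <- function(params, hyper, X, fw, g_lengths) {
  gv <- lengths_backward(fw$v, fw$lengths, g_lengths)
  gu_hat <- routing_backward(fw$routing, gv)
  pv <- predict_vectors_backward(fw$u, params$Wij, gu_hat)
  gA2 <- decapsule_grad(pv$gu)
  gH2 <- relu_backward(fw$H2, gA2)
  d2 <- dense_backward(fw$A1, params$W2, gH2)
  gH1 <- relu_backward(fw$H1, d2$gX)
  d1 <- dense_backward(X, params$W1, gH1)
  list(W1 = d1$gW, b1 = d1$gb, W2 = d2$gW, b2 = d2$gb, Wij = pv$gW)
}

#' Forward pass of an RBM-CapsNet
#'
#' @param model An \code{rbm_capsnet} object.
#' @param x Matrix of scaled feature vectors.
#' @return List with \code{lengths} and \code{v} as in
#'   \code{\link{forward_conv}}.
#' @export
forward_rbm <- function(model, x) {
  stopifnot(inherits(model, "rbm_capsnet"))
  x <- as.matrix(x)
  if (ncol(x) != model$input_len)
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(x), model$input_len))
  fw <- rbm_forward_full(model$params, model$hyper, x)
  list(lengths = fw$lengths, v = fw$v)
}

#' Fine-tune an RBM-CapsNet end-to-end
#'
#' All parameters (both dense layers and the routing weights) are updated by
#' backpropagation through the routing iterations on the margin loss.
#'
#' @param model An \code{rbm_capsnet} from \code{\link{init_rbm_capsnet}}.
#' @param x,y Scaled features and binary labels.
#' @param seed Integer seed (validation split and shuffling).
#' @param val_x,val_y Optional validation set; see
#'   \code{\link{train_conv_capsnet}}.
#' @param early_stop An \code{\link{early_stop_config}} or \code{NULL}.
#' @param loss_params Margin-loss margins.
#' @param verbose,log_file Per-epoch logging.
#' @return List with \code{model} and \code{history}.
#' @export
finetune_rbm_capsnet <- function(model, x, y, seed = 1L,
                                 val_x = NULL, val_y = NULL,
                                 early_stop = early_stop_config(),
                                 loss_params = margin_loss_params(),
                                 verbose = FALSE, log_file = NULL) {
  stopifnot(inherits(model, "rbm_capsnet"))
  x <- as.matrix(x); y <- as.integer(y)
  check_two_classes(y)
  hyper <- model$hyper
  if (is.null(val_x) && !is.null(early_stop)) {
    sp <- split_train_val(y, fraction = early_stop$fraction, seed = seed)
    val_x <- x[sp$val, , drop = FALSE]; val_y <- y[sp$val]
    x <- x[sp$train, , drop = FALSE]; y <- y[sp$train]
  }
  step_fn <- function(params, stats, xb, Tb) {
    fw <- rbm_forward_full(params, hyper, xb)
    loss <- margin_loss(fw$lengths, Tb, loss_params)
    gl <- margin_loss_backward(fw$lengths, Tb, loss_params)
    grads <- rbm_backward_full(params, hyper, xb, fw, gl)
    list(loss = loss, grads = grads, stats = stats)
  }
  eval_fn <- function(params, stats, xx) {
    fw <- rbm_forward_full(params, hyper, xx)
    list(lengths = fw$lengths)
  }
  out <- train_loop(model$params, list(), step_fn, eval_fn,
                    x, y, epochs = hyper$finetune_epochs,
                    batch_size = hyper$batch_size,
                    lr = hyper$network_lr, optimizer = hyper$optimizer,
                    loss_params = loss_params,
                    val_x = val_x, val_y = val_y, early_stop = early_stop,
                    seed = seed, verbose = verbose, log_file = log_file)
  model$params <- out$params
  list(model = model, history = out$history)
}

#' Pretrain and fine-tune an RBM-CapsNet
#'
#' Convenience wrapper: greedy CD-1 pretraining of the RBM stack, assembly,
#' then end-to-end fine-tuning.
#'
#' @inheritParams finetune_rbm_capsnet
#' @param hyper An \code{\link{rbm_hyperparams}} object.
#' @return List with \code{model}, \code{history} (fine-tuning), and
#'   \code{stack} (the pretrained RBMs).
#' @export
train_rbm_capsnet <- function(x, y, hyper = rbm_hyperparams(), seed = 1L,
                              val_x = NULL, val_y = NULL,
                              early_stop = early_stop_config(),
                              loss_params = margin_loss_params(),
                              verbose = FALSE, log_file = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  check_two_classes(y)
  if (is.null(val_x) && !is.null(early_stop)) {
    sp <- split_train_val(y, fraction = early_stop$fraction, seed = seed)
    val_x <- x[sp$val, , drop = FALSE]; val_y <- y[sp$val]
    x <- x[sp$train, , drop = FALSE]; y <- y[sp$train]
  }
  stack <- pretrain_stack(x, hyper, seed = seed, verbose = verbose)
  model <- init_rbm_capsnet(stack, hyper, seed = seed)
  ft <- finetune_rbm_capsnet(model, x, y, seed = seed,
                             val_x = val_x, val_y = val_y,
                             early_stop = early_stop,
                             loss_params = loss_params,
                             verbose = verbose, log_file = log_file)
  list(model = ft$model, history = ft$history, stack = stack)
}

#' Predict with a trained RBM-CapsNet
#'
#' @param object An \code{rbm_capsnet} model.
#' @param newdata Matrix of scaled feature vectors.
#' @param ... Unused.
#' @return Data frame with \code{label}, \code{score}, and both capsule
#'   lengths.
#' @export
predict.rbm_capsnet <- function(object, newdata, ...) {
  fw <- forward_rbm(object, newdata)
  out <- classify_capsules(fw$lengths)
  out$len_nonblocker <- fw$lengths[, 1L]
  out$len_blocker <- fw$lengths[, 2L]
  out
}
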