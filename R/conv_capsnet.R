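# Conv-CapsNet: 1-d convolution -> ReLU -> batch norm -> flatten -> dense
# hidden feature layer -> ReLU -> batch norm -> dense PrimaryCaps layer ->
# capsules -> dynamic routing -> DigitCaps lengths. Trained end-to-end on the
# margin loss plus an L2 penalty on the convolution weights.

#' Conv-CapsNet hyperparameters
#'
#' Defaults are the tuned settings of the published architecture: L2
#' coefficient 0.001 on the convolution weights, ReLU activations, batch
#' size 148, 300 epochs, Adam at learning rate 0.001, 32 filters of width 3,
#' a 128-node hidden feature layer, a 64-node PrimaryCaps layer grouped into
#' 8 capsules of dimension 8, and 2 routing iterations to 2 output capsules
#' of dimension 2.
#'
#' @param l2 L2 regularization coefficient.
#' @param activation Activation function name; only \code{"relu"} is
#'   supported.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of training epochs.
#' @param learning_rate Optimizer learning rate.
#' @param optimizer \code{"adam"} or \code{"sgd"}.
#' @param filters Number of convolution filters.
#' @param kernel_size Convolution kernel width (stride 1, no padding).
#' @param hidden_nodes Width of the dense hidden feature layer.
#' @param primarycaps_nodes Width of the PrimaryCaps layer; must be a
#'   multiple of \code{capsule_dim}.
#' @param routing_iterations Dynamic routing passes.
#' @param capsule_dim Dimension of each primary capsule.
#' @param n_classes Number of output capsules (2 for blocker/nonblocker).
#' @param digitcaps_dim Dimension of each output capsule.
#' @param l2_scope \code{"conv"} (default) penalizes only the convolution
#'   weights; \code{"all"} penalizes every weight matrix.
#' @return A list of class \code{conv_hyperparams}.
#' @export
conv_hyperparams <- function(l2 = 0.001, activation = "relu",
                             batch_size = 148L, epochs = 300L,
                             learning_rate = 0.001, optimizer = "adam",
                             filters = 32L, kernel_size = 3L,
                             hidden_nodes = 128L, primarycaps_nodes = 64L,
                             routing_iterations = 2L, capsule_dim = 8L,
                             n_classes = 2L, digitcaps_dim = 2L,
                             l2_scope = c("conv", "all")) {
  if (!identical(tolower(activation), "relu"))
    stop("only the rectified linear activation ('relu') is supported")
  optimizer <- match.arg(tolower(optimizer), c("adam", "sgd"))
  l2_scope <- match.arg(l2_scope)
  stopifnot(l2 >= 0, batch_size >= 1, epochs >= 0, learning_rate >= 0,
            filters >= 1, kernel_size >= 1, hidden_nodes >= 1,
            primarycaps_nodes >= 1, routing_iterations >= 1,
            capsule_dim >= 1, n_classes >= 2, digitcaps_dim >= 1)
  if (primarycaps_nodes %% capsule_dim != 0)
    stop("primarycaps_nodes must be a multiple of capsule_dim")
  structure(list(
    l2 = l2, activation = "relu", batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    optimizer = optimizer, filters = as.integer(filters),
    kernel_size = as.integer(kernel_size),
    hidden_nodes = as.integer(hidden_nodes),
    primarycaps_nodes = as.integer(primarycaps_nodes),
    routing_iterations = as.integer(routing_iterations),
    capsule_dim = as.integer(capsule_dim),
    n_classes = as.integer(n_classes),
    digitcaps_dim = as.integer(digitcaps_dim),
    l2_scope = l2_scope), class = "conv_hyperparams")
}

#' Initialize a Conv-CapsNet
#'
#' Weights are drawn from a truncated normal distribution (standard
#' deviation 0.01, truncated at two standard deviations); biases start at
#' zero, batch-norm scales at one.
#'
#' @param hyper A \code{\link{conv_hyperparams}} object.
#' @param seed Integer seed making initialization reproducible.
#' @param input_len Length of the input feature vector (179 for the MACCS +
#'   descriptor characterization).
#' @return An object of class \code{conv_capsnet}.
#' @export
init_conv_capsnet <- function(hyper = conv_hyperparams(), seed = 1L,
                              input_len = 179L) {
  set.seed(seed)
  Fk <- hyper$filters; k <- hyper$kernel_size
  L <- input_len - k + 1L
  if (L < 1L) stop("kernel_size exceeds input length")
  flat <- L * Fk
  n_caps <- hyper$primarycaps_nodes %/% hyper$capsule_dim
  params <- list(
    CW = tnorm_mat(k, Fk),
    cb = numeric(Fk),
    g1 = rep(1, Fk), be1 = numeric(Fk),
    W1 = tnorm_mat(flat, hyper$hidden_nodes),
    b1 = numeric(hyper$hidden_nodes),
    g2 = rep(1, hyper$hidden_nodes), be2 = numeric(hyper$hidden_nodes),
    W2 = tnorm_mat(hyper$hidden_nodes, hyper$primarycaps_nodes),
    b2 = numeric(hyper$primarycaps_nodes),
    Wij = array(tnorm(n_caps * hyper$n_classes *
                        hyper$digitcaps_dim * hyper$capsule_dim),
                dim = c(n_caps, hyper$n_classes,
                        hyper$digitcaps_dim, hyper$capsule_dim)))
  stats <- list(rm1 = numeric(Fk), rv1 = rep(1, Fk),
                rm2 = numeric(hyper$hidden_nodes),
                rv2 = rep(1, hyper$hidden_nodes))
  structure(list(params = params, stats = stats, hyper = hyper,
                 input_len = as.integer(input_len), seed = as.integer(seed)),
            class = "conv_capsnet")
}

# Reshape the PrimaryCaps activations (B x n_caps*d) into capsules
# (B x n_caps x d); each capsule takes a contiguous block of d values.
encapsule <- function(P, n_caps, d) {
  aperm(array(P, dim = c(nrow(P), d, n_caps)), c(1L, 3L, 2L))
}

decapsule_grad <- function(gu) {
  d <- dim(gu)
  matrix(aperm(gu, c(1L, 3L, 2L)), nrow = d[1L])
}

# Full forward pass with cache. params/stats as in init_conv_capsnet.
conv_forward_full <- function(params, stats, hyper, X, training) {
  cv <- conv1d_forward(X, params$CW, params$cb)
  A1 <- relu(cv$R)
  bn1 <- bn_forward(A1, params$g1, params$be1, stats$rm1, stats$rv1, training)
  flat <- matrix(array(bn1$Y, dim = c(cv$B, cv$L, hyper$filters)), nrow = cv$B)
  H1 <- dense_forward(flat, params$W1, params$b1)
  A2 <- relu(H1)
  bn2 <- bn_forward(A2, params$g2, params$be2, stats$rm2, stats$rv2, training)
  P <- dense_forward(bn2$Y, params$W2, params$b2)
  u <- encapsule(P, dim(params$Wij)[1L], hyper$capsule_dim)
  u_hat <- predict_vectors_batch(u, params$Wij)
  fw <- routing_forward(u_hat, hyper$routing_iterations)
  if (training) stats <- list(rm1 = bn1$run_mean, rv1 = bn1$run_var,
                              rm2 = bn2$run_mean, rv2 = bn2$run_var)
  list(lengths = fw$lengths, v = fw$v, routing = fw, u = u,
       cv = cv, A1 = A1, bn1 = bn1, flat = flat, H1 = H1, A2 = A2, bn2 = bn2,
       P = P, stats = stats)
}

# Backward pass from a gradient on the capsule lengths. Returns grads named
# like params (including the L2 term on the penalized weights).
conv_backward_full <- function(params, hyper, X, fw, g_lengths) {
  gv <- lengths_backward(fw$v, fw$lengths, g_lengths)
  gu_hat <- routing_backward(fw$routing, gv)
  pv <- predict_vectors_backward(fw$u, params$Wij, gu_hat)
  gP <- decapsule_grad(pv$gu)
  d2 <- dense_backward(fw$bn2$Y, params$W2, gP)
  bb2 <- bn_backward(fw$bn2, params$g2, d2$gX)
  gH1 <- relu_backward(fw$H1, bb2$gX)
  d1 <- dense_backward(fw$flat, params$W1, gH1)
  B <- nrow(X); L <- fw$cv$L
  gbn1Y <- matrix(array(d1$gX, dim = c(B, L, hyper$filters)), nrow = B * L)
  bb1 <- bn_backward(fw$bn1, params$g1, gbn1Y)
  gR <- relu_backward(fw$cv$R, bb1$gX)
  cvb <- conv1d_backward(fw$cv, params$CW, gR)
  grads <- list(CW = cvb$gCW, cb = cvb$gcb,
                g1 = bb1$ggamma, be1 = bb1$gbeta,
                W1 = d1$gW, b1 = d1$gb,
                g2 = bb2$ggamma, be2 = bb2$gbeta,
                W2 = d2$gW, b2 = d2$gb,
                Wij = pv$gW)
  grads$CW <- grads$CW + 2 * hyper$l2 * params$CW
  if (hyper$l2_scope == "all") {
    for (nm in c("W1", "W2", "Wij"))
      grads[[nm]] <- grads[[nm]] + 2 * hyper$l2 * params[[nm]]
  }
  grads
}

conv_l2_penalty <- function(params, hyper) {
  pen <- sum(params$CW^2)
  if (hyper$l2_scope == "all")
    pen <- pen + sum(params$W1^2) + sum(params$W2^2) + sum(params$Wij^2)
  hyper$l2 * pen
}

#' Forward pass of a Conv-CapsNet
#'
#' @param model A \code{conv_capsnet} object.
#' @param x Matrix of scaled feature vectors (one row per molecule).
#' @param training If \code{TRUE}, batch normalization uses batch statistics
#'   (and the returned model is not updated); inference mode (default) uses
#'   the stored running averages.
#' @return List with \code{lengths} (matrix, one row per sample, one column
#'   per class) and \code{v} (output capsule array).
#' @export
forward_conv <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "conv_capsnet"))
  x <- as.matrix(x)
  if (ncol(x) != model$input_len)
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(x), model$input_len))
  fw <- conv_forward_full(model$params, model$stats, model$hyper, x, training)
  list(lengths = fw$lengths, v = fw$v)
}

#' Train a Conv-CapsNet
#'
#' Minimizes the margin loss plus the L2 penalty by mini-batch gradient
#' descent (Adam by default), with gradients flowing through the unrolled
#' routing iterations. When a validation set is available (given explicitly
#' or split off internally), early stopping monitors the validation margin
#' loss and the best-epoch parameters are restored.
#'
#' @param x Matrix of scaled features (rows = molecules, 179 columns for the
#'   standard characterization).
#' @param y Binary labels (1 = blocker, 0 = nonblocker).
#' @param hyper A \code{\link{conv_hyperparams}} object.
#' @param seed Integer seed controlling initialization, the validation
#'   split, and epoch shuffling.
#' @param val_x,val_y Optional validation set. If \code{NULL} and
#'   \code{early_stop} is set, a stratified fraction of the training data is
#'   held out according to \code{early_stop$fraction}.
#' @param early_stop An \code{\link{early_stop_config}} or \code{NULL} to
#'   train for the full epoch budget.
#' @param loss_params Margin-loss margins, see
#'   \code{\link{margin_loss_params}}.
#' @param verbose Print one line per epoch.
#' @param log_file Optional path receiving the per-epoch log.
#' @return List with \code{model} (trained \code{conv_capsnet}) and
#'   \code{history} (per-epoch losses and accuracies).
#' @export
train_conv_capsnet <- function(x, y, hyper = conv_hyperparams(), seed = 1L,
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
  model <- init_conv_capsnet(hyper, seed = seed, input_len = ncol(x))
  step_fn <- function(params, stats, xb, Tb) {
    fw <- conv_forward_full(params, stats, hyper, xb, training = TRUE)
    loss <- margin_loss(fw$lengths, Tb, loss_params) +
      conv_l2_penalty(params, hyper)
    gl <- margin_loss_backward(fw$lengths, Tb, loss_params)
    grads <- conv_backward_full(params, hyper, xb, fw, gl)
    list(loss = loss, grads = grads, stats = fw$stats)
  }
  eval_fn <- function(params, stats, xx) {
    fw <- conv_forward_full(params, stats, hyper, xx, training = FALSE)
    list(lengths = fw$lengths)
  }
  out <- train_loop(model$params, model$stats, step_fn, eval_fn,
                    x, y, epochs = hyper$epochs,
                    batch_size = hyper$batch_size,
                    lr = hyper$learning_rate, optimizer = hyper$optimizer,
                    loss_params = loss_params,
                    val_x = val_x, val_y = val_y, early_stop = early_stop,
                    seed = seed, verbose = verbose, log_file = log_file)
  model$params <- out$params; model$stats <- out$stats
  list(model = model, history = out$history)
}

#' Predict with a trained Conv-CapsNet
#'
#' @param object A \code{conv_capsnet} model.
#' @param newdata Matrix of scaled feature vectors.
#' @param ... Unused.
#' @return Data frame with \code{label} (0/1), \code{score} (length of the
#'   blocker capsule), and both capsule lengths.
#' @export
predict.conv_capsnet <- function(object, newdata, ...) {
  fw <- forward_conv(object, newdata, training = FALSE)
  out <- classify_capsules(fw$lengths)
  out$len_nonblocker <- fw$lengths[, 1L]
  out$len_blocker <- fw$lengths[, 2L]
  out
}
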