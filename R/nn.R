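# Internal neural-network primitives: truncated-normal initialization, dense
# and 1-d convolution layers, batch normalization, ReLU, Adam/SGD updates and
# the shared mini-batch training loop. Everything here is plain R matrix
# arithmetic so gradients can be checked against finite differences.

# Truncated normal draws: N(0, sd^2) restricted to +/- 2 sd, via inverse-CDF
# sampling so a fixed RNG state reproduces the weights exactly.
tnorm <- function(n, sd = 0.01) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

tnorm_mat <- function(nr, nc, sd = 0.01) matrix(tnorm(nr * nc, sd), nr, nc)

# Repeat a length-K vector across B rows (column-aligned broadcasting).
rowrep <- function(v, B) matrix(v, B, length(v), byrow = TRUE)

relu <- function(X) pmax(X, 0)
relu_backward <- function(X, gY) gY * (X > 0)

dense_forward <- function(X, W, b) X %*% W + rowrep(b, nrow(X))

dense_backward <- function(X, W, gY) {
  list(gX = gY %*% t(W), gW = t(X) %*% gY, gb = colSums(gY))
}

# 1-d valid convolution of a batch of single-channel sequences.
# X: B x len, CW: kernel x filters, cb: filters.
# Returns R: (B * L) x filters with rows ordered batch-fastest, L = len - k + 1.
conv1d_forward <- function(X, CW, cb) {
  B <- nrow(X); k <- nrow(CW); L <- ncol(X) - k + 1L
  stopifnot(L >= 1L)
  Xcol <- matrix(0, B * L, k)
  for (kk in seq_len(k)) Xcol[, kk] <- as.vector(X[, kk:(kk + L - 1L)])
  R <- Xcol %*% CW
  R <- R + rowrep(cb, nrow(R))
  list(R = R, Xcol = Xcol, B = B, L = L)
}

conv1d_backward <- function(fw, CW, gR) {
  B <- fw$B; L <- fw$L; k <- nrow(CW)
  gCW <- t(fw$Xcol) %*% gR
  gcb <- colSums(gR)
  gXcol <- gR %*% t(CW)
  gX <- matrix(0, B, L + k - 1L)
  for (kk in seq_len(k))
    gX[, kk:(kk + L - 1L)] <- gX[, kk:(kk + L - 1L)] + matrix(gXcol[, kk], B, L)
  list(gX = gX, gCW = gCW, gcb = gcb)
}

.bn_eps <- 1e-5

# Batch normalization over columns. In training mode the batch statistics are
# used and running averages updated with the given momentum; in inference
# mode the stored running statistics are used.
bn_forward <- function(X, gamma, beta, run_mean, run_var,
                       training = TRUE, momentum = 0.9) {
  B <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2   # biased batch variance
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * va
  } else {
    mu <- run_mean; va <- run_var
  }
  xhat <- (X - rowrep(mu, B)) / rowrep(sqrt(va + .bn_eps), B)
  Y <- xhat * rowrep(gamma, B) + rowrep(beta, B)
  list(Y = Y, xhat = xhat, mu = mu, va = va,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(fw, gamma, gY) {
  B <- nrow(gY)
  gxhat <- gY * rowrep(gamma, B)
  sum_g <- colSums(gxhat)
  sum_gx <- colSums(gxhat * fw$xhat)
  gX <- (gxhat - rowrep(sum_g, B) / B - fw$xhat * rowrep(sum_gx, B) / B) /
    rowrep(sqrt(fw$va + .bn_eps), B)
  list(gX = gX, ggamma = colSums(gY * fw$xhat), gbeta = colSums(gY))
}

# --- optimizers -------------------------------------------------------------

optimizer_init <- function(params, method = c("adam", "sgd")) {
  method <- match.arg(method)
  st <- list(method = method, t = 0L)
  if (method == "adam") {
    st$m <- lapply(params, function(p) p * 0)   # zero moments, same shapes
    st$v <- st$m
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

optimizer_step <- function(params, grads, state, lr,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (state$method == "adam") {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]] / (1 - beta2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * g
    }
  }
  list(params = params, state = state)
}

# --- shared mini-batch training loop ----------------------------------------

one_hot <- function(y, n_classes = 2L) {
  stopifnot(all(y %in% 0:(n_classes - 1L)))
  oh <- matrix(0, length(y), n_classes)
  oh[cbind(seq_along(y), y + 1L)] <- 1
  oh
}

check_two_classes <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab < 2L))
    stop("training data must contain at least 2 samples of each class")
}

# Generic trainer used by both architectures.
#   step_fn(params, stats, xb, Tb): list(loss, grads, stats)
#   eval_fn(params, stats, x): list(lengths) in inference mode
# Early stopping follows check_early_stop(); the best-epoch parameters are
# restored when stopping fires (and at normal completion).
train_loop <- function(params, stats, step_fn, eval_fn,
                       x, y, epochs, batch_size, lr, optimizer,
                       loss_params = margin_loss_params(),
                       val_x = NULL, val_y = NULL, early_stop = NULL,
                       seed = 1L, verbose = FALSE, log_file = NULL) {
  check_two_classes(y)
  n <- nrow(x)
  opt <- optimizer_init(params, optimizer)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  has_val <- !is.null(val_x) && nrow(val_x) > 0L
  use_stop <- has_val && !is.null(early_stop)
  best <- list(err = Inf, params = params, stats = stats, epoch = 0L)
  val_errors <- numeric(0)
  set.seed(seed)
  logline <- function(msg) {
    if (verbose) message(msg)
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  }
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    tot_loss <- 0; tot_n <- 0L
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      Tb <- one_hot(y[idx])
      st <- step_fn(params, stats, xb, Tb)
      stats <- st$stats
      up <- optimizer_step(params, st$grads, opt, lr)
      params <- up$params; opt <- up$state
      tot_loss <- tot_loss + st$loss * length(idx)
      tot_n <- tot_n + length(idx)
    }
    tr <- eval_fn(params, stats, x)
    tr_pred <- classify_capsules(tr$lengths)
    tr_acc <- mean(tr_pred$label == y)
    tr_loss <- margin_loss(tr$lengths, one_hot(y), loss_params)
    va_loss <- NA_real_; va_acc <- NA_real_
    if (has_val) {
      va <- eval_fn(params, stats, val_x)
      va_pred <- classify_capsules(va$lengths)
      va_acc <- mean(va_pred$label == val_y)
      va_loss <- margin_loss(va$lengths, one_hot(val_y), loss_params)
      val_errors <- c(val_errors, va_loss)
      if (va_loss < best$err) {
        best <- list(err = va_loss, params = params, stats = stats,
                     epoch = epoch)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
      val_loss = va_loss, val_acc = va_acc))
    logline(sprintf(
      "epoch %d  train_loss %.5f  train_acc %.4f  val_loss %s  val_acc %s",
      epoch, tr_loss, tr_acc,
      ifelse(is.na(va_loss), "NA", sprintf("%.5f", va_loss)),
      ifelse(is.na(va_acc), "NA", sprintf("%.4f", va_acc))))
    if (use_stop) {
      es <- check_early_stop(val_errors, early_stop)
      if (es$stop) {
        logline(sprintf("early stop at epoch %d; restoring epoch %d",
                        epoch, es$best_epoch))
        params <- best$params; stats <- best$stats
        attr(history, "stopped_epoch") <- epoch
        attr(history, "best_epoch") <- es$best_epoch
        return(list(params = params, stats = stats, history = history))
      }
    }
  }
  if (has_val && best$epoch > 0L) {
    params <- best$params; stats <- best$stats
    attr(history, "best_epoch") <- best$epoch
  }
  list(params = params, stats = stats, history = history)
}
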