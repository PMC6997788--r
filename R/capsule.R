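# Core capsule mathematics shared by both network architectures: prediction
# vectors, dynamic routing by agreement, the squash nonlinearity, margin loss
# on capsule lengths, and length-based classification.

# Numerical guard used in backward-pass denominators so gradients stay finite
# at the origin (the squash forward needs no guard: s * ||s|| / (1 + ||s||^2)
# has no division).
.caps_tiny <- 1e-12

#' Squash nonlinearity for capsule vectors
#'
#' Rescales a vector to length \eqn{\|s\|^2 / (1 + \|s\|^2)} while preserving
#' its direction, so that capsule lengths can be read as probabilities in
#' \eqn{[0, 1)}. The zero vector maps to the zero vector.
#'
#' @param s Numeric vector (one capsule's pre-activation).
#' @return Numeric vector of the same length, with norm strictly below 1.
#' @examples
#' squash(c(3, 4))        # norm 25/26, direction (3,4)/5
#' squash(numeric(2))     # stays zero
#' @export
squash <- function(s) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  n2 <- sum(s^2)
  s * (sqrt(n2) / (1 + n2))
}

# Row-wise squash for a batch: S is B x d, returns B x d.
squash_rows <- function(S) {
  n2 <- rowSums(S^2)
  S * (sqrt(n2) / (1 + n2))
}

#' Prediction vectors from lower-layer capsules
#'
#' Computes the contribution \eqn{\hat{u}_{j|i} = W_{ij} u_i} of every input
#' capsule \eqn{i} to every output capsule \eqn{j}.
#'
#' @param u Matrix of input capsules, \code{n_in x d_in} (one capsule per
#'   row), or a 3-d array \code{B x n_in x d_in} for a batch.
#' @param W Routing weight array of dimension
#'   \code{c(n_in, n_out, d_out, d_in)}.
#' @return For matrix input, an array \code{c(n_in, n_out, d_out)}; for a
#'   batch, \code{c(B, n_in, n_out, d_out)}.
#' @export
predict_vectors <- function(u, W) {
  stopifnot(is.array(W), length(dim(W)) == 4L)
  if (is.matrix(u)) {
    ub <- array(u, dim = c(1L, nrow(u), ncol(u)))
    return(array(predict_vectors_batch(ub, W)[1L, , , , drop = FALSE],
                 dim = dim(W)[1:3]))
  }
  predict_vectors_batch(u, W)
}

# Batched prediction vectors: u is B x n_in x d_in.
predict_vectors_batch <- function(u, W) {
  d <- dim(W)
  n_in <- d[1L]; n_out <- d[2L]; d_out <- d[3L]; d_in <- d[4L]
  stopifnot(length(dim(u)) == 3L, dim(u)[2L] == n_in, dim(u)[3L] == d_in)
  B <- dim(u)[1L]
  u_hat <- array(0, dim = c(B, n_in, n_out, d_out))
  for (i in seq_len(n_in)) {
    ui <- matrix(u[, i, ], nrow = B)
    for (j in seq_len(n_out)) {
      Wij <- matrix(W[i, j, , ], nrow = d_out)    # d_out x d_in
      u_hat[, i, j, ] <- ui %*% t(Wij)
    }
  }
  u_hat
}

# Softmax of routing logits along the output-capsule axis.
# b is B x n_in x n_out; returns coupling coefficients of the same shape,
# rows (over j) summing to one.
routing_softmax <- function(b) {
  d <- dim(b); n_out <- d[3L]
  m <- b[, , 1L]
  if (n_out > 1L) for (j in 2:n_out) m <- pmax(m, b[, , j])
  e <- array(0, dim = d)
  for (j in seq_len(n_out)) e[, , j] <- exp(b[, , j] - m)
  z <- e[, , 1L]
  if (n_out > 1L) for (j in 2:n_out) z <- z + e[, , j]
  for (j in seq_len(n_out)) e[, , j] <- e[, , j] / z
  e
}

#' Dynamic routing between capsule layers
#'
#' Iteratively assigns the prediction vectors \eqn{\hat{u}_{j|i}} to output
#' capsules: logits start at zero, coupling coefficients are the softmax of
#' the logits over output capsules, each output capsule is the squashed
#' coupling-weighted sum of its predictions, and logits are incremented by
#' the agreement \eqn{\hat{u}_{j|i} \cdot v_j} inside every pass.
#'
#' @param u_hat Prediction array \code{c(n_in, n_out, d_out)} (or batched
#'   \code{c(B, n_in, n_out, d_out)}).
#' @param iterations Number of routing passes (positive integer; both
#'   network architectures default to 2).
#' @return A list with \code{v} (output capsules, \code{n_out x d_out}),
#'   \code{lengths}, and the final routing state \code{b} and \code{c}
#'   (\code{n_in x n_out}). Batched input gives arrays with a leading batch
#'   dimension.
#' @export
dynamic_routing <- function(u_hat, iterations = 2L) {
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1)
    stop("'iterations' must be a single integer >= 1")
  single <- length(dim(u_hat)) == 3L
  if (single) u_hat <- array(u_hat, dim = c(1L, dim(u_hat)))
  stopifnot(length(dim(u_hat)) == 4L)
  fw <- routing_forward(u_hat, as.integer(iterations))
  if (single) {
    dm <- dim(u_hat)
    list(v = matrix(fw$v[1L, , ], nrow = dm[3L]),
         lengths = as.numeric(fw$lengths[1L, ]),
         b = matrix(fw$b[1L, , ], nrow = dm[2L]),
         c = matrix(fw$c[1L, , ], nrow = dm[2L]))
  } else {
    list(v = fw$v, lengths = fw$lengths, b = fw$b, c = fw$c)
  }
}

# Forward routing with per-iteration cache (for backpropagation).
# u_hat: B x n_in x n_out x d_out. Returns final v, lengths, state, cache.
routing_forward <- function(u_hat, iterations) {
  d <- dim(u_hat)
  B <- d[1L]; n_in <- d[2L]; n_out <- d[3L]; d_out <- d[4L]
  b <- array(0, dim = c(B, n_in, n_out))
  cache <- vector("list", iterations)
  v <- NULL
  for (t in seq_len(iterations)) {
    cc <- routing_softmax(b)
    s <- array(0, dim = c(B, n_out, d_out))
    for (j in seq_len(n_out)) {
      acc <- matrix(0, B, d_out)
      for (i in seq_len(n_in))
        acc <- acc + cc[, i, j] * matrix(u_hat[, i, j, ], nrow = B)
      s[, j, ] <- acc
    }
    v <- array(0, dim = c(B, n_out, d_out))
    for (j in seq_len(n_out))
      v[, j, ] <- squash_rows(matrix(s[, j, ], nrow = B))
    cache[[t]] <- list(c = cc, s = s, v = v)
    # agreement update (runs inside every pass, including the last)
    for (i in seq_len(n_in)) for (j in seq_len(n_out))
      b[, i, j] <- b[, i, j] +
        rowSums(matrix(u_hat[, i, j, ], nrow = B) * matrix(v[, j, ], nrow = B))
  }
  lengths <- matrix(0, B, n_out)
  for (j in seq_len(n_out)) lengths[, j] <- sqrt(rowSums(matrix(v[, j, ], nrow = B)^2))
  list(v = v, lengths = lengths, b = b, c = cache[[iterations]]$c,
       cache = cache, u_hat = u_hat)
}

# Backward pass through squash for one output capsule across the batch.
# S: B x d pre-activations, gV: B x d upstream gradient. Returns B x d.
squash_rows_backward <- function(S, gV) {
  n2 <- rowSums(S^2)
  n <- sqrt(n2)
  a <- n / (1 + n2)
  aprime <- (1 - n2) / (1 + n2)^2
  gV * a + S * (rowSums(gV * S) * aprime / pmax(n, .caps_tiny))
}

# Backpropagation through the unrolled routing iterations.
# fw: output of routing_forward; gv: B x n_out x d_out gradient on final v.
# Returns gradient with respect to u_hat (B x n_in x n_out x d_out).
routing_backward <- function(fw, gv) {
  u_hat <- fw$u_hat
  d <- dim(u_hat)
  B <- d[1L]; n_in <- d[2L]; n_out <- d[3L]; d_out <- d[4L]
  iterations <- length(fw$cache)
  gu_hat <- array(0, dim = d)
  gb <- array(0, dim = c(B, n_in, n_out))   # grad wrt logits entering pass t+1
  for (t in rev(seq_len(iterations))) {
    st <- fw$cache[[t]]
    # gradient reaching v_t: the loss (final pass only) plus the agreement
    # update b_{t+1,ij} = b_{t,ij} + u_hat_ij . v_tj
    gvt <- if (t == iterations) gv else array(0, dim = c(B, n_out, d_out))
    for (i in seq_len(n_in)) for (j in seq_len(n_out)) {
      gvt[, j, ] <- matrix(gvt[, j, ], nrow = B) +
        gb[, i, j] * matrix(u_hat[, i, j, ], nrow = B)
      gu_hat[, i, j, ] <- matrix(gu_hat[, i, j, ], nrow = B) +
        gb[, i, j] * matrix(st$v[, j, ], nrow = B)
    }
    # through squash and the weighted sum
    gc <- array(0, dim = c(B, n_in, n_out))
    for (j in seq_len(n_out)) {
      gs <- squash_rows_backward(matrix(st$s[, j, ], nrow = B),
                                 matrix(gvt[, j, ], nrow = B))
      for (i in seq_len(n_in)) {
        uh <- matrix(u_hat[, i, j, ], nrow = B)
        gc[, i, j] <- rowSums(gs * uh)
        gu_hat[, i, j, ] <- matrix(gu_hat[, i, j, ], nrow = B) + st$c[, i, j] * gs
      }
    }
    # softmax backward (rows over j) plus the identity path b_t -> b_{t+1}
    dot <- matrix(0, B, n_in)
    for (j in seq_len(n_out)) dot <- dot + st$c[, , j] * gc[, , j]
    for (j in seq_len(n_out))
      gb[, , j] <- gb[, , j] + st$c[, , j] * (gc[, , j] - dot)
  }
  gu_hat
}

# Gradients through the prediction map u_hat = W_ij u_i.
# Returns gW (same shape as W) and gu (B x n_in x d_in).
predict_vectors_backward <- function(u, W, gu_hat) {
  d <- dim(W)
  n_in <- d[1L]; n_out <- d[2L]; d_out <- d[3L]; d_in <- d[4L]
  B <- dim(u)[1L]
  gW <- array(0, dim = d)
  gu <- array(0, dim = dim(u))
  for (i in seq_len(n_in)) {
    ui <- matrix(u[, i, ], nrow = B)
    acc <- matrix(0, B, d_in)
    for (j in seq_len(n_out)) {
      g <- matrix(gu_hat[, i, j, ], nrow = B)
      gW[i, j, , ] <- t(g) %*% ui
      acc <- acc + g %*% matrix(W[i, j, , ], nrow = d_out)
    }
    gu[, i, ] <- acc
  }
  list(gW = gW, gu = gu)
}

#' Margin loss parameters
#'
#' @param m_plus Upper margin for present classes (default 0.9).
#' @param m_minus Lower margin for absent classes (default 0.1).
#' @param lambda Down-weighting of the absent-class term (default 0.5).
#' @return A list of class \code{margin_loss_params}.
#' @export
margin_loss_params <- function(m_plus = 0.9, m_minus = 0.1, lambda = 0.5) {
  stopifnot(m_minus > 0, m_plus > m_minus, m_plus < 1, lambda > 0)
  structure(list(m_plus = m_plus, m_minus = m_minus, lambda = lambda),
            class = "margin_loss_params")
}

#' Margin loss on capsule lengths
#'
#' Per class \eqn{k}: \eqn{L_k = T_k \max(0, m^+ - \|v_k\|)^2 +
#' \lambda (1 - T_k) \max(0, \|v_k\| - m^-)^2}. The classwise sum is averaged
#' over the samples of the batch.
#'
#' @param lengths Capsule lengths, a matrix \code{B x n_classes} (a vector is
#'   treated as one sample).
#' @param labels One-hot matrix of the same shape (\code{T_k}).
#' @param params A \code{\link{margin_loss_params}} object.
#' @return Non-negative scalar loss.
#' @export
margin_loss <- function(lengths, labels, params = margin_loss_params()) {
  if (is.null(dim(lengths))) lengths <- matrix(lengths, nrow = 1L)
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  stopifnot(all(dim(lengths) == dim(labels)),
            all(labels %in% c(0, 1)), all(rowSums(labels) == 1))
  pos <- pmax(0, params$m_plus - lengths)^2
  neg <- pmax(0, lengths - params$m_minus)^2
  per_sample <- rowSums(labels * pos + params$lambda * (1 - labels) * neg)
  mean(per_sample)
}

# Gradient of margin_loss with respect to lengths (same shape as lengths).
margin_loss_backward <- function(lengths, labels, params = margin_loss_params()) {
  B <- nrow(lengths)
  gpos <- -2 * pmax(0, params$m_plus - lengths)
  gneg <- 2 * params$lambda * pmax(0, lengths - params$m_minus)
  (labels * gpos + (1 - labels) * gneg) / B
}

# Gradient from lengths back to the output capsules v (B x n_out x d_out).
lengths_backward <- function(v, lengths, g_lengths) {
  d <- dim(v)
  gv <- array(0, dim = d)
  for (j in seq_len(d[2L])) {
    vj <- matrix(v[, j, ], nrow = d[1L])
    lj <- pmax(sqrt(rowSums(vj^2)), .caps_tiny)
    gv[, j, ] <- vj * (g_lengths[, j] / lj)
  }
  gv
}

#' Classify from output capsule lengths
#'
#' The predicted class is the index (0-based) of the longest output capsule;
#' exact ties go to class 0. The ranking score is the length of the
#' positive-class (blocker) capsule, used for ROC curves.
#'
#' @param lengths Numeric vector of 2 capsule lengths (class 0, class 1), or
#'   a matrix with one row per sample.
#' @return A data.frame with columns \code{label} and \code{score}.
#' @export
classify_capsules <- function(lengths) {
  if (is.null(dim(lengths))) lengths <- matrix(lengths, nrow = 1L)
  stopifnot(ncol(lengths) == 2L)
  label <- as.integer(lengths[, 2L] > lengths[, 1L])
  data.frame(label = label, score = lengths[, 2L])
}
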