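# RBM energy, CD-1 training, stack pretraining, and the assembled
# RBM-CapsNet.

test_that("rbm energy evaluates the bilinear form exactly", {
  # zero parameters: zero energy
  p0 <- list(a = numeric(2), b = numeric(3), omega = matrix(0, 2, 3))
  expect_equal(rbm_energy(c(1, 0), c(1, 1, 0), p0), 0)

  # all-ones with identity weights: E = -n
  n <- 4
  pid <- list(a = numeric(n), b = numeric(n), omega = diag(n))
  expect_equal(rbm_energy(rep(1, n), rep(1, n), pid), -n)

  # hand-evaluated case
  ph <- list(a = c(0.5, 0), b = 0.25, omega = matrix(c(2, 0), 2, 1))
  expect_equal(rbm_energy(c(1, 0), 1, ph), -2.75)

  expect_error(rbm_energy(c(1, 0, 0), 1, ph))
})

test_that("rbm energy is linear in the biases and bilinear through omega", {
  set.seed(12)
  nv <- 3; nh <- 4
  v <- runif(nv); h <- runif(nh)
  om <- matrix(rnorm(nv * nh), nv, nh)
  a1 <- rnorm(nv); a2 <- rnorm(nv); b1 <- rnorm(nh)
  e <- function(a, b, om) rbm_energy(v, h, list(a = a, b = b, omega = om))
  # linearity in a (b, omega fixed at zero)
  z <- matrix(0, nv, nh)
  expect_equal(e(a1 + 2 * a2, numeric(nh), z),
               e(a1, numeric(nh), z) + 2 * e(a2, numeric(nh), z),
               tolerance = 1e-12)
  # additivity across the three terms
  expect_equal(e(a1, b1, om),
               e(a1, numeric(nh), z) + e(numeric(nv), b1, z) +
                 e(numeric(nv), numeric(nh), om),
               tolerance = 1e-12)
  # bilinearity: scaling v scales the omega term
  expect_equal(rbm_energy(2 * v, h, list(a = numeric(nv), b = numeric(nh),
                                         omega = om)),
               2 * rbm_energy(v, h, list(a = numeric(nv), b = numeric(nh),
                                         omega = om)),
               tolerance = 1e-12)
})

test_that("cd_update respects lr = 0, keeps shapes, and rejects bad input", {
  set.seed(13)
  p <- init_rbm(6, 4, seed = 1L)
  batch <- matrix(runif(30), 5, 6)
  up0 <- cd_update(p, batch, lr = 0, seed = 2L)
  expect_identical(up0$params$omega, p$omega)
  expect_identical(up0$params$a, p$a)
  expect_true(is.finite(up0$reconstruction_error))
  up <- cd_update(p, batch, lr = 0.1, seed = 2L)
  expect_identical(dim(up$params$omega), dim(p$omega))
  expect_false(identical(up$params$omega, p$omega))
  expect_error(cd_update(p, batch * 2, lr = 0.1), "\\[0, 1\\]")
})

test_that("CD-1 reduces reconstruction error on a repeated pattern", {
  set.seed(14)
  pattern <- rep(c(1, 0, 1, 1, 0, 0, 1, 0), 2)
  batch <- matrix(pattern, 40, 16, byrow = TRUE)
  p <- init_rbm(16, 8, seed = 3L)
  first <- cd_update(p, batch, lr = 0.1)$reconstruction_error
  errs <- numeric(100)
  for (e in 1:100) {
    up <- cd_update(p, batch, lr = 0.1)
    p <- up$params
    errs[e] <- up$reconstruction_error
  }
  expect_lt(errs[100], first)
  # trend check: late errors below early errors
  expect_lt(mean(errs[91:100]), mean(errs[1:10]))
})

test_that("stack pretraining is greedy, shaped by the hyperparameters, and seeded", {
  set.seed(15)
  x <- matrix(runif(60 * 179), 60, 179)
  h <- rbm_hyperparams(rbm_epochs = 2L, batch_size = 20L)
  st <- pretrain_stack(x, h, seed = 4L)
  expect_length(st, 2L)
  expect_identical(dim(st[[1]]$omega), c(179L, 256L))
  expect_identical(dim(st[[2]]$omega), c(256L, 128L))
  st2 <- pretrain_stack(x, h, seed = 4L)
  expect_identical(st, st2)
  # rbm_epochs = 0 returns initialized, untrained RBMs
  h0 <- rbm_hyperparams(rbm_epochs = 0L)
  st0 <- pretrain_stack(x, h0, seed = 4L)
  expect_length(attr(st0[[1]], "recon_errors"), 0L)
  expect_error(pretrain_stack(x[0, ], h, seed = 4L), "empty")
})

test_that("the assembled network copies pretrained weights and checks shapes", {
  set.seed(16)
  x <- matrix(runif(40 * 20), 40, 20)
  h <- rbm_hyperparams(hidden_sizes = c(8L, 6L), capsule_dim = 2L,
                       rbm_epochs = 1L, batch_size = 20L)
  st <- pretrain_stack(x, h, seed = 5L)
  m <- init_rbm_capsnet(st, h, seed = 5L)
  expect_identical(m$params$W1, st[[1]]$omega)
  expect_identical(m$params$b1, st[[1]]$b)
  expect_identical(m$params$W2, st[[2]]$omega)
  expect_identical(dim(m$params$Wij), c(3L, 2L, 2L, 2L))
  expect_error(init_rbm_capsnet(rev(st), h, seed = 5L), "inconsistent")
  expect_error(init_rbm_capsnet(st[1], h, seed = 5L), "2 RBMs")
})

test_that("RBM-CapsNet analytic gradients match finite differences", {
  ns <- asNamespace("hergcaps")
  hr <- tiny_rbm_hyper()
  set.seed(17)
  s1 <- init_rbm(7, 6, seed = 1L); s2 <- init_rbm(6, 4, seed = 2L)
  s1$omega <- matrix(rnorm(42, sd = 0.5), 7, 6); s1$b <- rnorm(6, sd = 0.2)
  s2$omega <- matrix(rnorm(24, sd = 0.5), 6, 4); s2$b <- rnorm(4, sd = 0.2)
  m <- init_rbm_capsnet(list(s1, s2), hr, seed = 3L)
  X <- matrix(runif(35), 5, 7)
  Tb <- cbind(c(1, 0, 0, 1, 0), c(0, 1, 1, 0, 1))
  lp <- margin_loss_params()
  lossfn <- function(params) {
    fw <- ns$rbm_forward_full(params, hr, X)
    margin_loss(fw$lengths, Tb, lp)
  }
  fw <- ns$rbm_forward_full(m$params, hr, X)
  gl <- ns$margin_loss_backward(fw$lengths, Tb, lp)
  gr <- ns$rbm_backward_full(m$params, hr, X, fw, gl)
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (ii in sample(length(m$params[[nm]]), min(5, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- m$params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_grad_close(num, gr[[nm]][ii])
    }
  }
})

test_that("fine-tuning at lr = 0 returns the initialization unchanged", {
  set.seed(18)
  x <- matrix(runif(30 * 10), 30, 10)
  y <- rep(c(0L, 1L), 15)
  h <- rbm_hyperparams(hidden_sizes = c(6L, 4L), capsule_dim = 2L,
                       rbm_epochs = 1L, finetune_epochs = 2L,
                       network_lr = 0, batch_size = 10L)
  st <- pretrain_stack(x, h, seed = 6L)
  m <- init_rbm_capsnet(st, h, seed = 6L)
  ft <- finetune_rbm_capsnet(m, x, y, seed = 6L, early_stop = NULL)
  expect_identical(ft$model$params, m$params)
  # defaults carry the tuned values
  hd <- rbm_hyperparams()
  expect_equal(hd$network_lr, 0.005)
  expect_equal(hd$rbm_lr, 0.001)
  expect_identical(hd$rbm_epochs, 100L)
  expect_identical(hd$finetune_epochs, 200L)
  expect_identical(hd$hidden_sizes, c(256L, 128L))
})

test_that("pretraining does not hurt relative to random initialization", {
  # small, clearly separable problem; compare held-out accuracy of the
  # pretrained+finetuned network against the same architecture fine-tuned
  # from a random (untrained-RBM) initialization
  ds <- generate_dataset(synthetic_spec(n_samples = 600L, separation = 2,
                                        seed = 19L))
  sp <- split_train_val(ds$labels, fraction = 0.25, seed = 19L)
  x <- ds$features[sp$train, ]; y <- ds$labels[sp$train]
  hx <- ds$features[sp$val, ]; hy <- ds$labels[sp$val]
  h <- rbm_hyperparams(hidden_sizes = c(64L, 32L), capsule_dim = 8L,
                       rbm_epochs = 10L, finetune_epochs = 40L,
                       batch_size = 64L)
  acc <- function(rbm_epochs) {
    hh <- h; hh$rbm_epochs <- as.integer(rbm_epochs)
    fit <- train_rbm_capsnet(x, y, hh, seed = 20L, early_stop = NULL)
    mean(predict(fit$model, hx)$label == hy)
  }
  expect_gte(acc(10L), acc(0L) - 0.05)
})
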