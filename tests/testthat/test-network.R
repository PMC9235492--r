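fast_ipm <- ipm_config(epsilon = 5, tolerance = 1e-4, max_iters = 20000)

test_that("model construction obeys the shape and determinism contracts", {
  cfg <- net_config(shared_layers = 8L, head_layers = 4L, seed = 7L)
  m <- build_model(cfg, 20)
  x <- matrix(rnorm(5 * 20), 5)
  h <- predict_log_hazards(m, x, standardize = FALSE)
  expect_length(h$h0, 5)
  expect_length(h$h1, 5)
  expect_equal(m$latent_dim, 8)
  # deepsurv: treatment appended, single head evaluated at both bits
  cfgd <- net_config(variant = "deepsurv", alpha = 0, shared_layers = 8L,
                     head_layers = 4L, seed = 7L)
  md <- build_model(cfgd, 20)
  expect_equal(md$d_in, 21)
  hd <- predict_log_hazards(md, x, standardize = FALSE)
  expect_length(hd$h0, 5)
  # identical seeds give identical parameters and initial losses
  m2 <- build_model(cfg, 20)
  expect_identical(m$params, m2$params)
  ds <- tiny_dataset(10, 20, seed = 1)
  l1 <- bites_loss(m, ds, cfg, q = 0.5)
  l2 <- bites_loss(m2, ds, cfg, q = 0.5)
  expect_identical(l1$total, l2$total)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(net_config(dropout_rate = 1), "dropout_rate")
  expect_error(net_config(alpha = -1), "alpha")
  expect_error(net_config(variant = "ites", alpha = 0.5), "alpha")
  expect_error(net_config(shared_layers = 0L), "shared_layers")
  expect_error(net_config(batch_size = 1L), "batch_size")
  # alpha = 0 is by definition the unbalanced variant
  expect_equal(net_config(variant = "bites", alpha = 0)$variant, "ites")
})

test_that("composite loss reduces exactly to weighted Cox terms at alpha 0", {
  ds <- tiny_dataset(12, 4, seed = 11)
  cfg <- net_config(shared_layers = 6L, head_layers = 3L, alpha = 0,
                    variant = "ites", seed = 2L)
  m <- build_model(cfg, 4)
  q <- 0.4
  out <- bites_loss(m, ds, cfg, q = q)
  expect_equal(out$total, q * out$cox0 + (1 - q) * out$cox1)
  expect_equal(out$ipm, 0)
})

test_that("composite loss equals hand-composed module terms", {
  ds <- tiny_dataset(10, 4, seed = 21)
  cfg <- net_config(shared_layers = 6L, head_layers = 3L, alpha = 0.7,
                    ipm = fast_ipm, dropout_rate = 0.3, seed = 5L)
  m <- build_model(cfg, 4)
  q <- mean(ds$t == 0)
  out <- bites_loss(m, ds, cfg, q = q)  # evaluation mode: deterministic
  h <- predict_log_hazards(m, ds$x, standardize = FALSE)
  Phi <- latent_representation(m, ds$x, standardize = FALSE)
  i0 <- ds$t == 0; i1 <- ds$t == 1
  cox0 <- cox_partial_loss(h$h0[i0], ds$y[i0], ds$e[i0], reduction = "mean")
  cox1 <- cox_partial_loss(h$h1[i1], ds$y[i1], ds$e[i1], reduction = "mean")
  S <- as.numeric(sinkhorn_divergence(Phi[i1, ], Phi[i0, ], cfg$ipm))
  expect_equal(out$total, q * cox0 + (1 - q) * cox1 + cfg$alpha * S,
               tolerance = 1e-6)
  expect_equal(out$cox0, as.numeric(cox0))
  expect_equal(out$cox1, as.numeric(cox1))
})

test_that("identical latent clouds for both arms zero the penalty", {
  set.seed(6)
  x_half <- matrix(rnorm(5 * 4), 5)
  ds <- survival_dataset(rbind(x_half, x_half), rep(c(1, 2, 3, 4, 5), 2),
                         rep(1L, 10), rep(c(0L, 1L), each = 5))
  cfg <- net_config(shared_layers = 6L, head_layers = 3L, alpha = 1,
                    ipm = fast_ipm, seed = 3L)
  m <- build_model(cfg, 4)
  out <- bites_loss(m, ds, cfg, q = 0.5)
  expect_lt(abs(out$ipm), 1e-8)
})

test_that("the full composite gradient matches finite differences", {
  set.seed(42)
  n <- 6; d <- 3
  x <- matrix(rnorm(n * d), n)
  y <- runif(n); e <- c(1, 1, 0, 1, 1, 1); t <- rep(c(0L, 1L), 3)
  cfg <- net_config(shared_layers = 5L, head_layers = 4L, dropout_rate = 0,
                    alpha = 0.5, ipm = ipm_config(epsilon = 20, tolerance = 1e-9,
                                                  max_iters = 20000),
                    seed = 7L)
  m <- build_model(cfg, d)
  res <- bites:::bites_loss_impl(m, x, y, e, t, cfg, q = 0.5, training = TRUE,
                                 gradient = TRUE, update_state = FALSE)
  expect_setequal(names(res$grads), names(m$params))
  set.seed(9)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    ii <- sample(length(p), 1)
    dl <- 1e-5
    mp <- m; mp$params[[nm]][ii] <- p[ii] + dl
    mm <- m; mm$params[[nm]][ii] <- p[ii] - dl
    fp <- bites:::bites_loss_impl(mp, x, y, e, t, cfg, q = 0.5, training = TRUE,
                                  gradient = FALSE, update_state = FALSE)$total
    fm <- bites:::bites_loss_impl(mm, x, y, e, t, cfg, q = 0.5, training = TRUE,
                                  gradient = FALSE, update_state = FALSE)$total
    expect_equal(res$grads[[nm]][ii], (fp - fm) / (2 * dl), tolerance = 1e-4)
  }
})

test_that("training descends and stops per the patience contract", {
  sim <- simulate_linear(600, seed = 3)
  sp <- stratified_split(sim, 0.8, seed = 4)
  cfg <- net_config(shared_layers = 16L, head_layers = 8L, alpha = 0.1,
                    max_epochs = 5L, patience = 10L, seed = 1L)
  m <- train_model(build_model(cfg, 20), sp$train, sp$val, cfg)
  expect_lt(m$history$train_total[5], m$history$train_total[1])
  # patience 0: stops exactly at the first non-improving epoch
  cfg0 <- net_config(shared_layers = 8L, head_layers = 4L, alpha = 0,
                     variant = "ites", max_epochs = 200L, patience = 0L,
                     seed = 2L)
  m0 <- train_model(build_model(cfg0, 20), sp$train, sp$val, cfg0)
  v <- m0$history$val_total
  first_flat <- which(v >= cummin(c(Inf, head(v, -1))) - 1e-12)[1]
  expect_equal(nrow(m0$history), first_flat)
  # returned parameters reproduce the best recorded validation loss
  vres <- bites_loss(m0, sp$val, m0$cfg, q = m0$q)
  expect_equal(vres$total, min(v), tolerance = 1e-10)
})

test_that("training is reproducible and rejects divergent losses", {
  sim <- simulate_linear(300, seed = 13)
  sp <- stratified_split(sim, 0.8, seed = 1)
  cfg <- net_config(shared_layers = 8L, head_layers = 4L, alpha = 0.1,
                    ipm = ipm_config(epsilon = 0.1, tolerance = 1e-2,
                                     max_iters = 50L),
                    max_epochs = 3L, seed = 6L)
  m1 <- train_model(build_model(cfg, 20), sp$train, sp$val, cfg)
  m2 <- train_model(build_model(cfg, 20), sp$train, sp$val, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("prediction is deterministic and respects variant semantics", {
  cfgd <- net_config(variant = "deepsurv", alpha = 0, shared_layers = 8L,
                     head_layers = 4L, seed = 4L)
  md <- build_model(cfgd, 6)
  x <- matrix(rnorm(12), 2)
  xx <- rbind(x, x)
  h <- predict_log_hazards(md, xx, standardize = FALSE)
  expect_equal(h$h0[1:2], h$h0[3:4])
  expect_equal(h$h1[1:2], h$h1[3:4])
  # the two outputs differ only through the treatment input bit
  h_manual0 <- bites:::forward_stack(md, "head0",
    bites:::forward_stack(md, "trunk", cbind(x, 0), FALSE)$out, FALSE)$out
  expect_equal(h$h0[1:2], drop(h_manual0))
  expect_error(predict_log_hazards(md, matrix(0, 1, 3), standardize = FALSE),
               "dimension mismatch")
})

test_that("arm-wise models of the T-learner variant are isolated", {
  sim <- simulate_linear(300, seed = 23)
  sp <- stratified_split(sim, 0.8, seed = 2)
  cfg <- net_config(variant = "t-deepsurv", alpha = 0, shared_layers = 8L,
                    head_layers = 4L, max_epochs = 3L, seed = 5L)
  m <- train_model(build_model(cfg, 20), sp$train, sp$val, cfg)
  # perturbing arm-1 data leaves the arm-0 model unchanged
  perturbed <- sp$train
  perturbed$x[perturbed$t == 1L, ] <- perturbed$x[perturbed$t == 1L, ] + 100
  m2 <- train_model(build_model(cfg, 20), perturbed, sp$val, cfg)
  x <- matrix(rnorm(3 * 20), 3)
  expect_equal(predict_log_hazards(m$m0, x)$h0,
               predict_log_hazards(m2$m0, x)$h0, tolerance = 1e-4)
})

test_that("an unbalanced linear configuration attains the Cox optimum", {
  train <- simulate_linear(400, seed = 11)
  val <- simulate_linear(2000, seed = 12)
  cfg <- net_config(shared_layers = integer(0), head_layers = integer(0),
                    dropout_rate = 0, alpha = 0, variant = "ites",
                    use_batchnorm = FALSE, learning_rate = 0.1,
                    max_epochs = 1200L, patience = 1200L, batch_size = 1024L,
                    seed = 3L)
  m <- train_model(build_model(cfg, 20), train, val, cfg)
  xs <- bites:::apply_scaler(m$scaler, train$x)
  h <- predict_log_hazards(m, train$x)
  for (arm in 0:1) {
    idx <- train$t == arm
    net_loss <- cox_partial_loss(if (arm == 0) h$h0[idx] else h$h1[idx],
                                 train$y[idx], train$e[idx])
    ds_arm <- subset_dataset(train, idx)
    ds_arm$x <- xs[idx, ]
    ref <- fit_linear_cox(ds_arm)
    expect_lt((net_loss - ref$loss) / ref$loss, 0.01)
  }
})
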