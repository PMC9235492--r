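#' Network and training configuration
#'
#' Defines the architecture and optimization settings of the balanced
#' treatment-effect network and its variants:
#' \describe{
#'   \item{`bites`}{shared trunk, two Cox heads, Sinkhorn balancing penalty
#'     of strength `alpha` on the latent representation.}
#'   \item{`ites`}{identical architecture with `alpha = 0` (no balancing).}
#'   \item{`deepsurv`}{single head; the treatment indicator is appended as
#'     an input covariate and one pooled baseline hazard is used.}
#'   \item{`t-deepsurv`}{two independent single-head networks, one per
#'     treatment arm.}
#' }
#' Hidden blocks are ordered dense -> ReLU -> dropout -> batch
#' normalization.
#'
#' @param shared_layers integer widths of the shared trunk layers (may be
#'   empty for an identity trunk).
#' @param head_layers integer widths of hidden layers in each outcome head
#'   (may be empty: the head is then a single linear map to the scalar
#'   log-hazard).
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param alpha balancing strength (`>= 0`); must be exactly 0 for the
#'   `ites` variant.
#' @param ipm an [ipm_config()] for the Sinkhorn penalty.
#' @param learning_rate,weight_decay Adam step size and L2 penalty on
#'   weight matrices.
#' @param lr_decay multiplicative per-epoch learning-rate decay factor in
#'   `(0, 1]` (1 = constant rate).
#' @param batch_size minibatch size; batches are stratified so both arms
#'   appear in their training-set proportion.
#' @param ipm_subsample during training, the Sinkhorn penalty and its
#'   gradient are estimated on at most this many latent samples per arm,
#'   drawn uniformly from the batch (the divergence is a batch-level
#'   estimator either way; subsampling bounds its quadratic cost so large
#'   Cox batches stay affordable). `Inf` disables subsampling; evaluation-
#'   mode losses always use the full batch.
#' @param max_epochs,patience epoch cap and early-stopping patience
#'   (training stops once the validation loss has failed to improve for
#'   more than `patience` consecutive epochs; the best-epoch weights are
#'   returned).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param variant one of `"bites"`, `"ites"`, `"deepsurv"`, `"t-deepsurv"`.
#' @param use_batchnorm disable to obtain a plain dense network (used e.g.
#'   to compare a linear configuration against the linear Cox fit).
#' @return list of class `net_config`.
#' @export
net_config <- function(shared_layers = c(32L, 16L), head_layers = 16L,
                       dropout_rate = 0.1, alpha = 0.1,
                       ipm = ipm_config(epsilon = 0.1, tolerance = 1e-2,
                                        max_iters = 100L),
                       learning_rate = 0.01, weight_decay = 1e-4,
                       lr_decay = 1,
                       batch_size = 256L, ipm_subsample = 64L,
                       max_epochs = 100L, patience = 10L,
                       seed = 1L,
                       variant = c("bites", "ites", "deepsurv", "t-deepsurv"),
                       use_batchnorm = TRUE) {
  variant <- match.arg(variant)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("invalid field dropout_rate: must be in [0, 1)")
  if (alpha < 0) stop("invalid field alpha: must be >= 0")
  if (variant == "ites" && alpha != 0)
    stop("invalid field alpha: the ites variant requires alpha = 0")
  if (variant == "bites" && alpha == 0)
    variant <- "ites"  # alpha = 0 is, by definition, the unbalanced variant
  if (any(shared_layers < 1) || any(head_layers < 1))
    stop("invalid field shared_layers/head_layers: widths must be positive")
  if (batch_size < 2) stop("invalid field batch_size: must be >= 2")
  if (!inherits(ipm, "ipm_config")) stop("invalid field ipm: need an ipm_config()")
  structure(list(shared_layers = as.integer(shared_layers),
                 head_layers = as.integer(head_layers),
                 dropout_rate = dropout_rate, alpha = alpha, ipm = ipm,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 ipm_subsample = ipm_subsample,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 variant = variant, use_batchnorm = use_batchnorm),
            class = "net_config")
}

BN_EPS <- 1e-5

init_linear <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

# Initialize the parameter (flat named list) and state (batchnorm running
# statistics) entries of a stack of hidden blocks under `prefix`.
init_stack <- function(params, state, prefix, d_in, widths, cfg, final_out = NA) {
  d <- d_in
  for (i in seq_along(widths)) {
    lin <- init_linear(d, widths[i])
    params[[paste0(prefix, ".", i, ".W")]] <- lin$W
    params[[paste0(prefix, ".", i, ".b")]] <- lin$b
    if (cfg$use_batchnorm) {
      params[[paste0(prefix, ".", i, ".gamma")]] <- rep(1, widths[i])
      params[[paste0(prefix, ".", i, ".beta")]] <- numeric(widths[i])
      state[[paste0(prefix, ".", i, ".mean")]] <- numeric(widths[i])
      state[[paste0(prefix, ".", i, ".var")]] <- rep(1, widths[i])
    }
    d <- widths[i]
  }
  if (!is.na(final_out)) {
    lin <- init_linear(d, final_out)
    params[[paste0(prefix, ".out.W")]] <- lin$W
    params[[paste0(prefix, ".out.b")]] <- lin$b
  }
  list(params = params, state = state, d_out = d)
}

#' Build an untrained representation model
#'
#' @param cfg a [net_config()].
#' @param d number of input covariates (the treatment indicator is appended
#'   automatically for the `deepsurv` variant).
#' @return an object of class `bites_model` holding the parameter list, the
#'   batch-normalization running statistics and the configuration. For the
#'   `t-deepsurv` variant the object wraps two single-head models (`m0`,
#'   `m1`).
#' @export
build_model <- function(cfg, d) {
  stopifnot(inherits(cfg, "net_config"))
  if (d < 1) stop("invalid input dimension d")
  if (cfg$variant == "t-deepsurv") {
    sub <- cfg; sub$variant <- "single"
    m0 <- build_model_single(sub, d, seed = cfg$seed)
    m1 <- build_model_single(sub, d, seed = cfg$seed + 1L)
    return(structure(list(cfg = cfg, d_in = d, m0 = m0, m1 = m1),
                     class = "bites_model"))
  }
  local_rng(cfg$seed)
  d_in <- if (cfg$variant == "deepsurv") d + 1L else d
  params <- list(); state <- list()
  st <- init_stack(params, state, "trunk", d_in, cfg$shared_layers, cfg)
  params <- st$params; state <- st$state; latent_dim <- st$d_out
  heads <- if (cfg$variant %in% c("deepsurv", "single")) "head0" else c("head0", "head1")
  for (hname in heads) {
    st <- init_stack(params, state, hname, latent_dim, cfg$head_layers, cfg,
                     final_out = 1L)
    params <- st$params; state <- st$state
  }
  structure(list(cfg = cfg, d_in = d_in, d_raw = d, latent_dim = latent_dim,
                 params = params, state = state, scaler = NULL, q = NULL,
                 history = NULL),
            class = "bites_model")
}

build_model_single <- function(cfg, d, seed) {
  sub <- cfg; sub$variant <- "single"; sub$seed <- as.integer(seed)
  class(sub) <- "net_config"
  build_model(sub, d)
}

#' @export
print.bites_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("bites_model (variant %s): trunk [%s], heads [%s], alpha = %g, epsilon = %g\n",
              cfg$variant, paste(cfg$shared_layers, collapse = ","),
              paste(cfg$head_layers, collapse = ","), cfg$alpha, cfg$ipm$epsilon))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best validation loss %.5g\n",
                nrow(x$history), min(x$history$val_total)))
  invisible(x)
}

# Forward pass through a block stack. Returns the output, per-block caches
# for backpropagation, and updated running statistics.
forward_stack <- function(model, prefix, X, training, update_state = training) {
  cfg <- model$cfg
  params <- model$params; state <- model$state
  widths <- if (prefix == "trunk") cfg$shared_layers else cfg$head_layers
  caches <- vector("list", length(widths))
  A <- X
  for (i in seq_along(widths)) {
    key <- function(s) paste0(prefix, ".", i, ".", s)
    Z <- A %*% params[[key("W")]]
    Z <- sweep(Z, 2, params[[key("b")]], "+")
    R <- pmax(Z, 0)
    mask <- NULL
    D <- R
    if (training && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(stats::rbinom(length(R), 1, keep), nrow(R)) / keep
      D <- R * mask
    }
    if (cfg$use_batchnorm) {
      if (training) {
        mu <- colMeans(D)
        v <- colMeans(sweep(D, 2, mu, "-")^2)
        if (update_state) {
          state[[key("mean")]] <- 0.9 * state[[key("mean")]] + 0.1 * mu
          state[[key("var")]] <- 0.9 * state[[key("var")]] + 0.1 * v
        }
      } else {
        mu <- state[[key("mean")]]
        v <- state[[key("var")]]
      }
      istd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(D, 2, mu, "-"), 2, istd, "*")
      out <- sweep(sweep(xhat, 2, params[[key("gamma")]], "*"), 2,
                   params[[key("beta")]], "+")
    } else {
      xhat <- NULL; istd <- NULL
      out <- D
    }
    caches[[i]] <- list(A_in = A, Z = Z, mask = mask, xhat = xhat, istd = istd,
                        batch_train = training)
    A <- out
  }
  final <- NULL
  if (!is.null(params[[paste0(prefix, ".out.W")]])) {
    final <- A
    A <- sweep(A %*% params[[paste0(prefix, ".out.W")]], 2,
               params[[paste0(prefix, ".out.b")]], "+")
  }
  list(out = A, caches = caches, final_in = final, state = state)
}

# Backward pass mirroring forward_stack. dOut has the stack output's shape.
# Returns gradient w.r.t. the stack input and a flat named gradient list.
backward_stack <- function(model, prefix, fw, dOut) {
  cfg <- model$cfg
  params <- model$params
  widths <- if (prefix == "trunk") cfg$shared_layers else cfg$head_layers
  grads <- list()
  dA <- dOut
  if (!is.null(params[[paste0(prefix, ".out.W")]])) {
    W <- params[[paste0(prefix, ".out.W")]]
    grads[[paste0(prefix, ".out.W")]] <- crossprod(fw$final_in, dA)
    grads[[paste0(prefix, ".out.b")]] <- colSums(dA)
    dA <- dA %*% t(W)
  }
  for (i in rev(seq_along(widths))) {
    key <- function(s) paste0(prefix, ".", i, ".", s)
    cache <- fw$caches[[i]]
    if (cfg$use_batchnorm) {
      xhat <- cache$xhat; istd <- cache$istd
      gam <- params[[key("gamma")]]
      grads[[key("gamma")]] <- colSums(dA * xhat)
      grads[[key("beta")]] <- colSums(dA)
      dxhat <- sweep(dA, 2, gam, "*")
      if (cache$batch_train) {
        m <- nrow(dA)
        sum_d <- colSums(dxhat)
        sum_dx <- colSums(dxhat * xhat)
        dD <- sweep(m * dxhat, 2, sum_d, "-")
        dD <- dD - sweep(xhat, 2, sum_dx, "*")
        dD <- sweep(dD, 2, istd / m, "*")
      } else {
        dD <- sweep(dxhat, 2, istd, "*")
      }
    } else {
      dD <- dA
    }
    if (!is.null(cache$mask)) dD <- dD * cache$mask
    dZ <- dD * (cache$Z > 0)
    grads[[key("W")]] <- crossprod(cache$A_in, dZ)
    grads[[key("b")]] <- colSums(dZ)
    dA <- dZ %*% t(params[[key("W")]])
  }
  list(dX = dA, grads = grads)
}

# Composite loss of the balanced two-head network on one (standardized)
# batch, optionally with gradients for every parameter.
# q is the control-cohort fraction of the full training set.
bites_loss_impl <- function(model, x, y, e, t, cfg, q, training = FALSE,
                            gradient = FALSE, update_state = training) {
  variant <- cfg$variant
  if (variant %in% c("deepsurv", "single")) {
    if (variant == "deepsurv") x <- cbind(x, t)
    tr <- forward_stack(model, "trunk", x, training, update_state)
    model$state <- tr$state
    hd <- forward_stack(model, "head0", tr$out, training, update_state)
    model$state <- hd$state
    h <- drop(hd$out)
    cox <- cox_partial_loss(h, y, e, gradient = gradient, reduction = "mean")
    out <- list(total = as.numeric(cox), cox0 = as.numeric(cox), cox1 = NA_real_,
                ipm = NA_real_, state = model$state)
    if (gradient) {
      dh <- matrix(attr(cox, "gradient"), ncol = 1)
      bh <- backward_stack(model, "head0", hd, dh)
      bt <- backward_stack(model, "trunk", tr, bh$dX)
      out$grads <- c(bh$grads, bt$grads)
    }
    return(out)
  }
  i0 <- which(t == 0L); i1 <- which(t == 1L)
  tr <- forward_stack(model, "trunk", x, training, update_state)
  model$state <- tr$state
  Phi <- tr$out
  n <- nrow(x)
  cox0 <- 0; cox1 <- 0
  h0_fw <- h1_fw <- NULL
  if (length(i0)) {
    h0_fw <- forward_stack(model, "head0", Phi[i0, , drop = FALSE], training, update_state)
    model$state <- h0_fw$state
    cox0 <- cox_partial_loss(drop(h0_fw$out), y[i0], e[i0], gradient = gradient,
                             reduction = "mean")
  }
  if (length(i1)) {
    h1_fw <- forward_stack(model, "head1", Phi[i1, , drop = FALSE], training, update_state)
    model$state <- h1_fw$state
    cox1 <- cox_partial_loss(drop(h1_fw$out), y[i1], e[i1], gradient = gradient,
                             reduction = "mean")
  }
  ipm_term <- 0
  ipm_missing_arm <- !length(i0) || !length(i1)
  sink <- NULL
  s1 <- i1; s0 <- i0
  if (cfg$alpha > 0) {
    if (ipm_missing_arm) {
      warning("batch contains a single treatment arm: IPM term skipped")
    } else {
      cap <- if (training && !is.null(cfg$ipm_subsample)) cfg$ipm_subsample else Inf
      if (length(s1) > cap) s1 <- sort(sample(i1, cap))
      if (length(s0) > cap) s0 <- sort(sample(i0, cap))
      sink <- sinkhorn_divergence(Phi[s1, , drop = FALSE], Phi[s0, , drop = FALSE],
                                  cfg$ipm, gradient = gradient)
      ipm_term <- as.numeric(sink)
    }
  }
  total <- q * as.numeric(cox0) + (1 - q) * as.numeric(cox1) + cfg$alpha * ipm_term
  out <- list(total = total, cox0 = as.numeric(cox0), cox1 = as.numeric(cox1),
              ipm = ipm_term, state = model$state)
  if (gradient) {
    dPhi <- matrix(0, n, ncol(Phi))
    grads <- list()
    if (length(i0)) {
      b0 <- backward_stack(model, "head0", h0_fw,
                           matrix(q * attr(cox0, "gradient"), ncol = 1))
      dPhi[i0, ] <- dPhi[i0, ] + b0$dX
      grads <- add_grads(grads, b0$grads)
    }
    if (length(i1)) {
      b1 <- backward_stack(model, "head1", h1_fw,
                           matrix((1 - q) * attr(cox1, "gradient"), ncol = 1))
      dPhi[i1, ] <- dPhi[i1, ] + b1$dX
      grads <- add_grads(grads, b1$grads)
    }
    if (!is.null(sink)) {
      dPhi[s1, ] <- dPhi[s1, ] + cfg$alpha * attr(sink, "grad_a")
      dPhi[s0, ] <- dPhi[s0, ] + cfg$alpha * attr(sink, "grad_b")
    }
    bt <- backward_stack(model, "trunk", tr, dPhi)
    grads <- add_grads(grads, bt$grads)
    out$grads <- grads
  }
  out
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

#' Composite training loss on a batch
#'
#' Evaluates the weighted treatment-specific Cox partial-likelihood terms
#' plus the Sinkhorn balancing penalty on the latent representation:
#' `total = q * cox0 + (1 - q) * cox1 + alpha * S(Phi(x1), Phi(x0))`, with
#' `q` the control-cohort fraction of the training set and risk sets formed
#' within the batch and within each arm. The Cox terms are per-event means
#' (`reduction = "mean"` of [cox_partial_loss()]): weighting the per-event
#' mean of each arm by its cohort fraction makes the composite an equal
#' per-event average over the whole batch, so a rare arm is not drowned
#' out.
#'
#' @param model a [build_model()] result (two-head variants).
#' @param batch a [survival_dataset()] on the original covariate scale; a
#'   trained model's stored scaler is applied automatically (an untrained
#'   model takes the covariates as given).
#' @param cfg the [net_config()] in use.
#' @param q control-cohort fraction; defaults to the model's stored training
#'   value, falling back to the batch's own fraction.
#' @param training evaluate with training-mode stochastic layers (dropout,
#'   batch statistics). The default `FALSE` gives the deterministic
#'   evaluation-mode value.
#' @return list with `total`, `cox0`, `cox1` and `ipm` components.
#' @export
bites_loss <- function(model, batch, cfg = model$cfg, q = NULL, training = FALSE) {
  stopifnot(inherits(batch, "survival_dataset"))
  if (model$cfg$variant == "t-deepsurv")
    stop("bites_loss applies to single-network variants; train t-deepsurv arms separately")
  if (is.null(q)) q <- if (!is.null(model$q)) model$q else mean(batch$t == 0L)
  x <- if (!is.null(model$scaler)) apply_scaler(model$scaler, batch$x) else batch$x
  res <- bites_loss_impl(model, x, batch$y, batch$e, batch$t, cfg, q,
                         training = training, gradient = FALSE,
                         update_state = FALSE)
  res[c("total", "cox0", "cox1", "ipm")]
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && grepl("\\.W$", nm)) g <- g + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# Stratified minibatches: each arm is shuffled and dealt across batches so
# every batch carries both arms in (approximately) the training proportion.
make_batches <- function(t, batch_size) {
  n <- length(t)
  nb <- max(1L, ceiling(n / batch_size))
  assign_arm <- function(idx) {
    idx <- idx[sample.int(length(idx))]
    split(idx, rep_len(seq_len(nb), length(idx)))
  }
  b0 <- assign_arm(which(t == 0L))
  b1 <- assign_arm(which(t == 1L))
  lapply(seq_len(nb), function(k) {
    c(b0[[as.character(k)]], b1[[as.character(k)]])
  })
}

#' Train a representation model
#'
#' Minibatch Adam on the composite loss, with dropout active only during
#' training, batch-normalization running statistics for evaluation, weight
#' decay, and early stopping on the validation loss (the parameters of the
#' best validation epoch are returned). Covariates are standardized to zero
#' mean and unit variance using training-set statistics; the scaler is
#' stored in the model and applied automatically at prediction time.
#'
#' @param model a freshly built [build_model()] (its input dimension must
#'   match the data).
#' @param train,val disjoint [survival_dataset()]s.
#' @param cfg a [net_config()]; defaults to the model's.
#' @return the trained `bites_model`, with `history` (per-epoch losses),
#'   `scaler`, `q` and per-arm follow-up horizons filled in.
#' @export
train_model <- function(model, train, val, cfg = model$cfg) {
  stopifnot(inherits(model, "bites_model"), inherits(train, "survival_dataset"),
            inherits(val, "survival_dataset"))
  if (cfg$variant == "t-deepsurv") {
    sub <- cfg; sub$variant <- "single"; class(sub) <- "net_config"
    tr0 <- subset_dataset(train, train$t == 0L); va0 <- subset_dataset(val, val$t == 0L)
    tr1 <- subset_dataset(train, train$t == 1L); va1 <- subset_dataset(val, val$t == 1L)
    model$m0 <- train_model(model$m0, tr0, va0, modifyList(sub, list(seed = cfg$seed)))
    model$m1 <- train_model(model$m1, tr1, va1, modifyList(sub, list(seed = cfg$seed + 1L)))
    model$q <- mean(train$t == 0L)
    model$horizon0 <- max(tr0$y); model$horizon1 <- max(tr1$y)
    model$history <- list(m0 = model$m0$history, m1 = model$m1$history)
    return(model)
  }
  local_rng(cfg$seed)
  scaler <- fit_scaler(train$x)
  xtr <- apply_scaler(scaler, train$x)
  xva <- apply_scaler(scaler, val$x)
  q <- mean(train$t == 0L)
  model$scaler <- scaler
  model$q <- q
  model$cfg <- cfg
  if (any(train$t == 0L)) model$horizon0 <- max(train$y[train$t == 0L])
  if (any(train$t == 1L)) model$horizon1 <- max(train$y[train$t == 1L])
  # minibatch penalty evaluation tolerates an occasional unconverged plan
  cfg_run <- cfg
  cfg_run$ipm$strict <- FALSE
  opt <- adam_init(model$params)
  best <- list(val = Inf, params = model$params, state = model$state, epoch = 0L)
  since_best <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_epoch <- cfg$learning_rate * cfg$lr_decay^(epoch - 1L)
    batches <- make_batches(train$t, cfg$batch_size)
    ep_tot <- ep_c0 <- ep_c1 <- ep_ipm <- 0
    for (idx in batches) {
      res <- suppressWarnings(
        bites_loss_impl(model, xtr[idx, , drop = FALSE], train$y[idx],
                        train$e[idx], train$t[idx], cfg_run, q,
                        training = TRUE, gradient = TRUE))
      if (!is.finite(res$total))
        stop("training loss diverged (non-finite) at epoch ", epoch)
      model$state <- res$state
      upd <- adam_step(model$params, res$grads, opt, lr_epoch, cfg$weight_decay)
      model$params <- upd$params
      opt <- upd$opt
      w <- length(idx) / train$n
      ep_tot <- ep_tot + w * res$total
      ep_c0 <- ep_c0 + w * res$cox0
      ep_c1 <- ep_c1 + w * res$cox1
      ep_ipm <- ep_ipm + w * ifelse(is.na(res$ipm), 0, res$ipm)
    }
    vres <- suppressWarnings(
      bites_loss_impl(model, xva, val$y, val$e, val$t, cfg_run, q,
                      training = FALSE, gradient = FALSE, update_state = FALSE))
    if (!is.finite(vres$total))
      stop("validation loss diverged (non-finite) at epoch ", epoch)
    hist[[epoch]] <- data.frame(epoch = epoch, train_total = ep_tot,
                                train_cox0 = ep_c0, train_cox1 = ep_c1,
                                train_ipm = ep_ipm, val_total = vres$total,
                                val_cox0 = vres$cox0, val_cox1 = vres$cox1,
                                val_ipm = ifelse(is.na(vres$ipm), 0, vres$ipm))
    if (vres$total < best$val - 1e-12) {
      best <- list(val = vres$total, params = model$params, state = model$state,
                   epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > cfg$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

#' Predict log-hazard scores under both arms
#'
#' Deterministic evaluation-mode forward pass (dropout off, running batch
#' statistics). Covariates are standardized with the stored training
#' scaler unless `standardize = FALSE`.
#'
#' @param model a trained (or freshly built) `bites_model`.
#' @param x covariate matrix on the original scale.
#' @param standardize apply the model's stored scaler (default when one is
#'   stored).
#' @return list with numeric vectors `h0` and `h1`: predicted log-hazards
#'   under control and treatment. For `deepsurv` the single head is
#'   evaluated with the treatment input set to 0 and 1; for `t-deepsurv`
#'   each arm's own network is used.
#' @export
predict_log_hazards <- function(model, x, standardize = !is.null(model$scaler)) {
  x <- as.matrix(x)
  cfg <- model$cfg
  if (cfg$variant == "t-deepsurv") {
    return(list(h0 = predict_log_hazards(model$m0, x)$h0,
                h1 = predict_log_hazards(model$m1, x)$h0))
  }
  if (standardize) {
    if (is.null(model$scaler)) stop("model carries no scaler; train first or pass standardize = FALSE")
    x <- apply_scaler(model$scaler, x)
  }
  if (ncol(x) + (cfg$variant == "deepsurv") != model$d_in)
    stop("covariate dimension mismatch: expected ",
         model$d_in - (cfg$variant == "deepsurv"), " columns, got ", ncol(x))
  eval_head <- function(xin, head) {
    tr <- forward_stack(model, "trunk", xin, training = FALSE)
    drop(forward_stack(model, head, tr$out, training = FALSE)$out)
  }
  if (cfg$variant %in% c("deepsurv")) {
    list(h0 = eval_head(cbind(x, 0), "head0"), h1 = eval_head(cbind(x, 1), "head0"))
  } else if (cfg$variant == "single") {
    list(h0 = eval_head(x, "head0"), h1 = NULL)
  } else {
    tr <- forward_stack(model, "trunk", x, training = FALSE)
    list(h0 = drop(forward_stack(model, "head0", tr$out, training = FALSE)$out),
         h1 = drop(forward_stack(model, "head1", tr$out, training = FALSE)$out))
  }
}

#' Latent representation of covariates
#'
#' Evaluation-mode output of the shared trunk, used e.g. to measure how
#' balanced the treated and control representations are.
#'
#' @inheritParams predict_log_hazards
#' @return numeric matrix of latent coordinates.
#' @export
latent_representation <- function(model, x, standardize = !is.null(model$scaler)) {
  x <- as.matrix(x)
  if (model$cfg$variant == "t-deepsurv")
    stop("t-deepsurv has no shared latent representation")
  if (standardize) x <- apply_scaler(model$scaler, x)
  if (model$cfg$variant == "deepsurv") x <- cbind(x, 0)
  forward_stack(model, "trunk", x, training = FALSE)$out
}
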