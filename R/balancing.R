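#' Configuration for integral probability metric computations
#'
#' @param p cost exponent of the ground metric `||x - y||^p`; must be in
#'   `[1, Inf)`. The default 2 gives the quadratic-Wasserstein family.
#' @param epsilon entropic smoothing strength, `>= 0`. Zero requests the
#'   exact (unsmoothed) optimal transport solver, available for small
#'   equal-size uniform clouds only.
#' @param max_iters Sinkhorn iteration cap.
#' @param tolerance convergence tolerance on the worst marginal violation of
#'   the transport plan.
#' @param strict if `TRUE` (default), failing to reach `tolerance` within
#'   `max_iters` is an error; if `FALSE`, a warning is issued and the
#'   current iterate is used. The trainer relaxes this for minibatch
#'   penalty evaluation, where an occasional slightly-unconverged plan only
#'   perturbs one stochastic gradient step.
#' @return list of class `ipm_config`.
#' @export
ipm_config <- function(p = 2, epsilon = 0.1, max_iters = 1000L, tolerance = 1e-6,
                       strict = TRUE) {
  if (p < 1) stop("cost exponent p must be >= 1")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(p = p, epsilon = epsilon, max_iters = as.integer(max_iters),
                 tolerance = tolerance, strict = isTRUE(strict)),
            class = "ipm_config")
}

#' Weighted point cloud (empirical probability measure)
#'
#' @param points numeric matrix, one row per support point.
#' @param weights probability weights; default uniform.
#' @return list of class `point_cloud`.
#' @export
point_cloud <- function(points, weights = NULL) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 1) stop("a point cloud needs at least one point")
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0))
    stop("weights must be non-negative, one per point")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(list(points = points, weights = weights / s), class = "point_cloud")
}

as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x else point_cloud(x)
}

#' Pairwise transport cost matrix
#'
#' `C[i, j] = ||a_i - b_j||^p` with the Euclidean norm.
#'
#' @param a,b point clouds (or plain matrices, taken as uniform clouds).
#' @param p cost exponent.
#' @return an `m x n` cost matrix.
#' @export
cost_matrix <- function(a, b, p = 2) {
  a <- as_point_cloud(a); b <- as_point_cloud(b)
  A <- a$points; B <- b$points
  if (ncol(A) != ncol(B)) stop("point clouds must share dimensionality")
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  if (p == 2) sq else sq^(p / 2)
}

#' Entropically smoothed optimal transport loss
#'
#' The minimum over couplings of `<pi, C> + epsilon * KL(pi | P (x) Q)`,
#' computed with log-domain Sinkhorn fixed-point iteration (with an
#' epsilon-scaling warm start for small `epsilon`). At `epsilon = 0` an
#' exact assignment solver is dispatched, restricted to uniform equal-size
#' clouds of at most 64 points.
#'
#' @param a,b point clouds (or matrices).
#' @param cfg an [ipm_config()].
#' @return the scalar loss, with the optimal plan and dual potentials
#'   attached as attributes `"plan"`, `"f"`, `"g"`.
#' @export
smoothed_ot <- function(a, b, cfg = ipm_config()) {
  a <- as_point_cloud(a); b <- as_point_cloud(b)
  C <- cost_matrix(a, b, cfg$p)
  if (cfg$epsilon == 0) return(exact_ot(a, b, C))
  res <- sinkhorn_potentials(C, a$weights, b$weights, cfg)
  pi_log <- (outer(res$f, res$g, "+") - C) / cfg$epsilon +
    outer(log(a$weights), log(b$weights), "+")
  plan <- exp(pi_log)
  kl <- sum(ifelse(plan > 0, plan * (pi_log - outer(log(a$weights), log(b$weights), "+")), 0)) -
    sum(plan) + 1
  value <- sum(plan * C) + cfg$epsilon * kl
  structure(value, plan = plan, f = res$f, g = res$g, iterations = res$iterations)
}

# Log-domain Sinkhorn on dual potentials f, g. Convergence is declared when
# both marginals of the implied plan match the target weights to tolerance.
sinkhorn_potentials <- function(C, wa, wb, cfg) {
  eps_target <- cfg$epsilon
  la <- log(wa); lb <- log(wb)
  f <- numeric(length(wa)); g <- numeric(length(wb))
  # epsilon-scaling warm start: anneal from near the cost scale down to target
  pos <- C[C > 0]
  med <- if (length(pos)) stats::median(pos) else 0
  eps_seq <- eps_target
  if (med > eps_target) {
    k <- ceiling(log(med / eps_target) / log(3))
    eps_seq <- eps_target * 3^(min(k, 8):0)
  }
  total_it <- 0L
  for (eps in eps_seq) {
    final <- (eps == eps_target)
    for (it in seq_len(cfg$max_iters)) {
      total_it <- total_it + 1L
      # f_i <- -eps * LSE_j [ log wb_j + (g_j - C_ij) / eps ]
      Sf <- sweep(sweep(-C, 2, g, "+") / eps, 2, lb, "+")
      f <- -eps * lse_rows(Sf)
      Sg <- sweep((-C + f) / eps, 1, la, "+")
      g <- -eps * lse_cols(Sg)
      if (!final && it >= 5L) break
      if (final) {
        pl <- exp(sweep(sweep(-C, 2, g, "+"), 1, f, "+") / eps + outer(la, lb, "+"))
        viol <- max(abs(colSums(pl) - wb), abs(rowSums(pl) - wa))
        if (viol <= cfg$tolerance) return(list(f = f, g = g, iterations = total_it))
      }
    }
    if (!final) next
    msg <- paste0("Sinkhorn iteration did not reach tolerance ", cfg$tolerance,
                  " within ", cfg$max_iters, " iterations (", total_it,
                  " total updates)")
    if (!isFALSE(cfg$strict)) stop(msg)
    warning(msg)
    return(list(f = f, g = g, iterations = total_it))
  }
}

# Stabilized row/column log-sum-exp of a matrix of log-terms.
lse_rows <- function(S) {
  mx <- apply(S, 1, max)
  mx + log(rowSums(exp(S - mx)))
}
lse_cols <- function(S) {
  mx <- apply(S, 2, max)
  mx + log(colSums(exp(sweep(S, 2, mx, "-"))))
}

# Exact OT at epsilon = 0: uniform equal-size clouds reduce to a linear
# assignment problem, solved by the Hungarian algorithm.
exact_ot <- function(a, b, C) {
  m <- nrow(C); n <- ncol(C)
  if (m > 64 || n > 64)
    stop("exact (epsilon = 0) transport is limited to at most 64 points; use epsilon > 0")
  uniform <- function(w) max(abs(w - 1 / length(w))) < 1e-12
  if (m != n || !uniform(a$weights) || !uniform(b$weights))
    stop("exact (epsilon = 0) transport requires uniform equal-size clouds; use epsilon > 0")
  assign_cols <- hungarian(C)
  plan <- matrix(0, m, n)
  plan[cbind(seq_len(m), assign_cols)] <- 1 / m
  value <- sum(C[cbind(seq_len(m), assign_cols)]) / m
  structure(value, plan = plan, f = NULL, g = NULL, iterations = NA_integer_)
}

# O(n^3) Hungarian algorithm (potentials + augmenting paths).
# Returns, for each row, the assigned column of a minimum-cost perfect
# matching on the square cost matrix.
hungarian <- function(C) {
  n <- nrow(C)
  INF <- Inf
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                  # columns are 1-indexed with a virtual column 1
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- C[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' Debiased Sinkhorn divergence
#'
#' `S = W(P, Q) - W(P, P) / 2 - W(Q, Q) / 2` with `W` the
#' [smoothed_ot()] loss. Symmetric, non-negative up to solver tolerance,
#' zero when the clouds coincide, and differentiable in the point
#' coordinates. It interpolates between exact quadratic-Wasserstein
#' transport (`epsilon -> 0`) and a kernel maximum mean discrepancy
#' (`epsilon -> Inf`).
#'
#' @inheritParams smoothed_ot
#' @param gradient if `TRUE`, attach gradients of the divergence with
#'   respect to the coordinates of `a` and `b` (attributes `"grad_a"`,
#'   `"grad_b"`), obtained from the optimal plans (envelope theorem).
#' @return the scalar divergence.
#' @export
sinkhorn_divergence <- function(a, b, cfg = ipm_config(), gradient = FALSE) {
  a <- as_point_cloud(a); b <- as_point_cloud(b)
  w_ab <- smoothed_ot(a, b, cfg)
  w_aa <- smoothed_ot(a, a, cfg)
  w_bb <- smoothed_ot(b, b, cfg)
  value <- as.numeric(w_ab) - 0.5 * as.numeric(w_aa) - 0.5 * as.numeric(w_bb)
  out <- value
  if (gradient) {
    ga <- ot_point_grad(attr(w_ab, "plan"), a, b, cfg$p, side = "row") -
      0.5 * ot_self_grad(attr(w_aa, "plan"), a, cfg$p)
    gb <- ot_point_grad(attr(w_ab, "plan"), b, a, cfg$p, side = "col") -
      0.5 * ot_self_grad(attr(w_bb, "plan"), b, cfg$p)
    attr(out, "grad_a") <- ga
    attr(out, "grad_b") <- gb
  }
  out
}

# Gradient of <plan, C(a, b)> w.r.t. the coordinates of one side.
# d ||r||^p / d a_i = p ||r||^(p-2) r with r = a_i - b_j.
ot_point_grad <- function(plan, a, b, p, side = c("row", "col")) {
  side <- match.arg(side)
  if (side == "col") plan <- t(plan)
  A <- a$points; B <- b$points
  if (p == 2) {
    2 * (plan %*% matrix(1, ncol(plan), 1))[, 1] * A - 2 * plan %*% B
  } else {
    G <- matrix(0, nrow(A), ncol(A))
    for (i in seq_len(nrow(A))) {
      r <- sweep(-B, 2, A[i, ], "+")        # a_i - b_j rows
      nr <- sqrt(rowSums(r^2))
      coef <- ifelse(nr > 0, p * nr^(p - 2), 0) * plan[i, ]
      G[i, ] <- colSums(r * coef)
    }
    G
  }
}

# Gradient of W(a, a): a enters as both marginals.
ot_self_grad <- function(plan, a, p) {
  ot_point_grad(plan, a, a, p, side = "row") +
    ot_point_grad(t(plan), a, a, p, side = "row")
}

#' Kernel maximum mean discrepancy between point clouds
#'
#' V-statistic estimate. With the default energy kernel
#' `k(x, y) = -||x - y||^p` the value returned is
#' `E[C(X, Y)] - E[C(X, X')] / 2 - E[C(Y, Y')] / 2` (half the squared
#' energy MMD), which is exactly the large-`epsilon` limit of
#' [sinkhorn_divergence()] with the same cost exponent. With
#' `kernel = "gaussian"` the standard squared-MMD V-statistic is returned.
#'
#' @param a,b point clouds (or matrices).
#' @param kernel `"energy"` (default) or `"gaussian"`.
#' @param p cost exponent of the energy kernel.
#' @param bandwidth Gaussian kernel bandwidth (`> 0`).
#' @return scalar discrepancy (non-negative for the V-statistic).
#' @export
mmd <- function(a, b, kernel = c("energy", "gaussian"), p = 2, bandwidth = 1) {
  kernel <- match.arg(kernel)
  a <- as_point_cloud(a); b <- as_point_cloud(b)
  wa <- a$weights; wb <- b$weights
  mean_c <- function(M, w1, w2) drop(crossprod(w1, M %*% w2))
  if (kernel == "energy") {
    Cab <- cost_matrix(a, b, p)
    Caa <- cost_matrix(a, a, p)
    Cbb <- cost_matrix(b, b, p)
    mean_c(Cab, wa, wb) - 0.5 * mean_c(Caa, wa, wa) - 0.5 * mean_c(Cbb, wb, wb)
  } else {
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    k <- function(M) exp(-M / (2 * bandwidth^2))
    Kab <- k(cost_matrix(a, b, 2))
    Kaa <- k(cost_matrix(a, a, 2))
    Kbb <- k(cost_matrix(b, b, 2))
    mean_c(Kaa, wa, wa) + mean_c(Kbb, wb, wb) - 2 * mean_c(Kab, wa, wb)
  }
}
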