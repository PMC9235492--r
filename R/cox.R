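#' Negative Cox partial log-likelihood
#'
#' Evaluates the negative partial log-likelihood of the proportional-hazards
#' model for a vector of log-hazard scores: the sum over events of
#' `log(sum_{j in R_i} exp(h_j)) - h_i`, with risk set
#' `R_i = {j : y_j >= y_i}`. Tied event times are handled with the Breslow
#' approximation (one log-sum-exp per distinct event time, counted with
#' multiplicity). The log-sum-exp is stabilized by max subtraction.
#'
#' @param h numeric vector of log-hazard scores (the linear predictor
#'   `beta' x` or a network output).
#' @param y observed times.
#' @param e event indicators (0/1).
#' @param gradient if `TRUE`, attach the exact gradient with respect to `h`
#'   as attribute `"gradient"`.
#' @param reduction `"sum"` (the partial log-likelihood as printed) or
#'   `"mean"` (divided by the number of events, the form used inside the
#'   composite training loss so that arms contribute per event rather than
#'   per arm size).
#' @return the scalar loss; zero (with attribute `"no_events" = TRUE`) when
#'   no events are present, since every partial-likelihood term vanishes.
#' @export
cox_partial_loss <- function(h, y, e, gradient = FALSE,
                             reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  n <- length(h)
  if (length(y) != n || length(e) != n)
    stop("h, y and e must have equal length")
  if (any(!is.finite(h))) stop("log-hazard scores must be finite")
  if (!any(e == 1)) {
    warning("no events in batch: Cox partial loss is 0")
    out <- 0
    attr(out, "no_events") <- TRUE
    if (gradient) attr(out, "gradient") <- numeric(n)
    return(out)
  }
  ord <- order(y, decreasing = TRUE)  # largest time first: risk sets by cumsum
  hs <- h[ord]; ys <- y[ord]; es <- e[ord]
  m <- max(hs)
  w <- exp(hs - m)
  cw <- cumsum(w)  # cw[k] = sum of exp(h - m) over the k largest times
  # ties: every subject with the same y shares the full risk set at that y;
  # walk backwards so each position points at the last index of its tie group
  last_at_time <- tie_group_last(ys)
  denom <- cw[last_at_time]
  ev <- which(es == 1)
  scale <- if (reduction == "mean") 1 / length(ev) else 1
  loss <- scale * sum(log(denom[ev]) + m - hs[ev])
  out <- loss
  if (gradient) {
    # d loss / d h_k = exp(h_k) * sum_{events i : y_i <= y_k} 1/denom_i - e_k
    inv <- numeric(n)
    inv[ev] <- 1 / denom[ev]
    rc <- rev(cumsum(rev(inv)))  # rc[k] = sum of inv over positions >= k
    # tied times: events tied with y_k also satisfy y_i <= y_k, so the sum
    # starts at the first position of k's tie group
    first_at_time <- seq_len(n)
    if (n > 1L) {
      for (k in 2:n) if (ys[k] == ys[k - 1L]) first_at_time[k] <- first_at_time[k - 1L]
    }
    g_sorted <- scale * (w * rc[first_at_time] - es)
    g <- numeric(n)
    g[ord] <- g_sorted
    attr(out, "gradient") <- g
  }
  out
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' Given fitted log-hazard scores, steps the cumulative baseline hazard at
#' each distinct event time `u` by `d_u / sum_{j : y_j >= u} exp(h_j)`,
#' where `d_u` is the number of events at `u`.
#'
#' @inheritParams cox_partial_loss
#' @return an object of class `baseline_hazard`: list with strictly
#'   increasing `times` (distinct event times) and the non-decreasing
#'   `cum_hazard` evaluated there; the implied step function is
#'   right-continuous with `Lambda0(0) = 0`.
#' @export
breslow_baseline <- function(h, y, e) {
  n <- length(h)
  if (n == 0) stop("empty input")
  if (length(y) != n || length(e) != n) stop("h, y and e must have equal length")
  ord <- order(y, decreasing = TRUE)
  hs <- h[ord]; ys <- y[ord]; es <- e[ord]
  mx <- max(hs)
  cw <- cumsum(exp(hs - mx))
  ev_times <- sort(unique(ys[es == 1]))
  if (!length(ev_times)) {
    return(structure(list(times = numeric(0), cum_hazard = numeric(0)),
                     class = "baseline_hazard"))
  }
  steps <- vapply(ev_times, function(u) {
    at_risk <- which(ys >= u)           # contiguous head of the reversed order
    d_u <- sum(es == 1 & ys == u)
    d_u / (cw[max(at_risk)] * exp(mx))
  }, numeric(1))
  structure(list(times = ev_times, cum_hazard = cumsum(steps)),
            class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat(sprintf("baseline_hazard: %d event times, Lambda0 up to %.4g\n",
              length(x$times), if (length(x$times)) max(x$cum_hazard) else 0))
  invisible(x)
}

#' Evaluate a cumulative baseline hazard at arbitrary times
#'
#' @param b a `baseline_hazard`.
#' @param t times at which to evaluate the right-continuous step function.
#' @return `Lambda0(t)` for each `t`.
#' @export
baseline_at <- function(b, t) {
  if (!length(b$times)) return(numeric(length(t)))
  idx <- findInterval(t, b$times)
  c(0, b$cum_hazard)[idx + 1L]
}

#' Survival curve under proportional hazards
#'
#' Composes a baseline cumulative hazard with a log-hazard score:
#' `S(t) = exp(-Lambda0(t) * exp(h))`.
#'
#' @param b a [breslow_baseline()] result.
#' @param h scalar log-hazard score for the patient.
#' @return an object of class `survival_curve`: list with `times` (starting
#'   at 0) and `surv`, non-increasing in `[0, 1]` with `S(0) = 1`.
#' @export
survival_curve <- function(b, h) {
  if (!is.finite(h)) stop("log-hazard must be finite")
  times <- c(0, b$times)
  s <- exp(-c(0, b$cum_hazard) * exp(h))
  structure(list(times = times, surv = s), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d time points, S(max t = %.3g) = %.4f\n",
              length(x$times), max(x$times), x$surv[length(x$surv)]))
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' @param sc a `survival_curve`.
#' @param t evaluation times; the curve is a right-continuous step function.
#' @return survival probabilities at `t`.
#' @export
survival_at <- function(sc, t) {
  idx <- findInterval(t, sc$times)
  idx[idx < 1L] <- 1L  # S(t < 0) treated as 1
  sc$surv[idx]
}

#' Median survival time of a curve
#'
#' The smallest time at which the survival probability reaches 0.5 or less.
#' When the curve never crosses 0.5 within follow-up the horizon is returned
#' and the result is flagged as capped, so downstream treatment effects stay
#' bounded rather than extrapolated.
#'
#' @param sc a `survival_curve`.
#' @param horizon follow-up horizon; must be at least the last curve time.
#' @return the median time, with attribute `"capped"` set to `TRUE` when the
#'   horizon was returned.
#' @export
median_survival <- function(sc, horizon) {
  if (!length(sc$times)) stop("empty survival curve")
  if (horizon < max(sc$times)) stop("horizon must cover the curve's support")
  hit <- which(sc$surv <= 0.5)
  if (length(hit)) {
    out <- sc$times[hit[1L]]
    attr(out, "capped") <- FALSE
  } else {
    out <- horizon
    attr(out, "capped") <- TRUE
  }
  out
}

#' Linear Cox proportional-hazards fit (one treatment arm)
#'
#' Maximizes the partial likelihood for a linear predictor `beta' x` by
#' damped Newton iteration on the package's own loss, then estimates the
#' baseline hazard with [breslow_baseline()]. Used as one arm of the Cox
#' T-learner baseline: fit it separately on the control and treated subsets.
#'
#' @param ds a [survival_dataset()] already restricted to a single arm (the
#'   treatment column is ignored).
#' @param tol convergence tolerance on the max-norm of the score (gradient).
#' @param max_iter maximum Newton iterations.
#' @return list with `beta` (named coefficients), `baseline`
#'   (a `baseline_hazard`), `loss` (final negative partial log-likelihood),
#'   and `iterations`.
#' @export
fit_linear_cox <- function(ds, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(ds, "survival_dataset"))
  x <- ds$x; y <- ds$y; e <- ds$e
  if (!any(e == 1)) stop("cannot fit a Cox model without events")
  d <- ncol(x)
  beta <- numeric(d)
  obj <- function(b) cox_objective(x, y, e, b)
  cur <- obj(beta)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    g <- cur$grad; H <- cur$hess
    if (max(abs(g)) <= tol) {
      return(list(beta = stats::setNames(beta, colnames(x)),
                  baseline = breslow_baseline(drop(x %*% beta), y, e),
                  loss = cur$loss, iterations = it - 1L))
    }
    # pseudo-inverse Newton step: uninformative directions (e.g. constant
    # covariates) have zero score and are left untouched
    eg <- eigen(H, symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values, 1e-300)
    step <- if (any(keep)) {
      eg$vectors[, keep, drop = FALSE] %*%
        (crossprod(eg$vectors[, keep, drop = FALSE], g) / eg$values[keep])
    } else g
    step <- drop(step)
    if (max(abs(step)) < 1e-12 * (1 + max(abs(beta)))) {
      # step numerically negligible: at the optimum to machine precision
      return(list(beta = stats::setNames(beta, colnames(x)),
                  baseline = breslow_baseline(drop(x %*% beta), y, e),
                  loss = cur$loss, iterations = it - 1L))
    }
    # damping: halve the step while the loss does not decrease
    lambda <- 1
    slack <- 1e-10 * (1 + abs(cur$loss))
    repeat {
      cand <- beta - lambda * step
      cand_obj <- obj(cand)
      if (is.finite(cand_obj$loss) && cand_obj$loss <= cur$loss + slack) break
      lambda <- lambda / 2
      if (lambda < 1e-10)
        stop("Newton step failed to decrease the partial likelihood; ",
             "iteration trace: ", paste(signif(trace, 6), collapse = ", "))
    }
    beta <- cand; cur <- cand_obj
    trace <- c(trace, cur$loss)
    if (sqrt(sum(beta^2)) > 50)
      stop("coefficients diverging (monotone likelihood / separation); ",
           "iteration trace: ", paste(signif(trace, 6), collapse = ", "))
  }
  if (max(abs(cur$grad)) <= tol) {
    return(list(beta = stats::setNames(beta, colnames(x)),
                baseline = breslow_baseline(drop(x %*% beta), y, e),
                loss = cur$loss, iterations = max_iter))
  }
  stop("Cox Newton iteration did not converge after ", max_iter,
       " iterations; loss trace: ", paste(signif(trace, 6), collapse = ", "))
}

# For times sorted in decreasing order, index of the last member of each tie
# group (so cumulative risk-set sums include the whole group).
tie_group_last <- function(ys) {
  n <- length(ys)
  out <- seq_len(n)
  if (n > 1L) {
    for (k in (n - 1L):1L) if (ys[k] == ys[k + 1L]) out[k] <- out[k + 1L]
  }
  out
}

# Loss, score and information of the Breslow partial likelihood for a linear
# predictor. Risk-set sums accumulated over decreasing time in O(n d^2).
cox_objective <- function(x, y, e, beta) {
  n <- nrow(x); d <- ncol(x)
  eta <- drop(x %*% beta)
  m <- max(eta)
  ord <- order(y, decreasing = TRUE)
  xs <- x[ord, , drop = FALSE]; ys <- y[ord]; es <- e[ord]
  w <- exp(eta[ord] - m)
  S0 <- cumsum(w)
  S1 <- apply(xs * w, 2, cumsum)
  if (d == 1L) S1 <- matrix(S1, ncol = 1L)
  # S2 cumulative sum of w * x x'; store as n x (d*d)
  xx <- t(vapply(seq_len(n), function(i) tcrossprod(xs[i, ])[seq_len(d * d)],
                 numeric(d * d)))
  S2 <- apply(xx * w, 2, cumsum)
  if (n == 1L) S2 <- matrix(S2, nrow = 1L)
  last_at_time <- tie_group_last(ys)
  ev <- which(es == 1)
  loss <- 0; grad <- numeric(d); hess <- matrix(0, d, d)
  for (i in ev) {
    r <- last_at_time[i]
    s0 <- S0[r]; s1 <- S1[r, ]; s2 <- matrix(S2[r, ], d, d)
    loss <- loss + log(s0) + m - eta[ord[i]]
    xbar <- s1 / s0
    grad <- grad + xbar - xs[i, ]
    hess <- hess + s2 / s0 - tcrossprod(xbar)
  }
  list(loss = loss, grad = grad, hess = hess)
}

#' Cox T-learner: one linear Cox model per treatment arm
#'
#' @param ds a [survival_dataset()] containing both arms.
#' @param ... passed to [fit_linear_cox()].
#' @return list with elements `arm0` and `arm1`, each a [fit_linear_cox()]
#'   result, plus per-arm follow-up horizons.
#' @export
fit_cox_tlearner <- function(ds, ...) {
  i0 <- ds$t == 0L; i1 <- ds$t == 1L
  if (!any(i0) || !any(i1)) stop("both treatment arms must be present")
  d0 <- subset_dataset(ds, i0)
  d1 <- subset_dataset(ds, i1)
  list(arm0 = fit_linear_cox(d0, ...), arm1 = fit_linear_cox(d1, ...),
       horizon0 = max(d0$y), horizon1 = max(d1$y))
}
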