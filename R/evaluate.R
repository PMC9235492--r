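#' Time-dependent concordance index
#'
#' Fraction of comparable pairs `(i, j)` -- those with `y_i < y_j` and an
#' event for `i` -- whose predicted survival probabilities at the earlier
#' event time are correctly ordered, `S(y_i | x_i) < S(y_i | x_j)`. Tied
#' predicted probabilities count 0.5; tied event times are incomparable.
#' For survival curves that never cross, this reduces to Harrell's
#' concordance on any monotone risk score.
#'
#' @param surv_matrix numeric matrix with entry `[i, j] = S(y_i | x_j)`,
#'   the predicted survival of subject `j` evaluated at subject `i`'s
#'   observed time (see [predicted_survival_matrix()]).
#' @param y observed times.
#' @param e event indicators.
#' @return list with the concordance `c` and the number of comparable
#'   pairs `n_pairs`.
#' @export
c_index_td <- function(surv_matrix, y, e) {
  n <- length(y)
  if (!is.matrix(surv_matrix) || nrow(surv_matrix) != n || ncol(surv_matrix) != n)
    stop("surv_matrix must be an n x n matrix of S(y_i | x_j)")
  conc <- 0; n_pairs <- 0L
  for (i in which(e == 1L)) {
    comp <- which(y > y[i])
    if (!length(comp)) next
    si <- surv_matrix[i, i]
    sj <- surv_matrix[i, comp]
    conc <- conc + sum(si < sj) + 0.5 * sum(si == sj)
    n_pairs <- n_pairs + length(comp)
  }
  if (n_pairs == 0L) stop("no comparable pairs")
  list(c = conc / n_pairs, n_pairs = n_pairs)
}

#' Predicted survival matrix for concordance evaluation
#'
#' Builds the `S(y_i | x_j)` matrix from a trained model and arm-specific
#' baselines, predicting each subject under their factual treatment arm.
#'
#' @param model a trained model.
#' @param baselines an [estimate_baselines()] result.
#' @param ds the evaluation [survival_dataset()].
#' @return an `n x n` matrix suitable for [c_index_td()].
#' @export
predicted_survival_matrix <- function(model, baselines, ds) {
  h <- predict_log_hazards(model, ds$x)
  n <- ds$n
  # S(t | x_j) = exp(-Lambda0_{arm_j}(t) * exp(h_j)) evaluated at all y_i
  L0 <- baseline_at(baselines$b0, ds$y)
  L1 <- baseline_at(baselines$b1, ds$y)
  S <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    if (ds$t[j] == 1L) S[, j] <- exp(-L1 * exp(h$h1[j]))
    else S[, j] <- exp(-L0 * exp(h$h0[j]))
  }
  S
}

#' Precision in estimating heterogeneous effects (PEHE)
#'
#' Mean squared difference between true and estimated individual treatment
#' effects. Reported as the mean square; the root is attached as attribute
#' `"rmse"`.
#'
#' @param tau_true true ITEs (from a simulator's potential outcomes).
#' @param tau_hat estimated ITEs.
#' @return scalar `>= 0`, zero iff the ITEs match exactly.
#' @export
pehe <- function(tau_true, tau_hat) {
  if (length(tau_true) != length(tau_hat)) stop("length mismatch")
  if (!length(tau_true)) stop("need at least one sample")
  out <- mean((tau_true - tau_hat)^2)
  attr(out, "rmse") <- sqrt(out)
  out
}

#' Fraction of correctly assigned best treatments
#'
#' Compares the recommendation implied by the estimated ITE (treat iff
#' `tau_hat > 0`; ties recommend control) with the truly best arm (treat
#' iff `tau_true > 0`).
#'
#' @inheritParams pehe
#' @return fraction in `[0, 1]`.
#' @export
correct_treatment_fraction <- function(tau_true, tau_hat) {
  if (length(tau_true) != length(tau_hat)) stop("length mismatch")
  if (!length(tau_true)) stop("need at least one sample")
  mean(as.integer(tau_hat > 0) == as.integer(tau_true > 0))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param y observed times.
#' @param e event indicators.
#' @return a `survival_curve` with steps at the distinct event times.
#' @export
km_estimate <- function(y, e) {
  if (!length(y)) stop("need at least one subject")
  ev_times <- sort(unique(y[e == 1L]))
  if (!length(ev_times))
    return(structure(list(times = 0, surv = 1), class = "survival_curve"))
  s <- 1
  surv <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    u <- ev_times[k]
    at_risk <- sum(y >= u)
    d <- sum(y == u & e == 1L)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  structure(list(times = c(0, ev_times), surv = c(1, surv)),
            class = "survival_curve")
}

#' Two-sample log-rank test
#'
#' Standard chi-square log-rank statistic with the hypergeometric variance,
#' one degree of freedom.
#'
#' @param y observed times.
#' @param e event indicators.
#' @param group two-level group labels.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(y, e, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("log-rank test requires exactly two groups")
  ev_times <- sort(unique(y[e == 1L]))
  O1 <- E1 <- V <- 0
  for (u in ev_times) {
    at <- y >= u
    n_tot <- sum(at)
    n1 <- sum(at & g == 1L)
    d <- sum(y == u & e == 1L)
    d1 <- sum(y == u & e == 1L & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n_tot
    if (n_tot > 1)
      V <- V + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Stratify survival by recommendation concordance
#'
#' Splits patients into a "recommended" group (applied treatment coincides
#' with the recommended one) and an "anti-recommended" group, estimates a
#' Kaplan-Meier curve per group, and -- when both groups are non-empty --
#' runs the two-sample log-rank test.
#'
#' @param ds a [survival_dataset()] with the applied treatments.
#' @param recs a `recommendation` data.frame aligned with `ds`.
#' @return list with `labels` (factor recommended/anti-recommended), `km`
#'   (named list of curves), `logrank` (or `NULL` if one group is empty)
#'   and `treated_fraction` (share of patients recommended for arm 1).
#' @export
stratify_by_recommendation <- function(ds, recs) {
  if (nrow(recs) != ds$n) stop("recommendations not aligned with dataset")
  concordant <- recs$recommended_arm == ds$t
  labels <- factor(ifelse(concordant, "recommended", "anti-recommended"),
                   levels = c("recommended", "anti-recommended"))
  km <- lapply(split(seq_len(ds$n), labels), function(idx) {
    if (!length(idx)) return(NULL)
    km_estimate(ds$y[idx], ds$e[idx])
  })
  lr <- NULL
  if (all(table(labels) > 0)) lr <- logrank_test(ds$y, ds$e, labels)
  list(labels = labels, km = km, logrank = lr,
       treated_fraction = mean(recs$recommended_arm == 1L))
}

#' Export Kaplan-Meier curves as a long data.frame
#'
#' @param km named list of `survival_curve`s (e.g. from
#'   [stratify_by_recommendation()]).
#' @return data.frame with columns `time`, `survival`, `group`.
#' @export
km_to_frame <- function(km) {
  do.call(rbind, lapply(names(km), function(g) {
    sc <- km[[g]]
    if (is.null(sc)) return(NULL)
    data.frame(time = sc$times, survival = sc$surv, group = g)
  }))
}
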