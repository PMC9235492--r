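#' Arm-specific Breslow baseline hazards for a trained model
#'
#' Estimates the cumulative baseline hazard of each treatment arm from that
#' arm's factual training samples and the corresponding head's log-hazard
#' scores. The `deepsurv` variant, which by construction shares one
#' baseline across arms, gets a single pooled estimate (returned for both
#' arms).
#'
#' @param model a trained [train_model()] result.
#' @param train the training [survival_dataset()] (original covariate
#'   scale).
#' @return list with `b0` and `b1` ([breslow_baseline()] objects) and the
#'   per-arm follow-up horizons `horizon0`, `horizon1` (maximum observed
#'   training time in each arm).
#' @export
estimate_baselines <- function(model, train) {
  stopifnot(inherits(train, "survival_dataset"))
  i0 <- train$t == 0L; i1 <- train$t == 1L
  if (!any(train$e[i0] == 1L)) stop("control arm has no events; baseline hazard undefined")
  if (!any(train$e[i1] == 1L)) stop("treated arm has no events; baseline hazard undefined")
  h <- predict_log_hazards(model, train$x)
  if (model$cfg$variant == "deepsurv") {
    hf <- ifelse(train$t == 1L, h$h1, h$h0)  # factual treatment input
    b <- breslow_baseline(hf, train$y, train$e)
    return(list(b0 = b, b1 = b,
                horizon0 = max(train$y[i0]), horizon1 = max(train$y[i1])))
  }
  list(b0 = breslow_baseline(h$h0[i0], train$y[i0], train$e[i0]),
       b1 = breslow_baseline(h$h1[i1], train$y[i1], train$e[i1]),
       horizon0 = max(train$y[i0]), horizon1 = max(train$y[i1]))
}

#' Individual treatment effects and recommendations
#'
#' For each patient, composes the predicted log-hazards with the
#' arm-specific baseline hazards into survival curves under both arms and
#' takes the difference of median survival times:
#' `tau = median(S1) - median(S0)`. Treatment (arm 1) is recommended when
#' `tau > 0`; ties -- including the case where both medians are capped at
#' the follow-up horizon -- recommend control, so intervention is never
#' suggested without predicted benefit.
#'
#' @param model a trained model.
#' @param baselines an [estimate_baselines()] result.
#' @param x covariate matrix of new patients (original scale).
#' @param curves if `TRUE`, attach the per-patient survival curves under
#'   both arms as attribute `"curves"`.
#' @return data.frame of class `recommendation` with columns `tau` (years),
#'   `recommended_arm` (0/1) and `capped` (`TRUE` when either arm's median
#'   hit its horizon).
#' @export
individual_treatment_effect <- function(model, baselines, x, curves = FALSE) {
  x <- as.matrix(x)
  h <- predict_log_hazards(model, x)
  n <- nrow(x)
  tau <- numeric(n); capped <- logical(n)
  curve_list <- if (curves) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s0 <- survival_curve(baselines$b0, h$h0[i])
    s1 <- survival_curve(baselines$b1, h$h1[i])
    m0 <- median_survival(s0, baselines$horizon0)
    m1 <- median_survival(s1, baselines$horizon1)
    tau[i] <- as.numeric(m1) - as.numeric(m0)
    capped[i] <- attr(m0, "capped") || attr(m1, "capped")
    if (curves) curve_list[[i]] <- list(s0 = s0, s1 = s1)
  }
  out <- data.frame(tau = tau, recommended_arm = as.integer(tau > 0),
                    capped = capped)
  class(out) <- c("recommendation", class(out))
  if (curves) attr(out, "curves") <- curve_list
  out
}

#' Hazard-difference recommendation of the single-network variant
#'
#' The `deepsurv` variant recommends by the sign of the hazard difference
#' `tau_DS = h(T = 1, x) - h(T = 0, x)`: a lower hazard under treatment
#' (`tau_DS < 0`) favours treating. The returned `tau` column stores
#' `-tau_DS` so that, as for the median-survival ITE, positive values mean
#' predicted benefit from treatment.
#'
#' @param model a trained `deepsurv`-variant model.
#' @param x covariate matrix (original scale).
#' @return a `recommendation` data.frame (`capped` is always `FALSE`; no
#'   time scale is involved).
#' @export
deepsurv_recommendation <- function(model, x) {
  if (model$cfg$variant != "deepsurv")
    stop("deepsurv_recommendation requires a model of variant 'deepsurv'")
  h <- predict_log_hazards(model, as.matrix(x))
  tau_ds <- h$h1 - h$h0
  out <- data.frame(tau = -tau_ds, recommended_arm = as.integer(tau_ds < 0),
                    capped = FALSE)
  class(out) <- c("recommendation", class(out))
  out
}

#' Write recommendations to CSV
#'
#' @param recs a `recommendation` data.frame.
#' @param path output file.
#' @export
write_recommendations <- function(recs, path) {
  utils::write.csv(as.data.frame(recs), path, row.names = FALSE)
  invisible(path)
}
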