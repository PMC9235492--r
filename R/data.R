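#' Survival dataset with treatment assignment
#'
#' Bundles the factual training data for treatment-effect estimation from
#' right-censored outcomes: a covariate matrix, the observed time (event or
#' censoring, in years), the event indicator and the binary treatment arm.
#'
#' @param x numeric matrix, one row per patient, one column per covariate.
#'   Column names are kept; unnamed columns are labelled `x1, x2, ...`.
#' @param y non-negative observed times (event time if `e == 1`, censoring
#'   time otherwise).
#' @param e event indicators, 0 (censored) or 1 (event).
#' @param t treatment indicators, 0 (control) or 1 (treated).
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `x`, `y`, `e`, `t` and `n`.
#' @export
survival_dataset <- function(x, y, e, t) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  e <- as.integer(e)
  t <- as.integer(t)
  n <- nrow(x)
  if (length(y) != n || length(e) != n || length(t) != n)
    stop("x, y, e and t must describe the same number of patients")
  if (n < 2) stop("a survival dataset needs at least 2 patients")
  if (anyNA(x) || anyNA(y) || anyNA(e) || anyNA(t))
    stop("missing values are not allowed; drop or impute before construction")
  if (any(y < 0)) stop("observed times must be non-negative")
  if (!all(e %in% c(0L, 1L))) stop("event indicators must be 0 or 1")
  if (!all(t %in% c(0L, 1L))) stop("treatment indicators must be 0 or 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(x = x, y = y, e = e, t = t, n = n),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "survival_dataset: %d patients, %d covariates, %d events (%.1f%%), %d treated (%.1f%%)\n",
    x$n, ncol(x$x), sum(x$e), 100 * mean(x$e), sum(x$t), 100 * mean(x$t)))
  invisible(x)
}

#' Ground-truth dataset with potential outcomes
#'
#' Extends [survival_dataset()] with the uncensored potential outcome times
#' under both arms and the derived true individual treatment effect
#' `tau_true = y1 - y0`. Only the simulators can construct this: for real
#' data the counterfactual outcome is unobservable.
#'
#' @param ds a `survival_dataset` (its `x` may already carry measurement
#'   noise).
#' @param y0,y1 uncensored potential outcome times under control / treatment.
#' @param x_clean the covariate matrix before measurement noise, used for
#'   assignment-mechanism diagnostics.
#' @param scenario label of the generating scenario.
#' @param seed the seed the generator was run with.
#'
#' @return An object of classes `counterfactual_dataset`, `survival_dataset`
#'   with extra fields `y0`, `y1`, `tau_true`, `x_clean`, `scenario`, `seed`.
#' @export
counterfactual_dataset <- function(ds, y0, y1, x_clean = ds$x,
                                   scenario = "unknown", seed = NA_integer_) {
  stopifnot(inherits(ds, "survival_dataset"))
  y0 <- as.numeric(y0); y1 <- as.numeric(y1)
  if (length(y0) != ds$n || length(y1) != ds$n)
    stop("potential outcomes must match the dataset size")
  if (anyNA(y0) || anyNA(y1) || any(!is.finite(y0 - y1)))
    stop("potential outcomes must be finite")
  yf <- ifelse(ds$t == 1L, y1, y0)
  if (any(ds$e == 1L & abs(yf - ds$y) > 1e-8) || any(ds$e == 0L & yf < ds$y - 1e-8))
    stop("factual potential outcome inconsistent with observed (y, e)")
  ds$y0 <- y0
  ds$y1 <- y1
  ds$tau_true <- y1 - y0
  ds$x_clean <- as.matrix(x_clean)
  ds$scenario <- scenario
  ds$seed <- seed
  class(ds) <- c("counterfactual_dataset", class(ds))
  ds
}

#' @export
print.counterfactual_dataset <- function(x, ...) {
  NextMethod()
  cat(sprintf("  scenario '%s' (seed %s): %.1f%% of patients have a positive true ITE\n",
              x$scenario, format(x$seed), 100 * mean(x$tau_true > 0)))
  invisible(x)
}

#' Subset a survival dataset by row index
#'
#' @param ds a `survival_dataset`.
#' @param idx integer or logical row index.
#' @return a dataset of the same class restricted to `idx`.
#' @export
subset_dataset <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , drop = FALSE]
  out$y <- ds$y[idx]
  out$e <- ds$e[idx]
  out$t <- ds$t[idx]
  out$n <- length(out$y)
  for (f in c("y0", "y1", "tau_true"))
    if (!is.null(ds[[f]])) out[[f]] <- ds[[f]][idx]
  if (!is.null(ds$x_clean)) out$x_clean <- ds$x_clean[idx, , drop = FALSE]
  out
}

#' Read a survival dataset from delimited text
#'
#' Expects a header with the reserved columns `time`, `event`, `treatment`;
#' every other column is taken as a covariate. Rows with missing covariates
#' are dropped and counted.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension,
#'   override with `sep`).
#' @param sep field separator; default `","`, or `"\t"` for `.tsv` files.
#' @return a `survival_dataset`; the number of dropped rows is attached as
#'   attribute `"n_dropped"`.
#' @export
read_survival_csv <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  required <- c("time", "event", "treatment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  covar_cols <- setdiff(names(df), required)
  if (!length(covar_cols)) stop("no covariate columns found")
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ds <- survival_dataset(as.matrix(df[covar_cols]), df$time, df$event, df$treatment)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Write a survival dataset as CSV
#'
#' Inverse of [read_survival_csv()]: covariate columns first, then
#' `time,event,treatment`.
#'
#' @param ds a `survival_dataset`.
#' @param path output file.
#' @export
write_survival_csv <- function(ds, path) {
  df <- as.data.frame(ds$x)
  df$time <- ds$y
  df$event <- ds$e
  df$treatment <- ds$t
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write simulator ground truth as CSV
#'
#' Stores the uncensored potential outcomes and the true ITE of a
#' [counterfactual_dataset()].
#'
#' @param ds a `counterfactual_dataset`.
#' @param path output file.
#' @export
write_truth_csv <- function(ds, path) {
  stopifnot(inherits(ds, "counterfactual_dataset"))
  utils::write.csv(data.frame(y0 = ds$y0, y1 = ds$y1, tau_true = ds$tau_true),
                   path, row.names = FALSE)
  invisible(path)
}

# Column-wise standardization fitted on training data only.
fit_scaler <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s < 1e-12] <- 1  # constant columns pass through centred
  list(mean = m, sd = s)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Stratified train/validation split
#'
#' Splits by row, stratifying on the treatment-by-event cross so both parts
#' keep the arm and censoring composition of the full data.
#'
#' @param ds a `survival_dataset`.
#' @param frac fraction of rows assigned to the first part (default 0.8).
#' @param seed integer seed controlling the permutation.
#' @return list with elements `train` and `val`.
#' @export
stratified_split <- function(ds, frac = 0.8, seed = 1L) {
  rng <- local_rng(seed)
  strata <- interaction(ds$t, ds$e, drop = TRUE)
  idx_train <- integer(0)
  for (lev in levels(strata)) {
    rows <- which(strata == lev)
    rows <- rows[sample.int(length(rows))]
    k <- max(1L, round(frac * length(rows)))
    if (k >= length(rows) && length(rows) > 1L) k <- length(rows) - 1L
    idx_train <- c(idx_train, rows[seq_len(k)])
  }
  idx_train <- sort(idx_train)
  idx_val <- setdiff(seq_len(ds$n), idx_train)
  list(train = subset_dataset(ds, idx_train), val = subset_dataset(ds, idx_val))
}

# Seed the RNG for the calling frame and restore the previous state when the
# caller exits, so package functions never disturb the user's random stream.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (!is.null(.bites_old_seed)) assign(".Random.seed", .bites_old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }), add = TRUE), envir = envir)
  assign(".bites_old_seed", old, envir = envir)
  set.seed(seed)
  invisible(NULL)
}
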