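#' Configuration of an end-to-end experiment
#'
#' @param scenario simulation scenario name (`"linear"`, `"nonlinear"`,
#'   `"biased"`), or `NULL` when `data_path` is given.
#' @param data_path CSV with `time,event,treatment` columns, used instead
#'   of simulation.
#' @param n_train,n_test simulated cohort sizes (test set carries ground
#'   truth).
#' @param seed master seed for simulation, splitting and training.
#' @param val_frac fraction of the training cohort used for fitting (the
#'   complement is the validation split).
#' @param base a [net_config()] used as the template for every candidate.
#' @param grid non-empty list of named lists of `net_config` overrides
#'   (e.g. `list(list(alpha = 0.1), list(alpha = 1))`); candidates are
#'   trained in order and the one with the lowest validation loss is
#'   selected.
#' @param out_dir optional output directory for the report, history and
#'   checkpoint files.
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = "linear", data_path = NULL, n_train = 600L,
                       n_test = 1000L, seed = 1L, val_frac = 0.8,
                       base = net_config(), grid = list(list()),
                       out_dir = NULL) {
  if (!length(grid)) stop("search grid must be non-empty")
  if (val_frac <= 0 || val_frac >= 1) stop("val_frac must be in (0, 1)")
  structure(list(scenario = scenario, data_path = data_path,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), val_frac = val_frac, base = base,
                 grid = grid, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a seeded experiment: simulate/load, grid search, evaluate
#'
#' Simulates (or loads) the data, splits off a validation set stratified by
#' treatment and event, trains every candidate of the hyper-parameter grid,
#' selects the model with the lowest validation loss (validation
#' concordance is logged alongside), and evaluates the winner on the
#' held-out test set -- with ground-truth ITE metrics (PEHE, correct
#' treatment fraction) when the data are simulated. Fully reproducible
#' from the seed.
#'
#' @param cfg a [run_config()].
#' @return list of class `experiment_report` with the selected model,
#'   baselines, the per-candidate search log and the test metrics; written
#'   to `cfg$out_dir` as JSON/CSV when that is set.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$data_path)) {
    full <- read_survival_csv(cfg$data_path)
    test <- NULL
  } else {
    full <- simulate_dataset(cfg$scenario, cfg$n_train, seed = cfg$seed)
    test <- simulate_dataset(cfg$scenario, cfg$n_test, seed = cfg$seed + 10000L)
  }
  sp <- stratified_split(full, frac = cfg$val_frac, seed = cfg$seed + 1L)
  search_log <- list()
  best <- NULL
  for (k in seq_along(cfg$grid)) {
    cand_cfg <- modifyList(cfg$base, cfg$grid[[k]])
    class(cand_cfg) <- "net_config"
    cand_cfg$seed <- cfg$seed + 100L + k
    model <- build_model(cand_cfg, ncol(full$x))
    model <- train_model(model, sp$train, sp$val, cand_cfg)
    val_loss <- model_val_loss(model)
    val_c <- tryCatch({
      b <- estimate_baselines(model, sp$train)
      c_index_td(predicted_survival_matrix(model, b, sp$val), sp$val$y, sp$val$e)$c
    }, error = function(err) NA_real_)
    search_log[[k]] <- data.frame(candidate = k,
                                  overrides = paste(names(cfg$grid[[k]]),
                                                    unlist(cfg$grid[[k]]),
                                                    sep = "=", collapse = ";"),
                                  val_loss = val_loss, val_c_index = val_c)
    if (is.null(best) || val_loss < best$val_loss)
      best <- list(model = model, cfg = cand_cfg, val_loss = val_loss,
                   val_c = val_c, candidate = k)
  }
  baselines <- estimate_baselines(best$model, sp$train)
  report <- list(seed = cfg$seed, config_hash = config_hash(cfg[setdiff(names(cfg), "base")]),
                 selected_candidate = best$candidate,
                 val_loss = best$val_loss, val_c_index = best$val_c)
  recs <- NULL
  if (!is.null(test)) {
    if (best$cfg$variant == "deepsurv") {
      recs <- deepsurv_recommendation(best$model, test$x)
    } else {
      recs <- individual_treatment_effect(best$model, baselines, test$x)
    }
    cidx <- c_index_td(predicted_survival_matrix(best$model, baselines, test),
                       test$y, test$e)
    report$c_index <- cidx$c
    report$n_pairs_used <- cidx$n_pairs
    report$pehe <- as.numeric(pehe(test$tau_true, recs$tau))
    report$correct_fraction <- correct_treatment_fraction(test$tau_true, recs$tau)
    report$treat_all_fraction <- positive_ite_fraction(test)
    report$recommended_treated_fraction <- mean(recs$recommended_arm == 1L)
  }
  out <- list(report = report, model = best$model, baselines = baselines,
              search = do.call(rbind, search_log), recommendations = recs)
  class(out) <- "experiment_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$search, file.path(cfg$out_dir, "search_log.csv"),
                     row.names = FALSE)
    if (!is.null(best$model$history) && is.data.frame(best$model$history))
      utils::write.csv(cbind(best$model$history, seed = cfg$seed,
                             config_hash = report$config_hash),
                       file.path(cfg$out_dir, "training_log.csv"),
                       row.names = FALSE)
    saveRDS(best$model, file.path(cfg$out_dir, "model.rds"))
  }
  out
}

model_val_loss <- function(model) {
  if (model$cfg$variant == "t-deepsurv")
    return(min(model$history$m0$val_total) + min(model$history$m1$val_total))
  min(model$history$val_total)
}

#' @export
print.experiment_report <- function(x, ...) {
  r <- x$report
  cat("experiment_report\n")
  cat(sprintf("  selected candidate %d (validation loss %.5g, validation C %.4f)\n",
              r$selected_candidate, r$val_loss, r$val_c_index))
  if (!is.null(r$c_index))
    cat(sprintf("  test: C-index %.4f, PEHE %.4g, correct treatments %.3f (treat-all %.3f)\n",
                r$c_index, r$pehe, r$correct_fraction, r$treat_all_fraction))
  invisible(x)
}

#' Breast-cancer cohorts: Rotterdam (training) and GBSG (test)
#'
#' Prepares the two classical node-positive breast cancer cohorts for the
#' hormone-treatment recommendation workflow: the Rotterdam tumour bank as
#' training data and the German Breast Cancer Study Group trial as an
#' independent randomized test set. By default the tables shipped with the
#' CRAN `survival` package are used; alternatively CSV exports of those
#' tables may be supplied. Recurrence-free survival is the time from
#' surgery to the earlier of recurrence or death; covariates are age,
#' menopausal status, number of positive lymph nodes, tumour grade and the
#' two hormone-receptor measurements (log1p-transformed); treatment is
#' hormonal therapy. Rotterdam is restricted to node-positive patients and
#' rows with missing covariates are dropped and counted.
#'
#' @param rotterdam_path,gbsg_path optional CSV exports of the respective
#'   tables (columns as in `survival::rotterdam` / `survival::gbsg`).
#' @return list with `train` and `test` [survival_dataset()]s (times in
#'   years); dropped-row counts attached as attributes `"n_dropped"`.
#' @export
prepare_gbsg_rotterdam <- function(rotterdam_path = NULL, gbsg_path = NULL) {
  rot <- load_table(rotterdam_path, "rotterdam")
  gb <- load_table(gbsg_path, "gbsg")
  if (is.null(rot) || is.null(gb))
    stop("Breast-cancer tables unavailable: install the 'survival' package or ",
         "supply CSV exports of its 'rotterdam' and 'gbsg' datasets via ",
         "rotterdam_path/gbsg_path.")
  rot <- rot[rot$nodes > 0, , drop = FALSE]
  rfs_time <- pmin(rot$rtime, rot$dtime) / 365.25
  rfs_event <- as.integer(pmax(rot$recur, rot$death) == 1)
  covar <- function(df) cbind(age = df$age, meno = df$meno, nodes = df$nodes,
                              grade = as.numeric(df$grade),
                              pgr = log1p(df$pgr), er = log1p(df$er))
  keep <- stats::complete.cases(covar(rot)) & is.finite(rfs_time) & rfs_time > 0
  train <- survival_dataset(covar(rot)[keep, , drop = FALSE], rfs_time[keep],
                            rfs_event[keep], rot$hormon[keep])
  attr(train, "n_dropped") <- sum(!keep)
  keep_g <- stats::complete.cases(covar(gb)) & gb$rfstime > 0
  test <- survival_dataset(covar(gb)[keep_g, , drop = FALSE],
                           gb$rfstime[keep_g] / 365.25, gb$status[keep_g],
                           gb$hormon[keep_g])
  attr(test, "n_dropped") <- sum(!keep_g)
  list(train = train, test = test)
}

load_table <- function(path, name) {
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    return(utils::read.csv(path))
  }
  if (!requireNamespace("survival", quietly = TRUE)) return(NULL)
  # the survival package ships these tables as lazy data in its namespace
  tryCatch(getExportedValue("survival", name), error = function(err) NULL)
}
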