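#' Weight-table and weight-curve report
#'
#' Computes the per-class weight table and the effective weighting curves
#' `W(p)` of the double-balanced loss on a probability grid — the material
#' behind hyperparameter diagnostics.
#'
#' @param counts a [class_counts()] object.
#' @param params a [balance_params()].
#' @param p_grid probabilities in `(0, 1)` (default 99 points).
#' @param variant double-balanced variant.
#' @return List with `table` (data frame: label, n, E, alpha, prior) and
#'   `curves` (long data frame: label, p, w).
#' @export
weight_report <- function(counts, params = balance_params(),
                          p_grid = seq(0.01, 0.99, by = 0.01),
                          variant = c("printed", "derived")) {
  variant <- match.arg(variant)
  counts <- as_class_counts(counts)
  tab <- weight_table(counts, params)
  k <- length(counts$counts)
  curves <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(label = counts$labels[i], p = p_grid,
               w = weight_curve(tab, i, p_grid, variant),
               stringsAsFactors = FALSE)
  }))
  list(table = as.data.frame(tab), curves = curves)
}

# One train+evaluate run; returns a one-row data frame of summary metrics.
run_one <- function(kind, train_ds, test_ds, params, control, gamma = 2,
                    variant = "printed") {
  cfg <- loss_config(kind, gamma = gamma, variant = variant)
  fit <- db_fit(train_ds, loss = cfg, params = params, control = control)
  ev <- evaluate(fit, test_ds)
  rep <- ev$report
  minority <- which.min(train_ds$spec$counts$counts)
  data.frame(loss = kind, seed = control$seed,
             accuracy = rep$accuracy,
             minority_recall = rep$per_class$recall[minority],
             macro_recall = rep$macro_recall,
             macro_fnr = rep$macro_fnr,
             macro_fpr = rep$macro_fpr,
             stringsAsFactors = FALSE)
}

# Generate the full-profile dataset for one seed and split it 8:2.
default_split <- function(seed, counts = lesion_counts("full"), dim = 2L,
                          spread = 1) {
  ds <- generate_dataset(dataset_spec(counts, dim = dim, spread = spread,
                                      seed = seed))
  split_train_test(ds, frac = 0.8, seed = seed)
}

#' Compare loss functions on synthetic imbalanced data
#'
#' For each loss kind and seed: generate the full lesion-profile dataset,
#' split it 8:2 (stratified), train a linear-softmax classifier, and
#' evaluate on the held-out 20%.  Reports per-run and aggregated
#' (mean/sd) accuracy, minority-class recall, macro recall, and macro
#' FNR/FPR.
#'
#' @param kinds loss kinds to compare.
#' @param seeds integer seeds; one dataset + training run per seed.
#' @param counts full-collection [class_counts()] before the split.
#' @param spread class overlap of the generator.
#' @param dim feature dimension.
#' @param params [balance_params()] for the weighted losses.
#' @param control [train_control()]; its seed field is overridden per run.
#' @param gamma focal exponent.
#' @return List with `runs` (one row per kind x seed) and `summary`
#'   (mean/sd per kind).  Per-run failures are recorded in `failures` and
#'   do not abort the sweep.
#' @export
compare_losses <- function(kinds = c("ce", "wce", "focal", "cb", "db"),
                           seeds = 1:10, counts = lesion_counts("full"),
                           spread = 1, dim = 2L,
                           params = balance_params(),
                           control = train_control(), gamma = 2) {
  runs <- list(); failures <- list()
  for (seed in seeds) {
    sp <- default_split(seed, counts, dim, spread)
    for (kind in kinds) {
      ctl <- control; ctl$seed <- seed
      res <- tryCatch(run_one(kind, sp$train, sp$test, params, ctl, gamma),
                      error = function(e) e)
      if (inherits(res, "error"))
        failures[[length(failures) + 1L]] <-
          data.frame(loss = kind, seed = seed, message = conditionMessage(res))
      else runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$loss), function(d) {
    data.frame(loss = d$loss[1], n_runs = nrow(d),
               accuracy = mean(d$accuracy),
               minority_recall = mean(d$minority_recall),
               minority_recall_sd = stats::sd(d$minority_recall),
               macro_recall = mean(d$macro_recall),
               macro_fnr = mean(d$macro_fnr),
               macro_fpr = mean(d$macro_fpr),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}

#' Hyperparameter grid sweep for the double-balanced loss
#'
#' Trains and evaluates the DB loss at every (beta, rho) pair and
#' aggregates over seeds.  The returned table marks the row with the best
#' macro recall.
#'
#' @param beta_grid effective-size hyperparameters (default
#'   `c(0.9, 0.99, 0.999, 0.9999)`).
#' @param rho_grid prior-flexibility hyperparameters (default
#'   `c(0.25, 0.5, 0.75)`).
#' @inheritParams compare_losses
#' @return Data frame with one row per (beta, rho): mean accuracy,
#'   minority recall, macro recall, macro FNR/FPR, and a logical `best`
#'   column.
#' @export
sweep_beta_rho <- function(beta_grid = c(0.9, 0.99, 0.999, 0.9999),
                           rho_grid = c(0.25, 0.5, 0.75),
                           seeds = 1:3, counts = lesion_counts("full"),
                           spread = 1, dim = 2L,
                           control = train_control()) {
  if (!length(beta_grid) || !length(rho_grid)) stop("grids must be non-empty")
  splits <- lapply(seeds, default_split, counts = counts, dim = dim,
                   spread = spread)
  rows <- list()
  for (beta in beta_grid) for (rho in rho_grid) {
    runs <- do.call(rbind, lapply(seq_along(seeds), function(j) {
      ctl <- control; ctl$seed <- seeds[j]
      run_one("db", splits[[j]]$train, splits[[j]]$test,
              balance_params(beta, rho), ctl)
    }))
    rows[[length(rows) + 1L]] <- data.frame(
      beta = beta, rho = rho, n_runs = nrow(runs),
      accuracy = mean(runs$accuracy),
      minority_recall = mean(runs$minority_recall),
      macro_recall = mean(runs$macro_recall),
      macro_fnr = mean(runs$macro_fnr),
      macro_fpr = mean(runs$macro_fpr))
  }
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$macro_recall)
  out
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds and package version of an experiment
#' run so deterministic outputs can be reproduced bit for bit.
#'
#' @param path output JSON path.
#' @param config named list describing the run.
#' @param seeds integer seeds used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds) {
  jsonlite::write_json(
    list(package = "dbloss",
         version = as.character(utils::packageVersion("dbloss")),
         config = config, seeds = seeds),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
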